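# miRNA expression-array screen: quantile normalization plus the
# replicate-consistency and fold-change selection criteria.

#' Construct an expression matrix with its array design
#'
#' @param values Numeric matrix of nonnegative intensities, miRNAs in rows
#'   (rownames = miRNA ids), arrays in columns (colnames = array ids).
#' @param design data.frame with columns `array_id`, `group` ("sham" or
#'   "tumour"), `replicate`, `timepoint`; one row per array.
#' @return An object of class `expression_matrix` (list with `values`,
#'   `design`).
#' @export
expression_matrix <- function(values, design) {
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique rownames (miRNA ids)", call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("values must have unique colnames (array ids)", call. = FALSE)
  }
  req <- c("array_id", "group", "replicate", "timepoint")
  if (!all(req %in% names(design))) {
    stop("design must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(design$array_id, colnames(values))) {
    stop("every array must have exactly one design entry", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("intensities must be finite and nonnegative", call. = FALSE)
  }
  design <- design[match(colnames(values), design$array_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d miRNAs x %d arrays\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$design$group, x$design$timepoint)
  print(tab)
  invisible(x)
}

#' Quantile normalization
#'
#' Forces all arrays (columns) to share one empirical intensity distribution
#' while preserving within-array rank order: each column's sorted values are
#' replaced by the across-array mean of sorted values. Ties within a column
#' receive the mean of the reference values their positions span, so the
#' matrix total is preserved and the transform is idempotent.
#'
#' @param x An `expression_matrix` or a plain numeric matrix.
#' @return Same type as `x`, normalized.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "expression_matrix")) {
    x$values <- quantile_normalize(x$values)
    return(x)
  }
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)
    stop("non-finite values at (row, col): ",
         paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " "),
         call. = FALSE)
  }
  if (ncol(x) == 1L) return(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    o <- order(col)
    sorted <- col[o]
    # group positions of tied values in sorted order
    grp <- cumsum(c(TRUE, diff(sorted) != 0))
    grp_mean <- tapply(ref, grp, mean)
    out[o, j] <- grp_mean[grp]
  }
  out
}

#' Screen configuration
#'
#' Parameters of the dysregulation screen: a miRNA is selected when the
#' distance between group means is at least `k` times the sum of the two group
#' SDs (replicate consistency) and its fold change is at least `fc_primary`
#' (up) or at most `1/fc_primary` (down). `fc_secondary` defines a looser
#' fold-change-only tier reported for context.
#'
#' @param k SD multiplier of the consistency criterion (default 5).
#' @param fc_primary Primary fold-change threshold (default 2.5).
#' @param fc_secondary Secondary fold-change threshold (default 2.0).
#' @param sd_mode "sample" (n - 1 denominator, default) or "population".
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(k = 5, fc_primary = 2.5, fc_secondary = 2.0,
                          sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  check_config_field(k > 0, "k", "must be > 0")
  check_config_field(fc_secondary > 1, "fc_secondary", "must be > 1")
  check_config_field(fc_primary >= fc_secondary, "fc_primary",
                     "must be >= fc_secondary")
  structure(list(k = k, fc_primary = fc_primary, fc_secondary = fc_secondary,
                 sd_mode = sd_mode), class = "screen_config")
}

#' Per-miRNA group means and SDs at one timepoint
#'
#' @param x An `expression_matrix`.
#' @param timepoint Timepoint label to screen (default: the single timepoint
#'   present).
#' @param sd_mode "sample" (n - 1) or "population" SD.
#' @return data.frame with columns `mirna_id`, `mean_sham`, `sd_sham`,
#'   `mean_tumour`, `sd_tumour`, `n_sham`, `n_tumour`.
#' @export
group_stats <- function(x, timepoint = NULL,
                        sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(inherits(x, "expression_matrix"))
  if (is.null(timepoint)) {
    tps <- unique(x$design$timepoint)
    if (length(tps) != 1L) {
      stop("multiple timepoints present; specify `timepoint`", call. = FALSE)
    }
    timepoint <- tps
  }
  d <- x$design[x$design$timepoint == timepoint, , drop = FALSE]
  for (g in c("sham", "tumour")) {
    if (sum(d$group == g) < 2) {
      stop(sprintf("group '%s' needs >= 2 arrays at timepoint '%s'",
                   g, timepoint), call. = FALSE)
    }
  }
  sd_fun <- if (sd_mode == "sample") stats::sd else
    function(v) sqrt(mean((v - mean(v))^2))
  sham <- x$values[, d$array_id[d$group == "sham"], drop = FALSE]
  tum <- x$values[, d$array_id[d$group == "tumour"], drop = FALSE]
  data.frame(
    mirna_id = rownames(x$values),
    mean_sham = rowMeans(sham), sd_sham = apply(sham, 1, sd_fun),
    mean_tumour = rowMeans(tum), sd_tumour = apply(tum, 1, sd_fun),
    n_sham = ncol(sham), n_tumour = ncol(tum),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the dysregulation screen to per-miRNA group statistics
#'
#' A miRNA passes the replicate-consistency criterion when
#' `|mean_tumour - mean_sham| >= k * (sd_tumour + sd_sham)` and the primary
#' fold-change criterion when `FC >= fc_primary` or `FC <= 1/fc_primary`,
#' with `FC = mean_tumour / mean_sham`; both comparisons are inclusive.
#' Selection requires both. miRNAs with a nonpositive group mean are flagged
#' unevaluable and excluded from selection rather than dropped.
#'
#' @param stats Output of [group_stats()].
#' @param config A [screen_config()].
#' @return A `screen_result` data.frame: per miRNA the group statistics,
#'   `fold_change`, `direction` ("up", "down", "none"), `evaluable`,
#'   `passes_consistency`, `passes_fc_primary`, `passes_fc_secondary`,
#'   `selected`.
#' @export
screen <- function(stats, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  req <- c("mirna_id", "mean_sham", "sd_sham", "mean_tumour", "sd_tumour")
  if (!all(req %in% names(stats))) {
    stop("stats must contain: ", paste(req, collapse = ", "), call. = FALSE)
  }
  evaluable <- stats$mean_sham > 0 & stats$mean_tumour > 0
  fc <- ifelse(evaluable, stats$mean_tumour / stats$mean_sham, NA_real_)
  consistency <- abs(stats$mean_tumour - stats$mean_sham) >=
    config$k * (stats$sd_tumour + stats$sd_sham)
  fc_primary <- evaluable &
    (fc >= config$fc_primary | fc <= 1 / config$fc_primary)
  fc_secondary <- evaluable &
    (fc >= config$fc_secondary | fc <= 1 / config$fc_secondary)
  selected <- evaluable & consistency & fc_primary
  direction <- rep("none", nrow(stats))
  direction[selected & stats$mean_tumour > stats$mean_sham] <- "up"
  direction[selected & stats$mean_tumour < stats$mean_sham] <- "down"
  out <- cbind(stats,
               data.frame(fold_change = fc, direction = direction,
                          evaluable = evaluable,
                          passes_consistency = evaluable & consistency,
                          passes_fc_primary = fc_primary,
                          passes_fc_secondary = fc_secondary,
                          selected = selected, stringsAsFactors = FALSE))
  class(out) <- c("screen_result", class(out))
  out
}

#' Worst-case t-test p-value implied by the consistency criterion
#'
#' For a two-group comparison with `n` replicates per group, consider all SD
#' configurations `(s_S, s_T) >= 0` (not both zero) in which the criterion
#' holds with equality, `|m_T - m_S| = k (s_T + s_S)`. The pooled
#' equal-variance two-sample t statistic is then
#' `t = k (s_S + s_T) / sqrt((s_S^2 + s_T^2) / n)`, minimized (p maximized)
#' as one SD tends to zero, giving `t_min = k * sqrt(n)` on `2n - 2` degrees
#' of freedom. The returned p-value is thus an upper bound on the two-tailed p
#' of any miRNA passing the criterion. With equal SDs the statistic is
#' `k * sqrt(2 n)`, strictly larger.
#'
#' @param k SD multiplier (> 0).
#' @param n Replicates per group (>= 2).
#' @return A list with `t_min`, `df`, and `p_value` (two-tailed upper bound).
#' @export
implied_t_bound <- function(k = 5, n = 3) {
  stopifnot(k > 0)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  t_min <- k * sqrt(n)
  df <- 2 * n - 2
  list(t_min = t_min, df = df, p_value = 2 * stats::pt(-t_min, df))
}

#' Summarize a screen result
#'
#' Reports selection counts by direction, the looser fold-change-only tier,
#' unevaluable miRNAs, and (when the normalized expression matrix is
#' supplied) a heatmap-ready matrix of the selected miRNAs with rows ordered
#' by direction then fold change.
#'
#' @param result A `screen_result` from [screen()].
#' @param config The [screen_config()] used (for threshold labels).
#' @param matrix Optional `expression_matrix` of normalized intensities.
#' @return A list of class `screen_report` with `counts` (named vector) and
#'   `heatmap` (matrix or NULL).
#' @export
screen_report <- function(result, config = screen_config(), matrix = NULL) {
  stopifnot(inherits(result, "screen_result"))
  counts <- c(
    n_mirnas = nrow(result),
    n_selected = sum(result$selected),
    n_selected_up = sum(result$direction == "up"),
    n_selected_down = sum(result$direction == "down"),
    n_fc_secondary = sum(result$passes_fc_secondary),
    n_fc_primary = sum(result$passes_fc_primary),
    n_unevaluable = sum(!result$evaluable))
  heatmap <- NULL
  if (!is.null(matrix) && any(result$selected)) {
    sel <- result[result$selected, , drop = FALSE]
    ord <- order(sel$direction,
                 ifelse(sel$direction == "up", -sel$fold_change,
                        sel$fold_change))
    heatmap <- matrix$values[sel$mirna_id[ord], , drop = FALSE]
  }
  structure(list(counts = counts, heatmap = heatmap,
                 fc_primary = config$fc_primary,
                 fc_secondary = config$fc_secondary, k = config$k),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("dysregulation screen (k = %g, FC >= %g, secondary FC >= %g)\n",
              x$k, x$fc_primary, x$fc_secondary))
  cat(sprintf("  %d miRNAs screened; %d selected (%d up, %d down)\n",
              x$counts[["n_mirnas"]], x$counts[["n_selected"]],
              x$counts[["n_selected_up"]], x$counts[["n_selected_down"]]))
  cat(sprintf("  %d pass the %g-fold-change-only tier; %d unevaluable\n",
              x$counts[["n_fc_secondary"]], x$fc_secondary,
              x$counts[["n_unevaluable"]]))
  invisible(x)
}
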