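# Consensus aggregation of miRNA-target predictions, housekeeping-normalized
# expression response filtering, and reciprocal-regulation scoring.

#' Tally algorithm support per predicted miRNA-target pair
#'
#' Counts the number of distinct prediction algorithms supporting each
#' (miRNA, gene) pair and flags consensus pairs supported by at least
#' `min_algorithms` algorithms (default 2, of the canonical 14). Duplicate
#' (algorithm, miRNA, gene) records are collapsed with a warning, so repeated
#' predictions by one algorithm count once.
#'
#' @param predictions A `prediction_table` data.frame (columns `algorithm`,
#'   `mirna`, `gene`) or a list of such tables (concatenated).
#' @param mirna Optional miRNA id to restrict the tally to.
#' @param min_algorithms Consensus threshold (default 2).
#' @return A `consensus_table` data.frame: `mirna`, `gene`, `n_algorithms`,
#'   `consensus`.
#' @export
tally <- function(predictions, mirna = NULL, min_algorithms = 2) {
  if (is.data.frame(predictions)) predictions <- list(predictions)
  tab <- do.call(rbind, lapply(predictions, function(p) {
    req <- c("algorithm", "mirna", "gene")
    if (!all(req %in% names(p))) {
      stop("prediction table must contain: ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    p[req]
  }))
  if (is.null(tab) || !nrow(tab)) {
    warning("empty prediction input; returning empty consensus table")
    return(structure(data.frame(mirna = character(), gene = character(),
                                n_algorithms = integer(),
                                consensus = logical(),
                                stringsAsFactors = FALSE),
                     class = c("consensus_table", "data.frame")))
  }
  if (!is.null(mirna)) tab <- tab[tab$mirna %in% mirna, , drop = FALSE]
  dup <- duplicated(tab)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate (algorithm, miRNA, gene) records",
                    sum(dup)))
    tab <- tab[!dup, , drop = FALSE]
  }
  key <- paste(tab$mirna, tab$gene, sep = "\r")
  counts <- tapply(tab$algorithm, key, function(a) length(unique(a)))
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- data.frame(mirna = vapply(parts, `[`, "", 1),
                    gene = vapply(parts, `[`, "", 2),
                    n_algorithms = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$consensus <- out$n_algorithms >= min_algorithms
  out <- out[order(out$mirna, -out$n_algorithms, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_table", class(out))
  out
}

#' Housekeeping-gene normalization of a digital count matrix
#'
#' Divides each sample's counts by the geometric mean of that sample's
#' housekeeping-gene counts, the standard multi-reference normalization for
#' digital expression counts. The result is invariant to per-sample scaling.
#'
#' @param counts Numeric matrix, genes x samples, nonnegative, with rownames
#'   and colnames.
#' @param housekeeping Character vector of housekeeping gene ids (all must be
#'   rows of `counts`) or a named logical vector per gene.
#' @return Numeric matrix of normalized expression, same dimensions as
#'   `counts`, with attribute `"hk_factor"` (the per-sample divisor).
#' @export
normalize_counts <- function(counts, housekeeping) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (is.logical(housekeeping)) {
    housekeeping <- names(housekeeping)[housekeeping]
  }
  if (!length(housekeeping)) {
    stop("at least one housekeeping gene is required", call. = FALSE)
  }
  miss <- setdiff(housekeeping, rownames(counts))
  if (length(miss)) {
    stop("housekeeping gene(s) absent from counts: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  hk <- counts[housekeeping, , drop = FALSE]
  zero <- which(hk <= 0, arr.ind = TRUE)
  if (nrow(zero)) {
    stop(sprintf(
      "nonpositive housekeeping count for gene '%s' in sample '%s'",
      rownames(hk)[zero[1, 1]], colnames(hk)[zero[1, 2]]), call. = FALSE)
  }
  hk_factor <- exp(colMeans(log(hk)))
  out <- sweep(counts, 2, hk_factor, "/")
  attr(out, "hk_factor") <- hk_factor
  out
}

#' Expression-response filter for predicted targets
#'
#' For each gene, computes the ratio of mean normalized expression under the
#' miRNA inhibitor to that under the mismatch control and flags responders
#' whose ratio is at least `min_ratio` (inclusive; the default 1.5 encodes
#' "at least 50% up-regulation" upon miRNA inhibition). The boundary is
#' applied with a relative numeric tolerance of 1e-9 so that ratios equal to
#' the threshold up to floating-point rounding from the normalization
#' arithmetic still count. Genes with a zero control mean are reported as
#' unevaluable, not dropped.
#'
#' @param norm Normalized expression matrix (genes x samples), e.g. from
#'   [normalize_counts()].
#' @param design data.frame with columns `sample_id`, `condition`
#'   ("inhibitor" / "control"); `sample_id` must match colnames of `norm`.
#' @param min_ratio Response threshold (default 1.5).
#' @return A `target_response` data.frame: `gene`, `mean_inhibitor`,
#'   `mean_control`, `response_ratio`, `evaluable`, `responder`.
#' @export
response_filter <- function(norm, design, min_ratio = 1.5) {
  req <- c("sample_id", "condition")
  if (!all(req %in% names(design))) {
    stop("design must contain: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!all(c("inhibitor", "control") %in% design$condition)) {
    stop("design must include both 'inhibitor' and 'control' samples",
         call. = FALSE)
  }
  if (!all(design$sample_id %in% colnames(norm))) {
    stop("every design sample_id must be a column of norm", call. = FALSE)
  }
  inh <- norm[, design$sample_id[design$condition == "inhibitor"],
              drop = FALSE]
  ctl <- norm[, design$sample_id[design$condition == "control"],
              drop = FALSE]
  mean_inh <- rowMeans(inh)
  mean_ctl <- rowMeans(ctl)
  evaluable <- mean_ctl > 0
  ratio <- ifelse(evaluable, mean_inh / mean_ctl, NA_real_)
  out <- data.frame(gene = rownames(norm),
                    mean_inhibitor = mean_inh, mean_control = mean_ctl,
                    response_ratio = ratio, evaluable = evaluable,
                    responder = evaluable &
                      ratio >= min_ratio * (1 - 1e-9),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("target_response", class(out))
  out
}

#' Score reciprocal miRNA-mRNA regulation over a time course
#'
#' A timepoint is concordant when the miRNA and its putative target change in
#' opposite directions (the sign of the miRNA's log2 fold change equals minus
#' the sign of the target's) and both actually change (|log2 FC| > 0). The
#' score is the concordant fraction of shared timepoints; the flag is set
#' when at least `min_concordant` timepoints are concordant.
#'
#' @param mirna_fc,target_fc data.frames with columns `timepoint` and
#'   `fold_change` (as returned by [timecourse_fc()]).
#' @param min_concordant Required concordant timepoints; defaults to
#'   `ceiling(n_shared / 2) + 1` (a strict majority with margin).
#' @return A list with `score`, `n_concordant`, `n_shared`, `min_concordant`,
#'   `flag`, and `per_timepoint` (data.frame of the shared timepoints).
#' @export
reciprocal_check <- function(mirna_fc, target_fc, min_concordant = NULL) {
  shared <- intersect(mirna_fc$timepoint, target_fc$timepoint)
  if (!length(shared)) stop("no shared timepoints", call. = FALSE)
  m <- log2(mirna_fc$fold_change[match(shared, mirna_fc$timepoint)])
  t <- log2(target_fc$fold_change[match(shared, target_fc$timepoint)])
  concordant <- sign(m) == -sign(t) & abs(m) > 0 & abs(t) > 0
  if (is.null(min_concordant)) {
    min_concordant <- ceiling(length(shared) / 2) + 1
  }
  list(score = mean(concordant),
       n_concordant = sum(concordant),
       n_shared = length(shared),
       min_concordant = min_concordant,
       flag = sum(concordant) >= min_concordant,
       per_timepoint = data.frame(timepoint = shared, log2_fc_mirna = m,
                                  log2_fc_target = t, concordant = concordant,
                                  stringsAsFactors = FALSE))
}
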