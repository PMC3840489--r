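# Tabular I/O with metadata comment headers.
#
# All pipeline artifacts are plain CSV/TSV with '#'-prefixed metadata lines
# (package version, producing stage, parameters, seed) so every output is
# self-describing and reruns are auditable.

meta_header <- function(stage, seed = NULL, params = list()) {
  lines <- c(sprintf("# painmiR %s",
                     as.character(utils::packageVersion("painmiR"))),
             sprintf("# stage: %s", stage))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", seed))
  if (length(params)) {
    kv <- vapply(names(params),
                 function(k) sprintf("%s=%s", k,
                                     paste(format(params[[k]]),
                                           collapse = ",")),
                 "")
    lines <- c(lines, paste("# params:", paste(kv, collapse = "; ")))
  }
  lines
}

#' Write a pipeline table with a metadata header
#'
#' @param x data.frame or matrix (matrices are written with an `id` first
#'   column holding rownames).
#' @param path Output file; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @param stage Producing stage name recorded in the header.
#' @param seed,params Optional seed and parameter list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(x, path, stage = "painmiR", seed = NULL,
                          params = list()) {
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), as.data.frame(x),
                    check.names = FALSE, stringsAsFactors = FALSE)
  }
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(stage, seed, params), con)
  utils::write.table(x, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline table written by [write_tabular()]
#'
#' @param path File path; '#' comment lines are skipped.
#' @param rownames_col Optional column name to promote to rownames (returning
#'   a matrix of the remaining numeric columns).
#' @return data.frame, or numeric matrix when `rownames_col` is given.
#' @export
read_tabular <- function(path, rownames_col = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(rownames_col)) {
    rn <- df[[rownames_col]]
    df[[rownames_col]] <- NULL
    m <- as.matrix(df)
    rownames(m) <- rn
    return(m)
  }
  df
}

#' Read an expression matrix and its design table
#'
#' @param values_path CSV of intensities (first column `id` = miRNA ids).
#' @param design_path CSV with columns `array_id`, `group`, `replicate`,
#'   `timepoint`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(values_path, design_path) {
  vals <- read_tabular(values_path, rownames_col = "id")
  design <- read_tabular(design_path)
  expression_matrix(vals, design)
}

#' Validate pipeline input files against their column contracts
#'
#' Runs lightweight structural checks on each supplied file: required
#' columns, duplicate ids, nonnegative intensities, withdrawal counts within
#' trial counts, Ct ranges. Each file type is optional; only supplied paths
#' are checked.
#'
#' @param expression,design,ct,predictions,counts,behavior Optional file
#'   paths (expression requires design).
#' @return data.frame with columns `file`, `check`, `pass`, `detail`; one row
#'   per executed check.
#' @export
validate_inputs <- function(expression = NULL, design = NULL, ct = NULL,
                            predictions = NULL, counts = NULL,
                            behavior = NULL) {
  out <- list()
  add <- function(file, check, pass, detail = "") {
    out[[length(out) + 1L]] <<- data.frame(
      file = file, check = check, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (!is.null(expression)) {
    vals <- try(read_tabular(expression, rownames_col = "id"), silent = TRUE)
    if (inherits(vals, "try-error")) {
      add(expression, "readable", FALSE, "parse failure")
    } else {
      dup <- rownames(vals)[duplicated(rownames(vals))]
      add(expression, "unique miRNA ids", !length(dup),
          if (length(dup)) paste("duplicated:", dup[1]) else "")
      add(expression, "nonnegative intensities", all(vals >= 0),
          if (!all(vals >= 0)) sprintf("%d negative cells", sum(vals < 0))
          else "")
      if (!is.null(design)) {
        des <- read_tabular(design)
        ok <- setequal(des$array_id, colnames(vals))
        add(design, "design covers all arrays", ok,
            if (!ok) "array/design mismatch" else "")
      }
    }
  }
  if (!is.null(ct)) {
    tab <- read_tabular(ct)
    req <- c("sample_id", "group", "assay_id", "role", "tech_rep", "ct")
    ok <- all(req %in% names(tab))
    add(ct, "required columns", ok,
        if (!ok) paste("missing:",
                       paste(setdiff(req, names(tab)), collapse = ",")) else "")
    if (ok) {
      bad <- which(!is.finite(tab$ct) | tab$ct <= 0 | tab$ct > 45)
      add(ct, "Ct values in (0, 45]", !length(bad),
          if (length(bad)) sprintf("row %d", bad[1]) else "")
    }
  }
  if (!is.null(predictions)) {
    tab <- read_tabular(predictions)
    req <- c("algorithm", "mirna", "gene")
    ok <- all(req %in% names(tab))
    add(predictions, "required columns", ok,
        if (!ok) paste("missing:",
                       paste(setdiff(req, names(tab)), collapse = ",")) else "")
  }
  if (!is.null(counts)) {
    tab <- read_tabular(counts)
    ok <- all(c("id", "housekeeping") %in% names(tab)) ||
      "housekeeping" %in% names(tab)
    add(counts, "housekeeping flag column", "housekeeping" %in% names(tab),
        if (!ok) "missing 'housekeeping' column" else "")
    num <- tab[, setdiff(names(tab), c("id", "housekeeping")), drop = FALSE]
    add(counts, "nonnegative counts", all(num >= 0),
        if (!all(num >= 0)) "negative counts" else "")
  }
  if (!is.null(behavior)) {
    tab <- read_tabular(behavior)
    req <- c("mouse_id", "group", "day", "force_g", "n_trials",
             "n_withdrawals")
    ok <- all(req %in% names(tab))
    add(behavior, "required columns", ok,
        if (!ok) paste("missing:",
                       paste(setdiff(req, names(tab)), collapse = ",")) else "")
    if (ok) {
      bad <- which(tab$n_withdrawals > tab$n_trials | tab$n_withdrawals < 0)
      add(behavior, "withdrawals within trials", !length(bad),
          if (length(bad)) sprintf("row %d", bad[1]) else "")
      add(behavior, "positive forces", all(tab$force_g > 0),
          if (!all(tab$force_g > 0)) "nonpositive force" else "")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
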