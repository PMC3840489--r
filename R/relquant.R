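# Delta-delta-Ct relative quantification from long-format Ct tables.
#
# Fold change = 2^(-ddCt), ddCt = mean dCt(treatment) - mean dCt(control),
# dCt = Ct(target) - Ct(reference), computed per biological sample after
# averaging technical replicates. Amplification efficiency is taken as 2.0
# (perfect doubling), as the reference method assumes.

#' Aggregate technical qPCR replicates
#'
#' Averages Ct over technical replicates per (sample, assay) and flags pairs
#' whose replicate SD exceeds `max_rep_sd` cycles. Flagged values are kept
#' (QC flag only, no exclusion). Rows with missing Ct (undetermined wells)
#' are dropped from the mean and counted in `n_missing`.
#'
#' @param table A `ct_table` data.frame with columns `sample_id`, `group`,
#'   `assay_id`, `role`, `tech_rep`, `ct`.
#' @param max_rep_sd Replicate-SD QC threshold in cycles (default 0.5).
#' @return data.frame with one row per (sample, assay): `sample_id`, `group`,
#'   `assay_id`, `role`, `ct_mean`, `ct_sd`, `n_rep`, `n_missing`, `qc_flag`.
#' @export
aggregate_technical <- function(table, max_rep_sd = 0.5) {
  req <- c("sample_id", "group", "assay_id", "role", "ct")
  if (!all(req %in% names(table))) {
    stop("ct table must contain: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(table$sample_id, table$assay_id, drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    sub <- table[idx, , drop = FALSE]
    ct <- sub$ct[is.finite(sub$ct)]
    data.frame(sample_id = sub$sample_id[1], group = sub$group[1],
               assay_id = sub$assay_id[1], role = sub$role[1],
               ct_mean = if (length(ct)) mean(ct) else NA_real_,
               ct_sd = if (length(ct) > 1) stats::sd(ct) else 0,
               n_rep = length(ct), n_missing = nrow(sub) - length(ct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$qc_flag <- out$ct_sd > max_rep_sd | out$n_rep == 0
  rownames(out) <- NULL
  out[order(out$sample_id, out$assay_id), , drop = FALSE]
}

#' Delta-delta-Ct relative quantification
#'
#' Computes, per biological sample, `dCt = Ct(target) - Ct(reference)` from
#' technical-replicate means, then
#' `ddCt = mean dCt(treatment) - mean dCt(control)` and the fold change
#' `2^(-ddCt)` of the target in the treatment group relative to control.
#'
#' @param table A `ct_table`.
#' @param target Target assay id (e.g. a miRNA assay).
#' @param reference Reference assay id (e.g. "sno202" for miRNAs, "Gapdh" for
#'   mRNAs).
#' @param treatment,control Group labels to compare.
#' @param max_rep_sd QC threshold passed to [aggregate_technical()].
#' @return A one-row `relquant_result` data.frame: `target`, `reference`,
#'   `treatment`, `control`, `n_treatment`, `n_control`, `dct_treatment`,
#'   `dct_control` (group mean dCt), `ddct`, `fold_change`, `n_qc_flagged`.
#' @export
ddct <- function(table, target, reference, treatment, control,
                 max_rep_sd = 0.5) {
  agg <- aggregate_technical(table, max_rep_sd = max_rep_sd)
  dct_group <- function(grp) {
    tgt <- agg[agg$group == grp & agg$assay_id == target & agg$n_rep > 0, ]
    ref <- agg[agg$group == grp & agg$assay_id == reference & agg$n_rep > 0, ]
    if (!nrow(ref)) {
      stop(sprintf("group '%s' lacks reference assay '%s'", grp, reference),
           call. = FALSE)
    }
    if (!nrow(tgt)) {
      stop(sprintf("group '%s' lacks target assay '%s'", grp, target),
           call. = FALSE)
    }
    m <- match(tgt$sample_id, ref$sample_id)
    if (anyNA(m)) {
      stop(sprintf("missing reference Ct for (sample '%s', assay '%s')",
                   tgt$sample_id[which(is.na(m))[1]], reference),
           call. = FALSE)
    }
    list(dct = tgt$ct_mean - ref$ct_mean[m],
         flagged = sum(tgt$qc_flag) + sum(ref$qc_flag[m]))
  }
  tr <- dct_group(treatment)
  co <- dct_group(control)
  ddct_val <- mean(tr$dct) - mean(co$dct)
  out <- data.frame(target = target, reference = reference,
                    treatment = treatment, control = control,
                    n_treatment = length(tr$dct), n_control = length(co$dct),
                    dct_treatment = mean(tr$dct), dct_control = mean(co$dct),
                    ddct = ddct_val, fold_change = 2^(-ddct_val),
                    n_qc_flagged = tr$flagged + co$flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("relquant_result", class(out))
  out
}

#' Fold-change time course from per-timepoint Ct tables
#'
#' Runs [ddct()] on each timepoint's Ct table (each timepoint carries its own
#' sham control) and returns the fold-change trajectory, the form consumed by
#' [reciprocal_check()].
#'
#' @param tables Named list of `ct_table`s, one per timepoint (names are the
#'   timepoint labels, e.g. "PID-4").
#' @param target,reference,treatment,control As in [ddct()].
#' @param max_rep_sd QC threshold passed through.
#' @return data.frame with columns `timepoint`, `ddct`, `fold_change`,
#'   `direction` ("up" if fold change > 1, "down" if < 1, else "none").
#' @export
timecourse_fc <- function(tables, target, reference,
                          treatment = "tumour", control = "sham",
                          max_rep_sd = 0.5) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("tables must be a named list (names = timepoint labels)",
         call. = FALSE)
  }
  rows <- lapply(names(tables), function(tp) {
    r <- ddct(tables[[tp]], target, reference, treatment, control,
              max_rep_sd = max_rep_sd)
    data.frame(timepoint = tp, ddct = r$ddct, fold_change = r$fold_change,
               direction = if (r$fold_change > 1) "up"
                           else if (r$fold_change < 1) "down" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
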