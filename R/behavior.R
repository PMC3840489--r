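# Von Frey psychophysics reduction: stimulus-response curves, interpolated
# mechanical thresholds with censoring, and AUC summaries.

#' Withdrawal response frequency
#'
#' @param withdrawals Number of withdrawals (0..trials); vectorized.
#' @param trials Number of stimulations (default 5).
#' @return Response frequency in percent (100 * withdrawals / trials).
#' @export
response_frequency <- function(withdrawals, trials = 5) {
  if (any(trials < 1)) stop("trials must be >= 1", call. = FALSE)
  if (any(withdrawals < 0) || any(withdrawals > trials)) {
    stop("withdrawals must lie in [0, trials]", call. = FALSE)
  }
  100 * withdrawals / trials
}

check_curve <- function(forces, freqs) {
  if (length(forces) < 2) stop("curve needs >= 2 filaments", call. = FALSE)
  if (length(forces) != length(freqs)) {
    stop("forces and freqs must have equal length", call. = FALSE)
  }
  if (any(forces <= 0) || anyDuplicated(forces) || is.unsorted(forces)) {
    stop("forces must be positive, strictly increasing and duplicate-free",
         call. = FALSE)
  }
  if (any(freqs < 0) || any(freqs > 100)) {
    stop("frequencies must lie in [0, 100]", call. = FALSE)
  }
}

#' Interpolated mechanical response threshold
#'
#' Finds the filament force at which the withdrawal-frequency curve first
#' reaches the response quantile `q` (in percent). Interpolation is linear in
#' log10(force) between the first adjacent filament pair `(F_i, F_{i+1})`
#' with `f_i < q <= f_{i+1}` (first-crossing rule for non-monotone curves).
#' If the smallest filament already responds at `>= q` the threshold is
#' left-censored at that filament; if no filament reaches `q` it is
#' right-censored at the largest.
#'
#' @param forces Filament forces in grams, strictly increasing.
#' @param freqs Withdrawal frequencies in percent, same length.
#' @param q Response quantile in percent, in (0, 100); 50 by default, 80 is
#'   the alternative used for steeper readouts.
#' @return A list with `threshold` (grams), `censoring` ("none", "left",
#'   "right"), and `q`.
#' @export
vf_threshold <- function(forces, freqs, q = 50) {
  check_curve(forces, freqs)
  if (q <= 0 || q >= 100) stop("q must lie in (0, 100)", call. = FALSE)
  if (freqs[1] >= q) {
    return(list(threshold = forces[1], censoring = "left", q = q))
  }
  for (i in seq_len(length(forces) - 1)) {
    if (freqs[i] < q && q <= freqs[i + 1]) {
      frac <- (q - freqs[i]) / (freqs[i + 1] - freqs[i])
      lg <- log10(forces[i]) + frac * (log10(forces[i + 1]) - log10(forces[i]))
      return(list(threshold = 10^lg, censoring = "none", q = q))
    }
  }
  list(threshold = forces[length(forces)], censoring = "right", q = q)
}

#' Area under the stimulus-response curve
#'
#' Trapezoidal integral of withdrawal frequency (percent) over the filament
#' range, by default on the log10(force) abscissa (filament sets are
#' log-spaced); a linear-force abscissa is available for sensitivity
#' analysis. With log10 scale the AUC is bounded by
#' `100 * log10(F_max / F_min)`.
#'
#' @param forces Filament forces in grams, strictly increasing.
#' @param freqs Withdrawal frequencies in percent.
#' @param scale "log10" (default) or "linear" abscissa.
#' @return A list with `auc`, `scale`, and `domain` (force range).
#' @export
vf_auc <- function(forces, freqs, scale = c("log10", "linear")) {
  check_curve(forces, freqs)
  scale <- match.arg(scale)
  x <- if (scale == "log10") log10(forces) else forces
  auc <- sum(diff(x) * (utils::head(freqs, -1) + utils::tail(freqs, -1)) / 2)
  list(auc = auc, scale = scale, domain = range(forces))
}

#' Per-animal stimulus-response curves
#'
#' @param data A `behavior_dataset` data.frame (columns `mouse_id`, `group`,
#'   `day`, `force_g`, `n_trials`, `n_withdrawals`).
#' @return data.frame with one row per (mouse, day, filament): `mouse_id`,
#'   `group`, `day`, `force_g`, `frequency` (percent), sorted by force within
#'   each curve.
#' @export
stimulus_response_curves <- function(data) {
  req <- c("mouse_id", "group", "day", "force_g", "n_trials", "n_withdrawals")
  if (!all(req %in% names(data))) {
    stop("behavior data must contain: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(mouse_id = data$mouse_id, group = data$group,
                    day = data$day, force_g = data$force_g,
                    frequency = response_frequency(data$n_withdrawals,
                                                   data$n_trials),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mouse_id, out$day, out$force_g), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group time course of frequencies, thresholds and AUC
#'
#' Reduces trial data per animal first (curve, interpolated threshold, AUC),
#' then averages across animals within each (group, day): mean and SEM of
#' frequency at each filament, of the threshold, and of the AUC. Censored
#' thresholds enter the mean at their censoring bound and the censored
#' fraction is reported. SEM is `NA` for single-animal cells.
#'
#' @param data A `behavior_dataset` data.frame.
#' @param q Response quantile (percent) for the threshold (default 50).
#' @param auc_scale "log10" or "linear" abscissa for the AUC.
#' @return A list of class `behavior_summary` with data.frames:
#'   \describe{
#'     \item{frequencies}{per (group, day, force): mean and SEM of frequency.}
#'     \item{animals}{per (mouse, day): threshold, censoring, AUC.}
#'     \item{summary}{per (group, day): mean/SEM threshold, censored
#'       fraction, mean/SEM AUC, n mice.}
#'   }
#' @export
group_timecourse <- function(data, q = 50, auc_scale = c("log10", "linear")) {
  auc_scale <- match.arg(auc_scale)
  curves <- stimulus_response_curves(data)

  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else
    NA_real_

  freq_key <- interaction(curves$group, curves$day, curves$force_g,
                          drop = TRUE)
  frequencies <- do.call(rbind, lapply(split(curves, freq_key), function(s) {
    data.frame(group = s$group[1], day = s$day[1], force_g = s$force_g[1],
               mean_frequency = mean(s$frequency),
               sem_frequency = sem(s$frequency), n = nrow(s),
               stringsAsFactors = FALSE)
  }))
  frequencies <- frequencies[order(frequencies$group, frequencies$day,
                                   frequencies$force_g), , drop = FALSE]
  rownames(frequencies) <- NULL

  an_key <- interaction(curves$mouse_id, curves$day, drop = TRUE)
  animals <- do.call(rbind, lapply(split(curves, an_key), function(s) {
    th <- vf_threshold(s$force_g, s$frequency, q = q)
    au <- vf_auc(s$force_g, s$frequency, scale = auc_scale)
    data.frame(mouse_id = s$mouse_id[1], group = s$group[1], day = s$day[1],
               threshold_g = th$threshold, censoring = th$censoring,
               auc = au$auc, stringsAsFactors = FALSE)
  }))
  animals <- animals[order(animals$group, animals$mouse_id, animals$day), ,
                     drop = FALSE]
  rownames(animals) <- NULL

  sum_key <- interaction(animals$group, animals$day, drop = TRUE)
  summary <- do.call(rbind, lapply(split(animals, sum_key), function(s) {
    data.frame(group = s$group[1], day = s$day[1], n_mice = nrow(s),
               mean_threshold_g = mean(s$threshold_g),
               sem_threshold_g = sem(s$threshold_g),
               frac_censored = mean(s$censoring != "none"),
               mean_auc = mean(s$auc), sem_auc = sem(s$auc),
               stringsAsFactors = FALSE)
  }))
  summary <- summary[order(summary$group, summary$day), , drop = FALSE]
  rownames(summary) <- NULL

  structure(list(frequencies = frequencies, animals = animals,
                 summary = summary, q = q, auc_scale = auc_scale),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf(
    "von Frey summary (threshold quantile %g%%, AUC on %s force scale)\n",
    x$q, x$auc_scale))
  print(x$summary)
  invisible(x)
}
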