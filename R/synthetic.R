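# Synthetic-data generators with planted, recorded ground truth.
#
# Every pipeline input (expression arrays, Ct tables, target predictions,
# digital count matrices, von Frey trial data) can be generated here so that
# each downstream stage is testable against known truth without animal data.

#' Configuration for synthetic miRNA expression arrays
#'
#' Describes a two-group (sham vs tumour) array experiment with a configurable
#' number of planted up- and down-regulated miRNAs. Baseline per-miRNA
#' abundances are drawn on the log2 scale (array intensities are positive and
#' right-skewed); within-group measurement noise is log-normal with a given
#' coefficient of variation on the linear scale, so expected linear-scale group
#' means equal the planted means exactly at any noise level.
#'
#' @param n_mirnas Number of miRNA probes on the array (default 615).
#' @param n_per_group Biological replicates per group (default 3).
#' @param n_up,n_down Numbers of planted up-/down-regulated miRNAs.
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD of per-miRNA
#'   baseline abundance on the log2 scale.
#' @param planted_fc Linear-scale fold change of planted miRNAs (> 1); planted
#'   up-regulated miRNAs have tumour mean `planted_fc` times the sham mean,
#'   planted down-regulated miRNAs the reciprocal.
#' @param noise_cv Coefficient of variation of within-group intensities on the
#'   linear scale (0 gives exactly the planted means).
#' @param timepoint Timepoint label attached to all arrays (e.g. "PID-8").
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `array_sim_config`.
#' @export
array_sim_config <- function(n_mirnas = 615, n_per_group = 3,
                             n_up = 26, n_down = 31,
                             baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                             planted_fc = 3, noise_cv = 0.05,
                             timepoint = "PID-8", seed = 1L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas),
              n_per_group = as.integer(n_per_group),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              planted_fc = planted_fc, noise_cv = noise_cv,
              timepoint = timepoint, seed = as.integer(seed))
  class(cfg) <- "array_sim_config"
  validate_array_sim_config(cfg)
  cfg
}

validate_array_sim_config <- function(cfg) {
  check_config_field(cfg$n_mirnas >= 1, "n_mirnas", "must be >= 1")
  check_config_field(cfg$n_per_group >= 2, "n_per_group", "must be >= 2")
  check_config_field(cfg$n_up >= 0, "n_up", "must be >= 0")
  check_config_field(cfg$n_down >= 0, "n_down", "must be >= 0")
  check_config_field(cfg$n_up + cfg$n_down <= cfg$n_mirnas,
                     "n_up/n_down", "n_up + n_down must not exceed n_mirnas")
  check_config_field(cfg$planted_fc > 1, "planted_fc", "must be > 1")
  check_config_field(cfg$noise_cv >= 0, "noise_cv", "must be >= 0")
  check_config_field(cfg$baseline_log2_sd >= 0, "baseline_log2_sd",
                     "must be >= 0")
  invisible(cfg)
}

check_config_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
}

# log-normal multiplicative noise with unit mean and linear-scale CV `cv`
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a synthetic miRNA expression array experiment
#'
#' @param config An [array_sim_config()].
#' @return A list with components:
#'   \describe{
#'     \item{matrix}{An [expression_matrix()] (intensities + design).}
#'     \item{truth}{Ground truth: `planted_up`, `planted_down`,
#'       `planted_fc_map` (named vector of true linear fold changes).}
#'   }
#' @export
gen_expression <- function(config = array_sim_config()) {
  validate_array_sim_config(config)
  set.seed(config$seed)
  n <- config$n_mirnas
  ids <- sprintf("miR-sim-%04d", seq_len(n))
  planted <- sample(ids, config$n_up + config$n_down)
  planted_up <- planted[seq_len(config$n_up)]
  planted_down <- setdiff(planted, planted_up)

  base_mean <- 2^stats::rnorm(n, config$baseline_log2_mean,
                              config$baseline_log2_sd)
  names(base_mean) <- ids
  fc <- rep(1, n)
  names(fc) <- ids
  fc[planted_up] <- config$planted_fc
  fc[planted_down] <- 1 / config$planted_fc

  k <- config$n_per_group
  sham_ids <- sprintf("sham_%s_r%d", config$timepoint, seq_len(k))
  tum_ids <- sprintf("tumour_%s_r%d", config$timepoint, seq_len(k))
  vals <- matrix(NA_real_, n, 2 * k,
                 dimnames = list(ids, c(sham_ids, tum_ids)))
  for (j in seq_len(k)) {
    vals[, j] <- base_mean * rlnorm_cv(n, config$noise_cv)
  }
  for (j in seq_len(k)) {
    vals[, k + j] <- base_mean * fc * rlnorm_cv(n, config$noise_cv)
  }
  design <- data.frame(
    array_id = c(sham_ids, tum_ids),
    group = rep(c("sham", "tumour"), each = k),
    replicate = rep(seq_len(k), 2),
    timepoint = config$timepoint,
    stringsAsFactors = FALSE)

  truth <- list(planted_up = planted_up, planted_down = planted_down,
                planted_fc_map = fc[planted])
  list(matrix = expression_matrix(vals, design), truth = truth)
}

#' Generate a synthetic long-format Ct table
#'
#' Emulates a qPCR experiment with a treatment (tumour) and a control (sham)
#' group. For every target assay the planted linear fold change `f` is encoded
#' as a tumour target Ct shifted by `-log2(f)` cycles relative to control; the
#' reference assay Ct is identical in expectation across groups, so the
#' expected delta-delta-Ct equals `-log2(f)`.
#'
#' @param targets Character vector of target assay ids.
#' @param true_fc_map Named numeric vector of true linear fold changes
#'   (treatment vs control), one per target; all values must be positive.
#' @param n_bio Biological replicates per group.
#' @param n_tech Technical replicates per (sample, assay) (default 3).
#' @param ct_noise_sd Gaussian noise SD (cycles) added independently to every
#'   recorded Ct value.
#' @param seed Integer seed.
#' @param reference Reference assay id (default "sno202").
#' @param treatment,control Group labels.
#' @param base_ct Control-group target Ct in expectation.
#' @param ref_ct Reference-assay Ct in expectation.
#' @return A `ct_table` data.frame with columns `sample_id`, `group`,
#'   `assay_id`, `role` ("target"/"reference"), `tech_rep`, `ct`.
#' @export
gen_ct <- function(targets, true_fc_map, n_bio = 3, n_tech = 3,
                   ct_noise_sd = 0, seed = 1L, reference = "sno202",
                   treatment = "tumour", control = "sham",
                   base_ct = 25, ref_ct = 20) {
  stopifnot(length(targets) >= 1, n_bio >= 1, n_tech >= 1, ct_noise_sd >= 0)
  true_fc_map <- true_fc_map[targets]
  if (any(is.na(true_fc_map)) || any(true_fc_map <= 0)) {
    stop("true_fc_map must provide a positive fold change for every target",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  groups <- c(control, treatment)
  rows <- list()
  for (g in groups) {
    for (b in seq_len(n_bio)) {
      sample_id <- sprintf("%s_b%d", g, b)
      for (tg in targets) {
        mu <- if (g == treatment) base_ct - log2(true_fc_map[[tg]]) else base_ct
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, group = g, assay_id = tg, role = "target",
          tech_rep = seq_len(n_tech),
          ct = mu + stats::rnorm(n_tech, 0, ct_noise_sd),
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, group = g, assay_id = reference,
        role = "reference", tech_rep = seq_len(n_tech),
        ct = ref_ct + stats::rnorm(n_tech, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ct_table", class(out))
  out
}

#' Generate synthetic per-algorithm miRNA-target prediction tables
#'
#' Planted genes are predicted by exactly their requested number of distinct
#' algorithms (a seeded random subset); background genes are predicted
#' independently by each algorithm with probability `background_rate`.
#'
#' @param n_algorithms Number of prediction algorithms (default 14).
#' @param genes Character vector of background gene ids.
#' @param planted Named list mapping miRNA id to a character vector of planted
#'   target genes.
#' @param support Named integer vector: algorithm-support count per planted
#'   gene; every value must be between 1 and `n_algorithms`.
#' @param background_rate Per-algorithm probability that a background gene is
#'   predicted for each miRNA.
#' @param seed Integer seed.
#' @return A `prediction_table` data.frame with columns `algorithm`, `mirna`,
#'   `gene`.
#' @export
gen_predictions <- function(n_algorithms = 14, genes = character(),
                            planted = list(), support = integer(),
                            background_rate = 0.05, seed = 1L) {
  stopifnot(n_algorithms >= 1, background_rate >= 0, background_rate <= 1)
  planted_genes <- unique(unlist(planted, use.names = FALSE))
  if (length(planted_genes)) {
    missing <- setdiff(planted_genes, names(support))
    if (length(missing)) {
      stop("support count missing for planted gene(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (any(support[planted_genes] > n_algorithms) ||
        any(support[planted_genes] < 1)) {
      stop("support counts must lie in [1, n_algorithms]", call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  algs <- sprintf("alg%02d", seq_len(n_algorithms))
  rows <- list()
  for (mir in names(planted)) {
    for (g in planted[[mir]]) {
      chosen <- sample(algs, support[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = chosen, mirna = mir, gene = g, stringsAsFactors = FALSE)
    }
    bg <- setdiff(genes, planted[[mir]])
    for (a in algs) {
      hit <- bg[stats::runif(length(bg)) < background_rate]
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = a, mirna = mir, gene = hit, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(algorithm = character(), mirna = character(),
               gene = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("prediction_table", class(out))
  out
}

#' Generate a synthetic digital count matrix with housekeeping genes
#'
#' Emulates digital (NanoString-style) gene counts for an inhibitor vs
#' mismatch-control comparison. Responder genes have expected
#' housekeeping-normalized inhibitor/control ratio equal to `response_ratio`;
#' housekeeping genes are group-invariant in expectation. Per-sample library
#' size factors are drawn so that normalization is exercised. With
#' `dispersion = 0` counts equal their expectations exactly (no sampling), so
#' downstream normalization and response filtering are exact.
#'
#' @param genes Character vector of non-housekeeping gene ids.
#' @param housekeeping Character vector of housekeeping gene ids (the study
#'   design uses 5: Cltc, Gapdh, Gusb, Hprt, Tubb5).
#' @param responders Character vector (subset of `genes`) of planted
#'   responders; must not overlap `housekeeping`.
#' @param response_ratio Expected inhibitor/control normalized ratio of
#'   responder genes (> 0).
#' @param n_per_group Samples per condition.
#' @param dispersion Negative-binomial dispersion (0 = deterministic means).
#' @param seed Integer seed.
#' @param base_mean Baseline expected count of non-housekeeping genes.
#' @param hk_mean Baseline expected count of housekeeping genes.
#' @return A list with `counts` (matrix genes x samples), `housekeeping`
#'   (logical vector per gene), `design` (data.frame sample_id, condition) and
#'   `truth` (planted responders and ratio).
#' @export
gen_counts <- function(genes, housekeeping, responders = character(),
                       response_ratio = 1.5, n_per_group = 3,
                       dispersion = 0, seed = 1L,
                       base_mean = 500, hk_mean = 2000) {
  if (length(intersect(housekeeping, responders))) {
    stop("housekeeping genes and responders must be disjoint: ",
         paste(intersect(housekeeping, responders), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(response_ratio > 0, n_per_group >= 1, dispersion >= 0)
  if (!all(responders %in% genes)) {
    stop("all responders must be listed in genes", call. = FALSE)
  }
  set.seed(as.integer(seed))
  all_genes <- c(genes, housekeeping)
  conds <- rep(c("control", "inhibitor"), each = n_per_group)
  sample_ids <- sprintf("%s_s%d", conds, rep(seq_len(n_per_group), 2))
  size_factor <- exp(stats::rnorm(length(sample_ids), 0, 0.2))
  base <- c(stats::setNames(rep(base_mean, length(genes)), genes),
            stats::setNames(rep(hk_mean, length(housekeeping)), housekeeping))
  mu <- outer(base, size_factor)
  dimnames(mu) <- list(all_genes, sample_ids)
  inh <- conds == "inhibitor"
  mu[responders, inh] <- mu[responders, inh, drop = FALSE] * response_ratio
  counts <- if (dispersion == 0) mu else {
    m <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                nrow(mu), ncol(mu), dimnames = dimnames(mu))
    storage.mode(m) <- "double"
    m
  }
  list(counts = counts,
       housekeeping = stats::setNames(all_genes %in% housekeeping, all_genes),
       design = data.frame(sample_id = sample_ids, condition = conds,
                           stringsAsFactors = FALSE),
       truth = list(responders = responders, response_ratio = response_ratio))
}

#' Configuration for synthetic von Frey behavioural data
#'
#' Withdrawal counts per (mouse, day, filament) are binomial with `n_trials`
#' trials and success probability given by a logistic psychometric function of
#' log10 filament force:
#' `p = floor + (ceiling - floor) * plogis(slope * (log10(F) - log10(thr)))`,
#' where `thr` is the animal's mechanical threshold that day. Sham thresholds
#' stay at `baseline_threshold_g`; tumour thresholds follow
#' `tumour_threshold_trajectory`.
#'
#' @param filaments Filament forces in grams, strictly increasing (default the
#'   graded set 0.02, 0.07, 0.16, 0.4, 1.0 g).
#' @param n_trials Stimulations per filament per test (default 5).
#' @param days Integer post-implantation days tested.
#' @param n_mice_per_group Mice per group (default 6).
#' @param baseline_threshold_g Sham (and day-0) threshold in grams.
#' @param tumour_threshold_trajectory Named numeric vector day -> threshold (g)
#'   for the tumour group; days absent from it fall back to baseline.
#' @param slope Psychometric steepness per log10-gram.
#' @param floor,ceiling Lower/upper asymptotes of withdrawal probability.
#' @param seed Integer seed.
#' @return An object of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(filaments = c(0.02, 0.07, 0.16, 0.4, 1.0),
                                n_trials = 5, days = c(0, 2, 4, 6, 8),
                                n_mice_per_group = 6,
                                baseline_threshold_g = 0.6,
                                tumour_threshold_trajectory =
                                  c("0" = 0.6, "2" = 0.45, "4" = 0.3,
                                    "6" = 0.15, "8" = 0.05),
                                slope = 4, floor = 0, ceiling = 1,
                                seed = 1L) {
  cfg <- list(filaments = filaments, n_trials = as.integer(n_trials),
              days = as.integer(days),
              n_mice_per_group = as.integer(n_mice_per_group),
              baseline_threshold_g = baseline_threshold_g,
              tumour_threshold_trajectory = tumour_threshold_trajectory,
              slope = slope, floor = floor, ceiling = ceiling,
              seed = as.integer(seed))
  class(cfg) <- "behavior_sim_config"
  validate_behavior_sim_config(cfg)
  cfg
}

validate_behavior_sim_config <- function(cfg) {
  check_config_field(length(cfg$filaments) >= 2 && all(cfg$filaments > 0) &&
                       all(diff(cfg$filaments) > 0),
                     "filaments", "must be positive and strictly increasing")
  check_config_field(cfg$n_trials >= 1, "n_trials", "must be >= 1")
  check_config_field(cfg$n_mice_per_group >= 1, "n_mice_per_group",
                     "must be >= 1")
  check_config_field(cfg$baseline_threshold_g > 0, "baseline_threshold_g",
                     "must be positive")
  check_config_field(all(cfg$tumour_threshold_trajectory > 0),
                     "tumour_threshold_trajectory", "thresholds must be positive")
  check_config_field(cfg$floor >= 0 && cfg$floor < cfg$ceiling &&
                       cfg$ceiling <= 1,
                     "floor/ceiling", "must satisfy 0 <= floor < ceiling <= 1")
  invisible(cfg)
}

#' Psychometric withdrawal probability
#'
#' Logistic in log10 force with floor/ceiling asymptotes. With `floor = 0`,
#' `ceiling = 1` the probability at `force == threshold` is exactly 0.5; as
#' `slope` grows the function approaches a step at the threshold.
#'
#' @param force Filament force (g).
#' @param threshold Mechanical threshold (g).
#' @param slope Steepness per log10-gram.
#' @param floor,ceiling Asymptotes.
#' @return Withdrawal probability in `[floor, ceiling]`.
#' @export
psychometric_p <- function(force, threshold, slope, floor = 0, ceiling = 1) {
  floor + (ceiling - floor) *
    stats::plogis(slope * (log10(force) - log10(threshold)))
}

#' Generate synthetic von Frey withdrawal data
#'
#' @param config A [behavior_sim_config()].
#' @return A list with `data` (a `behavior_dataset` data.frame: `mouse_id`,
#'   `group`, `day`, `force_g`, `n_trials`, `n_withdrawals`) and `truth`
#'   (data.frame of the true per-(group, day) thresholds).
#' @export
gen_behavior <- function(config = behavior_sim_config()) {
  validate_behavior_sim_config(config)
  set.seed(config$seed)
  traj <- config$tumour_threshold_trajectory
  thr_for <- function(group, day) {
    if (group == "sham") return(config$baseline_threshold_g)
    key <- as.character(day)
    if (key %in% names(traj)) traj[[key]] else config$baseline_threshold_g
  }
  grid <- expand.grid(group = c("sham", "tumour"),
                      mouse = seq_len(config$n_mice_per_group),
                      day = config$days,
                      force_g = config$filaments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$group, grid$mouse, grid$day, grid$force_g), ]
  thr <- mapply(thr_for, grid$group, grid$day)
  p <- psychometric_p(grid$force_g, thr, config$slope,
                      config$floor, config$ceiling)
  data <- data.frame(
    mouse_id = sprintf("%s_m%d", grid$group, grid$mouse),
    group = grid$group, day = grid$day, force_g = grid$force_g,
    n_trials = config$n_trials,
    n_withdrawals = stats::rbinom(nrow(grid), config$n_trials, p),
    stringsAsFactors = FALSE)
  rownames(data) <- NULL
  class(data) <- c("behavior_dataset", class(data))
  truth <- unique(data.frame(group = grid$group, day = grid$day,
                             threshold_g = thr, stringsAsFactors = FALSE))
  rownames(truth) <- NULL
  list(data = data, truth = truth)
}
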