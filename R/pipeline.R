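# End-to-end orchestration: simulate -> screen -> relquant -> targets ->
# behavior, with seeded determinism and a JSON artifact manifest.

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

#' Simulate a complete synthetic study on disk
#'
#' Generates all five pipeline inputs (expression + design, Ct table,
#' prediction table, count matrix + condition design, behavior table) and a
#' machine-readable ground-truth JSON, written as plain CSV with metadata
#' headers. Sub-seeds for the five generators are derived deterministically
#' from the master seed.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master integer seed.
#' @param array_config An [array_sim_config()] (its own seed is overridden by
#'   the derived sub-seed).
#' @param behavior_config A [behavior_sim_config()] (seed likewise derived).
#' @param n_target_genes Background gene-pool size for predictions/counts.
#' @param n_consensus Planted consensus targets (support >= 2).
#' @param n_responders Planted responders among consensus targets.
#' @param response_ratio Planted inhibitor/control response ratio.
#' @param ct_targets Named vector of true fold changes for the Ct table.
#' @param ct_noise_sd,count_dispersion,prediction_background_rate Noise knobs
#'   passed through to the generators.
#' @return Named list of written file paths (the simulate-stage manifest).
#' @export
simulate_study <- function(out_dir, seed = 1L,
                           array_config = array_sim_config(),
                           behavior_config = behavior_sim_config(),
                           n_target_genes = 100, n_consensus = 20,
                           n_responders = 8, response_ratio = 1.5,
                           ct_targets = c("miR-sim-0001" = 4,
                                          "miR-sim-0002" = 0.25),
                           ct_noise_sd = 0.1, count_dispersion = 0.01,
                           prediction_background_rate = 0.02) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  paths <- list()

  array_config$seed <- derive_seed(seed, 1L)
  expr <- gen_expression(array_config)
  paths$expression <- file.path(out_dir, "expression.csv")
  write_tabular(expr$matrix$values, paths$expression, "simulate",
                array_config$seed,
                list(n_mirnas = array_config$n_mirnas,
                     planted_fc = array_config$planted_fc,
                     noise_cv = array_config$noise_cv))
  paths$design <- file.path(out_dir, "design.csv")
  write_tabular(expr$matrix$design, paths$design, "simulate",
                array_config$seed)

  ct_seed <- derive_seed(seed, 2L)
  ct <- gen_ct(names(ct_targets), ct_targets, n_bio = 3, n_tech = 3,
               ct_noise_sd = ct_noise_sd, seed = ct_seed)
  paths$ct <- file.path(out_dir, "ct.csv")
  write_tabular(ct, paths$ct, "simulate", ct_seed,
                list(ct_noise_sd = ct_noise_sd))

  genes <- sprintf("Gene%03d", seq_len(n_target_genes))
  consensus_genes <- genes[seq_len(n_consensus)]
  responders <- consensus_genes[seq_len(n_responders)]
  support <- stats::setNames(rep(c(2L, 3L, 5L),
                                 length.out = n_consensus), consensus_genes)
  pred_seed <- derive_seed(seed, 3L)
  preds <- gen_predictions(n_algorithms = 14, genes = genes,
                           planted = list("miR-sim-0001" = consensus_genes),
                           support = support,
                           background_rate = prediction_background_rate,
                           seed = pred_seed)
  paths$predictions <- file.path(out_dir, "predictions.csv")
  write_tabular(preds, paths$predictions, "simulate", pred_seed,
                list(background_rate = prediction_background_rate))

  hk <- c("Cltc", "Gapdh", "Gusb", "Hprt", "Tubb5")
  count_seed <- derive_seed(seed, 4L)
  cnt <- gen_counts(genes = consensus_genes, housekeeping = hk,
                    responders = responders,
                    response_ratio = response_ratio,
                    dispersion = count_dispersion, seed = count_seed)
  paths$counts <- file.path(out_dir, "counts.csv")
  count_df <- data.frame(id = rownames(cnt$counts),
                         housekeeping = cnt$housekeeping,
                         as.data.frame(cnt$counts), check.names = FALSE,
                         stringsAsFactors = FALSE)
  write_tabular(count_df, paths$counts, "simulate", count_seed,
                list(response_ratio = response_ratio,
                     dispersion = count_dispersion))
  paths$counts_design <- file.path(out_dir, "counts_design.csv")
  write_tabular(cnt$design, paths$counts_design, "simulate", count_seed)

  behavior_config$seed <- derive_seed(seed, 5L)
  beh <- gen_behavior(behavior_config)
  paths$behavior <- file.path(out_dir, "behavior.csv")
  write_tabular(beh$data, paths$behavior, "simulate", behavior_config$seed,
                list(n_trials = behavior_config$n_trials))

  truth <- list(
    planted_up = expr$truth$planted_up,
    planted_down = expr$truth$planted_down,
    planted_fc = as.list(expr$truth$planted_fc_map),
    ct_true_fc = as.list(ct_targets),
    consensus_genes = consensus_genes,
    consensus_support = as.list(support),
    responders = responders,
    response_ratio = response_ratio,
    behavior_thresholds = beh$truth)
  paths$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}

#' Run the full pipeline on a synthetic study
#'
#' Orchestrates simulate -> screen -> relquant -> targets -> behavior. Every
#' stage reads the documented file formats written by the previous one and
#' writes its results as TSV with metadata headers; a JSON manifest lists
#' every artifact with its producing stage. Reruns with identical `seed` and
#' parameters reproduce byte-identical numeric outputs.
#'
#' @param out_dir Output directory.
#' @param seed Master integer seed.
#' @param stages Character vector of stages to run (subset of the default).
#' @param screen_cfg A [screen_config()].
#' @param min_algorithms Consensus threshold for target tallying.
#' @param min_ratio Response-filter threshold.
#' @param quantile Threshold response quantile (percent) for behavior.
#' @param auc_scale AUC abscissa ("log10" or "linear").
#' @param ... Passed to [simulate_study()].
#' @return A list with `manifest` (data.frame: artifact, stage, path) and
#'   `summary` (named list of headline numbers per stage), invisibly written
#'   to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         stages = c("simulate", "screen", "relquant",
                                    "targets", "behavior"),
                         screen_cfg = screen_config(),
                         min_algorithms = 2, min_ratio = 1.5,
                         quantile = 50,
                         auc_scale = c("log10", "linear"), ...) {
  auc_scale <- match.arg(auc_scale)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  manifest <- list()
  summary <- list()
  # manifest paths are relative to out_dir so runs are relocatable and
  # identical-seed runs byte-identical
  note <- function(artifact, stage, path) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      artifact = artifact, stage = stage,
      path = sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                  out_dir), "/?"), "", path),
      stringsAsFactors = FALSE)
  }

  if ("simulate" %in% stages) {
    sim_paths <- simulate_study(out_dir, seed = seed, ...)
    for (nm in names(sim_paths)) note(nm, "simulate", sim_paths[[nm]])
  }

  if ("screen" %in% stages) {
    em <- read_expression(file.path(out_dir, "expression.csv"),
                          file.path(out_dir, "design.csv"))
    em_norm <- quantile_normalize(em)
    stats_tab <- group_stats(em_norm, sd_mode = screen_cfg$sd_mode)
    res <- screen(stats_tab, screen_cfg)
    rep <- screen_report(res, screen_cfg, matrix = em_norm)
    p_screen <- file.path(out_dir, "screen_result.tsv")
    write_tabular(as.data.frame(res), p_screen, "screen", seed,
                  list(k = screen_cfg$k, fc_primary = screen_cfg$fc_primary,
                       fc_secondary = screen_cfg$fc_secondary,
                       sd_mode = screen_cfg$sd_mode))
    note("screen_result", "screen", p_screen)
    if (!is.null(rep$heatmap)) {
      p_heat <- file.path(out_dir, "screen_heatmap.tsv")
      write_tabular(rep$heatmap, p_heat, "screen", seed)
      note("screen_heatmap", "screen", p_heat)
    }
    summary$screen <- as.list(rep$counts)
  }

  if ("relquant" %in% stages) {
    ct <- read_tabular(file.path(out_dir, "ct.csv"))
    targets <- unique(ct$assay_id[ct$role == "target"])
    reference <- unique(ct$assay_id[ct$role == "reference"])[1]
    rq <- do.call(rbind, lapply(targets, function(tg) {
      ddct(ct, tg, reference, treatment = "tumour", control = "sham")
    }))
    p_rq <- file.path(out_dir, "relquant.tsv")
    write_tabular(as.data.frame(rq), p_rq, "relquant", seed)
    note("relquant", "relquant", p_rq)
    summary$relquant <- stats::setNames(as.list(rq$fold_change), rq$target)
  }

  if ("targets" %in% stages) {
    preds <- read_tabular(file.path(out_dir, "predictions.csv"))
    cons <- tally(preds, min_algorithms = min_algorithms)
    p_cons <- file.path(out_dir, "consensus.tsv")
    write_tabular(as.data.frame(cons), p_cons, "targets", seed,
                  list(min_algorithms = min_algorithms))
    note("consensus", "targets", p_cons)

    count_df <- read_tabular(file.path(out_dir, "counts.csv"))
    hk_flag <- as.logical(count_df$housekeeping)
    m <- as.matrix(count_df[, setdiff(names(count_df),
                                      c("id", "housekeeping")),
                            drop = FALSE])
    rownames(m) <- count_df$id
    cdes <- read_tabular(file.path(out_dir, "counts_design.csv"))
    norm <- normalize_counts(m, stats::setNames(hk_flag, count_df$id))
    resp <- response_filter(norm, cdes, min_ratio = min_ratio)
    p_resp <- file.path(out_dir, "target_response.tsv")
    write_tabular(as.data.frame(resp), p_resp, "targets", seed,
                  list(min_ratio = min_ratio))
    note("target_response", "targets", p_resp)
    summary$targets <- list(n_consensus = sum(cons$consensus),
                            n_responders = sum(resp$responder))
  }

  if ("behavior" %in% stages) {
    beh <- read_tabular(file.path(out_dir, "behavior.csv"))
    tc <- group_timecourse(beh, q = quantile, auc_scale = auc_scale)
    p_sum <- file.path(out_dir, "behavior_summary.tsv")
    write_tabular(tc$summary, p_sum, "behavior", seed,
                  list(quantile = quantile, auc_scale = auc_scale))
    note("behavior_summary", "behavior", p_sum)
    p_an <- file.path(out_dir, "behavior_animals.tsv")
    write_tabular(tc$animals, p_an, "behavior", seed,
                  list(quantile = quantile, auc_scale = auc_scale))
    note("behavior_animals", "behavior", p_an)
    tum <- tc$summary[tc$summary$group == "tumour", ]
    summary$behavior <- list(
      tumour_threshold_first = tum$mean_threshold_g[which.min(tum$day)],
      tumour_threshold_last = tum$mean_threshold_g[which.max(tum$day)])
  }

  manifest_df <- do.call(rbind, manifest)
  rownames(manifest_df) <- NULL
  jsonlite::write_json(
    list(seed = seed, stages = stages, artifacts = manifest_df),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(manifest = manifest_df, summary = summary))
}
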