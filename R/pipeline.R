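#' Build a pipeline run configuration
#'
#' Every stochastic stage carries an explicit seed derived from the master
#' seed, so a configuration reproduces a run exactly. Configurations
#' round-trip losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param seed Master integer seed; per-stage seeds derive from it.
#' @param n_per_group Listeners per group in the simulated cohort.
#' @param variants Model variants to fit.
#' @param n_starts Optimiser starts per fit.
#' @param neural List of neural-stage settings: `band` (Hz), `fraction`,
#'   `n_permutations`, `n_trials` (per simulated source set),
#'   `control_latency_range` / `patient_latency_range` (ms, implanted
#'   congruency-contrast latencies per group).
#' @param out_dir Output directory for stage artefacts.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, n_per_group = 11L,
                       variants = c("simple", "complex"),
                       n_starts = 32L,
                       neural = list(band = c(12, 24), fraction = 0.8,
                                     n_permutations = 200L, n_trials = 60L,
                                     control_latency_range = c(275, 400),
                                     patient_latency_range = c(412, 1000)),
                       out_dir = tempfile("priorclarity_run_")) {
  structure(list(seed = as.integer(seed),
                 seeds = list(design = child_seed(seed, 1L),
                              simulate = child_seed(seed, 2L),
                              fit = child_seed(seed, 3L),
                              stats = child_seed(seed, 4L),
                              neural = child_seed(seed, 5L)),
                 n_per_group = as.integer(n_per_group),
                 variants = variants, n_starts = as.integer(n_starts),
                 neural = neural, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$seeds <- lapply(cfg$seeds, as.integer)
  cfg$n_per_group <- as.integer(cfg$n_per_group)
  cfg$n_starts <- as.integer(cfg$n_starts)
  for (nm in c("band", "control_latency_range", "patient_latency_range"))
    cfg$neural[[nm]] <- as.numeric(cfg$neural[[nm]])
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order - design, cohort simulation,
#' per-listener model fitting (all requested variants plus AICc
#' comparison), group statistics (rank-sum on fitted prior SDs, congruency
#' effects), and the neural stage (per-listener implanted-latency
#' time-frequency maps and latency recovery; coupled-source imaginary
#' coherence and Granger with a permutation null) - writing per-stage CSV
#' and JSON artefacts under `config$out_dir` plus a digest manifest.
#'
#' @param config A [run_config()].
#' @return A list of class `"run_manifest"`: `config_hash`, per-stage
#'   output paths with MD5 digests, `timestamps`, `package_version`, and
#'   in-memory `results` for [pipeline_report()].
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(); times <- list()
  emit <- function(stage, name, writer) {
    p <- file.path(config$out_dir, name)
    writer(p)
    paths[[stage]] <<- c(paths[[stage]], p)
    times[[stage]] <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    p
  }

  # -- design -------------------------------------------------------------
  pool <- sprintf("w%03d", 1:432)
  sched1 <- exp1_schedule(pool, "A", seed = config$seeds$design)
  sched2 <- exp2_schedule(make_response_sets(), seed = config$seeds$design)
  emit("design", "exp1_schedule.csv", function(p) write_schedule(sched1, p))
  emit("design", "exp2_schedule.csv", function(p) write_schedule(sched2, p))
  emit("design", "design_summary.json", function(p)
    jsonlite::write_json(list(exp1 = schedule_summary(sched1),
                              exp2 = schedule_summary(sched2)),
                         p, auto_unbox = TRUE))

  # -- simulate -----------------------------------------------------------
  cohort <- simulate_cohort(cohort_spec(n_per_group = config$n_per_group,
                                        seed = config$seeds$simulate))
  behav <- do.call(rbind, lapply(cohort, function(s)
    cbind(subject = s$id, group = s$group, s$dataset$exp1)))
  emit("simulate", "behaviour.csv", function(p)
    utils::write.csv(behav, p, row.names = FALSE))

  # -- fit ----------------------------------------------------------------
  fits <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    fseed <- child_seed(config$seeds$fit, i)
    out <- lapply(config$variants, function(v)
      fit_clarity(s$dataset, variant = v, n_starts = config$n_starts,
                  seed = fseed))
    names(out) <- config$variants
    out
  })
  fit_tab <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]; f <- fits[[i]][["simple"]]
    cmp <- if (all(c("simple", "complex") %in% config$variants))
      compare_variants(fits[[i]]$simple, fits[[i]]$complex) else NULL
    data.frame(subject = s$id, group = s$group,
               true_sigma_prior = s$params$sigma_prior,
               true_threshold = s$params$threshold,
               sigma_prior = coef(f)[["sigma_prior"]],
               threshold = coef(f)[["threshold"]],
               rss = f$rss, aicc = f$aicc,
               variance_explained = f$variance_explained,
               aicc_winner = if (is.null(cmp)) NA_character_ else cmp$winner,
               delta_aicc = if (is.null(cmp)) NA_real_ else cmp$delta_aicc)
  }))
  emit("fit", "fits.csv", function(p)
    utils::write.csv(fit_tab, p, row.names = FALSE))

  # -- compare ------------------------------------------------------------
  compare <- list(
    simple_preferred = mean(fit_tab$aicc_winner == "simple"),
    mean_delta_aicc = mean(fit_tab$delta_aicc),
    sigma_recovery_spearman =
      stats::cor(fit_tab$true_sigma_prior, fit_tab$sigma_prior,
                 method = "spearman"))
  emit("compare", "comparison.json", function(p)
    jsonlite::write_json(compare, p, auto_unbox = TRUE, digits = NA))

  # -- stats --------------------------------------------------------------
  grp <- split(fit_tab$sigma_prior, fit_tab$group)
  rs <- rank_sum_test(grp$control, grp$patient)
  effects <- vapply(cohort, function(s)
    congruency_effect(s$dataset)$overall, numeric(1))
  stats_out <- list(
    rank_sum_u = rs$u, rank_sum_u_complement = rs$u_complement,
    rank_sum_p = rs$p_two_sided,
    mean_congruency_effect = list(
      control = mean(effects[fit_tab$group == "control"]),
      patient = mean(effects[fit_tab$group == "patient"])))
  emit("stats", "group_stats.json", function(p)
    jsonlite::write_json(stats_out, p, auto_unbox = TRUE, digits = NA))

  # -- neural -------------------------------------------------------------
  nn <- config$neural
  lat_true <- with_seed(config$seeds$neural, c(
    stats::runif(config$n_per_group, nn$control_latency_range[1],
                 nn$control_latency_range[2]),
    stats::runif(config$n_per_group, nn$patient_latency_range[1],
                 nn$patient_latency_range[2])))
  lat_rec <- vapply(seq_along(lat_true), function(i) {
    maps <- simulate_tf_contrast(lat_true[i],
                                 seed = child_seed(config$seeds$neural, i))
    band_contrast_latency(maps$match, maps$mismatch, band = nn$band,
                          fraction = nn$fraction)$t80_ms
  }, numeric(1))
  lat_tab <- data.frame(
    subject = vapply(cohort, `[[`, character(1), "id"),
    group = vapply(cohort, `[[`, character(1), "group"),
    implanted_latency_ms = lat_true, t80_ms = lat_rec)

  src <- simulate_coupled_sources(coupling_spec("frontal->temporal"),
                                  n_trials = nn$n_trials,
                                  seed = config$seeds$neural)
  src <- subtract_evoked(src)
  coh_null <- permutation_null(src, statistic = "imaginary_coherence",
                               n_permutations = nn$n_permutations,
                               seed = child_seed(config$seeds$neural, 99L))
  gc <- spectral_granger(src)
  neural_out <- list(
    latency = lat_tab,
    coherence_beta_exceeds = mean(coh_null$exceeds[
      coh_null$freqs >= 13 & coh_null$freqs <= 23]),
    granger_beta_means = as.list(colMeans(
      gc$granger[gc$freqs >= 13 & gc$freqs <= 23, ])))
  emit("neural", "latency.csv", function(p)
    utils::write.csv(lat_tab, p, row.names = FALSE))
  emit("neural", "neural_summary.json", function(p)
    jsonlite::write_json(neural_out[-1], p, auto_unbox = TRUE, digits = NA))

  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  structure(list(
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = lapply(paths, function(p)
      list(files = p, md5 = unname(tools::md5sum(p)))),
    timestamps = times,
    package_version = as.character(utils::packageVersion("priorclarity")),
    results = list(fits = fit_tab, compare = compare, stats = stats_out,
                   neural = neural_out),
    out_dir = config$out_dir
  ), class = "run_manifest")
}

#' Summarise a completed pipeline run
#'
#' Human-readable summary of a [run_pipeline()] manifest: recovered versus
#' true parameters, AICc variant preferences, the group comparison of
#' fitted prior SDs, per-listener latencies, and connectivity summaries.
#'
#' @param manifest A `run_manifest`.
#' @return The manifest's `results`, invisibly, after printing the tables.
#' @export
pipeline_report <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  res <- manifest$results
  if (is.null(res) || !length(res$fits)) stop("empty manifest: nothing to report")
  cat("== Per-listener model fits ==\n")
  print(res$fits[, c("subject", "group", "true_sigma_prior", "sigma_prior",
                     "true_threshold", "threshold", "aicc_winner")],
        row.names = FALSE, digits = 3)
  cat(sprintf("\nSimple variant preferred for %.0f%% of listeners; mean delta AICc %.2f\n",
              100 * res$compare$simple_preferred, res$compare$mean_delta_aicc))
  cat(sprintf("Prior-SD recovery (Spearman): %.3f\n",
              res$compare$sigma_recovery_spearman))
  cat(sprintf("\nGroup comparison of fitted prior SD: U = %g (complement %g), p = %.4g\n",
              res$stats$rank_sum_u, res$stats$rank_sum_u_complement,
              res$stats$rank_sum_p))
  cat(sprintf("Mean congruency effect: control %.3f, patient %.3f (rating points)\n",
              res$stats$mean_congruency_effect$control,
              res$stats$mean_congruency_effect$patient))
  cat("\n== Congruency-contrast latencies (ms) ==\n")
  print(res$neural$latency, row.names = FALSE, digits = 4)
  cat(sprintf("\nBeta-band imaginary coherence above null at %.0f%% of 13-23 Hz bins\n",
              100 * res$neural$coherence_beta_exceeds))
  gm <- res$neural$granger_beta_means
  cat(sprintf("Beta-band Granger means: %s = %.4g, %s = %.4g\n",
              names(gm)[1], gm[[1]], names(gm)[2], gm[[2]]))
  invisible(res)
}
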