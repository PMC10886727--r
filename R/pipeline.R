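#' Run the connectivity stages over a whole synthetic study
#'
#' The study-level driver used by the pipeline and the validation scripts.
#' For every (subject, session, condition) cell it theta-filters the epochs,
#' normalises trial amplitudes across the two conditions, computes windowed
#' connectivity, builds the surrogate null, and prunes non-significant cells;
#' it then applies the link-stability filter per (session, condition, metric)
#' across subjects and aggregates to the five ROI contrasts.
#'
#' @param study a `synthetic_study` (or a compatible list with `recordings`
#'   nested `[[subject]][[session]][[condition]]` and a `config`).
#' @param metrics subset of `c("plv", "wpli")`.
#' @param n_surrogates surrogates per cell (default 100).
#' @param alpha significance level for the surrogate pruning.
#' @param method surrogate method, `"phase"` or `"time"`.
#' @param within_thr,across_thr stability-filter thresholds.
#' @param band theta band passed to the filter.
#' @param surrogate_seed base seed of the surrogate streams; each cell uses
#'   `cell_seed(surrogate_seed, subject, session, condition)`.
#' @param progress print a line per subject.
#'
#' @return a list with `roi` (tidy data.frame: subject, session, condition,
#'   metric, window, contrast, value), `keep_rate` (per-cell significance
#'   keep rates), and `retained` (per (session, condition, metric) stability
#'   filter results).
#' @export
analyse_study <- function(study, metrics = "plv", n_surrogates = 100,
                          alpha = 0.05, method = "phase",
                          within_thr = 0.60, across_thr = 0.50,
                          band = c(3, 8), surrogate_seed = NULL,
                          progress = FALSE) {
  config <- study$config
  if (is.null(surrogate_seed)) surrogate_seed <- config$seed + 1
  sessions <- names(study$recordings[[1L]])
  conditions <- names(study$recordings[[1L]][[1L]])
  n_sub <- length(study$recordings)
  pruned <- masks <- list()
  keep_rate <- list()
  for (s in seq_len(n_sub)) {
    if (progress) message(sprintf("analyse_study(): subject %d / %d", s, n_sub))
    for (ses in sessions) {
      recs <- study$recordings[[s]][[ses]]
      filt <- lapply(recs, bandpass_theta, band = band)
      norm <- normalise_trials(filt$L, filt$R)
      for (cond in conditions) {
        rec <- norm[[cond]]
        tens <- windowed_connectivity(rec, metrics = metrics)
        null <- build_null(rec, metrics = metrics, n = n_surrogates,
                           method = method, band = band,
                           seed = cell_seed(surrogate_seed, s, ses, cond))
        pr <- significance_prune(tens, null, alpha = alpha)
        key <- paste(s, ses, cond, sep = ".")
        pruned[[key]] <- pr$pruned
        masks[[key]] <- pr$mask
        keep_rate[[key]] <- vapply(pr$mask$keep, mean, 0)
      }
    }
  }
  # stability filter per (session, condition, metric), then ROI aggregation
  retained <- list()
  roi_rows <- list()
  contrasts <- roi_contrasts()
  for (ses in sessions) for (cond in conditions) for (mm in metrics) {
    keys <- paste(seq_len(n_sub), ses, cond, sep = ".")
    ret <- stability_filter(lapply(keys, function(k) masks[[k]]$keep[[mm]]),
                            within_thr = within_thr, across_thr = across_thr)
    retained[[paste(ses, cond, mm, sep = ".")]] <- ret
    for (k in keys) {
      for (cn in names(contrasts)) {
        roi_rows[[length(roi_rows) + 1L]] <-
          roi_connectivity(pruned[[k]], masks[[k]], ret,
                           contrasts[[cn]][1L], contrasts[[cn]][2L],
                           metric = mm)
      }
    }
  }
  roi <- do.call(rbind, roi_rows)
  rownames(roi) <- NULL
  list(roi = roi, keep_rate = keep_rate, retained = retained)
}

default_pipeline_config <- function() {
  list(
    sim = list(n_subjects = 16, n_trials_per_cell = 60, fs = 100, snr = 2,
               seed = 1),
    couplings = "tmr_study",
    effects = list(),
    analysis = list(metrics = "plv", n_surrogates = 100, alpha = 0.05,
                    method = "phase", within_thr = 0.60, across_thr = 0.50),
    stats = list(n_boot = 50000, seed = 7),
    out_dir = "phaseconn_run"
  )
}

validate_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown pipeline config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(base)) {
    if (is.null(config[[nm]])) { config[[nm]] <- base[[nm]]; next }
    if (is.list(base[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(formals_or(base[[nm]], nm)))
      if (length(bad))
        stop("unknown field(s) in config$", nm, ": ", paste(bad, collapse = ", "))
      config[[nm]] <- utils::modifyList(base[[nm]], config[[nm]])
    }
  }
  config
}

formals_or <- function(base_section, nm) {
  switch(nm,
         sim = formals(sim_config),
         effects = formals(default_effects),
         base_section)
}

write_stage <- function(obj, path, manifest, stage) {
  if (is.data.frame(obj)) utils::write.csv(obj, path, row.names = FALSE)
  else saveRDS(obj, path, compress = FALSE)
  manifest$outputs[[length(manifest$outputs) + 1L]] <-
    list(stage = stage, file = basename(path),
         md5 = unname(tools::md5sum(path)))
  manifest
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> preprocess/connect/surrogate/summarise ->
#' behaviour -> statistics with one configuration, writing every stage output
#' and a provenance manifest (inputs, seeds, content hashes, package version)
#' into a run directory. Re-running the same configuration reproduces the
#' deterministic stage outputs bit-identically.
#'
#' @param config a named list (see `default_pipeline_config()` layout:
#'   `sim`, `couplings`, `effects`, `analysis`, `stats`, `out_dir`) or the
#'   path to a YAML/JSON file holding one; missing fields take defaults,
#'   unknown fields are rejected.
#'
#' @return (invisibly) a list with the run directory, the manifest, and the
#'   in-memory stage results (`study`, `analysis`, `skill`, `stats`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "phaseconn",
                   version = as.character(utils::packageVersion("phaseconn")),
                   config = config, outputs = list())
  stage <- "simulate"
  result <- list()
  tryCatch({
    sim_cfg <- do.call(sim_config, config$sim)
    couplings <- if (identical(config$couplings, "tmr_study"))
      tmr_study_couplings() else config$couplings
    effects <- do.call(default_effects, config$effects)
    study <- simulate_study(sim_cfg, couplings, effects)
    manifest <- write_stage(study$behavioural,
                            file.path(out_dir, "behaviour.csv"), manifest, stage)
    manifest <- write_stage(study$truth, file.path(out_dir, "truth.rds"),
                            manifest, stage)
    manifest <- write_stage(study$recordings,
                            file.path(out_dir, "epochs.rds"), manifest, stage)
    result$study <- study

    stage <- "connectivity"
    an <- do.call(analyse_study, c(list(study = study), config$analysis))
    manifest <- write_stage(an$roi, file.path(out_dir, "roi.csv"), manifest, stage)
    kr <- do.call(rbind, lapply(names(an$keep_rate), function(k)
      data.frame(cell = k, t(an$keep_rate[[k]]))))
    manifest <- write_stage(kr, file.path(out_dir, "keep_rates.csv"),
                            manifest, stage)
    result$analysis <- an

    stage <- "behaviour"
    skill_L <- study_skill_metrics(study$behavioural, hand = "L")
    skill_R <- study_skill_metrics(study$behavioural, hand = "R")
    skill <- rbind(cbind(hand = "L", skill_L), cbind(hand = "R", skill_R))
    manifest <- write_stage(skill, file.path(out_dir, "skill.csv"),
                            manifest, stage)
    result$skill <- skill

    stage <- "stats"
    stats_out <- pipeline_stats(an$roi, skill, config)
    manifest <- write_stage(stats_out$table,
                            file.path(out_dir, "stats.csv"), manifest, stage)
    writeLines(stats_out$report, file.path(out_dir, "report.txt"))
    manifest$outputs[[length(manifest$outputs) + 1L]] <-
      list(stage = stage, file = "report.txt",
           md5 = unname(tools::md5sum(file.path(out_dir, "report.txt"))))
    result$stats <- stats_out
  }, error = function(e) {
    stop("pipeline failed in stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(out_dir = out_dir, manifest = manifest, result = result))
}

# The inferential layer of a pipeline run: session RM-ANOVA and post-hocs on
# the hemisphere-frontal and between-hemisphere contrasts, hand comparisons
# on the within-hemisphere contrasts, and the connectivity-behaviour
# correlation (within-RHem, Sleep, w2, L-hand vs Re_ssi_early).
pipeline_stats <- function(roi, skill, config) {
  mm <- config$analysis$metrics[1L]
  rows <- list()
  report <- character()
  roi$unit <- paste(roi$subject, roi$condition, sep = ":")
  for (cn in c("LHem-Frontal", "RHem-Frontal", "LHem-RHem")) {
    for (w in c("w1", "w2", "w3")) {
      d <- roi[roi$metric == mm & roi$contrast == cn & roi$window == w, ]
      an <- rm_anova(d, dv = "value", within = "session",
                     between = "condition", unit = "unit")
      for (i in seq_len(nrow(an)))
        rows[[length(rows) + 1L]] <- data.frame(
          family = paste(cn, w), effect = an$effect[i], statistic = an$F[i],
          df1 = an$df1[i], df2 = an$df2[i], p_raw = an$p_uncorrected[i],
          p_adj = an$p[i], stringsAsFactors = FALSE)
      ph <- posthoc(d, dv = "value", within = "session", unit = "unit")
      for (i in seq_len(nrow(ph)))
        rows[[length(rows) + 1L]] <- data.frame(
          family = paste(cn, w),
          effect = paste("posthoc", ph$level_a[i], "vs", ph$level_b[i]),
          statistic = ph$statistic[i], df1 = NA, df2 = NA,
          p_raw = ph$p_raw[i], p_adj = ph$p_holm[i], stringsAsFactors = FALSE)
    }
  }
  for (cn in c("within-LHem", "within-RHem")) {
    for (w in c("w1", "w2", "w3")) {
      d <- roi[roi$metric == mm & roi$contrast == cn & roi$window == w, ]
      for (ses in c("Pre", "Sleep", "Post")) {
        ds <- d[d$session == ses, ]
        ds$hand <- ds$condition
        ph <- tryCatch(posthoc(ds, dv = "value", within = "hand",
                               unit = "subject"),
                       error = function(e) NULL)
        if (!is.null(ph))
          rows[[length(rows) + 1L]] <- data.frame(
            family = paste(cn, w, ses), effect = "L vs R hand",
            statistic = ph$statistic[1L], df1 = NA, df2 = NA,
            p_raw = ph$p_raw[1L], p_adj = ph$p_holm[1L],
            stringsAsFactors = FALSE)
      }
    }
  }
  conn <- roi[roi$metric == mm & roi$contrast == "within-RHem" &
                roi$window == "w2" & roi$session == "Sleep" &
                roi$condition == "L", c("subject", "value")]
  sk <- skill[skill$hand == "L", c("subject", "Re_ssi_early")]
  m <- merge(conn, sk, by = "subject")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) >= 5L && stats::sd(m$value) > 0) {
    cr <- bootstrap_correlation(m$value, m$Re_ssi_early,
                                n_boot = config$stats$n_boot,
                                seed = config$stats$seed)
    rows[[length(rows) + 1L]] <- data.frame(
      family = "within-RHem w2 Sleep L ~ Re_ssi_early(L)",
      effect = "spearman rho", statistic = cr$rho, df1 = NA, df2 = NA,
      p_raw = cr$p, p_adj = cr$p, stringsAsFactors = FALSE)
    report <- c(report, utils::capture.output(print(cr)))
  }
  table <- do.call(rbind, rows)
  report <- c("phaseconn pipeline statistics",
              sprintf("metric: %s; %d result rows", mm, nrow(table)),
              report, "",
              utils::capture.output(print(utils::head(table, 30))))
  list(table = table, report = report)
}
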