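#' Pipeline configuration
#'
#' Aggregates the stage options with their standard defaults: full
#' 15-scale ladder (k_max = 14), 15 mm closing ball, hull-based
#' hemisphere exposed area, log10 metric transforms, BCPE trajectory
#' family and B = 1000 bootstrap replicates.
#'
#' @param k_max ladder size.
#' @param closing_diameter closing ball diameter (mm).
#' @param ae_mode hemisphere exposed-area definition.
#' @param smooth pre-smooth masks before isosurfacing.
#' @param trajectory a [normative_config()].
#' @param brainage_k smooth basis dimension.
#' @param bootstrap_B bootstrap replicates.
#' @param seed master seed.
#' @export
pipeline_config <- function(k_max = 14, closing_diameter = 15,
                            ae_mode = "hull", smooth = TRUE,
                            trajectory = normative_config(),
                            brainage_k = 10, bootstrap_B = 1000,
                            seed = 1L) {
  list(k_max = k_max, closing_diameter = closing_diameter,
       ae_mode = ae_mode, smooth = smooth, trajectory = trajectory,
       brainage_k = brainage_k, bootstrap_B = bootstrap_B,
       seed = as.integer(seed))
}

log_stage <- function(log_con, ...) {
  rec <- list(...)
  rec$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  if (!is.null(log_con))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), log_con)
  invisible(NULL)
}

#' Generate and write a named synthetic dataset
#'
#' Presets: `"smooth-sphere"` (concentric-sphere pair with quadrant
#' labels), `"folded-sphere"` (folded pair, a = 3 mm, m = 12, with
#' labels), `"lifespan-cohort"` (cohort CSV from [cohort_preset()]).
#' Meshes are written in FreeSurfer binary format, labels as CSV, and a
#' manifest JSON records the preset, seed, parameters and MD5 checksums
#' of every file written.
#'
#' @param out_dir output directory (created if needed).
#' @param preset preset name.
#' @param seed integer seed.
#' @param n cohort-size override.
#' @return invisibly, the manifest as a list.
#' @export
cmd_simulate <- function(out_dir, preset = "lifespan-cohort", seed = 1L,
                         n = NULL) {
  known <- c("smooth-sphere", "folded-sphere", "lifespan-cohort")
  if (!preset %in% known)
    cs_stop(sprintf("unknown preset '%s'; available: %s", preset,
                    paste(known, collapse = ", ")), "cs_validation_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  params <- list()
  if (preset %in% c("smooth-sphere", "folded-sphere")) {
    spec <- if (preset == "smooth-sphere")
      synthetic_cortex_spec(R = 30, a = 0, m = 0, t = 2.5,
                            subdivisions = 4, seed = seed)
    else
      synthetic_cortex_spec(R = 30, a = 3, m = 12, t = 2.5,
                            subdivisions = 4, seed = seed)
    pair <- make_folded_sphere_pair(spec)
    pair$labels <- make_quadrant_labels(pair)
    fp <- file.path(out_dir, "lh.pial"); write_surface(pair$pial, fp)
    fw <- file.path(out_dir, "lh.white"); write_surface(pair$white, fw)
    fl <- file.path(out_dir, "lh.labels.csv")
    write_vertex_labels(pair$labels, fl, format = "csv")
    files <- c(fp, fw, fl)
    params <- unclass(spec)
  } else {
    cs <- cohort_preset("lifespan-multiscale", n = n, seed = seed)
    cohort <- make_cohort(cs)
    fc <- file.path(out_dir, "cohort.csv")
    write_cohort_csv(cohort, fc)
    files <- fc
    params <- list(n = cs$n, age_range = cs$age_range,
                   sites = cs$sites, metrics = names(cs$trajectories))
  }
  manifest <- list(preset = preset, seed = seed, parameters = params,
                   files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the scale sweep over surface pairs on disk
#'
#' Reads pial/white surfaces (and optional labels), runs
#' [run_scale_sweep()] per subject, writes one CSV per subject plus a
#' merged CSV, and a JSON-lines log of per-scale timings. Per-subject
#' failures are isolated: the run fails only if every subject fails.
#'
#' @param subjects data.frame with columns `subject_id`, `pial`, `white`
#'   and optionally `labels` (file paths).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return the merged multiscale table, invisibly.
#' @export
cmd_sweep <- function(subjects, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ladder <- scale_ladder(config$k_max)
  swcfg <- sweep_config(ae_mode = config$ae_mode,
                        closing_diameter = config$closing_diameter,
                        smooth = config$smooth)
  log_con <- file(file.path(out_dir, "sweep.log.jsonl"), "w")
  on.exit(close(log_con))
  tables <- list()
  failures <- character(0)
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    t0 <- proc.time()[3]
    res <- tryCatch({
      pial <- read_surface(subjects$pial[i])
      white <- read_surface(subjects$white[i])
      pair <- structure(list(pial = pial, white = white, labels = NULL,
                             hemisphere_id = "lh"),
                        class = "cortical_surface_pair")
      if ("labels" %in% names(subjects) && !is.na(subjects$labels[i]) &&
          nzchar(subjects$labels[i]))
        pair$labels <- read_vertex_labels(subjects$labels[i], pial)
      tab <- run_scale_sweep(pair, ladder, swcfg, subject_id = sid)
      write_multiscale_table(tab,
        file.path(out_dir, sprintf("%s_multiscale.csv", sid)))
      log_stage(log_con, stage = "sweep", subject = sid,
                seconds = round(proc.time()[3] - t0, 2), status = "ok")
      tab
    }, error = function(e) {
      log_stage(log_con, stage = "sweep", subject = sid,
                status = "error", message = conditionMessage(e))
      warning(sprintf("subject %s failed: %s", sid, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failures <- c(failures, sid) else
      tables[[sid]] <- res
  }
  if (length(tables) == 0)
    cs_stop("all subjects failed", "cs_sweep_error")
  merged <- do.call(rbind, tables)
  rownames(merged) <- NULL
  write_multiscale_table(merged, file.path(out_dir, "multiscale_all.csv"))
  invisible(merged)
}

#' Fit the statistical models over a cohort table
#'
#' `what = "trajectory"` fits a normative model per metric column and
#' writes serialized models, interquartile band CSVs and a plain-text
#' report with convergence diagnostics; `what = "brainage"` fits the
#' three additive brain-age models, runs the bootstrap and writes the
#' replicate CSV plus a JSON summary. The report echoes the exact
#' configuration used.
#'
#' @param cohort cohort data.frame or path to a cohort CSV.
#' @param what `"trajectory"` or `"brainage"`.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param metrics metric columns for trajectory fitting (default: all
#'   `<metric>@<lambda>` columns).
#' @return invisibly, a list of fitted objects.
#' @export
cmd_fit <- function(cohort, what = c("trajectory", "brainage"), out_dir,
                    config = pipeline_config(), metrics = NULL) {
  what <- match.arg(what)
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  need <- c("subject_id", "age", "sex", "site")
  if (!all(need %in% names(cohort)))
    cs_stop(sprintf("cohort table is missing column(s): %s",
                    paste(setdiff(need, names(cohort)), collapse = ", ")),
            "cs_validation_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- c(sprintf("cortexscales fit report (%s)", what),
              sprintf("n = %d subjects", nrow(cohort)),
              "configuration:",
              utils::capture.output(utils::str(config)))
  if (what == "trajectory") {
    if (is.null(metrics))
      metrics <- grep("@", names(cohort), value = TRUE)
    fits <- list()
    for (mcol in metrics) {
      fit <- fit_normative_model(cohort, mcol, config$trajectory)
      safe <- gsub("[^A-Za-z0-9.]+", "_", mcol)
      normative_to_json(fit, file.path(out_dir,
                                       sprintf("normative_%s.json", safe)))
      ages <- seq(config$trajectory$age_range[1],
                  config$trajectory$age_range[2], by = 1)
      band <- trajectory_band(fit, ages)
      write.csv(band, file.path(out_dir, sprintf("band_%s.csv", safe)),
                row.names = FALSE)
      report <- c(report, sprintf(
        "metric %-12s deviance = %10.2f  edf = %6.1f  converged = %s",
        mcol, fit$deviance, fit$edf, fit$converged))
      fits[[mcol]] <- fit
    }
    writeLines(report, file.path(out_dir, "trajectory_report.txt"))
    invisible(fits)
  } else {
    tab <- brainage_data(cohort)
    models <- lapply(c(native = "native", coarse = "coarse", both = "both"),
                     function(m) fit_brain_age(tab, m, k = config$brainage_k))
    boot <- bootstrap_adjusted_r2(tab, B = config$bootstrap_B,
                                  seed = config$seed, k = config$brainage_k)
    write.csv(boot$samples, file.path(out_dir, "bootstrap_adj_r2.csv"),
              row.names = FALSE)
    summary <- list(
      full_fit = lapply(models, function(m) m$adj_r2),
      bootstrap = boot$summary, B = boot$B, seed = boot$seed)
    jsonlite::write_json(summary, file.path(out_dir, "brainage_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    report <- c(report, vapply(models, function(m)
      sprintf("model %-8s adjusted R^2 = %.3f (edf %.1f)",
              m$model_id, m$adj_r2, m$edf), character(1)))
    writeLines(report, file.path(out_dir, "brainage_report.txt"))
    invisible(list(models = models, bootstrap = boot))
  }
}
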