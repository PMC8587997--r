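# End-to-end orchestration: simulate -> segment -> preprocess -> train ->
# relevance -> overlap -> profile, with deterministic per-stage seeds
# derived from one global seed and a JSON manifest of every artifact.

#' Configuration of a full pipeline run
#'
#' @param outdir output directory for artifacts and the manifest.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param scale "reduced" (6 joints, short trials; minutes on one CPU)
#'   or "full" (18 joints, 5400 variables).
#' @param cohort optional [cohort_config()] overriding the scale preset.
#' @param train_cycles training cycles per participant.
#' @param event_cfg,outlier_cfg,lrp_cfg,overlap_cfg stage configurations.
#' @param overlap_sizes explicit subspace sizes for the overlap stage
#'   (NULL for the config's schedule).
#' @return Object of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("gaitprint-run-"), seed = 1L,
                       scale = c("reduced", "full"), cohort = NULL,
                       train_cycles = 10L,
                       event_cfg = event_config(),
                       outlier_cfg = outlier_config(),
                       lrp_cfg = lrp_config(),
                       overlap_cfg = NULL,
                       overlap_sizes = NULL) {
  scale <- match.arg(scale)
  if (is.null(cohort)) {
    cohort <- if (scale == "reduced") {
      reduced_cohort_config(seed = seed)
    } else {
      cohort_config(seed = seed)
    }
  }
  if (is.null(overlap_cfg)) {
    overlap_cfg <- if (scale == "reduced") {
      overlap_config(start_size = 10L, step = 50L, mc_samples = 2000,
                     seed = seed)
    } else {
      overlap_config(seed = seed)
    }
  }
  structure(list(outdir = outdir, seed = seed, scale = scale,
                 cohort = cohort, train_cycles = as.integer(train_cycles),
                 event_cfg = event_cfg, outlier_cfg = outlier_cfg,
                 lrp_cfg = lrp_cfg, overlap_cfg = overlap_cfg,
                 overlap_sizes = overlap_sizes),
            class = "run_config")
}

#' Run the complete analysis pipeline
#'
#' Sequences the full analysis on a synthetic cohort and persists every
#' intermediate artifact as CSV/JSON under `config$outdir`: the scaled
#' cycle matrix, outlier report, accuracy report, ranked relevance,
#' overlap curves and variable profiles, plus a manifest with seeds,
#' stage counts and per-file MD5 checksums. Re-running with the same
#' config reproduces all numeric outputs.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, scale = config$scale,
                   stages = list(), files = list())
  t0 <- Sys.time()

  cohort <- synthesize_cohort(config$cohort)
  prep <- preprocess_cohort(cohort, config$event_cfg, config$outlier_cfg)
  mat <- prep$matrix
  info <- attr(mat, "info")
  manifest$stages$preprocess <- list(
    n_cycles_segmented = sum(prep$report$n_total),
    n_removed = sum(prep$report$n_removed),
    n_retained = nrow(mat), n_variables = ncol(mat))
  write_matrix_csv(mat, file.path(config$outdir, "cycles.csv"))
  utils::write.csv(prep$report,
                   file.path(config$outdir, "outlier_report.csv"),
                   row.names = FALSE)

  train_idx <- sample_training_cycles(info, config$train_cycles,
                                      seed = config$seed,
                                      trials = c("CR", "WR"))
  fit <- gait_mlp(mat[train_idx, , drop = FALSE],
                  info$participant[train_idx], seed = config$seed)
  test_rows <- which(info$trial == "TR")
  pred <- predict(fit, mat[test_rows, , drop = FALSE])
  acc <- accuracy_by_participant(pred, info$participant[test_rows])
  manifest$stages$classifier <- list(
    n_train = length(train_idx), n_test = length(test_rows),
    epochs = if (nrow(fit$log)) max(fit$log$epoch) else 0L,
    overall_accuracy = acc$overall)
  utils::write.csv(acc$per_participant,
                   file.path(config$outdir, "accuracy.csv"),
                   row.names = FALSE)

  correct <- test_rows[as.character(pred) == info$participant[test_rows]]
  raw <- relevance(fit, mat[correct, , drop = FALSE],
                   info$participant[correct], config$lrp_cfg)
  n_tp <- ncol(mat) / (length(prep$joints) * 3L)
  sm <- smooth_relevance(raw, n_tp, config$lrp_cfg)
  agg <- aggregate_relevance(sm, info$participant[correct])
  desc <- variable_descriptors(prep$joints, n_tp)
  ranked <- rank_variables(agg$overall, desc)
  manifest$stages$relevance <- list(n_patterns = nrow(raw))
  utils::write.csv(ranked, file.path(config$outdir, "ranked_variables.csv"),
                   row.names = FALSE)

  ocfg <- config$overlap_cfg
  if (!is.null(config$overlap_sizes)) {
    sizes <- config$overlap_sizes
  } else {
    sizes <- overlap_schedule(ocfg, ncol(mat))
  }
  curve <- do.call(rbind, lapply(sizes, function(s) {
    cfg <- ocfg; cfg$start_size <- as.integer(s); cfg$end_size <- as.integer(s)
    overlap_curve(mat[test_rows, , drop = FALSE],
                  info$participant[test_rows], ranked, cfg)
  }))
  utils::write.csv(curve, file.path(config$outdir, "overlap_curve.csv"),
                   row.names = FALSE)
  manifest$stages$overlap <- list(sizes = sizes)

  prof <- profile_variables(ranked)
  prof_df <- rbind(
    data.frame(direction = "most", stratum = names(prof$most$by_movement),
               fraction = as.numeric(prof$most$by_movement)),
    data.frame(direction = "least", stratum = names(prof$least$by_movement),
               fraction = as.numeric(prof$least$by_movement)),
    data.frame(direction = "most", stratum = names(prof$most$by_group),
               fraction = as.numeric(prof$most$by_group)),
    data.frame(direction = "least", stratum = names(prof$least$by_group),
               fraction = as.numeric(prof$least$by_group)))
  utils::write.csv(prof_df, file.path(config$outdir, "variable_profile.csv"),
                   row.names = FALSE)
  manifest$stages$profile <- list(k = prof$k)

  files <- list.files(config$outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- lapply(files, function(f) {
    list(name = basename(f), md5 = unname(tools::md5sum(f)))
  })
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Verify that persisted artifacts reload intact
#'
#' Re-checksums every file recorded in a run's manifest and re-parses the
#' CSV/JSON artifacts.
#'
#' @param outdir a completed run directory.
#' @return data.frame (file, ok); an error if the directory holds no
#'   manifest.
#' @export
validate_io_roundtrip <- function(outdir) {
  mpath <- file.path(outdir, "manifest.json")
  if (!file.exists(mpath)) stop("no artifacts: manifest.json missing",
                                call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  out <- data.frame(file = character(0), ok = logical(0))
  for (f in manifest$files) {
    path <- file.path(outdir, f$name)
    ok <- file.exists(path) && unname(tools::md5sum(path)) == f$md5
    if (ok && grepl("\\.csv$", f$name) && !grepl("^cycles", f$name)) {
      ok <- tryCatch({
        utils::read.csv(path); TRUE
      }, error = function(e) FALSE)
    }
    out <- rbind(out, data.frame(file = f$name, ok = ok))
  }
  out
}
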