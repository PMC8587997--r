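# Shared fixtures, built once per test run. All synthetic, all seeded.

.fixture_env <- new.env(parent = emptyenv())

# Small 3-participant cohort used across module tests.
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- reduced_cohort_config(n_participants = 3, trial_duration = 8,
                                 seed = 11)
    .fixture_env$small <- list(config = cfg, cohort = synthesize_cohort(cfg))
  }
  .fixture_env$small
}

# The small cohort run through segmentation/preprocessing.
small_prep <- function() {
  if (is.null(.fixture_env$small_prep)) {
    fx <- small_cohort()
    .fixture_env$small_prep <-
      suppressWarnings(preprocess_cohort(fx$cohort))
  }
  .fixture_env$small_prep
}

# The default 20-participant reduced-dimensionality cohort with its
# preprocessed matrix, fitted networks (5 and 10 training cycles per
# participant) and the relevance ranking of the 10-cycle fit. Built once
# and shared by the acceptance criteria.
acceptance_fixture <- function() {
  if (is.null(.fixture_env$acceptance)) {
    cfg <- reduced_cohort_config(seed = 1)
    cohort <- synthesize_cohort(cfg)
    prep <- suppressWarnings(preprocess_cohort(cohort))
    mat <- prep$matrix
    info <- attr(mat, "info")
    test_rows <- which(info$trial == "TR")
    fit_n <- function(n_train) {
      idx <- sample_training_cycles(info, n_train, seed = 1,
                                    trials = c("CR", "WR"))
      fit <- gait_mlp(mat[idx, , drop = FALSE], info$participant[idx],
                      seed = 1)
      pred <- predict(fit, mat[test_rows, , drop = FALSE])
      list(fit = fit, pred = pred,
           accuracy = accuracy_by_participant(
             pred, info$participant[test_rows])$overall)
    }
    f5 <- fit_n(5L)
    f10 <- fit_n(10L)
    correct <- test_rows[as.character(f10$pred) ==
                           info$participant[test_rows]]
    raw <- relevance(f10$fit, mat[correct, , drop = FALSE],
                     info$participant[correct])
    sm <- smooth_relevance(raw, 100)
    agg <- aggregate_relevance(sm, info$participant[correct])
    ranked <- rank_variables(agg$overall,
                             variable_descriptors(cfg$joints, 100))
    .fixture_env$acceptance <- list(
      config = cfg, cohort = cohort, matrix = mat, info = info,
      test_rows = test_rows, fit5 = f5, fit10 = f10,
      correct_rows = correct, raw_relevance = raw, ranked = ranked)
  }
  .fixture_env$acceptance
}

# Independent brute-force LoOP oracle, written directly from the
# published construction with plain loops (kept deliberately separate
# from the package implementation).
loop_bruteforce <- function(points, k, lambda = 3) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  nn <- vector("list", n)
  pdist <- numeric(n)
  for (i in seq_len(n)) {
    ds <- vapply(seq_len(n), function(j) d(i, j), 0)
    ord <- order(ds, seq_len(n))
    ord <- ord[ord != i]
    nn[[i]] <- ord[seq_len(k)]
    pdist[i] <- lambda * sqrt(sum(ds[nn[[i]]]^2) / k)
  }
  plof <- numeric(n)
  for (i in seq_len(n)) {
    ev <- mean(pdist[nn[[i]]])
    plof[i] <- if (ev == 0 && pdist[i] == 0) 0 else pdist[i] / ev - 1
  }
  nplof <- lambda * sqrt(mean(plof^2))
  if (nplof == 0) return(rep(0, n))
  vapply(plof, function(z) {
    max(0, 2 * stats::pnorm(z / (nplof * sqrt(2)) * sqrt(2)) - 1)
  }, 0)
}

# Tiny hand-built raw trial for event-detection edge cases.
flat_trial <- function(height = 0.5, n = 1200, fs = 240) {
  structure(list(
    participant_id = "T1", trial_label = "CR",
    time = (seq_len(n) - 1) / fs, sampling_rate = fs,
    angles = array(0, dim = c(n, 1, 3),
                   dimnames = list(NULL, "L5S1", plane_names())),
    foot_height_left = rep(height, n), foot_height_right = rep(height, n),
    toe_height_left = rep(height, n), toe_height_right = rep(height, n),
    true_events = data.frame()
  ), class = "raw_trial")
}
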