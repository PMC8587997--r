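# Quantifying unique vs generic movement characteristics: step cycles
# restricted to the k most/least relevant variables are projected onto
# their first three principal axes; each participant's cloud is bounded
# by an alpha shape and pairwise volume overlaps are expressed as a
# percentage of the reference participant's volume.

#' Subspace-overlap configuration
#'
#' @param start_size number of variables in the first iteration.
#' @param step increment of the variable count per iteration.
#' @param end_size last size (defaults to all variables at run time).
#' @param n_components principal axes of the projection (3).
#' @param mc_samples Monte-Carlo samples per overlap estimate.
#' @param seed integer seed for the Monte-Carlo draws.
#' @return Object of class `overlap_config`.
#' @export
overlap_config <- function(start_size = 10L, step = 5L, end_size = NULL,
                           n_components = 3L, mc_samples = 1e5,
                           seed = 1L) {
  if (start_size < n_components + 1) {
    stop("start_size must be at least n_components + 1", call. = FALSE)
  }
  if (step < 1) stop("step must be >= 1", call. = FALSE)
  structure(list(start_size = as.integer(start_size),
                 step = as.integer(step),
                 end_size = if (is.null(end_size)) NULL else as.integer(end_size),
                 n_components = as.integer(n_components),
                 mc_samples = mc_samples, seed = seed),
            class = "overlap_config")
}

#' Variable sizes of the iterative subsetting schedule
#' @param config an [overlap_config()].
#' @param total total number of ranked variables.
#' @return Integer vector `start, start+step, ...` capped at the end
#'   size; the full default schedule on 5400 variables has 1079 sizes.
#' @export
overlap_schedule <- function(config, total) {
  end <- if (is.null(config$end_size)) total else min(config$end_size, total)
  seq.int(config$start_size, end, by = config$step)
}

#' Select the k most or least relevant variables
#'
#' @param ranked ranking from [rank_variables()].
#' @param k subset size (1..total).
#' @param direction "most_relevant" or "least_relevant".
#' @return Integer flat indices (1-based) of the selected variables.
#' @export
select_subset <- function(ranked, k,
                          direction = c("most_relevant", "least_relevant")) {
  direction <- match.arg(direction)
  total <- nrow(ranked)
  if (k < 1 || k > total) stop("k out of range", call. = FALSE)
  if (direction == "most_relevant") {
    ranked$flat_index[seq_len(k)]
  } else {
    # lowest scores; ties resolved by ascending flat index
    ord <- order(ranked$score, ranked$flat_index)
    ranked$flat_index[ord[seq_len(k)]]
  }
}

#' Project step cycles onto their first three principal axes
#'
#' Mean-centered PCA of the cycle matrix restricted to a variable
#' subset; returns the scores on the three leading orthonormal axes.
#'
#' @param mat matrix cycles x variables (already restricted).
#' @param n_components number of axes (default 3).
#' @return Scores matrix n x n_components with the per-axis explained
#'   variance fraction as attribute `"explained"`.
#' @export
pca3_project <- function(mat, n_components = 3L) {
  mat <- as.matrix(mat)
  if (nrow(mat) < n_components + 1) stop("too few cycles", call. = FALSE)
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < n_components ||
      pc$sdev[n_components] < 1e-10 * pc$sdev[1]) {
    stop("degenerate subspace: data rank below ", n_components,
         call. = FALSE)
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  attr(scores, "explained") <-
    (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  scores
}

# Mean and SEM of all ordered-pair overlaps for one projection.
pairwise_overlaps <- function(scores, participants, mc_samples, seed) {
  parts <- unique(participants)
  shapes <- lapply(parts, function(p) {
    alpha_shape3d(scores[participants == p, , drop = FALSE])
  })
  names(shapes) <- parts
  vals <- c()
  with_seed(seed, {
    for (a in parts) {
      for (b in setdiff(parts, a)) {
        vals <- c(vals, pairwise_overlap_percent(shapes[[a]], shapes[[b]],
                                                 mc_samples))
      }
    }
  })
  c(mean = mean(vals), sem = stats::sd(vals) / sqrt(length(vals)),
    n_pairs = length(vals))
}

#' Overlap of participants' movement patterns vs subspace size
#'
#' For every size in the schedule the ranked variables are subset in the
#' requested direction, cycles are projected onto the first three
#' principal axes of the subset, per-participant alpha-shape volumes are
#' built, and the mean (with SEM) of all ordered pairwise overlap
#' percentages is recorded. A failure at one size (e.g. a degenerate
#' subspace) is recorded as missing and the run continues.
#'
#' @param mat scaled cycle matrix (typically the held-out trial).
#' @param participants participant label per row of `mat`.
#' @param ranked ranking from [rank_variables()].
#' @param config an [overlap_config()].
#' @param directions one or both of "most_relevant", "least_relevant".
#' @return data.frame: size, direction, mean_overlap, sem_overlap,
#'   n_pairs.
#' @export
overlap_curve <- function(mat, participants, ranked,
                          config = overlap_config(),
                          directions = c("most_relevant",
                                         "least_relevant")) {
  stopifnot(nrow(mat) == length(participants),
            nrow(ranked) == ncol(mat))
  sizes <- overlap_schedule(config, ncol(mat))
  out <- expand.grid(size = sizes, direction = directions,
                     stringsAsFactors = FALSE)
  out$mean_overlap <- NA_real_
  out$sem_overlap <- NA_real_
  out$n_pairs <- NA_integer_
  for (r in seq_len(nrow(out))) {
    res <- tryCatch({
      idx <- select_subset(ranked, out$size[r], out$direction[r])
      scores <- pca3_project(mat[, idx, drop = FALSE],
                             config$n_components)
      pairwise_overlaps(scores, participants, config$mc_samples,
                        config$seed + out$size[r])
    }, error = function(e) {
      warning("size ", out$size[r], " (", out$direction[r], ") skipped: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      out$mean_overlap[r] <- res[["mean"]]
      out$sem_overlap[r] <- res[["sem"]]
      out$n_pairs[r] <- res[["n_pairs"]]
    }
  }
  out
}

#' Profile the extreme 10% of ranked variables
#'
#' Stratifies the k most and least relevant variables (k defaults to 10%
#' of the total, 540 at full scale) by movement type
#' (flexion/extension, ab-/adduction, internal/external rotation), by
#' cycle timepoint (optionally smoothed with a 5-point moving average)
#' and by joint group (spine, upper, lower extremities).
#'
#' @param ranked ranking from [rank_variables()] including descriptor
#'   columns (pass `descriptors` to [rank_variables()]).
#' @param k subset size; default `floor(0.10 * total)`.
#' @param smooth_time apply the 5-point moving average to the timepoint
#'   histogram.
#' @return List with one element per direction, each containing
#'   `by_movement` and `by_group` (fractions summing to 1) and `by_time`
#'   (counts per timepoint).
#' @export
profile_variables <- function(ranked, k = NULL, smooth_time = TRUE) {
  stopifnot(all(c("plane", "timepoint", "group") %in% names(ranked)))
  total <- nrow(ranked)
  if (is.null(k)) k <- floor(0.10 * total)
  tps <- sort(unique(ranked$timepoint))
  strat <- function(idx) {
    sub <- ranked[idx, ]
    movement <- c(flexion = "flexion/extension",
                  abduction = "ab-/adduction",
                  rotation = "int/ext rotation")
    by_movement <- as.numeric(table(factor(sub$plane, names(movement)))) / k
    names(by_movement) <- movement
    counts <- as.numeric(table(factor(sub$timepoint, tps)))
    if (smooth_time) counts <- stats::filter(counts, rep(1 / 5, 5), sides = 2)
    by_group <- as.numeric(table(factor(sub$group,
                                        c("spine", "upper", "lower")))) / k
    names(by_group) <- c("spine", "upper", "lower")
    list(by_movement = by_movement,
         by_time = data.frame(timepoint = tps, count = as.numeric(counts)),
         by_group = by_group)
  }
  ord_least <- order(ranked$score, ranked$flat_index)
  list(most = strat(seq_len(k)), least = strat(ord_least[seq_len(k)]),
       k = k)
}
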