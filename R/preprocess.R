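# Per-participant outlier removal on 3-PC loadings via local outlier
# probabilities (LoOP), per-cycle scaling into [-1, 1], and assembly of
# the analysis matrix.

#' Outlier-detection configuration
#'
#' @param n_components principal components retained before outlier
#'   scoring (fixed at 3 in the analysis).
#' @param k_neighbors neighborhood size of the LoOP statistic.
#' @param lambda scale factor of the LoOP statistic.
#' @param probability_cutoff cycles with outlier probability above this
#'   value are removed.
#' @return Object of class `outlier_config`.
#' @export
outlier_config <- function(n_components = 3L, k_neighbors = 20L,
                           lambda = 3, probability_cutoff = 0.5) {
  if (probability_cutoff <= 0 || probability_cutoff > 1) {
    stop("probability_cutoff must be in (0, 1]", call. = FALSE)
  }
  if (k_neighbors < 2) stop("k_neighbors must be >= 2", call. = FALSE)
  structure(list(n_components = as.integer(n_components),
                 k_neighbors = as.integer(k_neighbors), lambda = lambda,
                 probability_cutoff = probability_cutoff),
            class = "outlier_config")
}

#' Local outlier probabilities (LoOP)
#'
#' Density-based outlier scores in \[0, 1\]: for each point the
#' probabilistic set distance over its k nearest neighbours defines a
#' local density estimate; the probabilistic local outlier factor (PLOF)
#' compares it with the neighbours' densities, is normalised by the
#' aggregate nPLOF, and squashed through the Gaussian error function.
#'
#' @param points numeric matrix (n x d), here 3-PC loadings.
#' @param k_neighbors neighbourhood size (n must exceed it).
#' @param lambda scale factor (3 corresponds to a three-sigma rule).
#' @return Numeric vector of n probabilities in \[0, 1\].
#' @export
loop_outlier_probabilities <- function(points, k_neighbors = 20L,
                                       lambda = 3) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= k_neighbors) {
    stop("invalid config: need more points than k_neighbors", call. = FALSE)
  }
  dm <- as.matrix(stats::dist(points))
  # k nearest neighbours, self excluded; ties resolved by ascending index
  nn <- matrix(0L, n, k_neighbors)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ], seq_len(n))
    nn[i, ] <- setdiff(ord, i)[seq_len(k_neighbors)]
  }
  sigma <- sqrt(vapply(seq_len(n),
                       function(i) mean(dm[i, nn[i, ]]^2), 0))
  pdist <- lambda * sigma
  expected <- vapply(seq_len(n), function(i) mean(pdist[nn[i, ]]), 0)
  plof <- ifelse(expected == 0,
                 ifelse(pdist == 0, 0, Inf),
                 pdist / expected - 1)
  plof[!is.finite(plof)] <- max(plof[is.finite(plof)], 0)
  nplof <- lambda * sqrt(mean(plof^2))
  if (nplof == 0) return(rep(0, n))
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  pmax(0, erf(plof / (nplof * sqrt(2))))
}

#' Remove outlier step cycles participant by participant
#'
#' For one participant at a time, cycles are projected onto their first
#' three principal axes (mean-centered, unscaled) and LoOP probabilities
#' computed on the loadings; cycles above the probability cutoff are
#' dropped. Participants with too few cycles for the neighbourhood size
#' are kept unfiltered with a warning.
#'
#' @param cycles matrix of step cycles (rows) x variables.
#' @param info data.frame aligned with the rows; must have a
#'   `participant` column.
#' @param config an [outlier_config()].
#' @return List with filtered `cycles`, `info`, and a `report`
#'   data.frame (participant, n_total, n_removed).
#' @export
filter_outliers <- function(cycles, info, config = outlier_config()) {
  stopifnot(nrow(cycles) == nrow(info))
  keep <- rep(TRUE, nrow(cycles))
  parts <- unique(info$participant)
  report <- data.frame(participant = parts, n_total = 0L, n_removed = 0L,
                       stringsAsFactors = FALSE)
  for (j in seq_along(parts)) {
    rows <- which(info$participant == parts[j])
    report$n_total[j] <- length(rows)
    if (length(rows) <= config$k_neighbors) {
      warning("participant ", parts[j],
              " has too few cycles for outlier detection; kept unfiltered")
      next
    }
    sc <- stats::prcomp(cycles[rows, , drop = FALSE], center = TRUE,
                        scale. = FALSE, rank. = config$n_components)$x
    prob <- loop_outlier_probabilities(sc, config$k_neighbors, config$lambda)
    drop <- prob > config$probability_cutoff
    keep[rows[drop]] <- FALSE
    report$n_removed[j] <- sum(drop)
  }
  list(cycles = cycles[keep, , drop = FALSE],
       info = info[keep, , drop = FALSE], report = report)
}

#' Scale one step cycle into \[-1, 1\]
#'
#' The cycle's variables are z-scored with the cycle's own mean and
#' standard deviation, then divided by the maximum absolute z so the
#' extreme value touches -1 or +1. The transform is invariant to affine
#' maps of the input and idempotent.
#'
#' @param x numeric vector (one flattened cycle).
#' @return Numeric vector of the same length with values in \[-1, 1\].
#' @export
scale_cycle <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate cycle: zero variance", call. = FALSE)
  }
  z <- (x - mean(x)) / s
  z / max(abs(z))
}

#' Row-wise [scale_cycle()] over a cycle matrix
#' @param cycles matrix of step cycles (rows) x variables.
#' @return Matrix of the same shape with every row in \[-1, 1\].
#' @export
scale_cycles <- function(cycles) {
  m <- rowMeans(cycles)
  s <- sqrt(rowSums((cycles - m)^2) / (ncol(cycles) - 1))
  if (any(s == 0)) stop("degenerate cycle: zero variance", call. = FALSE)
  z <- (cycles - m) / s
  z / apply(abs(z), 1L, max)
}

#' Assemble the analysis data matrix
#'
#' Stacks scaled step cycles of all participants in a deterministic row
#' order (participant, trial, cycle onset) and attaches the row index as
#' an attribute. At the study's full scale this matrix is
#' 97,899 x 5400; synthetic cohorts are far smaller.
#'
#' @param cycles matrix rows x variables (uniform canonical layout).
#' @param info aligned row metadata with columns `participant`, `trial`,
#'   `onset_sample`.
#' @return The reordered matrix with attribute `"info"`.
#' @export
assemble_matrix <- function(cycles, info) {
  if (is.null(cycles) || nrow(cycles) == 0) {
    out <- matrix(numeric(0), nrow = 0, ncol = if (is.null(cycles)) 0 else ncol(cycles))
    attr(out, "info") <- info[0, , drop = FALSE]
    return(out)
  }
  stopifnot(nrow(cycles) == nrow(info))
  ord <- order(info$participant, info$trial, info$onset_sample)
  out <- cycles[ord, , drop = FALSE]
  attr(out, "info") <- `rownames<-`(info[ord, , drop = FALSE], NULL)
  out
}

#' Segment, filter, scale and assemble a whole synthetic cohort
#'
#' Convenience wrapper running [process_trial()] over every trial of a
#' cohort, per-participant outlier filtering, per-cycle scaling and
#' matrix assembly.
#'
#' @param cohort result of [synthesize_cohort()].
#' @param event_cfg an [event_config()].
#' @param outlier_cfg an [outlier_config()].
#' @param n_timepoints timepoints of the normalized cycles.
#' @return List with the scaled `matrix` (attribute "info"), the outlier
#'   `report` and the canonical `joints`.
#' @export
preprocess_cohort <- function(cohort, event_cfg = event_config(),
                              outlier_cfg = outlier_config(),
                              n_timepoints = 100L) {
  pieces <- list()
  for (p in names(cohort$trials)) {
    for (tl in names(cohort$trials[[p]])) {
      pieces[[length(pieces) + 1L]] <-
        process_trial(cohort$trials[[p]][[tl]], event_cfg, n_timepoints)
    }
  }
  cycles <- do.call(rbind, lapply(pieces, `[[`, "cycles"))
  info <- do.call(rbind, lapply(pieces, `[[`, "info"))
  filt <- filter_outliers(cycles, info, outlier_cfg)
  scaled <- scale_cycles(filt$cycles)
  list(matrix = assemble_matrix(scaled, filt$info), report = filt$report,
       joints = pieces[[1]]$joints)
}
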