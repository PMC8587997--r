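# Layer-wise relevance propagation for the identification network:
# epsilon-rule backward decomposition of a correctly classified cycle's
# output score onto the 5400 input variables, 25/50/25 within-trajectory
# smoothing applied twice, participant-wise averaging, rectification and
# max-normalization, and the descending importance ranking.

#' Relevance-propagation configuration
#'
#' @param epsilon stabilizer of the epsilon rule.
#' @param smoothing_weights 3-point kernel (previous, current, next);
#'   must sum to 1.
#' @param smoothing_passes number of kernel applications (default 2).
#' @return Object of class `lrp_config`.
#' @export
lrp_config <- function(epsilon = 1e-6,
                       smoothing_weights = c(0.25, 0.5, 0.25),
                       smoothing_passes = 2L) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (length(smoothing_weights) != 3 ||
      abs(sum(smoothing_weights) - 1) > 1e-12) {
    stop("smoothing weights must be 3 values summing to 1", call. = FALSE)
  }
  structure(list(epsilon = epsilon, smoothing_weights = smoothing_weights,
                 smoothing_passes = as.integer(smoothing_passes)),
            class = "lrp_config")
}

#' Generic relevance decomposition
#' @param object a fitted model.
#' @param ... passed to methods.
#' @export
relevance <- function(object, ...) UseMethod("relevance")

#' Epsilon-rule relevance for step cycles
#'
#' Redistributes the pre-softmax score of each cycle's target output node
#' backwards through the network:
#' \eqn{R_j = \sum_k a_j w_{jk} / (\sum_j a_j w_{jk} + \epsilon\,
#' \mathrm{sign}) \; R_k}. The tanh nonlinearity is absorbed into the
#' neuron, so relevance passes through it unchanged. For a centering
#' network (the [gait_mlp()] default) the input activations are the
#' mean-centered cycles, so relevance expresses how a cycle's deviation
#' from the cohort-average movement pattern produced the identification. Cycles must be
#' correctly classified (the decomposition explains the decision that was
#' actually made); passing a misclassified cycle is a contract violation.
#'
#' @param object a fitted [gait_mlp()].
#' @param x matrix of cycles x variables.
#' @param target true participant label per cycle.
#' @param config an [lrp_config()].
#' @param check_classified error on misclassified cycles (default TRUE).
#' @param ... unused.
#' @return Matrix cycles x variables of raw relevance scores, with the
#'   explained output score as attribute `"output_score"` (and, for a
#'   network with biases, the bias-absorbed relevance per layer as
#'   attribute `"bias_absorbed"`).
#' @export
relevance.gait_mlp <- function(object, x, target, config = lrp_config(),
                               check_classified = TRUE, ...) {
  x <- as.matrix(x)
  target <- as.character(target)
  stopifnot(length(target) == nrow(x))
  fw <- forward_mlp(object, x)
  # a centering network scores deviations from the training-mean cycle;
  # its relevance decomposes onto the same centered activations
  if (!is.null(object$center)) x <- sweep(x, 2L, object$center)
  kidx <- match(target, object$levels)
  if (anyNA(kidx)) stop("unknown target label", call. = FALSE)
  pred <- max.col(fw$scores, ties.method = "first")
  if (check_classified && any(pred != kidx)) {
    stop("contract violation: ", sum(pred != kidx),
         " cycle(s) not classified as their target", call. = FALSE)
  }
  eps <- config$epsilon
  stab <- function(z) z + eps * ifelse(z >= 0, 1, -1)

  n <- nrow(x)
  s_target <- fw$scores[cbind(seq_len(n), kidx)]
  r_out <- matrix(0, n, length(object$levels))
  r_out[cbind(seq_len(n), kidx)] <- s_target

  z2 <- fw$scores
  ratio2 <- r_out / stab(z2)
  r_hidden <- fw$hidden * (ratio2 %*% t(object$W2))
  z1 <- x %*% object$W1
  if (isTRUE(object$config$use_bias)) z1 <- sweep(z1, 2L, object$b1, "+")
  ratio1 <- r_hidden / stab(z1)
  r_in <- x * (ratio1 %*% t(object$W1))

  attr(r_in, "output_score") <- s_target
  if (isTRUE(object$config$use_bias)) {
    # share of relevance absorbed by bias terms (and the stabilizer)
    attr(r_in, "bias_absorbed") <- cbind(
      layer2 = rowSums(r_out) - rowSums(r_hidden),
      layer1 = rowSums(r_hidden) - rowSums(r_in)
    )
  }
  r_in
}

#' Smooth relevance patterns along the cycle time axis
#'
#' Applies the (0.25, 0.5, 0.25) kernel along the timepoint axis within
#' each joint/plane trajectory independently (never across trajectory
#' boundaries), `smoothing_passes` times. Neighbouring timepoints carry
#' dependent information, so the smoothing damps sample-to-sample
#' fluctuations without moving the overall pattern. At the trajectory
#' edges the truncated kernel is renormalized (2/3, 1/3).
#'
#' @param patterns matrix patterns x variables (or a single vector) in
#'   the canonical layout.
#' @param n_timepoints timepoints per trajectory.
#' @param config an [lrp_config()].
#' @return Smoothed patterns, same shape as the input.
#' @export
smooth_relevance <- function(patterns, n_timepoints = 100L,
                             config = lrp_config()) {
  vec <- is.null(dim(patterns))
  m <- if (vec) matrix(patterns, nrow = 1) else as.matrix(patterns)
  if (ncol(m) %% n_timepoints != 0) {
    stop("pattern length is not a multiple of n_timepoints", call. = FALSE)
  }
  w <- config$smoothing_weights
  # arrange as timepoints x (trajectory * pattern) and convolve columns
  a <- matrix(t(m), nrow = n_timepoints)
  for (pass in seq_len(config$smoothing_passes)) {
    up <- rbind(a[-1, , drop = FALSE], 0)
    down <- rbind(0, a[-n_timepoints, , drop = FALSE])
    num <- w[1] * down + w[2] * a + w[3] * up
    norm <- rep(1, n_timepoints)
    norm[1] <- w[2] + w[3]
    norm[n_timepoints] <- w[1] + w[2]
    a <- num / norm
  }
  out <- t(matrix(a, ncol = nrow(m)))
  if (vec) drop(out) else `dimnames<-`(out, dimnames(m))
}

#' Aggregate relevance patterns into participant and overall patterns
#'
#' Smoothed patterns are averaged participant-wise, rectified (absolute
#' value) and normalized to their maximum, expressing every variable's
#' relevance relative to the participant's most relevant variable. The
#' overall pattern is the mean of the participant patterns, again
#' max-normalized.
#'
#' @param patterns matrix patterns x variables (smoothed stage).
#' @param participants participant label per pattern row.
#' @return List with `participant_patterns` (participants x variables,
#'   values in \[0, 1\]) and `overall` (vector, max exactly 1).
#' @export
aggregate_relevance <- function(patterns, participants) {
  patterns <- as.matrix(patterns)
  stopifnot(nrow(patterns) == length(participants))
  parts <- unique(as.character(participants))
  pm <- matrix(NA_real_, length(parts), ncol(patterns),
               dimnames = list(parts, colnames(patterns)))
  for (p in parts) {
    rows <- which(participants == p)
    mu <- abs(colMeans(patterns[rows, , drop = FALSE]))
    pm[p, ] <- mu / max(mu)
  }
  overall <- colMeans(pm)
  overall <- overall / max(overall)
  list(participant_patterns = pm, overall = overall)
}

#' Rank variables by overall relevance
#'
#' Stable descending sort of the overall relevance pattern; ties are
#' broken by ascending flat index so the ranking is reproducible.
#'
#' @param overall numeric vector of overall (max-normalized) relevance.
#' @param descriptors optional [variable_descriptors()] table to join.
#' @return data.frame with columns `rank`, `flat_index`, `score` and,
#'   when descriptors are given, `joint`, `plane`, `timepoint`, `group`.
#' @export
rank_variables <- function(overall, descriptors = NULL) {
  ord <- order(-overall, seq_along(overall))
  out <- data.frame(rank = seq_along(overall), flat_index = ord,
                    score = overall[ord])
  if (!is.null(descriptors)) {
    stopifnot(nrow(descriptors) == length(overall))
    out <- cbind(out, descriptors[ord, c("joint", "plane", "timepoint",
                                         "group")])
    rownames(out) <- NULL
  }
  out
}
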