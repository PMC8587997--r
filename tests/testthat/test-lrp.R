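fit_small_net <- function() {
  set.seed(8)
  p <- 12; k <- 3; n_per <- 25
  centers <- matrix(rnorm(k * p, sd = 3), k, p)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * p), n_per, p), 2, centers[i, ], "+")
  }))
  labels <- factor(rep(paste0("S", seq_len(k)), each = n_per))
  list(fit = gait_mlp(x, labels, epochs = 200, seed = 2),
       x = x, labels = labels)
}

test_that("relevance is conserved through a bias-free network", {
  net <- fit_small_net()
  r <- relevance(net$fit, net$x, net$labels)
  score <- attr(r, "output_score")
  # total input relevance equals the explained pre-softmax score
  expect_equal(rowSums(r), score, tolerance = 1e-4)
  s <- predict(net$fit, net$x, type = "score")
  expect_equal(score, s[cbind(seq_len(nrow(s)),
                              as.integer(net$labels))],
               tolerance = 1e-12)
})

test_that("relevance matches the closed form for a single linear path", {
  # 2 inputs -> 1 hidden -> 2 outputs with tiny weights keeps tanh ~ id;
  # relevance of input j must be a_j w_j1 / z * R with z the hidden input
  W1 <- matrix(c(0.003, 0.001), 2, 1)
  W2 <- matrix(c(0.5, -0.5), 1, 2)
  obj <- structure(list(W1 = W1, W2 = W2, levels = c("A", "B"),
                        config = list(input_nodes = 2, use_bias = FALSE)),
                   class = "gait_mlp")
  x <- matrix(c(2, 4), 1, 2)
  # a tiny stabilizer keeps the epsilon absorption negligible here
  # (the default 1e-6 is not small against z ~ 1e-2)
  r <- relevance(obj, x, "A", config = lrp_config(epsilon = 1e-12),
                 check_classified = FALSE)
  z <- drop(x %*% W1)
  score <- tanh(z) * W2[1, 1]
  expect_equal(as.numeric(r),
               as.numeric(x * t(W1) / z * score), tolerance = 1e-3)
  expect_equal(sum(r), score, tolerance = 1e-6)
})

test_that("misclassified cycles violate the relevance contract", {
  net <- fit_small_net()
  wrong <- as.character(net$labels)
  wrong[1] <- setdiff(levels(net$labels), wrong[1])[1]
  expect_error(relevance(net$fit, net$x, wrong), "contract violation")
  r <- relevance(net$fit, net$x, wrong, check_classified = FALSE)
  expect_equal(dim(r), dim(net$x))
  expect_error(relevance(net$fit, net$x, rep("nope", nrow(net$x))),
               "unknown target")
})

test_that("smoothing matches a direct per-trajectory convolution", {
  set.seed(6)
  n_tp <- 10
  pat <- matrix(rnorm(2 * 3 * n_tp), nrow = 2)  # 2 patterns, 3 trajectories
  ref_once <- function(v) {
    out <- numeric(n_tp)
    for (t in seq_len(n_tp)) {
      lo <- max(1, t - 1); hi <- min(n_tp, t + 1)
      w <- c(0.25, 0.5, 0.25)[(lo:hi) - t + 2]
      out[t] <- sum(w * v[lo:hi]) / sum(w)
    }
    out
  }
  expected <- pat
  for (r in 1:2) {
    for (tr in 0:2) {
      cols <- tr * n_tp + seq_len(n_tp)
      expected[r, cols] <- ref_once(ref_once(pat[r, cols]))
    }
  }
  expect_equal(smooth_relevance(pat, n_tp), expected, tolerance = 1e-12)
  # edge weights renormalize: a constant pattern is a fixed point
  expect_equal(smooth_relevance(rep(2, 30), n_tp), rep(2, 30))
  # a unit impulse keeps its mass in the interior
  imp <- numeric(n_tp); imp[5] <- 1
  expect_equal(sum(smooth_relevance(imp, n_tp)), 1, tolerance = 1e-12)
  expect_error(smooth_relevance(rep(1, 7), 10), "multiple")
})

test_that("smoothing never mixes adjacent trajectories", {
  n_tp <- 10
  pat <- c(rep(1, n_tp), rep(0, n_tp))
  out <- smooth_relevance(pat, n_tp)
  expect_equal(out[1:n_tp], rep(1, n_tp))
  expect_equal(out[n_tp + 1:n_tp], rep(0, n_tp))
})

test_that("aggregation rectifies, max-normalizes and averages", {
  pat <- rbind(c(2, -4, 0, 1), c(0, -4, 2, 1),   # participant A
               c(1, 1, -2, 0))                   # participant B
  agg <- aggregate_relevance(pat, c("A", "A", "B"))
  expect_equal(unname(agg$participant_patterns["A", ]),
               c(1, 4, 1, 1) / 4)
  expect_equal(unname(agg$participant_patterns["B", ]),
               c(0.5, 0.5, 1, 0))
  expect_equal(max(agg$overall), 1)
  expect_equal(unname(agg$overall),
               (c(1, 4, 1, 1) / 4 + c(0.5, 0.5, 1, 0)) / 2 / 0.75)
})

test_that("variable ranking is descending and stable under ties", {
  overall <- c(0.2, 0.9, 0.9, 0.1)
  rk <- rank_variables(overall)
  expect_equal(rk$flat_index, c(2, 3, 1, 4))
  expect_equal(rk$score, c(0.9, 0.9, 0.2, 0.1))
  d <- variable_descriptors(c("L5S1", "T9T8"), n_timepoints = 100)
  rk2 <- rank_variables(runif(nrow(d)), d)
  expect_equal(names(rk2), c("rank", "flat_index", "score", "joint",
                             "plane", "timepoint", "group"))
  expect_equal(d$joint[rk2$flat_index], rk2$joint)
})
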