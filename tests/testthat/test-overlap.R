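test_that("the subsetting schedule steps from start to the total", {
  cfg <- overlap_config(start_size = 10, step = 5)
  s <- overlap_schedule(cfg, 5400)
  expect_equal(s[1:3], c(10, 15, 20))
  expect_equal(length(s), 1079)
  expect_equal(s[length(s)], 5400)
  expect_equal(overlap_schedule(overlap_config(end_size = 30), 5400),
               c(10, 15, 20, 25, 30))
  expect_error(overlap_config(start_size = 3), "n_components")
})

test_that("subset selection honours rank order in both directions", {
  overall <- c(0.5, 1.0, 0.2, 0.2, 0.9)
  rk <- rank_variables(overall)
  expect_equal(select_subset(rk, 2, "most_relevant"), c(2, 5))
  expect_equal(select_subset(rk, 2, "least_relevant"), c(3, 4))
  expect_equal(sort(select_subset(rk, 5, "most_relevant")), 1:5)
  expect_error(select_subset(rk, 6), "out of range")
})

test_that("PCA projection returns three orthogonal axes of max variance", {
  set.seed(4)
  latent <- matrix(rnorm(100 * 3), ncol = 3) %*% diag(c(5, 2, 1))
  load <- matrix(rnorm(3 * 20), 3, 20)
  mat <- latent %*% load + matrix(rnorm(100 * 20, sd = 0.01), 100, 20)
  sc <- pca3_project(mat)
  expect_equal(dim(sc), c(100, 3))
  expect_equal(unname(colMeans(sc)), rep(0, 3), tolerance = 1e-10)
  cv <- crossprod(sc) / 99
  expect_equal(cv[upper.tri(cv)], rep(0, 3), tolerance = 1e-8)
  expect_true(all(diff(diag(cv)) < 0))        # variance-ordered
  expect_gt(sum(attr(sc, "explained")), 0.99) # 3 latent dims dominate
  # rank-2 data cannot support a 3-axis projection
  flat <- cbind(mat[, 1], mat[, 1] * 2, mat[, 1] - 1)
  expect_error(pca3_project(flat), "degenerate subspace")
  expect_error(pca3_project(mat[1:3, ]), "too few cycles")
})

test_that("overlap declines when moving from generic to unique variables", {
  set.seed(31)
  n_per <- 40; k <- 3
  # variables 1..10 are identical across participants (generic), 11..20
  # carry strongly participant-specific structure (unique)
  shared <- matrix(rnorm(n_per * k * 10), n_per * k, 10)
  unique_part <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * 10, sd = 0.3), n_per, 10), 2,
          rnorm(10, sd = 4 * i), "+")
  }))
  mat <- cbind(unique_part, shared)
  participants <- rep(paste0("P", seq_len(k)), each = n_per)
  overall <- c(rep(1, 10), rep(0.1, 10))  # unique vars ranked most relevant
  rk <- rank_variables(overall)
  cfg <- overlap_config(start_size = 10, step = 10, mc_samples = 4000,
                        seed = 2)
  cur <- overlap_curve(mat, participants, rk, cfg)
  most10 <- cur$mean_overlap[cur$size == 10 &
                               cur$direction == "most_relevant"]
  least10 <- cur$mean_overlap[cur$size == 10 &
                                cur$direction == "least_relevant"]
  # separated clouds barely overlap; shared ones overlap heavily
  expect_lt(most10, 25)
  expect_gt(least10, 45)
  expect_gt(least10, most10 + 30)
  # at the full size both directions use all variables: identical subsets
  full <- cur[cur$size == 20, ]
  expect_equal(full$mean_overlap[1], full$mean_overlap[2])
  expect_true(all(cur$n_pairs == k * (k - 1)))
  expect_true(all(cur$sem_overlap >= 0))
})

test_that("a failing size is recorded as missing, not fatal", {
  set.seed(2)
  mat <- matrix(rnorm(60 * 6), 60, 6)
  mat[, 5] <- mat[, 4]; mat[, 6] <- mat[, 4]  # rank-deficient tail
  overall <- c(1, 0.9, 0.8, 0.3, 0.2, 0.1)
  participants <- rep(c("A", "B"), each = 30)
  cfg <- overlap_config(start_size = 4, step = 2, mc_samples = 500, seed = 1)
  expect_warning(
    cur <- overlap_curve(mat, participants, rank_variables(overall), cfg,
                         directions = "least_relevant"),
    "skipped")
  expect_true(is.na(cur$mean_overlap[cur$size == 4]))
  expect_false(all(is.na(cur$mean_overlap)))
})

test_that("variable profiling stratifies the extremes by plane and group", {
  d <- variable_descriptors()
  # put all relevance on lower-extremity flexion, none on spine rotation
  overall <- runif(nrow(d), 0.3, 0.7)
  hot <- d$group == "lower" & d$plane == "flexion"
  cold <- d$group == "spine" & d$plane == "rotation"
  overall[hot] <- runif(sum(hot), 0.9, 1)
  overall[cold] <- runif(sum(cold), 0, 0.05)
  rk <- rank_variables(overall, d)
  prof <- profile_variables(rk, smooth_time = FALSE)
  expect_equal(prof$k, 540)
  expect_equal(sum(prof$most$by_movement), 1)
  expect_equal(sum(prof$most$by_group), 1)
  expect_equal(prof$most$by_movement[["flexion/extension"]], 540 / 540)
  expect_equal(prof$most$by_group[["lower"]], 1)
  expect_equal(prof$least$by_movement[["int/ext rotation"]], 1)
  expect_equal(prof$least$by_group[["spine"]], 1)
  expect_equal(sum(prof$most$by_time$count), 540)
  # smoothed histogram preserves location of mass
  prof2 <- profile_variables(rk, k = 100, smooth_time = TRUE)
  expect_equal(prof2$k, 100)
  expect_equal(nrow(prof2$most$by_time), 100)
})
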