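test_that("constant height series yields zero events", {
  tr <- flat_trial(0.5)
  expect_warning(ev <- detect_events(tr), "no gait events")
  expect_equal(nrow(ev$touchdowns), 0)
  expect_equal(nrow(ev$takeoffs), 0)
})

test_that("non-positive heights everywhere are rejected", {
  tr <- flat_trial(0)
  expect_error(detect_events(tr), "degenerate")
})

test_that("touchdowns match synthetic ground truth to within 10 ms", {
  fx <- small_cohort()
  tr <- fx$cohort$trials[[1]]$CR
  td <- tr$true_events[tr$true_events$type == "touchdown", ]
  ev <- detect_events(tr)
  err_ms <- vapply(seq_len(nrow(ev$touchdowns)), function(i) {
    same <- td[td$side == ev$touchdowns$side[i], ]
    min(abs(same$sample - ev$touchdowns$sample[i]))
  }, 0) / tr$sampling_rate * 1000
  expect_lte(mean(err_ms), 10)
  # events are ordered and takeoffs fall inside their stance window
  expect_true(all(diff(ev$touchdowns$sample) > 0))
  for (side in c("left", "right")) {
    tds <- ev$touchdowns$sample[ev$touchdowns$side == side]
    tos <- ev$takeoffs$sample[ev$takeoffs$side == side]
    for (i in seq_len(min(length(tds), length(tos)))) {
      expect_gt(tos[i], tds[i])
    }
  }
})

test_that("the detector follows whichever channel crosses first", {
  fx <- small_cohort()
  tr <- fx$cohort$trials[[1]]$CR
  base <- detect_events(tr)
  # simulate a forefoot strike: the toe reaches the ground 5 samples
  # before the calcaneus
  shift <- 5L
  fore <- tr
  for (ch in c("toe_height_left", "toe_height_right")) {
    fore[[ch]] <- c(tr[[ch]][-seq_len(shift)],
                    rep(utils::tail(tr[[ch]], 1), shift))
  }
  ahead <- detect_events(fore)
  n <- min(nrow(base$touchdowns), nrow(ahead$touchdowns))
  delta <- ahead$touchdowns$sample[seq_len(n)] -
    base$touchdowns$sample[seq_len(n)]
  # touchdown moves earlier (by up to the shift), never later
  expect_true(all(delta <= 0))
  expect_lt(mean(delta), 0)
})

test_that("segmentation pairs consecutive opposite-side touchdowns", {
  fx <- small_cohort()
  tr <- fx$cohort$trials[[1]]$CR
  ev <- structure(list(
    touchdowns = data.frame(sample = c(100L, 200L, 290L, 400L, 500L),
                            side = c("left", "right", "left", "right", "left")),
    takeoffs = data.frame(sample = integer(0), side = character(0))
  ), class = "gait_events")
  cyc <- segment_step_cycles(tr, ev)
  expect_length(cyc, 4)  # 5 touchdowns -> 4 cycles
  expect_equal(vapply(cyc, `[[`, "", "standing_side"),
               c("left", "right", "left", "right"))
  expect_equal(dim(cyc[[1]]$values)[1], 101)  # inclusive endpoints
  # same-side pair (missed event) is skipped
  ev$touchdowns$side[2] <- "left"
  # sides l,l,l,r,l leave only two opposite-side consecutive pairs
  cyc2 <- segment_step_cycles(tr, ev)
  expect_length(cyc2, 2)
  # fewer than two touchdowns
  ev$touchdowns <- ev$touchdowns[1, ]
  expect_warning(out <- segment_step_cycles(tr, ev), "fewer than 2")
  expect_length(out, 0)
})

test_that("time normalization preserves endpoints and analytic shapes", {
  ramp <- matrix(seq(0, 1, length.out = 237), ncol = 1)
  out <- time_normalize(ramp, 100)
  expect_equal(dim(out), c(100, 1))
  expect_equal(out[1, 1], 0)
  expect_equal(out[100, 1], 1)
  expect_equal(out[, 1], seq(0, 1, length.out = 100), tolerance = 1e-12)
  # identity on input already at the target length
  x <- matrix(rnorm(100), ncol = 1)
  expect_equal(time_normalize(x, 100), x, ignore_attr = TRUE)
  # dense sine resamples onto the analytic curve
  phase <- seq(0, 2 * pi, length.out = 480)
  sine <- matrix(sin(phase), ncol = 1)
  out <- time_normalize(sine, 100)
  expect_equal(out[, 1], sin(seq(0, 2 * pi, length.out = 100)),
               tolerance = 1e-4)
  expect_error(time_normalize(matrix(1, 1, 1)), "too short")
})

test_that("mirroring flips trunk frontal/transverse only for left stance", {
  vals <- array(rnorm(10 * 3 * 3), dim = c(10, 3, 3),
                dimnames = list(NULL, c("L5S1", "Hip-left", "Hip-right"),
                                plane_names()))
  cyc <- structure(list(values = vals, standing_side = "right"),
                   class = "step_cycle")
  out <- mirror_and_relabel(cyc)
  # right stance: relabel only, no sign changes anywhere
  expect_equal(out$values[, "L5S1", ], vals[, "L5S1", ])
  expect_equal(out$values[, "Hip-st.", ], vals[, "Hip-right", ])
  expect_equal(out$values[, "Hip-sw.", ], vals[, "Hip-left", ])

  cyc$standing_side <- "left"
  out <- mirror_and_relabel(cyc)
  expect_equal(out$values[, "L5S1", "abduction"],
               -vals[, "L5S1", "abduction"])
  expect_equal(out$values[, "L5S1", "rotation"], -vals[, "L5S1", "rotation"])
  expect_equal(out$values[, "L5S1", "flexion"], vals[, "L5S1", "flexion"])
  expect_equal(out$values[, "Hip-st.", ], vals[, "Hip-left", ])

  # involution: mirroring a left-standing canonical cycle twice restores it
  once <- mirror_and_relabel(structure(list(values = out$values,
                                            standing_side = "left"),
                                       class = "step_cycle"))
  twice <- mirror_and_relabel(structure(list(values = once$values,
                                             standing_side = "left"),
                                        class = "step_cycle"))
  expect_equal(twice$values, out$values)
})

test_that("a full trial parses into the expected cycle count and layout", {
  cfg <- reduced_cohort_config(n_participants = 2, trial_duration = 10,
                               seed = 5)
  tr <- synthesize_trial(make_cohort(cfg)[[1]], cfg, "CR")
  pt <- process_trial(tr)
  # ~ trial_duration / mean_step_duration cycles, minus edge losses
  expect_gt(nrow(pt$cycles), 20)
  expect_lte(nrow(pt$cycles), 30)
  expect_equal(ncol(pt$cycles), n_variables(cfg$joints))
  expect_equal(pt$joints, cfg$joints)
  expect_true(all(pt$info$standing_side %in% c("left", "right")))
})
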