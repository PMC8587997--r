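test_that("cohort generation is a pure function of the seed", {
  cfg <- reduced_cohort_config(n_participants = 2, trial_duration = 5,
                               seed = 7)
  p1 <- make_cohort(cfg)
  p2 <- make_cohort(cfg)
  expect_identical(p1, p2)
  t1 <- synthesize_trial(p1[[1]], cfg, "CR")
  t2 <- synthesize_trial(p2[[1]], cfg, "CR")
  expect_identical(t1, t2)
  # distinct participants differ in their signature bumps
  expect_false(identical(p1[[1]]$signature_bumps, p1[[2]]$signature_bumps))
})

test_that("config validation rejects degenerate cohorts", {
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(signature_windows = list(c(90, 110))),
               "within")
  expect_error(cohort_config(noise_sd = -1), "sd")
  cfg <- reduced_cohort_config(trial_duration = 0.5)
  expect_error(synthesize_trial(make_cohort(cfg)[[1]], cfg), "3 steps")
})

test_that("zero signature amplitude leaves all expected waveforms shared", {
  cfg <- reduced_cohort_config(n_participants = 3, trial_duration = 5,
                               signature_amplitude = 0, seed = 3)
  pro <- make_cohort(cfg)
  expect_null(pro[[1]]$signature_bumps)
  expect_identical(pro[[1]]$waves, pro[[2]]$waves)
  expect_identical(pro[[2]]$waves, pro[[3]]$waves)
})

test_that("trial sampling and ground-truth events are physically consistent", {
  cfg <- reduced_cohort_config(n_participants = 2, trial_duration = 10,
                               seed = 5)
  tr <- synthesize_trial(make_cohort(cfg)[[1]], cfg, "CR")
  expect_equal(length(tr$time), 2400)  # 240 Hz x 10 s
  expect_equal(dim(tr$angles)[1], 2400)
  expect_true(all(tr$foot_height_left >= 0))
  expect_true(all(tr$toe_height_right >= 0))
  td <- tr$true_events[tr$true_events$type == "touchdown", ]
  # about one touchdown per mean step duration
  expect_gt(nrow(td), 0.8 * cfg$trial_duration / cfg$mean_step_duration)
  expect_lt(nrow(td), 1.2 * cfg$trial_duration / cfg$mean_step_duration)
  # strictly increasing, alternating sides, >= 0.15 s apart
  expect_true(all(diff(td$sample) > 0))
  expect_true(all(td$side[-1] != td$side[-nrow(td)]))
  expect_true(all(diff(td$time) >= 0.15))
})

test_that("noise-free synthesis repeats the same cycle waveform", {
  cfg <- reduced_cohort_config(n_participants = 2, trial_duration = 5,
                               noise_sd = 0, step_duration_jitter = 0,
                               cadence_offset_sd = 0, height_noise_sd = 0,
                               seed = 9)
  tr <- synthesize_trial(make_cohort(cfg)[[1]], cfg, "CR")
  pt <- process_trial(tr)
  sides <- pt$info$standing_side
  same_side <- which(sides == sides[2])[1:2]
  expect_equal(pt$cycles[same_side[1], ], pt$cycles[same_side[2], ],
               tolerance = 1e-6)
})

test_that("participant separation grows with the signature amplitude", {
  sep <- vapply(c(0, 4, 8), function(a) {
    cfg <- reduced_cohort_config(n_participants = 3, trial_duration = 6,
                                 signature_amplitude = a, seed = 21)
    co <- synthesize_cohort(cfg, trials = "CR")
    means <- t(vapply(names(co$trials), function(p) {
      colMeans(process_trial(co$trials[[p]]$CR)$cycles)
    }, numeric(n_variables(cfg$joints))))
    mean(dist(means))
  }, 0)
  expect_true(all(diff(sep) > 0))
})

test_that("the planted-signature mask enumerates exactly the window variables", {
  cfg <- cohort_config(signature_joints = c("L5S1", "T9T8"),
                       signature_planes = "flexion")
  mask <- planted_signature_mask(cfg)
  # 2 joints x 1 plane x (11 + 11) timepoints
  expect_equal(sum(mask), 44)
  d <- variable_descriptors()
  expect_true(all(d$joint[mask] %in% c("L5S1", "T9T8")))
  expect_true(all(d$plane[mask] == "flexion"))
  expect_true(all((d$timepoint[mask] >= 25 & d$timepoint[mask] <= 35) |
                    (d$timepoint[mask] >= 70 & d$timepoint[mask] <= 80)))
  # no signature joints -> all-false mask of full length
  cfg0 <- cohort_config(signature_joints = character(0))
  expect_equal(sum(planted_signature_mask(cfg0)), 0)
  expect_equal(length(planted_signature_mask(cfg0)), 5400)
})

test_that("trials survive a CSV round trip", {
  fx <- small_cohort()
  tr <- fx$cohort$trials[[1]]$CR
  path <- tempfile(fileext = ".csv")
  write_trial_csv(tr, path)
  back <- read_trial_csv(path)
  expect_equal(back$angles, tr$angles, tolerance = 1e-12)
  expect_equal(back$foot_height_left, tr$foot_height_left)
  expect_equal(back$true_events$sample, tr$true_events$sample)
  unlink(c(path, paste0(path, ".json")))
})
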