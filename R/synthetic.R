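# Synthetic running-kinematics generator: a cohort shares one smooth
# periodic base waveform per joint/plane; individuals differ through
# planted Gaussian signature bumps in configurable phase windows, an
# individual cadence offset and (optionally) perturbed waveform
# coefficients. Vertical foot/toe trajectories carry a ground-contact
# plateau so threshold-based event detection is exercisable against known
# touchdown times.

#' Configuration of a synthetic running cohort
#'
#' @param n_participants number of athletes in the cohort (>= 2).
#' @param spine_joints,extremity_joints joint labels; extremities are
#'   expanded to left/right channels at synthesis and to standing/swinging
#'   channels after relabeling.
#' @param sampling_rate sampling frequency in Hz.
#' @param trial_duration trial length in seconds (must cover >= 3 steps).
#' @param mean_step_duration mean time between consecutive touchdowns of
#'   opposite feet, seconds.
#' @param step_duration_jitter relative s.d. of step-to-step duration.
#' @param cadence_offset_sd relative s.d. of the participant-level cadence
#'   offset.
#' @param noise_sd s.d. of i.i.d. angular noise per sample, degrees.
#' @param fourier_perturbation_sd s.d. (degrees) of participant-specific
#'   perturbations of the shared waveform coefficients; 0 keeps every
#'   participant's expected waveform identical to the base so that planted
#'   signatures are the only systematic between-participant differences.
#' @param n_harmonics harmonics of the truncated Fourier base waveform.
#' @param signature_windows list of `c(start, end)` phase windows in
#'   percent of the step cycle where signatures are planted.
#' @param signature_joints canonical joint labels carrying signatures.
#' @param signature_planes movement planes carrying signatures.
#' @param signature_amplitude nominal bump amplitude, degrees.
#' @param signature_width Gaussian bump s.d. in percent of the cycle.
#' @param stance_fraction fraction of a step cycle the standing foot stays
#'   on the ground.
#' @param plateau_height,swing_peak_foot,swing_peak_toe,height_noise_sd
#'   vertical foot/toe trajectory model, meters.
#' @param seed integer seed controlling the cohort and all trials.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20L,
                          spine_joints = spine_joint_names(),
                          extremity_joints = extremity_joint_names(),
                          sampling_rate = 240,
                          trial_duration = 20,
                          mean_step_duration = 0.35,
                          step_duration_jitter = 0.03,
                          cadence_offset_sd = 0.02,
                          noise_sd = 1,
                          fourier_perturbation_sd = 0,
                          n_harmonics = 4L,
                          signature_windows = list(c(25, 35), c(70, 80)),
                          signature_joints = c("L5S1", "T9T8", "Hip-st.",
                                               "Hip-sw.", "Knee-st.",
                                               "Knee-sw."),
                          signature_planes = plane_names(),
                          signature_amplitude = 4,
                          signature_width = 1.5,
                          stance_fraction = 0.6,
                          plateau_height = 0.012,
                          swing_peak_foot = 0.15,
                          swing_peak_toe = 0.12,
                          height_noise_sd = 0.003,
                          seed = 1L) {
  if (n_participants < 2) {
    stop("invalid config: n_participants must be >= 2", call. = FALSE)
  }
  for (w in signature_windows) {
    if (length(w) != 2 || w[1] >= w[2] || w[1] < 0 || w[2] > 100) {
      stop("invalid config: signature windows must lie within [0, 100]",
           call. = FALSE)
    }
  }
  sds <- c(step_duration_jitter, cadence_offset_sd, noise_sd,
           fourier_perturbation_sd, height_noise_sd)
  if (any(sds < 0)) stop("invalid config: all sd parameters must be >= 0",
                         call. = FALSE)
  joints <- canonical_joints(spine_joints, extremity_joints)
  if (!all(signature_joints %in% joints)) {
    stop("invalid config: signature_joints must be canonical joint labels",
         call. = FALSE)
  }
  if (!all(signature_planes %in% plane_names())) {
    stop("invalid config: unknown signature plane", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$joints <- joints
  structure(cfg, class = "cohort_config")
}

#' Reduced-scale cohort preset
#'
#' Same generative model as [cohort_config()] but with 6 joints
#' (2 spinal, hip and knee of both roles) and shorter trials, giving 1800
#' flattened variables per step cycle. Intended for routine analyses and
#' simulation studies on a single CPU; the full 18-joint layout remains
#' the documented default elsewhere.
#'
#' @param ... overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
reduced_cohort_config <- function(...) {
  defaults <- list(
    spine_joints = c("L5S1", "T9T8"),
    extremity_joints = c("Hip", "Knee"),
    trial_duration = 15,
    signature_joints = c("L5S1", "Hip-st.", "Hip-sw.", "Knee-sw.")
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# Evaluate and restore the RNG state around a seeded expression so the
# generator is a pure function of (config, ids).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

eval_fourier <- function(coef, phase, period) {
  # coef = c(a0, A_1..A_H, B_1..B_H)
  h <- (length(coef) - 1L) / 2L
  out <- rep(coef[1L], length(phase))
  for (k in seq_len(h)) {
    w <- 2 * pi * k * phase / period
    out <- out + coef[1L + k] * cos(w) + coef[1L + h + k] * sin(w)
  }
  out
}

# Shared base waveforms. Extremity trajectories are Fourier series over a
# full stride (period 200 phase units = two steps); the first half is the
# standing role, the second the swinging role, so left/right channels stay
# continuous across step boundaries. Spinal trajectories repeat every step
# (period 100); their frontal/transverse components use sine terms only,
# which vanish at the step boundaries and therefore stay continuous under
# the left-step sign convention. Sagittal amplitudes dominate, as in gait.
base_waveforms <- function(config) {
  h <- config$n_harmonics
  with_seed(config$seed * 104729 + 17, {
    plane_scale <- c(abduction = 4, rotation = 3, flexion = 12)
    ext <- list()
    for (j in config$extremity_joints) {
      ext[[j]] <- list()
      for (p in plane_names()) {
        decay <- plane_scale[[p]] / seq_len(h)
        a0 <- if (p == "flexion") stats::runif(1, 5, 25) else stats::runif(1, -4, 4)
        ext[[j]][[p]] <- c(a0, stats::rnorm(h) * decay, stats::rnorm(h) * decay)
      }
    }
    spine_scale <- c(abduction = 3, rotation = 3, flexion = 5)
    spn <- list()
    for (j in config$spine_joints) {
      spn[[j]] <- list()
      for (p in plane_names()) {
        decay <- spine_scale[[p]] / seq_len(h)
        if (p == "flexion") {
          spn[[j]][[p]] <- c(stats::runif(1, -10, 10), stats::rnorm(h) * decay,
                             stats::rnorm(h) * decay)
        } else {
          # sine-only: zero at 0 and 100 % of the step
          spn[[j]][[p]] <- c(0, rep(0, h), stats::rnorm(h) * decay)
        }
      }
    }
    list(extremity = ext, spine = spn)
  })
}

participant_seed <- function(config, i) {
  (as.numeric(config$seed) * 131071 + i * 524287) %% .Machine$integer.max
}

#' Build participant profiles for a synthetic cohort
#'
#' Each profile is a deterministic function of the config seed and the
#' participant index: perturbed (optionally) waveform coefficients, a set
#' of Gaussian signature bumps confined to the configured phase windows,
#' and a cadence offset.
#'
#' @param config a [cohort_config()].
#' @return List of `participant_profile` objects of length
#'   `config$n_participants`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  base <- base_waveforms(config)
  lapply(seq_len(config$n_participants), function(i) {
    with_seed(participant_seed(config, i), {
      waves <- base
      if (config$fourier_perturbation_sd > 0) {
        perturb <- function(coefs, sine_only) {
          h <- config$n_harmonics
          d <- stats::rnorm(length(coefs), 0, config$fourier_perturbation_sd)
          if (sine_only) d[seq_len(1 + h)] <- 0
          coefs + d
        }
        for (j in names(waves$extremity)) {
          for (p in plane_names()) {
            waves$extremity[[j]][[p]] <- perturb(waves$extremity[[j]][[p]], FALSE)
          }
        }
        for (j in names(waves$spine)) {
          for (p in plane_names()) {
            waves$spine[[j]][[p]] <-
              perturb(waves$spine[[j]][[p]], p != "flexion")
          }
        }
      }
      bumps <- NULL
      if (config$signature_amplitude > 0 && length(config$signature_joints)) {
        grid <- expand.grid(joint = config$signature_joints,
                            plane = config$signature_planes,
                            window = seq_along(config$signature_windows),
                            stringsAsFactors = FALSE)
        grid$center <- NA_real_
        grid$amplitude <- NA_real_
        for (r in seq_len(nrow(grid))) {
          w <- config$signature_windows[[grid$window[r]]]
          pad <- min(3, (w[2] - w[1]) * 0.3)
          grid$center[r] <- stats::runif(1, w[1] + pad, w[2] - pad)
          grid$amplitude[r] <- config$signature_amplitude *
            stats::runif(1, 0.7, 1.3) * sample(c(-1, 1), 1)
        }
        grid$width <- config$signature_width
        bumps <- grid
      }
      structure(list(
        participant_id = sprintf("P%02d", i),
        index = i,
        waves = waves,
        signature_bumps = bumps,
        cadence_offset = stats::rnorm(1, 0, config$cadence_offset_sd)
      ), class = "participant_profile")
    })
  })
}

# Sum of a participant's signature bumps for one canonical joint/plane at
# step phase u (0..100).
bump_value <- function(profile, joint, plane, u) {
  b <- profile$signature_bumps
  out <- numeric(length(u))
  if (is.null(b)) return(out)
  rows <- which(b$joint == joint & b$plane == plane)
  for (r in rows) {
    out <- out + b$amplitude[r] * exp(-(u - b$center[r])^2 / (2 * b$width[r]^2))
  }
  out
}

trial_stream <- function(profile, config, trial_label, seed_offset) {
  code <- match(trial_label, c("CR", "WR", "TR"))
  if (is.na(code)) code <- 9L
  (participant_seed(config, profile$index) + code * 97 +
     as.numeric(seed_offset) * 7907) %% .Machine$integer.max
}

#' Synthesize one continuous running trial
#'
#' Generates joint-angle channels (spinal joints plus left/right extremity
#' channels, 3 planes each) over a jittered step schedule, along with
#' vertical foot and toe trajectories whose stance plateaus make the 2 cm
#' touchdown threshold rule meaningful. Ground-truth touchdown/takeoff
#' samples are recorded for validation; they exist only in synthetic data.
#'
#' @param profile a `participant_profile` from [make_cohort()].
#' @param config the generating [cohort_config()].
#' @param trial_label one of "CR", "WR", "TR".
#' @param seed_offset extra integer folded into the trial's RNG stream.
#' @return An object of class `raw_trial`: time vector, `angles` array
#'   (samples x channels x 3 planes), the four height channels and
#'   `true_events` (sample, time, side, type).
#' @export
synthesize_trial <- function(profile, config, trial_label = "CR",
                             seed_offset = 0L) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(config, "cohort_config"))
  if (config$trial_duration < 3 * config$mean_step_duration) {
    stop("trial too short: must cover at least 3 steps", call. = FALSE)
  }
  fs <- config$sampling_rate
  n <- round(config$trial_duration * fs)
  t <- (seq_len(n) - 1) / fs

  with_seed(trial_stream(profile, config, trial_label, seed_offset), {
    mean_step <- config$mean_step_duration * (1 + profile$cadence_offset)
    # step boundaries (touchdown times), one spare step before t = 0 and
    # after the trial end so every sample falls inside a step
    lead <- 0.2
    durs <- c()
    total <- lead
    while (total < config$trial_duration + mean_step) {
      d <- max(0.18, mean_step * (1 + stats::rnorm(1) * config$step_duration_jitter))
      durs <- c(durs, d)
      total <- total + d
    }
    bounds <- c(lead - durs[1] - mean_step, lead, lead + cumsum(durs))
    durs <- diff(bounds)
    sides <- rep_len(c("left", "right"), length(bounds) - 1)

    k <- findInterval(t, bounds)
    u <- 100 * (t - bounds[k]) / durs[k]
    standing <- sides[k]
    left_standing <- standing == "left"

    channels <- c(config$spine_joints,
                  as.vector(t(outer(config$extremity_joints,
                                    c("-left", "-right"), paste0))))
    planes <- plane_names()
    angles <- array(0, dim = c(n, length(channels), 3L),
                    dimnames = list(NULL, channels, planes))

    for (j in config$spine_joints) {
      for (p in planes) {
        val <- eval_fourier(profile$waves$spine[[j]][[p]], u, 100) +
          bump_value(profile, j, p, u)
        if (p != "flexion") val <- val * ifelse(left_standing, -1, 1)
        angles[, j, p] <- val + stats::rnorm(n, 0, config$noise_sd)
      }
    }
    for (b in config$extremity_joints) {
      for (side in c("left", "right")) {
        stands <- if (side == "left") left_standing else !left_standing
        v <- u + ifelse(stands, 0, 100)  # stride phase of this channel
        ch <- paste0(b, "-", side)
        for (p in planes) {
          val <- eval_fourier(profile$waves$extremity[[b]][[p]], v, 200)
          val <- val +
            ifelse(stands, bump_value(profile, paste0(b, "-st."), p, u),
                   bump_value(profile, paste0(b, "-sw."), p, u))
          angles[, ch, p] <- val + stats::rnorm(n, 0, config$noise_sd)
        }
      }
    }

    heights <- synth_heights(t, bounds, durs, sides, config)

    inside <- bounds >= 0 & bounds < config$trial_duration
    td_times <- bounds[inside]
    td_sides <- sides[pmin(which(inside), length(sides))]
    td_samples <- round(td_times * fs) + 1L
    keep <- td_samples >= 1 & td_samples <= n
    sf <- config$stance_fraction
    to_times <- bounds[-length(bounds)] + sf * durs
    to_inside <- to_times >= 0 & to_times < config$trial_duration
    to_samples <- round(to_times[to_inside] * fs) + 1L
    to_sides <- sides[to_inside]
    events <- rbind(
      data.frame(sample = td_samples[keep], time = td_times[keep],
                 side = td_sides[keep], type = "touchdown",
                 stringsAsFactors = FALSE),
      data.frame(sample = to_samples, time = to_times[to_inside],
                 side = to_sides, type = "takeoff", stringsAsFactors = FALSE)
    )
    events <- events[order(events$sample), , drop = FALSE]
    rownames(events) <- NULL

    structure(list(
      participant_id = profile$participant_id,
      trial_label = trial_label,
      time = t,
      sampling_rate = fs,
      angles = angles,
      foot_height_left = heights$foot_left,
      foot_height_right = heights$foot_right,
      toe_height_left = heights$toe_left,
      toe_height_right = heights$toe_right,
      true_events = events
    ), class = "raw_trial")
  })
}

# Vertical foot/toe model: stance plateau at `plateau_height`, swing as a
# raised sine arc with steep approach (sin^0.7) so the descent crosses the
# 2 cm band a few milliseconds before ground truth at most. The toe lands
# slightly after and leaves slightly later than the calcaneus (rearfoot
# strike pattern).
synth_heights <- function(t, bounds, durs, sides, config) {
  arc <- function(w, peak) peak * pmax(0, sin(pi * pmin(pmax(w, 0), 1)))^0.7
  one_channel <- function(foot, land_delay, off_extra, peak) {
    h <- rep(config$plateau_height, length(t))
    td_idx <- which(sides == foot)
    td_times <- bounds[td_idx]
    sf <- config$stance_fraction
    for (i in seq_along(td_idx)) {
      k <- td_idx[i]
      on_t <- td_times[i] + land_delay * durs[k]
      off_t <- td_times[i] + (sf + off_extra) * durs[k]
      next_on <- if (i < length(td_idx)) {
        td_times[i + 1] + land_delay * durs[td_idx[i + 1]]
      } else max(t) + 1
      sw <- t > off_t & t < next_on
      if (any(sw)) {
        w <- (t[sw] - off_t) / (next_on - off_t)
        h[sw] <- config$plateau_height + arc(w, peak)
      }
      # before this foot's very first landing treat as swing tail
      if (i == 1) {
        pre <- t < on_t
        if (any(pre)) {
          w <- 1 - (on_t - t[pre]) / (0.4 * durs[k] + durs[k])
          h[pre] <- config$plateau_height + arc(w, peak)
        }
      }
    }
    pmax(0, h + stats::rnorm(length(t), 0, config$height_noise_sd))
  }
  list(
    foot_left = one_channel("left", 0, 0, config$swing_peak_foot),
    foot_right = one_channel("right", 0, 0, config$swing_peak_foot),
    toe_left = one_channel("left", 0.03, 0.05, config$swing_peak_toe),
    toe_right = one_channel("right", 0.03, 0.05, config$swing_peak_toe)
  )
}

#' Synthesize the full CR/WR/TR session for every participant
#'
#' @param config a [cohort_config()].
#' @param trials trial labels to generate per participant.
#' @return Nested list: `trials[[participant]][[trial_label]]` raw trials,
#'   plus the cohort profiles.
#' @export
synthesize_cohort <- function(config, trials = c("CR", "WR", "TR")) {
  profiles <- make_cohort(config)
  out <- lapply(profiles, function(pr) {
    setNames(lapply(trials, function(tl) synthesize_trial(pr, config, tl)),
             trials)
  })
  names(out) <- vapply(profiles, `[[`, "", "participant_id")
  list(profiles = profiles, trials = out, config = config)
}

#' Oracle mask of planted-signature variables
#'
#' Marks every flattened variable whose (joint, plane, timepoint) lies in
#' a configured signature window for a signature joint and plane. Used as
#' ground truth when checking that relevance rankings recover the planted
#' individual characteristics.
#'
#' @param config a [cohort_config()].
#' @param n_timepoints timepoints of the normalized cycle layout.
#' @return Logical vector of length `n_variables(config$joints,
#'   n_timepoints)`.
#' @export
planted_signature_mask <- function(config, n_timepoints = 100L) {
  d <- variable_descriptors(config$joints, n_timepoints)
  pct <- d$timepoint * (100 / n_timepoints)
  in_window <- rep(FALSE, nrow(d))
  for (w in config$signature_windows) {
    in_window <- in_window | (pct >= w[1] & pct <= w[2])
  }
  d$joint %in% config$signature_joints &
    d$plane %in% config$signature_planes & in_window
}
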