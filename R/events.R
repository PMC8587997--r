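# Parsing continuous recordings into time-normalized, side-labeled step
# cycles: touchdown/takeoff detection from vertical foot and toe
# trajectories, segmentation at consecutive touchdowns of opposite feet,
# piecewise-linear time normalization to 100 points, trunk mirroring and
# standing/swinging relabeling.

#' Event-detection configuration
#'
#' @param threshold_above_min height threshold above the local minimum of
#'   a channel, meters. Touchdown is the first sample of either the foot
#'   or the toe trajectory below this threshold within a window between
#'   consecutive swing maxima; takeoff the last such sample.
#' @param min_peak_separation minimum spacing between swing maxima,
#'   seconds.
#' @return Object of class `event_config`.
#' @export
event_config <- function(threshold_above_min = 0.02,
                         min_peak_separation = 0.2) {
  if (threshold_above_min <= 0) {
    stop("threshold_above_min must be > 0", call. = FALSE)
  }
  structure(list(threshold_above_min = threshold_above_min,
                 min_peak_separation = min_peak_separation),
            class = "event_config")
}

# Swing maxima of a height series: one peak per contiguous excursion
# above the signal's mid-range (robust against multi-modal swing arcs
# and plateau-level noise), then a minimum-separation rule keeping the
# highest peaks.
find_swing_maxima <- function(x, min_sep) {
  rng <- range(x)
  if (diff(rng) <= 0) return(integer(0))
  high <- x > rng[1] + 0.5 * diff(rng)
  if (!any(high)) return(integer(0))
  # close dips shorter than the minimum peak separation so one swing
  # excursion yields exactly one peak
  runs <- rle(high)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  inner <- which(!runs$values & runs$lengths < min_sep &
                   seq_along(runs$values) > 1 &
                   seq_along(runs$values) < length(runs$values))
  for (r in inner) high[starts[r]:ends[r]] <- TRUE
  runs <- rle(high)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sort(mapply(function(s, e) s - 1L + which.max(x[s:e]),
              starts[runs$values], ends[runs$values]))
}

#' Detect touchdown and takeoff events
#'
#' For each body side, swing maxima are located on the mean of the foot
#' and toe height; within every window between consecutive maxima, the
#' per-channel local minimum defines a threshold (`local min +
#' threshold_above_min`) and the touchdown (takeoff) is the first (last)
#' sample at which either channel drops below its threshold. Considering
#' both the foot and the toe keeps the rule consistent for rearfoot and
#' forefoot strike patterns.
#'
#' @param trial a `raw_trial` (or any list with `foot_height_left/right`,
#'   `toe_height_left/right` and `sampling_rate`).
#' @param config an [event_config()].
#' @return Object of class `gait_events` with data.frames `touchdowns`
#'   and `takeoffs` (columns `sample`, `side`), ordered by sample.
#' @export
detect_events <- function(trial, config = event_config()) {
  stopifnot(inherits(config, "event_config"))
  fs <- trial$sampling_rate
  min_sep <- round(config$min_peak_separation * fs)
  all_h <- c(trial$foot_height_left, trial$foot_height_right,
             trial$toe_height_left, trial$toe_height_right)
  if (all(all_h <= 0)) {
    stop("degenerate input: height channels are non-positive everywhere",
         call. = FALSE)
  }
  td <- list(); to <- list()
  for (side in c("left", "right")) {
    foot <- trial[[paste0("foot_height_", side)]]
    toe <- trial[[paste0("toe_height_", side)]]
    peaks <- find_swing_maxima((foot + toe) / 2, min_sep)
    if (length(peaks) < 2) next
    for (i in seq_len(length(peaks) - 1L)) {
      w <- peaks[i]:peaks[i + 1L]
      first <- Inf; last <- -Inf
      for (ch in list(foot, toe)) {
        seg <- ch[w]
        below <- which(seg < min(seg) + config$threshold_above_min)
        if (length(below)) {
          first <- min(first, w[below[1]])
          last <- max(last, w[below[length(below)]])
        }
      }
      if (is.finite(first)) {
        td[[length(td) + 1L]] <- data.frame(sample = first, side = side,
                                            stringsAsFactors = FALSE)
        to[[length(to) + 1L]] <- data.frame(sample = last, side = side,
                                            stringsAsFactors = FALSE)
      }
    }
  }
  tds <- if (length(td)) do.call(rbind, td) else
    data.frame(sample = integer(0), side = character(0))
  tos <- if (length(to)) do.call(rbind, to) else
    data.frame(sample = integer(0), side = character(0))
  if (!nrow(tds)) {
    warning("no gait events found")
  }
  tds <- tds[order(tds$sample), , drop = FALSE]
  tos <- tos[order(tos$sample), , drop = FALSE]
  rownames(tds) <- rownames(tos) <- NULL
  structure(list(touchdowns = tds, takeoffs = tos), class = "gait_events")
}

#' Cut a recording into raw step cycles
#'
#' A step cycle spans two consecutive touchdowns of opposite feet; the
#' side touching down at the cycle start is the standing side. Pairs of
#' same-side touchdowns (a missed contralateral event) are skipped, and
#' the trailing incomplete segment is dropped.
#'
#' @param trial a `raw_trial`.
#' @param events a `gait_events` from [detect_events()].
#' @return List of `step_cycle` objects (fields `values`: samples x
#'   channels x 3 array, `standing_side`, `participant_id`,
#'   `trial_label`, `onset_sample`).
#' @export
segment_step_cycles <- function(trial, events) {
  td <- events$touchdowns
  if (nrow(td) < 2) {
    warning("fewer than 2 touchdowns: no step cycles")
    return(list())
  }
  out <- list()
  for (i in seq_len(nrow(td) - 1L)) {
    if (td$side[i] == td$side[i + 1L]) next
    idx <- td$sample[i]:td$sample[i + 1L]
    out[[length(out) + 1L]] <- structure(list(
      values = trial$angles[idx, , , drop = FALSE],
      standing_side = td$side[i],
      participant_id = trial$participant_id,
      trial_label = trial$trial_label,
      onset_sample = td$sample[i]
    ), class = "step_cycle")
  }
  out
}

#' Time-normalize a cycle to a fixed number of points
#'
#' Each channel is resampled by piecewise-linear interpolation at
#' `n_out` equally spaced phases spanning the full cycle; both endpoints
#' are preserved.
#'
#' @param values numeric array samples x channels x planes (or a matrix
#'   samples x channels).
#' @param n_out number of output timepoints (default 100).
#' @return Array (or matrix) with `n_out` rows.
#' @export
time_normalize <- function(values, n_out = 100L) {
  dm <- dim(values)
  L <- dm[1]
  if (is.null(L) || L < 2) stop("cycle too short to normalize", call. = FALSE)
  xout <- seq(1, L, length.out = n_out)
  flat <- matrix(values, nrow = L)
  res <- apply(flat, 2L, function(y) stats::approx(seq_len(L), y, xout)$y)
  array(res, dim = c(n_out, dm[-1]), dimnames = c(list(NULL), dimnames(values)[-1]))
}

#' Mirror trunk angles and relabel extremities by stance role
#'
#' For left-standing cycles, the frontal- and transverse-plane angles of
#' the spinal joints are sign-flipped so both sides share one convention;
#' sagittal angles are never modified. Left/right extremity channels are
#' relabeled to standing ("-st.") and swinging ("-sw.") roles. Cycles
#' whose channels are already in canonical standing/swinging form are
#' mirrored only.
#'
#' @param cycle a `step_cycle` whose `values` are timepoints x channels x
#'   3 planes.
#' @return The cycle with `values` in canonical joint order.
#' @export
mirror_and_relabel <- function(cycle) {
  v <- cycle$values
  channels <- dimnames(v)[[2]]
  stopifnot(!is.null(channels))
  lefts <- grepl("-left$", channels)
  rights <- grepl("-right$", channels)
  spine <- channels[!lefts & !rights]
  if (any(lefts)) {
    bases <- sub("-left$", "", channels[lefts])
    st_suffix <- if (cycle$standing_side == "left") "-left" else "-right"
    sw_suffix <- if (cycle$standing_side == "left") "-right" else "-left"
    joints <- canonical_joints(spine, bases)
    out <- v[, c(spine,
                 as.vector(t(cbind(paste0(bases, st_suffix),
                                   paste0(bases, sw_suffix))))), , drop = FALSE]
    dimnames(out)[[2]] <- joints
  } else {
    out <- v
  }
  if (cycle$standing_side == "left" && length(spine)) {
    out[, spine, c("abduction", "rotation")] <-
      -out[, spine, c("abduction", "rotation")]
  }
  cycle$values <- out
  cycle
}

#' Run the full step-cycle extraction for one trial
#'
#' Detects events, segments step cycles, time-normalizes each to
#' `n_timepoints`, mirrors/relabels, and flattens into the canonical
#' variable layout.
#'
#' @param trial a `raw_trial`.
#' @param config an [event_config()].
#' @param n_timepoints timepoints of the normalized cycle.
#' @return List with `cycles` (matrix n_cycles x n_variables), `info`
#'   (data.frame participant, trial, standing_side, onset_sample) and
#'   `joints` (canonical joint labels of the columns).
#' @export
process_trial <- function(trial, config = event_config(),
                          n_timepoints = 100L) {
  events <- detect_events(trial, config)
  raw <- segment_step_cycles(trial, events)
  channels <- dimnames(trial$angles)[[2]]
  bases <- unique(sub("-left$|-right$", "", channels[grepl("-left$|-right$", channels)]))
  spine <- channels[!grepl("-left$|-right$", channels)]
  joints <- canonical_joints(spine, bases)
  rows <- lapply(raw, function(cy) {
    cy$values <- time_normalize(cy$values, n_timepoints)
    cy <- mirror_and_relabel(cy)
    flatten_cycle(cy$values[, joints, , drop = FALSE])
  })
  info <- data.frame(
    participant = vapply(raw, `[[`, "", "participant_id"),
    trial = vapply(raw, `[[`, "", "trial_label"),
    standing_side = vapply(raw, `[[`, "", "standing_side"),
    onset_sample = vapply(raw, function(x) as.integer(x$onset_sample), 1L),
    stringsAsFactors = FALSE
  )
  list(cycles = do.call(rbind, rows), info = info, joints = joints)
}
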