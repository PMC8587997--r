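# Plain-text persistence: long-format trial CSVs with a JSON sidecar for
# config and ground-truth events, cycle matrices as CSV with a JSON row
# index, and CSV exports of relevance patterns, rankings and overlap
# curves.

#' Write a raw trial as long-format CSV plus JSON sidecar
#'
#' Columns: `time_s`, `participant`, `trial`, `channel`, `value`. Angle
#' channels are named `<joint>|<plane>`; height channels keep their
#' field names. The sidecar stores the sampling rate and the
#' ground-truth events.
#'
#' @param trial a `raw_trial`.
#' @param path CSV output path; the sidecar is written to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  ang <- trial$angles
  dn <- dimnames(ang)
  blocks <- list()
  for (j in dn[[2]]) {
    for (p in dn[[3]]) {
      blocks[[paste(j, p, sep = "|")]] <- ang[, j, p]
    }
  }
  for (h in c("foot_height_left", "foot_height_right",
              "toe_height_left", "toe_height_right")) {
    blocks[[h]] <- trial[[h]]
  }
  n <- length(trial$time)
  df <- data.frame(
    time_s = rep(trial$time, times = length(blocks)),
    participant = trial$participant_id,
    trial = trial$trial_label,
    channel = rep(names(blocks), each = n),
    value = unlist(blocks, use.names = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(participant_id = trial$participant_id,
         trial_label = trial$trial_label,
         sampling_rate = trial$sampling_rate,
         true_events = trial$true_events),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a long-format trial CSV written by [write_trial_csv()]
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return A `raw_trial`.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  chans <- unique(df$channel)
  angle_chans <- chans[grepl("\\|", chans)]
  parts <- strsplit(angle_chans, "|", fixed = TRUE)
  joints <- unique(vapply(parts, `[[`, "", 1L))
  time <- unique(df$time_s)
  n <- length(time)
  ang <- array(NA_real_, dim = c(n, length(joints), 3L),
               dimnames = list(NULL, joints, plane_names()))
  for (ch in angle_chans) {
    jp <- strsplit(ch, "|", fixed = TRUE)[[1]]
    ang[, jp[1], jp[2]] <- df$value[df$channel == ch]
  }
  out <- list(participant_id = meta$participant_id,
              trial_label = meta$trial_label,
              time = time, sampling_rate = meta$sampling_rate,
              angles = ang,
              foot_height_left = df$value[df$channel == "foot_height_left"],
              foot_height_right = df$value[df$channel == "foot_height_right"],
              toe_height_left = df$value[df$channel == "toe_height_left"],
              toe_height_right = df$value[df$channel == "toe_height_right"],
              true_events = as.data.frame(meta$true_events))
  structure(out, class = "raw_trial")
}

#' Write a cycle matrix with its row index
#' @param mat matrix with attribute "info" (or `info` supplied).
#' @param path CSV path for the matrix; the row index goes to
#'   `<path>.json`.
#' @param info optional row metadata.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(mat, path, info = attr(mat, "info")) {
  utils::write.table(mat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cycle matrix written by [write_matrix_csv()]
#' @param path CSV path.
#' @return Matrix with attribute "info".
#' @export
read_matrix_csv <- function(path) {
  mat <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(mat) <- NULL
  attr(mat, "info") <-
    as.data.frame(jsonlite::read_json(paste0(path, ".json"),
                                      simplifyVector = TRUE))
  mat
}
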