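#' Speech segment tables
#'
#' Segments are represented as a data.frame with numeric columns `start` and
#' `end` (session-relative seconds, half-open intervals `[start, end)`) and a
#' character `label` column (`"speech"`, a cluster id, or a speaker role).
#'
#' @param start,end numeric vectors of onsets/offsets in seconds.
#' @param label character vector of labels (recycled).
#' @return a `data.frame` of segments sorted by onset.
#' @export
speech_segments <- function(start = numeric(), end = numeric(), label = "speech") {
  if (length(start) != length(end))
    dv_stop("dyadvox_input_error", "start and end must have equal length")
  if (any(start < 0) || any(end <= start))
    dv_stop("dyadvox_input_error", "segments require 0 <= start < end")
  out <- data.frame(start = as.numeric(start), end = as.numeric(end),
                    label = rep_len(as.character(label), length(start)),
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Read segments from an RTTM file
#'
#' Accepts the diarization-community RTTM dialect: whitespace-delimited rows
#' `SPEAKER <file-id> <channel> <onset> <duration> ... <speaker>` (speaker in
#' field 8 of a 10-field row, or field 6 of a compact 6-field row). Segments
#' are returned sorted by onset.
#'
#' @param path path to an RTTM file.
#' @return a segment `data.frame` (see [speech_segments()]).
#' @export
read_segments <- function(path) {
  if (!file.exists(path))
    dv_stop("dyadvox_input_error", "segment file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))
  if (length(lines_keep) == 0L) return(speech_segments())
  start <- end <- numeric(length(lines_keep))
  label <- character(length(lines_keep))
  for (i in seq_along(lines_keep)) {
    ln <- lines_keep[i]
    f <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(f) < 6L)
      dv_stop("dyadvox_parse_error", "RTTM line %d: expected >= 6 fields, got %d", ln, length(f))
    onset <- suppressWarnings(as.numeric(f[4]))
    dur <- suppressWarnings(as.numeric(f[5]))
    if (is.na(onset) || is.na(dur))
      dv_stop("dyadvox_parse_error", "RTTM line %d: non-numeric onset/duration", ln)
    if (dur <= 0)
      dv_stop("dyadvox_parse_error", "RTTM line %d: non-positive duration %g", ln, dur)
    start[i] <- onset
    end[i] <- onset + dur
    label[i] <- if (length(f) >= 8L) f[8] else f[6]
  }
  speech_segments(start, end, label)
}

#' Write segments to an RTTM file
#'
#' Times are written in seconds with 3-decimal precision.
#'
#' @param segments a segment `data.frame`.
#' @param path output path.
#' @param file_id recording identifier for the RTTM file-id field.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, file_id = "audio") {
  stopifnot(is.data.frame(segments), all(c("start", "end", "label") %in% names(segments)))
  rows <- sprintf("SPEAKER %s 1 %.3f %.3f <NA> <NA> %s <NA> <NA>",
                  file_id, segments$start, segments$end - segments$start,
                  segments$label)
  writeLines(rows, path)
  invisible(path)
}
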