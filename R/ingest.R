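# ISO-8601 (with or without the "T") to POSIXct, UTC.
parse_iso <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%d"))
}

#' Read a WAV recording and link it to its metadata row
#'
#' Reads a PCM WAV file, downmixes stereo to mono by channel mean (scoring
#' is per-clip presence, insensitive to channel), and attaches the
#' individual/start-time metadata. The file's sample rate must match the
#' metadata's expectation when one is given.
#'
#' @param path WAV file path.
#' @param metadata One-row data frame with (at least) `individual_id` and
#'   `start_datetime` (ISO-8601), optionally `sample_rate`; may be `NULL`.
#' @param expected_rate Required sample rate (default 44100); `NULL` skips
#'   the check.
#' @return A `recording`: list with `samples` (mono numeric), `sample_rate`,
#'   `start` (`POSIXct`), `individual_id`, `uri`.
#' @export
read_recording <- function(path, metadata = NULL, expected_rate = 44100) {
  w <- read_wav(path)
  if (!is.null(expected_rate) && w$sample_rate != expected_rate) {
    stop_invalid("sample rate ", w$sample_rate, " Hz of ", path,
                 " does not match expected ", expected_rate, " Hz.")
  }
  if (!is.null(metadata) && !is.null(metadata$sample_rate) &&
      metadata$sample_rate != w$sample_rate) {
    stop_invalid("sample rate mismatch between file and metadata for ", path)
  }
  start <- if (!is.null(metadata)) {
    parse_iso(metadata$start_datetime[1])
  } else {
    as.POSIXct(NA)
  }
  structure(
    list(samples = rowMeans(w$samples), sample_rate = w$sample_rate,
         start = start,
         individual_id = if (!is.null(metadata)) {
           metadata$individual_id[1]
         } else NA_character_,
         uri = path),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s | %.1f s @ %d Hz | %s\n", x$uri,
              length(x$samples) / x$sample_rate, x$sample_rate,
              x$individual_id))
  invisible(x)
}

#' Segment a recording into consecutive 60-second clips
#'
#' Tiles the recording with half-open `[t, t + clip_s)` intervals. Only
#' full clips are kept; a trailing partial clip is dropped and logged so
#' minute counts stay auditable.
#'
#' @param rec A [read_recording()] result.
#' @param clip_s Clip length in seconds (default 60).
#' @return Tibble with `file`, `clip_index` (0-based), `t_start`
#'   (`POSIXct`), `duration_s` and list-column `samples`.
#' @export
segment_clips <- function(rec, clip_s = 60) {
  stopifnot(inherits(rec, "recording"))
  n <- length(rec$samples)
  if (n == 0) stop_invalid("empty recording.")
  spc <- clip_s * rec$sample_rate
  n_clips <- n %/% spc
  rem <- n %% spc
  if (rem > 0) {
    inform(sprintf("dropping trailing partial clip of %.1f s from %s",
                   rem / rec$sample_rate, rec$uri))
  }
  if (n_clips == 0) {
    return(tibble(file = character(), clip_index = integer(),
                  t_start = as.POSIXct(character(), tz = "UTC"),
                  duration_s = numeric(), samples = list()))
  }
  idx <- seq_len(n_clips) - 1L
  tibble(
    file = rec$uri, clip_index = idx,
    t_start = rec$start + idx * clip_s,
    duration_s = clip_s,
    samples = lapply(idx, function(i) {
      rec$samples[(i * spc + 1):((i + 1) * spc)]
    })
  )
}

#' Attach experiment metadata to a clip manifest
#'
#' Joins clips to the experiment metadata table by `file` (each clip's file
#' must appear exactly once) and computes each clip's Zeitgeber time from
#' the regime active at its start: `zt = (clock - lights_on) mod 24` with
#' the row's own lights-on, so clips recorded after an LD -> DL reversal are
#' referenced to the reversed schedule.
#'
#' @param clips Tibble with columns `file` and `t_start`.
#' @param metadata Tibble with columns `file`, `individual_id`, `regime`,
#'   `lights_on`, `temperature_c` (and optionally more).
#' @return The clips annotated with `individual_id`, `regime`,
#'   `temperature_c` and `zt`.
#' @export
attach_metadata <- function(clips, metadata) {
  dup <- unique(metadata$file[duplicated(metadata$file)])
  if (length(dup) > 0) {
    stop_invalid("duplicate metadata rows for file(s): ",
                 paste(dup, collapse = ", "))
  }
  missing_f <- setdiff(unique(clips$file), metadata$file)
  if (length(missing_f) > 0) {
    stop_invalid("clip file(s) absent from metadata: ",
                 paste(missing_f, collapse = ", "))
  }
  meta_cols <- intersect(c("file", "individual_id", "regime", "lights_on",
                           "temperature_c", "incubator"), names(metadata))
  out <- left_join(clips, metadata[meta_cols], by = "file")
  clock_h <- as.numeric(format(out$t_start, "%H")) +
    as.numeric(format(out$t_start, "%M")) / 60 +
    as.numeric(format(out$t_start, "%S")) / 3600
  out$zt <- (clock_h - out$lights_on) %% 24
  out
}
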