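#' Frame schedule of a dynamic PET acquisition
#'
#' A `frame_schedule` stores the start time and duration of every temporal
#' frame, in seconds from injection. Frames must be contiguous and strictly
#' ordered; the acquisition is assumed to start at injection (t = 0).
#'
#' @param start_s numeric vector of frame start times (seconds).
#' @param dur_s numeric vector of frame durations (seconds), same length.
#' @return An object of class `frame_schedule` with fields `start_s`,
#'   `dur_s`, `n_frames`.
#' @seealso [make_default_schedule()] for the standard one-hour FDG framing.
#' @export
frame_schedule <- function(start_s, dur_s) {
  start_s <- as.numeric(start_s)
  dur_s <- as.numeric(dur_s)
  if (length(start_s) != length(dur_s) || length(start_s) < 1L)
    stop("start_s and dur_s must be non-empty vectors of equal length")
  if (any(dur_s <= 0)) stop("all frame durations must be positive")
  if (is.unsorted(start_s, strictly = TRUE))
    stop("frame start times must be strictly increasing")
  gaps <- start_s[-1L] - (start_s[-length(start_s)] + dur_s[-length(dur_s)])
  if (any(abs(gaps) > 1e-9))
    stop("frames must be contiguous: start[i+1] == start[i] + dur[i]")
  structure(
    list(start_s = start_s, dur_s = dur_s, n_frames = length(start_s)),
    class = "frame_schedule"
  )
}

#' Standard one-hour 41-frame FDG schedule
#'
#' Returns the dynamic framing used throughout the package's simulations:
#' 12 x 10 s, 12 x 20 s, 4 x 60 s, 5 x 120 s and 8 x 300 s, i.e. 41
#' contiguous frames covering exactly one hour from injection.
#'
#' @return A [frame_schedule()].
#' @examples
#' s <- make_default_schedule()
#' s$n_frames                      # 41
#' sum(s$dur_s)                    # 3600 s
#' @export
make_default_schedule <- function() {
  dur <- c(rep(10, 12), rep(20, 12), rep(60, 4), rep(120, 5), rep(300, 8))
  frame_schedule(start_s = cumsum(c(0, dur[-length(dur)])), dur_s = dur)
}

#' Frame mid-times in minutes
#'
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of frame center times, minutes post injection.
#' @export
frame_mid_times <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  (schedule$start_s + schedule$dur_s / 2) / 60
}

#' Total schedule duration in seconds
#' @param schedule a [frame_schedule()].
#' @return Scalar, seconds.
#' @export
schedule_end_s <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$start_s[schedule$n_frames] + schedule$dur_s[schedule$n_frames]
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat("frame_schedule:", x$n_frames, "frames,",
      schedule_end_s(x), "s total (",
      format(schedule_end_s(x) / 60, digits = 4), "min )\n")
  invisible(x)
}

#' Read / write a frame schedule as two-column text
#'
#' The interchange format is plain whitespace-separated text with two
#' columns, `start_s` and `dur_s`, one row per frame, with a header line.
#'
#' @param schedule a [frame_schedule()].
#' @param path file path.
#' @return `read_frame_schedule` returns a [frame_schedule()];
#'   `write_frame_schedule` returns `path` invisibly.
#' @export
write_frame_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  utils::write.table(
    data.frame(start_s = schedule$start_s, dur_s = schedule$dur_s),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_frame_schedule
#' @export
read_frame_schedule <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  if (!all(c("start_s", "dur_s") %in% names(tab)))
    stop("schedule file must have columns start_s and dur_s: ", path)
  frame_schedule(tab$start_s, tab$dur_s)
}
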