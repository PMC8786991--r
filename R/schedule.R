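# Frame schedules and count-based frame weighting.
#
# Time is in minutes package-wide; frame length enters the variance model in
# seconds (acquisition convention), conversion happens at the weighting
# boundary only.

C11_LAMBDA <- log(2) / 20.364  # 11C decay constant, min^-1

#' Construct a frame schedule
#'
#' A frame schedule holds, per frame, the start time and duration (minutes),
#' the decay-correction factor applied during reconstruction, and the whole
#' scanner true counts acquired in the frame. Trues and dcf drive the
#' count-based frame variance model (see [frame_weights()]).
#'
#' @param start numeric vector, frame start times in minutes; strictly
#'   increasing.
#' @param duration numeric vector, frame durations in minutes; all positive,
#'   frames must not overlap.
#' @param dcf decay-correction factors, one per frame, all >= 1. If `NULL`,
#'   computed for the 11C half-life (20.364 min) from the frame timing.
#' @param trues whole scanner true counts per frame (raw counts, not decay
#'   corrected), all >= 0. If `NULL`, filled from a smooth head-activity
#'   model so that weights are physiologically shaped (see
#'   [default_trues()]).
#' @return A `frame_schedule`: data.frame with columns `start`, `duration`,
#'   `dcf`, `trues` and attribute `mid` (frame mid-times, minutes).
#' @seealso [default_schedule()] for the standard 19-frame 60-min schedule.
#' @export
frame_schedule <- function(start, duration, dcf = NULL, trues = NULL) {
  start <- as.numeric(start); duration <- as.numeric(duration)
  n <- length(start)
  if (length(duration) != n) stop("start and duration lengths differ")
  if (n == 0) stop("empty schedule")
  if (any(diff(start) <= 0)) stop("frame starts must be strictly increasing")
  if (any(duration <= 0)) stop("frame durations must be positive")
  ends <- start + duration
  if (n > 1 && any(start[-1] < ends[-n] - 1e-9))
    stop("frames overlap")
  if (is.null(dcf)) dcf <- decay_correction_factor(start, duration)
  if (is.null(trues)) trues <- default_trues(start, duration)
  dcf <- as.numeric(dcf); trues <- as.numeric(trues)
  if (length(dcf) != n || length(trues) != n)
    stop("dcf and trues must have one value per frame")
  if (any(dcf < 1)) stop("dcf must be >= 1")
  if (any(trues < 0)) stop("trues must be non-negative")
  out <- data.frame(start = start, duration = duration,
                    dcf = dcf, trues = trues)
  attr(out, "mid") <- start + duration / 2
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Frame mid-times of a schedule
#' @param schedule a [frame_schedule()].
#' @return numeric vector of frame mid-times (minutes).
#' @export
frame_mid <- function(schedule) schedule$start + schedule$duration / 2

#' End of the last frame (minutes)
#' @param schedule a [frame_schedule()].
#' @export
scan_end <- function(schedule) {
  n <- nrow(schedule)
  schedule$start[n] + schedule$duration[n]
}

#' Decay-correction factors from frame timing
#'
#' dcf = lambda * L / (exp(-lambda t_s) - exp(-lambda t_e)): the factor that
#' restores the mean decay-corrected activity of a frame from its raw counts.
#' Always >= 1 for frames starting at or after injection.
#'
#' @param start,duration frame timing in minutes.
#' @param lambda decay constant in min^-1 (default: 11C).
#' @export
decay_correction_factor <- function(start, duration, lambda = C11_LAMBDA) {
  lambda * duration / (exp(-lambda * start) - exp(-lambda * (start + duration)))
}

#' Plausible whole-scanner true counts for a schedule
#'
#' Raw (non-decay-corrected) trues are modelled as the integral over the
#' frame of a smooth head-activity shape (fast uptake, slow washout) times
#' physical decay, scaled to a stated total. This is a simulation default,
#' used only when measured trues are not supplied.
#'
#' @param start,duration frame timing in minutes.
#' @param total total trues over the scan (counts).
#' @param lambda physical decay constant, min^-1.
#' @export
default_trues <- function(start, duration, total = 3e8, lambda = C11_LAMBDA) {
  shape <- function(t) (1 - exp(-t / 0.5)) * exp(-t / 80) * exp(-lambda * t)
  raw <- vapply(seq_along(start), function(i) {
    stats::integrate(shape, start[i], start[i] + duration[i])$value
  }, numeric(1))
  raw * total / sum(raw)
}

#' The default 19-frame, 60-minute schedule
#'
#' Frame durations 1x15, 3x5, 3x10, 4x60, 2x150, 2x300 and 4x600 seconds,
#' the standard rebinning for 60-min dynamic scans of fast-equilibrating
#' 11C tracers.
#'
#' @param trues optional per-frame trues; defaults to [default_trues()].
#' @return a [frame_schedule()] with 19 frames covering 0-60 min.
#' @export
default_schedule <- function(trues = NULL) {
  dur_s <- c(15, rep(5, 3), rep(10, 3), rep(60, 4), rep(150, 2),
             rep(300, 2), rep(600, 4))
  dur <- dur_s / 60
  start <- cumsum(c(0, dur[-length(dur)]))
  frame_schedule(start, dur, trues = trues)
}

#' Count-based frame variances and weights
#'
#' Per-frame variance sigma^2 = dcf^2 * T / L^2 with T the whole scanner
#' true counts in the frame and L the frame length in seconds; the fitting
#' weight is 1/sigma^2. Frames with zero trues carry zero weight (and their
#' sigma^2 is reported as Inf). Units of sigma^2 are arbitrary: only
#' relative weights matter in weighted least squares.
#'
#' @param schedule a [frame_schedule()].
#' @return data.frame with columns `sigma2` and `weight`, one row per frame.
#' @export
frame_weights <- function(schedule) {
  if (!inherits(schedule, "frame_schedule")) stop("need a frame_schedule")
  if (any(schedule$trues < 0)) stop("trues must be non-negative")
  L <- schedule$duration * 60        # seconds
  sigma2 <- schedule$dcf^2 * schedule$trues / L^2
  weight <- ifelse(schedule$trues > 0, 1 / sigma2, 0)
  data.frame(sigma2 = sigma2, weight = weight)
}

#' Read / write a frame schedule as TSV
#'
#' Columns: `frame_start_min`, `frame_duration_min`, `dcf`, `trues`.
#' @param schedule a [frame_schedule()].
#' @param path file path.
#' @export
write_schedule_tsv <- function(schedule, path) {
  df <- data.frame(frame_start_min = schedule$start,
                   frame_duration_min = schedule$duration,
                   dcf = schedule$dcf, trues = schedule$trues)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  df <- utils::read.delim(path)
  frame_schedule(df$frame_start_min, df$frame_duration_min,
                 dcf = df$dcf, trues = df$trues)
}
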