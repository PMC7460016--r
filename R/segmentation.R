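# Protocol segmentation: find the bilateral arm-flap "greeting" events
# that mark the start of each maneuver, carve the recording into labeled
# maneuver windows, and split dynamic maneuvers into repetitions.

#' Detect greeting events in a recording
#'
#' A greeting is a simultaneous vertical oscillation of both wrists.
#' Both wrist y-trajectories are band-pass filtered (4th-order
#' Butterworth, zero-phase) in `band`; an event is declared where the
#' oscillation envelopes of BOTH wrists exceed `min_amplitude / 2` for at
#' least one cycle. The onset is the first threshold crossing; candidate
#' onsets closer than 0.5 s are merged, keeping the earlier.
#'
#' @param rec a [recording()] of at least 2 s.
#' @param min_amplitude minimum peak-to-peak oscillation amplitude in
#'   meters for a flap to count.
#' @param band numeric length-2 pass band in Hz.
#' @return integer vector of 0-based onset frame indices, strictly
#'   increasing; empty when nothing oscillates.
#' @export
detect_greetings <- function(rec, min_amplitude = 0.1, band = c(0.5, 3)) {
  fr <- rec$frames
  fs <- 1 / frame_dt(rec)
  if (nrow(fr) < 2 * fs) stop("need at least 2 s of frames")
  thr <- min_amplitude / 2
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  a1 <- abs(signal::filtfilt(bf, fr$WRIST_L_y - mean(fr$WRIST_L_y)))
  a2 <- abs(signal::filtfilt(bf, fr$WRIST_R_y - mean(fr$WRIST_R_y)))
  w <- max(3L, round(fs / band[1]))          # one period of the slowest band freq
  env1 <- rolling_max(a1, w)
  env2 <- rolling_max(a2, w)
  active <- env1 > thr & env2 > thr
  min_run <- max(2L, round(fs / band[2]))    # >= one cycle of the fastest
  runs <- true_runs(active)
  if (!nrow(runs)) return(integer(0))
  runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= min_run, , drop = FALSE]
  # a flap oscillates: the band-passed signal must alternate between
  # significant positive and negative lobes (>= 3 sign alternations
  # among supra-threshold samples within the oscillation window); a
  # monotone limb transition produces at most one bipolar lobe pair
  bp1 <- signal::filtfilt(bf, fr$WRIST_L_y - mean(fr$WRIST_L_y))
  bp2 <- signal::filtfilt(bf, fr$WRIST_R_y - mean(fr$WRIST_R_y))
  oscillates <- function(bp, from) {
    win <- from:min(from + round(2.5 * fs), length(bp))
    s <- bp[win]
    ss <- sign(s)[abs(s) > thr]
    length(ss) > 1 && sum(diff(ss) != 0) >= 3
  }
  # onset refinement on the raw trajectories: first frame where both
  # wrists have risen min_amplitude/2 above their local pre-event
  # baseline (the zero-phase band-pass pre-rings, so its own threshold
  # crossing can sit a quarter second early)
  y1 <- fr$WRIST_L_y; y2 <- fr$WRIST_R_y
  raw_onset <- function(y, lo, hi) {
    base <- stats::median(y[max(1L, lo - 15L):lo])
    which(y[lo:hi] - base > thr)[1]
  }
  onsets <- integer(0)
  half <- floor(w / 2)
  for (i in seq_len(nrow(runs))) {
    lo <- max(1L, runs[i, "start"] - half)
    hi <- runs[i, "end"]
    c1 <- raw_onset(y1, lo, hi)
    c2 <- raw_onset(y2, lo, hi)
    if (is.na(c1) || is.na(c2)) next
    onset <- lo + max(c1, c2) - 1L
    if (oscillates(bp1, onset) && oscillates(bp2, onset))
      onsets <- c(onsets, onset)
  }
  if (!length(onsets)) return(integer(0))
  onsets <- sort(onsets)
  keep <- c(TRUE, diff(onsets) > 0.5 * fs)   # merge near-duplicates, keep earlier
  as.integer(onsets[keep] - 1L)              # 0-based
}

#' Maneuver segment object
#'
#' A labeled half-open frame span `[start, end)` (0-based) within a
#' recording, optionally with repetition sub-spans.
#'
#' @param maneuver one of RT, TT, FNT, SST, T45, CST.
#' @param start,end half-open 0-based frame span.
#' @param side `"left"`, `"right"`, `"both"` or `"na"`.
#' @param repetitions data.frame with columns `side`, `start`, `end`,
#'   `apex` (0-based frames), or NULL.
#' @return object of class `motorkin_segment`.
#' @export
maneuver_segment <- function(maneuver, start, end, side = "na",
                             repetitions = NULL) {
  maneuver <- match.arg(maneuver, c("RT", "TT", "FNT", "SST", "T45", "CST"))
  if (end <= start) stop("segment span must be non-empty")
  if (!is.null(repetitions)) {
    r <- repetitions[order(repetitions$start), ]
    if (any(r$start < start | r$end > end))
      stop("repetitions must be contained in the segment span")
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
      stop("repetitions must be disjoint")
    repetitions <- r
  }
  structure(list(maneuver = maneuver, start = as.integer(start),
                 end = as.integer(end), side = side,
                 repetitions = repetitions),
            class = "motorkin_segment")
}

#' @export
print.motorkin_segment <- function(x, ...) {
  cat(sprintf("<motorkin_segment> %s [%d, %d) side=%s reps=%d\n",
              x$maneuver, x$start, x$end, x$side,
              if (is.null(x$repetitions)) 0L else nrow(x$repetitions)))
  invisible(x)
}

#' Carve a recording into maneuver windows
#'
#' Given the detected greeting onsets and the protocol order, assigns to
#' maneuver `i` the window from the end of greeting `i` to the start of
#' greeting `i + 1` (the last window runs to the end of the recording).
#'
#' @param rec a [recording()].
#' @param greetings 0-based greeting onset frames, e.g. from
#'   [detect_greetings()].
#' @param order maneuver labels, one per greeting; defaults to the
#'   standard protocol order.
#' @param greeting_duration assumed flap duration in seconds, skipped
#'   after each onset before a window starts.
#' @return list of [maneuver_segment()], one per maneuver.
#' @export
segment_protocol <- function(rec, greetings,
                             order = c("RT", "TT", "FNT", "SST", "T45", "CST"),
                             greeting_duration = 4 / 3) {
  if (length(greetings) != length(order))
    stop(sprintf("segmentation error: expected %d greetings, found %d",
                 length(order), length(greetings)))
  if (!length(order)) return(list())
  fs <- 1 / frame_dt(rec)
  skip <- round(greeting_duration * fs)
  n <- n_frames(rec)
  starts <- pmin(greetings + skip, n - 1L)
  ends <- c(greetings[-1], n)
  lapply(seq_along(order), function(i)
    maneuver_segment(order[i], starts[i], ends[i]))
}

#' Split a dynamic maneuver into repetitions
#'
#' Repetitions are excursions of a scalar movement signal (reach
#' distance, step angle, or hip height) away from its baseline band. The
#' baseline is the median of the signal over the first 0.5 s of the
#' segment; the band half-width is twice the local noise SD over the same
#' window, floored at 5% of the largest excursion so that noise-free
#' signals split cleanly. Consecutive out-of-band runs are the
#' repetition spans; each apex is the frame of largest excursion.
#'
#' @param seg a [maneuver_segment()] (FNT, SST or CST).
#' @param rec the parent [recording()].
#' @param signal numeric vector of the movement signal, one value per
#'   frame of the segment (frames `seg$start .. seg$end - 1`).
#' @param n_expected expected repetition count; a mismatch is an error.
#' @param side side label stored on the repetitions.
#' @param min_duration minimum excursion duration in seconds.
#' @return the segment with `repetitions` filled (0-based global frames).
#' @export
split_repetitions <- function(seg, rec, signal, n_expected, side = "na",
                              min_duration = 0.2) {
  if (!seg$maneuver %in% c("FNT", "SST", "CST"))
    stop("repetition splitting applies to FNT, SST or CST segments")
  stopifnot(n_expected >= 1)
  nloc <- seg$end - seg$start
  if (length(signal) != nloc)
    stop("signal length must equal the segment frame count")
  fs <- 1 / frame_dt(rec)
  base_n <- max(2L, round(0.5 * fs))
  b <- stats::median(signal[seq_len(min(base_n, nloc))])
  sigma <- stats::sd(signal[seq_len(min(base_n, nloc))])
  if (!is.finite(sigma)) sigma <- 0
  exc <- abs(signal - b)
  peak <- max(exc)
  band <- max(2 * sigma, 0.05 * peak)
  if (peak <= band || peak == 0)
    stop(sprintf("repetition-count error: expected %d, found 0 (flat signal)",
                 n_expected))
  runs <- true_runs(exc > band)
  len_ok <- (runs[, "end"] - runs[, "start"] + 1L) >= round(min_duration * fs)
  peaks <- vapply(seq_len(nrow(runs)), function(i)
    max(exc[runs[i, "start"]:runs[i, "end"]]), numeric(1))
  runs <- runs[len_ok & peaks >= 0.3 * peak, , drop = FALSE]
  if (nrow(runs) != n_expected)
    stop(sprintf("repetition-count error: expected %d, found %d",
                 n_expected, nrow(runs)))
  reps <- data.frame(
    side = side,
    start = seg$start + runs[, "start"] - 1L,
    end = seg$start + runs[, "end"],            # half-open
    apex = seg$start + vapply(seq_len(nrow(runs)), function(i) {
      sp <- runs[i, "start"]:runs[i, "end"]
      sp[which.max(exc[sp])] - 1L
    }, integer(1)))
  maneuver_segment(seg$maneuver, seg$start, seg$end, side = seg$side,
                   repetitions = rbind(seg$repetitions, reps))
}

#' Segment every maneuver of a protocol recording
#'
#' Convenience wrapper: detect greetings, carve windows, and label them
#' with the standard order.
#'
#' @inheritParams detect_greetings
#' @inheritParams segment_protocol
#' @return list of [maneuver_segment()].
#' @export
segment_recording <- function(rec, min_amplitude = 0.1, band = c(0.5, 3),
                              order = c("RT", "TT", "FNT", "SST", "T45", "CST"),
                              greeting_duration = 4 / 3) {
  g <- detect_greetings(rec, min_amplitude, band)
  segment_protocol(rec, g, order, greeting_duration)
}
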