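#' EEG trace container
#'
#' @param samples numeric sample vector (microvolts)
#' @param fs sampling rate (Hz); the study's recordings used 1024 Hz
#' @param channel channel label
#' @param t0 time of the first sample (s)
#' @return an object of class `eeg_trace`
#' @export
eeg_trace <- function(samples, fs = 1024, channel = "EEG", t0 = 0) {
  if (fs <= 0) stop("fs must be > 0")
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs, channel = channel,
                 t0 = t0), class = "eeg_trace")
}

#' Band-pass and notch filtering of an EEG trace
#'
#' Applies a 50 Hz notch and a 1-90 Hz Butterworth band-pass, both
#' zero-phase (forward-backward).
#'
#' @param trace an [eeg_trace()]
#' @param notch_hz mains frequency to suppress (Hz)
#' @param band band-pass edges (Hz)
#' @return the filtered `eeg_trace`
#' @export
preprocess_eeg <- function(trace, notch_hz = 50, band = c(1, 90)) {
  fs <- trace$fs
  if (fs <= 2 * band[2])
    stop("sampling rate must exceed twice the band-pass upper edge")
  if (fs <= 200) stop("sampling rate must exceed 200 Hz")
  x <- trace$samples
  bstop <- signal::butter(2, c(notch_hz - 2, notch_hz + 2) / (fs / 2),
                          type = "stop")
  x <- filtfilt_padded(bstop, x, fs)
  bpass <- signal::butter(3, band / (fs / 2), type = "pass")
  x <- filtfilt_padded(bpass, x, fs)
  eeg_trace(x, fs, trace$channel, trace$t0)
}

# zero-phase filtering with odd-reflection padding to suppress edge
# transients (signal::filtfilt pads with zeros)
filtfilt_padded <- function(filt, x, fs, pad_s = 2) {
  np <- min(length(x) - 1, round(pad_s * fs))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[(np + 1):(np + length(x))]
}

#' Merge close seizure intervals and drop short ones
#'
#' Two successive detections separated by less than `merge_gap` seconds of
#' baseline are counted as one; the merged intervals are then kept only if
#' they last at least `min_duration` seconds. Idempotent.
#'
#' @param intervals data frame with columns `start`, `end` (s), sorted and
#'   non-overlapping
#' @param merge_gap maximum baseline gap merged away (s)
#' @param min_duration minimum retained seizure duration (s, inclusive)
#' @return filtered interval data frame
#' @export
merge_and_filter <- function(intervals, merge_gap = 1, min_duration = 2) {
  if (!nrow(intervals)) return(intervals[, c("start", "end"), drop = FALSE])
  if (is.unsorted(intervals$start))
    stop("intervals must be sorted by start time")
  if (any(intervals$end <= intervals$start))
    stop("intervals must have end > start")
  if (nrow(intervals) > 1 &&
      any(intervals$start[-1] < intervals$end[-nrow(intervals)]))
    stop("intervals must be non-overlapping")
  start <- intervals$start[1]
  end <- intervals$end[1]
  out <- list()
  for (k in seq_len(nrow(intervals))[-1]) {
    if (intervals$start[k] - end < merge_gap) {
      end <- max(end, intervals$end[k])
    } else {
      out[[length(out) + 1]] <- c(start, end)
      start <- intervals$start[k]
      end <- intervals$end[k]
    }
  }
  out[[length(out) + 1]] <- c(start, end)
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("start", "end")
  res <- res[res$end - res$start >= min_duration, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect spike-and-wave discharge intervals
#'
#' Automates the study's SWD criteria: a sample belongs to a raw detection
#' when (a) the short-time power fraction in the 7-12 Hz band exceeds
#' `frac_threshold` and (b) the short-time amplitude is at least `amp_ratio`
#' times the rolling baseline amplitude (the median amplitude of nearby
#' non-SWD-like windows). Raw detections are then merged (< `merge_gap` s of
#' baseline) and filtered (>= `min_duration` s), so no reported interval is
#' ever shorter than the minimum seizure duration.
#'
#' @param trace a preprocessed [eeg_trace()], at least 10 s long
#' @param band SWD frequency band (Hz)
#' @param amp_ratio minimum amplitude ratio over baseline (inclusive)
#' @param window sliding-window length (s); windows advance by half a window
#' @param frac_threshold minimum in-band power fraction (of 1-90 Hz power)
#' @param baseline_s span of the rolling baseline estimate (s)
#' @param merge_gap,min_duration interval post-processing rules (s)
#' @return data frame of detected intervals (`start`, `end`, in seconds
#'   relative to `trace$t0`)
#' @export
detect_swd <- function(trace, band = c(7, 12), amp_ratio = 2, window = 0.5,
                       frac_threshold = 0.3, baseline_s = 10,
                       merge_gap = 1, min_duration = 2) {
  fs <- trace$fs
  x <- trace$samples
  if (length(x) < 10 * fs)
    stop("trace must be at least 10 s long for baseline estimation")
  if (sd(x) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  nwin <- round(window * fs)
  hop <- max(1, nwin %/% 2)
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  nw <- length(starts)
  frac <- amp <- numeric(nw)
  for (k in seq_len(nw)) {
    seg <- x[starts[k]:(starts[k] + nwin - 1)]
    seg <- seg - mean(seg)
    sp <- abs(fft(seg))^2
    freqs <- (seq_along(seg) - 1) * fs / length(seg)
    half <- freqs <= fs / 2
    tot <- sum(sp[half & freqs >= 1 & freqs <= 90])
    inb <- sum(sp[half & freqs >= band[1] & freqs <= band[2]])
    frac[k] <- if (tot > 0) inb / tot else 0
    amp[k] <- sqrt(mean(seg^2))
  }
  rawflag <- frac >= frac_threshold
  # rolling baseline amplitude from non-SWD-like windows
  halfspan <- max(1, round(baseline_s / 2 / (hop / fs)))
  base <- numeric(nw)
  glob <- if (any(!rawflag)) median(amp[!rawflag]) else median(amp)
  for (k in seq_len(nw)) {
    lo <- max(1, k - halfspan); hi <- min(nw, k + halfspan)
    vals <- amp[lo:hi][!rawflag[lo:hi]]
    base[k] <- if (length(vals)) median(vals) else glob
  }
  flag <- rawflag & amp >= amp_ratio * base
  if (!any(flag)) return(data.frame(start = numeric(0), end = numeric(0)))
  runs <- rle(flag)
  ends_idx <- cumsum(runs$lengths)
  begins_idx <- ends_idx - runs$lengths + 1
  keep <- which(runs$values)
  ivs <- data.frame(
    start = (starts[begins_idx[keep]] - 1) / fs,
    end = (starts[ends_idx[keep]] - 1 + nwin) / fs)
  merge_and_filter(ivs, merge_gap, min_duration)
}

#' Fraction of a stimulation block overlapped by a seizure interval
#'
#' @param block list or one-row data frame with `onset` and `duration` (s)
#' @param interval list or one-row data frame with `start` and `end` (s)
#' @return overlap fraction in `[0, 1]` of the block duration
#' @export
overlap_fraction <- function(block, interval) {
  b0 <- block$onset
  b1 <- block$onset + block$duration
  inter <- max(0, min(b1, interval$end) - max(b0, interval$start))
  inter / block$duration
}

#' Classify stimulation blocks relative to seizures
#'
#' Assigns each stimulation block exactly one label of the 8-way taxonomy,
#' in precedence order: `ended_seizure` (block starts inside a seizure whose
#' end falls within `[0, end_window]` s of the block onset), `fully_inside`,
#' `started_during_mostly_inside` / `_outside` (onset inside a seizure,
#' overlap fraction > 0.5 vs <= 0.5), `started_before_mostly_inside` /
#' `_outside` (a seizure begins inside the block), `right_after_seizure`
#' (onset within `after_window` s after a seizure end), else `baseline`.
#'
#' @param blocks data frame with `onset`, `duration` (s), sorted,
#'   non-overlapping
#' @param seizures data frame of merged seizure intervals (`start`, `end`)
#' @param end_window seizure-termination window after block onset (s)
#' @param after_window window defining "right after seizure" (s)
#' @return `blocks` with an added `label` factor column
#' @export
classify_stimulations <- function(blocks, seizures, end_window = 2,
                                  after_window = 2) {
  if (nrow(blocks) > 1) {
    o <- order(blocks$onset)
    blocks <- blocks[o, , drop = FALSE]
    if (any(blocks$onset[-1] < (blocks$onset + blocks$duration)[-nrow(blocks)]))
      stop("stimulation blocks must not overlap")
  }
  labels <- c("baseline", "fully_inside", "started_during_mostly_inside",
              "started_during_mostly_outside", "started_before_mostly_inside",
              "started_before_mostly_outside", "ended_seizure",
              "right_after_seizure")
  lab <- character(nrow(blocks))
  for (k in seq_len(nrow(blocks))) {
    b <- list(onset = blocks$onset[k], duration = blocks$duration[k])
    b_end <- b$onset + b$duration
    lab[k] <- "baseline"
    if (nrow(seizures) == 0) next
    onset_in <- which(seizures$start <= b$onset & b$onset < seizures$end)
    if (length(onset_in)) {
      sz <- seizures[onset_in[1], ]
      if (sz$end - b$onset >= 0 && sz$end - b$onset <= end_window) {
        lab[k] <- "ended_seizure"
        next
      }
      if (sz$start <= b$onset && b_end <= sz$end) {
        lab[k] <- "fully_inside"
        next
      }
      ov <- overlap_fraction(b, sz)
      lab[k] <- if (ov > 0.5) "started_during_mostly_inside" else
        "started_during_mostly_outside"
      next
    }
    begins_in <- which(seizures$start > b$onset & seizures$start < b_end)
    if (length(begins_in)) {
      ov <- sum(vapply(begins_in, function(j)
        overlap_fraction(b, seizures[j, ]), 0))
      lab[k] <- if (ov > 0.5) "started_before_mostly_inside" else
        "started_before_mostly_outside"
      next
    }
    after <- which(b$onset - seizures$end >= 0 &
                     b$onset - seizures$end <= after_window)
    if (length(after)) lab[k] <- "right_after_seizure"
  }
  blocks$label <- factor(lab, levels = labels)
  blocks
}
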