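# Preprocessing chain: segment -> band-pass filter -> downsample ->
# (blink screen) -> channel interpolation -> common average reference.
# preprocess_recording() enforces this order; every step is also exported
# on its own. All filters are zero-phase (forward-backward), so the
# effective magnitude response is the square of the named design; the
# frequency-domain statistics downstream are phase-insensitive.

#' Cut a recording into fixed-length sequence epochs
#'
#' One epoch per sequence-onset event, spanning `epoch_pre` s before to
#' `epoch_post` s after the onset (defaults give the canonical 47 s epoch).
#' Epochs that would exceed the recording bounds are skipped with a
#' warning.
#'
#' @param recording An `fpvs_recording`.
#' @param epoch_pre Seconds before onset included in the epoch.
#' @param epoch_post Seconds after onset included in the epoch.
#' @return An object of class `fpvs_segments`: list with `segments` (list
#'   of channels x samples matrices), `conditions`, `sampling_rate`,
#'   `channel_labels`, and `t0_offset` (epoch start relative to onset, s).
#' @export
segment_sequences <- function(recording, epoch_pre = 2, epoch_post = 45) {
  stopifnot(inherits(recording, "fpvs_recording"))
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  len <- round((epoch_pre + epoch_post) * fs)
  segs <- list(); conds <- character(0)
  if (nrow(recording$events) == 0)
    warning("recording has no sequence-onset events; returning 0 segments")
  for (i in seq_len(nrow(recording$events))) {
    s0 <- recording$events$sample[i] - round(epoch_pre * fs)
    s1 <- s0 + len - 1L
    if (s0 < 1 || s1 > n) {
      warning(sprintf("sequence %d epoch [%d, %d] exceeds recording bounds; skipped",
                      i, s0, s1))
      next
    }
    segs[[length(segs) + 1L]] <- recording$data[, s0:s1, drop = FALSE]
    conds <- c(conds, recording$events$condition[i])
  }
  structure(list(segments = segs,
                 conditions = conds,
                 sampling_rate = fs,
                 channel_labels = recording$channel_labels,
                 t0_offset = -epoch_pre,
                 subject_id = recording$subject_id,
                 group = recording$group),
            class = "fpvs_segments")
}

# zero-phase Butterworth applied row-wise to a channels x samples matrix
.filtfilt_mat <- function(x, flt) {
  t(apply(x, 1, function(ch) signal::filtfilt(flt, ch)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass of the stated order forwards and
#' backwards (zero phase) to every channel of every segment.
#'
#' @param segments An `fpvs_segments` object.
#' @param low,high Pass-band edges in Hz.
#' @param order Filter order of the underlying one-pass design.
#' @return Filtered `fpvs_segments`.
#' @export
bandpass_segments <- function(segments, low = 0.1, high = 100, order = 4) {
  stopifnot(inherits(segments, "fpvs_segments"))
  nyq <- segments$sampling_rate / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyq)
    stop(sprintf("high edge (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 high, nyq))
  flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  segments$segments <- lapply(segments$segments, .filtfilt_mat, flt = flt)
  segments
}

#' Anti-aliased decimation of segments
#'
#' Downsamples every segment to `target` Hz. The decimation ratio must be
#' an integer; an eighth-order Chebyshev type-I low-pass (applied forwards
#' and backwards) precedes subsampling.
#'
#' @param segments An `fpvs_segments` object.
#' @param target Target sampling rate in Hz.
#' @return Decimated `fpvs_segments`.
#' @export
downsample_segments <- function(segments, target = 256) {
  stopifnot(inherits(segments, "fpvs_segments"))
  q <- segments$sampling_rate / target
  if (abs(q - round(q)) > 1e-9)
    stop(sprintf("sampling rate %g is not an integer multiple of target %g",
                 segments$sampling_rate, target))
  q <- as.integer(round(q))
  if (q == 1L) return(segments)
  segments$segments <- lapply(segments$segments, function(m) {
    t(apply(m, 1, function(ch) signal::decimate(ch, q, ftype = "iir")))
  })
  segments$sampling_rate <- target
  segments
}

#' Estimate blink rate from a frontal or EOG channel
#'
#' Low-passes the series (zero-phase Butterworth, 2nd order, 5 Hz), then
#' counts threshold-crossing peaks with a minimum inter-blink interval of
#' 0.2 s, and divides by the duration.
#'
#' @param x Numeric vector, one channel in µV.
#' @param sampling_rate Sampling rate in Hz.
#' @param threshold Peak detection threshold in µV on the low-passed
#'   signal.
#' @return Blink rate in events/s.
#' @export
blink_rate <- function(x, sampling_rate, threshold = 40) {
  stopifnot(length(x) > 1, sampling_rate > 0)
  dur <- length(x) / sampling_rate
  flt <- signal::butter(2, 5 / (sampling_rate / 2), type = "low")
  xl <- signal::filtfilt(flt, x - stats::median(x))
  above <- xl > threshold
  if (!any(above)) return(0)
  # rising edges, enforcing the refractory interval
  edges <- which(diff(c(FALSE, above)) == 1)
  min_gap <- round(0.2 * sampling_rate)
  keep <- c(TRUE, diff(edges) >= min_gap)
  sum(keep) / dur
}

#' Flag subjects blinking more than mean + 2 SD of the cohort
#'
#' @param rates Named numeric vector of per-subject blink rates (events/s).
#' @return Data frame with `subject`, `rate`, and logical `flagged`
#'   (`rate > mean(rates) + 2 * sd(rates)`).
#' @export
blink_screen <- function(rates) {
  thr <- mean(rates) + 2 * stats::sd(rates)
  data.frame(subject = names(rates), rate = as.numeric(rates),
             flagged = as.numeric(rates) > thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Interpolate noisy channels from their 3 nearest neighbours
#'
#' Each bad channel is replaced, in place, by the unweighted mean of its 3
#' spatially nearest good channels (Euclidean distance on the idealized
#' unit-sphere montage). At most 5% of the channels may be interpolated
#' (3 of 64).
#'
#' @param segments An `fpvs_segments` object.
#' @param bad Character vector of bad channel labels.
#' @param k Number of neighbours averaged.
#' @return `fpvs_segments` with bad channels replaced; channel count and
#'   order are unchanged.
#' @export
interpolate_channels <- function(segments, bad, k = 3) {
  stopifnot(inherits(segments, "fpvs_segments"))
  if (length(bad) == 0) return(segments)
  labels <- segments$channel_labels
  unknown <- setdiff(bad, labels)
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  cap <- floor(0.05 * length(labels))
  if (length(bad) > cap)
    stop(sprintf("%d bad channels exceed the 5%% cap (%d of %d)",
                 length(bad), cap, length(labels)))
  good <- setdiff(labels, bad)
  nb <- lapply(bad, nearest_electrodes, candidates = good, k = k)
  names(nb) <- bad
  segments$segments <- lapply(segments$segments, function(m) {
    for (b in bad) {
      m[match(b, labels), ] <- colMeans(m[match(nb[[b]], labels), , drop = FALSE])
    }
    m
  })
  segments$interpolated <- nb
  segments
}

#' Re-reference to the common average
#'
#' Subtracts, per time point, the mean across scalp channels from every
#' scalp channel.
#'
#' @param segments An `fpvs_segments` object.
#' @param exclude Channel labels excluded from the average (e.g. EOG);
#'   excluded channels are left untouched.
#' @return Re-referenced `fpvs_segments`.
#' @export
rereference_average <- function(segments, exclude = character(0)) {
  stopifnot(inherits(segments, "fpvs_segments"))
  scalp <- !(segments$channel_labels %in% exclude)
  if (sum(scalp) < 2) stop("need at least 2 scalp channels")
  segments$segments <- lapply(segments$segments, function(m) {
    avg <- colMeans(m[scalp, , drop = FALSE])
    m[scalp, ] <- sweep(m[scalp, , drop = FALSE], 2, avg)
    m
  })
  segments
}

#' Subtract an EOG channel by regression
#'
#' Optional blink attenuation: each channel is residualized on the given
#' reference series by ordinary least squares.
#'
#' @param segments An `fpvs_segments` object.
#' @param eog Numeric vector per segment sample count, or the label of a
#'   channel to use as the regressor.
#' @return `fpvs_segments` with the regressor's contribution removed.
#' @export
regress_eog <- function(segments, eog) {
  stopifnot(inherits(segments, "fpvs_segments"))
  use_label <- is.character(eog)
  segments$segments <- lapply(segments$segments, function(m) {
    r <- if (use_label) m[match(eog, segments$channel_labels), ] else eog
    r <- r - mean(r)
    denom <- sum(r^2)
    if (denom == 0) return(m)
    beta <- (m %*% r) / denom
    m - beta %*% t(r)
  })
  segments
}

#' Run the full preprocessing chain
#'
#' Applies, in order: segmentation, band-pass filtering, decimation,
#' channel interpolation, and common-average re-referencing. Blink
#' screening is a cohort-level decision and is exposed separately
#' ([blink_rate()], [blink_screen()]).
#'
#' @param recording An `fpvs_recording`.
#' @param epoch_pre,epoch_post Epoch window around onsets, s.
#' @param low,high,order Band-pass parameters (set `low = NULL` to skip
#'   filtering).
#' @param resample Target rate in Hz (`NULL` to skip decimation).
#' @param bad_channels Labels to interpolate.
#' @param reref Logical; apply the common average reference.
#' @return An `fpvs_segments` object.
#' @export
preprocess_recording <- function(recording, epoch_pre = 2, epoch_post = 45,
                                 low = 0.1, high = 100, order = 4,
                                 resample = 256, bad_channels = character(0),
                                 reref = TRUE) {
  segs <- segment_sequences(recording, epoch_pre, epoch_post)
  if (!is.null(low))
    segs <- bandpass_segments(segs, low = low, high = high, order = order)
  if (!is.null(resample))
    segs <- downsample_segments(segs, target = resample)
  segs <- interpolate_channels(segs, bad_channels)
  if (reref) segs <- rereference_average(segs)
  segs
}

#' @export
print.fpvs_segments <- function(x, ...) {
  ns <- if (length(x$segments)) ncol(x$segments[[1]]) else 0
  cat(sprintf("FPVS segments: %d epoch(s) x %d channels x %d samples @ %g Hz\n",
              length(x$segments), length(x$channel_labels), ns,
              x$sampling_rate))
  if (length(x$conditions))
    cat("  conditions:", paste(sprintf("%s (%d)", names(table(x$conditions)),
                                       table(x$conditions)), collapse = ", "),
        "\n")
  invisible(x)
}
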