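# Frequency-domain statistics. The amplitude spectrum is the one-sided
# FFT amplitude (2|X_k|/N, DC and Nyquist unscaled by 2). Per-bin noise is
# summarized over a window of surrounding bins: 12 bins on each side,
# excluding the bin directly adjacent on each side and the single highest-
# and lowest-amplitude bins of the remainder, leaving 20 bins. SNR,
# baseline-corrected amplitude and z-score are all defined against that
# window. No taper is applied before the FFT; cropping epochs to an
# integer number of oddball cycles is the leakage control.

#' Crop segments to an integer number of oddball cycles
#'
#' Retains, from each segment, the samples from the end of the fade-in
#' spanning `duration` seconds. With the canonical parameters (256 Hz,
#' 39.1992 s) this is exactly 10035 samples. The operation is idempotent:
#' cropped segments are returned unchanged.
#'
#' @param segments An `fpvs_segments` object.
#' @param fade_duration Fade-in duration after sequence onset, s.
#' @param duration Cropped window length, s.
#' @return `fpvs_segments` whose segments all have
#'   `round(duration * sampling_rate)` samples and whose `t0_offset`
#'   equals `fade_duration`.
#' @export
crop_to_cycles <- function(segments, fade_duration = 2, duration = 39.1992) {
  stopifnot(inherits(segments, "fpvs_segments"))
  fs <- segments$sampling_rate
  n_keep <- round(duration * fs)
  start <- round((fade_duration - segments$t0_offset) * fs)  # 0-based offset
  segments$segments <- lapply(segments$segments, function(m) {
    if (start + n_keep > ncol(m))
      stop(sprintf("segment too short to crop: need %d samples from offset %d, have %d",
                   n_keep, start, ncol(m)))
    m[, start + seq_len(n_keep), drop = FALSE]
  })
  segments$t0_offset <- fade_duration
  segments
}

#' Average segments per condition
#'
#' Time-domain mean across all segments of each condition, per channel.
#' Conditions with no segments are omitted with a warning.
#'
#' @param segments An `fpvs_segments` object.
#' @param conditions Conditions to average (default: all present).
#' @return `fpvs_segments` with one averaged segment per condition;
#'   `n_averaged` records how many segments entered each average.
#' @export
average_segments <- function(segments, conditions = NULL) {
  stopifnot(inherits(segments, "fpvs_segments"))
  if (is.null(conditions)) conditions <- unique(segments$conditions)
  avg <- list(); kept <- character(0); n_avg <- integer(0)
  for (cond in conditions) {
    i <- which(segments$conditions == cond)
    if (length(i) == 0) {
      warning("no segments for condition ", cond, "; omitted")
      next
    }
    avg[[length(avg) + 1L]] <- Reduce(`+`, segments$segments[i]) / length(i)
    kept <- c(kept, cond); n_avg <- c(n_avg, length(i))
  }
  segments$segments <- avg
  segments$conditions <- kept
  segments$n_averaged <- n_avg
  segments
}

#' One-sided FFT amplitude spectrum
#'
#' @param x Channels x samples matrix (or a single numeric vector).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Optional channel labels.
#' @param meta Optional list of provenance fields (subject, group,
#'   condition, n_segments_averaged).
#' @return Object of class `fpvs_spectrum`: `amplitudes` (channels x bins,
#'   µV), `frequencies` (Hz, starting at 0), `bin_width`
#'   (= sampling_rate / n_samples), `channel_labels`, `meta`.
#' @examples
#' fs <- 256; t <- (0:(fs * 5 - 1)) / fs
#' sp <- amplitude_spectrum(sin(2 * pi * 6 * t), fs)
#' sp$amplitudes[1, which.min(abs(sp$frequencies - 6))]  # ~1
#' @export
amplitude_spectrum <- function(x, sampling_rate, channel_labels = NULL,
                               meta = list()) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  nb <- floor(n / 2) + 1L
  X <- stats::mvfft(t(x))
  amp <- 2 * Mod(t(X[seq_len(nb), , drop = FALSE])) / n
  amp[, 1] <- amp[, 1] / 2
  if (n %% 2 == 0) amp[, nb] <- amp[, nb] / 2
  if (is.null(channel_labels)) channel_labels <- rownames(x)
  structure(list(amplitudes = amp,
                 frequencies = (seq_len(nb) - 1) * sampling_rate / n,
                 bin_width = sampling_rate / n,
                 sampling_rate = sampling_rate,
                 channel_labels = channel_labels,
                 meta = meta),
            class = "fpvs_spectrum")
}

#' Spectra of condition-averaged segments
#'
#' Convenience wrapper: [average_segments()] then [amplitude_spectrum()]
#' per condition.
#'
#' @param segments An `fpvs_segments` object (already cropped).
#' @return Named list of `fpvs_spectrum`, one per condition.
#' @export
condition_spectra <- function(segments) {
  avg <- average_segments(segments)
  out <- list()
  for (i in seq_along(avg$conditions)) {
    out[[avg$conditions[i]]] <- amplitude_spectrum(
      avg$segments[[i]], avg$sampling_rate, avg$channel_labels,
      meta = list(subject = avg$subject_id, group = avg$group,
                  condition = avg$conditions[i],
                  n_segments_averaged = avg$n_averaged[i]))
  }
  out
}

#' Noise-window specification
#'
#' Defaults encode the canonical rule: 12 bins on each side of the target
#' (24 bins), excluding the bin directly adjacent on each side and the two
#' bins with the most extreme values (the single maximum and the single
#' minimum of the remaining 22), leaving exactly 20 bins.
#'
#' @param side_bins Bins considered on each side of the target.
#' @param exclude_adjacent Bins dropped directly adjacent to the target,
#'   per side.
#' @param exclude_extreme Total extreme bins dropped (split between the
#'   maximum and the minimum).
#' @return Object of class `fpvs_noise_spec` with a `resulting_bins` field.
#' @export
noise_window_spec <- function(side_bins = 12, exclude_adjacent = 1,
                              exclude_extreme = 2) {
  resulting <- 2 * side_bins - 2 * exclude_adjacent - exclude_extreme
  if (resulting < 2) stop("noise window specification leaves too few bins")
  structure(list(side_bins = side_bins, exclude_adjacent = exclude_adjacent,
                 exclude_extreme = exclude_extreme,
                 resulting_bins = resulting),
            class = "fpvs_noise_spec")
}

#' Noise-window bin indices around a target bin
#'
#' @param amplitudes Numeric vector of per-bin amplitudes (one channel).
#' @param bin Target bin index (1-based; bin 1 is DC).
#' @param spec An [noise_window_spec()] object.
#' @return Integer vector of `spec$resulting_bins` indices.
#' @export
noise_window <- function(amplitudes, bin, spec = noise_window_spec()) {
  nb <- length(amplitudes)
  lo <- bin - spec$side_bins; hi <- bin + spec$side_bins
  if (lo < 2 || hi > nb)
    stop(sprintf("noise window [%d, %d] out of range (2..%d)", lo, hi, nb))
  adj <- if (spec$exclude_adjacent > 0)
    c(bin - seq_len(spec$exclude_adjacent), bin + seq_len(spec$exclude_adjacent))
  else integer(0)
  idx <- setdiff(lo:hi, c(bin, adj))
  if (spec$exclude_extreme > 0) {
    n_hi <- ceiling(spec$exclude_extreme / 2)
    n_lo <- spec$exclude_extreme - n_hi
    ord <- idx[order(amplitudes[idx])]
    drop <- c(utils::head(ord, n_lo), utils::tail(ord, n_hi))
    idx <- setdiff(idx, drop)
  }
  idx
}

# per-channel window statistics; x is an fpvs_spectrum. The extreme-bin
# exclusion only feeds the mean/SD, so it is applied on sorted values
# (equivalent to index bookkeeping, and much cheaper).
.window_stats <- function(x, bin, spec, sd_type, rows = NULL) {
  nb <- ncol(x$amplitudes)
  side <- spec$side_bins; adj <- spec$exclude_adjacent
  if (bin - side < 2 || bin + side > nb)
    stop(sprintf("noise window [%d, %d] out of range (2..%d)",
                 bin - side, bin + side, nb))
  idx <- c((bin - side):(bin - adj - 1L), (bin + adj + 1L):(bin + side))
  if (is.null(rows)) rows <- seq_len(nrow(x$amplitudes))
  n_hi <- ceiling(spec$exclude_extreme / 2)
  n_lo <- spec$exclude_extreme - n_hi
  out <- matrix(0, length(rows), 3,
                dimnames = list(NULL, c("amp", "mean", "sd")))
  for (j in seq_along(rows)) {
    v <- sort.int(x$amplitudes[rows[j], idx])
    if (spec$exclude_extreme > 0)
      v <- v[(n_lo + 1L):(length(v) - n_hi)]
    m <- sum(v) / length(v)
    vr <- sum((v - m)^2)
    vr <- if (sd_type == "population") vr / length(v) else vr / (length(v) - 1)
    out[j, ] <- c(x$amplitudes[rows[j], bin], m, sqrt(vr))
  }
  out
}

#' Map a frequency to its nearest FFT bin
#'
#' @param spectrum An `fpvs_spectrum`.
#' @param freq Frequency in Hz.
#' @return 1-based bin index; the residual offset in Hz is attached as
#'   attribute `"residual"`.
#' @export
freq_to_bin <- function(spectrum, freq) {
  bin <- which.min(abs(spectrum$frequencies - freq))
  structure(bin, residual = spectrum$frequencies[bin] - freq)
}

#' Signal-to-noise ratio at a frequency bin
#'
#' Amplitude at the target bin divided by the mean amplitude of the noise
#' window. A zero noise mean (degenerate noiseless input) yields `Inf`
#' with a warning.
#'
#' @param spectrum An `fpvs_spectrum`.
#' @param bin Target bin index (1-based).
#' @param spec An [noise_window_spec()].
#' @return Named numeric vector, one SNR per channel.
#' @export
snr <- function(spectrum, bin, spec = noise_window_spec()) {
  st <- .window_stats(spectrum, bin, spec, "population")
  out <- st[, "amp"] / st[, "mean"]
  if (any(st[, "mean"] == 0)) {
    warning("zero noise-window mean; SNR reported as Inf")
    out[st[, "mean"] == 0 & st[, "amp"] > 0] <- Inf
    out[st[, "mean"] == 0 & st[, "amp"] == 0] <- 1
  }
  stats::setNames(out, spectrum$channel_labels)
}

#' Baseline-corrected amplitude at a frequency bin
#'
#' Amplitude at the target bin minus the mean amplitude of the noise
#' window; may be negative.
#'
#' @inheritParams snr
#' @return Named numeric vector in µV, one value per channel.
#' @export
baseline_corrected <- function(spectrum, bin, spec = noise_window_spec()) {
  st <- .window_stats(spectrum, bin, spec, "population")
  stats::setNames(st[, "amp"] - st[, "mean"], spectrum$channel_labels)
}

#' Noise-window z-score at a frequency bin
#'
#' (amplitude - window mean) / window SD. The SD uses the population (n)
#' denominator by default. A zero numerator with zero SD yields 0; a
#' positive numerator with zero SD yields `Inf` with a warning.
#'
#' @inheritParams snr
#' @param sd_type `"population"` (n denominator) or `"sample"` (n - 1).
#' @return Named numeric vector, one z per channel.
#' @export
zscore_bin <- function(spectrum, bin, spec = noise_window_spec(),
                       sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  st <- .window_stats(spectrum, bin, spec, sd_type)
  num <- st[, "amp"] - st[, "mean"]
  out <- num / st[, "sd"]
  zero_sd <- st[, "sd"] == 0
  if (any(zero_sd)) {
    out[zero_sd & num == 0] <- 0
    if (any(zero_sd & num != 0))
      warning("zero noise-window SD with nonzero numerator; z reported as +/-Inf")
  }
  stats::setNames(out, spectrum$channel_labels)
}

#' Average spectra across subjects and/or channels
#'
#' Amplitude spectra are averaged bin-wise. All spectra must share the
#' same frequency axis.
#'
#' @param spectra List of `fpvs_spectrum` objects.
#' @param channels Optional channel subset to average over; `TRUE` (the
#'   default) averages over all channels, `FALSE` keeps channels separate.
#' @return An `fpvs_spectrum` (single-row if channel-averaged).
#' @export
average_spectra <- function(spectra, channels = TRUE) {
  stopifnot(length(spectra) >= 1)
  bw <- vapply(spectra, function(s) s$bin_width, numeric(1))
  if (max(abs(bw - bw[1])) > 1e-12)
    stop("spectra have different frequency axes")
  amp <- Reduce(`+`, lapply(spectra, `[[`, "amplitudes")) / length(spectra)
  out <- spectra[[1]]
  out$amplitudes <- amp
  out$meta <- list(n_spectra_averaged = length(spectra))
  if (isTRUE(channels)) {
    out$amplitudes <- matrix(colMeans(amp), nrow = 1)
    out$channel_labels <- "average"
  } else if (is.character(channels)) {
    i <- match(channels, out$channel_labels)
    if (anyNA(i)) stop("unknown channel(s): ",
                       paste(channels[is.na(i)], collapse = ", "))
    out$amplitudes <- matrix(colMeans(amp[i, , drop = FALSE]), nrow = 1)
    out$channel_labels <- "average"
  }
  out
}

#' @export
print.fpvs_spectrum <- function(x, ...) {
  cat(sprintf("FPVS amplitude spectrum: %d channel(s) x %d bins, bin width %.5f Hz (0..%.1f Hz)\n",
              nrow(x$amplitudes), ncol(x$amplitudes), x$bin_width,
              max(x$frequencies)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}
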