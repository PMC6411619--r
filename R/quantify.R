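# Harmonic selection and response quantification. At the group level,
# harmonics of the oddball (and base) frequency are walked upward on the
# grand-average spectrum and included while their noise-window z exceeds
# 1.64 (p < .05 one-tailed); bins at base-rate multiples are skipped,
# never counted as breaks, because they carry the base response. Responses
# are the sums of baseline-corrected amplitudes over the selected
# harmonics, averaged within regions of interest. Per-subject significance
# sums 41-bin spectrum windows centred on each selected harmonic and
# z-scores the centre of the summed window (threshold 2.33, p < .01
# one-tailed).

#' Default regions of interest
#'
#' Medial occipital (MO: Oz, Iz, O1, O2), left occipito-temporal
#' (LOT: P7, P9, PO7) and right occipito-temporal (ROT: P8, P10, PO8).
#'
#' @return Named list of electrode-label vectors.
#' @export
default_rois <- function() {
  list(MO = c("Oz", "Iz", "O1", "O2"),
       LOT = c("P7", "P9", "PO7"),
       ROT = c("P8", "P10", "PO8"))
}

#' Select significant harmonics on a grand-average spectrum
#'
#' Walks multiples of the oddball frequency upward, skipping base-rate
#' multiples (they are neither included nor treated as breaks), including
#' harmonics while the noise-window z exceeds `z_threshold`, and stopping
#' at the first non-significant non-base harmonic. Base-rate multiples are
#' walked the same way for the general visual response.
#'
#' @param grand_spectrum A subject- and electrode-averaged single-channel
#'   `fpvs_spectrum` (groups pooled).
#' @param oddball_freq,base_freq Stimulation frequencies in Hz.
#' @param z_threshold Inclusion threshold (1.64 = p < .05 one-tailed).
#' @param spec An [noise_window_spec()].
#' @return Object of class `fpvs_harmonic_plan`: `oddball_harmonics` and
#'   `base_harmonics` (Hz, ascending), their z-scores, and the threshold.
#' @export
select_harmonics <- function(grand_spectrum, oddball_freq = 1.2,
                             base_freq = 6, z_threshold = 1.64,
                             spec = noise_window_spec()) {
  stopifnot(inherits(grand_spectrum, "fpvs_spectrum"),
            nrow(grand_spectrum$amplitudes) == 1)
  nb <- length(grand_spectrum$frequencies)
  fmax <- grand_spectrum$frequencies[nb - spec$side_bins]

  walk <- function(step, skip_base) {
    freqs <- numeric(0); zs <- numeric(0); k <- 1L
    repeat {
      f <- k * step
      if (f >= fmax) break
      k <- k + 1L
      if (skip_base) {
        r <- f / base_freq
        if (abs(r - round(r)) < 1e-9) next   # base bin: skip, not a break
      }
      bin <- freq_to_bin(grand_spectrum, f)
      z <- zscore_bin(grand_spectrum, as.integer(bin), spec)
      if (z > z_threshold) {
        freqs <- c(freqs, f); zs <- c(zs, z)
      } else break
    }
    list(freqs = freqs, z = zs)
  }

  odd <- walk(oddball_freq, skip_base = TRUE)
  base <- walk(base_freq, skip_base = FALSE)
  if (length(odd$freqs) == 0)
    warning("first oddball harmonic not significant; empty oddball plan")
  structure(list(oddball_harmonics = odd$freqs,
                 base_harmonics = base$freqs,
                 oddball_z = odd$z,
                 base_z = base$z,
                 z_threshold = z_threshold),
            class = "fpvs_harmonic_plan")
}

#' @export
print.fpvs_harmonic_plan <- function(x, ...) {
  cat("FPVS harmonic plan (z >", x$z_threshold, ")\n")
  cat(sprintf("  oddball: %d harmonic(s): %s Hz\n",
              length(x$oddball_harmonics),
              paste(x$oddball_harmonics, collapse = ", ")))
  cat(sprintf("  base:    %d harmonic(s): %s Hz\n",
              length(x$base_harmonics),
              paste(x$base_harmonics, collapse = ", ")))
  invisible(x)
}

# ROI-averaged baseline-corrected amplitude at one frequency (fast path:
# window statistics computed for the ROI rows only)
.roi_baseline <- function(spectrum, freq, roi, spec) {
  i <- match(roi, spectrum$channel_labels)
  if (anyNA(i))
    stop("ROI electrode(s) missing from spectrum: ",
         paste(roi[is.na(i)], collapse = ", "))
  bin <- as.integer(freq_to_bin(spectrum, freq))
  st <- .window_stats(spectrum, bin, spec, "population", rows = i)
  mean(st[, "amp"] - st[, "mean"])
}

#' Per-harmonic ROI amplitudes
#'
#' Baseline-corrected amplitude per selected oddball harmonic, averaged
#' over the ROI electrodes.
#'
#' @param spectrum A subject's condition `fpvs_spectrum`.
#' @param plan An `fpvs_harmonic_plan`.
#' @param roi Character vector of electrode labels.
#' @param spec An [noise_window_spec()].
#' @param which `"oddball"` or `"base"` harmonic set.
#' @return Named numeric vector (names = frequencies in Hz), µV.
#' @export
harmonic_amplitudes <- function(spectrum, plan, roi,
                                spec = noise_window_spec(),
                                which = c("oddball", "base")) {
  which <- match.arg(which)
  freqs <- if (which == "oddball") plan$oddball_harmonics else plan$base_harmonics
  vapply(stats::setNames(freqs, freqs), function(f)
    .roi_baseline(spectrum, f, roi, spec), numeric(1))
}

#' Summed ROI response
#'
#' Baseline-corrected amplitudes, averaged over the ROI electrodes and
#' summed over the plan's harmonics. ROI-averaging and harmonic summation
#' commute (both are linear).
#'
#' @inheritParams harmonic_amplitudes
#' @return Summed amplitude in µV.
#' @export
summed_response <- function(spectrum, plan, roi, spec = noise_window_spec(),
                            which = c("oddball", "base")) {
  which <- match.arg(which)
  freqs <- if (which == "oddball") plan$oddball_harmonics else plan$base_harmonics
  if (length(freqs) == 0) stop("harmonic plan is empty")
  sum(harmonic_amplitudes(spectrum, plan, roi, spec, which))
}

#' Individual-subject significance of the oddball response
#'
#' The subject's raw spectrum is averaged over the ROI electrodes and cut
#' into windows of `side` bins on each side of every plan harmonic; the
#' windows are summed element-wise across harmonics and the centre bin of
#' the summed window is z-scored against its noise window. Significant if
#' z exceeds `threshold` (2.33 = p < .01 one-tailed).
#'
#' @inheritParams harmonic_amplitudes
#' @param side Window half-width in bins around each harmonic.
#' @param threshold Significance threshold on z.
#' @return List with `z` and logical `significant`.
#' @export
individual_significance <- function(spectrum, plan, roi,
                                    spec = noise_window_spec(), side = 20,
                                    threshold = 2.33) {
  if (length(plan$oddball_harmonics) == 0) stop("harmonic plan is empty")
  i <- match(roi, spectrum$channel_labels)
  if (anyNA(i))
    stop("ROI electrode(s) missing from spectrum: ",
         paste(roi[is.na(i)], collapse = ", "))
  a <- colMeans(spectrum$amplitudes[i, , drop = FALSE])
  nb <- length(a)
  win <- rep(0, 2 * side + 1)
  for (f in plan$oddball_harmonics) {
    bin <- as.integer(freq_to_bin(spectrum, f))
    if (bin - side < 1 || bin + side > nb)
      stop(sprintf("window around %g Hz collides with the spectrum edge", f))
    win <- win + a[(bin - side):(bin + side)]
  }
  centre <- side + 1L
  sub <- amplitude_stub(win, spectrum)
  z <- as.numeric(zscore_bin(sub, centre, spec))
  list(z = z, significant = z > threshold)
}

# wrap a plain amplitude vector as a single-channel spectrum so the
# window statistics can be reused on summed windows
amplitude_stub <- function(amps, template) {
  structure(list(amplitudes = matrix(amps, nrow = 1),
                 frequencies = (seq_along(amps) - 1) * template$bin_width,
                 bin_width = template$bin_width,
                 sampling_rate = template$sampling_rate,
                 channel_labels = "window", meta = list()),
            class = "fpvs_spectrum")
}

#' Build the subject x condition x ROI response table
#'
#' @param subject_spectra List with one element per subject: a list with
#'   `subject`, `group`, and `spectra` (named list condition ->
#'   `fpvs_spectrum`), as produced by the pipeline.
#' @param plan An `fpvs_harmonic_plan`.
#' @param rois Named list of ROI electrode vectors (default LOT + ROT).
#' @param spec An [noise_window_spec()].
#' @param which Harmonic set to sum (`"oddball"` or `"base"`).
#' @param individual_side,individual_threshold Parameters of the
#'   per-subject significance test.
#' @return Data frame of class `fpvs_response_table`: one row per subject
#'   x condition x ROI with `summed_amplitude` (µV), `mean_snr` (mean SNR
#'   over the plan harmonics), `individual_z` and `significant`.
#' @export
response_table <- function(subject_spectra, plan,
                           rois = default_rois()[c("LOT", "ROT")],
                           spec = noise_window_spec(),
                           which = c("oddball", "base"),
                           individual_side = 20,
                           individual_threshold = 2.33) {
  which <- match.arg(which)
  rows <- list()
  for (subj in subject_spectra) {
    for (cond in names(subj$spectra)) {
      sp <- subj$spectra[[cond]]
      for (rn in names(rois)) {
        amp <- summed_response(sp, plan, rois[[rn]], spec, which)
        freqs <- if (which == "oddball") plan$oddball_harmonics else plan$base_harmonics
        i <- match(rois[[rn]], sp$channel_labels)
        snrs <- vapply(freqs, function(f) {
          bin <- as.integer(freq_to_bin(sp, f))
          st <- .window_stats(sp, bin, spec, "population", rows = i)
          mean(st[, "amp"] / st[, "mean"])
        }, numeric(1))
        ind <- if (which == "oddball")
          individual_significance(sp, plan, rois[[rn]], spec,
                                  individual_side, individual_threshold)
        else list(z = NA_real_, significant = NA)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj$subject, group = subj$group, condition = cond,
          roi = rn, summed_amplitude = amp, mean_snr = mean(snrs),
          individual_z = ind$z, significant = ind$significant,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fpvs_response_table", "data.frame")
  out
}

#' Per-harmonic amplitude table
#'
#' Tidy table of baseline-corrected amplitudes per subject x condition x
#' ROI x harmonic (the classification features are drawn from this).
#'
#' @inheritParams response_table
#' @return Data frame with columns `subject`, `group`, `condition`, `roi`,
#'   `freq`, `amplitude`.
#' @export
harmonic_table <- function(subject_spectra, plan,
                           rois = default_rois()[c("LOT", "ROT")],
                           spec = noise_window_spec(), freqs = NULL) {
  if (is.null(freqs)) freqs <- plan$oddball_harmonics
  rows <- list()
  for (subj in subject_spectra) {
    for (cond in names(subj$spectra)) {
      sp <- subj$spectra[[cond]]
      for (rn in names(rois)) {
        amps <- vapply(freqs, function(f)
          .roi_baseline(sp, f, rois[[rn]], spec), numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj$subject, group = subj$group, condition = cond,
          roi = rn, freq = freqs,
          amplitude = as.numeric(amps), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Face-inversion effect for one subject and ROI
#'
#' Summed upright amplitude minus summed inverted amplitude.
#'
#' @param table An `fpvs_response_table`.
#' @param subject Subject identifier.
#' @param roi ROI name.
#' @param upright,inverted Condition labels.
#' @return Difference in µV.
#' @export
inversion_effect <- function(table, subject, roi, upright = "upright",
                             inverted = "inverted") {
  up <- table$summed_amplitude[table$subject == subject & table$roi == roi &
                                 table$condition == upright]
  inv <- table$summed_amplitude[table$subject == subject & table$roi == roi &
                                  table$condition == inverted]
  if (length(up) != 1 || length(inv) != 1)
    stop("subject/ROI must have exactly one row per orientation")
  up - inv
}

#' @export
print.fpvs_response_table <- function(x, ...) {
  cat(sprintf("FPVS response table: %d rows (%d subjects x %d condition(s) x %d ROI(s))\n",
              nrow(x), length(unique(x$subject)),
              length(unique(x$condition)), length(unique(x$roi))))
  print.data.frame(utils::head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
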