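#' Simulation configuration for synthetic FPVS-EEG cohorts
#'
#' Collects every parameter of the synthetic generator. Defaults emulate the
#' study design the package targets: two groups of children (a typically
#' developing group `"TD"` and a patient-like group `"ASD"`), 6 Hz base
#' stimulation with a 1.2 Hz oddball (every fifth stimulus), sequences of
#' full-contrast stimulation flanked by 2 s sinusoidal contrast fade-in and
#' fade-out, 512 Hz acquisition on a BioSemi-style montage, 1/f + alpha
#' background noise. The oddball response is occipito-temporal and
#' right-lateralized; the base response is medial-occipital. Group effects
#' follow the qualitative finding the generator is built to emulate:
#' in the control group upright sequences evoke a larger oddball response
#' than inverted ones, while the patient-like group shows the reduced
#' upright response (upright amplitude = inverted amplitude).
#'
#' @param n_per_group Subjects per group.
#' @param n_sequences_per_condition Stimulation sequences per condition.
#' @param sampling_rate Acquisition rate in Hz.
#' @param full_duration Full-contrast stimulation duration in s.
#' @param fade_duration Contrast fade-in (= fade-out) duration in s.
#' @param epoch_pre Epoch start relative to sequence onset in s (positive
#'   number of seconds before onset).
#' @param epoch_post Epoch end relative to sequence onset in s. The default
#'   `NULL` resolves to `fade + full + fade + 1`; with the default 40 s
#'   stimulation this gives the canonical 47 s epoch (2 s pre + 45 s post).
#' @param base_freq Base stimulation frequency in Hz.
#' @param oddball_freq Oddball frequency in Hz; `base_freq` must be an
#'   integer multiple of it.
#' @param groups Two group labels, control-like first.
#' @param conditions Condition labels (orientation factor).
#' @param channel_labels Montage subset to simulate. Must contain the
#'   occipito-temporal ROI electrodes (P7, P9, PO7, P8, P10, PO8); the
#'   medial-occipital set (Oz, Iz, O1, O2) is additionally needed for the
#'   base-rate ROI analysis.
#' @param base_amp First-harmonic amplitude of the base response, µV.
#' @param oddball_amp Named list `group -> condition -> µV`, first-harmonic
#'   oddball amplitude. Defaults: TD upright 0.9, all others 0.6 (the 1.5x
#'   control-group upright advantage).
#' @param harmonic_decay Geometric per-harmonic amplitude decay factor.
#' @param n_harmonics Number of injected oddball harmonics (counted after
#'   excluding base-rate multiples).
#' @param n_base_harmonics Number of injected base-rate harmonics.
#' @param subject_sd Between-subject log-normal standard deviation of the
#'   per-subject response gain (applied to all conditions of a subject).
#' @param noise_1f_exponent Spectral exponent of the background noise
#'   (power spectral density proportional to 1/f^exponent).
#' @param noise_scale Background noise RMS amplitude per channel, µV.
#'   The default is calibrated so that, at the canonical recording scale,
#'   single-subject oddball responses reach the signal-to-noise regime
#'   typical of this paradigm (first-harmonic SNR of roughly 2-5 at the
#'   occipito-temporal maximum and individual significance for most
#'   simulated control subjects).
#' @param alpha_amp Amplitude of the ~10 Hz alpha sinusoid, µV.
#' @param alpha_freq Alpha frequency, Hz.
#' @param blink_rate Poisson rate of stereotyped blinks, events/s (0 = none;
#'   blinks can also be added afterwards with [inject_blinks()]).
#' @param blink_amp Peak blink amplitude at frontal electrodes, µV.
#' @param topographies Optional list overriding the built-in per-channel
#'   gain maps; any of `base`, `oddball`, `alpha`, `blink` may be a
#'   numeric vector of gains in `[0, 1]`, one per `channel_labels` entry
#'   (e.g. a flat map `rep(1, n)`).
#' @param seed Master seed; identical configurations give bit-identical
#'   cohorts.
#' @return An object of class `fpvs_sim_config` (a validated list).
#' @seealso [simulate_subject()], [simulate_cohort()]
#' @export
sim_config <- function(n_per_group = 23,
                       n_sequences_per_condition = 4,
                       sampling_rate = 512,
                       full_duration = 40,
                       fade_duration = 2,
                       epoch_pre = 2,
                       epoch_post = NULL,
                       base_freq = 6,
                       oddball_freq = 1.2,
                       groups = c("TD", "ASD"),
                       conditions = c("upright", "inverted"),
                       channel_labels = biosemi64_montage()$label,
                       base_amp = 1.0,
                       oddball_amp = NULL,
                       harmonic_decay = 0.7,
                       n_harmonics = 6,
                       n_base_harmonics = 3,
                       subject_sd = 0.3,
                       noise_1f_exponent = 1.0,
                       noise_scale = 5,
                       alpha_amp = 3,
                       alpha_freq = 10,
                       blink_rate = 0,
                       blink_amp = 100,
                       topographies = list(),
                       seed = 1L) {
  if (is.null(epoch_post)) epoch_post <- 2 * fade_duration + full_duration + 1
  if (is.null(oddball_amp)) {
    oddball_amp <- stats::setNames(
      list(stats::setNames(c(0.9, 0.6), conditions[c(1, min(2, length(conditions)))]),
           stats::setNames(c(0.6, 0.6), conditions[c(1, min(2, length(conditions)))])),
      groups)
    if (length(conditions) == 1)
      oddball_amp <- lapply(oddball_amp, function(x) x[1])
  }
  cfg <- list(n_per_group = n_per_group,
              n_sequences_per_condition = n_sequences_per_condition,
              sampling_rate = sampling_rate,
              full_duration = full_duration,
              fade_duration = fade_duration,
              epoch_pre = epoch_pre,
              epoch_post = epoch_post,
              base_freq = base_freq,
              oddball_freq = oddball_freq,
              groups = groups,
              conditions = conditions,
              channel_labels = channel_labels,
              base_amp = base_amp,
              oddball_amp = oddball_amp,
              harmonic_decay = harmonic_decay,
              n_harmonics = n_harmonics,
              n_base_harmonics = n_base_harmonics,
              subject_sd = subject_sd,
              noise_1f_exponent = noise_1f_exponent,
              noise_scale = noise_scale,
              alpha_amp = alpha_amp,
              alpha_freq = alpha_freq,
              blink_rate = blink_rate,
              blink_amp = blink_amp,
              topographies = topographies,
              seed = as.integer(seed))
  class(cfg) <- "fpvs_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config An `fpvs_sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "fpvs_sim_config"))
  with(config, {
    if (n_per_group < 1) stop("n_per_group must be >= 1")
    if (length(groups) != 2) stop("exactly two group labels are required")
    ratio <- base_freq / oddball_freq
    if (abs(ratio - round(ratio)) > 1e-9)
      stop("base_freq must be an integer multiple of oddball_freq")
    amps <- c(base_amp, unlist(oddball_amp), noise_scale, alpha_amp, blink_amp)
    if (any(amps < 0)) stop("all amplitudes must be >= 0")
    if (!all(names(oddball_amp) %in% groups))
      stop("oddball_amp names must match the group labels")
    fmax <- max(oddball_harmonic_freqs(oddball_freq, base_freq, n_harmonics),
                base_freq * n_base_harmonics, alpha_freq)
    if (sampling_rate <= 2 * fmax)
      stop("sampling_rate must exceed twice the highest simulated frequency (",
           fmax, " Hz)")
    # the occipito-temporal ROI electrodes are always required; the
    # medial-occipital set is only needed when the base-rate ROI analysis
    # is run (its absence is caught there)
    roi_needed <- c("P7", "P9", "PO7", "P8", "P10", "PO8")
    miss <- setdiff(roi_needed, channel_labels)
    if (length(miss))
      stop("channel_labels must include the occipito-temporal ROI electrodes; missing: ",
           paste(miss, collapse = ", "))
    for (tn in names(topographies)) {
      if (!tn %in% c("base", "oddball", "alpha", "blink"))
        stop("unknown topography override: ", tn)
      if (length(topographies[[tn]]) != length(channel_labels))
        stop("topography '", tn, "' must have one gain per channel")
      if (any(topographies[[tn]] < 0))
        stop("topography gains must be >= 0")
    }
    if (epoch_post < 2 * fade_duration + full_duration)
      stop("epoch_post must cover the stimulation sequence")
  })
  invisible(config)
}

#' Oddball harmonic frequencies excluding base-rate multiples
#'
#' The first `n` multiples of the oddball frequency that are not multiples
#' of the base frequency (those bins carry the base response, not the
#' oddball response).
#'
#' @param oddball_freq,base_freq Frequencies in Hz.
#' @param n Number of harmonics to return.
#' @return Numeric vector of `n` frequencies in Hz, ascending.
#' @examples
#' oddball_harmonic_freqs(1.2, 6, 6)  # 1.2 2.4 3.6 4.8 7.2 8.4
#' @export
oddball_harmonic_freqs <- function(oddball_freq, base_freq, n) {
  k <- 1L
  out <- numeric(0)
  while (length(out) < n) {
    f <- k * oddball_freq
    r <- f / base_freq
    if (abs(r - round(r)) > 1e-9) out <- c(out, f)
    k <- k + 1L
  }
  out
}

#' @export
print.fpvs_sim_config <- function(x, ...) {
  cat("FPVS simulation configuration\n")
  cat(sprintf("  %d subjects/group (%s), %d sequence(s) x %d condition(s)\n",
              x$n_per_group, paste(x$groups, collapse = " vs "),
              x$n_sequences_per_condition, length(x$conditions)))
  cat(sprintf("  base %g Hz, oddball %g Hz, %d+%d harmonics, decay %g\n",
              x$base_freq, x$oddball_freq, x$n_base_harmonics, x$n_harmonics,
              x$harmonic_decay))
  cat(sprintf("  %d channels @ %g Hz, sequence %g s (+%g s fades), epoch -%g..+%g s\n",
              length(x$channel_labels), x$sampling_rate, x$full_duration,
              x$fade_duration, x$epoch_pre, x$epoch_post))
  cat(sprintf("  noise: 1/f^%g, RMS %g uV; alpha %g uV @ %g Hz; seed %d\n",
              x$noise_1f_exponent, x$noise_scale, x$alpha_amp, x$alpha_freq,
              x$seed))
  invisible(x)
}
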