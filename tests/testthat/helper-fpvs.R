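# Shared fixtures and independent oracle implementations.

# desk-scale simulation: 64 Hz sampling keeps the canonical 40-s sequences
# (and hence the 0.0255 Hz bin width) cheap; 16-channel montage subset
desk_channels <- c("Fp1", "Fp2", "Fz", "Cz", "Pz", "POz",
                   "P7", "P9", "PO7", "O1", "Oz", "Iz", "O2",
                   "PO8", "P10", "P8")

desk_sim <- function(...) {
  args <- list(...)
  defaults <- list(sampling_rate = 64, full_duration = 40,
                   channel_labels = desk_channels, seed = 7L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# brute-force noise-window statistics: explicit loops, written directly
# from the verbal rule, independent of the package implementation
bf_window <- function(a, bin, side = 12, adj = 1, extreme = 2) {
  idx <- integer(0)
  for (k in (bin - side):(bin + side)) {
    if (k == bin) next
    if (abs(k - bin) <= adj) next
    idx <- c(idx, k)
  }
  vals <- a[idx]
  if (extreme > 0) {
    drop_hi <- idx[which.max(vals)]
    idx2 <- setdiff(idx, drop_hi)
    drop_lo <- idx2[which.min(a[idx2])]
    idx <- setdiff(idx2, drop_lo)
  }
  idx
}

bf_stats <- function(a, bin) {
  idx <- bf_window(a, bin)
  v <- a[idx]
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))          # population SD
  list(snr = a[bin] / m, bc = a[bin] - m, z = (a[bin] - m) / s)
}

# direct projection of a series onto sin/cos at frequency f: amplitude of
# the matching sinusoid (valid for integer numbers of cycles)
projection_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  cs <- 2 * mean(x * cos(2 * pi * f * t))
  sn <- 2 * mean(x * sin(2 * pi * f * t))
  sqrt(cs^2 + sn^2)
}

# hand-worked split-plot sums of squares for a 2 (group) x 2 (A) x 2 (B)
# design, computed from marginal means only (no model fitting)
splitplot_ss_2x2x2 <- function(d) {
  # d: data.frame with subject, group, A, B, y; balanced complete
  M <- mean(d$y)
  n <- length(unique(d$subject[d$group == unique(d$group)[1]]))
  S <- length(unique(d$subject))
  mg <- tapply(d$y, d$group, mean)
  ma <- tapply(d$y, d$A, mean)
  mb <- tapply(d$y, d$B, mean)
  mga <- tapply(d$y, list(d$group, d$A), mean)
  mgb <- tapply(d$y, list(d$group, d$B), mean)
  mab <- tapply(d$y, list(d$A, d$B), mean)
  mgab <- tapply(d$y, list(d$group, d$A, d$B), mean)
  ms <- tapply(d$y, d$subject, mean)
  msa <- tapply(d$y, list(d$subject, d$A), mean)
  msb <- tapply(d$y, list(d$subject, d$B), mean)
  g_of_s <- tapply(as.character(d$group), d$subject, function(x) x[1])

  SS_G <- 4 * n * sum((mg - M)^2)
  SS_S <- 4 * sum((ms - mg[g_of_s])^2)
  SS_A <- 2 * S * sum((ma - M)^2)
  SS_GA <- 2 * n * sum((mga - outer(mg - M, ma, `+`))^2)
  SS_B <- 2 * S * sum((mb - M)^2)
  SS_GB <- 2 * n * sum((mgb - outer(mg - M, mb, `+`))^2)
  SS_AB <- S * sum((mab - outer(ma - M, mb, `+`))^2)
  SS_GAB <- 0
  for (g in names(mg)) for (a in colnames(mga)) for (b in colnames(mgb))
    SS_GAB <- SS_GAB + n * (mgab[g, a, b] - mga[g, a] - mgb[g, b] -
                              mab[a, b] + mg[g] + ma[a] + mb[b] - M)^2
  SS_AS <- 0
  for (s in rownames(msa)) for (a in colnames(msa))
    SS_AS <- SS_AS + 2 * (msa[s, a] - ms[s] - mga[g_of_s[s], a] +
                            mg[g_of_s[s]])^2
  SS_BS <- 0
  for (s in rownames(msb)) for (b in colnames(msb))
    SS_BS <- SS_BS + 2 * (msb[s, b] - ms[s] - mgb[g_of_s[s], b] +
                            mg[g_of_s[s]])^2
  SS_tot <- sum((d$y - M)^2)
  SS_ABS <- SS_tot - (SS_G + SS_S + SS_A + SS_GA + SS_B + SS_GB +
                        SS_AB + SS_GAB + SS_AS + SS_BS)
  df_s <- S - 2
  list(
    F_G = unname((SS_G / 1) / (SS_S / df_s)),
    F_A = unname((SS_A / 1) / (SS_AS / df_s)),
    F_GA = unname((SS_GA / 1) / (SS_AS / df_s)),
    F_B = unname((SS_B / 1) / (SS_BS / df_s)),
    F_GB = unname((SS_GB / 1) / (SS_BS / df_s)),
    F_AB = unname((SS_AB / 1) / (SS_ABS / df_s)),
    F_GAB = unname((SS_GAB / 1) / (SS_ABS / df_s)),
    SS = c(G = SS_G, S = SS_S, A = SS_A, GA = SS_GA, B = SS_B, GB = SS_GB,
           AB = SS_AB, GAB = SS_GAB, AS = SS_AS, BS = SS_BS, ABS = SS_ABS,
           total = SS_tot))
}

# build an fpvs_spectrum directly from an amplitude vector (bin width in Hz)
make_spectrum <- function(amps, bin_width, channel_labels = "ch1") {
  if (is.vector(amps)) amps <- matrix(amps, nrow = 1)
  structure(list(amplitudes = amps,
                 frequencies = (seq_len(ncol(amps)) - 1) * bin_width,
                 bin_width = bin_width,
                 sampling_rate = 2 * bin_width * ncol(amps),
                 channel_labels = channel_labels,
                 meta = list()),
            class = "fpvs_spectrum")
}
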