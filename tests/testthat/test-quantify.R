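# grand-average spectrum with unit peaks at given frequencies over a
# gently random noise floor (z at the peaks is far above any threshold)
peaked_spectrum <- function(peak_freqs, bin_width = 256 / 10035,
                            n_bins = 1000, floor_level = 0.1, seed = 1) {
  set.seed(seed)
  a <- runif(n_bins, 0.9, 1.1) * floor_level
  sp <- make_spectrum(a, bin_width)
  for (f in peak_freqs)
    a[as.integer(freq_to_bin(sp, f))] <- 1
  make_spectrum(a, bin_width)
}

test_that("harmonic selection reproduces the canonical 12- and 6-harmonic plans", {
  # significant through 16.8 Hz: harmonics 1..14 minus the base bins 6, 12
  sp1 <- peaked_spectrum(c(seq(1.2, 16.8, by = 1.2), 6, 12, 18))
  plan1 <- select_harmonics(sp1)
  expect_length(plan1$oddball_harmonics, 12)
  expect_equal(plan1$oddball_harmonics,
               1.2 * c(1:4, 6:9, 11:14), tolerance = 1e-9)
  expect_equal(plan1$base_harmonics, c(6, 12, 18))
  # significant through 8.4 Hz: harmonics 1..7 minus the base bin 6
  sp2 <- peaked_spectrum(c(seq(1.2, 8.4, by = 1.2), 6, 12, 18))
  plan2 <- select_harmonics(sp2)
  expect_length(plan2$oddball_harmonics, 6)
  expect_equal(plan2$oddball_harmonics, c(1.2, 2.4, 3.6, 4.8, 7.2, 8.4))
  # all selected z exceed the threshold and frequencies ascend
  expect_true(all(plan2$oddball_z > plan2$z_threshold))
  expect_true(all(diff(plan2$oddball_harmonics) > 0))
})

test_that("a non-significant base bin does not break the oddball walk", {
  # oddball peaks through 8.4 Hz but nothing at 6 Hz: the walk must skip 6
  sp <- peaked_spectrum(seq(1.2, 8.4, by = 1.2)[-5])   # 1.2..8.4 minus 6
  plan <- select_harmonics(sp)
  expect_equal(plan$oddball_harmonics, c(1.2, 2.4, 3.6, 4.8, 7.2, 8.4))
  expect_length(plan$base_harmonics, 0)
  # flat spectrum: empty plan with warning
  flat <- make_spectrum(runif(1000, 0.09, 0.11), 256 / 10035)
  expect_warning(p0 <- select_harmonics(flat), "not significant")
  expect_length(p0$oddball_harmonics, 0)
})

test_that("summed response recovers injected per-harmonic amplitudes", {
  # noiseless subject, flat topography, amplitudes 1, 0.5, 0.25 uV
  nch <- length(desk_channels)
  cfg <- desk_sim(n_per_group = 1, noise_scale = 0, alpha_amp = 0,
                  base_amp = 0, subject_sd = 0, n_harmonics = 3,
                  harmonic_decay = 0.5,
                  oddball_amp = list(TD = list(upright = 1, inverted = 1),
                                     ASD = list(upright = 1, inverted = 1)),
                  topographies = list(oddball = rep(1, nch)))
  ss <- simulate_subject(cfg, "TD", seed = 2)
  segs <- crop_to_cycles(segment_sequences(ss$recording, cfg$epoch_pre,
                                           cfg$epoch_post),
                         cfg$fade_duration, duration = 40)
  sp <- condition_spectra(segs)[["upright"]]
  plan <- structure(list(oddball_harmonics = c(1.2, 2.4, 3.6),
                         base_harmonics = numeric(0), z_threshold = 1.64),
                    class = "fpvs_harmonic_plan")
  expect_equal(summed_response(sp, plan, default_rois()$ROT), 1.75,
               tolerance = 1e-3)
  ha <- harmonic_amplitudes(sp, plan, default_rois()$LOT)
  expect_equal(unname(ha), c(1, 0.5, 0.25), tolerance = 1e-3)
  # linearity: doubling the recording doubles the summed response
  sp2 <- sp; sp2$amplitudes <- 2 * sp2$amplitudes
  expect_equal(summed_response(sp2, plan, default_rois()$ROT),
               2 * summed_response(sp, plan, default_rois()$ROT))
  # additivity over disjoint harmonic subsets
  p1 <- plan; p1$oddball_harmonics <- c(1.2)
  p2 <- plan; p2$oddball_harmonics <- c(2.4, 3.6)
  expect_equal(summed_response(sp, p1, default_rois()$ROT) +
                 summed_response(sp, p2, default_rois()$ROT),
               summed_response(sp, plan, default_rois()$ROT),
               tolerance = 1e-12)
  expect_error(summed_response(sp, plan, c("P8", "NOPE")), "missing")
})

test_that("individual significance detects strong signal and respects edges", {
  cfg <- desk_sim(n_per_group = 1, noise_scale = 1, alpha_amp = 0,
                  subject_sd = 0)
  ss <- simulate_subject(cfg, "TD", seed = 6)
  segs <- crop_to_cycles(segment_sequences(ss$recording, cfg$epoch_pre,
                                           cfg$epoch_post),
                         cfg$fade_duration)
  sp <- condition_spectra(segs)[["upright"]]
  plan <- structure(list(oddball_harmonics = c(1.2, 2.4, 3.6, 4.8, 7.2, 8.4),
                         base_harmonics = c(6), z_threshold = 1.64),
                    class = "fpvs_harmonic_plan")
  ind <- individual_significance(sp, plan, default_rois()$ROT)
  expect_true(ind$significant)
  expect_gt(ind$z, 2.33)
  # a window colliding with the spectrum edge errors
  plan_edge <- plan; plan_edge$oddball_harmonics <- c(0.025)
  expect_error(individual_significance(sp, plan_edge, default_rois()$ROT),
               "edge")
})

test_that("inversion effect is positive for control-like, ~zero for patient-like subjects", {
  cfg <- desk_sim(n_per_group = 1, noise_scale = 0, alpha_amp = 0,
                  subject_sd = 0)
  plan <- structure(list(oddball_harmonics = c(1.2, 2.4, 3.6, 4.8, 7.2, 8.4),
                         base_harmonics = c(6, 12, 18), z_threshold = 1.64),
                    class = "fpvs_harmonic_plan")
  subj <- function(g, id) {
    ss <- simulate_subject(cfg, g, seed = 8)
    segs <- crop_to_cycles(segment_sequences(ss$recording, cfg$epoch_pre,
                                             cfg$epoch_post),
                           cfg$fade_duration)
    list(subject = id, group = g, spectra = condition_spectra(segs))
  }
  tbl <- response_table(list(subj("TD", "TD_01"), subj("ASD", "ASD_01")),
                        plan)
  expect_gt(inversion_effect(tbl, "TD_01", "ROT"), 0.1)
  expect_equal(inversion_effect(tbl, "ASD_01", "ROT"), 0, tolerance = 1e-6)
  expect_error(inversion_effect(tbl, "TD_01", "MO"), "exactly one row")
  # equal conditions give exactly zero
  tbl2 <- tbl
  tbl2$summed_amplitude[tbl2$subject == "TD_01"] <- 1
  expect_equal(inversion_effect(tbl2, "TD_01", "ROT"), 0)
})

test_that("pipeline recovery: summed response tracks ground-truth amplitude", {
  cfg <- desk_sim(n_per_group = 8, seed = 99)
  pcfg <- pipeline_config(sim = cfg, low = NULL, resample = NULL)
  plan <- structure(list(oddball_harmonics = c(1.2, 2.4, 3.6, 4.8, 7.2, 8.4),
                         base_harmonics = c(6, 12, 18), z_threshold = 1.64),
                    class = "fpvs_harmonic_plan")
  subs <- list(); gt_total <- numeric(0)
  k <- 0
  for (i in 1:8) for (g in c("TD", "ASD")) {
    k <- k + 1
    s <- fpvs:::.subject_spectra(pcfg, g, seed = cfg$seed + 131L * k,
                                 subject_id = sprintf("%s_%02d", g, i))
    subs[[k]] <- s
    i_roi <- match(unlist(default_rois()[c("LOT", "ROT")]),
                   cfg$channel_labels)
    gt_total <- c(gt_total,
                  sum(colMeans(s$ground_truth$oddball$upright[i_roi, ])))
  }
  tbl <- response_table(subs, plan)
  est <- tapply(tbl$summed_amplitude[tbl$condition == "upright"],
                tbl$subject[tbl$condition == "upright"], mean)
  est <- est[sprintf("%s_%02d", rep(c("TD", "ASD"), 8),
                     rep(1:8, each = 2))]
  expect_gt(stats::cor(gt_total, est, method = "spearman"), 0.9)
})

test_that("summed response is monotone in the configured oddball amplitude", {
  plan <- structure(list(oddball_harmonics = c(1.2, 2.4, 3.6, 4.8, 7.2, 8.4),
                         base_harmonics = numeric(0), z_threshold = 1.64),
                    class = "fpvs_harmonic_plan")
  grid <- c(0.2, 0.5, 0.9, 1.5, 2.5)
  resp <- vapply(grid, function(a) {
    cfg <- desk_sim(n_per_group = 1, subject_sd = 0, seed = 10,
                    oddball_amp = list(TD = list(upright = a, inverted = a),
                                       ASD = list(upright = a, inverted = a)))
    ss <- simulate_subject(cfg, "TD", seed = 123)
    segs <- crop_to_cycles(segment_sequences(ss$recording, cfg$epoch_pre,
                                             cfg$epoch_post),
                           cfg$fade_duration)
    sp <- condition_spectra(segs)[["upright"]]
    summed_response(sp, plan, default_rois()$ROT)
  }, numeric(1))
  expect_true(all(diff(resp) > 0))
})
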