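toy_table_2x2x2 <- function(n = 4, seed = 14, shift = 0) {
  set.seed(seed)
  d <- expand.grid(subject = sprintf("S%02d", 1:(2 * n)),
                   condition = c("upright", "inverted"),
                   roi = c("LOT", "ROT"), stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("S", "", d$subject)) <= n, "TD", "ASD")
  d$summed_amplitude <- round(rnorm(nrow(d), 1, 0.4), 3)
  d$summed_amplitude[d$group == "TD" & d$condition == "upright"] <-
    d$summed_amplitude[d$group == "TD" & d$condition == "upright"] + shift
  d
}

test_that("split-plot F values match the hand-worked sums-of-squares oracle", {
  d <- toy_table_2x2x2(n = 3, seed = 2, shift = 0.5)
  an <- mixed_anova(d)
  o <- splitplot_ss_2x2x2(data.frame(subject = d$subject, group = d$group,
                                     A = d$condition, B = d$roi,
                                     y = d$summed_amplitude))
  eff <- an$effects
  getF <- function(e) eff$F[eff$effect == e]
  expect_equal(getF("group"), o$F_G, tolerance = 1e-9)
  expect_equal(getF("condition"), o$F_A, tolerance = 1e-9)
  expect_equal(getF("group:condition"), o$F_GA, tolerance = 1e-9)
  expect_equal(getF("roi"), o$F_B, tolerance = 1e-9)
  expect_equal(getF("group:roi"), o$F_GB, tolerance = 1e-9)
  expect_equal(getF("condition:roi"), o$F_AB, tolerance = 1e-9)
  expect_equal(getF("group:condition:roi"), o$F_GAB, tolerance = 1e-9)
  # partial eta^2 stays within [0, 1] and follows its definition
  expect_true(all(eff$partial_eta_sq >= 0 & eff$partial_eta_sq <= 1))
  expect_equal(eff$partial_eta_sq,
               eff$ss / (eff$ss + eff$ss_error), tolerance = 1e-12)
})

test_that("ANOVA decomposition conserves total variance", {
  d <- toy_table_2x2x2(n = 5, seed = 3, shift = 0.3)
  an <- mixed_anova(d)
  eff <- an$effects
  ss_err_unique <- unique(round(eff$ss_error, 12))
  total <- sum(eff$ss) + sum(ss_err_unique)
  expect_equal(total,
               sum((d$summed_amplitude - mean(d$summed_amplitude))^2),
               tolerance = 1e-9)
})

test_that("constant dependent variable yields F = 0, p = 1", {
  d <- toy_table_2x2x2(n = 3)
  d$summed_amplitude <- 2.5
  an <- mixed_anova(d)
  expect_true(all(an$effects$F == 0))
  expect_true(all(an$effects$p == 1))
})

test_that("incomplete designs and unbalanced groups are rejected", {
  d <- toy_table_2x2x2(n = 3)
  expect_error(mixed_anova(d[-1, ]), "complete|balanced")
  d2 <- toy_table_2x2x2(n = 3)
  d2$group[d2$subject == "S01"] <- "ASD"
  expect_error(mixed_anova(d2), "unbalanced")
})

test_that("Greenhouse-Geisser correction matches the mlm route and never helps", {
  set.seed(8)
  n <- 8
  d <- expand.grid(subject = sprintf("S%02d", 1:(2 * n)),
                   roi = c("MO", "LOT", "ROT"), stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("S", "", d$subject)) <= n, "TD", "ASD")
  # sphericity violation (one noisy level) plus a real ROI effect so the
  # F statistics sit in the region where the correction matters
  d$summed_amplitude <- rnorm(nrow(d), 1, 0.1) +
    ifelse(d$roi == "ROT", 0.4, 0)
  d$summed_amplitude[d$roi == "MO"] <-
    d$summed_amplitude[d$roi == "MO"] + rnorm(sum(d$roi == "MO"), 0, 1.2)
  an <- mixed_anova(d, within = "roi")
  eff <- an$effects
  roi_row <- eff[eff$effect == "roi", ]
  expect_false(is.na(roi_row$gg_epsilon))
  expect_true(roi_row$gg_epsilon > 0.5 && roi_row$gg_epsilon <= 1)
  expect_gt(roi_row$F, 1)
  expect_gte(roi_row$p_gg, roi_row$p)    # correction cannot help when F > 1
  expect_false(is.na(roi_row$mauchly_p))
  # independent route: anova.mlm with test = "Spherical"
  # (row 1 = within main effect via the intercept, row 2 = group:roi)
  Y <- an$cell_matrix
  mlm <- lm(Y ~ an$group_per_subject)
  idata <- data.frame(roi = factor(colnames(Y)))
  a2 <- anova(mlm, X = ~1, M = ~roi, idata = idata, test = "Spherical")
  expect_equal(roi_row$F, a2$F[1], tolerance = 1e-9)
  expect_equal(roi_row$p_gg, a2[["G-G Pr"]][1], tolerance = 1e-9)
  expect_equal(eff$p_gg[eff$effect == "group:roi"], a2[["G-G Pr"]][2],
               tolerance = 1e-9)
  # 2-level within factors carry no sphericity entries
  d2 <- toy_table_2x2x2(n = 4)
  an2 <- mixed_anova(d2)
  expect_true(all(is.na(an2$effects$gg_epsilon)))
})

test_that("Bonferroni post-hocs scale p-values and find the shifted cell", {
  d <- toy_table_2x2x2(n = 8, seed = 21, shift = 1.5)
  an <- mixed_anova(d)
  ph <- bonferroni_posthoc(an, "group:condition")
  expect_equal(nrow(ph), choose(4, 2))
  expect_equal(ph$p_bonferroni, pmin(1, ph$p_uncorrected * nrow(ph)),
               tolerance = 1e-12)
  # the TD upright cell drives the most extreme contrasts
  best <- ph$contrast[which.min(ph$p_bonferroni)]
  expect_match(best, "TD:upright")
  expect_error(bonferroni_posthoc(an, "nope"), "unknown effect")
  # identical groups (subject-for-subject the same values): corrected p = 1
  d0 <- toy_table_2x2x2(n = 6, seed = 4)
  vals <- rnorm(6)
  idx <- as.integer(sub("S", "", d0$subject))
  d0$summed_amplitude <- vals[(idx - 1) %% 6 + 1] +
    0.1 * as.integer(factor(d0$condition))
  an0 <- suppressWarnings(mixed_anova(d0))
  ph0 <- suppressWarnings(bonferroni_posthoc(an0, "group"))
  expect_true(all(ph0$p_bonferroni > 0.999))
})

test_that("electrode-wise ANOVA masks only truly affected electrodes", {
  set.seed(31)
  labels <- biosemi64_montage()$label
  n <- 12
  affected <- c("P7", "P9", "PO7", "P8", "P10", "PO8")
  amps <- matrix(rnorm(2 * n * 64, 1, 0.3), 2 * n, 64,
                 dimnames = list(NULL, labels))
  grp <- rep(c("TD", "ASD"), each = n)
  amps[grp == "TD", affected] <- amps[grp == "TD", affected] + 1.5
  res <- electrodewise_anova(amps, grp, expected_channels = 64)
  expect_equal(res$threshold, 0.05 / 64)
  expect_equal(round(res$threshold, 5), 0.00078)
  hits <- res$per_electrode$electrode[res$per_electrode$significant]
  expect_true(all(hits %in% affected))
  expect_gte(length(hits), 4)
  expect_error(electrodewise_anova(amps[, 1:10], grp,
                                   expected_channels = 64), "expected 64")
  # null data: mask is (almost always) empty
  amps0 <- matrix(rnorm(2 * n * 64), 2 * n, 64,
                  dimnames = list(NULL, labels))
  res0 <- electrodewise_anova(amps0, grp)
  expect_lte(sum(res0$per_electrode$significant), 1)
})

test_that("severity correlation distinguishes pooled from within-group association", {
  mk_tbl <- function(dv, subjects, groups) {
    d <- expand.grid(subject = subjects, condition = "upright",
                     roi = c("LOT", "ROT"), stringsAsFactors = FALSE)
    d$group <- groups[match(d$subject, subjects)]
    d$summed_amplitude <- dv[match(d$subject, subjects)]
    d
  }
  subjects <- sprintf("S%02d", 1:20)
  groups <- rep(c("TD", "ASD"), each = 10)
  # dv equals the score exactly -> r = 1
  dv <- rnorm(20)
  sc <- stats::setNames(dv, subjects)
  res <- severity_correlation(mk_tbl(dv, subjects, groups), sc)
  expect_equal(res$pooled$r, 1, tolerance = 1e-12)
  # two clusters offset in both variables, no within-group association
  set.seed(12)
  off <- ifelse(groups == "ASD", 3, 0)
  dv2 <- off + rnorm(20, 0, 0.5)
  sc2 <- stats::setNames(off + rnorm(20, 0, 0.5), subjects)
  res2 <- severity_correlation(mk_tbl(dv2, subjects, groups), sc2)
  expect_gt(abs(res2$pooled$r), 0.6)
  expect_true(all(abs(res2$by_group$r) < abs(res2$pooled$r)))
  # zero variance is reported as NA with a warning
  dv3 <- rep(1, 20)
  expect_warning(res3 <- severity_correlation(mk_tbl(dv3, subjects, groups), sc2))
  expect_true(is.na(res3$pooled$r))
  # independent dv and score: long-run mean r ~ 0
  set.seed(13)
  rs <- replicate(60, {
    severity_correlation(mk_tbl(rnorm(20), subjects, groups),
                         stats::setNames(rnorm(20), subjects))$pooled$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})
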