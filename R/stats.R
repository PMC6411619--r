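# Group-level inference on response tables: split-plot (mixed)
# repeated-measures ANOVA with sphericity handling, Bonferroni post-hocs,
# electrode-wise group contrasts, and severity-score correlation.
# The ANOVA is the classical univariate split-plot decomposition (fitted
# with aov() and Error() strata; the design is enforced balanced, where
# Type I/II/III sums of squares coincide). Sphericity is checked with
# Mauchly's test for within effects with more than 2 levels; when violated
# (p < .05) the Greenhouse-Geisser-corrected p-value is the headline one.

# orthonormal basis of the M-model space orthogonal to the X-model space,
# over the within-cell grid
.contrast_basis <- function(Mf, Xf, idata) {
  Mm <- stats::model.matrix(Mf, idata)
  Xm <- stats::model.matrix(Xf, idata)
  R <- qr.resid(qr(Xm), Mm)
  R <- R[, colSums(R^2) > 1e-10, drop = FALSE]
  q <- qr(R)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

# Greenhouse-Geisser epsilon for the contrasts T1 given the residual SSD
.gg_epsilon <- function(SSD, T1) {
  S <- t(T1) %*% SSD %*% T1
  d <- ncol(S)
  sum(diag(S))^2 / (d * sum(S * S))
}

#' Split-plot repeated-measures ANOVA
#'
#' Fits the classical mixed-design ANOVA with one between-subject factor
#' and one or two within-subject factors on a long-format response table.
#' The design must be complete and balanced. For within effects with more
#' than 2 levels, Mauchly's sphericity test and the Greenhouse-Geisser
#' correction are reported; the corrected p-value is flagged as the one to
#' read whenever Mauchly's p < .05. Shapiro-Wilk (normality of the
#' dependent variable) and Levene (homogeneity across groups) assumption
#' checks are attached.
#'
#' @param table Data frame (e.g. an `fpvs_response_table`).
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns.
#' @param between Name of the between-subject factor column (2 levels).
#' @param subject Name of the subject identifier column.
#' @return Object of class `fpvs_anova`: `effects` data.frame (F, dfs, p,
#'   partial eta squared, GG epsilon and corrected p where applicable,
#'   Mauchly W/p), `assumptions` (Shapiro-Wilk and Levene), and the cell
#'   data needed by [bonferroni_posthoc()].
#' @export
mixed_anova <- function(table, dv = "summed_amplitude",
                        within = c("condition", "roi"), between = "group",
                        subject = "subject") {
  d <- as.data.frame(table)
  for (v in c(within, between, subject)) d[[v]] <- factor(d[[v]])
  d$.y <- d[[dv]]

  # completeness / balance checks
  cell <- interaction(d[, within, drop = FALSE], drop = FALSE)
  tab <- table(d[[subject]], cell)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("design is not complete/balanced; offending subject x cell: ",
         paste(rownames(tab)[bad[, 1]], colnames(tab)[bad[, 2]],
               sep = "/", collapse = ", "))
  }
  gsize <- table(unique(d[, c(subject, between)])[[between]])
  if (length(unique(gsize)) != 1)
    stop("groups are unbalanced (", paste(gsize, collapse = " vs "), ")")

  wterm <- paste(within, collapse = "*")
  form <- stats::as.formula(paste(
    ".y ~", between, "*", wterm,
    "+ Error(", subject, "/(", wterm, "))"))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)

  effects <- list()
  for (stratum in names(sm)) {
    st <- sm[[stratum]][[1]]
    rn <- trimws(rownames(st))
    res <- rn == "Residuals"
    ss_err <- st[res, "Sum Sq"]; df_err <- st[res, "Df"]
    for (i in which(!res)) {
      ss <- st[i, "Sum Sq"]; dfn <- st[i, "Df"]
      if (ss_err <= 1e-12 * max(ss, 1) && ss <= 1e-12) {
        Fv <- 0; p <- 1
      } else {
        Fv <- (ss / dfn) / (ss_err / df_err)
        p <- stats::pf(Fv, dfn, df_err, lower.tail = FALSE)
      }
      effects[[length(effects) + 1L]] <- data.frame(
        effect = rn[i], df_num = dfn, df_den = df_err,
        ss = ss, ss_error = ss_err, F = Fv, p = p,
        partial_eta_sq = if (ss + ss_err > 0) ss / (ss + ss_err) else 0,
        gg_epsilon = NA_real_, p_gg = NA_real_,
        mauchly_W = NA_real_, mauchly_p = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  eff <- do.call(rbind, effects)

  # sphericity: wide subject x cell matrix, mlm on the between factor
  idata <- unique(d[, within, drop = FALSE])
  idata <- idata[do.call(order, idata), , drop = FALSE]
  rownames(idata) <- NULL
  subj_levels <- levels(d[[subject]])
  cells <- apply(idata, 1, paste, collapse = ".")
  Y <- matrix(NA_real_, length(subj_levels), nrow(idata),
              dimnames = list(subj_levels, cells))
  key <- apply(d[, within, drop = FALSE], 1, paste, collapse = ".")
  Y[cbind(match(d[[subject]], subj_levels), match(key, cells))] <- d$.y
  grp <- d[[between]][match(subj_levels, d[[subject]])]
  mlm <- stats::lm(Y ~ grp)
  ssd <- stats::SSD(mlm)

  within_terms <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, paste, collapse = ":", simplify = FALSE)))
  for (wt in within_terms) {
    parts <- strsplit(wt, ":")[[1]]
    dfw <- prod(vapply(parts, function(p) nlevels(d[[p]]) - 1L, integer(1)))
    if (dfw < 2) next  # 2-level effects: sphericity holds trivially
    Mf <- stats::as.formula(paste("~", paste(parts, collapse = "*")))
    Xf <- if (length(parts) == 1) ~1 else
      stats::as.formula(paste("~", paste(parts, collapse = "+")))
    T1 <- .contrast_basis(Mf, Xf, idata)
    eps <- .gg_epsilon(ssd$SSD, T1)
    mt <- tryCatch(stats::mauchly.test(mlm, M = Mf, X = Xf, idata = idata),
                   error = function(e) NULL)
    # the within effect itself and its interaction with the between factor
    rows <- which(eff$effect == wt | eff$effect == paste(between, wt, sep = ":"))
    for (r in rows) {
      eff$gg_epsilon[r] <- eps
      eff$p_gg[r] <- stats::pf(eff$F[r], eff$df_num[r] * eps,
                               eff$df_den[r] * eps, lower.tail = FALSE)
      if (!is.null(mt)) {
        eff$mauchly_W[r] <- unname(mt$statistic)
        eff$mauchly_p[r] <- mt$p.value
      }
    }
  }

  subj_means <- rowMeans(Y)
  assumptions <- list(
    shapiro = tryCatch(stats::shapiro.test(d$.y), error = function(e) NULL),
    levene = tryCatch(car::leveneTest(subj_means ~ grp),
                      error = function(e) NULL))

  structure(list(effects = eff, assumptions = assumptions,
                 data = d, dv = dv, within = within, between = between,
                 subject = subject, cell_matrix = Y, group_per_subject = grp),
            class = "fpvs_anova")
}

#' @export
print.fpvs_anova <- function(x, ...) {
  cat("Split-plot repeated-measures ANOVA (dv:", x$dv, ")\n")
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    line <- sprintf("  %-28s F(%g, %g) = %.3f, p = %.4g, pes = %.3f",
                    e$effect[i], e$df_num[i], e$df_den[i], e$F[i], e$p[i],
                    e$partial_eta_sq[i])
    if (!is.na(e$gg_epsilon[i]))
      line <- paste0(line, sprintf("  [GG eps = %.3f, p_GG = %.4g, Mauchly p = %.3g]",
                                   e$gg_epsilon[i], e$p_gg[i], e$mauchly_p[i]))
    cat(line, "\n")
  }
  if (!is.null(x$assumptions$shapiro))
    cat(sprintf("  Shapiro-Wilk p = %.3g", x$assumptions$shapiro$p.value))
  if (!is.null(x$assumptions$levene))
    cat(sprintf("; Levene p = %.3g", x$assumptions$levene[["Pr(>F)"]][1]))
  cat("\n")
  invisible(x)
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' Pairwise t-contrasts between the cells of an effect. Per-subject cell
#' means are first averaged over every within factor not in the effect.
#' Comparisons between cells of different groups use two-sample t-tests
#' (pooled variance); comparisons within a group (or for purely
#' within-subject effects) use paired t-tests. p-values are multiplied by
#' the number of comparisons and capped at 1.
#'
#' @param anova An `fpvs_anova` object.
#' @param effect Effect name as it appears in `anova$effects$effect`
#'   (e.g. `"group:condition"`).
#' @return Data frame with one row per contrast: `contrast`, `mean_diff`,
#'   `t`, `df`, `p_uncorrected`, `p_bonferroni`.
#' @export
bonferroni_posthoc <- function(anova, effect) {
  stopifnot(inherits(anova, "fpvs_anova"))
  if (!effect %in% anova$effects$effect)
    stop("unknown effect: ", effect, " (available: ",
         paste(anova$effects$effect, collapse = ", "), ")")
  if (anova$effects$p[anova$effects$effect == effect] >= 0.05)
    warning("effect '", effect, "' is not significant; post-hocs are exploratory")
  d <- anova$data
  parts <- strsplit(effect, ":")[[1]]
  has_group <- anova$between %in% parts
  wparts <- setdiff(parts, anova$between)

  # per-subject means within each cell of the effect
  cellf <- if (length(wparts))
    interaction(d[, wparts, drop = FALSE], drop = TRUE, sep = ":")
  else factor(rep("all", nrow(d)))
  agg <- stats::aggregate(d$.y,
                          by = list(subject = d[[anova$subject]],
                                    group = d[[anova$between]],
                                    cell = cellf),
                          FUN = mean)
  if (has_group) agg$cell_full <- paste(agg$group, agg$cell, sep = ":")
  else agg$cell_full <- as.character(agg$cell)
  if (!length(wparts)) agg$cell_full <- as.character(agg$group)
  cells <- unique(agg$cell_full)
  cmb <- utils::combn(cells, 2, simplify = FALSE)
  rows <- lapply(cmb, function(pr) {
    a <- agg[agg$cell_full == pr[1], ]
    b <- agg[agg$cell_full == pr[2], ]
    paired <- setequal(a$subject, b$subject)
    tt <- if (paired) {
      b <- b[match(a$subject, b$subject), ]
      stats::t.test(a$x, b$x, paired = TRUE)
    } else {
      stats::t.test(a$x, b$x, var.equal = TRUE)
    }
    data.frame(contrast = paste(pr[1], "-", pr[2]),
               mean_diff = mean(a$x) - mean(b$x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_uncorrected = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_uncorrected * nrow(out))
  out
}

#' Electrode-wise group ANOVA with Bonferroni mask
#'
#' Group x Electrode split-plot ANOVA on per-electrode amplitudes,
#' followed by per-electrode two-sample t-contrasts between groups with a
#' Bonferroni-corrected significance mask at `alpha / n_electrodes`.
#'
#' @param amplitudes Subjects x electrodes numeric matrix (column names =
#'   electrode labels).
#' @param group Factor of group labels, one per subject.
#' @param alpha Family-wise alpha.
#' @param expected_channels If given, the number of electrodes is checked
#'   against it (e.g. 64 for the full montage).
#' @return List with `anova` (`fpvs_anova`), `per_electrode` data.frame
#'   (t, p, significant), and `threshold` (= alpha / n_electrodes).
#' @export
electrodewise_anova <- function(amplitudes, group, alpha = 0.05,
                                expected_channels = NULL) {
  ne <- ncol(amplitudes)
  if (!is.null(expected_channels) && ne != expected_channels)
    stop(sprintf("expected %d electrodes, got %d", expected_channels, ne))
  labels <- colnames(amplitudes)
  if (is.null(labels)) labels <- paste0("E", seq_len(ne))
  ns <- nrow(amplitudes)
  long <- data.frame(
    subject = rep(sprintf("S%03d", seq_len(ns)), ne),
    group = rep(as.character(group), ne),
    electrode = rep(labels, each = ns),
    amplitude = as.vector(amplitudes), stringsAsFactors = FALSE)
  an <- mixed_anova(long, dv = "amplitude", within = "electrode",
                    between = "group", subject = "subject")
  thr <- alpha / ne
  g <- factor(group); gl <- levels(g)
  per <- do.call(rbind, lapply(seq_len(ne), function(j) {
    tt <- stats::t.test(amplitudes[g == gl[1], j],
                        amplitudes[g == gl[2], j], var.equal = TRUE)
    data.frame(electrode = labels[j], t = unname(tt$statistic),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  per$significant <- per$p < thr
  list(anova = an, per_electrode = per, threshold = thr)
}

#' Correlation between response amplitude and a severity score
#'
#' Pearson correlation between a per-subject dependent variable (by
#' default the upright summed amplitude averaged over LOT and ROT) and a
#' severity score, pooled across groups and within each group.
#'
#' @param table An `fpvs_response_table`.
#' @param scores Named numeric vector of severity scores (names = subject
#'   identifiers).
#' @param rois ROI names averaged into the dependent variable.
#' @param condition Condition used for the dependent variable.
#' @return List with `pooled` (r, p, n) and `by_group` (data.frame of r, p,
#'   n per group). Zero variance in either variable yields `NA` with a
#'   warning.
#' @export
severity_correlation <- function(table, scores,
                                 rois = c("LOT", "ROT"),
                                 condition = "upright") {
  d <- table[table$roi %in% rois & table$condition == condition, ]
  agg <- stats::aggregate(summed_amplitude ~ subject + group, data = d,
                          FUN = mean)
  agg$score <- scores[agg$subject]
  if (anyNA(agg$score)) stop("missing severity score for: ",
                             paste(agg$subject[is.na(agg$score)], collapse = ", "))
  corr <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance; correlation undefined")
      return(list(r = NA_real_, p = NA_real_, n = length(x)))
    }
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  }
  pooled <- corr(agg$summed_amplitude, agg$score)
  by_group <- do.call(rbind, lapply(split(agg, agg$group), function(s) {
    cc <- corr(s$summed_amplitude, s$score)
    data.frame(group = s$group[1], r = cc$r, p = cc$p, n = cc$n,
               stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  list(pooled = pooled, by_group = by_group)
}
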