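# Diagnostic classification from oddball harmonic amplitudes. Feature
# vectors are the per-harmonic baseline-corrected amplitudes of the first
# five oddball harmonics (1.2, 2.4, 3.6, 4.8, 7.2 Hz; the 6 Hz bin belongs
# to the base response) for the left and right occipito-temporal ROIs
# (10 columns; optionally 12 with 8.4 Hz). Three linear models are
# supported: LDA (pooled covariance), L2-penalized logistic regression
# (C = 1), and a linear-kernel SVM (C = 1). Features are
# standardized inside each training fold only, so no information from the
# held-out subject leaks into the fit. Significance comes from a label
# permutation test with the add-one estimator.

#' Build the classification feature matrix
#'
#' @param harmonics Per-harmonic amplitude table as returned by
#'   [harmonic_table()] (columns subject, group, condition, roi, freq,
#'   amplitude).
#' @param condition Condition the features are taken from.
#' @param rois ROIs contributing columns (ROI-major column order).
#' @param freqs Harmonic frequencies used per ROI. The default is the
#'   first five oddball harmonics; set `include_8_4 = TRUE` to append
#'   8.4 Hz.
#' @param include_8_4 Append the 8.4 Hz harmonic (12 columns total).
#' @return Object of class `fpvs_features`: numeric matrix (subjects x
#'   features, ordered ROI-major then frequency-ascending) with attributes
#'   `labels` (group factor) and `subjects`.
#' @export
build_features <- function(harmonics, condition = "upright",
                           rois = c("LOT", "ROT"),
                           freqs = c(1.2, 2.4, 3.6, 4.8, 7.2),
                           include_8_4 = FALSE) {
  if (include_8_4) freqs <- c(freqs, 8.4)
  h <- harmonics[harmonics$condition == condition & harmonics$roi %in% rois, ]
  subjects <- unique(h$subject)
  cols <- expand.grid(freq = freqs, roi = rois,
                      stringsAsFactors = FALSE)[, c("roi", "freq")]
  X <- matrix(NA_real_, length(subjects), nrow(cols),
              dimnames = list(subjects,
                              paste0(cols$roi, "_", cols$freq, "Hz")))
  for (i in seq_len(nrow(cols))) {
    sel <- h[h$roi == cols$roi[i] & abs(h$freq - cols$freq[i]) < 1e-9, ]
    X[sel$subject, i] <- sel$amplitude
  }
  if (anyNA(X)) {
    bad <- rownames(X)[apply(X, 1, anyNA)]
    stop("missing per-harmonic amplitudes for subject(s): ",
         paste(bad, collapse = ", "))
  }
  labels <- factor(h$group[match(subjects, h$subject)])
  structure(X, labels = labels, subjects = subjects, class = "fpvs_features")
}

# fold-internal standardization
.standardize <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

# LDA with shrinkage fallback for singular pooled covariance
.fit_predict_lda <- function(xtr, ytr, xte) {
  fit <- tryCatch(suppressWarnings(MASS::lda(xtr, grouping = ytr)),
                  error = function(e) NULL)
  if (!is.null(fit)) return(stats::predict(fit, xte)$class)
  # shrinkage fallback: blend the pooled covariance towards its diagonal
  message("singular pooled covariance; using shrinkage LDA fallback")
  lv <- levels(ytr); p <- ncol(xtr)
  mus <- t(vapply(lv, function(g) colMeans(xtr[ytr == g, , drop = FALSE]),
                  numeric(p)))
  ctr <- xtr - mus[as.integer(ytr), , drop = FALSE]
  S <- crossprod(ctr) / (nrow(xtr) - length(lv))
  lam <- 0.1
  S <- (1 - lam) * S + lam * diag(diag(S) + 1e-8, p)
  Si <- solve(S)
  disc <- vapply(seq_along(lv), function(k) {
    w <- Si %*% mus[k, ]
    as.numeric(xte %*% w - 0.5 * sum(mus[k, ] * w) +
                 log(mean(ytr == lv[k])))
  }, numeric(nrow(xte)))
  disc <- matrix(disc, nrow(xte))
  # exact argmax per row (max.col's tie tolerance is relative and can
  # swallow real differences when a constant feature inflates all scores)
  factor(lv[apply(disc, 1, which.max)], levels = lv)
}

.fit_predict <- function(model, xtr, ytr, xte) {
  switch(model,
    lda = .fit_predict_lda(xtr, ytr, xte),
    lr = {
      # L2-penalized logistic regression with C = 1 in the
      # sum-loss + ||w||^2/2 convention, i.e. lambda = 1 / (n * C) in
      # glmnet's mean-loss parametrization; intercept unpenalized.
      # glmnet needs >= 2 observations per class; tiny folds fall back
      # to the unpenalized GLM.
      pr <- if (min(table(ytr)) >= 2) {
        fit <- suppressWarnings(
          glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                         lambda = 1 / nrow(xtr), standardize = FALSE))
        stats::predict(fit, xte, type = "response")[, 1]
      } else {
        df <- data.frame(y = ytr, xtr)
        fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                           family = stats::binomial()))
        suppressWarnings(stats::predict(fit, newdata = data.frame(xte),
                                        type = "response"))
      }
      factor(levels(ytr)[1 + (pr > 0.5)], levels = levels(ytr))
    },
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = 1, scale = FALSE)
      stats::predict(fit, xte)
    },
    stop("unknown model: ", model))
}

#' Leave-one-out cross-validated classification
#'
#' For each subject the model is fitted on the remaining n - 1 subjects
#' (with fold-internal feature standardization) and the held-out subject
#' is predicted. Recall is the correctly identified fraction of the
#' patient-like class; accuracy the overall correct fraction.
#'
#' @param features An `fpvs_features` matrix (or plain matrix).
#' @param model `"lda"`, `"lr"` or `"svm"`.
#' @param labels Group factor (taken from the feature attributes if
#'   absent).
#' @param positive Label of the patient-like class whose recall is
#'   reported (default: the second factor level).
#' @return Object of class `fpvs_classifier_report`: `model`,
#'   `predictions` (per-fold data.frame), `recall`, `accuracy`,
#'   `positive`.
#' @export
loo_cv <- function(features, model = c("lda", "lr", "svm"), labels = NULL,
                   positive = NULL) {
  model <- match.arg(model)
  if (is.null(labels)) labels <- attr(features, "labels")
  labels <- factor(labels)
  X <- unclass(features); attributes(X)[c("labels", "subjects")] <- NULL
  n <- nrow(X)
  if (min(table(labels)) < 2) stop("need at least 2 subjects per class")
  if (is.null(positive)) positive <- levels(labels)[2]
  pred <- factor(rep(NA, n), levels = levels(labels))
  for (i in seq_len(n)) {
    sx <- .standardize(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    pred[i] <- .fit_predict(model, sx$train, labels[-i], sx$test)
  }
  acc <- mean(pred == labels)
  rec <- mean(pred[labels == positive] == positive)
  structure(list(model = model,
                 predictions = data.frame(
                   subject = rownames(X) %||% seq_len(n),
                   truth = labels, predicted = pred,
                   stringsAsFactors = FALSE),
                 recall = rec, accuracy = acc, positive = positive),
            class = "fpvs_classifier_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation test of leave-one-out accuracy
#'
#' Group labels are shuffled `n_perm` times; the full leave-one-out
#' cross-validation is re-run per permutation and the permutation p-value
#' uses the add-one estimator
#' `(1 + #(perm accuracy >= observed)) / (n_perm + 1)`.
#'
#' @inheritParams loo_cv
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the label shuffles.
#' @return The observed `fpvs_classifier_report` with `perm_accuracies`,
#'   `perm_p` and `n_perm` fields filled in.
#' @export
permutation_test <- function(features, model = c("lda", "lr", "svm"),
                             n_perm = 10000, seed = 1L, labels = NULL,
                             positive = NULL) {
  model <- match.arg(model)
  if (is.null(labels)) labels <- attr(features, "labels")
  obs <- loo_cv(features, model, labels = labels, positive = positive)
  set.seed(as.integer(seed))
  perm_acc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    perm_acc[b] <- loo_cv(features, model, labels = perm)$accuracy
  }
  obs$perm_accuracies <- perm_acc
  obs$perm_p <- (1 + sum(perm_acc >= obs$accuracy)) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs
}

#' One-dimensional LDA projection
#'
#' Discriminant scores of every subject along the (single) LDA axis fitted
#' to the full data set, with the decision boundary, for violin-type
#' displays of group separability.
#'
#' @inheritParams loo_cv
#' @return List with `scores` (named numeric), `boundary` (scalar
#'   threshold on the scores), `labels`.
#' @export
lda_projection <- function(features, labels = NULL) {
  if (is.null(labels)) labels <- attr(features, "labels")
  labels <- factor(labels)
  X <- unclass(features); attributes(X)[c("labels", "subjects")] <- NULL
  sx <- .standardize(X, X)
  fit <- suppressWarnings(MASS::lda(sx$train, grouping = labels))
  sc <- as.numeric(stats::predict(fit, sx$train)$x[, 1])
  names(sc) <- rownames(X)
  m <- vapply(levels(labels), function(g) mean(sc[labels == g]), numeric(1))
  pri <- fit$prior
  boundary <- (m[1] + m[2]) / 2 + (log(pri[2]) - log(pri[1])) /
    (m[1] - m[2])
  list(scores = sc, boundary = unname(boundary), labels = labels)
}

#' @export
print.fpvs_classifier_report <- function(x, ...) {
  cat(sprintf("Leave-one-out %s classification: accuracy %.1f%%, recall(%s) %.1f%%\n",
              toupper(x$model), 100 * x$accuracy, x$positive, 100 * x$recall))
  if (!is.null(x$perm_p))
    cat(sprintf("  permutation test: p = %.4g (%d permutations)\n",
                x$perm_p, x$n_perm))
  invisible(x)
}
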