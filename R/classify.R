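#' Classifier evaluation specification
#'
#' Hyperparameter search space and cross-validation settings for the
#' logistic-regression group classifier: inverse-regularisation strength C
#' log-spaced over [0.01, 100], penalty in {l1, l2, none}, intercept on/off,
#' stratified inner cross-validation for hyperparameter selection, and
#' greedy forward selection up to `max_features` features.
#'
#' @param C_grid Inverse regularisation strengths (sklearn-style C; the
#'   penalised log-likelihood weight is 1/(n C)).
#' @param penalties Subset of `c("l2", "l1", "none")`; "none" is
#'   unregularised maximum likelihood.
#' @param fit_intercept Logical vector of intercept options.
#' @param inner_cv_folds Stratified folds for hyperparameter selection.
#' @param max_features Greedy selection budget.
#' @param seed Master seed; all per-fold randomness is derived from it.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(C_grid = 10^seq(-2, 2, length.out = 9),
                            penalties = c("l2", "l1", "none"),
                            fit_intercept = c(TRUE, FALSE),
                            inner_cv_folds = 3L,
                            max_features = 3L,
                            seed = 1L) {
  stopifnot(all(C_grid >= 0.01 - 1e-12), all(C_grid <= 100 + 1e-12),
            inner_cv_folds >= 2L, max_features >= 1L,
            all(penalties %in% c("l1", "l2", "none")))
  sp <- list(C_grid = as.numeric(C_grid), penalties = penalties,
             fit_intercept = as.logical(fit_intercept),
             inner_cv_folds = as.integer(inner_cv_folds),
             max_features = as.integer(max_features),
             seed = as.integer(seed))
  class(sp) <- "classifier_spec"
  sp
}

#' ROC curve and area under the curve
#'
#' ROC points by descending-score thresholds with tied scores grouped; AUC
#' by the trapezoid rule, which equals the pair-counting estimator
#' P(score+ > score-) + 0.5 P(tie).
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels; the positive class is the second factor
#'   level (or 1 / TRUE).
#' @return List with `roc` (data frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L) {
    stop("roc_auc: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tpr <- c(0, cumsum(p)[last] / P)
  fpr <- c(0, cumsum(!p)[last] / N)
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  list(roc = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

as_positive <- function(labels) {
  if (is.factor(labels)) {
    labels == levels(labels)[2]
  } else if (is.logical(labels)) {
    labels
  } else if (is.numeric(labels)) {
    labels == max(labels)
  } else {
    f <- factor(labels)
    f == levels(f)[2]
  }
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Closed-form standard error of a trapezoidal AUC given the class counts:
#' `SE^2 = (A(1-A) + (n_pos-1)(Q1 - A^2) + (n_neg-1)(Q2 - A^2)) /
#' (n_pos n_neg)` with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`, and a Wald
#' interval `A +/- z SE` clipped to [0, 1].
#'
#' @param auc AUC estimate in [0, 1].
#' @param n_pos,n_neg Class counts (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Object of class `auc_estimate`: `auc`, `se`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `level`.
#' @export
hanley_mcneil_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 1, n_neg >= 1,
            level > 0, level < 1)
  A <- auc
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  se2 <- (A * (1 - A) + (n_pos - 1) * (Q1 - A^2) +
            (n_neg - 1) * (Q2 - A^2)) / (n_pos * n_neg)
  se <- sqrt(max(0, se2))
  z <- qnorm(1 - (1 - level) / 2)
  res <- list(auc = A, se = se,
              ci_low = max(0, A - z * se),
              ci_high = min(1, A + z * se),
              n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              level = level)
  class(res) <- "auc_estimate"
  res
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%d%% CI %.3f-%.3f, Hanley-McNeil SE %.4f; n+=%d, n-=%d)\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high, x$se,
              x$n_pos, x$n_neg))
  invisible(x)
}

# canonical hyperparameter grid, in tie-break order
config_grid <- function(spec) {
  cfgs <- list()
  for (pen in spec$penalties) {
    for (ic in spec$fit_intercept) {
      if (pen == "none") {
        cfgs[[length(cfgs) + 1L]] <- list(penalty = "none", C = Inf,
                                          intercept = ic)
      } else {
        for (C in spec$C_grid) {
          cfgs[[length(cfgs) + 1L]] <- list(penalty = pen, C = C,
                                            intercept = ic)
        }
      }
    }
  }
  cfgs
}

# Newton/IRLS ridge-logistic solver: minimises
#   (1/n) sum nll(beta) + (lambda/2) ||beta_slopes||^2
# (the intercept is never penalised; lambda = 0 gives unregularised maximum
# likelihood, capped at `maxit` Newton steps like glm). Returns the
# coefficient vector c(intercept, slopes) -- intercept fixed at 0 when
# intercept = FALSE.
logistic_newton <- function(x, ypos, lambda, intercept, beta0 = NULL,
                            maxit = 30L, tol = 1e-9) {
  n <- nrow(x)
  X <- if (intercept) cbind(1, x) else x
  p <- ncol(X)
  pen <- rep(lambda, p)
  if (intercept) pen[1] <- 0
  y <- as.numeric(ypos)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, mu - y)) / n + pen * beta
    H <- crossprod(X * w, X) / n
    diag(H) <- diag(H) + pen + 1e-12
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  if (intercept) beta else c(0, beta)
}

newton_predict <- function(beta, newx) {
  stats::plogis(drop(beta[1] + newx %*% beta[-1]))
}

# fit logistic regression under one config on standardized x; returns a
# closure predicting P(positive) for new standardized rows
fit_logistic <- function(x, ypos, cfg) {
  n <- nrow(x)
  if (cfg$penalty == "l1") {
    lam <- 1 / (n * cfg$C)
    xx <- if (ncol(x) == 1L) cbind(x, pad_ = 0) else x
    fit <- glmnet::glmnet(xx, factor(ypos, levels = c(FALSE, TRUE)),
                          family = "binomial", alpha = 1,
                          lambda = lam, intercept = cfg$intercept,
                          standardize = FALSE, thresh = 1e-8)
    function(newx) {
      nx <- if (ncol(x) == 1L) cbind(newx, pad_ = 0) else newx
      as.numeric(stats::predict(fit, nx, type = "response", s = lam))
    }
  } else {
    lam <- if (cfg$penalty == "none") 0 else 1 / (n * cfg$C)
    beta <- logistic_newton(x, ypos, lam, cfg$intercept)
    function(newx) newton_predict(beta, newx)
  }
}

# fit one (penalty, intercept) family on standardized x for every C in the
# grid at once (glmnet computes the whole regularisation path in one call);
# returns a matrix of validation predictions, one column per C
fit_family_predict <- function(x, ypos, pen, ic, C_grid, newx) {
  n <- nrow(x)
  if (pen == "none") {
    beta <- logistic_newton(x, ypos, 0, ic)
    return(matrix(newton_predict(beta, newx), ncol = 1L))
  }
  lam <- 1 / (n * C_grid)
  if (pen == "l2") {
    # warm-started Newton down the ridge path
    out <- matrix(NA_real_, nrow = nrow(newx), ncol = length(C_grid))
    ord <- order(lam, decreasing = TRUE)
    beta <- NULL
    for (j in ord) {
      beta <- logistic_newton(x, ypos, lam[j], ic,
                              beta0 = if (ic || is.null(beta)) beta else
                                beta[-1])
      out[, j] <- newton_predict(beta, newx)
    }
    return(out)
  }
  ord <- order(lam, decreasing = TRUE)
  xx <- if (ncol(x) == 1L) cbind(x, pad_ = 0) else x
  nx <- if (ncol(x) == 1L) cbind(newx, pad_ = 0) else newx
  fit <- tryCatch(
    glmnet::glmnet(xx, factor(ypos, levels = c(FALSE, TRUE)),
                   family = "binomial", alpha = 1,
                   lambda = lam[ord], intercept = ic,
                   standardize = FALSE, thresh = 1e-8),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(matrix(NA_real_, nrow = nrow(newx), ncol = length(C_grid)))
  }
  p <- stats::predict(fit, nx, type = "response", s = lam[ord])
  p[, order(ord), drop = FALSE]  # back to C_grid order
}

standardizer <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  function(newx) sweep(sweep(newx, 2, mu), 2, sdv, "/")
}

stratified_folds <- function(ypos, k) {
  fold <- integer(length(ypos))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(ypos == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# select a config by pooled inner-CV AUC on (x, ypos); x already standardized
select_config <- function(x, ypos, spec) {
  cfgs <- config_grid(spec)
  if (length(cfgs) == 1L) return(cfgs[[1L]])
  k <- min(spec$inner_cv_folds, sum(ypos), sum(!ypos))
  if (k < 2L) return(cfgs[[1L]])
  # columns of the prediction matrix, grouped by (penalty, intercept) family
  # in the same canonical order as config_grid()
  col_of <- 0L
  fams <- list()
  for (pen in spec$penalties) {
    for (ic in spec$fit_intercept) {
      nc <- if (pen == "none") 1L else length(spec$C_grid)
      fams[[length(fams) + 1L]] <- list(pen = pen, ic = ic,
                                        cols = col_of + seq_len(nc))
      col_of <- col_of + nc
    }
  }
  fold <- stratified_folds(ypos, k)
  preds <- matrix(NA_real_, nrow = length(ypos), ncol = length(cfgs))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(ypos[tr])) < 2L) next
    std <- standardizer(x[tr, , drop = FALSE])
    xtr <- std(x[tr, , drop = FALSE])
    xva <- std(x[!tr, , drop = FALSE])
    for (fam in fams) {
      preds[!tr, fam$cols] <- fit_family_predict(xtr, ypos[tr], fam$pen,
                                                 fam$ic, spec$C_grid, xva)
    }
  }
  aucs <- vapply(seq_along(cfgs), function(ci) {
    ok <- !is.na(preds[, ci])
    if (!any(ok) || length(unique(ypos[ok])) < 2L) return(-Inf)
    roc_auc(preds[ok, ci], ypos[ok])$auc
  }, numeric(1))
  cfgs[[which.max(aucs)]]
}

#' Pooled leave-one-out cross-validated classifier scores
#'
#' For each sample in turn: hold it out; within the training fold only,
#' up-sample the minority class with replacement to parity (seeded per
#' fold); standardize features with training-fold statistics; select the
#' hyperparameters maximising pooled stratified inner-CV AUC over the spec's
#' grid; fit the regularised logistic regression on the selected feature
#' subset; and record the held-out sample's predicted probability of the
#' positive class. The result is fully deterministic given `spec$seed`.
#'
#' @param feature_matrix Numeric matrix or data frame (samples x features).
#' @param labels Binary labels (positive class = second factor level).
#' @param feature_subset Columns (names or indices) to use.
#' @param spec A [classifier_spec()].
#' @return Numeric vector of pooled held-out scores, one per sample.
#' @export
loocv_scores <- function(feature_matrix, labels,
                         feature_subset = colnames(feature_matrix),
                         spec = classifier_spec()) {
  x <- as.matrix(as.data.frame(feature_matrix)[, feature_subset, drop = FALSE])
  storage.mode(x) <- "double"
  ypos <- as_positive(labels)
  n <- nrow(x)
  if (n < 4L || sum(ypos) < 2L || sum(!ypos) < 2L) {
    stop("loocv_scores: need n >= 4 with >= 2 samples per class",
         call. = FALSE)
  }
  fold_seeds <- withr::with_seed(spec$seed,
                                 sample.int(.Machine$integer.max - 1L, n))
  scores <- numeric(n)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- ypos[-i]
    withr::with_seed(fold_seeds[i], {
      # up-sample minority class to parity inside the training fold
      n_pos <- sum(yt); n_neg <- sum(!yt)
      if (n_pos != n_neg) {
        minority <- which(yt == (n_pos < n_neg))
        extra <- minority[sample.int(length(minority),
                                     abs(n_pos - n_neg), replace = TRUE)]
        xt <- rbind(xt, xt[extra, , drop = FALSE])
        yt <- c(yt, yt[extra])
      }
      cfg <- select_config(xt, yt, spec)
      std <- standardizer(xt)
      model <- fit_logistic(std(xt), yt, cfg)
      scores[i] <- model(std(x[i, , drop = FALSE]))
    })
  }
  scores
}

#' Greedy forward feature selection by LOOCV AUC
#'
#' Step 1 picks the single feature with the highest pooled leave-one-out AUC;
#' each subsequent step adds the feature that maximises the pooled LOOCV AUC
#' of the enlarged subset, up to `spec$max_features`. Ties are broken by
#' canonical (column) order. Each step carries a Hanley-McNeil confidence
#' interval computed from the class counts.
#'
#' @param feature_matrix Numeric matrix or data frame (samples x features).
#' @param labels Binary labels.
#' @param spec A [classifier_spec()].
#' @param level Confidence level for the per-step intervals.
#' @return Object of class `selection_trace`: `steps` (data frame: step,
#'   feature, auc, ci_low, ci_high, se), `features` (selected, in order),
#'   `pooled_scores` (held-out scores of the final model), `n_pos`, `n_neg`.
#' @export
greedy_select <- function(feature_matrix, labels, spec = classifier_spec(),
                          level = 0.95) {
  X <- as.data.frame(feature_matrix)
  candidates <- colnames(X)
  if (!length(candidates)) stop("greedy_select: no candidate features",
                                call. = FALSE)
  ypos <- as_positive(labels)
  n_pos <- sum(ypos); n_neg <- sum(!ypos)
  selected <- character()
  steps <- list()
  final_scores <- NULL
  for (step in seq_len(min(spec$max_features, length(candidates)))) {
    remaining <- setdiff(candidates, selected)
    best <- NULL
    for (f in remaining) {  # canonical order => first max wins ties
      sc <- loocv_scores(X, labels, c(selected, f), spec)
      a <- roc_auc(sc, labels)$auc
      if (is.null(best) || a > best$auc + 1e-12) {
        best <- list(feature = f, auc = a, scores = sc)
      }
    }
    selected <- c(selected, best$feature)
    est <- hanley_mcneil_ci(best$auc, n_pos, n_neg, level)
    steps[[step]] <- data.frame(step = step, feature = best$feature,
                                auc = best$auc, se = est$se,
                                ci_low = est$ci_low, ci_high = est$ci_high,
                                stringsAsFactors = FALSE)
    final_scores <- best$scores
  }
  res <- list(steps = do.call(rbind, steps), features = selected,
              pooled_scores = final_scores,
              n_pos = n_pos, n_neg = n_neg, level = level)
  class(res) <- "selection_trace"
  res
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Greedy forward selection by pooled LOOCV AUC\n")
  for (i in seq_len(nrow(x$steps))) {
    s <- x$steps[i, ]
    cat(sprintf("  step %d: + %-28s AUC %.3f (%d%% CI %.3f-%.3f)\n",
                s$step, s$feature, s$auc, round(100 * x$level),
                s$ci_low, s$ci_high))
  }
  invisible(x)
}
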