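#' @importFrom stats lm anova median sd pf pt pnorm qnorm p.adjust wilcox.test
#'   complete.cases setNames coef
NULL

#' One-way ANCOVA for a single feature
#'
#' Least-squares comparison of group means on a feature after adjusting for
#' continuous covariates: `y ~ covariates + group`, with the group term
#' tested added last (type-II sums of squares; with a single categorical
#' predictor and no interactions this is order-invariant). The effect size
#' is classical eta-squared, `SS_group / SS_total`, with partial eta-squared
#' (`SS_group / (SS_group + SS_error)`) available via `eta`.
#' With no covariates this reduces exactly to a one-way ANOVA.
#'
#' Rows with any missing value are dropped listwise.
#'
#' @param y Numeric response (one feature).
#' @param group Group labels (factor or character); at least 2 groups with
#'   at least 2 non-missing observations each.
#' @param covariates Optional data frame / named list of numeric covariates.
#' @param eta `"classical"` (default) or `"partial"`.
#' @return List of class `ancova_result`: `F`, `df_effect`, `df_error`,
#'   `p`, `eta_squared`, `n_used`, plus the underlying sums of squares.
#' @examples
#' ancova_compare(c(1, 2, 3, 3, 4, 5), rep(c("A", "B"), each = 3))
#' @export
ancova_compare <- function(y, group, covariates = NULL,
                           eta = c("classical", "partial")) {
  eta <- match.arg(eta)
  y <- as.numeric(y)
  group <- factor(group)
  if (is.null(covariates) || length(covariates) == 0L) {
    covariates <- data.frame(row.names = seq_along(y))
    k <- 0L
  } else {
    covariates <- as.data.frame(covariates)
    k <- ncol(covariates)
  }
  ok <- !is.na(y) & !is.na(group)
  if (k > 0L) ok <- ok & complete.cases(covariates)
  y <- y[ok]
  group <- droplevels(group[ok])
  if (k > 0L) covariates <- covariates[ok, , drop = FALSE]
  n <- length(y)
  if (nlevels(group) < 2L) {
    stop("ancova_compare: need at least 2 groups with data", call. = FALSE)
  }
  if (any(table(group) < 2L)) {
    stop("ancova_compare: every group needs >= 2 non-missing observations",
         call. = FALSE)
  }
  # least squares on explicit model matrices (reduced: intercept +
  # covariates; full: + dummy-coded group)
  X0 <- cbind(`(Intercept)` = rep(1, n),
              if (k > 0L) as.matrix(covariates))
  G <- stats::model.matrix(~group)[, -1, drop = FALSE]
  X1 <- cbind(X0, G)
  ss_res0 <- sum(qr.resid(qr(X0), y)^2)
  ss_res1 <- sum(qr.resid(qr(X1), y)^2)
  ss_group <- ss_res0 - ss_res1
  ss_total <- sum((y - mean(y))^2)
  df_effect <- nlevels(group) - 1L
  df_error <- n - df_effect - k - 1L
  if (df_error < 1L) stop("ancova_compare: no error degrees of freedom",
                          call. = FALSE)
  if (ss_res1 <= .Machine$double.eps * max(1, ss_total)) {
    stop("ancova_compare: degenerate model (zero residual variance)",
         call. = FALSE)
  }
  Fstat <- (ss_group / df_effect) / (ss_res1 / df_error)
  res <- list(
    F = Fstat,
    df_effect = df_effect,
    df_error = df_error,
    p = pf(Fstat, df_effect, df_error, lower.tail = FALSE),
    eta_squared = if (eta == "classical") ss_group / ss_total else
      ss_group / (ss_group + ss_res1),
    eta_type = eta,
    n_used = n,
    ss_group = ss_group, ss_error = ss_res1, ss_total = ss_total)
  class(res) <- "ancova_result"
  res
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("One-way ANCOVA: F(%d, %d) = %.4g, p = %.3g, eta^2 (%s) = %.3g, n = %d\n",
              x$df_effect, x$df_error, x$F, x$p, x$eta_type, x$eta_squared,
              x$n_used))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; rejecting adjusted values at level alpha is
#' equivalent to the classical step-up rule.
#'
#' @param p Numeric vector of p-values in [0, 1] (NAs passed through).
#' @return Adjusted p-values, clipped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' ANCOVA battery over a feature table with FDR control
#'
#' Runs [ancova_compare()] for each feature column and adjusts the raw
#' p-values with Benjamini-Hochberg across the family of features actually
#' tested. Features whose test cannot be run (all missing, degenerate model,
#' a group below 2 observations) are reported as skipped with the reason and
#' excluded from the BH family.
#'
#' @param feature_table Data frame containing the feature columns.
#' @param group Group labels (vector, or name of a column of
#'   `feature_table`).
#' @param covariates Covariate data frame, or character vector of column
#'   names of `feature_table`.
#' @param features Character vector of feature columns to test; defaults to
#'   the intersection of [feature_names()] with the table's columns.
#' @param alpha Significance level recorded in the result (default 0.05).
#' @param eta Eta-squared convention, see [ancova_compare()].
#' @return Data frame of class `comparison_table`: feature, F, df_effect,
#'   df_error, p_raw, p_adjusted, eta_squared, n_used, skipped_reason.
#' @export
compare_all <- function(feature_table, group, covariates = NULL,
                        features = NULL, alpha = 0.05,
                        eta = c("classical", "partial")) {
  eta <- match.arg(eta)
  if (is.character(group) && length(group) == 1L) {
    group <- feature_table[[group]]
  }
  if (is.character(covariates)) {
    missing_cov <- setdiff(covariates, colnames(feature_table))
    if (length(missing_cov)) {
      stop("compare_all: covariate column(s) not found: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    covariates <- feature_table[, covariates, drop = FALSE]
  }
  if (is.null(features)) {
    features <- intersect(feature_names(), colnames(feature_table))
  }
  if (!length(features)) stop("compare_all: no feature columns", call. = FALSE)

  rows <- lapply(features, function(f) {
    res <- tryCatch(
      ancova_compare(feature_table[[f]], group, covariates, eta = eta),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(feature = f, F = NA_real_, df_effect = NA_integer_,
                 df_error = NA_integer_, p_raw = NA_real_,
                 p_adjusted = NA_real_, eta_squared = NA_real_,
                 n_used = NA_integer_, skipped_reason = res,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(feature = f, F = res$F, df_effect = res$df_effect,
                 df_error = res$df_error, p_raw = res$p,
                 p_adjusted = NA_real_, eta_squared = res$eta_squared,
                 n_used = res$n_used, skipped_reason = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  tested <- is.na(out$skipped_reason)
  out$p_adjusted[tested] <- bh_adjust(out$p_raw[tested])
  attr(out, "alpha") <- alpha
  class(out) <- c("comparison_table", class(out))
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat("Covariate-adjusted group comparisons (BH-adjusted across ",
      sum(is.na(x$skipped_reason)), " features)\n", sep = "")
  y <- as.data.frame(x)
  y <- y[order(y$p_adjusted), ]
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, 4)
  print(utils::head(y, 15), row.names = FALSE)
  if (nrow(y) > 15) cat("... (", nrow(y) - 15, " more rows)\n", sep = "")
  if (!is.null(alpha)) {
    cat(sum(x$p_adjusted <= alpha, na.rm = TRUE),
        " features significant at FDR ", alpha, "\n", sep = "")
  }
  invisible(x)
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' Two-sided Mann-Whitney U test: U counts, for sample `x`, pairs in which
#' the x value exceeds the y value (ties counted half, via midranks). The
#' p-value is exact (full-enumeration distribution) when the combined sample
#' size is at most 20 and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections. The effect size is the
#' rank-biserial correlation `r = 1 - 2U / (n1 n2)`.
#'
#' @param x,y Numeric samples (both non-empty).
#' @return List of class `rank_test`: `U`, `p_two_sided`, `r_rank_biserial`,
#'   `method` ("exact" or "normal_approx"), `n1`, `n2`.
#' @export
mannwhitney_rb <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("mannwhitney_rb: both samples must be non-empty",
                       call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2) <= 20L && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                     correct = !exact,
                                     alternative = "two.sided"))
  U <- unname(wt$statistic)
  res <- list(U = U,
              p_two_sided = min(1, wt$p.value),
              r_rank_biserial = 1 - 2 * U / (n1 * n2),
              method = if (exact) "exact" else "normal_approx",
              n1 = n1, n2 = n2)
  class(res) <- "rank_test"
  res
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1=%d, n2=%d), two-sided p = %.4g (%s), rank-biserial r = %.3f\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method, x$r_rank_biserial))
  invisible(x)
}

#' Two-sample proportion z-test
#'
#' Pooled two-sample z statistic
#' `Z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with a two-sided normal
#' p-value, where `p` is the pooled proportion.
#'
#' @param successes Length-2 integer vector of success counts.
#' @param totals Length-2 integer vector of trial counts.
#' @return List with `Z` and `p_two_sided`.
#' @export
proportions_ztest <- function(successes, totals) {
  stopifnot(length(successes) == 2L, length(totals) == 2L)
  if (any(totals <= 0) || any(successes < 0) || any(successes > totals)) {
    stop("proportions_ztest: need 0 <= successes <= totals, totals > 0",
         call. = FALSE)
  }
  p1 <- successes[1] / totals[1]
  p2 <- successes[2] / totals[2]
  pool <- sum(successes) / sum(totals)
  if (pool <= 0 || pool >= 1) {
    stop("proportions_ztest: degenerate pooled proportion (all successes or all failures)",
         call. = FALSE)
  }
  Z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / totals[1] + 1 / totals[2]))
  list(Z = Z, p_two_sided = 2 * pnorm(-abs(Z)))
}

#' Partial Spearman correlation with Student-t significance
#'
#' Rank-transforms `x`, `y` and the covariates (midranks), residualises the
#' ranked `x` and `y` on the ranked covariates plus an intercept by least
#' squares, and reports the Pearson correlation of the residuals. With no
#' covariates this is the plain Spearman correlation. Significance uses
#' `t = rho * sqrt((n - 2 - k) / (1 - rho^2))` with `n - 2 - k` degrees of
#' freedom (`k` = number of retained covariates; constant covariates are
#' dropped). Rows with any missing value are removed listwise.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric data frame / named list of covariates.
#' @param x_name,y_name Labels carried into the result.
#' @return List of class `partial_corr`: `rho`, `p`, `n`, `covariates`,
#'   `x_name`, `y_name`.
#' @export
spearman_partial <- function(x, y, covariates = NULL,
                             x_name = deparse(substitute(x)),
                             y_name = deparse(substitute(y))) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (is.null(covariates) || length(covariates) == 0L) {
    covariates <- data.frame(row.names = seq_along(x))
  } else {
    covariates <- as.data.frame(covariates)
  }
  ok <- !is.na(x) & !is.na(y)
  if (ncol(covariates)) ok <- ok & complete.cases(covariates)
  x <- x[ok]; y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  # drop constant covariates
  if (ncol(covariates)) {
    keep <- vapply(covariates, function(v) length(unique(v)) > 1L, logical(1))
    covariates <- covariates[, keep, drop = FALSE]
  }
  n <- length(x)
  k <- ncol(covariates)
  if (n <= k + 2L) stop("spearman_partial: need n > covariates + 2",
                        call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("spearman_partial: zero variance in x or y", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  if (k > 0L) {
    rz <- vapply(covariates, rank, numeric(n))
    X <- cbind(1, rz)
    qx <- qr(X)
    rx <- qr.resid(qx, rx)
    ry <- qr.resid(qx, ry)
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt(df / (1 - rho^2))
    2 * pt(-abs(tt), df)
  }
  res <- list(rho = rho, p = p, n = n,
              covariates = colnames(covariates),
              x_name = x_name, y_name = y_name)
  class(res) <- "partial_corr"
  res
}

#' @export
print.partial_corr <- function(x, ...) {
  ctrl <- if (length(x$covariates)) {
    paste(" controlling for", paste(x$covariates, collapse = ", "))
  } else ""
  cat(sprintf("Partial Spearman %s ~ %s%s: rho = %.3f, p = %.4g, n = %d\n",
              x$x_name, x$y_name, ctrl, x$rho, x$p, x$n))
  invisible(x)
}

#' Feature-by-clinical-score partial correlation matrix
#'
#' Applies [spearman_partial()] to every (feature, score) pair, controlling
#' for the given covariates (typically age).
#'
#' @param feature_table Data frame with feature and score columns.
#' @param features,scores Character vectors of column names.
#' @param covariates Character vector of covariate column names (default
#'   `"age_months"`).
#' @return Data frame: feature, score, rho, p, n.
#' @export
correlate_features <- function(feature_table, features, scores,
                               covariates = "age_months") {
  rows <- list()
  for (f in features) {
    for (s in scores) {
      res <- tryCatch(
        spearman_partial(feature_table[[f]], feature_table[[s]],
                         feature_table[, covariates, drop = FALSE],
                         x_name = f, y_name = s),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, score = s,
        rho = if (is.null(res)) NA_real_ else res$rho,
        p = if (is.null(res)) NA_real_ else res$p,
        n = if (is.null(res)) NA_integer_ else res$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
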