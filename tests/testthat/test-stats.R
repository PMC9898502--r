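test_that("covariate-free ANCOVA reproduces the hand sums-of-squares ANOVA", {
  # between SS = 6, within SS = 4 -> F(1,4) = 6, eta^2 = 0.6
  res <- ancova_compare(c(1, 2, 3, 3, 4, 5), rep(c("A", "B"), each = 3))
  expect_equal(res$F, 6)
  expect_identical(res$df_effect, 1L)
  expect_identical(res$df_error, 4L)
  expect_equal(res$eta_squared, 0.6)
  expect_equal(res$p, pf(6, 1, 4, lower.tail = FALSE))

  # random datasets: closed-form one-way ANOVA decomposition to 1e-10
  set.seed(201)
  for (rep in 1:25) {
    g <- factor(sample(letters[1:3], 30, replace = TRUE))
    while (any(table(g) < 2)) g <- factor(sample(letters[1:3], 30, TRUE))
    y <- rnorm(30, mean = as.integer(g))
    res <- ancova_compare(y, g)
    gm <- tapply(y, g, mean)
    ssb <- sum(table(g) * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    Fref <- (ssb / (nlevels(g) - 1)) / (ssw / (30 - nlevels(g)))
    expect_equal(res$F, Fref, tolerance = 1e-10)
    expect_equal(res$eta_squared, ssb / (ssb + ssw), tolerance = 1e-10)
  }
})

test_that("ANCOVA group F matches a brute-force normal-equations oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 40L
    g <- factor(sample(c("a", "b"), n, replace = TRUE))
    while (any(table(g) < 2)) g <- factor(sample(c("a", "b"), n, TRUE))
    z1 <- rnorm(n); z2 <- rnorm(n)
    y <- 0.6 * z1 - 0.2 * z2 + (g == "b") * 0.5 + rnorm(n)
    res <- ancova_compare(y, g, data.frame(z1 = z1, z2 = z2))

    # oracle: explicit normal equations for both nested models
    X0 <- cbind(1, z1, z2)
    X1 <- cbind(X0, as.numeric(g == "b"))
    rss <- function(X) {
      b <- solve(t(X) %*% X, t(X) %*% y)
      sum((y - X %*% b)^2)
    }
    ss_g <- rss(X0) - rss(X1)
    Fref <- ss_g / (rss(X1) / (n - 4))
    expect_equal(res$F, Fref, tolerance = 1e-8)
    expect_equal(res$eta_squared, ss_g / sum((y - mean(y))^2),
                 tolerance = 1e-8)
    expect_identical(res$df_error, n - 4L)
  }
})

test_that("ANCOVA rejects degenerate inputs", {
  expect_error(ancova_compare(rep(1, 10), rep(c("a", "b"), 5)),
               "degenerate")
  expect_error(ancova_compare(rnorm(10), rep("a", 10)), "2 groups")
  # listwise deletion drops incomplete rows
  y <- c(1, 2, 3, NA, 5, 6, 7, 8)
  g <- rep(c("a", "b"), 4)
  z <- c(NA, rnorm(7))
  res <- ancova_compare(y, g, data.frame(z = z))
  expect_identical(res$n_used, 6L)
})

test_that("BH adjustment equals the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # rejecting adjusted values at alpha equals the classical step-up rule,
  # and adjusted values are monotone in the sorted order
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^2
    q <- bh_adjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    for (alpha in c(0.05, 0.2)) {
      m <- length(p)
      ps <- sort(p)
      kmax <- suppressWarnings(max(which(ps <= (seq_len(m) / m) * alpha)))
      stepup <- if (is.finite(kmax)) p <= ps[kmax] else rep(FALSE, m)
      expect_identical(q <= alpha, stepup)
    }
  }
})

test_that("compare_all adjusts within the tested family and reports skips", {
  set.seed(5)
  n <- 40
  tab <- data.frame(group = rep(c("a", "b"), each = n / 2),
                    age_months = runif(n, 18, 36))
  tab$touch_duration_mean <- rnorm(n) + (tab$group == "b")
  tab$touch_length_mean <- rnorm(n)
  tab$bubble_popping_rate <- NA_real_  # skipped: all missing
  res <- compare_all(tab, group = "group", covariates = "age_months")
  expect_identical(nrow(res), 3L)
  skipped <- res[!is.na(res$skipped_reason), ]
  expect_identical(skipped$feature, "bubble_popping_rate")
  tested <- res[is.na(res$skipped_reason), ]
  expect_equal(tested$p_adjusted, bh_adjust(tested$p_raw))
  expect_error(compare_all(tab, group = "group", covariates = "iq"),
               "covariate column")
})

test_that("Mann-Whitney exact branch matches full enumeration", {
  res <- mannwhitney_rb(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$U), 0)
  expect_equal(res$r_rank_biserial, 1)
  expect_identical(res$method, "exact")
  expect_equal(res$p_two_sided, 0.1)  # 2/20 splits as extreme

  # identical multisets: U = n1 n2 / 2, r = 0
  res0 <- mannwhitney_rb(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$r_rank_biserial, 0)

  # antisymmetry under swapping samples
  set.seed(3)
  x <- rnorm(7); y <- rnorm(5)
  a <- mannwhitney_rb(x, y); b <- mannwhitney_rb(y, x)
  expect_equal(unname(a$U + b$U), 35)
  expect_equal(a$r_rank_biserial, -b$r_rank_biserial)
  expect_equal(a$p_two_sided, b$p_two_sided)

  # enumeration oracle over a few size combinations
  set.seed(11)
  for (n1 in c(2, 4, 6)) {
    for (n2 in c(3, 5)) {
      x <- rnorm(n1); y <- rnorm(n2)
      res <- mannwhitney_rb(x, y)
      pooled <- c(x, y)
      U_obs <- sum(outer(x, y, ">"))
      splits <- utils::combn(n1 + n2, n1)
      Us <- apply(splits, 2, function(ix) {
        sum(outer(pooled[ix], pooled[-ix], ">"))
      })
      mu <- n1 * n2 / 2
      p_ref <- mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
      expect_equal(unname(res$U), U_obs)
      expect_equal(res$p_two_sided, p_ref, tolerance = 1e-12)
    }
  }
})

test_that("the proportion z-test evaluates the pooled formula", {
  res <- proportions_ztest(c(5, 5), c(10, 10))
  expect_equal(res$Z, 0)
  expect_equal(res$p_two_sided, 1)

  res2 <- proportions_ztest(c(9, 3), c(10, 10))
  Zref <- (0.9 - 0.3) / sqrt(0.6 * 0.4 * (1 / 10 + 1 / 10))
  expect_equal(res2$Z, Zref)
  expect_equal(res2$p_two_sided, 2 * pnorm(-Zref))
  expect_equal(res2$Z, 2.7386, tolerance = 1e-4)

  # one-sided saturation is fine as long as the pooled rate is interior
  res3 <- proportions_ztest(c(10, 0), c(10, 10))
  expect_equal(res3$Z, 1 / sqrt(0.25 * 0.2), tolerance = 1e-12)
  expect_error(proportions_ztest(c(10, 10), c(10, 10)), "degenerate")
})

test_that("partial Spearman reduces to plain Spearman and is monotone-invariant", {
  set.seed(7)
  x <- rnorm(30)
  y <- x^3  # monotone transform
  res <- spearman_partial(x, y)
  expect_equal(res$rho, 1)
  expect_equal(res$p, 0)

  # no covariates == stats::cor spearman to 1e-12
  y2 <- rnorm(30)
  res2 <- spearman_partial(x, y2)
  expect_equal(res2$rho, cor(x, y2, method = "spearman"), tolerance = 1e-12)
  tref <- res2$rho * sqrt((30 - 2) / (1 - res2$rho^2))
  expect_equal(res2$p, 2 * pt(-abs(tref), 28), tolerance = 1e-12)

  # a constant covariate is dropped
  res3 <- spearman_partial(x, y2, data.frame(c0 = rep(1, 30)))
  expect_equal(res3$rho, res2$rho, tolerance = 1e-12)
  expect_identical(res3$covariates, character(0))

  expect_error(spearman_partial(rnorm(3), rnorm(3), data.frame(z = rnorm(3))),
               "n > covariates")
  expect_error(spearman_partial(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("partial Spearman matches an independent residualisation oracle", {
  set.seed(123)
  n <- 500
  z <- rnorm(n)
  x <- 0.7 * z + rnorm(n)
  y <- 0.7 * z + rnorm(n)
  res <- spearman_partial(x, y, data.frame(z = z))

  # oracle: lm() on ranks, then Pearson correlation of the residuals
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- residuals(lm(rx ~ rz))
  ey <- residuals(lm(ry ~ rz))
  rho_ref <- cor(ex, ey)
  expect_equal(res$rho, rho_ref, tolerance = 1e-10)
  # the shared driver is removed: partial rho much smaller than marginal
  expect_lt(abs(res$rho), abs(cor(x, y, method = "spearman")))
  expect_lt(abs(res$rho), 0.15)
})

test_that("cohort-level partial correlations recover planted clinical loadings", {
  prof <- default_profiles()
  spec <- cohort_spec(groups = list(autistic = list(profile = prof$case, n = 60)),
                      clinical_score_model = list(fine_motor = c(8, 2),
                                                  unrelated = c(0, 2)),
                      seed = 17)
  co <- simulate_cohort(spec)
  ft <- features_table(co$sessions)
  tab <- correlate_features(ft,
                            features = c("distance_to_center_mean",
                                         "bubble_popping_rate"),
                            scores = c("fine_motor", "unrelated"),
                            covariates = "age_months")
  # fine-motor loads on low aim error: aim error worsens distance-to-center
  r_fm <- tab$rho[tab$feature == "distance_to_center_mean" &
                    tab$score == "fine_motor"]
  expect_lt(r_fm, 0)
  r_un <- tab$rho[tab$feature == "distance_to_center_mean" &
                    tab$score == "unrelated"]
  expect_lt(abs(r_un), 0.35)
})
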