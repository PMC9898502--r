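test_that("touch kinematics match closed-form values", {
  k <- touch_kinematics(make_trace("T1", c(0, 0.1), c(0, 3), c(0, 4)))
  expect_equal(k$duration_s, 0.1)
  expect_equal(k$length_mm, 5)
  expect_equal(k$velocity_mm_s, 50)

  k1 <- touch_kinematics(make_trace("T1", 0.5, 3, 4))
  expect_equal(k1$duration_s, 0)
  expect_equal(k1$length_mm, 0)
  expect_true(is.na(k1$velocity_mm_s))

  # out-and-back path accumulates both legs
  k2 <- touch_kinematics(make_trace("T1", c(0, 0.1, 0.2),
                                    c(0, 3, 0), c(0, 4, 0)))
  expect_equal(k2$length_mm, 10)
  expect_equal(k2$velocity_mm_s, 50)

  expect_error(touch_kinematics(list(touch_id = "T1", t = numeric(),
                                     x_mm = numeric(), y_mm = numeric())),
               "empty")
})

test_that("double-touch detection applies the time-and-radius rule pairwise", {
  cfg <- game_config()
  two <- list(make_trace("T1", c(1, 1.05), c(50, 50), c(50, 50)),
              make_trace("T2", 1.15, 52, 50))
  expect_identical(detect_double_touches(two, cfg), c(FALSE, TRUE))

  apart <- list(make_trace("T1", c(1, 1.05), c(50, 50), c(50, 50)),
                make_trace("T2", 2.05, 50, 50))
  expect_identical(detect_double_touches(apart, cfg), c(FALSE, FALSE))

  # three rapid same-spot touches: both later touches are flagged
  three <- list(make_trace("T1", 1.0, 50, 50),
                make_trace("T2", 1.2, 51, 50),
                make_trace("T3", 1.4, 50, 51))
  expect_identical(detect_double_touches(three, cfg),
                   c(FALSE, TRUE, TRUE))
})

test_that("pop detection honors the 18.5 mm boundary and nearest-bubble rule", {
  cfg <- game_config()
  b <- one_bubble(cfg)
  t0 <- 2
  by <- bubble_y(b, t0, cfg)
  at_d <- function(d) list(make_trace("T1", t0, b$center_x_mm + d, by))

  expect_identical(nrow(detect_pops(at_d(18.5), b, cfg)), 1L)
  expect_identical(nrow(detect_pops(at_d(18.6), b, cfg)), 0L)
  p <- detect_pops(at_d(18.5), b, cfg)
  expect_equal(p$distance_to_center_mm, 18.5)

  # with the boundary configured exclusive, 18.5 no longer pops
  cfg_ex <- game_config(pop_boundary_inclusive = FALSE)
  expect_identical(nrow(detect_pops(at_d(18.5), b, cfg_ex)), 0L)

  # two candidate bubbles: only the nearer one pops, exactly once
  b2 <- rbind(b, one_bubble(cfg, lane = 1L, id = "B2"))
  tr <- list(make_trace("T1", t0, b2$center_x_mm[1] + 10, by))
  d1 <- 10
  d2 <- sqrt((b2$center_x_mm[2] - (b2$center_x_mm[1] + 10))^2)
  stopifnot(d2 > d1)
  pp <- detect_pops(tr, b2, cfg)
  expect_identical(nrow(pp), 1L)
  expect_identical(pp$bubble_id, "B1")
})

test_that("target association merges consecutive touches and respects the radius", {
  cfg <- game_config()
  b <- one_bubble(cfg)
  near <- function(id, t, dx) {
    make_trace(id, t, b$center_x_mm + dx, bubble_y(b, t, cfg))
  }
  # three touches near one bubble -> one episode with 3 touches
  trs <- list(near("T1", 1.0, 25), near("T2", 1.3, 24), near("T3", 1.6, 23))
  eps <- associate_targets(trs, b, cfg)
  expect_length(eps, 1L)
  expect_identical(eps[[1]]$n_touches, 3L)
  expect_identical(eps[[1]]$touch_ids, c("T1", "T2", "T3"))

  # A, A, B, A -> three episodes
  bb <- rbind(b, one_bubble(cfg, lane = 4L, id = "B2"))
  nearb <- function(id, t) {
    make_trace(id, t, bb$center_x_mm[2], bubble_y(bb[2, ], t, cfg))
  }
  trs2 <- list(near("T1", 1.0, 5), near("T2", 1.3, 5),
               nearb("T3", 1.6), near("T4", 2.0, 5))
  eps2 <- associate_targets(trs2, bb, cfg)
  expect_length(eps2, 3L)
  expect_identical(vapply(eps2, `[[`, character(1), "bubble_id"),
                   c("B1", "B2", "B1"))

  # a touch 30 mm from every bubble is unassigned
  far <- list(make_trace("T1", 1, b$center_x_mm + 30, bubble_y(b, 1, cfg)))
  expect_length(associate_targets(far, b, cfg), 0L)
})

test_that("popping accuracy decays linearly beyond the bubble edge", {
  cfg <- game_config()
  b <- one_bubble(cfg)
  t0 <- 1
  by <- bubble_y(b, t0, cfg)
  acc_at <- function(d) {
    popping_accuracy(make_trace("T1", t0, b$center_x_mm + d, by), b, cfg)
  }
  expect_equal(acc_at(10)$mean_pct, 100)     # inside the disc
  expect_equal(acc_at(27.75)$mean_pct, 50)   # half a decay length out
  expect_equal(acc_at(40)$mean_pct, 0)       # floored
  expect_true(is.na(acc_at(10)$std_pct))     # single sample
  expect_error(popping_accuracy(make_trace("T1", t0, 1, 1), NULL, cfg),
               "no assigned bubble")
})

test_that("the force proxy integrates squared high-passed acceleration", {
  cfg <- game_config()
  # direct check of the trapezoid on a constant squared magnitude
  hp <- list(t = seq(0, 0.5, by = 1 / 60), mag2 = rep(0.2^2, 31))
  expect_equal(bubblepop:::integrate_force(hp, 0, 0.5, cfg), 0.02,
               tolerance = 1e-12)

  # zero acceleration -> zero force
  prof0 <- agent_profile(force_scale = 0)
  acc0 <- synthesize_accel(list(), prof0, cfg, seed = 1, noise_sd = 0)
  tr <- make_trace("T1", c(5, 5.5), c(10, 10), c(10, 10))
  expect_equal(applied_force(tr, acc0, cfg), 0, tolerance = 1e-20)

  # synthesized impulse matches the analytic Gaussian-squared integral
  # integral of A^2 exp(-(t-t0)^2/sigma^2) = A^2 sigma sqrt(pi)
  A <- 1.8
  sigma <- 0.08 / 4
  prof <- agent_profile(force_scale = A)
  tr2 <- make_trace("T1", c(10, 10.4), c(10, 10), c(10, 10))
  acc <- synthesize_accel(list(tr2), prof, cfg, seed = 1, noise_sd = 0)
  analytic <- A^2 * sigma * sqrt(pi)
  # widen the integration window to cover the whole impulse
  got <- bubblepop:::integrate_force(bubblepop:::highpass_accel(acc, cfg),
                                     9.5, 10.9, cfg)
  expect_equal(got, analytic, tolerance = 0.02 * analytic)
})

test_that("screen exploration counts occupied grid cells", {
  cfg <- game_config(screen_width_mm = 100, screen_height_mm = 100,
                     exploration_cell_mm = 10)
  # samples in 5 distinct cells of a 10x10 grid
  tr <- make_trace("T1", seq(1, 1.4, by = 0.1),
                   c(5, 15, 25, 35, 45), c(5, 15, 25, 35, 45))
  expect_equal(exploration_percentage(list(tr), cfg), 0.05)
  expect_equal(exploration_percentage(list(), cfg), 0)
  one <- make_trace("T1", c(1, 1.1), c(3, 4), c(3, 4))
  expect_equal(exploration_percentage(list(one), cfg), 1 / 100)
  # edge samples land in the last cell, not a phantom one
  edge <- make_trace("T1", 1, 100, 100)
  expect_equal(exploration_percentage(list(edge), cfg), 1 / 100)
})

test_that("session-level features follow their definitions on a constructed session", {
  cfg <- game_config()
  b0 <- one_bubble(cfg, lane = 2L, character_id = 3L, id = "P1")
  t1 <- 1
  y1 <- bubble_y(b0, t1, cfg)
  # pop P1 at distance 3 -> respawn P2 (same lane+char), pop at distance 5
  # -> respawn P3; then pop a lane-3 bubble (transition)
  b0$end_t <- t1; b0$end_reason <- "popped"
  t2 <- 9
  b1 <- data.frame(bubble_id = "P2", lane = 2L, character_id = 3L,
                   spawn_t = t1 + 0.5, end_t = t2, end_reason = "popped",
                   center_x_mm = b0$center_x_mm, stringsAsFactors = FALSE)
  b2 <- data.frame(bubble_id = "P3", lane = 2L, character_id = 3L,
                   spawn_t = t2 + 0.5, end_t = 20, end_reason = "exited",
                   center_x_mm = b0$center_x_mm, stringsAsFactors = FALSE)
  bL3 <- one_bubble(cfg, lane = 3L, character_id = 5L, id = "Q1",
                    spawn_t = 8)
  t3 <- 18
  bL3$end_t <- t3; bL3$end_reason <- "popped"
  bubbles <- rbind(b0, b1, b2, bL3)

  trs <- list(
    make_trace("T1", t1, b0$center_x_mm + 3, bubble_y(b0, t1, cfg)),
    make_trace("T2", t2, b1$center_x_mm + 5, bubble_y(b1, t2, cfg)),
    make_trace("T3", t3, bL3$center_x_mm, bubble_y(bL3, t3, cfg)),
    make_trace("T4", 19.5, 5, 5))  # far from everything: no pop, no target
  rec <- make_record(trs, bubbles = bubbles, config = cfg)
  expect_identical(nrow(rec$pops), 3L)

  fx <- extract_features(rec)
  expect_equal(unname(fx["number_of_touches"]), 4)
  expect_equal(unname(fx["number_of_pops"]), 3)
  expect_equal(unname(fx["bubble_popping_rate"]), 0.75)
  # pop pairs: (P1,P2) same lane+char, (P2,Q1) different lane
  expect_equal(unname(fx["repeat_percentage"]), 0.5)
  expect_equal(unname(fx["number_of_transitions"]), 1)
  # distances 3, 5, 0
  expect_equal(unname(fx["distance_to_center_mean"]), mean(c(3, 5, 0)))
  expect_equal(unname(fx["distance_to_center_median"]), 3)
  expect_equal(unname(fx["distance_to_center_std"]), sd(c(3, 5, 0)))
  expect_equal(unname(fx["number_of_targeted_bubbles"]), 3)

  # two pops at 3 and 5 mm alone: mean 4, median 4, sample sd sqrt(2)
  rec2 <- make_record(trs[1:2], bubbles = rbind(b0, b1, b2), config = cfg)
  fx2 <- extract_features(rec2)
  expect_equal(unname(fx2["distance_to_center_mean"]), 4)
  expect_equal(unname(fx2["distance_to_center_median"]), 4)
  expect_equal(unname(fx2["distance_to_center_std"]), sqrt(2))
})

test_that("std features are NA (not zero) below two observations and bounds hold", {
  for (s in c(3, 14)) {
    rec <- simulate_session(default_profiles()$nt, 24, seed = s)
    fx <- extract_features(rec)
    expect_true(fx["number_of_pops"] <= fx["number_of_touches"])
    rates <- fx[c("bubble_popping_rate", "double_touch_rate",
                  "screen_exploratory_percentage", "repeat_percentage")]
    rates <- rates[!is.na(rates)]
    expect_true(all(rates >= 0 & rates <= 1))
    acc <- fx[c("popping_accuracy_mean", "popping_accuracy_median")]
    expect_true(all(acc >= 0 & acc <= 100, na.rm = TRUE))
    expect_true(all(fx[c("applied_force_mean", "applied_force_median")] >= 0,
                    na.rm = TRUE))
  }
  # single-pop record: distance std undefined, row still complete
  cfg <- game_config()
  b <- one_bubble(cfg)
  tr <- list(make_trace("T1", 1, b$center_x_mm, bubble_y(b, 1, cfg)))
  fx1 <- extract_features(make_record(tr, bubbles = b, config = cfg))
  expect_true(is.na(fx1["distance_to_center_std"]))
  expect_equal(unname(fx1["number_of_pops"]), 1)
})

test_that("feature tables keep one row per session and survive CSV round-trips", {
  sessions <- lapply(1:3, function(s) {
    simulate_session(default_profiles()$nt, 20 + s, seed = s,
                     session_id = sprintf("S%d", s))
  })
  ft <- features_table(sessions)
  expect_identical(nrow(ft), 3L)
  expect_true(all(feature_names() %in% colnames(ft)))

  f <- tempfile(fileext = ".csv")
  utils::write.csv(ft, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_identical(nrow(back), 3L)
  expect_equal(is.na(back[feature_names()]), is.na(ft[feature_names()]),
               ignore_attr = TRUE)
  unlink(f)

  dup <- c(sessions, sessions[1])
  expect_error(features_table(dup), "duplicate session_id")
})

test_that("larger aim error does not improve popping accuracy (paired seeds)", {
  base <- agent_profile()
  worse <- agent_profile(aim_sd_mm = base$aim_sd_mm * 2)
  d_base <- d_worse <- r_base <- r_worse <- numeric(20)
  for (s in 1:20) {
    f1 <- extract_features(simulate_session(base, 24, seed = s))
    f2 <- extract_features(simulate_session(worse, 24, seed = s))
    d_base[s] <- f1["distance_to_center_mean"]
    d_worse[s] <- f2["distance_to_center_mean"]
    r_base[s] <- f1["bubble_popping_rate"]
    r_worse[s] <- f2["bubble_popping_rate"]
  }
  expect_gte(mean(d_worse, na.rm = TRUE), mean(d_base, na.rm = TRUE))
  expect_lte(mean(r_worse, na.rm = TRUE), mean(r_base, na.rm = TRUE))
})

test_that("age-related feature trends match the developmental directions", {
  prof <- default_profiles()
  spec <- cohort_spec(groups = list(NT = list(profile = prof$nt, n = 120)),
                      seed = 77)
  co <- simulate_cohort(spec)
  ft <- features_table(co$sessions)
  rho <- function(f) cor(ft$age_months, ft[[f]], method = "spearman",
                         use = "complete.obs")
  expect_gt(rho("number_of_touches"), 0)
  expect_gt(rho("bubble_popping_rate"), 0)
  expect_lt(rho("distance_to_center_median"), 0)
  expect_lt(rho("touch_duration_mean"), 0)
  expect_lt(rho("touch_length_mean"), 0)
})
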