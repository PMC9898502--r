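# Independent brute-force recomputation of every session feature, written
# directly from the feature definitions with plain loops and no shared
# helpers with the package internals. Used to cross-check extract_features.

oracle_features <- function(rec) {
  cfg <- rec$config
  H <- cfg$screen_height_mm
  v <- cfg$bubble_speed_mm_s

  # sort touches by onset
  onsets <- sapply(rec$touches, function(tr) tr$t[1])
  trs <- if (length(onsets)) rec$touches[order(onsets)] else list()
  nt <- length(trs)
  pops <- rec$pops
  if (nrow(pops) > 1) pops <- pops[order(pops$t), , drop = FALSE]
  np <- nrow(pops)

  sdev <- function(z) { z <- z[!is.na(z)]
    if (length(z) >= 2) stats::sd(z) else NA_real_ }
  mmed <- function(z) { z <- z[!is.na(z)]
    if (length(z)) c(mean(z), stats::median(z)) else c(NA_real_, NA_real_) }

  out <- c()
  out["number_of_touches"] <- nt
  out["number_of_pops"] <- np
  out["bubble_popping_rate"] <- if (nt > 0) np / nt else NA_real_

  # double touches: pairwise rule on consecutive touches
  dbl <- 0L
  if (nt >= 2) {
    for (i in 2:nt) {
      a <- trs[[i - 1]]; b <- trs[[i]]
      gap <- b$t[1] - a$t[length(a$t)]
      dd <- sqrt((b$x_mm[1] - a$x_mm[1])^2 + (b$y_mm[1] - a$y_mm[1])^2)
      if (gap <= cfg$double_touch_window_s &&
          dd <= cfg$double_touch_radius_mm) dbl <- dbl + 1L
    }
  }
  out["double_touch_rate"] <- if (nt > 0) dbl / nt else NA_real_

  # exploration: count occupied grid cells
  cell <- cfg$exploration_cell_mm
  nx <- ceiling(cfg$screen_width_mm / cell)
  ny <- ceiling(H / cell)
  seen <- character()
  for (tr in trs) {
    for (k in seq_along(tr$t)) {
      cx <- min(floor(tr$x_mm[k] / cell), nx - 1)
      cy <- min(floor(tr$y_mm[k] / cell), ny - 1)
      seen <- union(seen, paste(cx, cy))
    }
  }
  out["screen_exploratory_percentage"] <- length(seen) / (nx * ny)

  # pop sequence: lane transitions and lane+character repeats
  trans <- 0L; rept <- 0L
  if (np >= 2) {
    for (i in 2:np) {
      b1 <- rec$bubbles[rec$bubbles$bubble_id == pops$bubble_id[i - 1], ]
      b2 <- rec$bubbles[rec$bubbles$bubble_id == pops$bubble_id[i], ]
      if (b1$lane != b2$lane) trans <- trans + 1L
      if (b1$lane == b2$lane && b1$character_id == b2$character_id) {
        rept <- rept + 1L
      }
    }
  }
  out["number_of_transitions"] <- trans
  out["repeat_percentage"] <- if (np >= 2) rept / (np - 1) else NA_real_

  # kinematics
  durs <- lens <- vels <- rep(NA_real_, nt)
  for (i in seq_len(nt)) {
    tr <- trs[[i]]
    m <- length(tr$t)
    durs[i] <- tr$t[m] - tr$t[1]
    L <- 0
    if (m > 1) {
      for (k in 2:m) {
        L <- L + sqrt((tr$x_mm[k] - tr$x_mm[k - 1])^2 +
                        (tr$y_mm[k] - tr$y_mm[k - 1])^2)
      }
    }
    lens[i] <- L
    vels[i] <- if (durs[i] > 0) L / durs[i] else NA_real_
  }
  out[c("touch_duration_mean", "touch_duration_median")] <- mmed(durs)
  out["touch_duration_std"] <- sdev(durs)
  out[c("touch_length_mean", "touch_length_median")] <- mmed(lens)
  out["touch_length_std"] <- sdev(lens)
  out[c("touch_velocity_mean", "touch_velocity_median")] <- mmed(vels)
  out["touch_velocity_std"] <- sdev(vels)

  # applied force: own sliding-window median high-pass (1 s window,
  # constant end extension) and trapezoid integral of |a_hp|^2
  forces <- rep(NA_real_, nt)
  at <- rec$accel$t
  if (length(at) >= 2) {
    k <- round(cfg$sensor_rate_hz)
    if (k %% 2 == 0) k <- k + 1
    k <- min(k, if (length(at) %% 2 == 1) length(at) else length(at) - 1)
    k2 <- (k - 1) / 2
    hp1 <- function(a) {
      n <- length(a)
      med <- rep(NA_real_, n)
      for (i in (k2 + 1):(n - k2)) med[i] <- stats::median(a[(i - k2):(i + k2)])
      med[1:k2] <- med[k2 + 1]
      med[(n - k2 + 1):n] <- med[n - k2]
      a - med
    }
    hx <- hp1(rec$accel$ax); hy <- hp1(rec$accel$ay); hz <- hp1(rec$accel$az)
    mag2 <- hx^2 + hy^2 + hz^2
    for (i in seq_len(nt)) {
      tr <- trs[[i]]
      lo <- max(tr$t[1], at[1])
      hi <- min(tr$t[length(tr$t)], at[length(at)])
      if (hi <= lo) { forces[i] <- 0; next }
      idx <- which(at >= lo - 1e-9 & at <= hi + 1e-9)
      if (length(idx) < 2) {
        j <- which.min(abs(at - (lo + hi) / 2))
        forces[i] <- mag2[j] * (hi - lo)
        next
      }
      s <- 0
      for (k3 in idx[-length(idx)]) {
        s <- s + (at[k3 + 1] - at[k3]) * (mag2[k3] + mag2[k3 + 1]) / 2
      }
      forces[i] <- s
    }
    out[c("applied_force_mean", "applied_force_median")] <- mmed(forces)
    out["applied_force_std"] <- sdev(forces)
  } else {
    out[c("applied_force_mean", "applied_force_median",
          "applied_force_std")] <- NA_real_
  }

  # distance to center over pops
  out[c("distance_to_center_mean", "distance_to_center_median")] <-
    mmed(if (np) pops$distance_to_center_mm else numeric())
  out["distance_to_center_std"] <- sdev(pops$distance_to_center_mm)

  # targeting: nearest on-screen bubble within the targeting radius at onset
  assign_of <- rep(NA_character_, nt)
  for (i in seq_len(nt)) {
    t0 <- trs[[i]]$t[1]
    best <- NA_character_; bestd <- Inf
    for (r in seq_len(nrow(rec$bubbles))) {
      b <- rec$bubbles[r, ]
      if (t0 < b$spawn_t || t0 > b$end_t) next
      by <- H - v * (t0 - b$spawn_t)
      if (by < 0) next
      d <- sqrt((trs[[i]]$x_mm[1] - b$center_x_mm)^2 +
                  (trs[[i]]$y_mm[1] - by)^2)
      if (d < bestd) { bestd <- d; best <- b$bubble_id }
    }
    if (bestd <= cfg$targeting_radius_mm) assign_of[i] <- best
  }
  # episodes: consecutive same-bubble runs
  eps <- list()
  i <- 1
  while (i <= nt) {
    if (is.na(assign_of[i])) { i <- i + 1; next }
    j <- i
    while (j < nt && !is.na(assign_of[j + 1]) &&
           assign_of[j + 1] == assign_of[i]) j <- j + 1
    eps[[length(eps) + 1]] <- list(bubble = assign_of[i], idx = i:j)
    i <- j + 1
  }
  out["number_of_targeted_bubbles"] <- length(eps)

  if (length(eps)) {
    tpt <- sapply(eps, function(e) length(e$idx))
    spans <- sapply(eps, function(e) {
      last <- trs[[e$idx[length(e$idx)]]]
      last$t[length(last$t)] - trs[[e$idx[1]]]$t[1]
    })
    freq <- ifelse(spans > 0, tpt / spans, NA_real_)
    out["touches_per_target_mean"] <- mean(tpt)
    out["touches_per_target_std"] <- sdev(tpt)
    out[c("touch_frequency_mean", "touch_frequency_median")] <- mmed(freq)
    out["touch_frequency_std"] <- sdev(freq)
    out[c("time_on_target_mean", "time_on_target_median")] <- mmed(spans)
    out["time_on_target_std"] <- sdev(spans)

    # popping accuracy per targeted touch against its episode's bubble,
    # evaluated at each sample time with the position clamped to the track
    am <- ax <- asd <- numeric()
    for (e in eps) {
      b <- rec$bubbles[rec$bubbles$bubble_id == e$bubble, ]
      for (ii in e$idx) {
        tr <- trs[[ii]]
        acc <- numeric(length(tr$t))
        for (k4 in seq_along(tr$t)) {
          tc <- min(max(tr$t[k4], b$spawn_t), b$end_t)
          by <- H - v * (tc - b$spawn_t)
          d <- sqrt((tr$x_mm[k4] - b$center_x_mm)^2 + (tr$y_mm[k4] - by)^2)
          de <- max(0, d - cfg$bubble_radius_mm)
          acc[k4] <- 100 * max(0, 1 - de / cfg$accuracy_decay_mm)
        }
        am <- c(am, mean(acc))
        ax <- c(ax, max(acc))
        asd <- c(asd, if (length(acc) >= 2) stats::sd(acc) else NA_real_)
      }
    }
    out[c("popping_accuracy_mean", "popping_accuracy_median")] <- mmed(am)
    out["popping_accuracy_std"] <- sdev(am)
    out["accuracy_variation_mean"] <-
      if (any(!is.na(asd))) mean(asd[!is.na(asd)]) else NA_real_
    out["accuracy_mean_variability"] <- sdev(am)
    out["accuracy_max_variability"] <- sdev(ax)
  }

  full <- stats::setNames(rep(NA_real_, length(feature_names())),
                          feature_names())
  full[names(out)] <- out
  full
}
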