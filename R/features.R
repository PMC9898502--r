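#' Canonical motor-feature names
#'
#' The 19 feature families extracted from a session, expanded into 37 named
#' session-level features (mean/median/std variants where applicable), in the
#' stable column order used by [features_table()].
#'
#' @return Character vector of feature names.
#' @export
feature_names <- function() {
  c("number_of_touches", "number_of_pops", "bubble_popping_rate",
    "double_touch_rate", "screen_exploratory_percentage",
    "number_of_targeted_bubbles", "number_of_transitions",
    "repeat_percentage",
    "touch_duration_mean", "touch_duration_median", "touch_duration_std",
    "touch_length_mean", "touch_length_median", "touch_length_std",
    "touch_velocity_mean", "touch_velocity_median", "touch_velocity_std",
    "applied_force_mean", "applied_force_median", "applied_force_std",
    "distance_to_center_mean", "distance_to_center_median",
    "distance_to_center_std",
    "popping_accuracy_mean", "popping_accuracy_median",
    "popping_accuracy_std",
    "accuracy_variation_mean", "accuracy_mean_variability",
    "accuracy_max_variability",
    "touches_per_target_mean", "touches_per_target_std",
    "touch_frequency_mean", "touch_frequency_median", "touch_frequency_std",
    "time_on_target_mean", "time_on_target_median", "time_on_target_std")
}

# mean/median/sample-sd summary; sd is NA below 2 observations
summary3 <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, median = NA_real_, std = NA_real_))
  c(mean = mean(x), median = stats::median(x),
    std = if (length(x) >= 2L) stats::sd(x) else NA_real_)
}

touch_onset <- function(tr) tr$t[1]
touch_offset <- function(tr) tr$t[length(tr$t)]

#' Per-touch kinematics
#'
#' @param trace A touch trace (list with `touch_id`, `t`, `x_mm`, `y_mm`).
#' @return List with `touch_id`, `duration_s` (offset minus onset),
#'   `length_mm` (sum of Euclidean steps between consecutive samples),
#'   `velocity_mm_s` (length over duration; NA for single-sample traces),
#'   and `onset_xy`.
#' @export
touch_kinematics <- function(trace) {
  n <- length(trace$t)
  if (n < 1L) stop("touch_kinematics: empty trace", call. = FALSE)
  duration <- trace$t[n] - trace$t[1]
  len <- if (n > 1L) {
    sum(sqrt(diff(trace$x_mm)^2 + diff(trace$y_mm)^2))
  } else 0
  list(touch_id = trace$touch_id[1],
       duration_s = duration,
       length_mm = len,
       velocity_mm_s = if (duration > 0) len / duration else NA_real_,
       onset_xy = c(trace$x_mm[1], trace$y_mm[1]))
}

#' Detect double touches
#'
#' Touch `i+1` is flagged a double touch of touch `i` when the gap between
#' touch `i`'s offset and touch `i+1`'s onset is at most
#' `double_touch_window_s` and their onset locations are at most
#' `double_touch_radius_mm` apart.
#'
#' @param traces List of touch traces, sorted by onset time.
#' @param config A [game_config()].
#' @return Logical vector, one flag per touch (the first touch is never
#'   flagged).
#' @export
detect_double_touches <- function(traces, config = game_config()) {
  n <- length(traces)
  flags <- logical(n)
  if (n < 2L) return(flags)
  for (i in 2:n) {
    gap <- touch_onset(traces[[i]]) - touch_offset(traces[[i - 1L]])
    d <- sqrt((traces[[i]]$x_mm[1] - traces[[i - 1L]]$x_mm[1])^2 +
                (traces[[i]]$y_mm[1] - traces[[i - 1L]]$y_mm[1])^2)
    flags[i] <- gap <= config$double_touch_window_s &&
      d <= config$double_touch_radius_mm
  }
  flags
}

# index of the nearest row of `st` (data frame with x, y); ties broken by
# first (schedule) order
nearest_bubble <- function(st, x, y) {
  d <- sqrt((x - st$x)^2 + (y - st$y)^2)
  j <- which.min(d)
  list(idx = j, dist = d[j])
}

# bubbles on screen at time t as a position list
bubble_positions_at <- function(bubbles, t, config) {
  act <- which(bubble_active_at(bubbles, t, config))
  list(n = length(act), row = act,
       bubble_id = bubbles$bubble_id[act],
       x = bubbles$center_x_mm[act],
       y = bubble_y_at(bubbles$spawn_t[act], bubbles$end_t[act], t, config))
}

#' Recompute pop events from touches and bubble tracks
#'
#' For each touch onset (in time order), the nearest on-screen bubble not
#' already popped is popped if the onset lies within the pop radius of its
#' center (boundary inclusive by default). On simulator output this
#' reproduces the logged pop events exactly.
#'
#' @param traces List of touch traces.
#' @param bubbles Bubble-track data frame.
#' @param config A [game_config()].
#' @return Data frame of pop events (see [session_record()]).
#' @export
detect_pops <- function(traces, bubbles, config = game_config()) {
  ord <- order(vapply(traces, touch_onset, numeric(1)))
  popped <- character()
  out <- list()
  for (i in ord) {
    tr <- traces[[i]]
    t0 <- tr$t[1]
    st <- bubble_positions_at(bubbles, t0, config)
    keep <- !(st$bubble_id %in% popped)
    st <- list(n = sum(keep), bubble_id = st$bubble_id[keep],
               x = st$x[keep], y = st$y[keep])
    if (!st$n) next
    nb <- nearest_bubble(st, tr$x_mm[1], tr$y_mm[1])
    hit <- if (config$pop_boundary_inclusive) {
      nb$dist <= config$pop_radius_mm
    } else {
      nb$dist < config$pop_radius_mm
    }
    if (hit) {
      popped <- c(popped, st$bubble_id[nb$idx])
      out[[length(out) + 1L]] <- list(
        t = t0, bubble_id = st$bubble_id[nb$idx],
        touch_id = tr$touch_id[1], distance_to_center_mm = nb$dist)
    }
  }
  bind_rowlists(out, empty_pops())
}

#' Associate touches with targeted bubbles
#'
#' Each touch is assigned to the nearest on-screen bubble within the
#' targeting radius at its onset (unassigned otherwise). Maximal runs of
#' consecutive touches assigned to the same bubble form target episodes; a
#' run necessarily ends when its bubble pops or exits, since later touches
#' land on a different (respawned) track. An episode spans its first touch's
#' onset to its last touch's offset.
#'
#' @param traces List of touch traces.
#' @param bubbles Bubble-track data frame.
#' @param config A [game_config()].
#' @return List of episodes, each a list with `bubble_id`, `touch_idx`
#'   (indices into the time-sorted trace list), `touch_ids`, `start_t`,
#'   `end_t`, `n_touches`.
#' @export
associate_targets <- function(traces, bubbles, config = game_config()) {
  if (!length(traces)) return(list())
  ord <- order(vapply(traces, touch_onset, numeric(1)))
  assigned <- rep(NA_character_, length(traces))
  for (k in seq_along(ord)) {
    tr <- traces[[ord[k]]]
    st <- bubble_positions_at(bubbles, tr$t[1], config)
    if (!st$n) next
    nb <- nearest_bubble(st, tr$x_mm[1], tr$y_mm[1])
    if (nb$dist <= config$targeting_radius_mm) {
      assigned[k] <- st$bubble_id[nb$idx]
    }
  }
  episodes <- list()
  k <- 1L
  while (k <= length(ord)) {
    if (is.na(assigned[k])) { k <- k + 1L; next }
    j <- k
    while (j < length(ord) && !is.na(assigned[j + 1L]) &&
           assigned[j + 1L] == assigned[k]) {
      j <- j + 1L
    }
    idx <- ord[k:j]
    episodes[[length(episodes) + 1L]] <- list(
      bubble_id = assigned[k],
      touch_idx = idx,
      touch_ids = vapply(traces[idx], function(tr) as.character(tr$touch_id[1]),
                         character(1)),
      start_t = touch_onset(traces[[idx[1]]]),
      end_t = touch_offset(traces[[idx[length(idx)]]]),
      n_touches = length(idx))
    k <- j + 1L
  }
  episodes
}

#' Popping-accuracy profile of a touch
#'
#' For every sample of a touch assigned to a bubble, accuracy is 100% when
#' the sample lies on the bubble disc and decays linearly with the distance
#' beyond the bubble edge, reaching 0% at `accuracy_decay_mm` beyond the
#' edge. The reference is the bubble's instantaneous position at the sample
#' time (frozen at the pop location once the bubble has popped).
#'
#' @param trace A touch trace.
#' @param bubble The episode's bubble: a one-row bubble-track data frame or
#'   a list with `spawn_t`, `end_t`, `center_x_mm`.
#' @param config A [game_config()].
#' @return List with `per_sample_accuracy` (vector in [0, 100]), `mean_pct`,
#'   `max_pct`, `std_pct` (NA below 2 samples).
#' @export
popping_accuracy <- function(trace, bubble, config = game_config()) {
  if (is.null(bubble) || !length(bubble$spawn_t) ||
      is.na(bubble$spawn_t[1])) {
    stop("popping_accuracy: trace has no assigned bubble", call. = FALSE)
  }
  y <- bubble_y_at(bubble$spawn_t, bubble$end_t, trace$t, config)
  d <- sqrt((trace$x_mm - bubble$center_x_mm)^2 + (trace$y_mm - y)^2)
  d_edge <- pmax(0, d - config$bubble_radius_mm)
  acc <- 100 * pmax(0, 1 - d_edge / config$accuracy_decay_mm)
  list(per_sample_accuracy = acc,
       mean_pct = mean(acc),
       max_pct = max(acc),
       std_pct = if (length(acc) >= 2L) stats::sd(acc) else NA_real_)
}

#' Applied-force proxy for one touch
#'
#' Surrogate for the pressure applied to the screen: gravity is removed from
#' each accelerometer axis by subtracting a 1-second running median, and the
#' proxy is the trapezoidal integral of the squared magnitude of the
#' high-passed acceleration over the touch window.
#'
#' @param trace A touch trace.
#' @param accel Inertial stream (list with `t`, `ax`, `ay`, `az`).
#' @param config A [game_config()].
#' @return Non-negative scalar (m^2 s^-3); 0 for zero-duration touches.
#' @export
applied_force <- function(trace, accel, config = game_config()) {
  hp <- highpass_accel(accel, config)
  integrate_force(hp, touch_onset(trace), touch_offset(trace), config)
}

# running-median gravity removal; returns list(t, mag2) with the squared
# high-passed magnitude
highpass_accel <- function(accel, config) {
  n <- length(accel$t)
  if (!n) return(list(t = numeric(), mag2 = numeric()))
  k <- as.integer(round(config$sensor_rate_hz))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  hp <- function(a) {
    if (n < 3L || k < 3L) a - stats::median(a) else
      a - stats::runmed(a, k, endrule = "constant")
  }
  axh <- hp(accel$ax); ayh <- hp(accel$ay); azh <- hp(accel$az)
  list(t = accel$t, mag2 = axh^2 + ayh^2 + azh^2)
}

integrate_force <- function(hp, onset, offset, config) {
  if (offset <= onset || !length(hp$t)) return(0)
  eps <- 1e-9
  # clamp to the stream extent (the stream's last sample precedes the end
  # of the session window by one sampling step)
  onset <- max(onset, hp$t[1])
  offset <- min(offset, hp$t[length(hp$t)])
  if (offset <= onset) return(0)
  sel <- hp$t >= onset - eps & hp$t <= offset + eps
  t <- hp$t[sel]
  if (length(t) < 2L) {
    if (offset - onset > 2.5 / config$sensor_rate_hz) {
      stop("applied_force: inertial stream does not cover the touch window [",
           signif(onset, 6), ", ", signif(offset, 6), "]", call. = FALSE)
    }
    # touch shorter than the sampling step: rectangle rule at the nearest
    # sample
    mid <- (onset + offset) / 2
    j <- which.min(abs(hp$t - mid))
    return(hp$mag2[j] * (offset - onset))
  }
  if (max(diff(t)) > 3 / config$sensor_rate_hz) {
    stop("applied_force: gap in inertial stream over the touch window",
         call. = FALSE)
  }
  m <- hp$mag2[sel]
  sum(diff(t) * (m[-length(m)] + m[-1]) / 2)
}

#' Screen exploration percentage
#'
#' The screen is tiled with `exploration_cell_mm` squares (partial cells at
#' the edges count as cells); the feature is the proportion of cells
#' containing at least one touch sample.
#'
#' @param traces List of touch traces.
#' @param config A [game_config()].
#' @return Proportion in [0, 1].
#' @export
exploration_percentage <- function(traces, config = game_config()) {
  cell <- config$exploration_cell_mm
  nx <- ceiling(config$screen_width_mm / cell)
  ny <- ceiling(config$screen_height_mm / cell)
  if (!length(traces)) return(0)
  x <- unlist(lapply(traces, `[[`, "x_mm"))
  y <- unlist(lapply(traces, `[[`, "y_mm"))
  cx <- pmin(floor(x / cell), nx - 1L)
  cy <- pmin(floor(y / cell), ny - 1L)
  length(unique(cx * ny + cy)) / (nx * ny)
}

#' Extract the full motor-feature vector from a session
#'
#' Computes the 19 touch- and inertial-derived feature families (37
#' session-level values, see [feature_names()]): engagement counts and the
#' popping rate, double-touch rate, screen exploration, targeting structure
#' (episodes, transitions between lanes, repeats of the same lane-and-
#' character bubble), touch kinematics (duration, path length, velocity),
#' the applied-force proxy, distance to the popped bubble's center, the
#' popping-accuracy score family, touches per target, touch frequency and
#' time on target.
#'
#' Rates and percentages are stored as proportions in [0, 1]; accuracy is in
#' percent [0, 100]. Standard deviations are sample SDs and are NA (not 0)
#' below two observations; ratio features are NA when undefined (e.g. the
#' popping rate of a session with no touches).
#'
#' @param record A [session_record()].
#' @return Named numeric vector of class `feature_vector`, in
#'   [feature_names()] order.
#' @examples
#' rec <- simulate_session(agent_profile(), age_months = 24, seed = 1)
#' extract_features(rec)[c("number_of_touches", "bubble_popping_rate")]
#' @export
extract_features <- function(record) {
  cfg <- record$config
  traces <- record$touches
  n_touch <- length(traces)
  pops <- record$pops
  if (nrow(pops) > 1L) pops <- pops[order(pops$t), , drop = FALSE]
  n_pops <- nrow(pops)

  out <- stats::setNames(rep(NA_real_, length(feature_names())),
                         feature_names())
  out["number_of_touches"] <- n_touch
  out["number_of_pops"] <- n_pops
  out["bubble_popping_rate"] <- if (n_touch > 0) n_pops / n_touch else NA_real_
  out["number_of_transitions"] <- 0
  out["number_of_targeted_bubbles"] <- 0
  out["screen_exploratory_percentage"] <- exploration_percentage(traces, cfg)

  # pop sequence structure: lane transitions and same-bubble repeats
  if (n_pops >= 2L) {
    bi <- match(pops$bubble_id, record$bubbles$bubble_id)
    lanes <- record$bubbles$lane[bi]
    chars <- record$bubbles$character_id[bi]
    prev <- seq_len(n_pops - 1L)
    out["number_of_transitions"] <- sum(lanes[prev] != lanes[prev + 1L])
    out["repeat_percentage"] <-
      sum(lanes[prev] == lanes[prev + 1L] &
            chars[prev] == chars[prev + 1L]) / (n_pops - 1L)
  }
  if (n_pops > 0) {
    out[c("distance_to_center_mean", "distance_to_center_median",
          "distance_to_center_std")] <- summary3(pops$distance_to_center_mm)
  }
  if (n_touch == 0L) {
    class(out) <- c("feature_vector", class(out))
    return(out)
  }

  # ---- flattened trace arrays (touches in onset order) -----------------
  ord <- order(vapply(traces, function(tr) tr$t[1], numeric(1)))
  traces <- traces[ord]
  ns <- vapply(traces, function(tr) length(tr$t), integer(1))
  all_t <- unlist(lapply(traces, `[[`, "t"), use.names = FALSE)
  all_x <- unlist(lapply(traces, `[[`, "x_mm"), use.names = FALSE)
  all_y <- unlist(lapply(traces, `[[`, "y_mm"), use.names = FALSE)
  tid <- rep.int(seq_len(n_touch), ns)
  last_i <- cumsum(ns)
  first_i <- last_i - ns + 1L
  t0 <- all_t[first_i]; x0 <- all_x[first_i]; y0 <- all_y[first_i]
  t1 <- all_t[last_i]; x1 <- all_x[last_i]; y1 <- all_y[last_i]

  # kinematics: grouped sums of Euclidean steps
  dur <- t1 - t0
  if (length(all_t) > 1L) {
    step <- sqrt(diff(all_x)^2 + diff(all_y)^2)
    step[last_i[-n_touch]] <- 0  # no step across touch boundaries
    len <- as.numeric(rowsum(c(step, 0), tid, reorder = FALSE))
  } else {
    len <- 0
  }
  vel <- ifelse(dur > 0, len / dur, NA_real_)
  out[c("touch_duration_mean", "touch_duration_median",
        "touch_duration_std")] <- summary3(dur)
  out[c("touch_length_mean", "touch_length_median",
        "touch_length_std")] <- summary3(len)
  out[c("touch_velocity_mean", "touch_velocity_median",
        "touch_velocity_std")] <- summary3(vel)

  # double touches: pairwise window-and-radius rule
  if (n_touch >= 2L) {
    i2 <- 2:n_touch
    dbl <- (t0[i2] - t1[i2 - 1L] <= cfg$double_touch_window_s) &
      (sqrt((x0[i2] - x0[i2 - 1L])^2 + (y0[i2] - y0[i2 - 1L])^2) <=
         cfg$double_touch_radius_mm)
    out["double_touch_rate"] <- sum(dbl) / n_touch
  } else {
    out["double_touch_rate"] <- 0
  }

  # applied force per touch
  if (length(record$accel$t) >= 2L) {
    hp <- highpass_accel(record$accel, cfg)
    force <- vapply(seq_len(n_touch), function(i) {
      integrate_force(hp, t0[i], t1[i], cfg)
    }, numeric(1))
    out[c("applied_force_mean", "applied_force_median",
          "applied_force_std")] <- summary3(force)
  }

  # ---- targeting: nearest on-screen bubble within radius at each onset --
  bb <- record$bubbles
  nb <- nrow(bb)
  assigned <- rep(NA_integer_, n_touch)
  if (nb > 0L) {
    H <- cfg$screen_height_mm
    v <- cfg$bubble_speed_mm_s
    by <- H - v * (outer(t0, bb$spawn_t, `-`))     # touch x bubble
    act <- outer(t0, bb$spawn_t, `>=`) & outer(t0, bb$end_t, `<=`) & by >= 0
    D <- sqrt((outer(x0, bb$center_x_mm, `-`))^2 + (y0 - by)^2)
    D[!act] <- Inf
    j <- max.col(-D, ties.method = "first")
    dmin <- D[cbind(seq_len(n_touch), j)]
    assigned[dmin <= cfg$targeting_radius_mm] <-
      j[dmin <= cfg$targeting_radius_mm]
  }

  # episodes: maximal runs of consecutive touches on the same bubble
  r <- rle(ifelse(is.na(assigned), -1L, assigned))
  ep_end <- cumsum(r$lengths)
  ep_start <- ep_end - r$lengths + 1L
  keep <- r$values > 0L
  ep_start <- ep_start[keep]; ep_end <- ep_end[keep]
  ep_bubble <- r$values[keep]
  n_ep <- length(ep_start)
  out["number_of_targeted_bubbles"] <- n_ep

  if (n_ep > 0L) {
    tpt <- ep_end - ep_start + 1L
    spans <- t1[ep_end] - t0[ep_start]
    freq <- ifelse(spans > 0, tpt / spans, NA_real_)
    s <- summary3(tpt)
    out["touches_per_target_mean"] <- s["mean"]
    out["touches_per_target_std"] <- s["std"]
    out[c("touch_frequency_mean", "touch_frequency_median",
          "touch_frequency_std")] <- summary3(freq)
    out[c("time_on_target_mean", "time_on_target_median",
          "time_on_target_std")] <- summary3(spans)

    # popping accuracy: all samples of targeted touches against the
    # episode's bubble (position clamped to the track interval)
    ep_of_touch <- rep(NA_integer_, n_touch)
    for (e in seq_len(n_ep)) ep_of_touch[ep_start[e]:ep_end[e]] <- e
    targ <- which(!is.na(ep_of_touch))
    sel <- tid %in% targ
    st <- all_t[sel]; sx <- all_x[sel]; sy <- all_y[sel]
    stid <- match(tid[sel], targ)              # 1..n_targeted index
    bidx <- ep_bubble[ep_of_touch[targ]][stid] # bubble row per sample
    tc <- pmin(pmax(st, bb$spawn_t[bidx]), bb$end_t[bidx])
    byc <- cfg$screen_height_mm -
      cfg$bubble_speed_mm_s * (tc - bb$spawn_t[bidx])
    d <- sqrt((sx - bb$center_x_mm[bidx])^2 + (sy - byc)^2)
    acc <- 100 * pmax(0, 1 - pmax(0, d - cfg$bubble_radius_mm) /
                        cfg$accuracy_decay_mm)
    cnt <- as.numeric(rowsum(rep(1, length(acc)), stid, reorder = FALSE))
    s1 <- as.numeric(rowsum(acc, stid, reorder = FALSE))
    acc_mean <- s1 / cnt
    dev2 <- (acc - acc_mean[stid])^2
    acc_var <- ifelse(cnt >= 2,
                      as.numeric(rowsum(dev2, stid, reorder = FALSE)) /
                        (cnt - 1),
                      NA_real_)
    acc_std <- sqrt(acc_var)
    acc_max <- vapply(split(acc, stid), max, numeric(1))
    out[c("popping_accuracy_mean", "popping_accuracy_median",
          "popping_accuracy_std")] <- summary3(acc_mean)
    out["accuracy_variation_mean"] <-
      if (any(!is.na(acc_std))) mean(acc_std, na.rm = TRUE) else NA_real_
    out["accuracy_mean_variability"] <-
      if (length(acc_mean) >= 2L) stats::sd(acc_mean) else NA_real_
    out["accuracy_max_variability"] <-
      if (length(acc_max) >= 2L) stats::sd(acc_max) else NA_real_
  }

  class(out) <- c("feature_vector", class(out))
  out
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> (", length(x), " features)\n", sep = "")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' Feature matrix for a cohort of sessions
#'
#' One row per session: metadata columns (session_id, group, age_months, iq,
#' clinical scores) followed by the 37 features in [feature_names()] order.
#' Missing values are explicit NAs.
#'
#' @param sessions List of [session_record()] objects (normally after
#'   [qc_filter()]).
#' @return Data frame with one row per session.
#' @export
features_table <- function(sessions) {
  ids <- vapply(sessions, `[[`, character(1), "session_id")
  if (anyDuplicated(ids)) {
    stop("features_table: duplicate session_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  meta <- cohort_metadata(sessions)
  fx <- t(vapply(sessions, function(s) as.numeric(extract_features(s)),
                 numeric(length(feature_names()))))
  colnames(fx) <- feature_names()
  cbind(meta, as.data.frame(fx))
}
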