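#' @importFrom stats rnorm runif rexp rgeom rlnorm rbinom rgamma
NULL

# lognormal draws parameterised by the distribution's own mean and sd
rlnorm_ms <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

# attempts per target: geometric with support >= 1 and the given mean
rgeom1 <- function(n, mean) 1L + rgeom(n, prob = 1 / mean)

# person-to-person variation: multiplicative lognormal jitter (mean 1) on
# the kinematic profile parameters, clipped back to legal domains
jitter_profile <- function(profile, cv) {
  if (is.null(cv) || cv <= 0) return(profile)
  p <- unclass(profile)
  fields <- c("aim_sd_mm", "touch_duration_mean_s", "path_length_scale_mm",
              "inter_touch_mean_s", "touches_per_target_mean")
  mult <- rlnorm_ms(length(fields), 1, cv)
  for (i in seq_along(fields)) p[[fields[i]]] <- p[[fields[i]]] * mult[i]
  p$touches_per_target_mean <- max(1, p$touches_per_target_mean)
  class(p) <- "agent_profile"
  p
}

lane_centers <- function(config) {
  w <- config$screen_width_mm / config$n_lanes
  (seq_len(config$n_lanes) - 0.5) * w
}

N_CHARACTERS <- 8L

#' Simulate bubble tracks for a session
#'
#' Generates the game's bubble dynamics for a fixed schedule of pops: each of
#' the `n_lanes` vertical lanes carries one bubble at a time, rising linearly
#' from the bottom of the screen. A popped bubble respawns in the same lane
#' with the same character; when a bubble exits the top, its successor's
#' character is drawn uniformly at random.
#'
#' Bubble ids are deterministic (`"L<lane>_<k>"` for the k-th bubble of
#' 0-based lane `<lane>`), so pop times for specific bubbles can be supplied
#' upfront via `pop_times_by_bubble`.
#'
#' @param config A [game_config()].
#' @param pop_times_by_bubble Named list/vector mapping bubble ids to pop
#'   times (s); each must fall within that bubble's on-screen interval.
#' @param seed Integer seed for the random successor characters.
#' @return Data frame of bubble tracks (see [session_record()]).
#' @export
simulate_bubbles <- function(config = game_config(),
                             pop_times_by_bubble = list(), seed = 1L) {
  withr::with_seed(seed, {
    simulate_bubbles_impl(config, pop_times_by_bubble)
  })
}

simulate_bubbles_impl <- function(config, pop_times_by_bubble = list()) {
  dur <- config$session_duration_s
  rise_time <- config$screen_height_mm / config$bubble_speed_mm_s
  centers <- lane_centers(config)
  pop_times <- unlist(pop_times_by_bubble)
  rows <- list()
  for (lane in seq_len(config$n_lanes) - 1L) {
    t <- 0
    k <- 0L
    char <- sample.int(N_CHARACTERS, 1L)
    while (t < dur) {
      id <- sprintf("L%d_%d", lane, k)
      natural_end <- t + rise_time
      pop_t <- pop_times[id]
      if (!is.null(pop_t) && length(pop_t) && !is.na(pop_t)) {
        if (pop_t <= t || pop_t > min(natural_end, dur)) {
          stop("simulate_bubbles: pop time ", pop_t, " for bubble `", id,
               "` is outside its on-screen interval (", t, ", ", natural_end,
               "]", call. = FALSE)
        }
        end_t <- pop_t
        reason <- "popped"
        next_char <- char
      } else {
        end_t <- natural_end
        reason <- "exited"
        next_char <- sample.int(N_CHARACTERS, 1L)
      }
      rows[[length(rows) + 1L]] <- list(
        bubble_id = id, lane = lane, character_id = char,
        spawn_t = t, end_t = end_t, end_reason = reason,
        center_x_mm = centers[lane + 1L])
      t <- end_t + config$spawn_gap_s
      char <- next_char
      k <- k + 1L
    }
  }
  bind_rowlists(rows, empty_bubbles())
}

# column-wise assembly of a list of same-shape row lists (faster than
# rbind-ing one-row data frames)
bind_rowlists <- function(rows, prototype) {
  if (!length(rows)) return(prototype)
  cols <- lapply(names(prototype), function(nm) {
    unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  })
  names(cols) <- names(prototype)
  structure(cols, class = "data.frame",
            row.names = c(NA_integer_, -length(cols[[1]])))
}

# Build one touch trace: samples at the sensor rate from onset to
# onset + duration; the finger drags along a smooth random walk of total
# length `path_len` (0 for single-sample traces). Positions are clipped to
# the screen.
gen_trace <- function(touch_id, onset_t, onset_x, onset_y, duration,
                      path_len, config) {
  n <- max(1L, as.integer(round(duration * config$sensor_rate_hz)) + 1L)
  if (n == 1L) {
    return(list(touch_id = touch_id, t = onset_t,
                x_mm = onset_x, y_mm = onset_y))
  }
  t <- onset_t + seq(0, duration, length.out = n)
  theta <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 2L, 0, 0.6)))
  step <- path_len / (n - 1L)
  x <- onset_x + c(0, cumsum(step * cos(theta)))
  y <- onset_y + c(0, cumsum(step * sin(theta)))
  list(touch_id = touch_id,
       t = t,
       x_mm = pmin(pmax(x, 0), config$screen_width_mm),
       y_mm = pmin(pmax(y, 0), config$screen_height_mm))
}

# Joint agent/bubble event loop. In dynamic mode (bubbles = NULL) the lane
# states evolve with the agent's pops (same-character respawn). In static
# mode the supplied track schedule is fixed and a popped track simply stops
# being targetable.
agent_loop <- function(profile, config, bubbles = NULL) {
  dyn <- is.null(bubbles)
  dur <- config$session_duration_s
  rate <- config$sensor_rate_hz
  rise_time <- config$screen_height_mm / config$bubble_speed_mm_s
  centers <- lane_centers(config)
  n_lanes <- config$n_lanes

  if (dyn) {
    # per-lane current bubble state
    lane_spawn <- rep(0, n_lanes)
    lane_char <- sample.int(N_CHARACTERS, n_lanes, replace = TRUE)
    lane_k <- rep(0L, n_lanes)
    done <- list()   # finalized tracks
    finalize <- function(lane, end_t, reason, respawn_char) {
      i <- lane - 0L
      done[[length(done) + 1L]] <<- list(
        bubble_id = sprintf("L%d_%d", i - 1L, lane_k[i]),
        lane = i - 1L, character_id = lane_char[i],
        spawn_t = lane_spawn[i], end_t = end_t, end_reason = reason,
        center_x_mm = centers[i])
      lane_spawn[i] <<- end_t + config$spawn_gap_s
      lane_char[i] <<- respawn_char
      lane_k[i] <<- lane_k[i] + 1L
    }
    advance_lanes <- function(t) {
      # finalize bubbles that exited the top before time t
      repeat {
        exits <- which(lane_spawn + rise_time < t)
        if (!length(exits)) break
        for (i in exits) {
          finalize(i, lane_spawn[i] + rise_time, "exited",
                   sample.int(N_CHARACTERS, 1L))
        }
      }
    }
    active_state <- function(t) {
      advance_lanes(t)
      on <- which(lane_spawn <= t)
      list(n = length(on), idx = on,
           bubble_id = sprintf("L%d_%d", on - 1L, lane_k[on]),
           x = centers[on],
           y = config$screen_height_mm -
             config$bubble_speed_mm_s * (t - lane_spawn[on]))
    }
  } else {
    popped_ids <- character()
    active_state <- function(t) {
      y <- config$screen_height_mm -
        config$bubble_speed_mm_s * (t - bubbles$spawn_t)
      on <- which(bubbles$spawn_t <= t & bubbles$end_t >= t & y >= 0 &
                    !(bubbles$bubble_id %in% popped_ids))
      list(n = length(on), idx = on, bubble_id = bubbles$bubble_id[on],
           x = bubbles$center_x_mm[on], y = y[on])
    }
  }

  traces <- list()
  pops <- list()
  touch_i <- 0L
  last_x <- config$screen_width_mm / 2
  last_y <- config$screen_height_mm / 2
  last_pop_lane <- NA_integer_
  t_cursor <- 0

  emit_touch <- function(onset_t, aim_x, aim_y) {
    # returns list(offset_t, x, y, popped_lane or NA)
    touch_i <<- touch_i + 1L
    id <- sprintf("T%03d", touch_i)
    duration <- rlnorm_ms(1, profile$touch_duration_mean_s,
                          profile$touch_duration_sd_s)
    duration <- min(duration, dur - onset_t)
    path_len <- if (profile$path_length_scale_mm > 0) {
      rgamma(1, shape = 4, rate = 4 / profile$path_length_scale_mm)
    } else 0
    tr <- gen_trace(id, onset_t, aim_x, aim_y, duration, path_len, config)
    traces[[touch_i]] <<- tr
    # pop check against the nearest active bubble at onset
    st <- active_state(onset_t)
    popped_lane <- NA_integer_
    if (st$n) {
      d <- sqrt((aim_x - st$x)^2 + (aim_y - st$y)^2)
      j <- which.min(d)
      hit <- if (config$pop_boundary_inclusive) {
        d[j] <= config$pop_radius_mm
      } else {
        d[j] < config$pop_radius_mm
      }
      if (hit) {
        pops[[length(pops) + 1L]] <<- list(
          t = onset_t, bubble_id = st$bubble_id[j], touch_id = id,
          distance_to_center_mm = d[j])
        if (dyn) {
          finalize(st$idx[j], onset_t, "popped", lane_char[st$idx[j]])
          popped_lane <- st$idx[j]
        } else {
          popped_ids <<- c(popped_ids, st$bubble_id[j])
          popped_lane <- bubbles$lane[match(st$bubble_id[j],
                                            bubbles$bubble_id)] + 1L
        }
      }
    }
    k <- length(tr$t)
    last_x <<- tr$x_mm[k]
    last_y <<- tr$y_mm[k]
    list(offset_t = tr$t[k], popped_lane = popped_lane)
  }

  margin <- 1.5 / rate
  t_cursor <- rexp(1, 1 / profile$inter_touch_mean_s)
  while (t_cursor < dur - margin) {
    st <- active_state(t_cursor)
    if (!st$n) {
      # all lanes in a spawn gap; wait for the next spawn
      nxt <- if (dyn) min(lane_spawn[lane_spawn < dur]) else {
        cand <- bubbles$spawn_t[bubbles$spawn_t > t_cursor]
        if (!length(cand)) break
        min(cand)
      }
      if (!is.finite(nxt) || nxt >= dur - margin) break
      t_cursor <- nxt + 1e-6
      next
    }
    # pick a target: the just-popped bubble's respawn with prob repeat_prob,
    # else the bubble nearest the last touch position
    target_idx <- NULL
    if (!is.na(last_pop_lane) && runif(1) < profile$repeat_prob) {
      j <- if (dyn) match(last_pop_lane, st$idx) else {
        lanes <- bubbles$lane[match(st$bubble_id, bubbles$bubble_id)] + 1L
        match(last_pop_lane, lanes)
      }
      if (!is.na(j)) target_idx <- j
    }
    if (is.null(target_idx)) {
      d <- sqrt((last_x - st$x)^2 + (last_y - st$y)^2)
      target_idx <- which.min(d)
    }
    target_id <- st$bubble_id[target_idx]
    attempts <- rgeom1(1, profile$touches_per_target_mean)

    for (a in seq_len(attempts)) {
      if (t_cursor >= dur - margin) break
      st_now <- active_state(t_cursor)
      j <- match(target_id, st_now$bubble_id)
      if (is.na(j)) break  # target popped/exited meanwhile
      aim_x <- min(max(st_now$x[j] + rnorm(1, 0, profile$aim_sd_mm), 0),
                   config$screen_width_mm)
      aim_y <- min(max(st_now$y[j] + rnorm(1, 0, profile$aim_sd_mm), 0),
                   config$screen_height_mm)
      res <- emit_touch(t_cursor, aim_x, aim_y)
      t_cursor <- res$offset_t
      popped <- !is.na(res$popped_lane)
      if (popped) last_pop_lane <- res$popped_lane

      # occasional rapid second touch at almost the same spot
      if (runif(1) < profile$double_touch_prob) {
        gap2 <- runif(1, 0.05, 0.25)
        if (t_cursor + gap2 < dur - margin) {
          jit <- rnorm(2, 0, 2)
          res2 <- emit_touch(t_cursor + gap2,
                             min(max(last_x + jit[1], 0), config$screen_width_mm),
                             min(max(last_y + jit[2], 0), config$screen_height_mm))
          t_cursor <- res2$offset_t
          if (!is.na(res2$popped_lane)) {
            popped <- TRUE
            last_pop_lane <- res2$popped_lane
          }
        }
      }
      t_cursor <- t_cursor + rexp(1, 1 / profile$inter_touch_mean_s)
      if (popped) break
    }
  }

  out_bubbles <- if (dyn) {
    # flush the pending track in every lane (keeps the same-character
    # respawn of a late pop materialized in the schedule)
    for (i in seq_len(n_lanes)) {
      finalize(i, lane_spawn[i] + rise_time, "exited", lane_char[i])
    }
    bind_rowlists(done, empty_bubbles())
  } else {
    bubbles
  }
  pops_df <- bind_rowlists(pops, empty_pops())
  list(traces = traces, pops = pops_df, bubbles = out_bubbles)
}

#' Simulate agent touches against a fixed bubble schedule
#'
#' Runs the parametric child-agent model over `[0, session_duration_s]`: the
#' agent targets the respawn of the bubble it just popped with probability
#' `repeat_prob`, otherwise the nearest on-screen bubble; aims at the
#' target's instantaneous center with isotropic Gaussian error; produces a
#' lognormal-duration touch trace whose finger path is a random walk; and
#' re-attempts each target a geometric number of times. A touch pops the
#' nearest on-screen bubble whenever its onset lands within the pop radius.
#' A popped track stops being targetable; the schedule itself is not
#' modified (use [simulate_session()] for the co-simulated game).
#'
#' @param profile An [agent_profile()].
#' @param bubbles Bubble-track data frame, e.g. from [simulate_bubbles()].
#' @param config A [game_config()].
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return List with `traces` (list of touch traces) and `pops` (data frame).
#' @export
simulate_agent_touches <- function(profile, bubbles, config = game_config(),
                                   seed = 1L) {
  validate_agent_profile(profile)
  withr::with_seed(seed, {
    res <- agent_loop(profile, config, bubbles = bubbles)
  })
  list(traces = res$traces, pops = res$pops)
}

#' Synthesize the device inertial stream
#'
#' Models the tablet accelerometer during a session: a constant gravity
#' baseline plus white noise on each axis, and a Gaussian-shaped impulse on
#' the axis normal to the screen centered at each touch onset (peak
#' `force_scale` m/s^2, width `impulse_width_s`, i.e. the Gaussian's
#' +/- 2 SD extent).
#'
#' @param traces List of touch traces.
#' @param profile An [agent_profile()] (supplies `force_scale`).
#' @param config A [game_config()].
#' @param seed Integer seed for the noise.
#' @param noise_sd White-noise SD per axis (m/s^2).
#' @param gravity Length-3 gravity baseline (m/s^2).
#' @param impulse_width_s Impulse width (s); the Gaussian SD is a quarter of
#'   this.
#' @return List with numeric vectors `t`, `ax`, `ay`, `az` sampled at
#'   `sensor_rate_hz` over the session (e.g. 1200 samples for 20 s at 60 Hz).
#' @export
synthesize_accel <- function(traces, profile, config = game_config(),
                             seed = 1L, noise_sd = 0.05,
                             gravity = c(0, 0, 9.81),
                             impulse_width_s = 0.08) {
  n <- as.integer(round(config$session_duration_s * config$sensor_rate_hz))
  t <- (seq_len(n) - 1L) / config$sensor_rate_hz
  withr::with_seed(seed, {
    ax <- gravity[1] + rnorm(n, 0, noise_sd)
    ay <- gravity[2] + rnorm(n, 0, noise_sd)
    az <- gravity[3] + rnorm(n, 0, noise_sd)
  })
  if (profile$force_scale > 0) {
    sigma <- impulse_width_s / 4
    for (tr in traces) {
      t0 <- tr$t[1]
      win <- abs(t - t0) < 5 * sigma
      az[win] <- az[win] +
        profile$force_scale * exp(-(t[win] - t0)^2 / (2 * sigma^2))
    }
  }
  list(t = t, ax = ax, ay = ay, az = az)
}

#' Simulate one complete game session
#'
#' Co-simulates bubble dynamics and agent behaviour (so that pops trigger
#' same-character respawns in the same lane, and exits draw a random
#' successor character), then synthesizes the inertial stream, and returns a
#' fully valid [session_record()].
#'
#' @param profile An [agent_profile()].
#' @param age_months Participant age recorded in the session metadata.
#' @param config A [game_config()].
#' @param seed Integer seed; the record is a pure function of
#'   (profile, age, config, seed).
#' @param session_id,group Metadata carried into the record.
#' @param iq,clinical_scores Optional metadata.
#' @param accel_noise_sd White-noise SD of the inertial stream (m/s^2).
#' @return A validated [session_record()].
#' @examples
#' rec <- simulate_session(agent_profile(), age_months = 24, seed = 1)
#' rec
#' @export
simulate_session <- function(profile, age_months, config = game_config(),
                             seed = 1L, session_id = sprintf("S%06d", seed),
                             group = "NT", iq = NULL, clinical_scores = NULL,
                             accel_noise_sd = 0.05) {
  validate_agent_profile(profile)
  withr::with_seed(seed, {
    res <- agent_loop(profile, config, bubbles = NULL)
  })
  accel_seed <- as.integer((as.numeric(seed) + 104729) %%
                             .Machine$integer.max)
  accel <- synthesize_accel(res$traces, profile, config,
                            seed = accel_seed, noise_sd = accel_noise_sd)
  session_record(
    session_id = session_id, group = group, age_months = age_months,
    config = config, touches = res$traces, accel = accel,
    bubbles = res$bubbles, pops = res$pops,
    iq = iq, clinical_scores = clinical_scores)
}

#' Simulate a full synthetic cohort
#'
#' Draws one session per participant under a [cohort_spec()]: ages uniform
#' over the age-model range, group profiles adjusted linearly for age
#' (clipped to their legal domains), IQ drawn from the per-group model, and
#' clinical scores generated from the linear-Gaussian latent-skill model
#' (`skill` = minus the standardized age-adjusted aim error, so that more
#' accurate children score higher on positively loaded scales).
#'
#' @param spec A [cohort_spec()]; `spec$seed` makes the cohort reproducible.
#' @return List with `sessions` (list of [session_record()]) and `metadata`
#'   (data frame: session_id, group, age_months, iq, clinical scores).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cfg <- spec$config
  groups <- names(spec$groups)
  n_total <- sum(vapply(spec$groups, function(g) as.integer(g$n), integer(1)))

  withr::with_seed(spec$seed, {
    group_vec <- rep(groups, vapply(spec$groups, function(g) as.integer(g$n),
                                    integer(1)))
    ages <- if (!is.null(spec$age_mod)) {
      runif(n_total, spec$age_mod$age_range_months[1],
            spec$age_mod$age_range_months[2])
    } else {
      rep(NA_real_, n_total)
    }
    session_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    iq <- rep(NA_real_, n_total)
    if (!is.null(spec$iq_model)) {
      for (g in groups) {
        gi <- which(group_vec == g)
        m <- spec$iq_model[[g]]
        if (!is.null(m)) iq[gi] <- rnorm(length(gi), m[1], m[2])
      }
    }
    profiles <- lapply(seq_len(n_total), function(i) {
      p <- adjust_profile_for_age(spec$groups[[group_vec[i]]]$profile,
                                  spec$age_mod,
                                  if (is.na(ages[i])) {
                                    if (is.null(spec$age_mod)) 0 else
                                      mean(spec$age_mod$age_range_months)
                                  } else ages[i])
      jitter_profile(p, spec$profile_jitter_cv)
    })
    aims <- vapply(profiles, `[[`, numeric(1), "aim_sd_mm")
    skill <- if (stats::sd(aims) > 0) {
      -(aims - mean(aims)) / stats::sd(aims)
    } else {
      rep(0, n_total)
    }
    scores <- NULL
    if (!is.null(spec$clinical_score_model)) {
      scores <- lapply(names(spec$clinical_score_model), function(s) {
        m <- spec$clinical_score_model[[s]]
        m[1] * skill + rnorm(n_total, 0, m[2])
      })
      names(scores) <- names(spec$clinical_score_model)
    }
  })

  sessions <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cs <- if (!is.null(scores)) {
      stats::setNames(lapply(scores, `[[`, i), names(scores))
    } else NULL
    sessions[[i]] <- simulate_session(
      profiles[[i]],
      age_months = if (is.na(ages[i])) 0 else ages[i],
      config = cfg, seed = session_seeds[i],
      session_id = sprintf("P%04d", i), group = group_vec[i],
      iq = if (is.na(iq[i])) NULL else iq[i],
      clinical_scores = cs)
  }
  list(sessions = sessions, metadata = cohort_metadata(sessions))
}
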