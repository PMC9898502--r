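# Hand-built traces, bubbles and records used across the test files.

make_trace <- function(id, t, x, y) {
  list(touch_id = id, t = as.numeric(t), x_mm = as.numeric(x),
       y_mm = as.numeric(y))
}

# a single stationary-ish bubble: spawns at t=0 in lane 0 and rises for the
# whole window
one_bubble <- function(config, lane = 0L, character_id = 1L,
                       spawn_t = 0, end_t = config$session_duration_s,
                       id = "B1") {
  centers <- (seq_len(config$n_lanes) - 0.5) *
    config$screen_width_mm / config$n_lanes
  data.frame(bubble_id = id, lane = lane, character_id = character_id,
             spawn_t = spawn_t, end_t = end_t, end_reason = "exited",
             center_x_mm = centers[lane + 1L], stringsAsFactors = FALSE)
}

# y-coordinate of that bubble at time t
bubble_y <- function(bubble, t, config) {
  config$screen_height_mm - config$bubble_speed_mm_s * (t - bubble$spawn_t)
}

# minimal valid record: `touches` list and matching pops recomputed by
# detect_pops so invariants hold by construction
make_record <- function(touches = list(), bubbles = NULL,
                        config = game_config(), session_id = "S1",
                        group = "NT", age_months = 24, ...) {
  if (is.null(bubbles)) {
    bubbles <- one_bubble(config)
  }
  pops <- detect_pops(touches, bubbles, config)
  session_record(session_id = session_id, group = group,
                 age_months = age_months, config = config,
                 touches = touches, bubbles = bubbles, pops = pops, ...)
}

# cheap two-group cohort simulation without the cohort_spec plumbing
simulate_two_groups <- function(n_per_group, profile_a, profile_b, seed,
                                config = game_config(), age_range = c(18, 36)) {
  sessions <- vector("list", 2L * n_per_group)
  set.seed(seed)
  ages <- runif(2L * n_per_group, age_range[1], age_range[2])
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_group)
  for (i in seq_len(n_per_group)) {
    sessions[[i]] <- simulate_session(
      profile_a, ages[i], config, seed = seeds[i],
      session_id = sprintf("A%03d", i), group = "A")
    j <- n_per_group + i
    sessions[[j]] <- simulate_session(
      profile_b, ages[j], config, seed = seeds[j],
      session_id = sprintf("B%03d", i), group = "B")
  }
  sessions
}
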