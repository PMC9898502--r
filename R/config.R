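#' Game configuration
#'
#' Describes the bubble-popping game as administered: screen geometry, bubble
#' kinematics, sensor rate, and the thresholds used by pop detection, feature
#' extraction and quality control. Defaults mirror the published protocol:
#' a touch pops a bubble when its onset lands within 18.5 mm of the bubble
#' center, a session is the 20-second analysis window, the device samples at
#' 60 Hz, the play field has 5 vertical lanes, and sessions with fewer than 3
#' touches are excluded as insufficiently engaged.
#'
#' @param screen_width_mm,screen_height_mm Physical screen size in mm
#'   (portrait 10.2-inch tablet class by default).
#' @param n_lanes Number of vertical bubble lanes.
#' @param pop_radius_mm Maximum touch-onset distance from a bubble center that
#'   still registers a pop (mm).
#' @param bubble_radius_mm Visual bubble disc radius used by the popping
#'   accuracy score (mm).
#' @param bubble_speed_mm_s Upward bubble speed (mm/s).
#' @param spawn_gap_s Delay between a bubble leaving the lane (pop or exit)
#'   and the next spawn in that lane (s).
#' @param session_duration_s Length of the analysed recording window (s).
#' @param sensor_rate_hz Touch/inertial sampling rate (Hz).
#' @param targeting_radius_mm Maximum onset distance at which a touch counts
#'   as targeting a bubble (mm).
#' @param accuracy_decay_mm Distance beyond the bubble edge over which the
#'   popping-accuracy score decays linearly from 100% to 0% (mm).
#' @param exploration_cell_mm Side of the square grid cells used by the
#'   screen-exploration feature (mm).
#' @param double_touch_window_s,double_touch_radius_mm Maximum offset-to-onset
#'   gap (s) and onset separation (mm) for two touches to count as a double
#'   touch.
#' @param min_touches_qc Minimum number of touches for a session to pass
#'   quality control (sessions with fewer are excluded).
#' @param pop_boundary_inclusive Whether a touch exactly at `pop_radius_mm`
#'   pops (default TRUE: distance <= radius).
#'
#' @return An object of class `game_config` (a validated named list).
#' @examples
#' cfg <- game_config()
#' cfg$pop_radius_mm
#' @export
game_config <- function(screen_width_mm = 160,
                        screen_height_mm = 220,
                        n_lanes = 5L,
                        pop_radius_mm = 18.5,
                        bubble_radius_mm = 18.5,
                        bubble_speed_mm_s = 20,
                        spawn_gap_s = 0.5,
                        session_duration_s = 20,
                        sensor_rate_hz = 60,
                        targeting_radius_mm = 27.75,
                        accuracy_decay_mm = 18.5,
                        exploration_cell_mm = 10,
                        double_touch_window_s = 0.3,
                        double_touch_radius_mm = 10,
                        min_touches_qc = 3L,
                        pop_boundary_inclusive = TRUE) {
  cfg <- list(
    screen_width_mm = as.numeric(screen_width_mm),
    screen_height_mm = as.numeric(screen_height_mm),
    n_lanes = as.integer(n_lanes),
    pop_radius_mm = as.numeric(pop_radius_mm),
    bubble_radius_mm = as.numeric(bubble_radius_mm),
    bubble_speed_mm_s = as.numeric(bubble_speed_mm_s),
    spawn_gap_s = as.numeric(spawn_gap_s),
    session_duration_s = as.numeric(session_duration_s),
    sensor_rate_hz = as.numeric(sensor_rate_hz),
    targeting_radius_mm = as.numeric(targeting_radius_mm),
    accuracy_decay_mm = as.numeric(accuracy_decay_mm),
    exploration_cell_mm = as.numeric(exploration_cell_mm),
    double_touch_window_s = as.numeric(double_touch_window_s),
    double_touch_radius_mm = as.numeric(double_touch_radius_mm),
    min_touches_qc = as.integer(min_touches_qc),
    pop_boundary_inclusive = isTRUE(pop_boundary_inclusive)
  )
  class(cfg) <- "game_config"
  validate_game_config(cfg)
  cfg
}

validate_game_config <- function(cfg) {
  pos <- c("screen_width_mm", "screen_height_mm", "pop_radius_mm",
           "bubble_radius_mm", "bubble_speed_mm_s", "spawn_gap_s",
           "session_duration_s", "sensor_rate_hz", "targeting_radius_mm",
           "accuracy_decay_mm", "exploration_cell_mm",
           "double_touch_window_s", "double_touch_radius_mm")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("game_config: `", f, "` must be a single positive number", call. = FALSE)
    }
  }
  if (cfg$n_lanes < 1L) stop("game_config: `n_lanes` must be >= 1", call. = FALSE)
  if (cfg$min_touches_qc < 1L) stop("game_config: `min_touches_qc` must be >= 1", call. = FALSE)
  if (cfg$pop_radius_mm > cfg$targeting_radius_mm) {
    stop("game_config: `pop_radius_mm` must not exceed `targeting_radius_mm`", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.game_config <- function(x, ...) {
  cat("Bubble-popping game configuration\n")
  cat(sprintf("  screen: %g x %g mm, %d lanes\n",
              x$screen_width_mm, x$screen_height_mm, x$n_lanes))
  cat(sprintf("  pop radius: %g mm (boundary %s), bubble speed: %g mm/s\n",
              x$pop_radius_mm,
              if (x$pop_boundary_inclusive) "inclusive" else "exclusive",
              x$bubble_speed_mm_s))
  cat(sprintf("  window: %g s at %g Hz, QC minimum touches: %d\n",
              x$session_duration_s, x$sensor_rate_hz, x$min_touches_qc))
  invisible(x)
}

#' Agent behaviour profile
#'
#' Parametric description of a child agent playing the game. The parameters
#' encode the behavioural contrasts observed between diagnostic groups as
#' generative quantities: spatial aim error, touch duration and drag length,
#' pacing, perseveration (re-targeting the just-popped bubble), and the
#' amplitude of the device-acceleration impulse caused by a touch.
#'
#' @param aim_sd_mm Isotropic SD of the touch-onset aim error around the
#'   targeted bubble center (mm).
#' @param touch_duration_mean_s,touch_duration_sd_s Mean and SD of the
#'   lognormal touch-duration distribution (s).
#' @param path_length_scale_mm Mean total path length of the finger drag
#'   during a touch (mm).
#' @param inter_touch_mean_s Mean gap between one touch's offset and the next
#'   touch's onset (s), exponentially distributed.
#' @param touches_per_target_mean Mean number of attempts per targeted bubble
#'   (geometric, support >= 1).
#' @param repeat_prob Probability of re-targeting the respawn of the bubble
#'   just popped rather than the nearest bubble.
#' @param force_scale Peak amplitude of the touch-impact acceleration impulse
#'   (m/s^2).
#' @param double_touch_prob Probability that a touch is immediately followed
#'   by a rapid second touch at nearly the same location.
#'
#' @return An object of class `agent_profile`.
#' @seealso [default_profiles()] for the built-in group profiles.
#' @export
agent_profile <- function(aim_sd_mm = 8,
                          touch_duration_mean_s = 0.20,
                          touch_duration_sd_s = 0.10,
                          path_length_scale_mm = 6,
                          inter_touch_mean_s = 0.7,
                          touches_per_target_mean = 1.5,
                          repeat_prob = 0.4,
                          force_scale = 0.6,
                          double_touch_prob = 0.10) {
  p <- list(
    aim_sd_mm = as.numeric(aim_sd_mm),
    touch_duration_mean_s = as.numeric(touch_duration_mean_s),
    touch_duration_sd_s = as.numeric(touch_duration_sd_s),
    path_length_scale_mm = as.numeric(path_length_scale_mm),
    inter_touch_mean_s = as.numeric(inter_touch_mean_s),
    touches_per_target_mean = as.numeric(touches_per_target_mean),
    repeat_prob = as.numeric(repeat_prob),
    force_scale = as.numeric(force_scale),
    double_touch_prob = as.numeric(double_touch_prob)
  )
  class(p) <- "agent_profile"
  validate_agent_profile(p)
  p
}

validate_agent_profile <- function(p) {
  nonneg <- c("aim_sd_mm", "touch_duration_sd_s", "path_length_scale_mm",
              "force_scale")
  for (f in nonneg) {
    if (!is.finite(p[[f]]) || p[[f]] < 0) {
      stop("agent_profile: `", f, "` must be >= 0", call. = FALSE)
    }
  }
  pos <- c("touch_duration_mean_s", "inter_touch_mean_s",
           "touches_per_target_mean")
  for (f in pos) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      stop("agent_profile: `", f, "` must be > 0", call. = FALSE)
    }
  }
  if (p$touches_per_target_mean < 1) {
    stop("agent_profile: `touches_per_target_mean` must be >= 1", call. = FALSE)
  }
  for (f in c("repeat_prob", "double_touch_prob")) {
    if (!is.finite(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      stop("agent_profile: `", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(p)
}

#' Built-in group behaviour profiles
#'
#' Two reference profiles used throughout the package's examples and tests: a
#' neurotypical-like profile (`nt`) and a case profile (`case`) with 50%
#' larger aim error, 50% longer touch durations and 50% longer drag paths,
#' together with mildly elevated perseveration and double touching. The case
#' profile is constructed so that, in expectation, it pops bubbles at a lower
#' rate, lands farther from bubble centers, and produces longer and more
#' variable touches -- the direction of the group contrasts the game is
#' designed to measure.
#'
#' @return Named list with elements `nt` and `case`, each an [agent_profile()].
#' @export
default_profiles <- function() {
  nt <- agent_profile()
  case <- agent_profile(
    aim_sd_mm = nt$aim_sd_mm * 1.5,
    touch_duration_mean_s = nt$touch_duration_mean_s * 1.5,
    touch_duration_sd_s = nt$touch_duration_sd_s * 1.5,
    path_length_scale_mm = nt$path_length_scale_mm * 1.5,
    inter_touch_mean_s = 0.8,
    touches_per_target_mean = 2.0,
    repeat_prob = 0.5,
    force_scale = nt$force_scale,
    double_touch_prob = 0.15
  )
  list(nt = nt, case = case)
}

#' Age model for agent parameters
#'
#' Linear per-month adjustments of agent-profile parameters, centered on the
#' midpoint of the cohort age range: a participant of age `a` months plays
#' with profile parameter `theta + slope * (a - mid)`, clipped to the
#' parameter's legal domain. The default slopes make older children touch
#' more often, more accurately, and with shorter, shorter-lasting touches,
#' matching the developmental trends the game exhibits.
#'
#' @param slopes Named numeric vector of per-month slopes; names must be
#'   [agent_profile()] fields.
#' @param age_range_months Length-2 numeric, cohort age range (months).
#' @return An object of class `age_model`.
#' @export
age_model <- function(slopes = c(aim_sd_mm = -0.15,
                                 touch_duration_mean_s = -0.004,
                                 path_length_scale_mm = -0.10,
                                 inter_touch_mean_s = -0.010),
                      age_range_months = c(18, 36)) {
  stopifnot(length(age_range_months) == 2L,
            age_range_months[1] < age_range_months[2])
  slopes <- unlist(slopes)
  bad <- setdiff(names(slopes), names(agent_profile()))
  if (length(bad)) {
    stop("age_model: unknown profile fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- list(slopes = slopes, age_range_months = as.numeric(age_range_months))
  class(m) <- "age_model"
  m
}

# Apply age adjustment to a profile, clipping into the legal domain.
adjust_profile_for_age <- function(profile, age_mod, age_months) {
  if (is.null(age_mod)) return(profile)
  mid <- mean(age_mod$age_range_months)
  p <- unclass(profile)
  for (f in names(age_mod$slopes)) {
    p[[f]] <- p[[f]] + age_mod$slopes[[f]] * (age_months - mid)
  }
  # clip back into legal domains
  eps <- 1e-6
  p$aim_sd_mm <- max(0, p$aim_sd_mm)
  p$touch_duration_sd_s <- max(0, p$touch_duration_sd_s)
  p$path_length_scale_mm <- max(0, p$path_length_scale_mm)
  p$force_scale <- max(0, p$force_scale)
  p$touch_duration_mean_s <- max(eps, p$touch_duration_mean_s)
  p$inter_touch_mean_s <- max(eps, p$inter_touch_mean_s)
  p$touches_per_target_mean <- max(1, p$touches_per_target_mean)
  p$repeat_prob <- min(1, max(0, p$repeat_prob))
  p$double_touch_prob <- min(1, max(0, p$double_touch_prob))
  class(p) <- "agent_profile"
  p
}

#' Cohort specification
#'
#' Generative description of a synthetic study cohort: one behaviour profile
#' and sample size per group, an age model shared across groups, an optional
#' per-group IQ model, and a linear-Gaussian clinical-score model in which
#' each score loads on a latent motor-skill variable (defined as minus the
#' standardized age-adjusted aim error, so larger skill means more accurate
#' popping).
#'
#' @param groups Named list: group label -> list(profile = [agent_profile()],
#'   n = participants).
#' @param age_mod An [age_model()] or NULL for no age structure.
#' @param iq_model Optional named list: group label -> c(mean, sd) of IQ.
#' @param clinical_score_model Optional named list: score name ->
#'   c(loading, noise_sd); the score is `loading * skill + N(0, noise_sd)`.
#' @param profile_jitter_cv Coefficient of variation of the multiplicative
#'   lognormal person-to-person jitter applied to the kinematic profile
#'   parameters (aim error, touch duration, path length, pacing, attempts
#'   per target). Individual variation beyond age is what lets clinical
#'   scores correlate with motor features after age adjustment; 0 makes all
#'   same-age children within a group identical.
#' @param seed Integer seed making the cohort fully reproducible.
#' @return An object of class `cohort_spec`.
#' @examples
#' prof <- default_profiles()
#' spec <- cohort_spec(groups = list(NT = list(profile = prof$nt, n = 5),
#'                                   autistic = list(profile = prof$case, n = 5)),
#'                     seed = 1)
#' @export
cohort_spec <- function(groups,
                        age_mod = age_model(),
                        iq_model = NULL,
                        clinical_score_model = NULL,
                        config = game_config(),
                        profile_jitter_cv = 0.15,
                        seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  for (g in names(groups)) {
    if (!inherits(groups[[g]]$profile, "agent_profile")) {
      stop("cohort_spec: groups$", g, "$profile must be an agent_profile",
           call. = FALSE)
    }
    if (is.null(groups[[g]]$n) || groups[[g]]$n < 1) {
      stop("cohort_spec: groups$", g, "$n must be >= 1", call. = FALSE)
    }
  }
  if (!is.null(clinical_score_model)) {
    for (s in names(clinical_score_model)) {
      v <- clinical_score_model[[s]]
      if (length(v) != 2L || v[2] < 0) {
        stop("cohort_spec: clinical score `", s,
             "` needs c(loading, noise_sd >= 0)", call. = FALSE)
      }
    }
  }
  stopifnot(profile_jitter_cv >= 0)
  sp <- list(groups = groups, age_mod = age_mod, iq_model = iq_model,
             clinical_score_model = clinical_score_model,
             config = config, profile_jitter_cv = profile_jitter_cv,
             seed = as.integer(seed))
  class(sp) <- "cohort_spec"
  sp
}

#' @param config [game_config()] used for every session in the cohort.
#' @rdname cohort_spec
#' @export
print.cohort_spec <- function(x, ...) {
  ns <- vapply(x$groups, function(g) as.integer(g$n), integer(1))
  cat("Synthetic cohort specification\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(ns), ns), collapse = ", "), "\n")
  if (!is.null(x$age_mod)) {
    cat(sprintf("  ages: uniform over [%g, %g] months\n",
                x$age_mod$age_range_months[1], x$age_mod$age_range_months[2]))
  }
  if (!is.null(x$clinical_score_model)) {
    cat("  clinical scores:", paste(names(x$clinical_score_model), collapse = ", "), "\n")
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Read a cohort specification from a YAML file
#'
#' The YAML mirrors the [cohort_spec()] arguments: a `groups` map whose
#' entries have `n_participants` and profile fields, optional `age_model`
#' (`slopes`, `age_range_months`), `iq_model`, `clinical_score_model`
#' (score -> [loading, noise_sd]), optional `game` overrides, and `seed`.
#' (The key is `n_participants` rather than `n` because a bare `n` is a
#' YAML 1.1 boolean.)
#'
#' @param path Path to a YAML file.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$groups)) stop("cohort YAML: missing `groups`", call. = FALSE)
  groups <- lapply(y$groups, function(g) {
    n <- g$n_participants
    if (is.null(n)) stop("cohort YAML: each group needs `n_participants`",
                         call. = FALSE)
    g$n_participants <- NULL
    list(profile = do.call(agent_profile, g), n = n)
  })
  am <- if (!is.null(y$age_model)) {
    age_model(slopes = unlist(y$age_model$slopes),
              age_range_months = unlist(y$age_model$age_range_months))
  } else {
    age_model()
  }
  csm <- if (!is.null(y$clinical_score_model)) {
    lapply(y$clinical_score_model, unlist)
  } else NULL
  iqm <- if (!is.null(y$iq_model)) lapply(y$iq_model, unlist) else NULL
  cfg <- if (!is.null(y$game)) do.call(game_config, y$game) else game_config()
  cohort_spec(groups = groups, age_mod = am, iq_model = iqm,
              clinical_score_model = csm, config = cfg,
              seed = if (is.null(y$seed)) 1L else y$seed)
}
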