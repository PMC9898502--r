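#' Construct a game session record
#'
#' The unit of analysis: one participant's recorded window of the
#' bubble-popping game. Touch traces are finger-down coordinate streams, the
#' inertial stream is the device's 3-axis accelerometer, bubble tracks give
#' each bubble's lane, character and linear upward trajectory, and pop events
#' link a touch onset to the bubble it popped.
#'
#' Coordinates are millimetres with the origin at the top-left of the screen,
#' x rightward and y downward; a rising bubble therefore has decreasing y.
#'
#' @param session_id Unique identifier.
#' @param group Group label (e.g. "NT", "autistic", "autistic_adhd").
#' @param age_months Participant age in months.
#' @param config A [game_config()].
#' @param touches List of touch traces, each a list with elements `touch_id`
#'   and equal-length numeric vectors `t`, `x_mm`, `y_mm` (strictly
#'   increasing `t`).
#' @param accel Inertial stream: list with numeric vectors `t`, `ax`, `ay`,
#'   `az` (m/s^2).
#' @param bubbles Data frame of bubble tracks with columns `bubble_id`,
#'   `lane` (0-based), `character_id`, `spawn_t`, `end_t`, `end_reason`
#'   ("popped" or "exited"), `center_x_mm`.
#' @param pops Data frame of pop events with columns `t`, `bubble_id`,
#'   `touch_id`, `distance_to_center_mm`.
#' @param iq Optional IQ score.
#' @param clinical_scores Optional named list of clinical scores.
#' @param meta Named list of extra fields carried through serialisation.
#' @param validate Run [validate_session()] and fail on violations?
#'
#' @return An object of class `session_record`.
#' @export
session_record <- function(session_id, group, age_months,
                           config = game_config(),
                           touches = list(),
                           accel = list(t = numeric(), ax = numeric(),
                                        ay = numeric(), az = numeric()),
                           bubbles = empty_bubbles(),
                           pops = empty_pops(),
                           iq = NULL, clinical_scores = NULL,
                           meta = list(), validate = TRUE) {
  rec <- structure(list(
    session_id = as.character(session_id),
    group = as.character(group),
    age_months = as.numeric(age_months),
    iq = if (is.null(iq)) NULL else as.numeric(iq),
    clinical_scores = clinical_scores,
    config = config,
    touches = touches,
    accel = accel,
    bubbles = bubbles,
    pops = pops,
    meta = meta
  ), class = "session_record")
  if (validate) {
    v <- validate_session(rec)
    if (length(v)) {
      stop("invalid session record:\n  ", paste(v, collapse = "\n  "),
           call. = FALSE)
    }
  }
  rec
}

empty_bubbles <- function() {
  data.frame(bubble_id = character(), lane = integer(),
             character_id = integer(), spawn_t = numeric(),
             end_t = numeric(), end_reason = character(),
             center_x_mm = numeric(), stringsAsFactors = FALSE)
}

empty_pops <- function() {
  data.frame(t = numeric(), bubble_id = character(), touch_id = character(),
             distance_to_center_mm = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record %s> group=%s age=%g months\n",
              x$session_id, x$group, x$age_months))
  cat(sprintf("  %d touches, %d pops, %d bubble tracks, %d inertial samples\n",
              length(x$touches), nrow(x$pops), nrow(x$bubbles),
              length(x$accel$t)))
  invisible(x)
}

# y-coordinate of a bubble's center at time t (linear upward motion;
# spawns at the bottom edge, y decreasing while it rises). Times are clamped
# to the track's on-screen interval so a popped bubble's position is frozen
# at the pop location.
bubble_y_at <- function(spawn_t, end_t, t, config) {
  tt <- pmin(pmax(t, spawn_t), end_t)
  config$screen_height_mm - config$bubble_speed_mm_s * (tt - spawn_t)
}

# Bubbles on screen (active) at time t: spawned, not ended, not yet above top.
bubble_active_at <- function(bubbles, t, config) {
  if (nrow(bubbles) == 0L) return(logical(0))
  y <- config$screen_height_mm - config$bubble_speed_mm_s * (t - bubbles$spawn_t)
  t >= bubbles$spawn_t & t <= bubbles$end_t & y >= 0
}

#' Validate a session record
#'
#' Total function returning a character vector of invariant violations (empty
#' when the record is valid). Checks touch-trace ordering and screen bounds,
#' event times against the session window, inertial-stream monotonicity,
#' bubble-track geometry (per-lane fixed x, upward motion), referential
#' integrity of pop events, and consistency of every pop with the pop-radius
#' rule given the touch onset and the bubble position at pop time.
#'
#' @param record A [session_record()] (validated structurally first).
#' @return Character vector of violation messages, each naming the field, the
#'   rule broken and the observed value; empty if the record is valid.
#' @export
validate_session <- function(record) {
  v <- character()
  cfg <- record$config
  bad <- function(...) v <<- c(v, sprintf(...))
  if (!inherits(cfg, "game_config")) {
    return("config: must be a game_config object")
  }
  dur <- cfg$session_duration_s

  ids <- vapply(record$touches, function(tr) as.character(tr$touch_id[1]),
                character(1))
  if (anyDuplicated(ids)) bad("touches: duplicate touch_id (%s)",
                              paste(unique(ids[duplicated(ids)]), collapse = ","))
  for (tr in record$touches) {
    id <- tr$touch_id[1]
    n <- length(tr$t)
    if (n < 1L) { bad("touches[%s]: trace must have >= 1 sample", id); next }
    if (length(tr$x_mm) != n || length(tr$y_mm) != n) {
      bad("touches[%s]: t/x_mm/y_mm lengths differ (%d/%d/%d)",
          id, n, length(tr$x_mm), length(tr$y_mm))
      next
    }
    if (n > 1L && any(diff(tr$t) <= 0)) {
      bad("touches[%s]: sample times not strictly increasing (min diff %g)",
          id, min(diff(tr$t)))
    }
    if (any(tr$t < 0 | tr$t > dur)) {
      bad("touches[%s]: sample time outside [0, %g] (observed %g)",
          id, dur, tr$t[which(tr$t < 0 | tr$t > dur)[1]])
    }
    if (any(tr$x_mm < 0 | tr$x_mm > cfg$screen_width_mm) ||
        any(tr$y_mm < 0 | tr$y_mm > cfg$screen_height_mm)) {
      bad("touches[%s]: sample coordinates outside screen bounds", id)
    }
  }

  at <- record$accel$t
  if (length(at) > 1L && any(diff(at) < 0)) {
    bad("accel: timestamps decrease (first at index %d)",
        which(diff(at) < 0)[1] + 1L)
  }
  if (length(at) && (min(at) < 0 || max(at) > dur)) {
    bad("accel: timestamps outside [0, %g]", dur)
  }

  bb <- record$bubbles
  if (nrow(bb)) {
    if (any(bb$spawn_t >= bb$end_t)) {
      i <- which(bb$spawn_t >= bb$end_t)[1]
      bad("bubbles[%s]: spawn_t (%g) must precede end_t (%g)",
          bb$bubble_id[i], bb$spawn_t[i], bb$end_t[i])
    }
    if (any(bb$lane < 0 | bb$lane >= cfg$n_lanes)) {
      bad("bubbles: lane index outside [0, %d)", cfg$n_lanes)
    }
    if (!all(bb$end_reason %in% c("popped", "exited"))) {
      bad("bubbles: end_reason must be 'popped' or 'exited' (observed %s)",
          paste(setdiff(unique(bb$end_reason), c("popped", "exited")),
                collapse = ","))
    }
    for (ln in unique(bb$lane)) {
      cx <- unique(bb$center_x_mm[bb$lane == ln])
      if (length(cx) > 1L) {
        bad("bubbles: lane %d has varying center_x_mm (%s)", ln,
            paste(signif(cx, 6), collapse = ","))
      }
    }
    if (anyDuplicated(bb$bubble_id)) bad("bubbles: duplicate bubble_id")
  }

  pp <- record$pops
  if (nrow(pp)) {
    tol <- 1e-9
    unknown_b <- setdiff(pp$bubble_id, bb$bubble_id)
    if (length(unknown_b)) {
      bad("pops: bubble_id not found in bubbles (%s)",
          paste(unknown_b, collapse = ","))
    }
    unknown_t <- setdiff(pp$touch_id, ids)
    if (length(unknown_t)) {
      bad("pops: touch_id not found in touches (%s)",
          paste(unknown_t, collapse = ","))
    }
    if (any(pp$t < 0 | pp$t > dur)) bad("pops: event time outside [0, %g]", dur)
    over <- pp$distance_to_center_mm > cfg$pop_radius_mm + tol
    if (!cfg$pop_boundary_inclusive) {
      over <- pp$distance_to_center_mm >= cfg$pop_radius_mm - tol
    }
    if (any(over)) {
      bad("pops: distance_to_center_mm %g exceeds pop radius %g mm",
          max(pp$distance_to_center_mm), cfg$pop_radius_mm)
    }
    # consistency of each pop with touch onset and bubble position
    if (!length(unknown_b) && !length(unknown_t)) {
      ti <- match(pp$touch_id, ids)
      bi <- match(pp$bubble_id, bb$bubble_id)
      ox <- vapply(record$touches[ti], function(tr) tr$x_mm[1], numeric(1))
      oy <- vapply(record$touches[ti], function(tr) tr$y_mm[1], numeric(1))
      ot <- vapply(record$touches[ti], function(tr) tr$t[1], numeric(1))
      bad_t <- which(abs(ot - pp$t) > 1e-6)
      for (i in bad_t) {
        bad("pops[%d]: pop time %g does not match touch onset %g",
            i, pp$t[i], ot[i])
      }
      by <- bubble_y_at(bb$spawn_t[bi], bb$end_t[bi], pp$t, cfg)
      d <- sqrt((ox - bb$center_x_mm[bi])^2 + (oy - by)^2)
      for (i in setdiff(which(abs(d - pp$distance_to_center_mm) > 1e-6),
                        bad_t)) {
        bad("pops[%d]: recorded distance %g inconsistent with geometry (%g)",
            i, pp$distance_to_center_mm[i], d[i])
      }
    }
  }
  v
}

#' Number of touches in a session
#' @param record A [session_record()].
#' @return Integer count of touch traces.
#' @export
n_touches <- function(record) length(record$touches)

#' Engagement quality-control filter
#'
#' Excludes sessions from children who did not engage sufficiently with the
#' game, defined as touching the screen fewer than `min_touches` times
#' (default 3, so a session with exactly 3 touches is kept).
#'
#' @param sessions List of [session_record()] objects.
#' @param min_touches Minimum touch count to keep a session; defaults to the
#'   first session's `config$min_touches_qc` (3).
#' @return List with elements `kept` (sessions passing QC, order preserved),
#'   `excluded` (failing sessions, each annotated with
#'   `meta$qc_exclusion_reason = "insufficient_engagement"`), and `summary`
#'   (data frame: session_id, n_touches, kept).
#' @export
qc_filter <- function(sessions, min_touches = NULL) {
  if (length(sessions) == 0L) {
    return(list(kept = list(), excluded = list(),
                summary = data.frame(session_id = character(),
                                     n_touches = integer(),
                                     kept = logical())))
  }
  if (is.null(min_touches)) min_touches <- sessions[[1]]$config$min_touches_qc
  stopifnot(min_touches >= 1)
  nt <- vapply(sessions, n_touches, integer(1))
  keep <- nt >= min_touches
  excluded <- lapply(sessions[!keep], function(s) {
    s$meta$qc_exclusion_reason <- "insufficient_engagement"
    s
  })
  list(kept = sessions[keep],
       excluded = excluded,
       summary = data.frame(
         session_id = vapply(sessions, `[[`, character(1), "session_id"),
         n_touches = nt, kept = keep, stringsAsFactors = FALSE))
}

SCHEMA_VERSION <- 1L

session_to_list <- function(record) {
  list(
    schema_version = SCHEMA_VERSION,
    session_id = record$session_id,
    group = record$group,
    age_months = record$age_months,
    iq = record$iq,
    clinical_scores = record$clinical_scores,
    config = unclass(record$config),
    touches = lapply(record$touches, function(tr) {
      list(touch_id = as.character(tr$touch_id[1]),
           t = as.numeric(tr$t), x_mm = as.numeric(tr$x_mm),
           y_mm = as.numeric(tr$y_mm))
    }),
    accel = list(t = as.numeric(record$accel$t),
                 ax = as.numeric(record$accel$ax),
                 ay = as.numeric(record$accel$ay),
                 az = as.numeric(record$accel$az)),
    bubbles = list(bubble_id = as.character(record$bubbles$bubble_id),
                   lane = as.integer(record$bubbles$lane),
                   character_id = as.integer(record$bubbles$character_id),
                   spawn_t = as.numeric(record$bubbles$spawn_t),
                   end_t = as.numeric(record$bubbles$end_t),
                   end_reason = as.character(record$bubbles$end_reason),
                   center_x_mm = as.numeric(record$bubbles$center_x_mm)),
    pops = list(t = as.numeric(record$pops$t),
                bubble_id = as.character(record$pops$bubble_id),
                touch_id = as.character(record$pops$touch_id),
                distance_to_center_mm = as.numeric(record$pops$distance_to_center_mm)),
    meta = record$meta
  )
}

#' Write a session record to a JSON file
#'
#' One JSON document per session (`schema_version` 1), numbers serialised at
#' full decimal precision so that `read_session(write_session(r))`
#' reproduces `r` exactly and re-writing yields a byte-identical file.
#'
#' @param record A valid [session_record()].
#' @param destination File path to write.
#' @param pretty Indent the JSON (several times larger on disk; the compact
#'   default is still plain JSON).
#' @return The destination path, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(record, destination, pretty = FALSE) {
  v <- validate_session(record)
  if (length(v)) {
    stop("refusing to write invalid session:\n  ",
         paste(v, collapse = "\n  "), call. = FALSE)
  }
  json <- jsonlite::toJSON(session_to_list(record), auto_unbox = TRUE,
                           digits = I(17), null = "null", na = "null",
                           pretty = pretty)
  writeLines(json, destination, useBytes = TRUE)
  invisible(destination)
}

need_field <- function(x, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  cur <- x
  for (p in parts) {
    if (is.null(cur[[p]])) {
      stop("session JSON: missing required field `", path, "`", call. = FALSE)
    }
    cur <- cur[[p]]
  }
  cur
}

#' Read a session record from a JSON file
#'
#' Parses and fully validates a session document written by
#' [write_session()]. Schema violations are reported with the offending
#' field path; unknown top-level fields are preserved in the record's `meta`
#' bag.
#'
#' @param source Path to a session JSON file.
#' @return A validated [session_record()].
#' @export
read_session <- function(source) {
  x <- tryCatch(jsonlite::fromJSON(source, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE),
                error = function(e) {
                  stop("malformed session JSON in `", source, "`: ",
                       conditionMessage(e), call. = FALSE)
                })
  for (f in c("session_id", "group", "age_months", "config", "touches",
              "accel", "bubbles", "pops")) {
    need_field(x, f)
  }
  cfg_fields <- setdiff(names(game_config()), "pop_boundary_inclusive")
  for (f in cfg_fields) need_field(x, paste0("config.", f))
  cfg <- do.call(game_config, x$config[names(x$config) %in% names(formals(game_config))])

  touches <- lapply(x$touches, function(tr) {
    list(touch_id = tr$touch_id, t = as.numeric(tr$t),
         x_mm = as.numeric(tr$x_mm), y_mm = as.numeric(tr$y_mm))
  })
  as_chr0 <- function(v) if (is.null(v)) character() else as.character(v)
  as_num0 <- function(v) if (is.null(v)) numeric() else as.numeric(v)
  as_int0 <- function(v) if (is.null(v)) integer() else as.integer(v)
  bubbles <- data.frame(bubble_id = as_chr0(x$bubbles$bubble_id),
                        lane = as_int0(x$bubbles$lane),
                        character_id = as_int0(x$bubbles$character_id),
                        spawn_t = as_num0(x$bubbles$spawn_t),
                        end_t = as_num0(x$bubbles$end_t),
                        end_reason = as_chr0(x$bubbles$end_reason),
                        center_x_mm = as_num0(x$bubbles$center_x_mm),
                        stringsAsFactors = FALSE)
  pops <- data.frame(t = as_num0(x$pops$t),
                     bubble_id = as_chr0(x$pops$bubble_id),
                     touch_id = as_chr0(x$pops$touch_id),
                     distance_to_center_mm = as_num0(x$pops$distance_to_center_mm),
                     stringsAsFactors = FALSE)
  known <- c("schema_version", "session_id", "group", "age_months", "iq",
             "clinical_scores", "config", "touches", "accel", "bubbles",
             "pops", "meta")
  meta <- if (is.null(x$meta)) list() else x$meta
  extra <- setdiff(names(x), known)
  if (length(extra)) meta[extra] <- x[extra]

  rec <- session_record(
    session_id = x$session_id, group = x$group, age_months = x$age_months,
    config = cfg, touches = touches,
    accel = list(t = as_num0(x$accel$t), ax = as_num0(x$accel$ax),
                 ay = as_num0(x$accel$ay), az = as_num0(x$accel$az)),
    bubbles = bubbles, pops = pops,
    iq = x$iq, clinical_scores = x$clinical_scores,
    meta = meta, validate = FALSE)
  v <- validate_session(rec)
  if (length(v)) {
    stop("session JSON `", source, "` violates invariants:\n  ",
         paste(v, collapse = "\n  "), call. = FALSE)
  }
  rec
}

#' Write a cohort of sessions plus a JSON-lines index and metadata CSV
#'
#' @param sessions List of [session_record()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (sessions, index, metadata CSV).
#' @export
write_cohort <- function(sessions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(sessions))
  for (i in seq_along(sessions)) {
    paths[i] <- file.path(dir, paste0(sessions[[i]]$session_id, ".json"))
    write_session(sessions[[i]], paths[i])
  }
  index <- file.path(dir, "cohort_index.jsonl")
  lines <- vapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    as.character(jsonlite::toJSON(
      list(session_id = s$session_id, group = s$group,
           age_months = s$age_months, file = basename(paths[i])),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, index, useBytes = TRUE)
  meta <- cohort_metadata(sessions)
  meta_path <- file.path(dir, "cohort_metadata.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(list(sessions = paths, index = index, metadata = meta_path))
}

#' Cohort metadata table
#'
#' @param sessions List of [session_record()] objects.
#' @return Data frame with session_id, group, age_months, iq and one column
#'   per clinical score.
#' @export
cohort_metadata <- function(sessions) {
  score_names <- unique(unlist(lapply(sessions, function(s) names(s$clinical_scores))))
  meta <- data.frame(
    session_id = vapply(sessions, `[[`, character(1), "session_id"),
    group = vapply(sessions, `[[`, character(1), "group"),
    age_months = vapply(sessions, `[[`, numeric(1), "age_months"),
    iq = vapply(sessions, function(s) if (is.null(s$iq)) NA_real_ else s$iq,
                numeric(1)),
    stringsAsFactors = FALSE)
  for (sc in score_names) {
    meta[[sc]] <- vapply(sessions, function(s) {
      v <- s$clinical_scores[[sc]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  meta
}

#' Read all sessions referenced by a cohort directory
#'
#' @param dir Directory written by [write_cohort()] (or containing
#'   one-session-per-file JSON documents).
#' @return List of [session_record()] objects.
#' @export
read_cohort <- function(dir) {
  index <- file.path(dir, "cohort_index.jsonl")
  files <- if (file.exists(index)) {
    vapply(readLines(index), function(l) jsonlite::fromJSON(l)$file,
           character(1), USE.NAMES = FALSE)
  } else {
    setdiff(basename(Sys.glob(file.path(dir, "*.json"))), "manifest.json")
  }
  lapply(file.path(dir, files), read_session)
}
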