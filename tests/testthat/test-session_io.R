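test_that("session JSON round-trips exactly and re-writes byte-identically", {
  cfg <- game_config()
  # hand-built minimal record plus simulated ones (property over seeds)
  tr <- make_trace("T1", c(1, 1.05), c(16.05, 17), c(218.95, 218))
  recs <- c(list(make_record(list(tr), config = cfg,
                             iq = 101.5, clinical_scores = list(fm = 38.25))),
            lapply(1:5, function(s) {
              simulate_session(agent_profile(), age_months = 20 + s,
                               seed = s)
            }))
  for (rec in recs) {
    f1 <- tempfile(fileext = ".json")
    f2 <- tempfile(fileext = ".json")
    write_session(rec, f1)
    r2 <- read_session(f1)
    expect_equal(r2$touches, rec$touches, tolerance = 0)
    expect_equal(r2$accel, rec$accel, tolerance = 0)
    expect_equal(r2$bubbles, rec$bubbles, tolerance = 0)
    expect_equal(r2$pops, rec$pops, tolerance = 0)
    expect_identical(r2$session_id, rec$session_id)
    expect_equal(r2$age_months, rec$age_months, tolerance = 0)
    write_session(r2, f2)
    expect_identical(readLines(f1), readLines(f2))
    unlink(c(f1, f2))
  }
})

test_that("records with no touches are writable; out-of-window events are not", {
  rec0 <- make_record(list())
  expect_identical(validate_session(rec0), character(0))
  f <- tempfile(fileext = ".json")
  write_session(rec0, f)
  expect_identical(n_touches(read_session(f)), 0L)
  unlink(f)

  # touch at t = 21 s under a 20 s window must be rejected before writing
  bad <- make_trace("T1", 21, 10, 10)
  expect_error(make_record(list(bad)), "outside \\[0, 20\\]")
  rec <- make_record(list())
  rec$touches <- list(bad)
  expect_error(write_session(rec, tempfile()), "refusing to write")
})

test_that("schema violations are reported with the offending path", {
  rec <- simulate_session(agent_profile(), 24, seed = 2)
  f <- tempfile(fileext = ".json")
  write_session(rec, f)
  x <- jsonlite::fromJSON(f, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$config$pop_radius_mm <- NULL
  f2 <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                              null = "null", na = "null"), f2)
  expect_error(read_session(f2), "config\\.pop_radius_mm")

  # a logged pop farther than the pop radius violates the pop rule
  y <- jsonlite::fromJSON(f, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  y$pops$distance_to_center_mm[1] <- 19
  f3 <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(y, auto_unbox = TRUE, digits = I(17),
                              null = "null", na = "null"), f3)
  expect_error(read_session(f3), "pop radius|inconsistent")
  expect_error(read_session(tempfile()), "malformed|cannot")
  unlink(c(f, f2, f3))
})

test_that("the shipped synthetic example session loads with 4 touches and 2 pops", {
  f <- system.file("extdata", "example_session.json", package = "bubblepop")
  expect_true(nzchar(f))
  rec <- read_session(f)
  expect_identical(n_touches(rec), 4L)
  expect_identical(nrow(rec$pops), 2L)
  expect_identical(validate_session(rec), character(0))
  fx <- extract_features(rec)
  expect_equal(unname(fx["bubble_popping_rate"]), 0.5)
  expect_equal(unname(fx["number_of_targeted_bubbles"]), 3)
})

test_that("unknown top-level JSON fields are preserved in the meta bag", {
  rec <- simulate_session(agent_profile(), 24, seed = 4)
  f <- tempfile(fileext = ".json")
  write_session(rec, f)
  x <- jsonlite::fromJSON(f, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$vendor_tag <- "device-123"
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                              null = "null", na = "null"), f)
  r2 <- read_session(f)
  expect_identical(r2$meta$vendor_tag, "device-123")
  unlink(f)
})

test_that("validate_session flags ordering and referential violations", {
  cfg <- game_config()
  rec <- make_record(list(make_trace("T1", c(1, 1.05), c(10, 11), c(20, 21))))
  # decreasing timestamps within a trace
  bad <- rec
  bad$touches[[1]]$t <- c(1.05, 1)
  v <- validate_session(bad)
  expect_length(grep("not strictly increasing", v), 1L)

  # pop referencing an unknown bubble id
  bad2 <- rec
  bad2$pops <- data.frame(t = 1, bubble_id = "nope", touch_id = "T1",
                          distance_to_center_mm = 1,
                          stringsAsFactors = FALSE)
  expect_length(grep("bubble_id not found", validate_session(bad2)), 1L)

  # well-formed records validate cleanly
  expect_identical(validate_session(rec), character(0))
})

test_that("qc_filter keeps sessions with at least three touches and partitions its input", {
  cfg <- game_config(session_duration_s = 20)
  mk <- function(k, id) {
    trs <- lapply(seq_len(k), function(i) {
      make_trace(sprintf("T%d", i), 1 + 0.5 * i, 10 + i, 30)
    })
    make_record(trs, config = cfg, session_id = id)
  }
  sessions <- lapply(0:5, function(k) mk(k, sprintf("S%d", k)))
  res <- qc_filter(sessions)
  expect_identical(vapply(res$kept, `[[`, character(1), "session_id"),
                   c("S3", "S4", "S5"))
  expect_identical(vapply(res$excluded, `[[`, character(1), "session_id"),
                   c("S0", "S1", "S2"))
  expect_true(all(vapply(res$excluded,
                         function(s) s$meta$qc_exclusion_reason,
                         character(1)) == "insufficient_engagement"))
  expect_identical(length(res$kept) + length(res$excluded), length(sessions))

  # inclusive boundary at min_touches = 1
  res1 <- qc_filter(sessions[2], min_touches = 1)
  expect_length(res1$kept, 1L)

  # empty input
  res0 <- qc_filter(list())
  expect_length(res0$kept, 0L)
  expect_length(res0$excluded, 0L)
})

test_that("cohort round-trip through a directory preserves sessions and metadata", {
  prof <- default_profiles()
  spec <- cohort_spec(groups = list(NT = list(profile = prof$nt, n = 3),
                                    autistic = list(profile = prof$case, n = 3)),
                      iq_model = list(NT = c(100, 10), autistic = c(90, 12)),
                      clinical_score_model = list(fine_motor = c(6, 3)),
                      seed = 11)
  co <- simulate_cohort(spec)
  d <- tempfile("cohort_")
  write_cohort(co$sessions, d)
  back <- read_cohort(d)
  expect_length(back, 6L)
  expect_identical(vapply(back, `[[`, character(1), "session_id"),
                   vapply(co$sessions, `[[`, character(1), "session_id"))
  expect_equal(back[[1]]$clinical_scores$fine_motor,
               co$sessions[[1]]$clinical_scores$fine_motor, tolerance = 0)
  meta <- utils::read.csv(file.path(d, "cohort_metadata.csv"))
  expect_identical(nrow(meta), 6L)
  expect_true(all(c("session_id", "group", "age_months", "iq",
                    "fine_motor") %in% colnames(meta)))
  unlink(d, recursive = TRUE)
})
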