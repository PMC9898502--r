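#' Pipeline configuration
#'
#' Describes a full analysis run: which cohort to use (a [cohort_spec()] to
#' simulate, or a directory of session JSON files), the covariates for the
#' group comparisons (e.g. `"age_months"` for a toddler study,
#' `c("age_months", "iq")` for an older sample), which group pairs to
#' compare, which clinical scores to correlate with the motor features, and
#' the classifier settings.
#'
#' @param cohort A [cohort_spec()] or a path to a session directory.
#' @param covariates Character vector of metadata columns used as ANCOVA
#'   covariates and correlation controls.
#' @param comparisons List of length-2 character vectors of group labels.
#' @param correlation_targets Clinical-score columns to correlate against
#'   the motor features (NULL to skip).
#' @param classifier A [classifier_spec()] (NULL to skip classification).
#' @param classify_candidates Candidate feature columns for greedy
#'   selection; the default is the six-feature panel used for group
#'   discrimination (touch length, touch duration, time on target, distance
#'   to center, number of targets, screen exploration).
#' @param alpha FDR significance level.
#' @param output_dir Directory for artifacts.
#' @param seed Integer master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort,
                            covariates = "age_months",
                            comparisons = NULL,
                            correlation_targets = NULL,
                            classifier = classifier_spec(),
                            classify_candidates = c(
                              "touch_length_mean", "touch_duration_mean",
                              "time_on_target_mean", "distance_to_center_mean",
                              "number_of_targeted_bubbles",
                              "screen_exploratory_percentage"),
                            alpha = 0.05,
                            output_dir = tempfile("bubblepop_run_"),
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  cfg <- list(cohort = cohort, covariates = covariates,
              comparisons = comparisons,
              correlation_targets = correlation_targets,
              classifier = classifier,
              classify_candidates = classify_candidates,
              alpha = alpha, output_dir = output_dir, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_log <- function(con, verbose, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  if (verbose) message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> quality control -> feature extraction ->
#' group comparisons -> clinical correlations -> classification, writing all
#' artifacts (`features.csv`, `comparisons.csv`, `correlations.csv`,
#' `classification.json`, `qc_summary.csv`, `manifest.json`, `run.log`) to
#' the configured output directory. Identical configuration and seed produce
#' identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, the run manifest (also written as `manifest.json`):
#'   seed, package version, stage artifact paths and md5 digests.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  artifacts <- character()
  stage <- "pre-flight"
  run_stage <- function(name, expr) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    pipeline_log(con, verbose, "stage %-10s done in %.2f s", name,
                 proc.time()[["elapsed"]] - t0)
    res
  }

  # ---- pre-flight -----------------------------------------------------
  simulated <- inherits(config$cohort, "cohort_spec")
  if (simulated) {
    known_scores <- names(config$cohort$clinical_score_model)
    known_cols <- c("age_months", "iq", known_scores)
    bad <- setdiff(config$covariates, known_cols)
    if (length(bad)) {
      stop("pipeline pre-flight: covariate column(s) not produced by the cohort: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    bad_t <- setdiff(config$correlation_targets, known_scores)
    if (length(bad_t)) {
      stop("pipeline pre-flight: correlation target(s) not produced by the cohort: ",
           paste(bad_t, collapse = ", "), call. = FALSE)
    }
    groups <- names(config$cohort$groups)
    for (pair in config$comparisons) {
      if (!all(pair %in% groups)) {
        stop("pipeline pre-flight: comparison groups not in cohort: ",
             paste(setdiff(pair, groups), collapse = ", "), call. = FALSE)
      }
    }
  }
  bad_cand <- setdiff(config$classify_candidates, feature_names())
  if (length(bad_cand)) {
    stop("pipeline pre-flight: unknown candidate feature(s): ",
         paste(bad_cand, collapse = ", "), call. = FALSE)
  }
  pipeline_log(con, verbose, "pre-flight checks passed (seed %d)", config$seed)

  # ---- sessions -------------------------------------------------------
  sessions <- run_stage("simulate", {
    if (simulated) {
      spec <- config$cohort
      spec$seed <- config$seed
      res <- simulate_cohort(spec)
      write_cohort(res$sessions, file.path(out, "sessions"))
      artifacts <- c(artifacts, file.path(out, "sessions", "cohort_index.jsonl"))
      res$sessions
    } else {
      read_cohort(config$cohort)
    }
  })

  qc <- run_stage("qc", {
    res <- qc_filter(sessions)
    p <- file.path(out, "qc_summary.csv")
    utils::write.csv(res$summary, p, row.names = FALSE)
    artifacts <- c(artifacts, p)
    res
  })

  features <- run_stage("features", {
    ft <- features_table(qc$kept)
    p <- file.path(out, "features.csv")
    utils::write.csv(ft, p, row.names = FALSE)
    artifacts <- c(artifacts, p)
    ft
  })
  if (!simulated) {
    bad <- setdiff(config$covariates, colnames(features))
    if (length(bad)) {
      stop("pipeline: covariate column(s) missing from feature table: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  comparisons <- config$comparisons
  if (is.null(comparisons)) {
    g <- unique(features$group)
    comparisons <- if (length(g) >= 2L) list(g[1:2]) else list()
  }
  cmp <- run_stage("compare", {
    rows <- lapply(comparisons, function(pair) {
      sub <- features[features$group %in% pair, , drop = FALSE]
      res <- compare_all(sub, group = "group",
                         covariates = config$covariates,
                         alpha = config$alpha)
      cbind(comparison = paste(pair, collapse = "_vs_"), as.data.frame(res))
    })
    tbl <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(tbl)) {
      p <- file.path(out, "comparisons.csv")
      utils::write.csv(tbl, p, row.names = FALSE)
      artifacts <- c(artifacts, p)
    }
    tbl
  })

  correlations <- NULL
  if (!is.null(config$correlation_targets)) {
    correlations <- run_stage("correlate", {
      tbl <- correlate_features(features,
                                features = intersect(feature_names(),
                                                     colnames(features)),
                                scores = config$correlation_targets,
                                covariates = config$covariates)
      p <- file.path(out, "correlations.csv")
      utils::write.csv(tbl, p, row.names = FALSE)
      artifacts <- c(artifacts, p)
      tbl
    })
  }

  classification <- NULL
  if (!is.null(config$classifier)) {
    classification <- run_stage("classify", {
      tasks <- lapply(comparisons, function(pair) {
        sub <- features[features$group %in% pair, , drop = FALSE]
        labels <- factor(sub$group, levels = pair)
        cand <- intersect(config$classify_candidates, colnames(sub))
        cand <- cand[vapply(cand, function(f) !anyNA(sub[[f]]), logical(1))]
        cs <- config$classifier
        cs$seed <- config$seed
        trace <- greedy_select(sub[, cand, drop = FALSE], labels, cs)
        roc <- roc_auc(trace$pooled_scores, labels)
        list(comparison = paste(pair, collapse = "_vs_"),
             positive_class = pair[2],
             candidates = cand,
             steps = trace$steps,
             pooled_scores = trace$pooled_scores,
             roc = roc$roc,
             final_auc = roc$auc)
      })
      p <- file.path(out, "classification.json")
      jsonlite::write_json(tasks, p, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", pretty = TRUE)
      artifacts <- c(artifacts, p)
      tasks
    })
  }

  digests <- as.character(tools::md5sum(artifacts))
  manifest <- list(
    package_version = as.character(utils::packageVersion("bubblepop")),
    seed = config$seed,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    output_dir = out,
    n_sessions = length(sessions),
    n_kept = length(qc$kept),
    covariates = config$covariates,
    alpha = config$alpha,
    artifacts = data.frame(path = artifacts, md5 = digests,
                           stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  pipeline_log(con, verbose, "run complete: %d artifacts", length(artifacts))
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' Render a markdown report for a completed run
#'
#' Single-document summary of a pipeline run: QC exclusions, the comparison
#' table sorted by adjusted p-value with effect sizes, the clinical
#' correlation table, and per-task classification results (selection steps
#' with AUC and confidence intervals). Sections whose stage did not run are
#' omitted.
#'
#' @param manifest A run manifest from [run_pipeline()], or the path to a
#'   run's `manifest.json`.
#' @param path Output file (default `report.md` in the run directory).
#' @return The report path, invisibly.
#' @export
make_report <- function(manifest, path = NULL) {
  if (is.character(manifest)) {
    manifest <- jsonlite::fromJSON(manifest, simplifyDataFrame = TRUE)
  }
  out <- manifest$output_dir
  if (is.null(out) || !dir.exists(out)) {
    stop("make_report: manifest does not point at an existing run directory",
         call. = FALSE)
  }
  if (is.null(path)) path <- file.path(out, "report.md")
  art <- function(name) {
    p <- file.path(out, name)
    if (file.exists(p)) p else NULL
  }
  lines <- c("# Bubble-popping motor analysis report", "",
             sprintf("- package version: %s", manifest$package_version),
             sprintf("- seed: %s", manifest$seed),
             sprintf("- sessions: %s analysed of %s recorded",
                     manifest$n_kept, manifest$n_sessions), "")
  md_table <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, 4)
    c(paste("|", paste(colnames(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i) {
        paste("|", paste(vapply(df[i, ], function(v) {
          if (is.na(v)) "NA" else as.character(v)
        }, character(1)), collapse = " | "), "|")
      }, character(1)))
  }
  qc <- art("qc_summary.csv")
  if (!is.null(qc)) {
    s <- utils::read.csv(qc)
    lines <- c(lines, "## Quality control", "",
               sprintf("%d of %d sessions kept (threshold: minimum touches); %d excluded for insufficient engagement.",
                       sum(s$kept), nrow(s), sum(!s$kept)), "")
  }
  cmp <- art("comparisons.csv")
  if (!is.null(cmp)) {
    tbl <- utils::read.csv(cmp)
    tbl <- tbl[order(tbl$p_adjusted), ]
    lines <- c(lines, "## Group comparisons (ANCOVA, BH-adjusted)", "",
               md_table(tbl), "")
  }
  cor_p <- art("correlations.csv")
  if (!is.null(cor_p)) {
    tbl <- utils::read.csv(cor_p)
    lines <- c(lines, "## Clinical correlations (partial Spearman)", "",
               md_table(tbl[order(tbl$p), ][seq_len(min(20, nrow(tbl))), ]),
               "")
  }
  cls <- art("classification.json")
  if (!is.null(cls)) {
    tasks <- jsonlite::fromJSON(cls, simplifyDataFrame = FALSE)
    lines <- c(lines, "## Classification (greedy LOOCV logistic regression)", "")
    for (task in tasks) {
      lines <- c(lines, sprintf("### %s (positive class: %s)",
                                task$comparison, task$positive_class), "")
      st <- as.data.frame(task$steps)
      lines <- c(lines, md_table(st), "",
                 sprintf("Final pooled LOOCV AUC: %.3f", task$final_auc), "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
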