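#' Pipeline configuration
#'
#' One configuration object drives the whole synthetic replication: the
#' shared peptide universe, both study designs, every threshold of the
#' discovery/selection/classification stages, and stage toggles. The two
#' studies share the peptide universe (same universe seed and universe
#' dimensions), as two CE-MS studies of the same biofluid share the
#' underlying peptidome; `discordant_ids` optionally flips the planted
#' direction of chosen markers in study A to exercise the concordance
#' filter.
#'
#' @param seed master RNG seed; study seeds derive from it.
#' @param study study-design [study_config()] shared by both cohorts
#'   (study B uses its dose/day grid; study A only its universe/noise
#'   fields).
#' @param n_control_a,n_case_a study-A (two-group) design sizes.
#' @param n_discordant number of planted markers whose direction is
#'   flipped in study A (default 0).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param freq_threshold detection-frequency threshold (default 0.30).
#' @param criteria [screen_criteria()] for the temporal screen.
#' @param scheme [tolerance_scheme()] for matching.
#' @param classifier_cost SVM regularization constant (default 1).
#' @param case_days study-B discovery-case collection days (default
#'   3, 7, 10 — the first samples after the dosing block).
#' @param stages named logical vector of stage toggles.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            study = study_config(seed = seed),
                            n_control_a = 14, n_case_a = 25,
                            n_discordant = 0,
                            alpha = 0.05, freq_threshold = 0.30,
                            criteria = screen_criteria(),
                            scheme = tolerance_scheme(),
                            classifier_cost = 1,
                            case_days = c(3, 7, 10),
                            stages = c(simulate = TRUE, calibrate = TRUE,
                                       match = TRUE, discover = TRUE,
                                       select = TRUE, train = TRUE,
                                       timecourse = TRUE, correlate = TRUE)) {
  stopifnot(alpha > 0, alpha < 1, freq_threshold > 0, freq_threshold < 1,
            classifier_cost > 0, n_discordant >= 0)
  order <- c("simulate", "calibrate", "match", "discover", "select",
             "train", "timecourse", "correlate")
  stages <- stages[order]
  if (any(is.na(stages))) stop("stages must name all pipeline stages")
  on <- which(stages)
  if (length(on) > 0 && !all(seq_len(max(on)) %in% on)) {
    first_gap <- order[setdiff(seq_len(max(on)), on)][1]
    stop("configuration error: stage '", first_gap,
         "' is disabled but a later stage depends on it")
  }
  structure(list(
    seed = as.integer(seed), study = study,
    n_control_a = n_control_a, n_case_a = n_case_a,
    n_discordant = n_discordant,
    alpha = alpha, freq_threshold = freq_threshold,
    criteria = criteria, scheme = scheme,
    classifier_cost = classifier_cost, case_days = case_days,
    stages = stages
  ), class = "pipeline_config")
}

## Polynomial rolling hash (mod 2^31 - 1) of the serialized
## configuration, for provenance stamping of output artifacts.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(rapply(unclass(config), unclass,
                                       how = "replace")),
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full synthetic replication pipeline
#'
#' Executes simulate -> calibrate -> match -> discover (both studies) ->
#' select -> train (linear and margin classifiers, with take-one-out
#' cross-validation on the two-group training study) -> time-course
#' scoring of the dosing cohort -> endpoint correlation, honouring the
#' stage toggles in the configuration. Artifacts are optionally written
#' under `out_dir`, each run stamped with the configuration hash and
#' seed in a `MANIFEST.json` sidecar.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @param quiet suppress progress messages.
#' @return a run report: per-stage counts, cross-validated AUCs, the
#'   panel, time-course score tables, the endpoint correlation and the
#'   provenance stamp. Intermediate objects are in `$objects`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  st <- config$stages
  obj <- list()
  summary <- list(config_hash = config_hash(config), seed = config$seed)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (st[["simulate"]]) {
    say("simulate: generating study A (two-group) and study B (time course)")
    run_stage("simulate", {
      cfg_b <- config$study
      cfg_a <- cfg_b
      cfg_a$seed <- cfg_b$seed  # shared universe
      flips <- character(0)
      obj$study_b <- generate_study(cfg_b)
      if (config$n_discordant > 0) {
        mk <- obj$study_b$truth$marker_ids
        flips <- mk[seq_len(min(config$n_discordant, length(mk)))]
      }
      obj$study_a <- generate_two_group(config$n_control_a, config$n_case_a,
                                        cfg_a, flip_directions = flips)
    })
    summary$n_samples_a <- length(obj$study_a$samples)
    summary$n_samples_b <- length(obj$study_b$samples)
  }

  if (st[["calibrate"]]) {
    say("calibrate: fitting reference calibrations per sample")
    run_stage("calibrate", {
      obj$cal_a <- calibrate_cohort(obj$study_a$samples, obj$study_a$refs)
      obj$cal_b <- calibrate_cohort(obj$study_b$samples, obj$study_b$refs)
    })
  }

  if (st[["match"]]) {
    say("match: building master lists")
    run_stage("match", {
      obj$master_a <- build_master_list(obj$cal_a, config$scheme)
      obj$master_b <- build_master_list(obj$cal_b, config$scheme)
    })
    summary$n_consensus_a <- nrow(obj$master_a$peptides)
    summary$n_consensus_b <- nrow(obj$master_b$peptides)
  }

  if (st[["discover"]]) {
    say("discover: per-study differential statistics")
    run_stage("discover", {
      des_a <- obj$study_a$design
      obj$disc_a <- discover_markers(
        obj$master_a,
        case_ids = des_a$sample_id[des_a$group == "treated"],
        control_ids = des_a$sample_id[des_a$group == "control"],
        alpha = config$alpha, freq_threshold = config$freq_threshold
      )
      des_b <- obj$study_b$design
      obj$disc_b <- discover_markers(
        obj$master_b,
        case_ids = des_b$sample_id[des_b$dose_mg_kg > 0 &
                                     des_b$day %in% config$case_days],
        control_ids = des_b$sample_id[des_b$dose_mg_kg == 0],
        alpha = config$alpha, freq_threshold = config$freq_threshold
      )
    })
    summary$n_significant_a <- nrow(obj$disc_a)
    summary$n_significant_b <- nrow(obj$disc_b)
  }

  if (st[["select"]]) {
    say("select: two-study selection workflow")
    run_stage("select", {
      obj$report <- build_panel(obj$disc_a, obj$disc_b,
                                obj$master_a, obj$master_b,
                                obj$study_b$design,
                                criteria = config$criteria,
                                scheme = config$scheme)
    })
    summary$n_intersection <- nrow(obj$report$intersection)
    summary$n_combined <- length(obj$report$combined)
    summary$n_final_panel <- length(obj$report$final_panel)
  }

  if (st[["train"]]) {
    say("train: panel classifiers on study A with take-one-out CV")
    run_stage("train", {
      map <- match_master_lists(obj$master_a, obj$master_b, config$scheme)
      panel_b <- obj$report$final_panel
      panel_a <- map$id_a[match(panel_b, map$id_b)]
      keep <- !is.na(panel_a)
      obj$panel_a <- panel_a[keep]
      obj$panel_b <- panel_b[keep]
      if (length(obj$panel_a) == 0) stop("empty trainable panel")
      des_a <- obj$study_a$design
      case_a <- des_a$sample_id[des_a$group == "treated"]
      ctrl_a <- des_a$sample_id[des_a$group == "control"]
      obj$model_linear <- fit_linear_model(obj$panel_a,
                                           obj$master_a$intensity,
                                           case_a, ctrl_a)
      obj$model_margin <- fit_margin_model(obj$panel_a,
                                           obj$master_a$intensity,
                                           case_a, ctrl_a,
                                           cost = config$classifier_cost)
      obj$cv_linear <- loo_cv(obj$panel_a, obj$master_a$intensity,
                              case_a, ctrl_a, kind = "linear")
      obj$cv_margin <- loo_cv(obj$panel_a, obj$master_a$intensity,
                              case_a, ctrl_a, kind = "margin",
                              cost = config$classifier_cost)
    })
    summary$panel_size_trained <- length(obj$panel_a)
    summary$loo_auc_linear <- obj$cv_linear$auc
    summary$loo_auc_margin <- obj$cv_margin$auc
  }

  if (st[["timecourse"]]) {
    say("timecourse: scoring the dosing cohort")
    run_stage("timecourse", {
      ## rename study-B matrix rows to the A panel for scoring with the
      ## A-trained models
      mat_b <- obj$master_b$intensity[obj$panel_b, , drop = FALSE]
      rownames(mat_b) <- obj$panel_a
      mb <- list(intensity = mat_b)
      obj$tc_linear <- time_course_scores(obj$model_linear, mb,
                                          obj$study_b$design)
      obj$tc_margin <- time_course_scores(obj$model_margin, mb,
                                          obj$study_b$design)
    })
  }

  if (st[["correlate"]]) {
    say("correlate: endpoints vs markers and model scores")
    run_stage("correlate", {
      obj$endpoints <- generate_endpoints(obj$study_b$design, config$study)
      sc_lin <- attr(obj$tc_linear, "scores")
      sc_mar <- attr(obj$tc_margin, "scores")
      obj$correlation <- correlate_panel(
        list(markers = obj$master_b$intensity[obj$panel_b, , drop = FALSE],
             model_linear = stats::setNames(sc_lin$score, sc_lin$sample_id),
             model_margin = stats::setNames(sc_mar$score, sc_mar$sample_id)),
        obj$endpoints
      )
    })
  }

  if (!is.null(out_dir)) {
    write_pipeline_artifacts(obj, summary, config, out_dir)
  }

  structure(list(summary = summary, objects = obj, config = config),
            class = "pipeline_report")
}

write_pipeline_artifacts <- function(obj, summary, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(obj$study_a)) write_study(obj$study_a, file.path(out_dir, "study_a"))
  if (!is.null(obj$study_b)) write_study(obj$study_b, file.path(out_dir, "study_b"))
  if (!is.null(obj$master_a)) write_master_list(obj$master_a, file.path(out_dir, "master_a"))
  if (!is.null(obj$master_b)) write_master_list(obj$master_b, file.path(out_dir, "master_b"))
  if (!is.null(obj$disc_a)) {
    utils::write.csv(obj$disc_a, file.path(out_dir, "markers_a.csv"),
                     row.names = FALSE)
    utils::write.csv(obj$disc_b, file.path(out_dir, "markers_b.csv"),
                     row.names = FALSE)
  }
  if (!is.null(obj$report)) {
    write_selection_report(obj$report, file.path(out_dir, "selection_report.csv"))
  }
  if (!is.null(obj$model_linear)) {
    write_model(obj$model_linear, file.path(out_dir, "model_linear.json"))
    write_model(obj$model_margin, file.path(out_dir, "model_margin.json"))
  }
  if (!is.null(obj$tc_linear)) {
    utils::write.csv(obj$tc_linear, file.path(out_dir, "timecourse_linear.csv"),
                     row.names = FALSE)
    utils::write.csv(obj$tc_margin, file.path(out_dir, "timecourse_margin.csv"),
                     row.names = FALSE)
  }
  if (!is.null(obj$correlation)) {
    write_correlation(obj$correlation, file.path(out_dir, "endpoint_correlation.csv"))
  }
  jsonlite::write_json(summary, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  s <- x$summary
  for (f in names(s)) {
    v <- s[[f]]
    cat(sprintf("  %-20s %s\n", f,
                if (is.numeric(v)) format(v, digits = 6) else as.character(v)))
  }
  invisible(x)
}
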