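#' Criteria for the temporal response screen
#'
#' Codifies the "clear response" visual screen as two ratio rules:
#' (a) during the peak window the top-dose / control mean-intensity ratio
#' must reach `r_min` (or `1/r_min` for down-regulation), and (b) from
#' `resolve_day` on, the ratio must be back inside `[1/r_return,
#' r_return]`.
#'
#' @param r_min minimum peak-window fold change (default 2).
#' @param r_return maximum late-window fold change (default 2).
#' @param peak_window `c(start, end)` days of maximal effect (default 3-10).
#' @param resolve_day first day of the late window (default 29).
#' @param floor intensity floor applied to cell means before forming
#'   ratios (default 1 AU).
#' @return a list of class `screen_criteria`.
#' @export
screen_criteria <- function(r_min = 2, r_return = 2,
                            peak_window = c(3, 10), resolve_day = 29,
                            floor = 1) {
  stopifnot(r_min >= 1, r_return >= 1, floor > 0,
            length(peak_window) == 2, resolve_day > peak_window[2])
  structure(list(r_min = r_min, r_return = r_return,
                 peak_window = peak_window, resolve_day = resolve_day,
                 floor = floor),
            class = "screen_criteria")
}

#' Temporal response screen for one peptide
#'
#' Both ratios compare geometric means of floored dose/day cell means:
#' the peak (and late) level of the top dose against the control
#' reference level estimated from all control cells. Geometric averaging
#' and the pooled control reference keep the estimator variance small at
#' the 3-4 animals per cell typical of these designs, so a genuinely
#' transient marker is not rejected by one noisy late cell.
#'
#' @param means data.frame with columns dose, day, mean_intensity for one
#'   peptide (as produced by [day_dose_means()]), covering the control
#'   dose (0) and at least one treated dose over the day grid.
#' @param criteria a [screen_criteria()].
#' @return logical; attributes `peak_ratio`, `late_ratio` and `direction`
#'   (+1/-1 by the peak ratio) carry the evidence.
#' @export
temporal_response_screen <- function(means, criteria = screen_criteria()) {
  if (!any(means$dose == 0)) stop("control (dose 0) means are required")
  doses <- sort(unique(means$dose))
  if (length(doses) < 2) stop("at least one treated dose is required")
  top <- max(doses)
  fl <- criteria$floor
  ## geometric mean of floored cell means: robust to the heavy right
  ## tail of small-sample lognormal cell means
  cell <- function(dose, days) {
    v <- means$mean_intensity[means$dose == dose & means$day %in% days]
    if (length(v) == 0) NA_real_ else exp(mean(log(pmax(v, fl))))
  }
  peak_days <- means$day[means$day >= criteria$peak_window[1] &
                           means$day <= criteria$peak_window[2]]
  late_days <- means$day[means$day >= criteria$resolve_day]
  ## control reference level pools all control cells (controls carry no
  ## time trend), minimizing the variance of the ratio estimates
  ctrl_ref <- cell(0, unique(means$day))
  peak_ratio <- cell(top, peak_days) / ctrl_ref
  late_ratio <- cell(top, late_days) / ctrl_ref
  responds <- !is.na(peak_ratio) &&
    (peak_ratio >= criteria$r_min || peak_ratio <= 1 / criteria$r_min)
  resolves <- !is.na(late_ratio) &&
    late_ratio <= criteria$r_return && late_ratio >= 1 / criteria$r_return
  out <- responds && resolves
  attr(out, "peak_ratio") <- peak_ratio
  attr(out, "late_ratio") <- late_ratio
  attr(out, "direction") <- if (!is.na(peak_ratio) && peak_ratio < 1) -1L else 1L
  out
}

#' Intersect two studies' marker id sets
#'
#' @param ids_a,ids_b marker id vectors.
#' @param map optional cross-study match table (columns `id_a`, `id_b`,
#'   e.g. from [match_master_lists()]) when the studies do not share a
#'   consensus id space. Without a map the ids are intersected directly.
#' @return with a map, a data.frame of matched pairs both of which are
#'   markers; without, the plain intersection vector.
#' @export
intersect_studies <- function(ids_a, ids_b, map = NULL) {
  if (is.null(map)) return(intersect(ids_a, ids_b))
  if (!all(c("id_a", "id_b") %in% names(map))) {
    stop("cross-study map must have columns id_a, id_b")
  }
  map[map$id_a %in% ids_a & map$id_b %in% ids_b, c("id_a", "id_b")]
}

#' Direction-concordance filter
#'
#' Retains candidates whose regulation direction agrees in every study
#' where they were significant; candidates significant in a single study
#' pass vacuously.
#'
#' @param candidates data.frame with columns `direction_a`,
#'   `direction_b` (+1 / -1 / NA when not significant in that study).
#' @return the retained subset; removed rows are attached as attribute
#'   `"removed"` with their opposite signs recorded.
#' @export
direction_concordance <- function(candidates) {
  da <- candidates$direction_a
  db <- candidates$direction_b
  if (any(is.na(da) & is.na(db))) {
    stop("every candidate needs a direction in at least one study")
  }
  discordant <- !is.na(da) & !is.na(db) & da != db
  out <- candidates[!discordant, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- candidates[discordant, , drop = FALSE]
  out
}

#' Run the two-study biomarker selection workflow
#'
#' Executes, in order: per-study significant sets (from
#' [discover_markers()] results), cross-study intersection via consensus
#' centroid matching, the temporal response screen of every candidate on
#' the time-course study's dose/day means, combination of both studies'
#' screened candidates, and the direction-concordance filter. An audit
#' trail records, per candidate, which rule admitted or removed it.
#'
#' Candidates are reported in the time-course study's (study B) id space;
#' a study-A marker can only be screened and enter the panel if its
#' consensus peptide matches one in study B.
#'
#' @param disc_a,disc_b [discover_markers()] results for study A (e.g.
#'   cis-platin two-group) and study B (the dosing time course).
#' @param master_a,master_b the corresponding master lists.
#' @param design_b design of the time-course study.
#' @param criteria a [screen_criteria()].
#' @param scheme a [tolerance_scheme()] for cross-study matching.
#' @return object of class `selection_report`: sets at each stage, the
#'   final panel ids (study-B space), and the audit data.frame.
#' @export
build_panel <- function(disc_a, disc_b, master_a, master_b, design_b,
                        criteria = screen_criteria(),
                        scheme = tolerance_scheme()) {
  map <- match_master_lists(master_a, master_b, scheme)
  sig_a <- disc_a$id
  sig_b <- disc_b$id
  inter <- intersect_studies(sig_a, sig_b, map = map)

  ## candidate pool in study-B id space
  a_in_b <- map$id_b[map$id_a %in% sig_a]
  pool <- sort(unique(c(sig_b, a_in_b)))
  means <- day_dose_means(master_b, design_b, ids = pool)

  audit <- do.call(rbind, lapply(pool, function(id) {
    scr <- temporal_response_screen(means[means$id == id, ], criteria)
    ida <- map$id_a[match(id, map$id_b)]
    in_a <- !is.na(ida) && ida %in% sig_a
    in_b <- id %in% sig_b
    data.frame(
      id_b = id, id_a = if (in_a) ida else NA_character_,
      sig_a = in_a, sig_b = in_b,
      in_intersection = in_a && in_b,
      temporal_pass = as.logical(scr),
      peak_ratio = attr(scr, "peak_ratio"),
      late_ratio = attr(scr, "late_ratio"),
      direction_a = if (in_a) disc_a$direction[match(ida, disc_a$id)]
                    else NA_integer_,
      direction_b = if (in_b) disc_b$direction[match(id, disc_b$id)]
                    else NA_integer_,
      stringsAsFactors = FALSE
    )
  }))

  if (is.null(audit) || nrow(audit) == 0) {
    audit <- data.frame(id_b = character(0), id_a = character(0),
                        sig_a = logical(0), sig_b = logical(0),
                        in_intersection = logical(0),
                        temporal_pass = logical(0),
                        peak_ratio = numeric(0), late_ratio = numeric(0),
                        direction_a = integer(0), direction_b = integer(0))
  }

  combined <- audit[audit$temporal_pass, , drop = FALSE]
  conc <- direction_concordance(combined)
  removed <- attr(conc, "removed")

  audit$in_combined <- audit$temporal_pass
  audit$concordant <- !(audit$id_b %in% removed$id_b)
  audit$in_final <- audit$in_combined & audit$concordant
  audit$removal_reason <- ifelse(audit$in_final, NA_character_,
                                 ifelse(!audit$temporal_pass, "temporal",
                                        "discordant"))

  structure(list(
    sig_a = sig_a, sig_b = sig_b,
    intersection = inter,
    pass_a = audit$id_b[audit$sig_a & audit$temporal_pass],
    pass_b = audit$id_b[audit$sig_b & audit$temporal_pass],
    combined = combined$id_b,
    final_panel = audit$id_b[audit$in_final],
    audit = audit,
    criteria = criteria
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n",
      sprintf("  study A significant : %d\n", length(x$sig_a)),
      sprintf("  study B significant : %d\n", length(x$sig_b)),
      sprintf("  intersection        : %d\n", nrow(x$intersection)),
      sprintf("  temporal pass A/B   : %d / %d\n",
              length(x$pass_a), length(x$pass_b)),
      sprintf("  combined candidates : %d\n", length(x$combined)),
      sprintf("  final panel         : %d\n", length(x$final_panel)),
      sep = "")
  invisible(x)
}

#' Write a selection report
#'
#' One row per candidate with each rule outcome, plus a summary sidecar.
#'
#' @param report a `selection_report`.
#' @param path CSV path for the audit table.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  utils::write.csv(report$audit, path, row.names = FALSE)
  invisible(path)
}
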