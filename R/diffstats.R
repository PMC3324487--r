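#' Detection-frequency filter
#'
#' A peptide enters differential testing only if it is detected (nonzero
#' intensity) at a frequency strictly above `threshold` in the case group
#' or in the control group. Peptides failing the filter are excluded
#' before multiplicity correction, so the tested family consists of
#' frequency-surviving peptides only.
#'
#' @param row named numeric intensity vector for one peptide (0 = not
#'   detected), names are sample ids.
#' @param case_ids,control_ids disjoint, nonempty sample id vectors.
#' @param threshold detection fraction in (0, 1); default 0.30.
#' @return logical.
#' @export
frequency_filter <- function(row, case_ids, control_ids, threshold = 0.30) {
  if (length(case_ids) == 0 || length(control_ids) == 0) {
    stop("case and control groups must be nonempty")
  }
  if (length(intersect(case_ids, control_ids)) > 0) {
    stop("case and control groups must be disjoint")
  }
  stopifnot(threshold > 0, threshold < 1)
  f_case <- mean(row[case_ids] > 0)
  f_ctrl <- mean(row[control_ids] > 0)
  f_case > threshold || f_ctrl > threshold
}

#' Two-sample Wilcoxon rank-sum test on ln-transformed intensities
#'
#' Intensities are passed through the classifier's ln-floor transform
#' (values below 1 AU, including undetected zeros, map to ln 1 = 0) so
#' that undetected samples enter the ranking as the minimum tied value.
#' The p-value is exact (by the null rank-sum distribution) when
#' `min(n1, n2) <= 8` and there are no ties, otherwise a midrank normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param case,control numeric intensity vectors (each of length >= 3
#'   after zero handling).
#' @param include_zeros if FALSE, undetected (zero) intensities are
#'   dropped instead of entered as ties (the alternative zero-handling
#'   convention).
#' @return two-sided p-value.
#' @export
wilcoxon_ln <- function(case, control, include_zeros = TRUE) {
  if (!include_zeros) {
    case <- case[case > 0]
    control <- control[control > 0]
  }
  if (length(case) < 3 || length(control) < 3) {
    stop("each group must have at least 3 values")
  }
  x <- log_floor_transform(case)
  y <- log_floor_transform(control)
  if (length(unique(c(x, y))) == 1L) {
    warning("degenerate data: all values identical in both groups")
    return(1)
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && min(n1, n2) <= 8) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    return(min(1, p))
  }
  ## midrank normal approximation, tie-corrected, continuity-corrected
  n <- n1 + n2
  tab <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
  z <- u - n1 * n2 / 2
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted values (monotone in p, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / seq(n, 1) * p[o]))[ro]
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen case value exceeds a randomly
#' chosen control value, with ties counted one half:
#' `U / (n1 * n2)` computed from midranks.
#'
#' @param case,control nonempty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(case, control) {
  n1 <- length(case); n2 <- length(control)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  r <- rank(c(case, control))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Regulation factor
#'
#' Mean case intensity divided by mean control intensity, with undetected
#' samples contributing 0 to the mean and both means floored at `floor`
#' AU so that near-zero control means yield large but finite factors.
#'
#' @param case,control nonempty numeric intensity vectors.
#' @param floor positive intensity floor (default 1 AU, the classifier's
#'   ln-floor).
#' @return positive factor; values > 1 indicate up-regulation.
#' @export
regulation_factor <- function(case, control, floor = 1) {
  stopifnot(length(case) > 0, length(control) > 0, floor > 0)
  max(mean(case), floor) / max(mean(control), floor)
}

#' Per-peptide biomarker discovery
#'
#' For every consensus peptide: apply the detection-frequency filter;
#' for surviving peptides compute the ln-Wilcoxon p-value, adjust across
#' the surviving family by Benjamini-Hochberg, and compute the AUC and
#' regulation factor. Records with `p_adj < alpha` are returned; the full
#' tested table is attached as attribute `"tested"`.
#'
#' @param master a [build_master_list()] result (or any object with an
#'   `intensity` matrix and `peptides` table).
#' @param case_ids,control_ids disjoint sample id vectors, all present in
#'   the master matrix.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param freq_threshold detection-frequency threshold (default 0.30).
#' @param floor regulation-factor floor (default 1 AU).
#' @param include_zeros zero-handling for the rank test, see
#'   [wilcoxon_ln()].
#' @return data.frame of marker records: id, mass_da, time_min, n_case,
#'   n_control (detected counts), p_raw, p_adj, auc, regulation_factor,
#'   direction (+1 up / -1 down).
#' @export
discover_markers <- function(master, case_ids, control_ids,
                             alpha = 0.05, freq_threshold = 0.30,
                             floor = 1, include_zeros = TRUE) {
  mat <- master$intensity
  missing <- setdiff(c(case_ids, control_ids), colnames(mat))
  if (length(case_ids) == 0 || length(control_ids) == 0 ||
      length(missing) > 0) {
    stop("case/control selectors must match samples in the master list",
         if (length(missing)) paste0(" (missing: ",
                                     paste(missing, collapse = ", "), ")"))
  }
  keep <- apply(mat, 1, frequency_filter, case_ids = case_ids,
                control_ids = control_ids, threshold = freq_threshold)
  ids <- rownames(mat)[keep]
  if (length(ids) == 0) {
    empty <- data.frame(id = character(0), mass_da = numeric(0),
                        time_min = numeric(0), n_case = integer(0),
                        n_control = integer(0), p_raw = numeric(0),
                        p_adj = numeric(0), auc = numeric(0),
                        regulation_factor = numeric(0), direction = integer(0))
    attr(empty, "tested") <- empty
    return(empty)
  }
  p_raw <- vapply(ids, function(i) {
    wilcoxon_ln(mat[i, case_ids], mat[i, control_ids],
                include_zeros = include_zeros)
  }, numeric(1))
  p_adj <- bh_adjust(p_raw)
  auc <- vapply(ids, function(i) {
    auc_mw(log_floor_transform(mat[i, case_ids]),
           log_floor_transform(mat[i, control_ids]))
  }, numeric(1))
  rf <- vapply(ids, function(i) {
    regulation_factor(mat[i, case_ids], mat[i, control_ids], floor = floor)
  }, numeric(1))
  pep <- master$peptides[match(ids, master$peptides$id), ]
  tested <- data.frame(
    id = ids,
    mass_da = pep$mass_da, time_min = pep$time_min,
    n_case = vapply(ids, function(i) sum(mat[i, case_ids] > 0), integer(1)),
    n_control = vapply(ids, function(i) sum(mat[i, control_ids] > 0),
                       integer(1)),
    p_raw = p_raw, p_adj = p_adj, auc = auc, regulation_factor = rf,
    direction = ifelse(rf >= 1, 1L, -1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- tested[tested$p_adj < alpha, ]
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}

#' Mean intensity per dose x day cell
#'
#' Cell means over all samples in each dose/day cell of a design, with
#' undetected samples contributing 0. Used by the temporal response
#' screen and for plotting marker time courses.
#'
#' @param master a master list (or object with an `intensity` matrix).
#' @param design design data.frame with sample_id, dose_mg_kg, day.
#' @param ids peptide ids to summarize (default all).
#' @return data.frame with columns id, dose, day, n, mean_intensity.
#' @export
day_dose_means <- function(master, design, ids = rownames(master$intensity)) {
  mat <- master$intensity
  design <- design[design$sample_id %in% colnames(mat), ]
  cells <- unique(design[, c("dose_mg_kg", "day")])
  cells <- cells[order(cells$dose_mg_kg, cells$day), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    sel <- design$sample_id[design$dose_mg_kg == cells$dose_mg_kg[k] &
                              design$day == cells$day[k]]
    data.frame(id = ids, dose = cells$dose_mg_kg[k], day = cells$day[k],
               n = length(sel),
               mean_intensity = rowMeans(mat[ids, sel, drop = FALSE]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}
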