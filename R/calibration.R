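#' Reference peptide set for calibration
#'
#' Housekeeping peptides (stable landmarks with known mass and migration
#' time) anchor mass and migration-time calibration; internal-standard
#' peptides (highly abundant, stable species with a reference intensity)
#' anchor amplitude normalization, correcting analytical and dilution
#' variance.
#'
#' @param housekeeping data.frame with columns `mass_da`, `time_min`.
#' @param standards data.frame with columns `mass_da`, `time_min`,
#'   `intensity_ref` (> 0).
#' @return an object of class `reference_set`.
#' @export
reference_set <- function(housekeeping, standards) {
  housekeeping <- as.data.frame(housekeeping)
  standards <- as.data.frame(standards)
  stopifnot(all(c("mass_da", "time_min") %in% names(housekeeping)),
            all(c("mass_da", "time_min", "intensity_ref") %in% names(standards)))
  if (any(standards$intensity_ref <= 0)) {
    stop("reference intensities must be > 0")
  }
  if (any(housekeeping$mass_da <= 0) || any(housekeeping$time_min <= 0) ||
      any(standards$mass_da <= 0) || any(standards$time_min <= 0)) {
    stop("reference masses and times must be > 0")
  }
  structure(list(housekeeping = housekeeping, standards = standards),
            class = "reference_set")
}

#' @rdname reference_set
#' @param path CSV path. The file has columns `role` (housekeeping /
#'   internal_standard), `mass_da`, `time_min`, `intensity_ref`.
#' @export
read_reference_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reference_set(
    housekeeping = df[df$role == "housekeeping",
                      c("mass_da", "time_min")],
    standards = df[df$role == "internal_standard",
                   c("mass_da", "time_min", "intensity_ref")]
  )
}

#' @rdname reference_set
#' @param refs a `reference_set`.
#' @export
write_reference_set <- function(refs, path) {
  hk <- cbind(role = "housekeeping", refs$housekeeping, intensity_ref = NA)
  is <- cbind(role = "internal_standard", refs$standards)
  utils::write.csv(rbind(hk, is), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Match reference peptides to sample features using wide pre-calibration
## windows (+/-300 ppm, +/-5 min), nearest neighbour by smallest combined
## normalized deviation. Returns indices into `refs_df` and the sample's
## feature table.
match_references <- function(sample, refs_df,
                             ppm_window = 300, time_window = 5) {
  f <- sample$features
  ref_idx <- integer(0)
  feat_idx <- integer(0)
  for (i in seq_len(nrow(refs_df))) {
    dm <- abs(f$mass_da - refs_df$mass_da[i]) /
      (refs_df$mass_da[i] * 1e-6)          # ppm
    dt <- abs(f$time_min - refs_df$time_min[i])
    d <- pmax(dm / ppm_window, dt / time_window)
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= 1) {
      ref_idx <- c(ref_idx, i)
      feat_idx <- c(feat_idx, j)
    }
  }
  list(ref = ref_idx, feature = feat_idx)
}

#' Fit the migration-time calibration for one sample
#'
#' Matches housekeeping reference peptides to the sample's features within
#' generous pre-calibration windows and fits, by least squares, the affine
#' map from observed to reference migration time. Applying the map yields
#' calibrated times. With `local = TRUE` a windowed-linear (lowess)
#' refinement of the residuals is added on top of the global fit.
#'
#' @param sample a [peak_sample()].
#' @param refs a [reference_set()].
#' @param min_refs minimum matched housekeeping peptides (default 5).
#' @param local logical; add a local residual-smoothing refinement.
#' @return object of class `time_calibration` with elements `slope`,
#'   `offset` (the correction map `t_cal = offset + slope * t_obs`),
#'   `distortion` (the implied injected affine distortion, i.e. the
#'   inverse map), `n_refs`, and optionally `local` smoothing points.
#' @export
fit_time_calibration <- function(sample, refs, min_refs = 5, local = FALSE) {
  stopifnot(inherits(sample, "peak_sample"), inherits(refs, "reference_set"))
  m <- match_references(sample, refs$housekeeping)
  if (length(m$ref) < min_refs) {
    stop("time calibration failure for sample ", sample$sample_id,
         ": only ", length(m$ref), " housekeeping references matched (need ",
         min_refs, ")")
  }
  t_obs <- sample$features$time_min[m$feature]
  t_ref <- refs$housekeeping$time_min[m$ref]
  fit <- stats::lm.fit(cbind(1, t_obs), t_ref)
  offset <- fit$coefficients[1]
  slope <- fit$coefficients[2]
  loc <- NULL
  if (local && length(t_obs) >= 10) {
    resid <- t_ref - (offset + slope * t_obs)
    loc <- stats::lowess(t_obs, resid, f = 2 / 3)
  }
  structure(list(
    slope = unname(slope), offset = unname(offset),
    distortion = c(slope = unname(1 / slope),
                   offset = unname(-offset / slope)),
    n_refs = length(t_obs), local = loc
  ), class = "time_calibration")
}

#' @rdname fit_time_calibration
#' @param cal a fitted `time_calibration`.
#' @param time numeric times to calibrate.
#' @export
apply_time_calibration <- function(cal, time) {
  out <- cal$offset + cal$slope * time
  if (!is.null(cal$local)) {
    out <- out + stats::approx(cal$local$x, cal$local$y, xout = time,
                               rule = 2)$y
  }
  out
}

#' Fit the mass calibration for one sample
#'
#' Matches housekeeping reference peptides and regresses the relative mass
#' error (ppm) on observed mass (global linear fit). The correction
#' removes the fitted mass-dependent ppm bias.
#'
#' @inheritParams fit_time_calibration
#' @return object of class `mass_calibration` with elements `ppm_offset`
#'   (intercept, ppm), `ppm_slope` (ppm per Da) and `n_refs`.
#' @export
fit_mass_calibration <- function(sample, refs, min_refs = 5) {
  stopifnot(inherits(sample, "peak_sample"), inherits(refs, "reference_set"))
  m <- match_references(sample, refs$housekeeping)
  if (length(m$ref) < min_refs) {
    stop("mass calibration failure for sample ", sample$sample_id,
         ": only ", length(m$ref), " housekeeping references matched (need ",
         min_refs, ")")
  }
  m_obs <- sample$features$mass_da[m$feature]
  m_ref <- refs$housekeeping$mass_da[m$ref]
  ppm <- (m_obs - m_ref) / m_ref * 1e6
  fit <- stats::lm.fit(cbind(1, m_obs), ppm)
  structure(list(
    ppm_offset = unname(fit$coefficients[1]),
    ppm_slope = unname(fit$coefficients[2]),
    n_refs = length(m_obs)
  ), class = "mass_calibration")
}

#' @rdname fit_mass_calibration
#' @param cal a fitted `mass_calibration`.
#' @param mass numeric masses (Da) to calibrate.
#' @export
apply_mass_calibration <- function(cal, mass) {
  mass / (1 + (cal$ppm_offset + cal$ppm_slope * mass) * 1e-6)
}

#' Normalize a sample's intensities against internal standards
#'
#' Matches the internal-standard peptides and fits, through the origin,
#' the global linear factor relating observed standard intensities to
#' their reference intensities; all intensities in the sample are rescaled
#' by that factor. A single positive multiplicative factor is used because
#' urine dilution acts multiplicatively; rank order of intensities is
#' therefore preserved.
#'
#' @inheritParams fit_time_calibration
#' @param min_refs minimum matched internal standards (default 5).
#' @return the rescaled [peak_sample()]; the factor is attached as
#'   attribute `"scale"`.
#' @export
normalize_intensities <- function(sample, refs, min_refs = 5) {
  stopifnot(inherits(sample, "peak_sample"), inherits(refs, "reference_set"))
  m <- match_references(sample, refs$standards)
  if (length(m$ref) < min_refs) {
    stop("intensity normalization failure for sample ", sample$sample_id,
         ": only ", length(m$ref), " internal standards matched (need ",
         min_refs, ")")
  }
  obs <- sample$features$intensity[m$feature]
  ref <- refs$standards$intensity_ref[m$ref]
  s <- sum(obs * ref) / sum(obs^2)  # least-squares slope through origin
  out <- sample
  out$features$intensity <- out$features$intensity * s
  attr(out, "scale") <- s
  out
}

#' Calibrate one sample end to end
#'
#' Fits and applies migration-time calibration, mass calibration and
#' internal-standard intensity normalization, and marks the sample
#' calibrated. The fitted maps are attached as attribute `"calibration"`.
#'
#' @inheritParams fit_time_calibration
#' @param min_refs minimum matched references for each fit.
#' @return a calibrated [peak_sample()].
#' @export
calibrate_sample <- function(sample, refs, min_refs = 5, local = FALSE) {
  tc <- fit_time_calibration(sample, refs, min_refs = min_refs, local = local)
  mc <- fit_mass_calibration(sample, refs, min_refs = min_refs)
  out <- sample
  out$features$time_min <- apply_time_calibration(tc, out$features$time_min)
  out$features$mass_da <- apply_mass_calibration(mc, out$features$mass_da)
  out <- normalize_intensities(out, refs, min_refs = min_refs)
  sc <- attr(out, "scale")
  out$calibrated <- TRUE
  attr(out, "calibration") <- list(time = tc, mass = mc, scale = sc)
  out
}

#' @rdname calibrate_sample
#' @param samples a list of [peak_sample()] objects.
#' @export
calibrate_cohort <- function(samples, refs, min_refs = 5, local = FALSE) {
  lapply(samples, calibrate_sample, refs = refs, min_refs = min_refs,
         local = local)
}
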