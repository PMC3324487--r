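#' Configuration for a synthetic CE-MS cohort
#'
#' Describes the "stated world" of a simulated nephrotoxin study: a peptide
#' universe with planted up/down-regulated markers, a dose/day sampling
#' grid, a transient temporal effect profile, internal-standard and
#' housekeeping peptides, per-sample dilution and migration-time
#' distortions, ppm-scale mass noise and random missingness.
#'
#' Defaults emulate the gentamicin arm of a rat nephrotoxicity study:
#' doses 0/150/300 mg/kg, collection days 1,2,3,7,10,15,18,22,29,36,44
#' with 3 animals per dose, a maximal response plateau over days 3-10 and
#' resolution by day 29, and 37 internal-standard peptides.
#'
#' @param n_peptides number of assay peptides (markers included).
#' @param n_markers_up,n_markers_down planted marker counts.
#' @param doses dose levels in mg/kg (0 = control).
#' @param days collection days after first dose.
#' @param n_per_cell animals per dose level (each sampled at every day).
#' @param effect_size log-scale group separation at full effect, in units
#'   of `noise_sd`.
#' @param noise_sd SD of ln-intensity biological + technical noise.
#' @param peak_window `c(day_start, day_end)` of maximal effect.
#' @param resolve_day day by which treated means return to control level
#'   (effect share decayed to 5 percent of maximum).
#' @param mass_range,time_range instrument ranges, Da and min.
#' @param ppm_noise_sd SD of multiplicative mass error, ppm.
#' @param time_noise_sd SD of migration-time jitter, min.
#' @param time_distortion `c(slope_jitter, offset_min)`: each sample's
#'   times are passed through an affine map with slope drawn uniformly in
#'   `1 +/- slope_jitter` and offset uniform in `+/- offset_min`.
#' @param intensity_scale_sd SD of the per-sample ln dilution factor.
#' @param missing_rate probability a true feature goes undetected
#'   (never applied to internal standards).
#' @param rescue_upregulated logical; if TRUE, up-regulated markers in
#'   affected samples are less likely to go missing (detectability rises
#'   with abundance).
#' @param n_internal_standards,n_housekeeping reference peptide counts.
#' @param is_noise_sd SD of ln-intensity noise for internal-standard and
#'   housekeeping peptides (stable, abundant species).
#' @param seed integer RNG seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_peptides = 200,
                         n_markers_up = 20,
                         n_markers_down = 10,
                         doses = c(0, 150, 300),
                         days = c(1, 2, 3, 7, 10, 15, 18, 22, 29, 36, 44),
                         n_per_cell = 3,
                         effect_size = 4,
                         noise_sd = 0.5,
                         peak_window = c(3, 10),
                         resolve_day = 29,
                         mass_range = c(800, 8000),
                         time_range = c(19, 50),
                         ppm_noise_sd = 10,
                         time_noise_sd = 0.1,
                         time_distortion = c(0.05, 1),
                         intensity_scale_sd = 0.3,
                         missing_rate = 0.1,
                         rescue_upregulated = FALSE,
                         n_internal_standards = 37,
                         n_housekeeping = 30,
                         is_noise_sd = 0.1,
                         seed = 1L) {
  cfg <- list(
    n_peptides = n_peptides, n_markers_up = n_markers_up,
    n_markers_down = n_markers_down, doses = doses, days = days,
    n_per_cell = n_per_cell, effect_size = effect_size,
    noise_sd = noise_sd, peak_window = peak_window,
    resolve_day = resolve_day, mass_range = mass_range,
    time_range = time_range, ppm_noise_sd = ppm_noise_sd,
    time_noise_sd = time_noise_sd, time_distortion = time_distortion,
    intensity_scale_sd = intensity_scale_sd, missing_rate = missing_rate,
    rescue_upregulated = rescue_upregulated,
    n_internal_standards = n_internal_standards,
    n_housekeeping = n_housekeeping, is_noise_sd = is_noise_sd,
    seed = as.integer(seed)
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  pos_counts <- c("n_peptides", "n_per_cell", "n_internal_standards",
                  "n_housekeeping")
  for (f in pos_counts) {
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1) {
      stop("invalid study_config: ", f, " must be a positive count")
    }
  }
  for (f in c("n_markers_up", "n_markers_down")) {
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      stop("invalid study_config: ", f, " must be a non-negative count")
    }
  }
  if (cfg$n_markers_up + cfg$n_markers_down > cfg$n_peptides) {
    stop("invalid study_config: n_markers_up + n_markers_down exceeds n_peptides")
  }
  if (length(cfg$peak_window) != 2 || diff(cfg$peak_window) < 0) {
    stop("invalid study_config: peak_window must be c(start, end)")
  }
  dspan <- range(cfg$days)
  if (cfg$peak_window[1] < 0 || cfg$peak_window[2] > dspan[2]) {
    stop("invalid study_config: peak_window outside the span of days")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("invalid study_config: missing_rate must be in [0, 1)")
  }
  if (any(cfg$days < 0)) stop("invalid study_config: days must be >= 0")
  if (cfg$effect_size < 0) stop("invalid study_config: effect_size must be >= 0")
  if (cfg$noise_sd <= 0) stop("invalid study_config: noise_sd must be > 0")
  if (cfg$resolve_day <= cfg$peak_window[2]) {
    stop("invalid study_config: resolve_day must exceed the peak window")
  }
  invisible(cfg)
}

#' Temporal effect profile of a transient nephrotoxic insult
#'
#' Dimensionless share of the maximal treatment effect as a function of
#' collection day: zero at day 0 (pre-treatment), linear rise to the start
#' of the peak window, a flat plateau across the peak window, then
#' exponential decay calibrated so the share is exactly 0.05 at
#' `resolve_day` (and below 0.05 thereafter).
#'
#' @param day collection day(s), must be >= 0.
#' @param config a [study_config()] supplying `peak_window` and
#'   `resolve_day`.
#' @return numeric vector of multipliers in \[0, 1\].
#' @export
temporal_profile <- function(day, config) {
  if (any(day < 0)) stop("day must be >= 0")
  p1 <- config$peak_window[1]
  p2 <- config$peak_window[2]
  lambda <- -log(0.05) / (config$resolve_day - p2)
  out <- numeric(length(day))
  rise <- day > 0 & day < p1
  out[rise] <- day[rise] / p1
  out[day >= p1 & day <= p2] <- 1
  dec <- day > p2
  out[dec] <- exp(-lambda * (day[dec] - p2))
  out
}

## ---- internal simulation machinery ----------------------------------------

## Draw a peptide universe (assay + internal-standard + housekeeping
## peptides) with masses/times separated by several matching windows so
## that distinct true peptides cannot collide in the master list.
make_universe <- function(cfg) {
  n_total <- cfg$n_peptides + cfg$n_internal_standards + cfg$n_housekeeping
  mass <- numeric(n_total)
  time <- numeric(n_total)
  k <- 0
  sep <- 6  # minimum separation in tolerance units
  while (k < n_total) {
    m <- stats::runif(1, cfg$mass_range[1], cfg$mass_range[2])
    t <- stats::runif(1, cfg$time_range[1], cfg$time_range[2])
    if (k > 0) {
      dm <- abs(mass[seq_len(k)] - m) / (m * mass_tolerance(m) * 1e-6)
      dt <- abs(time[seq_len(k)] - t) / time_tolerance(t)
      if (min(pmax(dm, dt)) < sep) next
    }
    k <- k + 1
    mass[k] <- m
    time[k] <- t
  }
  kind <- c(rep("assay", cfg$n_peptides),
            rep("internal_standard", cfg$n_internal_standards),
            rep("housekeeping", cfg$n_housekeeping))
  ## markers among assay peptides
  dir <- rep(0L, n_total)
  mk <- sample.int(cfg$n_peptides, cfg$n_markers_up + cfg$n_markers_down)
  if (cfg$n_markers_up > 0) dir[mk[seq_len(cfg$n_markers_up)]] <- 1L
  if (cfg$n_markers_down > 0) {
    dir[mk[cfg$n_markers_up + seq_len(cfg$n_markers_down)]] <- -1L
  }
  kind[dir == 1L] <- "marker_up"
  kind[dir == -1L] <- "marker_down"
  ## ln-baselines: assay log-uniform over [10, 1e4] AU; reference peptides
  ## abundant (upper decade) so they are reliably matched.
  base_ln <- stats::runif(n_total, log(10), log(1e4))
  ref <- kind %in% c("internal_standard", "housekeeping")
  base_ln[ref] <- stats::runif(sum(ref), log(1e3), log(1e4))
  data.frame(
    id = sprintf("P%04d", seq_len(n_total)),
    mass_da = mass, time_min = time, base_ln = base_ln,
    kind = kind, direction = dir,
    stringsAsFactors = FALSE
  )
}

## Simulate one set of samples over a fixed universe. `meta` must have
## columns sample_id, animal_id, compound, dose_mg_kg, day, group and
## effect_share (share of the maximal marker effect for that sample).
simulate_samples <- function(universe, meta, cfg) {
  n_pep <- nrow(universe)
  is_is <- universe$kind == "internal_standard"
  is_ref <- is_is | universe$kind == "housekeeping"
  shift_unit <- cfg$effect_size * cfg$noise_sd
  sj <- cfg$time_distortion[1]
  oj <- cfg$time_distortion[2]

  samples <- vector("list", nrow(meta))
  mat <- matrix(0, n_pep, nrow(meta),
                dimnames = list(universe$id, meta$sample_id))
  scales <- numeric(nrow(meta))
  slopes <- numeric(nrow(meta))
  offsets <- numeric(nrow(meta))

  for (k in seq_len(nrow(meta))) {
    share <- meta$effect_share[k]
    mu <- universe$base_ln + universe$direction * shift_unit * share
    sd_vec <- ifelse(is_ref, cfg$is_noise_sd, cfg$noise_sd)
    ln_int <- stats::rnorm(n_pep, mu, sd_vec)
    intensity <- exp(ln_int)

    ## missingness: independent Bernoulli, never internal standards;
    ## optionally rescued for up-regulated markers at high abundance
    p_miss <- rep(cfg$missing_rate, n_pep)
    if (cfg$rescue_upregulated) {
      up <- universe$direction == 1L
      p_miss[up] <- cfg$missing_rate * (1 - 0.8 * share)
    }
    p_miss[is_is] <- 0
    detected <- stats::runif(n_pep) >= p_miss

    scale_k <- exp(stats::rnorm(1, 0, cfg$intensity_scale_sd))
    slope_k <- stats::runif(1, 1 - sj, 1 + sj)
    offset_k <- stats::runif(1, -oj, oj)
    scales[k] <- scale_k; slopes[k] <- slope_k; offsets[k] <- offset_k

    obs_mass <- universe$mass_da *
      (1 + stats::rnorm(n_pep, 0, cfg$ppm_noise_sd) * 1e-6)
    obs_time <- slope_k *
      (universe$time_min + stats::rnorm(n_pep, 0, cfg$time_noise_sd)) +
      offset_k

    feats <- data.frame(
      mass_da = obs_mass[detected],
      time_min = obs_time[detected],
      intensity = intensity[detected] * scale_k
    )
    samples[[k]] <- peak_sample(meta$sample_id[k], feats)
    mat[detected, k] <- intensity[detected]
  }

  truth <- list(
    peptides = universe,
    marker_ids = universe$id[universe$direction != 0L],
    directions = stats::setNames(universe$direction[universe$direction != 0L],
                                 universe$id[universe$direction != 0L]),
    internal_standard_ids = universe$id[is_is],
    housekeeping_ids = universe$id[universe$kind == "housekeeping"],
    sample_effects = data.frame(
      sample_id = meta$sample_id, effect_share = meta$effect_share,
      intensity_scale = scales, time_slope = slopes, time_offset = offsets,
      stringsAsFactors = FALSE
    ),
    matrix_true = mat
  )
  list(samples = samples, truth = truth)
}

## Reference set derived from the generated universe: housekeeping peptides
## anchor mass/time calibration, internal standards anchor amplitude.
truth_reference_set <- function(universe) {
  hk <- universe[universe$kind == "housekeeping", ]
  is <- universe[universe$kind == "internal_standard", ]
  reference_set(
    housekeeping = data.frame(mass_da = hk$mass_da, time_min = hk$time_min),
    standards = data.frame(mass_da = is$mass_da, time_min = is$time_min,
                           intensity_ref = exp(is$base_ln))
  )
}

#' Generate a synthetic dosing-time-course study
#'
#' Simulates one urine peak list per animal x collection-day cell of the
#' configured dose/day grid. Planted marker peptides have their
#' ln-intensity means shifted by `direction x effect_size x noise_sd`,
#' scaled by the dose (linear in dose relative to the top dose) and by the
#' transient [temporal_profile()]. Internal-standard and housekeeping
#' peptides are never shifted. Each sample receives its own multiplicative
#' intensity (dilution) factor, affine migration-time distortion and
#' ppm-scale mass noise; features are then dropped independently at
#' `missing_rate` (never internal standards).
#'
#' @param config a [study_config()].
#' @return a list with components:
#' \describe{
#'   \item{samples}{list of uncalibrated [peak_sample()] objects.}
#'   \item{design}{cohort design data.frame (sample_id, animal_id,
#'     compound, dose_mg_kg, day, group).}
#'   \item{truth}{ground-truth ledger: peptide universe with planted
#'     directions, per-sample injected distortions and scale factors,
#'     reference ids, and `matrix_true`, the peptide x sample intensity
#'     matrix a perfect calibration + matching would recover (0 = not
#'     detected).}
#'   \item{refs}{the matching [reference_set()] for calibration.}
#' }
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  universe <- make_universe(config)

  grid <- expand.grid(rep = seq_len(config$n_per_cell),
                      day = config$days, dose = config$doses,
                      KEEP.OUT.ATTRS = FALSE)
  top <- max(config$doses)
  dose_scale <- if (top > 0) grid$dose / top else rep(0, nrow(grid))
  meta <- data.frame(
    sample_id = sprintf("S_d%03d_t%02d_r%d", grid$dose, grid$day, grid$rep),
    animal_id = sprintf("A_d%03d_r%d", grid$dose, grid$rep),
    compound = "gentamicin",
    dose_mg_kg = grid$dose,
    day = grid$day,
    group = ifelse(grid$dose > 0, "treated", "control"),
    effect_share = dose_scale * temporal_profile(grid$day, config),
    stringsAsFactors = FALSE
  )

  sim <- simulate_samples(universe, meta, config)
  design <- meta[, c("sample_id", "animal_id", "compound",
                     "dose_mg_kg", "day", "group")]
  sim$truth$config <- config
  list(samples = sim$samples, design = design, truth = sim$truth,
       refs = truth_reference_set(universe))
}

#' Generate a synthetic two-group (case/control) study
#'
#' Emulates a cis-platin-style discovery cohort: `n_control` untreated and
#' `n_case` treated samples at full effect (effect share 1), sharing the
#' peptide universe machinery of [generate_study()]. Group sizes may be
#' unequal (the emulated training design is 14 controls vs 25 treated).
#'
#' @param n_control,n_case group sizes.
#' @param config a [study_config()]; its dose/day grid is ignored, all
#'   other fields (universe, noise, distortions, missingness) apply.
#' @param compound label recorded in the design table.
#' @param flip_directions ids of planted markers whose regulation
#'   direction is negated in this study (used to plant cross-study
#'   direction-discordant peptides).
#' @return same structure as [generate_study()].
#' @export
generate_two_group <- function(n_control = 14, n_case = 25,
                               config = study_config(),
                               compound = "cis-platin",
                               flip_directions = character(0)) {
  stopifnot(inherits(config, "study_config"), n_control >= 1, n_case >= 1)
  set.seed(config$seed)
  universe <- make_universe(config)
  if (length(flip_directions) > 0) {
    idx <- universe$id %in% flip_directions & universe$direction != 0L
    universe$direction[idx] <- -universe$direction[idx]
    universe$kind[idx] <- ifelse(universe$direction[idx] == 1L,
                                 "marker_up", "marker_down")
  }
  n <- n_control + n_case
  treated <- c(rep(FALSE, n_control), rep(TRUE, n_case))
  meta <- data.frame(
    sample_id = sprintf("S_%s_%02d", ifelse(treated, "case", "ctrl"),
                        c(seq_len(n_control), seq_len(n_case))),
    animal_id = sprintf("A%03d", seq_len(n)),
    compound = compound,
    dose_mg_kg = ifelse(treated, 6, 0),
    day = 3,
    group = ifelse(treated, "treated", "control"),
    effect_share = as.numeric(treated),
    stringsAsFactors = FALSE
  )
  sim <- simulate_samples(universe, meta, config)
  design <- meta[, c("sample_id", "animal_id", "compound",
                     "dose_mg_kg", "day", "group")]
  sim$truth$config <- config
  list(samples = sim$samples, design = design, truth = sim$truth,
       refs = truth_reference_set(universe))
}

#' Generate synthetic histopathology / clinical chemistry endpoints
#'
#' Produces a per-sample endpoint table driven by the same latent injury
#' signal that drives the planted markers (dose share x temporal profile),
#' plus endpoint-specific noise. Histology scores are ordinal 0-4; BUN and
#' serum creatinine are only mildly elevated (the emulated studies found
#' classical serum markers insensitive); urinary albumin responds more
#' strongly.
#'
#' @param design a design data.frame from [generate_study()].
#' @param config the [study_config()] used to generate the cohort.
#' @param seed RNG seed (separate from the cohort seed so endpoints can be
#'   regenerated independently).
#' @return data.frame with sample_id, histopathology/necrosis/apoptosis/
#'   regeneration scores, BUN, serum_creatinine, albumin.
#' @export
generate_endpoints <- function(design, config, seed = config$seed + 1L) {
  set.seed(seed)
  top <- max(design$dose_mg_kg)
  share <- if (top > 0) design$dose_mg_kg / top else rep(0, nrow(design))
  injury <- share * temporal_profile(design$day, config)
  n <- nrow(design)
  ord_score <- function(injury, noise_sd) {
    raw <- 4 * injury + stats::rnorm(n, 0, noise_sd)
    pmin(4, pmax(0, round(raw)))
  }
  data.frame(
    sample_id = design$sample_id,
    histopathology_score = ord_score(injury, 0.5),
    necrosis_score = ord_score(injury, 0.6),
    apoptosis_score = ord_score(injury, 0.6),
    regeneration_score = ord_score(injury * 0.7, 0.6),
    bun = 20 * (1 + 0.3 * injury) * exp(stats::rnorm(n, 0, 0.1)),
    serum_creatinine = 0.5 * (1 + 0.2 * injury) * exp(stats::rnorm(n, 0, 0.1)),
    albumin = 1 * (1 + 2 * injury) * exp(stats::rnorm(n, 0, 0.3)),
    stringsAsFactors = FALSE
  )
}

#' Write a generated study to disk
#'
#' Peak lists as one TSV per sample, the design as CSV, the reference set
#' as CSV and the ground truth as JSON.
#'
#' @param study result of [generate_study()] or [generate_two_group()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in study$samples) {
    write_peak_list(s, file.path(dir, paste0(s$sample_id, ".tsv")))
  }
  write_design(study$design, file.path(dir, "design.csv"))
  write_reference_set(study$refs, file.path(dir, "references.csv"))
  truth <- study$truth
  truth$matrix_true <- NULL  # large; reproducible from config
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
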