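## Average residue masses (Da). Lowercase codes are the urinary-peptidome
## modification conventions: p = hydroxyproline, k = hydroxylysine,
## m = oxidized methionine (each +O on the parent residue).
AA_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
MOD_MASS <- c(p = AA_MASS[["P"]] + 15.9994,
              k = AA_MASS[["K"]] + 15.9994,
              m = AA_MASS[["M"]] + 15.9994)
WATER_MASS <- 18.0153

split_sequence <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, c(names(AA_MASS), names(MOD_MASS)))
  if (length(bad) > 0) {
    stop("unknown residue code(s) in sequence: ",
         paste(unique(bad), collapse = ", "))
  }
  chars
}

#' Count basic residues in a peptide sequence
#'
#' Basic residues carry positive charge at the CE working pH of 2:
#' lysine (K, including hydroxylysine k), arginine (R) and histidine
#' (H). The N-terminal amine contributes identically for all peptides
#' and is absorbed into the migration model's stratum intercepts, so it
#' is not counted here. Modification codes p and m are non-basic.
#'
#' @param sequence peptide sequence over the 20 amino acids plus the
#'   modification codes p, k, m.
#' @return integer count.
#' @export
count_basic_residues <- function(sequence) {
  chars <- split_sequence(sequence)
  sum(chars %in% c("K", "R", "H", "k"))
}

#' Theoretical peptide mass from average residue masses
#'
#' @inheritParams count_basic_residues
#' @return mass in Da (average-mass scale; used for synthetic fixtures
#'   and plausibility gates, not for isotope-resolved work).
#' @export
peptide_mass <- function(sequence) {
  chars <- split_sequence(sequence)
  masses <- ifelse(chars %in% names(MOD_MASS),
                   MOD_MASS[chars], AA_MASS[chars])
  sum(masses) + WATER_MASS
}

#' Build a sequence-annotation table
#'
#' @param sequence peptide sequences (modification codes allowed).
#' @param protein parent protein names.
#' @param start,stop first/last residue positions in the parent protein.
#' @param mass_da theoretical masses; computed with [peptide_mass()] when
#'   omitted.
#' @return data.frame of class `sequence_annotation` with an `n_basic`
#'   column.
#' @export
sequence_annotation <- function(sequence, protein, start, stop,
                                mass_da = NULL) {
  stopifnot(length(sequence) == length(protein))
  start <- rep_len(start, length(sequence))
  stop <- rep_len(stop, length(sequence))
  if (any(start >= stop)) stop("start must be < stop")
  len <- vapply(sequence, function(s) length(split_sequence(s)), integer(1))
  if (any(len != stop - start + 1)) {
    stop("sequence length must equal stop - start + 1")
  }
  if (is.null(mass_da)) {
    mass_da <- vapply(sequence, peptide_mass, numeric(1))
  }
  out <- data.frame(
    sequence = sequence, protein = protein, start = start, stop = stop,
    mass_da = unname(mass_da),
    n_basic = vapply(sequence, count_basic_residues, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("sequence_annotation", "data.frame")
  out
}

#' Fit the charge-stratified migration-time model
#'
#' At pH 2 a peptide's CE mobility is governed by its charge (number of
#' basic residues plus the common N-terminal amine) and its size. Within
#' each basic-residue stratum the migration time is regressed linearly
#' on log(mass); the fitted family predicts migration time for new
#' (mass, n_basic) pairs and anchors the plausibility gate on sequence
#' assignments.
#'
#' @param peptides data.frame with columns `mass_da`, `time_min` and
#'   either `n_basic` or `sequence`. Needs >= 10 peptides spanning >= 2
#'   basic-residue counts; strata with < 3 points are excluded with a
#'   warning.
#' @return object of class `migration_model`: per-stratum coefficients
#'   and residual SD.
#' @export
fit_migration_model <- function(peptides) {
  df <- as.data.frame(peptides)
  if (is.null(df$n_basic)) {
    if (is.null(df$sequence)) stop("need an n_basic or sequence column")
    df$n_basic <- vapply(df$sequence, count_basic_residues, integer(1))
  }
  if (nrow(df) < 10) stop("need >= 10 training peptides")
  if (length(unique(df$n_basic)) < 2) {
    stop("training peptides must span >= 2 basic-residue counts")
  }
  strata <- sort(unique(df$n_basic))
  fits <- list()
  for (b in strata) {
    sub <- df[df$n_basic == b, ]
    if (nrow(sub) < 3) {
      warning("stratum n_basic = ", b, " has < 3 peptides; excluded")
      next
    }
    fit <- stats::lm(time_min ~ log(mass_da), data = sub)
    fits[[as.character(b)]] <- list(
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      resid_sd = stats::sd(stats::residuals(fit)),
      n = nrow(sub)
    )
  }
  if (length(fits) == 0) stop("no stratum has >= 3 peptides")
  structure(list(strata = fits), class = "migration_model")
}

#' @rdname fit_migration_model
#' @param model a fitted `migration_model`.
#' @param mass_da,n_basic vectors of masses and basic-residue counts.
#' @return predicted migration times (NA, with a warning, for strata
#'   absent from the training data).
#' @export
predict_migration <- function(model, mass_da, n_basic) {
  stopifnot(inherits(model, "migration_model"))
  key <- as.character(n_basic)
  out <- rep(NA_real_, length(mass_da))
  for (i in seq_along(mass_da)) {
    st <- model$strata[[key[i]]]
    if (is.null(st)) {
      warning("no migration stratum for n_basic = ", n_basic[i])
      next
    }
    out[i] <- st$intercept + st$slope * log(mass_da[i])
  }
  out
}

#' Final acceptance gate on a sequence assignment
#'
#' A candidate sequence assignment for an observed (mass, time) feature
#' is accepted only if: the observed mass is within `mass_tol_ppm` of
#' the theoretical mass, the observed (calibrated) migration time is
#' within `time_tol_min` of the charge-model prediction, and the
#' candidate was found by both database search engines (the engine
#' agreement flag is an input; searching itself is out of scope).
#'
#' @param observed_mass observed mass, Da.
#' @param observed_time observed calibrated migration time, min.
#' @param annotation one-row [sequence_annotation()] (or a list with
#'   `mass_da` and `sequence` / `n_basic`).
#' @param model a fitted [fit_migration_model()].
#' @param both_engines logical; TRUE when both search engines reported
#'   the peptide.
#' @param mass_tol_ppm mass gate, default 50 ppm.
#' @param time_tol_min migration-time gate, default 2 min.
#' @return list with `accept` (logical), `reasons` (character vector
#'   among "mass", "migration", "engines"; empty when accepted),
#'   `ppm_error`, `time_error`, `predicted_time`.
#' @export
validate_assignment <- function(observed_mass, observed_time, annotation,
                                model, both_engines = TRUE,
                                mass_tol_ppm = 50, time_tol_min = 2) {
  theo <- annotation$mass_da
  if (is.null(theo) || is.na(theo)) stop("annotation lacks a theoretical mass")
  nb <- annotation$n_basic
  if (is.null(nb)) nb <- count_basic_residues(annotation$sequence)
  ppm_error <- (observed_mass - theo) / theo * 1e6
  pred <- predict_migration(model, theo, nb)
  time_error <- observed_time - pred
  reasons <- character(0)
  if (abs(ppm_error) > mass_tol_ppm) reasons <- c(reasons, "mass")
  if (is.na(time_error) || abs(time_error) > time_tol_min) {
    reasons <- c(reasons, "migration")
  }
  if (!isTRUE(both_engines)) reasons <- c(reasons, "engines")
  list(accept = length(reasons) == 0, reasons = reasons,
       ppm_error = ppm_error, time_error = time_error,
       predicted_time = pred)
}

#' Targeted lookup of protein fragments with differential testing
#'
#' Selects all annotated fragments of the named parent proteins from the
#' master list and runs the differential workflow on just that subset,
#' with Benjamini-Hochberg correction over the subset family (a targeted
#' hypothesis-driven comparison, not a genome-wide screen).
#'
#' @param annotations [sequence_annotation()] table with an `id` column
#'   linking rows to master-list peptide ids.
#' @param master a master list.
#' @param proteins character vector of parent protein names.
#' @param case_ids,control_ids sample groups for the differential test.
#' @param alpha significance level (default 0.05).
#' @param ... passed to [discover_markers()].
#' @return list with `fragments` (the selected annotation rows) and
#'   `stats` (the tested subset's marker records with subset-family BH
#'   adjustment; significant subset in `significant`).
#' @export
find_protein_fragments <- function(annotations, master, proteins,
                                   case_ids, control_ids, alpha = 0.05,
                                   ...) {
  if (is.null(annotations$id)) {
    stop("annotations need an id column linking to master peptide ids")
  }
  hit <- annotations$protein %in% proteins
  missing <- setdiff(proteins, annotations$protein)
  if (length(missing) > 0) {
    warning("no annotated fragments for: ", paste(missing, collapse = ", "))
  }
  frags <- annotations[hit, , drop = FALSE]
  if (nrow(frags) == 0) {
    return(list(fragments = frags, stats = NULL, significant = NULL))
  }
  sub <- master
  sub$intensity <- master$intensity[frags$id, , drop = FALSE]
  sub$peptides <- master$peptides[match(frags$id, master$peptides$id), ]
  disc <- discover_markers(sub, case_ids, control_ids, alpha = alpha, ...)
  list(fragments = frags, stats = attr(disc, "tested"), significant = disc)
}
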