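#' Tolerance scheme for cross-sample peptide matching
#'
#' Peptides in different samples are considered identical when their mass
#' and migration-time deviations both fall inside mass- and
#' time-dependent windows. The default scheme: +/-50 ppm below 4000 Da,
#' ramping linearly to +/-150 ppm at 6000 Da and constant above; +/-1.0
#' min at/below 19 min, ramping linearly to +/-2.5 min at 50 min and
#' constant above.
#'
#' @param mass_anchors numeric `c(mass_lo, ppm_lo, mass_hi, ppm_hi)`.
#' @param time_anchors numeric `c(time_lo, tol_lo, time_hi, tol_hi)`.
#' @return an object of class `tolerance_scheme`.
#' @export
tolerance_scheme <- function(mass_anchors = c(4000, 50, 6000, 150),
                             time_anchors = c(19, 1.0, 50, 2.5)) {
  stopifnot(length(mass_anchors) == 4, length(time_anchors) == 4,
            mass_anchors[3] > mass_anchors[1],
            time_anchors[3] > time_anchors[1],
            all(c(mass_anchors[c(2, 4)], time_anchors[c(2, 4)]) > 0))
  structure(list(mass_anchors = mass_anchors, time_anchors = time_anchors),
            class = "tolerance_scheme")
}

#' Mass-dependent matching tolerance
#'
#' @param mass molecular mass in Da (> 0), vectorized.
#' @param scheme a [tolerance_scheme()].
#' @return tolerance in ppm.
#' @export
mass_tolerance <- function(mass, scheme = tolerance_scheme()) {
  if (any(mass <= 0)) stop("mass must be > 0")
  a <- scheme$mass_anchors
  ramp <- a[2] + (a[4] - a[2]) * (mass - a[1]) / (a[3] - a[1])
  pmin(pmax(ramp, a[2]), a[4])
}

#' Time-dependent matching tolerance
#'
#' @param time migration time in min (> 0), vectorized.
#' @param scheme a [tolerance_scheme()].
#' @return tolerance in min.
#' @export
time_tolerance <- function(time, scheme = tolerance_scheme()) {
  if (any(time <= 0)) stop("time must be > 0")
  a <- scheme$time_anchors
  ramp <- a[2] + (a[4] - a[2]) * (time - a[1]) / (a[3] - a[1])
  pmin(pmax(ramp, a[2]), a[4])
}

#' Build the cross-sample master list
#'
#' Greedy centroid clustering of calibrated peptide features into
#' consensus peptides. Features are processed in descending intensity
#' order (ties broken by mass, time, then sample id, so the result does
#' not depend on the order of the input list). Each feature is assigned
#' to the nearest existing centroid lying within both the mass and time
#' tolerance windows of that centroid, with distance
#' `max(|dmass|/mass_tol, |dtime|/time_tol)`; the centroid is then
#' updated as the intensity-weighted running mean. A feature with no
#' qualifying centroid seeds a new consensus peptide. One sample can
#' contribute at most one feature per consensus peptide: if the nearest
#' qualifying centroid already holds a (necessarily more intense) feature
#' from the same sample, the feature seeds a new consensus peptide.
#'
#' @param samples list of calibrated [peak_sample()] objects.
#' @param scheme a [tolerance_scheme()].
#' @return object of class `master_list`: `peptides` (data.frame id,
#'   mass_da, time_min, n_detected) and `intensity` (peptides x samples
#'   matrix, 0 = not detected).
#' @export
build_master_list <- function(samples, scheme = tolerance_scheme()) {
  if (!all(vapply(samples, function(s) isTRUE(s$calibrated), logical(1)))) {
    stop("build_master_list requires calibrated samples")
  }
  sample_ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")

  feats <- do.call(rbind, lapply(samples, function(s) {
    if (nrow(s$features) == 0) return(NULL)
    cbind(s$features, sample_id = s$sample_id)
  }))
  ord_cols <- sort(sample_ids)  # deterministic column order
  if (is.null(feats) || nrow(feats) == 0) {
    return(structure(list(
      peptides = data.frame(id = character(0), mass_da = numeric(0),
                            time_min = numeric(0), n_detected = integer(0)),
      intensity = matrix(0, 0, length(ord_cols),
                         dimnames = list(NULL, ord_cols))
    ), class = "master_list"))
  }
  o <- order(-feats$intensity, feats$mass_da, feats$time_min,
             feats$sample_id)
  feats <- feats[o, ]

  n <- nrow(feats)
  cm <- numeric(n); ct <- numeric(n); cw <- numeric(n)  # centroids
  members <- vector("list", n)                          # sample ids per cluster
  assign_cluster <- integer(n)
  nc <- 0L
  for (i in seq_len(n)) {
    m <- feats$mass_da[i]; t <- feats$time_min[i]; w <- feats$intensity[i]
    sid <- feats$sample_id[i]
    j <- 0L
    if (nc > 0L) {
      idx <- seq_len(nc)
      mtol <- cm[idx] * mass_tolerance(cm[idx], scheme) * 1e-6
      ttol <- time_tolerance(ct[idx], scheme)
      d <- pmax(abs(m - cm[idx]) / mtol, abs(t - ct[idx]) / ttol)
      cand <- which(d <= 1)
      if (length(cand)) {
        best <- cand[which.min(d[cand])]  # which.min: lowest id on ties
        if (!(sid %in% members[[best]])) j <- best
      }
    }
    if (j == 0L) {
      nc <- nc + 1L
      cm[nc] <- m; ct[nc] <- t; cw[nc] <- w
      members[[nc]] <- sid
      assign_cluster[i] <- nc
    } else {
      tot <- cw[j] + w
      cm[j] <- (cm[j] * cw[j] + m * w) / tot
      ct[j] <- (ct[j] * cw[j] + t * w) / tot
      cw[j] <- tot
      members[[j]] <- c(members[[j]], sid)
      assign_cluster[i] <- j
    }
  }

  ids <- sprintf("M%05d", seq_len(nc))
  intensity <- matrix(0, nc, length(ord_cols),
                      dimnames = list(ids, ord_cols))
  intensity[cbind(assign_cluster, match(feats$sample_id, ord_cols))] <-
    feats$intensity
  structure(list(
    peptides = data.frame(
      id = ids, mass_da = cm[seq_len(nc)], time_min = ct[seq_len(nc)],
      n_detected = vapply(members[seq_len(nc)], length, integer(1)),
      stringsAsFactors = FALSE
    ),
    intensity = intensity
  ), class = "master_list")
}

#' @export
print.master_list <- function(x, ...) {
  cat(sprintf("<master_list> %d consensus peptides x %d samples\n",
              nrow(x$peptides), ncol(x$intensity)))
  invisible(x)
}

#' Match consensus peptides between two master lists
#'
#' Pairs each peptide of `master_a` with the nearest peptide of
#' `master_b` lying within both tolerance windows (evaluated at the A
#' centroid), then enforces one-to-one pairing by keeping, for every B
#' peptide, only its closest A partner.
#'
#' @param master_a,master_b [build_master_list()] results.
#' @param scheme a [tolerance_scheme()].
#' @return data.frame with columns `id_a`, `id_b`.
#' @export
match_master_lists <- function(master_a, master_b,
                               scheme = tolerance_scheme()) {
  pa <- master_a$peptides
  pb <- master_b$peptides
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    return(data.frame(id_a = character(0), id_b = character(0)))
  }
  out_a <- character(0); out_b <- character(0); out_d <- numeric(0)
  for (i in seq_len(nrow(pa))) {
    mtol <- pa$mass_da[i] * mass_tolerance(pa$mass_da[i], scheme) * 1e-6
    ttol <- time_tolerance(pa$time_min[i], scheme)
    d <- pmax(abs(pb$mass_da - pa$mass_da[i]) / mtol,
              abs(pb$time_min - pa$time_min[i]) / ttol)
    j <- which.min(d)
    if (d[j] <= 1) {
      out_a <- c(out_a, pa$id[i])
      out_b <- c(out_b, pb$id[j])
      out_d <- c(out_d, d[j])
    }
  }
  ## one-to-one: keep the closest A partner per B peptide
  keep <- !logical(length(out_b))
  for (b in unique(out_b[duplicated(out_b)])) {
    idx <- which(out_b == b)
    keep[idx[-which.min(out_d[idx])]] <- FALSE
  }
  data.frame(id_a = out_a[keep], id_b = out_b[keep],
             stringsAsFactors = FALSE)
}

#' Write a master list as two CSV files
#'
#' @param master a `master_list`.
#' @param dir output directory; writes `consensus.csv` and
#'   `intensity_matrix.csv`.
#' @return `dir`, invisibly.
#' @export
write_master_list <- function(master, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(master$peptides, file.path(dir, "consensus.csv"),
                   row.names = FALSE, quote = FALSE)
  mat <- data.frame(id = rownames(master$intensity), master$intensity,
                    check.names = FALSE)
  utils::write.csv(mat, file.path(dir, "intensity_matrix.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_master_list
#' @export
read_master_list <- function(dir) {
  peptides <- utils::read.csv(file.path(dir, "consensus.csv"),
                              stringsAsFactors = FALSE)
  mat <- utils::read.csv(file.path(dir, "intensity_matrix.csv"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  intensity <- as.matrix(mat[, -1, drop = FALSE])
  rownames(intensity) <- mat$id
  structure(list(peptides = peptides, intensity = intensity),
            class = "master_list")
}
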