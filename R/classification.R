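#' Natural-log transform with unit floor
#'
#' Normalized signal intensities below 1 AU (including undetected zeros)
#' are substituted with 1 before taking the natural logarithm, so the
#' transform never yields negative values and undetected maps to 0.
#'
#' @param intensity non-negative intensities (vector or matrix).
#' @return ln of the floored intensities.
#' @export
log_floor_transform <- function(intensity) {
  if (any(intensity < 0)) stop("intensity must be >= 0")
  log(pmax(intensity, 1))
}

#' Fit the linear distance-2 panel classifier
#'
#' For each panel marker i with case ln-mean `mu_c` and control ln-mean
#' `mu_0` (ln-floor transformed training intensities), the marker is
#' centred at `m_i = (mu_c + mu_0)/2` and scaled by `w_i = 2/(mu_c -
#' mu_0)`, so that the scaled case-group mean minus the scaled
#' control-group mean equals exactly 2 for every marker — the
#' normalization that prevents high-amplitude markers from dominating
#' the combination. A sample's score is the unweighted mean of its
#' scaled marker values; control samples score around -1 and cases
#' around +1. Down-regulated markers get a negative scale, preserving
#' the +2 distance.
#'
#' Markers whose training contrast `|mu_c - mu_0|` falls below
#' `min_separation` are treated as degenerate and dropped with a warning:
#' their scale `2/(mu_c - mu_0)` would amplify measurement noise without
#' bound, letting a single contrast-free marker dominate the panel mean —
#' the exact artificial weighting the normalization exists to prevent.
#'
#' @param panel character vector of peptide ids (rows of `X`).
#' @param X peptides x samples raw intensity matrix.
#' @param case_ids,control_ids nonempty disjoint sample id vectors.
#' @param min_separation smallest usable |case - control| ln-mean
#'   contrast (default 0.5, the scale of one biological noise SD).
#' @return object of class `nephro_model`, kind `"linear"`.
#' @export
fit_linear_model <- function(panel, X, case_ids, control_ids,
                             min_separation = 0.5) {
  check_training_input(panel, X, case_ids, control_ids)
  L <- log_floor_transform(X[panel, , drop = FALSE])
  mu_c <- rowMeans(L[, case_ids, drop = FALSE])
  mu_0 <- rowMeans(L[, control_ids, drop = FALSE])
  degenerate <- abs(mu_c - mu_0) < min_separation
  if (any(degenerate)) {
    warning("dropping ", sum(degenerate),
            " marker(s) with negligible case/control separation: ",
            paste(panel[degenerate], collapse = ", "))
    panel <- panel[!degenerate]
    mu_c <- mu_c[!degenerate]; mu_0 <- mu_0[!degenerate]
  }
  if (length(panel) == 0) stop("empty panel after dropping degenerate markers")
  structure(list(
    kind = "linear",
    panel = panel,
    center = stats::setNames((mu_c + mu_0) / 2, panel),
    scale = stats::setNames(2 / (mu_c - mu_0), panel),
    meta = list(n_case = length(case_ids), n_control = length(control_ids))
  ), class = "nephro_model")
}

#' Fit the margin (SVM-type) panel classifier
#'
#' Trains a linear soft-margin support vector machine (hinge loss,
#' regularization `cost`, deterministic dual coordinate descent) on
#' ln-floor transformed, per-marker standardized panel intensities.
#' Decision scores are continuous; higher means more case-like.
#'
#' @inheritParams fit_linear_model
#' @param cost soft-margin regularization constant C (default 1).
#' @param seed unused by the deterministic solver; recorded in the model
#'   metadata for provenance.
#' @return object of class `nephro_model`, kind `"margin"`.
#' @export
fit_margin_model <- function(panel, X, case_ids, control_ids,
                             cost = 1, seed = NULL) {
  check_training_input(panel, X, case_ids, control_ids)
  L <- log_floor_transform(X[panel, c(case_ids, control_ids), drop = FALSE])
  ctr <- rowMeans(L)
  sdv <- apply(L, 1, stats::sd)
  degenerate <- sdv == 0
  if (any(degenerate)) {
    warning("dropping ", sum(degenerate), " constant marker(s): ",
            paste(panel[degenerate], collapse = ", "))
    panel <- panel[!degenerate]
    L <- L[!degenerate, , drop = FALSE]
    ctr <- ctr[!degenerate]; sdv <- sdv[!degenerate]
  }
  if (length(panel) == 0) stop("empty panel after dropping constant markers")
  Z <- t((L - ctr) / sdv)  # samples x markers
  y <- c(rep(1, length(case_ids)), rep(-1, length(control_ids)))
  fit <- svm_dcd(Z, y, cost = cost)
  structure(list(
    kind = "margin",
    panel = panel,
    center = stats::setNames(ctr, panel),
    scale = stats::setNames(sdv, panel),
    weights = stats::setNames(fit$w, panel),
    bias = fit$b,
    meta = list(n_case = length(case_ids), n_control = length(control_ids),
                cost = cost, seed = seed, iterations = fit$iterations)
  ), class = "nephro_model")
}

check_training_input <- function(panel, X, case_ids, control_ids) {
  if (length(panel) < 1) stop("panel must contain at least one peptide")
  if (!all(panel %in% rownames(X))) {
    stop("panel peptides missing from the training matrix: ",
         paste(setdiff(panel, rownames(X)), collapse = ", "))
  }
  if (length(case_ids) == 0 || length(control_ids) == 0) {
    stop("both groups must be nonempty")
  }
  if (length(intersect(case_ids, control_ids)) > 0) {
    stop("case and control groups must be disjoint")
  }
  if (!all(c(case_ids, control_ids) %in% colnames(X))) {
    stop("group sample ids missing from the training matrix")
  }
  invisible(TRUE)
}

#' Score samples with a fitted panel model
#'
#' @param model a `nephro_model`.
#' @param X peptides x samples raw intensity matrix containing all panel
#'   peptides.
#' @return named numeric vector of scores, one per column of `X`.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "nephro_model"))
  if (!all(model$panel %in% rownames(X))) {
    stop("panel peptides missing from the scoring matrix")
  }
  L <- log_floor_transform(X[model$panel, , drop = FALSE])
  if (model$kind == "linear") {
    colMeans(model$scale * (L - model$center))
  } else {
    Z <- (L - model$center) / model$scale
    drop(crossprod(Z, model$weights)) + model$bias
  }
}

#' @export
print.nephro_model <- function(x, ...) {
  cat(sprintf("<nephro_model> kind=%s, panel of %d markers\n",
              x$kind, length(x$panel)))
  invisible(x)
}

#' Save / load a panel model as structured text (JSON)
#'
#' Round-trips the full numeric state at maximum precision, so reloaded
#' models reproduce scores to machine precision.
#'
#' @param model a `nephro_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("center", "scale", "weights")) {
    if (!is.null(obj[[f]])) obj[[f]] <- unlist(obj[[f]])
  }
  structure(obj, class = "nephro_model")
}

#' Take-one-out cross-validation of a panel classifier
#'
#' Each sample is scored by a model refit on all remaining samples —
#' including the per-marker normalization constants, so no information
#' from the held-out sample leaks into its own score. The cross-validated
#' AUC is the Mann-Whitney estimator over the held-out scores.
#'
#' @param panel peptide ids.
#' @param X peptides x samples raw intensity matrix.
#' @param case_ids,control_ids sample ids; each class needs >= 2 samples.
#' @param kind `"margin"` or `"linear"`.
#' @param keep_fits if TRUE, the per-fold models are returned (used by
#'   leakage audits).
#' @param ... passed to the fitting function.
#' @return list with `auc`, `scores` (data.frame sample_id, group,
#'   score) and optionally `fits`.
#' @export
loo_cv <- function(panel, X, case_ids, control_ids,
                   kind = c("margin", "linear"), keep_fits = FALSE, ...) {
  kind <- match.arg(kind)
  if (length(case_ids) < 2 || length(control_ids) < 2) {
    stop("take-one-out cross-validation needs >= 2 samples per class")
  }
  fit_fun <- if (kind == "margin") fit_margin_model else fit_linear_model
  all_ids <- c(case_ids, control_ids)
  fits <- if (keep_fits) vector("list", length(all_ids)) else NULL
  scores <- vapply(seq_along(all_ids), function(k) {
    held <- all_ids[k]
    m <- fit_fun(panel, X,
                 setdiff(case_ids, held), setdiff(control_ids, held), ...)
    if (keep_fits) fits[[k]] <<- m
    predict_scores(m, X[, held, drop = FALSE])
  }, numeric(1))
  names(scores) <- all_ids
  out <- list(
    auc = auc_mw(scores[case_ids], scores[control_ids]),
    scores = data.frame(
      sample_id = all_ids,
      group = c(rep("case", length(case_ids)),
                rep("control", length(control_ids))),
      score = unname(scores), stringsAsFactors = FALSE
    )
  )
  if (keep_fits) out$fits <- fits
  out
}

#' Time-course classification scores
#'
#' Scores every sample of a dosing time course and aggregates mean
#' scores per dose x day cell, ordered by day — the classification-factor
#' trajectories used to read out onset, dose response and resolution of
#' injury.
#'
#' @param model a `nephro_model`.
#' @param master master list (or any object with an `intensity` matrix).
#' @param design design data.frame covering every scored sample.
#' @return data.frame with dose, day, n, mean_score; per-sample scores
#'   attached as attribute `"scores"`.
#' @export
time_course_scores <- function(model, master, design) {
  mat <- master$intensity
  missing <- setdiff(colnames(mat), design$sample_id)
  if (length(missing) > 0) {
    stop("samples missing from the design: ",
         paste(missing, collapse = ", "))
  }
  s <- predict_scores(model, mat)
  design <- design[match(colnames(mat), design$sample_id), ]
  agg <- stats::aggregate(
    list(mean_score = s),
    by = list(dose = design$dose_mg_kg, day = design$day),
    FUN = mean
  )
  n <- stats::aggregate(list(n = s),
                        by = list(dose = design$dose_mg_kg,
                                  day = design$day), FUN = length)
  agg$n <- n$n
  agg <- agg[order(agg$day, agg$dose), c("dose", "day", "n", "mean_score")]
  rownames(agg) <- NULL
  attr(agg, "scores") <- data.frame(sample_id = colnames(mat),
                                    score = unname(s),
                                    dose = design$dose_mg_kg,
                                    day = design$day,
                                    stringsAsFactors = FALSE)
  agg
}
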