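## Shared fixture builders (all data generated in code).

## Master-list-shaped object straight from a generated study's ground
## truth: what a perfect calibration + matching would recover.
truth_master <- function(study) {
  list(intensity = study$truth$matrix_true,
       peptides = study$truth$peptides[, c("id", "mass_da", "time_min")])
}

## Peak sample from bare vectors.
ps <- function(id, mass, time, intensity, calibrated = FALSE) {
  peak_sample(id, data.frame(mass_da = mass, time_min = time,
                             intensity = intensity),
              calibrated = calibrated)
}

## A small reference set with evenly spread housekeeping peptides and
## internal standards, usable as exact ground truth for calibration.
toy_refs <- function(n_hk = 12, n_is = 8, seed = 42) {
  set.seed(seed)
  hk <- data.frame(mass_da = seq(900, 6000, length.out = n_hk),
                   time_min = seq(20, 48, length.out = n_hk))
  st <- data.frame(mass_da = seq(1100, 5500, length.out = n_is) + 17,
                   time_min = seq(21, 47, length.out = n_is) + 0.4,
                   intensity_ref = round(stats::runif(n_is, 500, 5000)))
  reference_set(housekeeping = hk, standards = st)
}

## Sample whose features are exactly the reference peptides (plus extras),
## optionally distorted: time -> slope*time + offset, mass scaled by
## (1 + ppm_bias(mass)*1e-6), all intensities scaled.
refs_sample <- function(refs, slope = 1, offset = 0,
                        ppm_bias = function(m) 0, int_scale = 1,
                        time_noise = 0, seed = 1) {
  set.seed(seed)
  f <- rbind(
    data.frame(mass_da = refs$housekeeping$mass_da,
               time_min = refs$housekeeping$time_min,
               intensity = 1000),
    data.frame(mass_da = refs$standards$mass_da,
               time_min = refs$standards$time_min,
               intensity = refs$standards$intensity_ref)
  )
  f$time_min <- slope * (f$time_min + stats::rnorm(nrow(f), 0, time_noise)) +
    offset
  f$mass_da <- f$mass_da * (1 + ppm_bias(f$mass_da) * 1e-6)
  f$intensity <- f$intensity * int_scale
  peak_sample("toy", f)
}

## Intensity matrix with named rows/columns built from per-group
## log-means: markers x (case, control) design for classifier tests.
toy_matrix <- function(mu_case, mu_control, n_case = 4, n_control = 4,
                       noise_sd = 0, seed = 1) {
  set.seed(seed)
  p <- length(mu_case)
  case_ids <- sprintf("case%d", seq_len(n_case))
  ctrl_ids <- sprintf("ctrl%d", seq_len(n_control))
  L <- cbind(
    matrix(rep(mu_case, n_case), p) + stats::rnorm(p * n_case, 0, noise_sd),
    matrix(rep(mu_control, n_control), p) +
      stats::rnorm(p * n_control, 0, noise_sd)
  )
  X <- exp(L)
  dimnames(X) <- list(sprintf("M%02d", seq_len(p)), c(case_ids, ctrl_ids))
  attr(X, "case_ids") <- case_ids
  attr(X, "control_ids") <- ctrl_ids
  X
}
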