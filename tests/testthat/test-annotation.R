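test_that("basic-residue counting handles modifications and rejects junk", {
  expect_identical(count_basic_residues("DSYVGDEAQSK"), 1L)
  expect_identical(count_basic_residues("GGGG"), 0L)
  expect_identical(count_basic_residues("IDELYLPK"), 1L)
  ## hydroxylysine k counts as K; p and m are non-basic
  expect_identical(count_basic_residues("GkPR"), 2L)
  expect_identical(count_basic_residues("ApGmP"), 0L)
  expect_identical(count_basic_residues("HHH"), 3L)
  expect_error(count_basic_residues("AXZ"), "unknown residue")
})

test_that("annotation table enforces positional invariants", {
  ann <- sequence_annotation("DSYVGDEAQSK", "ACTS_RAT", 53, 63)
  expect_identical(ann$n_basic, 1L)
  expect_gt(ann$mass_da, 1000)
  expect_error(sequence_annotation("AG", "X", 10, 5), "start")
  expect_error(sequence_annotation("AG", "X", 1, 5), "length")
})

test_that("peptide masses are consistent with modification chemistry", {
  ## hydroxylation adds one oxygen
  expect_equal(peptide_mass("ApG") - peptide_mass("APG"), 15.9994)
  expect_equal(peptide_mass("Gk") - peptide_mass("GK"), 15.9994)
  expect_equal(peptide_mass("G"), 57.0519 + 18.0153, tolerance = 1e-4)
})

test_that("migration model recovers a per-stratum linear law exactly", {
  set.seed(61)
  ## stated monotone law: fewer basic residues -> later migration
  intercepts <- c(`1` = 40, `2` = 30, `3` = 22)
  slopes <- c(`1` = 1.5, `2` = 1.8, `3` = 2.0)
  train <- do.call(rbind, lapply(1:3, function(b) {
    mass <- stats::runif(8, 900, 4000)
    data.frame(mass_da = mass, n_basic = b,
               time_min = intercepts[b] + slopes[b] * log(mass))
  }))
  model <- fit_migration_model(train)
  for (b in 1:3) {
    st <- model$strata[[as.character(b)]]
    expect_equal(st$intercept, unname(intercepts[b]), tolerance = 1e-8)
    expect_equal(st$slope, unname(slopes[b]), tolerance = 1e-8)
    expect_lt(st$resid_sd, 1e-8)
  }
  ## monotone in charge at fixed mass, as generated
  pred <- predict_migration(model, rep(2000, 3), 3:1)
  expect_true(all(diff(pred) > 0))
  ## in-sample residual sanity under noise
  train$time_min <- train$time_min + stats::rnorm(nrow(train), 0, 0.3)
  m2 <- fit_migration_model(train)
  p1 <- predict_migration(m2, train$mass_da[1], train$n_basic[1])
  st1 <- m2$strata[[as.character(train$n_basic[1])]]
  expect_lt(abs(train$time_min[1] - p1), 3 * st1$resid_sd + 1e-9)
})

test_that("small strata are excluded and degenerate training rejected", {
  train <- data.frame(mass_da = stats::runif(12, 900, 4000),
                      n_basic = c(rep(1, 10), 2, 2),
                      time_min = stats::runif(12, 20, 45))
  expect_warning(model <- fit_migration_model(train), "excluded")
  expect_named(model$strata, "1")
  expect_warning(p <- predict_migration(model, 1500, 2), "no migration")
  expect_true(is.na(p))
  expect_error(fit_migration_model(train[1:8, ]), ">= 10")
  expect_error(fit_migration_model(transform(train, n_basic = 1)),
               ">= 2 basic-residue")
})

test_that("the acceptance gate applies mass, migration and engine rules", {
  set.seed(62)
  train <- do.call(rbind, lapply(1:2, function(b) {
    mass <- stats::runif(10, 900, 4000)
    data.frame(mass_da = mass, n_basic = b,
               time_min = 45 - 8 * b + 1.2 * log(mass))
  }))
  model <- fit_migration_model(train)
  ann <- sequence_annotation("DSYVGDEAQSK", "ACTS_RAT", 53, 63)
  t_pred <- predict_migration(model, ann$mass_da, ann$n_basic)

  ok <- validate_assignment(ann$mass_da * (1 + 30e-6), t_pred + 1, ann,
                            model, both_engines = TRUE)
  expect_true(ok$accept)
  expect_length(ok$reasons, 0)

  bad_mass <- validate_assignment(ann$mass_da * (1 + 60e-6), t_pred, ann,
                                  model)
  expect_false(bad_mass$accept)
  expect_identical(bad_mass$reasons, "mass")

  bad_time <- validate_assignment(ann$mass_da, t_pred + 2.5, ann, model)
  expect_false(bad_time$accept)
  expect_identical(bad_time$reasons, "migration")

  one_engine <- validate_assignment(ann$mass_da, t_pred, ann, model,
                                    both_engines = FALSE)
  expect_identical(one_engine$reasons, "engines")

  ## monotone: tightening either tolerance never accepts a rejected candidate
  set.seed(63)
  for (i in 1:25) {
    dm <- stats::runif(1, -80, 80); dt <- stats::runif(1, -3, 3)
    loose <- validate_assignment(ann$mass_da * (1 + dm * 1e-6),
                                 t_pred + dt, ann, model,
                                 mass_tol_ppm = 50, time_tol_min = 2)
    tight <- validate_assignment(ann$mass_da * (1 + dm * 1e-6),
                                 t_pred + dt, ann, model,
                                 mass_tol_ppm = 25, time_tol_min = 1)
    expect_true(loose$accept || !tight$accept)
  }
})

test_that("targeted protein-fragment lookup tests only the named subset", {
  set.seed(64)
  proteins <- c(rep("clusterin", 5), rep("osteopontin", 16),
                rep("albumin", 11), rep("other", 8))
  n_pep <- length(proteins)
  ids <- sprintf("M%03d", seq_len(n_pep))
  seqs <- vapply(seq_len(n_pep), function(i) {
    paste(sample(c("A", "G", "P", "K", "D", "E", "S"), 8, replace = TRUE),
          collapse = "")
  }, character(1))
  ann <- sequence_annotation(seqs, proteins, start = 10, stop = 17)
  ann$id <- ids
  cases <- sprintf("c%d", 1:8); ctrls <- sprintf("k%d", 1:8)
  mat <- matrix(exp(stats::rnorm(n_pep * 16, 4)), n_pep,
                dimnames = list(ids, c(cases, ctrls)))
  mat[2, cases] <- mat[2, cases] * 50  # one clusterin fragment shifted
  master <- list(intensity = mat,
                 peptides = data.frame(id = ids, mass_da = ann$mass_da,
                                       time_min = 30))
  res <- find_protein_fragments(ann, master,
                                c("clusterin", "osteopontin", "albumin"),
                                cases, ctrls)
  expect_identical(nrow(res$fragments), 32L)         # 5 + 16 + 11
  expect_identical(nrow(res$stats), 32L)             # BH family = subset
  expect_true(ids[2] %in% res$significant$id)
  expect_warning(
    empty <- find_protein_fragments(ann, master, "kim-1", cases, ctrls),
    "kim-1")
  expect_identical(nrow(empty$fragments), 0L)
})
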