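test_that("log-floor transform floors at 1 AU and uses natural log", {
  expect_identical(log_floor_transform(0), 0)
  expect_identical(log_floor_transform(0.5), 0)
  expect_equal(log_floor_transform(exp(1)), 1)
  expect_equal(log_floor_transform(c(0, 1, 10)), c(0, 0, log(10)))
  expect_error(log_floor_transform(-1), ">= 0")
})

test_that("linear model realizes the distance-2 normalization exactly", {
  ## mu_case = 5, mu_control = 3 -> center 4, scale 1
  X <- toy_matrix(mu_case = c(5, 3, 8), mu_control = c(3, 5, 7.5))
  cases <- attr(X, "case_ids"); ctrls <- attr(X, "control_ids")
  m <- fit_linear_model(rownames(X), X, cases, ctrls)
  expect_equal(unname(m$center["M01"]), 4)
  expect_equal(unname(m$scale["M01"]), 1)
  ## down-regulated marker: sign flip, scaled distance still +2
  expect_lt(m$scale["M02"], 0)
  L <- log_floor_transform(X)
  for (i in rownames(X)) {
    scaled <- m$scale[i] * (L[i, ] - m$center[i])
    expect_equal(mean(scaled[cases]) - mean(scaled[ctrls]), 2,
                 tolerance = 1e-12)
  }
  ## group means score -1 / +1 by the algebra of the scaling
  s <- predict_scores(m, X)
  expect_equal(unname(mean(s[ctrls])), -1, tolerance = 1e-12)
  expect_equal(unname(mean(s[cases])), 1, tolerance = 1e-12)
  ## single-marker model scoring the training control mean -> -1
  m1 <- fit_linear_model("M01", X, cases, ctrls)
  expect_equal(unname(predict_scores(m1, X)[ctrls[1]]), -1,
               tolerance = 1e-12)
})

test_that("degenerate markers are dropped with a warning", {
  X <- toy_matrix(mu_case = c(5, 4), mu_control = c(3, 4))
  expect_warning(
    m <- fit_linear_model(rownames(X), X,
                          attr(X, "case_ids"), attr(X, "control_ids")),
    "negligible case/control separation")
  expect_identical(m$panel, "M01")
  expect_error(suppressWarnings(
    fit_linear_model("M02", X, attr(X, "case_ids"), attr(X, "control_ids"))),
    "empty panel")
})

test_that("linear scoring is invariant to marker-wise rescaling of raw intensities", {
  X <- toy_matrix(mu_case = c(6, 4.5), mu_control = c(4, 6),
                  noise_sd = 0.4, seed = 9)
  cases <- attr(X, "case_ids"); ctrls <- attr(X, "control_ids")
  ## rescale each marker by its own positive factor (train and test alike);
  ## all values stay above the floor so the transform is a pure shift
  Y <- X * c(3, 0.5)
  m_x <- fit_linear_model(rownames(X), X, cases, ctrls)
  m_y <- fit_linear_model(rownames(Y), Y, cases, ctrls)
  expect_equal(predict_scores(m_x, X), predict_scores(m_y, Y),
               tolerance = 1e-10)
})

test_that("margin model separates separable data and round-trips through JSON", {
  X <- toy_matrix(mu_case = c(7, 3, 6), mu_control = c(4, 6, 5),
                  n_case = 6, n_control = 6, noise_sd = 0.3, seed = 2)
  cases <- attr(X, "case_ids"); ctrls <- attr(X, "control_ids")
  m <- fit_margin_model(rownames(X), X, cases, ctrls)
  s <- predict_scores(m, X)
  expect_identical(auc_mw(s[cases], s[ctrls]), 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(predict_scores(m2, X), s, tolerance = 1e-12)
  ## linear model serialization too
  ml <- fit_linear_model(rownames(X), X, cases, ctrls)
  write_model(ml, path)
  expect_equal(predict_scores(read_model(path), X), predict_scores(ml, X),
               tolerance = 1e-12)
})

test_that("take-one-out CV refits normalization per fold and needs 2 per class", {
  X <- toy_matrix(mu_case = c(7, 3), mu_control = c(4, 6),
                  n_case = 5, n_control = 5, noise_sd = 0.5, seed = 4)
  cases <- attr(X, "case_ids"); ctrls <- attr(X, "control_ids")
  cv <- loo_cv(rownames(X), X, cases, ctrls, kind = "linear",
               keep_fits = TRUE)
  expect_gte(cv$auc, 0.9)
  ## no-leakage audit: per-fold centers differ (the held-out sample is
  ## excluded from its own fold's normalization constants)
  centers <- vapply(cv$fits, function(f) f$center[["M01"]], numeric(1))
  expect_gt(length(unique(centers)), 1)
  expect_error(loo_cv(rownames(X), X, cases[1], ctrls, kind = "linear"),
               ">= 2 samples")
})

test_that("label permutation drives LOO-CV AUC to chance", {
  set.seed(12)
  X <- toy_matrix(mu_case = rep(5, 4), mu_control = rep(5, 4),
                  n_case = 8, n_control = 8, noise_sd = 1, seed = 12)
  ids <- c(attr(X, "case_ids"), attr(X, "control_ids"))
  aucs <- sapply(1:4, function(i) {
    perm <- sample(ids)
    loo_cv(rownames(X), X, perm[1:8], perm[9:16], kind = "margin")$auc
  })
  expect_gt(mean(aucs), 0.2)
  expect_lt(mean(aucs), 0.8)
})

test_that("time-course scores are dose-ordered at peak and resolve late", {
  cfg <- study_config(n_peptides = 50, n_markers_up = 8, n_markers_down = 4,
                      seed = 51)
  study_b <- generate_study(cfg)
  study_a <- generate_two_group(14, 25, cfg)
  Xa <- study_a$truth$matrix_true
  des_a <- study_a$design
  panel <- study_a$truth$marker_ids
  model <- fit_linear_model(panel, Xa,
                            des_a$sample_id[des_a$group == "treated"],
                            des_a$sample_id[des_a$group == "control"])
  tc <- time_course_scores(model, truth_master(study_b), study_b$design)
  peak <- tc[tc$day %in% c(3, 7, 10), ]
  pk <- function(d) mean(peak$mean_score[peak$dose == d])
  expect_gt(pk(150), pk(0))
  expect_gte(pk(300), pk(150))
  late <- tc[tc$day >= 29, ]
  spread <- pk(300) - pk(0)
  ## control band: control cell means define the resolution scale
  band <- max(0.25 * spread, 4 * stats::sd(tc$mean_score[tc$dose == 0]))
  expect_lt(abs(mean(late$mean_score[late$dose == 300]) -
                  mean(late$mean_score[late$dose == 0])), band)
  ## a sample absent from the design is a data error
  expect_error(time_course_scores(model, truth_master(study_b),
                                  study_b$design[-1, ]), "missing")
})
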