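test_that("frequency filter uses a strict threshold on either group", {
  row <- c(rep(1, 4), rep(0, 6), rep(0, 10))
  names(row) <- c(sprintf("c%d", 1:10), sprintf("k%d", 1:10))
  cases <- sprintf("c%d", 1:10); ctrls <- sprintf("k%d", 1:10)
  expect_true(frequency_filter(row, cases, ctrls))        # 4/10 vs 0/10
  row2 <- stats::setNames(c(rep(1, 3), rep(0, 7), rep(1, 3), rep(0, 7)),
                          c(cases, ctrls))
  expect_false(frequency_filter(row2, cases, ctrls))      # 30% is not > 30%
  row3 <- stats::setNames(c(rep(0, 10), rep(1, 10)), c(cases, ctrls))
  expect_true(frequency_filter(row3, cases, ctrls))       # 0/10 and 10/10
  expect_error(frequency_filter(row, character(0), ctrls), "nonempty")
  expect_error(frequency_filter(row, cases, cases), "disjoint")
})

test_that("rank-sum p-values match the enumeration oracle", {
  ## canonical exact case: full separation of 3 vs 3
  expect_equal(wilcoxon_ln(c(1, 2, 3), c(4, 5, 6)), 0.1)
  ## identical groups
  expect_warning(p <- wilcoxon_ln(c(2, 2, 2), c(2, 2, 2)), "degenerate")
  expect_identical(p, 1)
  ## random tie-free small-n cases vs enumeration (values kept > 1 so the
  ## ln-floor is inactive and ranks equal those of the raw data)
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:8, 1)
    x <- exp(stats::runif(n1, 0.5, 5)); y <- exp(stats::runif(n2, 0.5, 5))
    expect_equal(wilcoxon_ln(x, y), oracle_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
  ## rank invariance under strictly increasing transforms (above the floor)
  x <- exp(c(1, 2.2, 3.1, 0.4)); y <- exp(c(1.5, 2.9, 4, 5))
  f <- function(v) v^1.7 + 3
  expect_equal(wilcoxon_ln(x, y), wilcoxon_ln(f(x), f(y)))
  expect_error(wilcoxon_ln(c(1, 2), c(3, 4, 5)), "at least 3")
})

test_that("large-sample path uses the tie-corrected normal approximation", {
  set.seed(8)
  x <- exp(stats::rnorm(15, 1)); y <- exp(stats::rnorm(20, 1.5))
  ref <- function(a, b) suppressWarnings(
    stats::wilcox.test(log(pmax(a, 1)), log(pmax(b, 1)),
                       correct = TRUE, exact = FALSE)$p.value)
  expect_equal(wilcoxon_ln(x, y), ref(x, y), tolerance = 1e-10)
  ## zeros enter as the minimum tied value
  xz <- c(x, 0, 0)
  expect_equal(wilcoxon_ln(xz, y), ref(xz, y), tolerance = 1e-10)
})

test_that("BH adjustment equals the literal step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.2), 0.2)
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(21)
  for (i in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("AUC equals the all-pairs count and is antisymmetric", {
  expect_identical(auc_mw(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_identical(auc_mw(rep(2, 4), rep(2, 6)), 0.5)
  expect_error(auc_mw(numeric(0), 1), "nonempty")
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:10, sample(2:8, 1), replace = TRUE)
    y <- sample(1:10, sample(2:8, 1), replace = TRUE)
    expect_equal(auc_mw(x, y), oracle_auc(x, y), tolerance = 1e-12)
  }
  ## tie-free antisymmetry
  x <- c(1.1, 5.3, 2.2); y <- c(0.7, 4.1, 9.9, 3.3)
  expect_equal(auc_mw(x, y) + auc_mw(y, x), 1)
})

test_that("regulation factor applies the intensity floor", {
  expect_equal(regulation_factor(rep(100, 5), rep(10, 5)), 10)
  expect_equal(regulation_factor(rep(500, 4), rep(0, 6), floor = 1), 500)
  expect_equal(regulation_factor(c(2, 4), c(4, 2)), 1)
  expect_error(regulation_factor(numeric(0), 1), "length")
})

test_that("discovery tests only the frequency-surviving family", {
  set.seed(3)
  n <- 20
  ids <- sprintf("P%02d", 1:3)
  cases <- sprintf("c%d", 1:10); ctrls <- sprintf("k%d", 1:10)
  mat <- rbind(
    exp(stats::rnorm(n, 3)),                       # always detected
    c(exp(stats::rnorm(10, 8)), rep(0, 10)),       # separated marker
    c(rep(0, 8), exp(stats::rnorm(2, 3)), rep(0, 8), exp(stats::rnorm(2, 3)))
  )                                                # fails 30% filter
  dimnames(mat) <- list(ids, c(cases, ctrls))
  master <- list(intensity = mat,
                 peptides = data.frame(id = ids, mass_da = 1:3,
                                       time_min = 21:23))
  disc <- discover_markers(master, cases, ctrls)
  tested <- attr(disc, "tested")
  expect_identical(sort(tested$id), c("P01", "P02"))  # P03 never tested
  expect_true("P02" %in% disc$id)
  expect_identical(disc$direction[disc$id == "P02"], 1L)
  ## BH family = 2 tests: adjusted p is raw p * 2 / rank
  expect_equal(tested$p_adj, bh_adjust(tested$p_raw))
  expect_error(discover_markers(master, cases, c("nope")), "missing")
})

test_that("planted markers at >= 4 SD are recovered; null cohorts control FDR", {
  ## complete detection: this example probes rank-test power, not
  ## zero-handling (zeros rank an up-marker s absent samples below every
  ## control, which is a deliberate, conservative default elsewhere)
  cfg <- study_config(n_peptides = 60, n_markers_up = 8, n_markers_down = 4,
                      effect_size = 4, noise_sd = 1, missing_rate = 0,
                      seed = 29)
  tg <- generate_two_group(10, 10, cfg)
  des <- tg$design
  disc <- discover_markers(truth_master(tg),
                           des$sample_id[des$group == "treated"],
                           des$sample_id[des$group == "control"])
  recovered <- mean(tg$truth$marker_ids %in% disc$id)
  expect_gte(recovered, 0.9)
  ## null run: nothing planted, few discoveries expected
  cfg0 <- study_config(n_peptides = 200, n_markers_up = 0,
                       n_markers_down = 0, seed = 31)
  tg0 <- generate_two_group(10, 10, cfg0)
  des0 <- tg0$design
  disc0 <- discover_markers(truth_master(tg0),
                            des0$sample_id[des0$group == "treated"],
                            des0$sample_id[des0$group == "control"])
  expect_lte(nrow(disc0), 2)
})

test_that("day/dose means aggregate cells with zeros included", {
  mat <- rbind(P1 = c(10, 0, 30, 50))
  colnames(mat) <- sprintf("s%d", 1:4)
  design <- data.frame(sample_id = colnames(mat),
                       dose_mg_kg = c(0, 0, 300, 300), day = c(3, 3, 3, 3))
  m <- day_dose_means(list(intensity = mat), design)
  expect_equal(m$mean_intensity[m$dose == 0], 5)    # (10 + 0) / 2
  expect_equal(m$mean_intensity[m$dose == 300], 40)
})
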