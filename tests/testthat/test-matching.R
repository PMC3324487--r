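test_that("mass tolerance follows the anchored ramp", {
  expect_equal(mass_tolerance(3000), 50)   # below the first anchor
  expect_equal(mass_tolerance(5000), 100)  # midpoint of the ramp
  expect_equal(mass_tolerance(8000), 150)  # above the last anchor
  expect_equal(mass_tolerance(c(4000, 6000)), c(50, 150))
  expect_error(mass_tolerance(0), "mass")
})

test_that("time tolerance follows the anchored ramp", {
  expect_equal(time_tolerance(19), 1.0)
  expect_equal(time_tolerance(50), 2.5)
  expect_equal(time_tolerance(34.5), 1.75)  # midpoint
  expect_equal(time_tolerance(10), 1.0)
  expect_equal(time_tolerance(60), 2.5)
  expect_error(time_tolerance(-1), "time")
})

test_that("features inside / outside the windows merge / stay apart", {
  s1 <- ps("a", 1000.00, 30, 500, calibrated = TRUE)
  s2 <- ps("b", 1000.04, 30, 400, calibrated = TRUE)  # 40 ppm apart
  m <- build_master_list(list(s1, s2))
  expect_identical(nrow(m$peptides), 1L)
  expect_identical(sum(m$intensity > 0), 2L)
  s3 <- ps("b", 1000.20, 30, 400, calibrated = TRUE)  # 200 ppm apart
  m2 <- build_master_list(list(s1, s3))
  expect_identical(nrow(m2$peptides), 2L)
  ## uncalibrated input is a state error
  expect_error(build_master_list(list(ps("c", 1000, 30, 1))), "calibrated")
})

test_that("one sample contributes at most one feature per consensus peptide", {
  ## two near-identical features in the same sample: the more intense
  ## seeds the cluster, the other must seed its own
  s <- peak_sample("a", data.frame(mass_da = c(1000.00, 1000.01),
                                   time_min = c(30, 30),
                                   intensity = c(500, 400)),
                   calibrated = TRUE)
  m <- build_master_list(list(s))
  expect_identical(nrow(m$peptides), 2L)
  expect_equal(unname(colSums(m$intensity > 0)), 2)
})

test_that("greedy clustering equals the transitive-closure oracle on random instances", {
  set.seed(101)
  n_checked <- 0
  for (inst in 1:60) {
    n_feat <- sample(5:50, 1)
    n_samp <- sample(2:5, 1)
    feats <- data.frame(
      mass_da = stats::runif(n_feat, 900, 7000),
      time_min = stats::runif(n_feat, 19, 50),
      intensity = stats::runif(n_feat, 10, 1e4),
      sample_id = sample(sprintf("s%d", seq_len(n_samp)), n_feat,
                         replace = TRUE)
    )
    ## occasionally plant tight clusters so merges actually occur
    if (inst %% 2 == 0) {
      k <- sample(2:4, 1)
      base <- feats[sample(n_feat, 1), ]
      for (j in seq_len(k)) {
        mtol <- base$mass_da * mass_tolerance(base$mass_da) * 1e-6
        feats <- rbind(feats, data.frame(
          mass_da = base$mass_da + stats::runif(1, -0.2, 0.2) * mtol,
          time_min = base$time_min + stats::runif(1, -0.2, 0.2) *
            time_tolerance(base$time_min),
          intensity = stats::runif(1, 10, 1e4),
          sample_id = sprintf("s%d", j)
        ))
      }
    }
    feats <- feats[!duplicated(feats[, c("mass_da", "time_min")]), ]
    oracle <- oracle_match_partition(feats)
    if (is.null(oracle)) next  # not window-consistent; oracle silent
    n_checked <- n_checked + 1
    samples <- lapply(split(feats, feats$sample_id), function(df) {
      peak_sample(df$sample_id[1],
                  df[, c("mass_da", "time_min", "intensity")],
                  calibrated = TRUE)
    })
    master <- build_master_list(samples)
    ## recover the greedy partition by tracing features to matrix cells
    greedy <- vapply(seq_len(nrow(feats)), function(i) {
      which(master$intensity[, feats$sample_id[i]] == feats$intensity[i])[1]
    }, integer(1))
    expect_identical(partition_key(greedy), partition_key(oracle))
  }
  expect_gt(n_checked, 30)
})

test_that("cluster memberships are invariant to sample order and conserve features", {
  cfg <- study_config(n_peptides = 40, n_markers_up = 4, n_markers_down = 2,
                      doses = c(0, 300), days = c(3, 10), n_per_cell = 3,
                      seed = 13)
  st <- generate_study(cfg)
  cal <- calibrate_cohort(st$samples, st$refs)
  m1 <- build_master_list(cal)
  m2 <- build_master_list(rev(cal))
  expect_identical(m1$peptides, m2$peptides)
  expect_identical(m1$intensity, m2$intensity)
  ## conservation: every input feature lands in exactly one cell
  n_in <- sum(vapply(cal, function(s) nrow(s$features), integer(1)))
  expect_identical(sum(m1$intensity > 0), n_in)
})

test_that("at default noise >= 95% of features map to their true peptide", {
  cfg <- study_config(n_peptides = 60, n_markers_up = 6, n_markers_down = 3,
                      doses = c(0, 300), days = c(3, 10, 29), n_per_cell = 3,
                      seed = 19)
  st <- generate_study(cfg)
  cal <- calibrate_cohort(st$samples, st$refs)
  master <- build_master_list(cal)
  map <- match_master_lists(master, truth_master(st))
  ## fraction of detected cells whose consensus peptide maps to the true one
  tr <- st$truth$matrix_true
  hits <- 0; total <- 0
  for (id_b in rownames(tr)) {
    id_m <- map$id_a[map$id_b == id_b]
    detected <- sum(tr[id_b, ] > 0)
    total <- total + detected
    if (length(id_m) == 1) {
      hits <- hits + sum(master$intensity[id_m, colnames(tr)] > 0 &
                           tr[id_b, ] > 0)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("master lists round-trip through CSV", {
  s1 <- ps("a", c(1000, 2000), c(25, 30), c(10, 20), calibrated = TRUE)
  s2 <- ps("b", c(1000.01, 3000), c(25, 40), c(15, 5), calibrated = TRUE)
  m <- build_master_list(list(s1, s2))
  dir <- withr::local_tempdir()
  write_master_list(m, dir)
  m2 <- read_master_list(dir)
  expect_equal(m2$intensity, m$intensity, tolerance = 1e-9)
  expect_equal(m2$peptides$mass_da, m$peptides$mass_da, tolerance = 1e-9)
})
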