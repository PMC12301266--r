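test_that("the generator is a deterministic function of (config, seed)", {
  a <- small_cohort(seed = 3)
  b <- small_cohort(seed = 3)
  expect_identical(a$table$intensities, b$table$intensities)
  expect_identical(a$peak_qc, b$peak_qc)
  expect_identical(a$truth, b$truth)
  c_ <- small_cohort(seed = 4)
  expect_false(identical(a$table$intensities, c_$table$intensities))
})

test_that("marker log-scale z-scores against generated controls match the configured effects", {
  co <- small_cohort(
    seed = 11, n_controls = 60, imds = c(A = 20L),
    n_features = 150, effect_range = c(6, 6), missing_rate = 0
  )
  md <- co$metadata
  logm <- log(co$table$intensities)
  zm <- zscore(logm[md$sample_id[md$role == "study"], ],
    controls = control_ids(md)
  )
  pat <- md$sample_id[md$class_label == "A"]
  mk <- co$truth$A$markers
  zbar <- mean(abs(zm$z[pat, mk]))
  # mean |z| of markers ~ effect size 6 (Monte-Carlo error over 100 draws)
  expect_lt(abs(zbar - 6), 0.5)
  # and each patient marker clears 3 SDs essentially always at effect 6
  expect_gt(mean(abs(zm$z[pat, mk]) >= 3), 0.99)
})

test_that("zero effect sizes leave patients indistinguishable from controls", {
  co <- small_cohort(
    seed = 13, n_controls = 40, imds = c(A = 15L),
    n_features = 60, effect_range = c(0, 0), missing_rate = 0
  )
  md <- co$metadata
  logm <- log(co$table$intensities[md$sample_id[md$role == "study"], ])
  pat <- md$sample_id[md$class_label == "A"]
  ctl <- control_ids(md)
  pvals <- vapply(
    co$truth$A$markers,
    function(f) stats::t.test(logm[pat, f], logm[ctl, f])$p.value,
    numeric(1)
  )
  expect_gt(min(pvals), 0.001) # no marker separates at the null
})

test_that("treated samples carry attenuated marker shifts", {
  cfg <- synthetic_cohort_config(
    n_controls = 50,
    imd_spec = data.frame(
      imd_id = "A", n_samples = 30L, n_treated = 15L,
      stringsAsFactors = FALSE
    ),
    n_features = 80, effect_range = c(6, 6), prop_up = 1,
    treated_attenuation = 0.5, missing_rate = 0
  )
  co <- simulate_cohort(cfg, seed = 5)
  md <- co$metadata
  logm <- log(co$table$intensities)
  zm <- zscore(logm[md$sample_id[md$role == "study"], ],
    controls = control_ids(md)
  )
  untr <- md$sample_id[md$treatment_status == "untreated" & md$class_label == "A"]
  trt <- md$sample_id[md$treatment_status == "treated"]
  mk <- co$truth$A$markers
  expect_gt(mean(zm$z[untr, mk]), 4.5) # ~6
  z_trt <- mean(zm$z[trt, mk]) # ~3
  expect_lt(z_trt, mean(zm$z[untr, mk]) - 1.5)
  expect_gt(z_trt, 1.5)
})

test_that("missingness is left-censoring at roughly the configured rate", {
  co <- small_cohort(
    seed = 17, n_controls = 100, imds = c(A = 1L),
    n_features = 200, missing_rate = 0.10
  )
  md <- co$metadata
  study <- co$table$intensities[md$sample_id[md$role == "study"], ]
  study <- study[, !grepl("^IS_", colnames(study))]
  rate <- mean(is.na(study))
  expect_lt(abs(rate - 0.10), 0.02)
  # censoring is intensity-dependent: observed minima exceed censored truth,
  # i.e. every remaining value sits above that feature's missing values
  expect_true(all(!is.na(co$table$intensities[md$sample_id[md$role == "qc"], ])))
})

test_that("QC peak table contains designed passes and failures", {
  co <- small_cohort(seed = 19, n_features = 200)
  kept <- qc_filter(co$peak_qc, reference_mass = co$reference_mass)
  all_feats <- unique(co$peak_qc$feature_id)
  expect_gt(length(kept), 0.8 * length(all_feats)) # most features are clean
  expect_lt(length(kept), length(all_feats)) # but not all
  # markers and internal standards are always generated well-behaved
  mk <- unlist(lapply(co$truth, `[[`, "markers"))
  expect_true(all(mk %in% kept))
  expect_true(all(co$is_ids %in% kept))
})

test_that("shared-marker disorders have more similar signatures than unrelated ones", {
  cfg <- synthetic_cohort_config(
    n_controls = 20,
    imd_spec = data.frame(
      imd_id = c("A", "B", "C"), n_samples = c(1L, 1L, 1L),
      stringsAsFactors = FALSE
    ),
    n_features = 120, effect_range = c(5, 8), prop_up = 1,
    shared_pairs = data.frame(
      imd_a = "A", imd_b = "B", n_shared = 3L,
      stringsAsFactors = FALSE
    ),
    missing_rate = 0
  )
  co <- simulate_cohort(cfg, seed = 23)
  expect_length(intersect(co$truth$A$markers, co$truth$B$markers), 3L)
  expect_length(intersect(co$truth$A$markers, co$truth$C$markers), 0L)
  m <- log(study_matrix(co))
  ctrls <- control_ids(co$metadata)
  groups <- imd_groups(co$metadata)
  store <- list()
  for (imd in names(groups)) {
    sets <- build_training_sets(
      m, groups[[imd]][1], ctrls,
      other_samples = vapply(
        groups[setdiff(names(groups), imd)], `[[`, character(1), 1
      ),
      seed = 31
    )
    store[[imd]] <- discover_signature(sets, imd)
  }
  sim_ab <- as.numeric(
    signature_similarity(effective_scores(store$A), store$B)
  )
  sim_ac <- as.numeric(
    signature_similarity(effective_scores(store$A), store$C)
  )
  expect_gt(sim_ab, sim_ac)
})

test_that("case-study fixtures reproduce the documented class topology", {
  co1 <- make_case_study_fixture(1, n_features = 200)
  md1 <- co1$metadata
  expect_length(control_ids(md1), 136L)
  g1 <- imd_groups(md1)
  expect_length(g1, 35L)
  expect_equal(sum(lengths(g1)), 77L)
  expect_equal(sum(lengths(g1) >= 2L), 12L)

  co2 <- make_case_study_fixture(2, n_features = 200)
  md2 <- co2$metadata
  expect_length(control_ids(md2), 68L)
  g2 <- imd_groups(md2)
  expect_length(g2, 11L)
  expect_equal(sum(lengths(g2)), 95L)

  # same seed -> identical fixture
  expect_identical(
    make_case_study_fixture(1, n_features = 200)$table$intensities,
    co1$table$intensities
  )
})
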