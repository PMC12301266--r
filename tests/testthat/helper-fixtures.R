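# Shared fixture builders; everything is generated in code, seeded.

toy_matrix <- function(n = 4, p = 3, seed = 1, prefix = "s") {
  set.seed(seed)
  matrix(stats::rlnorm(n * p, log(1e5), 0.4), n, p,
    dimnames = list(paste0(prefix, seq_len(n)), sprintf("F%03d", seq_len(p)))
  )
}

toy_table <- function(n = 4, p = 3, seed = 1) {
  feature_table(toy_matrix(n, p, seed))
}

# two-injection peak rows whose CVs land near a target (delta = cv/sqrt(2))
peak_rows <- function(id, rt_cv = 0.01, ppm = 0, area_cv = 0.05,
                      rt0 = 5, mz0 = 200, area0 = 1e5) {
  d_rt <- rt_cv / sqrt(2)
  d_ar <- area_cv / sqrt(2)
  data.frame(
    feature_id = id,
    rt = c(rt0 * (1 - d_rt), rt0 * (1 + d_rt)),
    mz = rep(mz0 * (1 + ppm / 1e6), 2),
    area = c(area0 * (1 - d_ar), area0 * (1 + d_ar)),
    stringsAsFactors = FALSE
  )
}

# compact synthetic cohort used across signature/diagnosis tests
small_cohort <- function(seed = 7, n_controls = 20,
                         imds = c(A = 3L, B = 2L, C = 1L),
                         n_features = 120, effect_range = c(5, 8),
                         missing_rate = 0.03) {
  cfg <- synthetic_cohort_config(
    n_controls = n_controls,
    imd_spec = data.frame(
      imd_id = names(imds), n_samples = unname(imds),
      stringsAsFactors = FALSE
    ),
    n_features = n_features, effect_range = effect_range,
    missing_rate = missing_rate
  )
  simulate_cohort(cfg, seed = seed)
}

# study-sample intensity matrix with LOD imputation applied
study_matrix <- function(cohort) {
  tab <- suppressWarnings(impute_lod(cohort$table))
  md <- cohort$metadata
  tab$intensities[md$sample_id[md$role == "study"], , drop = FALSE]
}
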