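#' Peak quality-control criteria
#'
#' Thresholds for retaining an LC-MS feature based on its behaviour across
#' repeated pooled-QC injections: retention-time reproducibility, mass
#' accuracy against a theoretical m/z, and peak-area reproducibility. A
#' feature is retained iff its RT CV is strictly below `rt_cv_max`, its mean
#' mass deviation is within `mass_ppm_max` ppm (inclusive), and its area CV
#' is strictly below `area_cv_max`. CVs use the n-1 standard deviation.
#'
#' @param rt_cv_max maximum retention-time CV, as a fraction (default 0.02,
#'   i.e. 2\%)
#' @param mass_ppm_max maximum absolute mass deviation in ppm (default 5)
#' @param area_cv_max maximum peak-area CV, as a fraction (default 0.20)
#' @return a `qc_criteria` list
#' @export
qc_criteria <- function(rt_cv_max = 0.02, mass_ppm_max = 5, area_cv_max = 0.20) {
  if (rt_cv_max <= 0 || mass_ppm_max <= 0 || area_cv_max <= 0) {
    stop_imdsig("all QC thresholds must be > 0")
  }
  structure(
    list(
      rt_cv_max = rt_cv_max, mass_ppm_max = mass_ppm_max,
      area_cv_max = area_cv_max
    ),
    class = "qc_criteria"
  )
}

#' Filter features on pooled-QC peak statistics
#'
#' Applies the three retention criteria of [qc_criteria()] to a long-format
#' table of per-injection peak observations. Features whose mean peak area is
#' zero are rejected and flagged rather than erroring; features without a
#' reference mass skip the ppm criterion and are flagged.
#'
#' @param peaks data.frame with columns `feature_id`, `rt` (minutes),
#'   `mz` (measured m/z) and `area` (counts); one row per QC injection.
#'   Every feature needs at least two injections.
#' @param criteria a [qc_criteria()]
#' @param reference_mass named numeric vector of theoretical m/z per feature
#'   (names are feature ids); features absent from it skip criterion 2.
#' @return character vector of retained feature ids, with attributes
#'   `stats` (per-feature data.frame of `rt_cv`, `mass_ppm`, `area_cv`,
#'   `retained`, `flag`) and `flagged` (ids that skipped a criterion or were
#'   rejected for a degenerate peak).
#' @export
qc_filter <- function(peaks, criteria = qc_criteria(), reference_mass = NULL) {
  need <- c("feature_id", "rt", "mz", "area")
  missing_cols <- setdiff(need, colnames(peaks))
  if (length(missing_cols)) {
    stop_imdsig("peak table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  by_feat <- split(peaks[, c("rt", "mz", "area")], peaks$feature_id)
  n_obs <- vapply(by_feat, nrow, integer(1))
  if (any(n_obs < 2L)) {
    stop_imdsig(
      "feature(s) with fewer than 2 QC injections: ",
      paste(names(by_feat)[n_obs < 2L], collapse = ", ")
    )
  }
  fid <- names(by_feat)
  rt_cv <- vapply(by_feat, function(d) cv_of(d$rt), numeric(1))
  area_mean <- vapply(by_feat, function(d) mean(d$area), numeric(1))
  area_cv <- vapply(by_feat, function(d) cv_of(d$area), numeric(1))
  mz_mean <- vapply(by_feat, function(d) mean(d$mz), numeric(1))

  has_ref <- fid %in% names(reference_mass)
  mass_ppm <- rep(NA_real_, length(fid))
  mass_ppm[has_ref] <- abs(mz_mean[has_ref] - reference_mass[fid[has_ref]]) /
    reference_mass[fid[has_ref]] * 1e6

  pass_rt <- !is.na(rt_cv) & rt_cv < criteria$rt_cv_max
  pass_mass <- ifelse(has_ref, mass_ppm <= criteria$mass_ppm_max, TRUE)
  pass_area <- !is.na(area_cv) & area_cv < criteria$area_cv_max
  zero_area <- area_mean == 0

  retained <- pass_rt & pass_mass & pass_area & !zero_area
  flag <- character(length(fid))
  flag[!has_ref] <- "no_reference_mass"
  flag[zero_area] <- "zero_mean_area"

  stats_df <- data.frame(
    feature_id = fid, rt_cv = rt_cv, mass_ppm = mass_ppm,
    area_cv = area_cv, retained = retained, flag = flag,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    fid[retained],
    stats = stats_df,
    flagged = fid[flag != ""]
  )
}
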