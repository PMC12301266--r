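#' Configuration for the synthetic cohort generator
#'
#' Describes a simulated untargeted-metabolomics cohort: a control
#' population with log-normal feature intensities, IMD patients whose marker
#' metabolites are shifted on the log scale by a stated number of control
#' SDs, attenuated effects in treated patients, intensity-dependent
#' (left-censored) missingness, pooled-QC samples with spiked internal
#' standards, and per-feature peak statistics over repeated QC injections so
#' the full QC-filter / normalization / discovery / diagnosis pipeline can
#' run end to end.
#'
#' @param n_controls number of control study samples (default 136)
#' @param imd_spec data.frame with one row per patient-sample block:
#'   columns `imd_id`, `n_samples`, and optionally `n_treated` (how many of
#'   the samples are treated; default 0). Marker architecture is generated
#'   per IMD from `n_markers`, `effect_range`, `prop_up`, unless
#'   `shared_pairs` links two IMDs.
#' @param n_features number of metabolite features (default 1000)
#' @param n_markers markers per IMD (default 5)
#' @param effect_range range (SD units on the log scale) from which marker
#'   effect sizes are drawn uniformly (default `c(3, 8)`)
#' @param prop_up probability a marker is elevated rather than depleted
#'   (default 0.8)
#' @param shared_pairs optional data.frame with columns `imd_a`, `imd_b`,
#'   `n_shared`: the two disorders share `n_shared` marker metabolites
#'   (same direction), emulating biochemically related IMDs
#' @param treated_attenuation multiplier on effect sizes for treated
#'   samples (default 0.5)
#' @param missing_rate expected left-censoring rate per feature among
#'   controls (default 0.05)
#' @param n_qc_samples pooled-QC injections included as table rows
#'   (default 6)
#' @param n_qc_injections peak-level QC observations per feature
#'   (default 6)
#' @param qc_fail_rate fraction of non-marker features generated to violate
#'   one QC retention criterion (default 0.05)
#' @param methods acquisition-method tags to spread features over
#' @return a `synthetic_cohort_config` list
#' @export
synthetic_cohort_config <- function(n_controls = 136L,
                                    imd_spec = NULL,
                                    n_features = 1000L,
                                    n_markers = 5L,
                                    effect_range = c(3, 8),
                                    prop_up = 0.8,
                                    shared_pairs = NULL,
                                    treated_attenuation = 0.5,
                                    missing_rate = 0.05,
                                    n_qc_samples = 6L,
                                    n_qc_injections = 6L,
                                    qc_fail_rate = 0.05,
                                    methods = c("RP+", "RP-", "HILIC-")) {
  if (is.null(imd_spec)) {
    imd_spec <- data.frame(
      imd_id = sprintf("IMD%02d", 1:5),
      n_samples = c(3L, 3L, 2L, 1L, 1L),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(imd_spec$n_treated)) imd_spec$n_treated <- 0L
  if (any(imd_spec$n_treated > imd_spec$n_samples)) {
    stop_imdsig("n_treated cannot exceed n_samples")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_imdsig("`missing_rate` must be in [0, 1)")
  }
  if (any(effect_range < 0)) stop_imdsig("effect sizes must be >= 0")
  if (n_markers * nrow(imd_spec) > n_features) {
    stop_imdsig("not enough features for disjoint marker sets")
  }
  structure(
    list(
      n_controls = as.integer(n_controls), imd_spec = imd_spec,
      n_features = as.integer(n_features), n_markers = as.integer(n_markers),
      effect_range = effect_range, prop_up = prop_up,
      shared_pairs = shared_pairs,
      treated_attenuation = treated_attenuation,
      missing_rate = missing_rate,
      n_qc_samples = as.integer(n_qc_samples),
      n_qc_injections = as.integer(n_qc_injections),
      qc_fail_rate = qc_fail_rate, methods = methods
    ),
    class = "synthetic_cohort_config"
  )
}

#' Simulate a synthetic metabolomics cohort
#'
#' Draws a complete cohort under a [synthetic_cohort_config()]: control
#' log-intensities are normal per feature (location uniform over
#' `log(1e4)`--`log(1e7)`, log-SD uniform over 0.2--0.6), patient samples
#' shift their IMD's marker features by `effect * log-SD` on the log scale
#' (so effects line up with downstream control-referenced z-scores), and
#' treated patients use attenuated effects. Missingness is
#' intensity-dependent: values below the feature's `missing_rate` control
#' quantile are censored to `NA`, mimicking limit-of-detection dropout.
#' Pooled-QC rows, one internal-standard feature per acquisition method
#' (low-CV, never missing), and a per-feature peak-QC table (retention
#' time, measured mass, area over repeated injections, with a configurable
#' fraction of deliberately failing features) complete the bundle.
#'
#' @param config a [synthetic_cohort_config()]
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   `(config, seed)`
#' @return list with `table` ([feature_table()], includes QC rows and IS
#'   features), `metadata` ([sample_metadata()]), `peak_qc` (data.frame for
#'   [qc_filter()]), `reference_mass` (named vector), `is_ids` (internal
#'   standards per method) and `truth` (marker ids, effects and directions
#'   per IMD)
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  with_seed(seed, {
    p <- config$n_features
    fid <- sprintf("F%04d", seq_len(p))
    method <- sample(config$methods, p, replace = TRUE)
    names(method) <- fid
    mu <- stats::runif(p, log(1e4), log(1e7))
    sig <- stats::runif(p, 0.2, 0.6)
    names(mu) <- names(sig) <- fid

    # marker architecture: disjoint marker sets, then overwrite shared pairs
    imds <- config$imd_spec$imd_id
    free <- sample(fid)
    truth <- list()
    k <- config$n_markers
    for (i in seq_along(imds)) {
      mk <- free[seq_len(k)]
      free <- free[-seq_len(k)]
      truth[[imds[i]]] <- list(
        markers = mk,
        effects = stats::runif(k, config$effect_range[1], config$effect_range[2]),
        direction = ifelse(stats::runif(k) < config$prop_up, 1, -1)
      )
    }
    if (!is.null(config$shared_pairs)) {
      for (r in seq_len(nrow(config$shared_pairs))) {
        a <- config$shared_pairs$imd_a[r]
        b <- config$shared_pairs$imd_b[r]
        ns <- config$shared_pairs$n_shared[r]
        sel <- seq_len(ns)
        truth[[b]]$markers[sel] <- truth[[a]]$markers[sel]
        truth[[b]]$effects[sel] <- truth[[a]]$effects[sel]
        truth[[b]]$direction[sel] <- truth[[a]]$direction[sel]
      }
    }

    ctrl_ids <- sprintf("CTRL%03d", seq_len(config$n_controls))
    pat <- do.call(rbind, lapply(seq_along(imds), function(i) {
      n <- config$imd_spec$n_samples[i]
      nt <- config$imd_spec$n_treated[i]
      data.frame(
        sample_id = sprintf("%s_S%02d", imds[i], seq_len(n)),
        class_label = imds[i],
        treatment_status = c(
          rep("untreated", n - nt),
          rep("treated", nt)
        ),
        stringsAsFactors = FALSE
      )
    }))
    qc_ids <- sprintf("QCPOOL%02d", seq_len(config$n_qc_samples))

    all_ids <- c(ctrl_ids, pat$sample_id, qc_ids)
    n_all <- length(all_ids)
    logx <- matrix(
      stats::rnorm(n_all * p, mean = rep(mu, each = n_all), sd = rep(sig, each = n_all)),
      nrow = n_all, dimnames = list(all_ids, fid)
    )
    # pooled QC rows: tight around the feature location
    logx[qc_ids, ] <- matrix(rep(mu, each = length(qc_ids)),
      nrow = length(qc_ids)
    ) + stats::rnorm(length(qc_ids) * p, 0, 0.05)
    # patient marker shifts on the log scale
    for (i in seq_len(nrow(pat))) {
      tr <- truth[[pat$class_label[i]]]
      att <- if (pat$treatment_status[i] == "treated") {
        config$treated_attenuation
      } else {
        1
      }
      logx[pat$sample_id[i], tr$markers] <-
        logx[pat$sample_id[i], tr$markers] +
        tr$direction * tr$effects * att * sig[tr$markers]
    }
    x <- exp(logx)

    # left-censor study rows below the per-feature missing_rate quantile
    if (config$missing_rate > 0) {
      thr <- exp(stats::qnorm(config$missing_rate, mu, sig))
      study_rows <- c(ctrl_ids, pat$sample_id)
      xs <- x[study_rows, , drop = FALSE]
      xs[sweep(xs, 2, thr, "<")] <- NA_real_
      x[study_rows, ] <- xs
    }

    # internal standards: one per method, constant spike with tiny CV
    is_ids <- paste0(
      "IS_",
      gsub("\\-", "neg", gsub("\\+", "pos", config$methods))
    )
    names(is_ids) <- config$methods
    is_mat <- exp(matrix(
      stats::rnorm(n_all * length(is_ids), log(1e6), 0.03),
      nrow = n_all, dimnames = list(all_ids, is_ids)
    ))
    x <- cbind(x, is_mat)
    method <- c(method, stats::setNames(config$methods, is_ids))

    tab <- feature_table(x, method = method)
    metadata <- sample_metadata(
      c(ctrl_ids, pat$sample_id, qc_ids),
      c(rep("control", length(ctrl_ids)), pat$class_label, rep("qc", length(qc_ids))),
      treatment_status = c(
        rep("untreated", length(ctrl_ids)),
        pat$treatment_status, rep("unknown", length(qc_ids))
      ),
      role = c(rep("study", length(ctrl_ids) + nrow(pat)), rep("qc", length(qc_ids)))
    )

    # peak-level QC observations; markers and IS always drawn well-behaved
    all_fid <- c(fid, unname(is_ids))
    marker_ids <- unique(unlist(lapply(truth, `[[`, "markers")))
    protected <- c(marker_ids, unname(is_ids))
    n_bad <- round(config$qc_fail_rate * length(all_fid))
    bad <- sample(setdiff(all_fid, protected), n_bad)
    rt0 <- stats::runif(length(all_fid), 0.5, 14)
    mz0 <- stats::runif(length(all_fid), 60, 900)
    names(rt0) <- names(mz0) <- all_fid
    nq <- config$n_qc_injections
    peak_rows <- lapply(all_fid, function(f) {
      fail_mode <- if (f %in% bad) sample(c("rt", "mass", "area"), 1) else "none"
      rt_cv <- if (fail_mode == "rt") {
        stats::runif(1, 0.05, 0.10)
      } else {
        stats::runif(1, 0.002, 0.008)
      }
      ppm_off <- if (fail_mode == "mass") {
        sample(c(-1, 1), 1) * stats::runif(1, 10, 20)
      } else {
        stats::runif(1, -2, 2)
      }
      area_cv <- if (fail_mode == "area") {
        stats::runif(1, 0.35, 0.6)
      } else {
        stats::runif(1, 0.03, 0.12)
      }
      area0 <- exp(stats::runif(1, log(1e4), log(1e7)))
      data.frame(
        feature_id = f,
        injection = seq_len(nq),
        rt = stats::rnorm(nq, rt0[f], rt0[f] * rt_cv),
        mz = stats::rnorm(nq, mz0[f] * (1 + ppm_off / 1e6), mz0[f] * 0.2e-6),
        area = area0 * exp(stats::rnorm(nq, 0, area_cv)),
        stringsAsFactors = FALSE
      )
    })
    peak_qc <- do.call(rbind, peak_rows)

    list(
      table = tab, metadata = metadata, peak_qc = peak_qc,
      reference_mass = mz0, is_ids = is_ids, truth = truth,
      config = config, seed = seed
    )
  })
}

#' Seeded fixtures shaped like the two evaluation cohorts
#'
#' Builds a synthetic cohort matching the class topology of the two
#' evaluation datasets: fixture 1 has 136 controls and 77 patients across 35
#' IMDs, 12 of them with multiple samples (multiplicities 17, 7, 7, 5, 3, 3
#' and six 2s, plus 23 singletons); fixture 2 has 68 controls and 95
#' patients across 11 IMDs (multiplicities 18, 17, 9, 9, 9, 8, 8, 6, 5, 4,
#' 2). Marker architectures are synthetic: 5 markers per IMD with effect
#' sizes drawn uniformly from 5--8 control SDs, one pair of disorders
#' sharing 2 of their 5 markers (emulating biochemically related IMDs), and
#' roughly a quarter of the extra samples of multi-sample IMDs marked as
#' treated (effects halved). 500 features keep full cross-validation runs
#' at desk scale.
#'
#' @param which 1 or 2
#' @param seed integer seed
#' @param n_features number of metabolite features (default 500)
#' @return a cohort bundle as returned by [simulate_cohort()]
#' @export
make_case_study_fixture <- function(which = 1L, seed = 2026L,
                                    n_features = 500L) {
  mult <- if (which == 1L) {
    c(17L, 7L, 7L, 5L, 3L, 3L, rep(2L, 6L), rep(1L, 23L))
  } else if (which == 2L) {
    c(18L, 17L, 9L, 9L, 9L, 8L, 8L, 6L, 5L, 4L, 2L)
  } else {
    stop_imdsig("`which` must be 1 or 2")
  }
  spec <- data.frame(
    imd_id = sprintf("IMD%02d", seq_along(mult)),
    n_samples = mult,
    n_treated = ifelse(mult > 1L, pmax(0L, (mult - 1L) %/% 4L), 0L),
    stringsAsFactors = FALSE
  )
  cfg <- synthetic_cohort_config(
    n_controls = if (which == 1L) 136L else 68L,
    imd_spec = spec,
    n_features = n_features,
    n_markers = 5L,
    effect_range = c(5, 8),
    prop_up = 0.8,
    shared_pairs = data.frame(
      imd_a = "IMD02", imd_b = "IMD03", n_shared = 2L,
      stringsAsFactors = FALSE
    ),
    treated_attenuation = 0.5,
    missing_rate = 0.03
  )
  simulate_cohort(cfg, seed = seed)
}
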