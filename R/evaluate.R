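#' Repeated random sub-sampling cross-validation scheme
#'
#' Controls the evaluation harness. Each repetition draws, within each
#' class: `n_train_controls` controls for training and `n_test_controls` for
#' the diagnostic test; per IMD with `m` samples, one discovery sample,
#' `max(0, min(n_refine_rounds, m - 3))` refinement samples (one per round)
#' and the remaining `m - 1 - n_refine` as test samples, so every
#' multi-sample IMD contributes at least one test sample and singleton IMDs
#' contribute their sample to discovery only. Samples are re-drawn every
#' repetition, so the same sample may serve different phases across
#' repetitions.
#'
#' @param n_repetitions repetitions of the random sub-sampling (default 100)
#' @param n_refine_rounds refinement rounds tracked after the initial
#'   discovery (default 3)
#' @param n_train_controls controls available to training sets (default 20)
#' @param n_test_controls controls accompanying the test samples, used as
#'   their z-reference and scored as negatives (default 5)
#' @param n_set1 set1 replicates per discovery, see [build_training_sets()]
#' @param k_top top-weight metabolites per set1, see [discover_signature()]
#' @param s L1 bound for [sparse_weights()] (`NULL` = `sqrt(p)/2`)
#' @param top_k ranks counted as a correct diagnosis (default 3)
#' @param method similarity variant, see [signature_similarity()]
#' @param training_treatment `"all"` or `"untreated"`: which patient samples
#'   may serve discovery/refinement (treated samples are then test-only)
#' @param log_intensities log-transform intensities before standardization
#'   (default `TRUE`): LC-MS intensity noise is multiplicative, so z-scores
#'   of raw intensities are heavy-tailed and a single extreme background
#'   value can dominate a similarity score; on the log scale control
#'   z-values are approximately standard normal
#' @param seed master seed; the whole harness is a deterministic function
#'   of it
#' @return a `cv_scheme` list
#' @export
cv_scheme <- function(n_repetitions = 100L, n_refine_rounds = 3L,
                      n_train_controls = 20L, n_test_controls = 5L,
                      n_set1 = 3L, k_top = 20L, s = NULL, top_k = 3L,
                      method = "signature_norm",
                      training_treatment = c("all", "untreated"),
                      log_intensities = TRUE,
                      seed = 1L) {
  structure(
    list(
      n_repetitions = as.integer(n_repetitions),
      n_refine_rounds = as.integer(n_refine_rounds),
      n_train_controls = as.integer(n_train_controls),
      n_test_controls = as.integer(n_test_controls),
      n_set1 = as.integer(n_set1), k_top = as.integer(k_top), s = s,
      top_k = as.integer(top_k), method = method,
      training_treatment = match.arg(training_treatment),
      log_intensities = isTRUE(log_intensities),
      seed = as.integer(seed)
    ),
    class = "cv_scheme"
  )
}

# discovery / refinement / test split sizes for an IMD with m samples
refine_allocation <- function(m, n_rounds) {
  n_refine <- max(0L, min(n_rounds, m - 3L))
  c(discovery = 1L, refine = n_refine, test = m - 1L - n_refine)
}

#' Run the cross-validation harness
#'
#' For every repetition: allocate samples per [cv_scheme()], discover one
#' signature per IMD (set2 companions are the other IMDs' discovery
#' samples), diagnose the held-out test samples and test controls against
#' the store, then perform the configured refinement rounds (set2 companions
#' are the other IMDs' existing signatures) re-diagnosing after each round.
#' The rank of the true IMD is recorded per test sample and stage; test
#' controls have no true IMD and contribute a false-positive summary (their
#' top similarity per stage).
#'
#' IMDs with a single sample are used for discovery and as set2 companions
#' but are excluded from testing, with a message the first time.
#'
#' @param x a [feature_table()] ready for analysis (QC-filtered, normalized,
#'   imputed — or raw synthetic intensities)
#' @param metadata a [sample_metadata()]
#' @param scheme a [cv_scheme()]
#' @return a `cv_result`: list with `stage_counts` (repetitions x stages x
#'   ranks array of correct-diagnosis counts), `imd_counts` (repetitions x
#'   IMD x stages x ranks), `control_top_sim` (repetitions x stages mean
#'   top similarity of test controls), `n_test`, `stages`, `imds_tested`
#'   and the `scheme`
#' @export
run_cross_validation <- function(x, metadata, scheme = cv_scheme()) {
  m <- if (inherits(x, "feature_table")) x$intensities else x
  if (anyNA(m)) stop_imdsig("table contains missing values; impute first")
  if (scheme$log_intensities) {
    if (any(m <= 0)) {
      stop_imdsig("log transform requires strictly positive intensities")
    }
    m <- log(m)
  }
  ctrls <- control_ids(metadata)
  groups <- imd_groups(metadata)
  if (length(ctrls) < scheme$n_train_controls + scheme$n_test_controls) {
    stop_imdsig(
      "need at least ", scheme$n_train_controls + scheme$n_test_controls,
      " controls; got ", length(ctrls)
    )
  }
  sizes <- vapply(groups, length, integer(1))
  singletons <- names(groups)[sizes < 2L]
  if (length(singletons)) {
    message(
      length(singletons), " IMD(s) with a single sample excluded from ",
      "testing (used for discovery only)"
    )
  }
  tested <- names(groups)[sizes >= 2L]
  if (!length(tested)) stop_imdsig("no IMD has >= 2 samples; nothing to test")
  alloc <- lapply(sizes, refine_allocation, n_rounds = scheme$n_refine_rounds)
  n_test_total <- sum(vapply(alloc[tested], `[[`, integer(1), "test"))
  stages <- c("initial", paste0("iteration", seq_len(scheme$n_refine_rounds)))
  n_stage <- length(stages)

  treated_ok <- function(ids) {
    if (scheme$training_treatment == "untreated") {
      tr <- metadata$treatment_status[match(ids, metadata$sample_id)]
      ids[tr != "treated"]
    } else {
      ids
    }
  }

  stage_counts <- array(0L,
    dim = c(scheme$n_repetitions, n_stage, 3L),
    dimnames = list(NULL, stages, paste0("rank", 1:3))
  )
  imd_counts <- array(0L,
    dim = c(scheme$n_repetitions, length(tested), n_stage, 3L),
    dimnames = list(NULL, tested, stages, paste0("rank", 1:3))
  )
  control_top_sim <- matrix(NA_real_,
    nrow = scheme$n_repetitions, ncol = n_stage,
    dimnames = list(NULL, stages)
  )

  with_seed(scheme$seed, {
    for (rep_i in seq_len(scheme$n_repetitions)) {
      csh <- sample(ctrls)
      train_ctrl <- csh[seq_len(scheme$n_train_controls)]
      test_ctrl <- csh[scheme$n_train_controls + seq_len(scheme$n_test_controls)]

      split_of <- lapply(names(groups), function(imd) {
        ids <- groups[[imd]]
        a <- alloc[[imd]]
        train_pool <- treated_ok(ids)
        n_train <- a[["discovery"]] + a[["refine"]]
        if (length(train_pool) < n_train) train_pool <- ids
        train <- sample(train_pool, n_train)
        list(
          discovery = train[1L],
          refine = if (a[["refine"]] > 0L) train[-1L] else character(0),
          test = setdiff(ids, train)
        )
      })
      names(split_of) <- names(groups)

      disc_sample <- vapply(split_of, `[[`, character(1), "discovery")
      store <- list()
      for (imd in names(groups)) {
        others <- disc_sample[setdiff(names(groups), imd)]
        sets <- build_training_sets(
          m, disc_sample[[imd]], train_ctrl,
          other_samples = others,
          n_set1 = scheme$n_set1
        )
        store[[imd]] <- discover_signature(
          sets, imd,
          k_top = scheme$k_top, s = scheme$s
        )
      }

      test_ids <- unlist(lapply(split_of[tested], `[[`, "test"))
      test_truth <- rep(tested, vapply(split_of[tested], function(sp) length(sp$test), integer(1)))
      zt <- suppressWarnings(
        zscore(m[c(test_ids, test_ctrl), , drop = FALSE], controls = test_ctrl)
      )

      diagnose_stage <- function(stage_i) {
        for (t in seq_along(test_ids)) {
          rep_t <- rank_diagnoses(zt$z[test_ids[t], ], store,
            top_k = scheme$top_k, method = scheme$method
          )
          r <- true_rank(rep_t, test_truth[t])
          if (!is.na(r) && r <= 3L) {
            stage_counts[rep_i, stage_i, r] <<- stage_counts[rep_i, stage_i, r] + 1L
            imd_counts[rep_i, test_truth[t], stage_i, r] <<-
              imd_counts[rep_i, test_truth[t], stage_i, r] + 1L
          }
        }
        tops <- vapply(test_ctrl, function(cid) {
          rep_c <- rank_diagnoses(zt$z[cid, ], store,
            top_k = scheme$top_k, method = scheme$method
          )
          rep_c$similarity[1L]
        }, numeric(1))
        control_top_sim[rep_i, stage_i] <<- mean(tops, na.rm = TRUE)
      }

      diagnose_stage(1L)
      for (round_i in seq_len(scheme$n_refine_rounds)) {
        for (imd in names(groups)) {
          rs <- split_of[[imd]]$refine
          if (length(rs) < round_i) next
          sets <- build_training_sets(
            m, rs[round_i], train_ctrl,
            other_signatures = store[setdiff(names(store), imd)],
            n_set1 = scheme$n_set1
          )
          new_sig <- discover_signature(
            sets, imd,
            k_top = scheme$k_top, s = scheme$s
          )
          store[[imd]] <- refine_signature(store[[imd]], new_sig)
        }
        diagnose_stage(round_i + 1L)
      }
    }
  })

  structure(
    list(
      stage_counts = stage_counts, imd_counts = imd_counts,
      control_top_sim = control_top_sim,
      n_test = n_test_total, stages = stages, imds_tested = tested,
      n_test_per_imd = vapply(alloc[tested], `[[`, integer(1), "test"),
      scheme = scheme
    ),
    class = "cv_result"
  )
}

#' Per-stage rank-count table
#'
#' Summarizes a [run_cross_validation()] result as the mean (SD across
#' repetitions) number of test samples whose true IMD appeared at rank 1, 2
#' and 3, per refinement stage, plus the top-3 total.
#'
#' @param cv a `cv_result`
#' @return data.frame with one row per stage and columns
#'   `rank1_mean`, `rank1_sd`, ..., `total_mean`, `total_sd`, `n_test`
#' @export
rank_count_table <- function(cv) {
  sc <- cv$stage_counts
  tot <- sc[, , 1L, drop = FALSE] + sc[, , 2L, drop = FALSE] +
    sc[, , 3L, drop = FALSE]
  out <- data.frame(
    stage = cv$stages,
    rank1_mean = apply(sc[, , 1L, drop = FALSE], 2, mean),
    rank1_sd = apply(sc[, , 1L, drop = FALSE], 2, stats::sd),
    rank2_mean = apply(sc[, , 2L, drop = FALSE], 2, mean),
    rank2_sd = apply(sc[, , 2L, drop = FALSE], 2, stats::sd),
    rank3_mean = apply(sc[, , 3L, drop = FALSE], 2, mean),
    rank3_sd = apply(sc[, , 3L, drop = FALSE], 2, stats::sd),
    total_mean = apply(tot, 2, mean),
    total_sd = apply(tot, 2, stats::sd),
    n_test = cv$n_test,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Per-IMD rank-count table
#'
#' Mean (SD) correct diagnoses per rank for each tested IMD at one stage
#' (default the final refinement stage), mirroring the per-disorder
#' breakdown of the evaluation.
#'
#' @param cv a `cv_result`
#' @param stage stage name or index; defaults to the last stage
#' @return data.frame with one row per tested IMD
#' @export
summarize_per_imd <- function(cv, stage = NULL) {
  stage <- stage %||% cv$stages[length(cv$stages)]
  if (is.numeric(stage)) stage <- cv$stages[stage]
  ic <- cv$imd_counts[, , stage, , drop = FALSE]
  dn <- dimnames(cv$imd_counts)[[2L]]
  get <- function(r, f) {
    vapply(seq_along(dn), function(i) f(ic[, i, 1L, r]), numeric(1))
  }
  tot <- ic[, , 1L, 1L, drop = FALSE] + ic[, , 1L, 2L, drop = FALSE] +
    ic[, , 1L, 3L, drop = FALSE]
  data.frame(
    imd_id = dn,
    n_test = unname(cv$n_test_per_imd[dn]),
    rank1_mean = get(1L, mean), rank1_sd = get(1L, stats::sd),
    rank2_mean = get(2L, mean), rank2_sd = get(2L, stats::sd),
    rank3_mean = get(3L, mean), rank3_sd = get(3L, stats::sd),
    total_mean = vapply(seq_along(dn), function(i) mean(tot[, i, 1L, 1L]), numeric(1)),
    total_sd = vapply(seq_along(dn), function(i) stats::sd(tot[, i, 1L, 1L]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(
    "cv_result: ", x$scheme$n_repetitions, " repetitions, ",
    x$n_test, " test samples from ", length(x$imds_tested), " IMDs\n",
    sep = ""
  )
  print(rank_count_table(x))
  invisible(x)
}
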