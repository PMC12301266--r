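#' Build the two groups of training sets for one target patient
#'
#' Signature discovery for a target IMD patient uses two kinds of small
#' training sets. A *set1* pairs the target sample with five control samples
#' and finds metabolites separating the patient from the control population;
#' by default `n_set1` such sets are drawn (control quintets resampled
#' without replacement within a set, independently across sets). A *set2*
#' pairs the target with one sample from a different IMD — or, during
#' refinement, with an existing signature's reference profile — and finds
#' metabolites separating the two disorders; one set2 is built per other
#' IMD.
#'
#' Within a set1, z-scores are referenced to that set's five controls.
#' A set2 contains no controls of its own, so both its rows are referenced
#' to the full control pool supplied in `controls`. When the companion is a
#' signature, its row is the reference-score profile (expert multipliers
#' applied), zero off-signature.
#'
#' @param x a [feature_table()] (imputed, i.e. no missing cells) or matrix
#' @param target_id the target patient sample id
#' @param controls pool of control sample ids (>= 5)
#' @param other_samples named character vector of one sample id per other
#'   IMD (names = IMD ids); may be empty
#' @param other_signatures named list of [imd_signature()] used as set2
#'   companions (refinement); may be empty, but at least one set2 companion
#'   of either kind is required
#' @param n_set1 number of set1 replicates (default 3)
#' @param seed optional integer seed making the control draws reproducible
#' @return list of `training_set` objects, each with `kind` (`"set1"` or
#'   `"set2"`), `target_id`, `companion_ids`, `z` (set z-matrix) and
#'   `target_z` (the target's z-profile in that set)
#' @export
build_training_sets <- function(x, target_id, controls,
                                other_samples = character(0),
                                other_signatures = list(),
                                n_set1 = 3L, seed = NULL) {
  m <- if (inherits(x, "feature_table")) x$intensities else x
  if (!target_id %in% rownames(m)) {
    stop_imdsig("target sample '", target_id, "' not in table")
  }
  if (length(controls) < 5L) {
    stop_imdsig(
      "need at least 5 control samples for a training set; got ",
      length(controls)
    )
  }
  if (!length(other_samples) && !length(other_signatures)) {
    stop_imdsig("need at least one other-IMD sample or signature for set2")
  }
  if (n_set1 < 1L) stop_imdsig("`n_set1` must be >= 1")

  sets <- list()
  with_seed(seed, {
    for (i in seq_len(n_set1)) {
      quintet <- sample(controls, 5L)
      sub <- m[c(target_id, quintet), , drop = FALSE]
      zm <- suppressWarnings(zscore(sub, controls = quintet))
      sets[[length(sets) + 1L]] <- structure(
        list(
          kind = "set1", target_id = target_id, companion_ids = quintet,
          z = zm$z, target_z = zm$z[target_id, ]
        ),
        class = "training_set"
      )
    }
    # pool-referenced z for the target and every set2 sample companion
    pool_rows <- unique(c(target_id, unname(other_samples), controls))
    zp <- suppressWarnings(
      zscore(m[pool_rows, , drop = FALSE], controls = controls)
    )
    for (imd in names(other_samples)) {
      comp <- other_samples[[imd]]
      zmat <- zp$z[c(target_id, comp), , drop = FALSE]
      sets[[length(sets) + 1L]] <- structure(
        list(
          kind = "set2", target_id = target_id, companion_ids = comp,
          companion_imd = imd, z = zmat, target_z = zmat[target_id, ]
        ),
        class = "training_set"
      )
    }
    for (imd in names(other_signatures)) {
      sig <- other_signatures[[imd]]
      prof <- rep(0, ncol(zp$z))
      names(prof) <- colnames(zp$z)
      sc <- effective_scores(sig)
      shared <- intersect(names(sc), names(prof))
      prof[shared] <- sc[shared]
      zmat <- rbind(zp$z[target_id, ], prof)
      rownames(zmat) <- c(target_id, paste0("signature:", imd))
      sets[[length(sets) + 1L]] <- structure(
        list(
          kind = "set2", target_id = target_id,
          companion_ids = paste0("signature:", imd), companion_imd = imd,
          z = zmat, target_z = zmat[target_id, ]
        ),
        class = "training_set"
      )
    }
  })
  sets
}

#' Discover an IMD signature from training sets
#'
#' Runs sparse hierarchical clustering weighting on every training set and
#' assembles the signature by the discovery rule: the intersection across
#' set1 replicates of each set's top-`k_top` weighted metabolites, unioned
#' with the single top-weighted metabolite from every set2. The reference
#' score of each signature metabolite is the mean of the target sample's
#' z-values across all training sets in which that metabolite was scored.
#'
#' @param sets list of training sets from [build_training_sets()], at least
#'   one of each kind
#' @param imd_id disorder id for the resulting signature
#' @param k_top number of top-weighted metabolites taken per set1
#'   (default 20)
#' @param s L1 bound for [sparse_weights()]; `NULL` for the `sqrt(p)/2`
#'   default
#' @param metric dissimilarity metric for [feature_dissimilarities()]
#' @return an [imd_signature()] with `iteration = 0`
#' @export
discover_signature <- function(sets, imd_id, k_top = 20L, s = NULL,
                               metric = "squared") {
  kinds <- vapply(sets, function(st) st$kind, character(1))
  if (!any(kinds == "set1") || !any(kinds == "set2")) {
    stop_imdsig("need at least one training set of each kind")
  }
  top_by_set <- lapply(sets, function(st) {
    D <- feature_dissimilarities(st$z, metric = metric)
    wv <- sparse_weights(D, s = s)
    select_top_k(wv, if (st$kind == "set1") k_top else 1L)
  })
  set1_tops <- top_by_set[kinds == "set1"]
  set2_tops <- top_by_set[kinds == "set2"]
  core <- Reduce(intersect, set1_tops)
  extra <- unique(unlist(set2_tops))
  metab <- sort(union(core, extra))
  if (!length(metab)) {
    stop_imdsig(
      "no discriminating metabolites: top-", k_top, " intersection and ",
      "set2 union are both empty; consider fewer set1 replicates or a ",
      "larger k_top"
    )
  }
  zvals <- vapply(
    sets,
    function(st) unname(st$target_z[metab]),
    numeric(length(metab))
  )
  zvals <- matrix(zvals, nrow = length(metab))
  ref <- rowMeans(zvals, na.rm = TRUE)
  target <- unique(vapply(sets, function(st) st$target_id, character(1)))
  entries <- data.frame(
    feature_id = metab, reference_score = ref,
    weight_multiplier = 1, n_contributions = 1L,
    stringsAsFactors = FALSE
  )
  imd_signature(
    imd_id, entries,
    iteration = 0L,
    provenance = list(list(
      iteration = 0L, target = target,
      n_set1 = sum(kinds == "set1"), n_set2 = sum(kinds == "set2")
    ))
  )
}

#' Refine a signature with a newly discovered one
#'
#' Merges the signature discovered from a new patient sample into the
#' existing one. The metabolite union is retained, and each metabolite's
#' reference score is updated as a running mean over refinement rounds,
#' `(n_old * old + new) / (n_old + 1)`, so scores accumulated over earlier
#' rounds carry proportionally higher weight and outlier rounds are damped.
#'
#' Under the default `absent = "decay"` policy, a metabolite missing from
#' the incoming signature contributes a zero observation to its running
#' mean: metabolites repeatedly confirmed across patients keep their score,
#' while entries specific to a single training sample are gradually phased
#' out as refinement accumulates. `absent = "keep"` instead freezes the
#' score and count of metabolites absent from the incoming signature.
#' Metabolites appearing for the first time enter with their observed score
#' and a contribution count of 1, so they carry little cumulative weight
#' until later rounds confirm them. The iteration counter increases by one.
#'
#' @param old the current [imd_signature()]
#' @param new a signature for the same IMD discovered from the new sample
#' @param absent `"decay"` (default) or `"keep"`, see Details
#' @return the refined [imd_signature()]
#' @export
refine_signature <- function(old, new, absent = c("decay", "keep")) {
  absent <- match.arg(absent)
  if (!identical(old$imd_id, new$imd_id)) {
    stop_imdsig(
      "cannot refine '", old$imd_id, "' with a signature for '",
      new$imd_id, "'"
    )
  }
  eo <- old$entries
  en <- new$entries
  all_ids <- sort(union(eo$feature_id, en$feature_id))
  io <- match(all_ids, eo$feature_id)
  jn <- match(all_ids, en$feature_id)
  score <- numeric(length(all_ids))
  n_contr <- numeric(length(all_ids))
  mult <- numeric(length(all_ids))
  for (k in seq_along(all_ids)) {
    if (!is.na(io[k]) && !is.na(jn[k])) {
      n_old <- eo$n_contributions[io[k]]
      score[k] <- (n_old * eo$reference_score[io[k]] +
        en$reference_score[jn[k]]) / (n_old + 1)
      n_contr[k] <- n_old + 1
      mult[k] <- eo$weight_multiplier[io[k]]
    } else if (!is.na(io[k])) {
      n_old <- eo$n_contributions[io[k]]
      if (absent == "decay") {
        score[k] <- n_old * eo$reference_score[io[k]] / (n_old + 1)
        n_contr[k] <- n_old + 1
      } else {
        score[k] <- eo$reference_score[io[k]]
        n_contr[k] <- n_old
      }
      mult[k] <- eo$weight_multiplier[io[k]]
    } else {
      score[k] <- en$reference_score[jn[k]]
      n_contr[k] <- en$n_contributions[jn[k]]
      mult[k] <- en$weight_multiplier[jn[k]]
    }
  }
  imd_signature(
    old$imd_id,
    data.frame(
      feature_id = all_ids, reference_score = score,
      weight_multiplier = mult, n_contributions = n_contr,
      stringsAsFactors = FALSE
    ),
    iteration = old$iteration + 1L,
    provenance = c(old$provenance, new$provenance)
  )
}

#' Apply expert weight overrides to a signature
#'
#' Scales selected metabolites' influence on similarity scoring without
#' altering their learned reference scores, e.g. down-weighting metabolites
#' shared between biochemically related disorders before a second-round
#' subtype diagnosis.
#'
#' @param sig an [imd_signature()]
#' @param overrides named numeric vector of positive factors
#'   (names = feature ids)
#' @return the signature with `weight_multiplier` updated
#' @export
apply_expert_weights <- function(sig, overrides) {
  if (!length(overrides)) {
    return(sig)
  }
  if (any(overrides <= 0)) {
    stop_imdsig("expert weight factors must be > 0")
  }
  absent <- setdiff(names(overrides), sig$entries$feature_id)
  if (length(absent)) {
    warn_imdsig(
      "ignoring override(s) for metabolite(s) not in signature '",
      sig$imd_id, "': ", paste(absent, collapse = ", ")
    )
  }
  present <- intersect(names(overrides), sig$entries$feature_id)
  idx <- match(present, sig$entries$feature_id)
  sig$entries$weight_multiplier[idx] <- overrides[present]
  sig
}

#' Seed a newly detected metabolite into a signature
#'
#' Metabolites that appear in the assay panel after a signature was built
#' are integrated gradually: the entry starts with its observed score damped
#' by `initial_scale`, gaining full influence only as later refinement
#' rounds confirm it.
#'
#' @param sig an [imd_signature()]
#' @param feature_id the new metabolite (must not already be present)
#' @param score the observed reference z-score for the new metabolite
#' @param initial_scale damping factor in (0, 1] (default 0.1)
#' @return the extended [imd_signature()]
#' @export
seed_new_metabolite <- function(sig, feature_id, score, initial_scale = 0.1) {
  if (feature_id %in% sig$entries$feature_id) {
    stop_imdsig(
      "metabolite '", feature_id, "' already in signature '", sig$imd_id, "'"
    )
  }
  if (initial_scale <= 0 || initial_scale > 1) {
    stop_imdsig("`initial_scale` must be in (0, 1]")
  }
  sig$entries <- rbind(
    sig$entries,
    data.frame(
      feature_id = feature_id, reference_score = score * initial_scale,
      weight_multiplier = 1, n_contributions = 1L,
      stringsAsFactors = FALSE
    )
  )
  imd_signature(sig$imd_id, sig$entries,
    iteration = sig$iteration,
    provenance = sig$provenance
  )
}
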