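co <- small_cohort()
# training and diagnosis operate on log intensities
m_study <- log(study_matrix(co))
md <- co$metadata
ctrls <- control_ids(md)
groups <- imd_groups(md)

test_that("training sets follow the two-group design and are seeded", {
  sets <- build_training_sets(m_study, "A_S01", ctrls,
    other_samples = c(B = "B_S01", C = "C_S01"),
    n_set1 = 3, seed = 99
  )
  kinds <- vapply(sets, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "set1"), 3L)
  expect_equal(sum(kinds == "set2"), 2L) # one per other IMD
  for (st in sets[kinds == "set1"]) {
    expect_length(st$companion_ids, 5L)
    expect_true(all(st$companion_ids %in% ctrls))
  }
  # reproducible control quintets
  sets2 <- build_training_sets(m_study, "A_S01", ctrls,
    other_samples = c(B = "B_S01", C = "C_S01"),
    n_set1 = 3, seed = 99
  )
  expect_identical(
    lapply(sets, `[[`, "companion_ids"),
    lapply(sets2, `[[`, "companion_ids")
  )
  # preconditions
  expect_error(
    build_training_sets(m_study, "A_S01", ctrls[1:4],
      other_samples = c(B = "B_S01")
    ),
    "at least 5 control"
  )
  expect_error(
    build_training_sets(m_study, "A_S01", ctrls),
    "other-IMD sample or signature"
  )
})

test_that("discovery combines the top-20 intersection with set2 top-1 union", {
  # construct training sets with controlled z so the selections are known:
  # features A, B dominate both set1 replicates; C dominates the set2 pair
  mk_set <- function(kind, zrow, ids) {
    z <- rbind(target = zrow, other = rep(0, length(zrow)))
    colnames(z) <- ids
    structure(
      list(
        kind = kind, target_id = "target", companion_ids = "other",
        z = z, target_z = z["target", ]
      ),
      class = "training_set"
    )
  }
  ids <- c("A", "B", "C", "D")
  s1a <- mk_set("set1", c(6, 5, 0, 0.2), ids)
  s1b <- mk_set("set1", c(6, 5, 0, 0), ids)
  s2 <- mk_set("set2", c(0.1, 0, 8, 0), ids)
  sig <- discover_signature(list(s1a, s1b, s2), "X", k_top = 2, s = 2)
  expect_identical(sig$entries$feature_id, c("A", "B", "C"))
  # reference scores are the mean target z across all sets
  expect_equal(
    sig$entries$reference_score,
    c(mean(c(6, 6, 0.1)), mean(c(5, 5, 0)), mean(c(0, 0, 8)))
  )
  expect_equal(sig$iteration, 0L)

  # a set2 top-1 already in the intersection does not duplicate
  s2b <- mk_set("set2", c(9, 0, 0, 0), ids)
  sig2 <- discover_signature(list(s1a, s1b, s2b), "X", k_top = 2, s = 2)
  expect_identical(sig2$entries$feature_id, c("A", "B"))

  # discovery is invariant to the order of training sets
  sig3 <- discover_signature(list(s2, s1b, s1a), "X", k_top = 2, s = 2)
  expect_equal(sig3$entries, sig$entries)
})

test_that("end-to-end discovery recovers strongly shifted marker features", {
  sets <- build_training_sets(m_study, "A_S01", ctrls,
    other_samples = c(B = "B_S01", C = "C_S01"),
    n_set1 = 3, seed = 1
  )
  sig <- discover_signature(sets, "A")
  up_markers <- co$truth$A$markers[co$truth$A$direction > 0]
  expect_true(all(up_markers %in% sig$entries$feature_id))
  # marker z ~ effect (>= 5) + unit patient noise: clearly positive scores
  scores <- with(sig$entries, stats::setNames(reference_score, feature_id))
  expect_true(all(scores[up_markers] > 2))
})

test_that("refinement is a running mean that weights earlier rounds more", {
  old <- imd_signature("X", data.frame(
    feature_id = c("A", "B"), reference_score = c(3, 1),
    weight_multiplier = 1, n_contributions = c(2, 1)
  ))
  new <- imd_signature("X", data.frame(
    feature_id = c("A", "C"), reference_score = c(0, 4),
    weight_multiplier = 1, n_contributions = 1
  ))
  ref <- refine_signature(old, new)
  e <- ref$entries
  expect_identical(e$feature_id, c("A", "B", "C"))
  # shared A: running mean (2*3 + 0)/3; B absent from new: decays toward 0;
  # C newly observed: enters at its score with a single contribution
  expect_equal(e$reference_score, c((2 * 3 + 0) / 3, (1 * 1 + 0) / 2, 4))
  expect_equal(e$n_contributions, c(3, 2, 1))
  expect_equal(ref$iteration, 1L)

  # the keep policy freezes metabolites absent from the incoming signature
  kept <- refine_signature(old, new, absent = "keep")
  expect_equal(kept$entries$reference_score, c(2, 1, 4))
  expect_equal(kept$entries$n_contributions, c(3, 1, 1))

  # refining with an identical signature leaves scores fixed, counts up
  twice <- refine_signature(ref, imd_signature("X", ref$entries[
    ,
    c("feature_id", "reference_score")
  ] |> transform(weight_multiplier = 1, n_contributions = 1)))
  expect_equal(twice$entries$reference_score, e$reference_score)
  expect_equal(twice$entries$n_contributions, e$n_contributions + 1)

  expect_error(
    refine_signature(old, imd_signature("Y", new$entries)),
    "cannot refine"
  )
})

test_that("metabolite count never decreases under refinement", {
  set.seed(5)
  sig <- imd_signature("X", data.frame(
    feature_id = sprintf("f%02d", 1:6),
    reference_score = rnorm(6)
  ))
  for (i in 1:10) {
    ids <- sample(sprintf("f%02d", 1:12), 4)
    new <- imd_signature("X", data.frame(
      feature_id = sort(ids), reference_score = rnorm(4)
    ))
    refined <- refine_signature(sig, new)
    expect_gte(nrow(refined$entries), nrow(sig$entries))
    expect_true(all(sig$entries$feature_id %in% refined$entries$feature_id))
    sig <- refined
  }
})

test_that("expert weights rescale scoring without touching learned scores", {
  sig <- imd_signature("X", data.frame(
    feature_id = c("A", "B"), reference_score = c(4, 2)
  ))
  half <- apply_expert_weights(sig, c(A = 0.5))
  expect_equal(half$entries$reference_score, c(4, 2))
  expect_equal(unname(effective_scores(half)), c(2, 2))
  expect_equal(apply_expert_weights(sig, stats::setNames(numeric(0), character(0))), sig)
  expect_warning(
    apply_expert_weights(sig, c(Z = 2)),
    "not in signature"
  )
  expect_error(apply_expert_weights(sig, c(A = -1)), "must be > 0")
})

test_that("new metabolites enter with damped weight", {
  sig <- imd_signature("X", data.frame(feature_id = "A", reference_score = 3))
  out <- seed_new_metabolite(sig, "B", score = 4)
  expect_equal(
    out$entries$reference_score[out$entries$feature_id == "B"], 0.4
  )
  undamped <- seed_new_metabolite(sig, "B", score = 4, initial_scale = 1)
  expect_equal(
    undamped$entries$reference_score[undamped$entries$feature_id == "B"], 4
  )
  expect_error(seed_new_metabolite(sig, "A", score = 1), "already in signature")
})
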