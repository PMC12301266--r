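sig_from <- function(id, scores) {
  imd_signature(id, data.frame(
    feature_id = names(scores), reference_score = unname(scores)
  ))
}

test_that("cosine similarity meets its boundary contracts", {
  sc <- c(f1 = 2, f2 = -1, f3 = 4)
  sig <- sig_from("X", sc)
  expect_equal(as.numeric(signature_similarity(sc, sig, method = "cosine")), 1)
  expect_equal(as.numeric(signature_similarity(-sc, sig, method = "cosine")), -1)
  orth <- c(f1 = 1, f2 = 2, f3 = 0) # 2 - 2 + 0 = 0
  expect_equal(as.numeric(signature_similarity(orth, sig, method = "cosine")), 0)
  # the default signature-norm score carries the sample magnitude instead
  expect_equal(
    as.numeric(signature_similarity(sc, sig)), sqrt(sum(sc^2))
  )
})

test_that("similarity is scale invariant and coverage aware", {
  set.seed(3)
  for (i in 1:20) {
    sc <- stats::setNames(rnorm(8), sprintf("f%d", 1:8))
    zs <- stats::setNames(rnorm(8), sprintf("f%d", 1:8))
    sig <- sig_from("X", sc)
    s1 <- as.numeric(signature_similarity(zs, sig, method = "cosine"))
    s2 <- as.numeric(signature_similarity(
      zs * stats::runif(1, 0.01, 100), sig,
      method = "cosine"
    ))
    expect_equal(s1, s2, tolerance = 1e-12)
    expect_true(abs(s1) <= 1 + 1e-9)
  }
  # unmeasured signature metabolites are dropped, not zero-filled
  sig <- sig_from("X", c(f1 = 3, f2 = 3, f9 = 100))
  zs <- c(f1 = 3, f2 = 3)
  out <- signature_similarity(zs, sig, method = "cosine")
  expect_equal(as.numeric(out), 1)
  expect_equal(attr(out, "n_shared"), 2L)
  # no shared metabolites at all -> NA with zero coverage
  none <- signature_similarity(c(g1 = 1), sig)
  expect_true(is.na(none))
  expect_equal(attr(none, "n_shared"), 0L)
  # signature-norm variant is not sample-scale invariant
  zs2 <- c(f1 = 6, f2 = 6)
  expect_equal(
    as.numeric(signature_similarity(zs2, sig, method = "signature_norm")),
    2 * as.numeric(signature_similarity(zs, sig, method = "signature_norm"))
  )
})

test_that("diagnosis ranking sorts by similarity with deterministic ties", {
  zs <- c(f1 = 2, f2 = 2, f3 = -1)
  store <- list(
    match = sig_from("match", zs),
    anti = sig_from("anti", -zs),
    tie_b = sig_from("tie_b", c(f1 = 1)),
    tie_a = sig_from("tie_a", c(f2 = 1)),
    nocov = sig_from("nocov", c(g9 = 5))
  )
  rep1 <- rank_diagnoses(zs, store)
  expect_equal(rep1$imd_id[1], "match")
  # default signature-norm score of an exact match is the sample z-norm
  expect_equal(rep1$similarity[1], sqrt(sum(zs^2)))
  # the two partial-coverage signatures tie exactly; lexicographic order
  ti <- which(rep1$imd_id %in% c("tie_a", "tie_b"))
  expect_identical(rep1$imd_id[ti], c("tie_a", "tie_b"))
  expect_true(all(rep1$tie[ti]))
  # no-coverage signatures rank last and are flagged
  expect_equal(rep1$imd_id[nrow(rep1)], "nocov")
  expect_true(rep1$no_coverage[nrow(rep1)])
  expect_equal(rep1$imd_id[rep1$rank == nrow(rep1)], "nocov")
  # store order must not matter
  rep2 <- rank_diagnoses(zs, rev(store))
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
  expect_error(rank_diagnoses(zs, list()), "store is empty")
})

test_that("irrelevant signatures never reorder existing candidates", {
  set.seed(8)
  zs <- stats::setNames(rnorm(10), sprintf("f%d", 1:10))
  store <- list(
    one = sig_from("one", stats::setNames(rnorm(5), sprintf("f%d", 1:5))),
    two = sig_from("two", stats::setNames(rnorm(5), sprintf("f%d", 6:10)))
  )
  base <- rank_diagnoses(zs, store)
  extended <- rank_diagnoses(zs, c(store, list(
    junk = sig_from("junk", stats::setNames(rnorm(3), sprintf("g%d", 1:3)))
  )))
  kept <- extended[extended$imd_id %in% c("one", "two"), ]
  expect_identical(kept$imd_id, base$imd_id)
  expect_equal(kept$similarity, base$similarity)
})

test_that("true_rank locates the correct disorder", {
  zs <- c(f1 = 1, f2 = 2)
  store <- list(
    a = sig_from("a", c(f1 = 1, f2 = 2)),
    b = sig_from("b", c(f1 = -1, f2 = 1))
  )
  rep1 <- rank_diagnoses(zs, store)
  expect_equal(true_rank(rep1, "a"), 1L)
  expect_equal(true_rank(rep1, "b"), 2L)
  expect_true(is.na(true_rank(rep1, "zzz")))
})
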