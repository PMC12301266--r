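test_that("feature dissimilarities decompose pairwise distances per feature", {
  z <- rbind(s1 = c(0, 0), s2 = c(3, 0))
  colnames(z) <- c("a", "b")
  D <- feature_dissimilarities(z)
  expect_equal(unname(D$D[1, ]), c(9, 0))
  # identical samples give an all-zero row
  z3 <- rbind(s1 = c(1, 2), s2 = c(1, 2), s3 = c(2, 4))
  colnames(z3) <- c("a", "b")
  D3 <- feature_dissimilarities(z3)
  expect_equal(nrow(D3$D), 3L)
  expect_equal(D3$pairs, cbind(c(1, 1, 2), c(2, 3, 3)))
  expect_equal(unname(D3$D[1, ]), c(0, 0))
  # absolute metric
  Da <- feature_dissimilarities(z, metric = "absolute")
  expect_equal(unname(Da$D[1, ]), c(3, 0))
})

test_that("sparse weights concentrate on discriminating features", {
  # all signal in one feature -> all weight on it
  d <- matrix(c(5, 0, 3, 0, 2, 0), 3, 2, byrow = TRUE,
    dimnames = list(NULL, c("a", "b"))
  )
  wv <- sparse_weights(d, s = 1.4)
  expect_equal(unname(wv$w), c(1, 0))
  # symmetric columns at s = sqrt(2) -> equal weights
  d2 <- matrix(c(4, 1, 4, 1), 2, 2, dimnames = list(NULL, c("a", "b")))
  wv2 <- sparse_weights(d2, s = sqrt(2))
  expect_equal(unname(wv2$w), c(1, 1) / sqrt(2), tolerance = 1e-8)
})

test_that("solver output honors its constraints and monotone objective", {
  set.seed(11)
  for (i in 1:25) {
    n_pairs <- sample(3:10, 1)
    p <- sample(3:12, 1)
    d <- matrix(stats::rexp(n_pairs * p), n_pairs, p,
      dimnames = list(NULL, sprintf("f%02d", 1:p))
    )
    s <- stats::runif(1, 1, sqrt(p))
    wv <- sparse_weights(d, s = s)
    expect_true(all(wv$w >= 0))
    expect_lte(sqrt(sum(wv$w^2)), 1 + 1e-8)
    expect_lte(sum(wv$w), s + 1e-8)
    expect_true(all(diff(wv$objective_trace) >= -1e-9))
  }
})

test_that("scaling the dissimilarities leaves the weights unchanged", {
  set.seed(4)
  d <- matrix(stats::rexp(18), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  w1 <- sparse_weights(d, s = 1.4)$w
  w2 <- sparse_weights(d * 37.5, s = 1.4)$w
  expect_equal(w1, w2, tolerance = 1e-9)
})

test_that("an unconstrained bound recovers the dominant-direction weights", {
  # at s = sqrt(p) the L1 constraint is inactive and the solution is the
  # leading nonneg decomposition: w proportional to D^T u with u = Dw/||Dw||
  set.seed(9)
  d <- matrix(stats::rexp(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  wv <- sparse_weights(d, s = sqrt(3))
  u <- as.vector(d %*% wv$w)
  u <- u / sqrt(sum(u^2))
  a <- as.vector(crossprod(d, u))
  expect_equal(unname(wv$w), a / sqrt(sum(a^2)), tolerance = 1e-5)
})

test_that("solver matches the brute-force grid oracle on small instances", {
  set.seed(21)
  for (i in 1:10) {
    p <- sample(2:4, 1)
    n <- sample(3:5, 1)
    z <- matrix(stats::rnorm(n * p), n, p,
      dimnames = list(paste0("s", 1:n), sprintf("f%d", 1:p))
    )
    D <- feature_dissimilarities(z)
    s <- stats::runif(1, 1, sqrt(p))
    wv <- sparse_weights(D, s = s)
    expect_gte(
      objective_of(D$D, wv$w),
      grid_max_objective(D$D, s) - 1e-3
    )
  }
})

test_that("degenerate decompositions are rejected", {
  d <- matrix(0, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(sparse_weights(d), "no between-sample dissimilarity")
  expect_error(
    sparse_weights(matrix(1, 2, 4, dimnames = list(NULL, letters[1:4])), s = 3),
    "must lie in"
  )
})

test_that("top-k selection orders by weight with lexicographic ties", {
  w <- c(f1 = 0.9, f2 = 0.1, f3 = 0.4)
  expect_identical(select_top_k(w, 2), c("f1", "f3"))
  expect_identical(select_top_k(w, 1), "f1")
  # ties broken by feature id
  wt <- c(b = 0.5, a = 0.5, c = 0.5)
  expect_identical(select_top_k(wt, 2), c("a", "b"))
  # only positive-weight features are eligible
  wz <- c(a = 0.8, b = 0, c = 0)
  short <- select_top_k(wz, 2)
  expect_identical(as.character(short), "a")
  expect_true(attr(short, "short"))
})
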