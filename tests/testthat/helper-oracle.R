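# Independent brute-force oracle for the sparse-weight problem:
# maximize ||D w||_2 over {w >= 0, ||w||_2 <= 1, ||w||_1 <= s} by scanning a
# dense grid of non-negative directions, each scaled to the feasible
# boundary (the objective is linear in the scale of w, so the maximum lies
# where one constraint binds).
grid_max_objective <- function(d, s, step = 0.05) {
  p <- ncol(d)
  W <- as.matrix(do.call(
    expand.grid,
    replicate(p, seq(0, 1, by = step), simplify = FALSE)
  ))
  W <- W[rowSums(W) > 0, , drop = FALSE]
  l2 <- sqrt(rowSums(W^2))
  l1 <- rowSums(W)
  scale <- pmin(1 / l2, s / l1)
  obj <- sqrt(colSums((d %*% t(W))^2)) * scale
  max(obj)
}

# objective achieved by a weight vector (what the alternating solver maximizes)
objective_of <- function(d, w) sqrt(sum((d %*% w)^2))
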