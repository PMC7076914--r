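# Independent brute-force oracle for the L1 objective
#   sum((y - X b)^2) + lambda * sum(|b|)
# Exhaustive coordinate-wise grid refinement: each coordinate is minimized
# over a shrinking value grid (with 0 always included to land exactly on
# the kink); the objective is separable-convex so the sweep limit is the
# global optimum. Deliberately does not use the soft-threshold closed form.
lasso_bruteforce <- function(X, y, lambda, sweeps = 60, grid_n = 21) {
  p <- ncol(X)
  b <- numeric(p)
  obj <- function(bb) sum((y - drop(X %*% bb))^2) + lambda * sum(abs(bb))
  width <- rep(max(abs(crossprod(X, y))) / pmax(colSums(X^2), 1e-12), p)
  for (s in seq_len(sweeps)) {
    for (j in seq_len(p)) {
      cand <- c(b[j] + seq(-width[j], width[j], length.out = grid_n), 0)
      vals <- vapply(cand, function(v) {
        bb <- b; bb[j] <- v; obj(bb)
      }, numeric(1))
      b[j] <- cand[which.min(vals)]
    }
    width <- width * 0.7
  }
  b
}

# simulated-truth ROC labels for a fitted model, directed
directed_auroc <- function(scores_df, true_edges) {
  roc <- evaluate_roc(scores_df, true_edges, n_perm = 2, seed = 1,
                      directed = TRUE)
  roc$auc
}
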