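# Independent oracles and shared fixtures for the test suite.

# residual-based Spearman partial correlation: correlate the residuals of
# least-squares fits of the ranks of x and y on the ranks of z
pcor_residual_oracle <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::residuals(stats::lm(rx ~ rz))
  ey <- stats::residuals(stats::lm(ry ~ rz))
  stats::cor(ex, ey)
}

# exhaustive hypergeometric tail: enumerate all size-a subsets of L peaks
# (B of them positive) and count those with >= b positives
hyper_tail_oracle <- function(b, B, L, a) {
  sets <- utils::combn(L, a)
  mean(colSums(sets <= B) >= b)  # peaks 1..B are the positives
}

# brute-force threshold sweep for average precision and precision at recall
pr_sweep_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(thr))
  for (t in seq_along(thr)) {
    pred <- as.integer(scores >= thr[t])
    prec[t] <- sum(pred & labels) / sum(pred)
    rec[t] <- sum(pred & labels) / sum(labels)
  }
  list(thresholds = thr, precision = prec, recall = rec,
       ap = sum(prec * diff(c(0, rec))))
}

pr_at_recall_oracle <- function(scores, labels, r) {
  sw <- pr_sweep_oracle(scores, labels)
  sw$precision[which(sw$recall >= r)[1]]
}

# exhaustive expected F1 under uniform reassignment of m predicted
# positives within a domain of n peaks with the given labels
expected_f1_oracle <- function(labels, m) {
  n <- length(labels)
  placements <- utils::combn(n, m)
  vals <- apply(placements, 2, function(idx) {
    pred <- integer(n); pred[idx] <- 1L
    f1_score(pred, labels)
  })
  mean(vals)
}

# rounding half away from zero, the package's sampling-count convention
rhu <- function(x) floor(x + 0.5)

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n <- comb2(sum(tab))
  exp_ <- si * sj / n
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# one small simulated dataset shared across test files (computed once)
.fixture_env <- new.env()
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_multiome(simulation_config(
      n_metacells = 120, n_tfs = 5, n_peaks = 800, n_genes = 100, seed = 3))
  }
  .fixture_env$sim
}

# triplet-scoring products on the shared simulation (computed once)
small_triplets <- function() {
  if (is.null(.fixture_env$trip)) {
    sim <- small_sim()
    cand <- assign_peaks_to_genes(sim$peaks, sim$genes, sim$accessibility,
                                  sim$expression)
    trip <- score_triplets(cand, sim$motifs, sim$accessibility,
                           sim$expression)
    .fixture_env$trip <- list(candidates = cand, triplets = trip,
                              links = call_tf_links(trip))
  }
  .fixture_env$trip
}
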