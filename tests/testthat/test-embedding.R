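test_that("truncated SVD embedding satisfies exact low-rank reconstruction", {
  set.seed(3)
  u <- rnorm(30); v <- rnorm(8)
  m <- outer(u, v)
  rownames(m) <- paste0("p", 1:30)
  emb <- suppressWarnings(embed_peaks(m, 1))
  recon <- emb$embedding %*% t(emb$v)
  expect_lt(max(abs(recon - m)), 1e-9)

  full <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(paste0("p", 1:30)))
  embf <- embed_peaks(full, 6)
  expect_lt(max(abs(embf$embedding %*% t(embf$v) - full)), 1e-9)
})

test_that("truncation error equals the discarded singular values (Eckart-Young)", {
  set.seed(8)
  m <- matrix(rnorm(200 * 30), 200, 30, dimnames = list(paste0("p", 1:200)))
  d <- 10
  emb <- embed_peaks(m, d)
  err <- sum((m - emb$embedding %*% t(emb$v))^2)
  sv <- svd(m)$d  # full SVD oracle
  expect_equal(err, sum(sv[(d + 1):length(sv)]^2), tolerance = 1e-8)
})

test_that("components beyond the rank are zeroed with a warning", {
  m <- outer(rnorm(12), rnorm(5))
  rownames(m) <- paste0("p", 1:12)
  expect_warning(emb <- embed_peaks(m, 4), "beyond the numerical rank")
  expect_true(all(emb$embedding[, 2:4] == 0))
  expect_error(embed_peaks(m, 9), "exceeds")
})

test_that("the sign convention makes embeddings deterministic", {
  set.seed(5)
  m <- matrix(rnorm(50 * 10), 50, 10, dimnames = list(paste0("p", 1:50)))
  e1 <- embed_peaks(m, 4); e2 <- embed_peaks(m, 4)
  expect_identical(e1$embedding, e2$embedding)
  for (k in 1:4) expect_gt(e1$v[which.max(abs(e1$v[, k])), k], 0)
})

test_that("clustering separates well-separated blobs and is deterministic", {
  set.seed(42)
  blob <- rbind(matrix(rnorm(60 * 2, 0, 0.3), ncol = 2),
                matrix(rnorm(60 * 2, 8, 0.3), ncol = 2))
  rownames(blob) <- paste0("p", 1:120)
  emb <- structure(list(embedding = blob, d = 2, space = "ATAC",
                        peak_ids = rownames(blob), cluster = NULL),
                   class = "peak_embedding")
  c1 <- cluster_embedding(emb, knn = 30, seed = 7)
  expect_equal(adjusted_rand(c1$cluster, rep(1:2, each = 60)), 1)
  c2 <- cluster_embedding(emb, knn = 30, seed = 7)
  expect_identical(c1$cluster, c2$cluster)
  expect_error(cluster_embedding(emb, knn = 120), "smaller")
})

test_that("identical points collapse to a single cluster", {
  pts <- matrix(1, 40, 3, dimnames = list(paste0("p", 1:40)))
  emb <- structure(list(embedding = pts, d = 3, space = "seq",
                        peak_ids = rownames(pts), cluster = NULL),
                   class = "peak_embedding")
  cl <- cluster_embedding(emb, knn = 10, seed = 1)
  expect_equal(length(unique(cl$cluster)), 1)
})

test_that("paired groups intersect the two labelings and partition the peaks", {
  mk <- function(lab, space) structure(
    list(embedding = matrix(0, 3, 1), d = 1, space = space,
         peak_ids = paste0("p", 1:3), cluster = lab),
    class = "peak_embedding")
  pg <- pair_groups(mk(c(0L, 0L, 1L), "ATAC"), mk(c(0L, 1L, 1L), "seq"))
  expect_equal(pg$groups[["0_0"]], "p1")
  expect_equal(pg$groups[["0_1"]], "p2")
  expect_equal(pg$groups[["1_1"]], "p3")
  expect_setequal(unlist(pg$groups), paste0("p", 1:3))
  expect_equal(anyDuplicated(unlist(pg$groups)), 0)
  # identical labelings reproduce the clusters themselves
  pg2 <- pair_groups(mk(c(1L, 2L, 2L), "ATAC"), mk(c(1L, 2L, 2L), "seq"))
  expect_equal(lengths(pg2$groups), c("1_1" = 1L, "2_2" = 2L))
  bad <- mk(c(0L, 1L, 1L), "seq"); bad$peak_ids <- c("q1", "q2", "q3")
  expect_error(pair_groups(mk(c(0L, 0L, 1L), "ATAC"), bad), "orderings")
})

test_that("group enrichment equals the hypergeometric tail", {
  mk_groups <- function(sizes) {
    ids <- paste0("p", seq_len(sum(sizes)))
    k <- rep(seq_along(sizes), sizes)
    a <- structure(list(embedding = matrix(0, length(ids), 1), d = 1,
                        space = "ATAC", peak_ids = ids, cluster = k),
                   class = "peak_embedding")
    s <- a; s$space <- "seq"; s$cluster <- rep(1L, length(ids))
    pair_groups(a, s)
  }
  # L = 20 peaks, one group of 10 holding all 10 positives
  pg <- mk_groups(c(10, 10))
  enr <- fisher_enrichment(pg, paste0("p", 1:10))
  expect_equal(enr$p[enr$k == 1], 1 / choose(20, 10))
  expect_equal(enr$p[enr$k == 2], 1)  # b = 0 -> one-sided p = 1
  expect_false(enr$enriched[enr$k == 2])
  # agreement with fisher.test on a nontrivial table
  pg2 <- mk_groups(c(6, 14))
  pos <- paste0("p", c(1:4, 7:9))
  enr2 <- fisher_enrichment(pg2, pos)
  ft <- fisher.test(matrix(c(4, 2, 3, 11), 2), alternative = "greater")
  expect_equal(enr2$p[enr2$k == 1], ft$p.value, tolerance = 1e-12)
})

test_that("candidate expansion collects motif-less peaks of seeded groups", {
  mk <- function(labA, labS, ids) {
    a <- structure(list(embedding = matrix(0, length(ids), 1), d = 1,
                        space = "ATAC", peak_ids = ids, cluster = labA),
                   class = "peak_embedding")
    s <- a; s$space <- "seq"; s$cluster <- labS
    pair_groups(a, s)
  }
  ids <- paste0("p", 1:6)
  pg <- mk(c(1L, 1L, 1L, 2L, 2L, 2L), rep(1L, 6), ids)
  nonmotif <- c("p2", "p3", "p5")
  # seed in group 1 only -> its motif-less members
  expect_setequal(expand_candidates(pg, "p1", nonmotif), c("p2", "p3"))
  # no group holds a seed -> empty
  expect_length(expand_candidates(pg, character(0), nonmotif), 0)
  # every group seeded -> all motif-less peaks
  expect_setequal(expand_candidates(pg, c("p1", "p4"), nonmotif), nonmotif)
  # result never contains a motif-bearing peak
  expect_length(intersect(expand_candidates(pg, c("p1", "p4"), nonmotif),
                          setdiff(ids, nonmotif)), 0)
})

test_that("seed-neighbor union matches a brute-force all-pairs oracle", {
  set.seed(6)
  n <- 300
  mkemb <- function(mat) structure(
    list(embedding = mat, d = ncol(mat), space = "ATAC",
         peak_ids = paste0("p", 1:n), cluster = NULL),
    class = "peak_embedding")
  eA <- mkemb(matrix(rnorm(n * 5), n, 5))
  eS <- mkemb(matrix(rnorm(n * 4), n, 4))
  seeds <- paste0("p", sample(n, 12))
  K <- 7
  got <- neighbor_union(eA, eS, seeds, K = K)
  oracle <- unique(unlist(lapply(list(eA, eS), function(e) {
    d <- as.matrix(dist(e$embedding))
    diag(d) <- Inf
    unlist(lapply(match(seeds, e$peak_ids), function(i) {
      e$peak_ids[order(d[i, ])[1:K]]
    }))
  })))
  expect_setequal(got, oracle)
  expect_length(neighbor_union(eA, eS, character(0), K = K), 0)
})

test_that("a duplicated point is its duplicate's nearest neighbor", {
  m <- rbind(p1 = c(0, 0), p2 = c(0, 0), p3 = c(9, 9), p4 = c(5, 5))
  emb <- structure(list(embedding = m, d = 2, space = "ATAC",
                       peak_ids = rownames(m), cluster = NULL),
                  class = "peak_embedding")
  got <- neighbor_union(emb, emb, "p1", K = 1)
  expect_equal(got, "p2")
})
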