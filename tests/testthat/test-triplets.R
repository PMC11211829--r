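test_that("motif-score normalization follows the quantile convention", {
  scan <- motif_scan(presence = cbind(m1 = c(0, 1, 1), m2 = c(1, 1, 0),
                                      m3 = c(0, 0, 0)),
                     scores = cbind(m1 = c(0, 5, 10), m2 = c(7, 7, 0),
                                    m3 = c(0, 0, 0)),
                     peak_ids = paste0("p", 1:3))
  th <- normalize_motif_scores(scan)
  expect_equal(unname(th[, "m1"]), c(0, 0.5, 1))
  expect_equal(unname(th[, "m2"]), c(1, 1, 0))   # tied positives map to 1
  expect_equal(unname(th[, "m3"]), c(0, 0, 0))   # all-zero column stays 0
})

test_that("peak max accessibility is quantile-transformed across peaks", {
  m <- rbind(p1 = c(0.5, 1), p2 = c(2, 0.1), p3 = c(1, 3))
  colnames(m) <- c("m1", "m2")
  pi_ <- peak_max_accessibility(metacell_matrix(m))
  expect_equal(unname(pi_), c(1 / 3, 2 / 3, 1))
  # a metacell that changes no maximum leaves the transform unchanged
  m2 <- cbind(m, m3 = c(0, 0, 0))
  expect_equal(peak_max_accessibility(metacell_matrix(m2)), pi_)
  # all-identical maxima map to 1
  m3 <- rbind(p1 = c(2, 1), p2 = c(1, 2))
  colnames(m3) <- c("m1", "m2")
  expect_equal(unname(peak_max_accessibility(metacell_matrix(m3))), c(1, 1))
})

test_that("the min-max regularizer maps the scope affinely to [0, 1]", {
  expect_equal(minmax_regularizer(c(0.2, 0.4, 0.6), c(1, 1, 1)),
               c(0, 0.5, 1))
  expect_equal(minmax_regularizer(0.3, 0.8), 1)  # single-peak scope
  # zero motif score at the scope minimum pins the regularizer at 0
  reg <- minmax_regularizer(c(0, 0.5, 1), c(0.9, 0.9, 0.9))
  expect_equal(reg[1], 0)
  expect_error(minmax_regularizer(numeric(0), numeric(0)), "empty")
})

test_that("peak-gene assignment honors window, rho_min and the ambiguity margin", {
  # 6 metacells; peak tracks gene gA strongly, gB weakly
  acc <- metacell_matrix(rbind(pk = c(1, 2, 3, 4, 5, 6)),
                         metacell_ids = paste0("m", 1:6))
  expr <- metacell_matrix(rbind(gA = c(1.1, 2.2, 2.9, 4.3, 5.1, 6.2),
                                gB = c(2, 1, 4, 3, 5, 6),
                                gC = c(6, 5, 4, 3, 2, 1)),
                         metacell_ids = paste0("m", 1:6))
  peaks <- data.frame(peak_id = "pk", chrom = "chr1",
                      start = 10000L, end = 10500L)
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      tss = c(20000L, 15000L, 900000L), strand = "+")
  cand <- assign_peaks_to_genes(peaks, genes, acc, expr, window_bp = 50000,
                                rho_min = 0.1, delta_rho = 0.05)
  expect_setequal(cand$gene_id, c("gA", "gB"))       # gC beyond the window
  expect_true(cand$retained[cand$gene_id == "gA"])   # |rho| = 1
  expect_false(cand$retained[cand$gene_id == "gB"])  # loses by > delta_rho
  expect_equal(cand$tss_distance[cand$gene_id == "gA"], -9750L)
  # a peak out of range of every TSS yields no candidates
  far <- data.frame(peak_id = "far", chrom = "chr1",
                    start = 500000L, end = 500500L)
  expect_equal(nrow(assign_peaks_to_genes(far, genes["3", ], acc2 <-
    metacell_matrix(rbind(far = 1:6), metacell_ids = paste0("m", 1:6)),
    expr, window_bp = 10000)), 0)
})

test_that("triplet scores follow the two-term weighted formula", {
  trip <- small_triplets()$triplets
  w <- 0.5
  expect_equal(trip$score1,
               (trip$sign * w * trip$rho_tf_peak +
                  trip$sign * w * trip$rho_partial) * trip$regularizer)
  expect_equal(trip$score2,
               (trip$sign * w * trip$rho_peak_gene +
                  trip$sign * w * trip$rho_partial) * trip$regularizer)
  expect_equal(trip$sign, ifelse(trip$rho_tf_peak >= 0, 1, -1))
})

test_that("score magnitudes stay within 1 and die with the regularizer", {
  trip <- small_triplets()$triplets
  expect_true(all(abs(trip$score1) <= 1))
  expect_true(all(abs(trip$score2) <= 1))
  expect_true(all(trip$regularizer >= 0 & trip$regularizer <= 1))
  zero_reg <- trip$regularizer == 0
  expect_gt(sum(zero_reg), 0)
  expect_true(all(trip$score1[zero_reg] == 0))
  expect_true(all(trip$score2[zero_reg] == 0))
  expect_false(anyNA(trip))
})

test_that("link calling keeps ties, honors quantile 1.0, and stays in the motif set", {
  trip3 <- data.frame(peak_id = c("p1", "p2", "p3"), tf_id = "tfX",
                      gene_id = "g", score1 = c(0.4, 0.4, 0.4))
  expect_setequal(call_tf_links(trip3)$tfX, c("p1", "p2", "p3"))
  trip4 <- data.frame(peak_id = c("p1", "p2", "p3"), tf_id = "tfX",
                      gene_id = "g", score1 = c(0.1, 0.9, 0.5))
  expect_equal(call_tf_links(trip4, score_quantile = 1)$tfX, "p2")

  sim <- small_sim()
  links <- small_triplets()$links
  for (tf in names(links)) {
    expect_true(all(links[[tf]] %in% motif_peaks(sim$motifs, tf)))
  }
})

test_that("called links are more precise than raw motif presence", {
  sim <- small_sim()
  links <- small_triplets()$links
  better <- vapply(sim$tf_ids, function(tf) {
    truthv <- sim$truth$binding[, tf]
    mean(truthv[links[[tf]]]) > mean(truthv[motif_peaks(sim$motifs, tf)])
  }, logical(1))
  expect_gte(sum(better), length(better) - 1)
})

test_that("triplet scores are invariant under monotone transforms of the data", {
  sim <- small_sim()
  cand <- small_triplets()$candidates
  sub_peaks <- unique(cand$peak_id[cand$retained])[1:30]
  cand_sub <- cand[cand$peak_id %in% sub_peaks, ]
  acc <- sim$accessibility; expr <- sim$expression
  t1 <- score_triplets(cand_sub, sim$motifs, acc, expr)
  # strictly increasing transform of expression changes no rank
  expr2 <- metacell_matrix(exp(as.matrix(expr$values) / 2),
                           expr$entity_ids, expr$metacell_ids)
  t2 <- score_triplets(cand_sub, sim$motifs, acc, expr2)
  expect_equal(t1$rho_tf_peak, t2$rho_tf_peak)
  expect_equal(t1$rho_partial, t2$rho_partial)
  expect_equal(t1$score1, t2$score1)
})
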