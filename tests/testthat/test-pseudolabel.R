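test_that("quantile score normalization follows the rank/n convention", {
  rho <- c(p1 = 10, p2 = 20, p3 = 30, p4 = 40)
  s <- quantile_scores(rho, rho)
  expect_equal(s$s1, c(0.25, 0.5, 0.75, 1))
  same <- quantile_scores(c(a = 2, b = 2, c = 2), c(a = 1, b = 1, c = 1))
  expect_equal(same$s1, c(1, 1, 1))   # all equal -> all 1
  one <- quantile_scores(c(solo = 5), c(solo = 0.1))
  expect_equal(c(one$s1, one$s2), c(1, 1))
  # monotone invariance of the transform
  s2 <- quantile_scores(exp(rho), rho^3)
  expect_equal(s2$s1, s$s1)
  expect_equal(s2$s2, s$s2)
})

test_that("pseudo-positive selection flips exactly at tau1/tau2", {
  sc <- data.frame(peak_id = paste0("p", 1:4),
                   s1 = c(0.3, 0, 0.3, 0), s2 = c(0, 0.3, 0.3, 0.8))
  enr <- c(p1 = TRUE, p2 = FALSE, p3 = FALSE, p4 = FALSE)
  sel <- select_pseudo_positives(sc, enr, tau1 = 0.25, tau2 = 0.75)
  expect_true("p1" %in% sel)    # enriched group, s1 = 0.3 > 0.25
  expect_false("p2" %in% sel)   # non-enriched, 0.3 < 0.75
  expect_false("p3" %in% sel)   # non-enriched, both 0.3 < 0.75
  expect_true("p4" %in% sel)    # non-enriched, s2 = 0.8 > 0.75
  # strict inequality: exactly tau never selects
  sc2 <- data.frame(peak_id = c("q1", "q2"), s1 = c(0.25, 0.75),
                    s2 = c(0, 0))
  expect_length(select_pseudo_positives(sc2, c(q1 = TRUE, q2 = FALSE)), 0)
  expect_error(select_pseudo_positives(sc, enr, tau1 = 0.5, tau2 = 0.5),
               "tau2")
})

test_that("pseudo-negative counts and exclusions are honored", {
  all_peaks <- paste0("p", 1:600)
  motif_set <- paste0("p", 1:200)
  seeds <- paste0("p", 1:50)
  expanded <- paste0("p", 301:320)
  enriched <- paste0("p", c(51:70, 321:340))
  nbr <- paste0("p", c(71:90, 341:360))
  neg <- select_pseudo_negatives(motif_set, seeds, all_peaks, expanded,
                                 enriched, nbr, n1 = 100, seed = 4)
  expect_length(neg$pool1, 25)    # round(0.25 * 100)
  expect_length(neg$pool2, 150)   # round(1.5 * 100)
  expect_length(intersect(neg$pool1, c(seeds, expanded, enriched, nbr)), 0)
  expect_length(intersect(neg$pool2, c(motif_set, expanded, enriched, nbr)), 0)
  expect_true(all(neg$pool1 %in% motif_set))
  # deterministic under the seed
  neg2 <- select_pseudo_negatives(motif_set, seeds, all_peaks, expanded,
                                  enriched, nbr, n1 = 100, seed = 4)
  expect_identical(neg, neg2)
})

test_that("short pools are clamped with a warning; empty pools error", {
  all_peaks <- paste0("p", 1:100)
  motif_set <- paste0("p", 1:60)
  seeds <- paste0("p", 1:50)
  warns <- testthat::capture_warnings(
    neg <- select_pseudo_negatives(motif_set, seeds, all_peaks,
                                   character(0), character(0), character(0),
                                   n1 = 100, seed = 1))
  expect_length(warns, 2)  # both pools run short
  expect_match(warns, "taking all", all = TRUE)
  expect_length(neg$pool1, 10)   # only 10 eligible motif peaks
  expect_length(neg$pool2, 40)   # only 40 motif-less peaks
  expect_error(select_pseudo_negatives(
    paste0("p", 1:5), paste0("p", 1:5), paste0("p", 1:5),
    character(0), character(0), character(0), n1 = 10),
    "empty")
})

test_that("fractional negative counts round half away from zero", {
  all_peaks <- paste0("p", 1:500)
  motif_set <- paste0("p", 1:100)
  seeds <- paste0("p", 1:10)
  neg <- select_pseudo_negatives(motif_set, seeds, all_peaks, character(0),
                                 character(0), character(0), n1 = 2,
                                 seed = 1)
  expect_length(neg$pool1, 1)   # round(0.5) -> 1, not 0
  expect_length(neg$pool2, 3)
})

test_that("the classifier fits separable pseudo-labels and bounds probabilities", {
  set.seed(12)
  n <- 200
  emb <- matrix(rnorm(n * 4), n, 4)
  emb[1:60, 1] <- emb[1:60, 1] + 6
  rownames(emb) <- paste0("p", 1:n)
  mk <- function(m, space) structure(
    list(embedding = m, d = ncol(m), space = space, peak_ids = rownames(m),
         cluster = NULL), class = "peak_embedding")
  pred <- train_predict(mk(emb, "ATAC"), mk(emb * 0.5, "seq"),
                        positives = paste0("p", 1:60),
                        negatives = paste0("p", 61:200))
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  acc <- mean(c(pred$call[1:60] == 1, pred$call[61:200] == 0))
  expect_gte(acc, 0.99)
  expect_error(train_predict(mk(emb, "ATAC"), mk(emb, "seq"),
                             paste0("p", 1:5), paste0("p", 3:8)), "overlap")
  expect_error(train_predict(mk(emb, "ATAC"), mk(emb, "seq"),
                             character(0), paste0("p", 1:5)), "both classes")
})

test_that("per-TF recovery is deterministic and respects label invariants", {
  sim <- small_sim()
  tri <- small_triplets()
  rec <- suppressWarnings(recover_binding(
    tri$links, tri$triplets, sim$accessibility, sim$expression, sim$motifs,
    min_positives = 10, seed = 5))
  expect_gt(length(rec$results), 0)
  for (tf in names(rec$results)) {
    r <- rec$results[[tf]]
    expect_true(all(r$pseudo$positives %in% tri$links[[tf]]))
    negs <- c(r$pseudo$negatives_pool1, r$pseudo$negatives_pool2)
    expect_length(intersect(negs, r$pseudo$positives), 0)
    expect_length(intersect(negs, r$pseudo$neighbors), 0)
    expect_length(intersect(negs, r$pseudo$expanded), 0)
    expect_true(all(r$pseudo$negatives_pool1 %in%
                      motif_peaks(sim$motifs, tf)))
    expect_length(intersect(r$pseudo$negatives_pool2,
                            motif_peaks(sim$motifs, tf)), 0)
    # ratio honored when pools sufficed
    if (r$pseudo$eligible1 >= rhu(0.25 * r$pseudo$n1)) {
      expect_equal(r$pseudo$n2_1, rhu(0.25 * r$pseudo$n1))
    }
    if (r$pseudo$eligible2 >= rhu(1.5 * r$pseudo$n1)) {
      expect_equal(r$pseudo$n2_2, rhu(1.5 * r$pseudo$n1))
    }
    expect_equal(nrow(r$prediction), nrow(sim$peaks))
  }
  rec2 <- suppressWarnings(recover_binding(
    tri$links, tri$triplets, sim$accessibility, sim$expression, sim$motifs,
    min_positives = 10, seed = 5))
  for (tf in names(rec$results)) {
    expect_identical(rec$results[[tf]]$prediction,
                     rec2$results[[tf]]$prediction)
  }
})

test_that("recovery works from raw motif-scan seeds and skips tiny TFs", {
  sim <- small_sim()
  tri <- small_triplets()
  scan_seeds <- lapply(stats::setNames(sim$tf_ids[1], sim$tf_ids[1]),
                       function(tf) motif_peaks(sim$motifs, tf))
  rec <- suppressWarnings(recover_binding(
    scan_seeds, NULL, sim$accessibility, sim$expression, sim$motifs,
    min_positives = 10, seed = 2))
  expect_equal(nrow(rec$results[[1]]$prediction), nrow(sim$peaks))
  # a TF below min_positives is skipped with a message, not an error
  few <- list(TF01 = motif_peaks(sim$motifs, "TF01")[1:3])
  expect_message(
    rec2 <- suppressWarnings(recover_binding(
      few, NULL, sim$accessibility, sim$expression, sim$motifs,
      min_positives = 10, seed = 2)),
    "skipped")
  expect_length(rec2$results, 0)
})

test_that("masked-motif bound peaks are recovered far above prevalence", {
  sim <- small_sim()
  tri <- small_triplets()
  rec <- suppressWarnings(recover_binding(
    tri$links, tri$triplets, sim$accessibility, sim$expression, sim$motifs,
    min_positives = 10, seed = 5))
  gains <- vapply(names(rec$results), function(tf) {
    pred <- rec$results[[tf]]$prediction
    dom <- setdiff(pred$peak_id, motif_peaks(sim$motifs, tf))
    y <- sim$truth$binding[dom, tf]
    if (sum(y) == 0) return(NA_real_)
    aupr(pred$probability[match(dom, pred$peak_id)], y) / mean(y)
  }, numeric(1))
  expect_true(all(gains >= 2, na.rm = TRUE))
})
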