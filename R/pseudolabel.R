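# Pseudo semi-supervised TF binding prediction: quantile-normalized seed
# scores, clustering-guided pseudo-positive/negative selection, and a
# per-TF L2-regularized logistic regression on the concatenated embeddings.

# round half away from zero (so 0.5 -> 1), used for the negative counts
round_half_up <- function(x) floor(x + 0.5)

#' Quantile-normalized seed scores
#'
#' Normalizes, over a TF's seed-linked peaks, (i) the peak
#' accessibility-TF expression correlation and (ii) the triplet binding
#' score (best `score1` per peak), each to `[0, 1]` by the package's
#' quantile transform (ties share the upper quantile; max maps to 1; a
#' single peak gets 1 for both).
#'
#' @param rho_peak_tf named numeric vector over the seed peaks.
#' @param score1 named numeric vector over the same peaks.
#' @return data.frame `peak_id`, `s1`, `s2`.
#' @export
quantile_scores <- function(rho_peak_tf, score1) {
  if (is.null(names(rho_peak_tf)) || is.null(names(score1))) {
    stop("named vectors required")
  }
  if (!setequal(names(rho_peak_tf), names(score1))) {
    stop("the two score vectors cover different peaks")
  }
  score1 <- score1[names(rho_peak_tf)]
  data.frame(peak_id = names(rho_peak_tf),
             s1 = quantile_transform(unname(rho_peak_tf)),
             s2 = quantile_transform(unname(score1)),
             stringsAsFactors = FALSE)
}

#' Select pseudo-positive training peaks
#'
#' A seed-linked peak is selected when either normalized score strictly
#' exceeds the threshold of its paired group: the permissive `tau1` if the
#' group is enriched for seed links, the stringent `tau2` otherwise
#' (defaults 0.25 / 0.75).
#'
#' @param scores output of [quantile_scores()].
#' @param in_enriched_group named or aligned logical vector: is each
#'   peak's paired group enriched?
#' @param tau1,tau2 thresholds, `tau2 > tau1`.
#' @return Character vector of selected peak ids.
#' @export
select_pseudo_positives <- function(scores, in_enriched_group,
                                    tau1 = 0.25, tau2 = 0.75) {
  if (tau2 <= tau1) stop("tau2 must be > tau1")
  if (!is.null(names(in_enriched_group))) {
    in_enriched_group <- in_enriched_group[scores$peak_id]
  }
  if (length(in_enriched_group) != nrow(scores)) {
    stop("in_enriched_group does not align with scores")
  }
  thr <- ifelse(in_enriched_group, tau1, tau2)
  scores$peak_id[scores$s1 > thr | scores$s2 > thr]
}

#' Select pseudo-negative training peaks
#'
#' Negatives come from two pools: (1) motif-bearing peaks without a seed
#' link and (2) motif-less peaks. Both exclude (a) feature-group-expanded
#' binding candidates, (b) peaks in groups enriched for seed links, and
#' (c) the seed peaks' K-nearest-neighbor set. `round(r1 * n1)` and
#' `round(r2 * n1)` peaks (half away from zero) are sampled uniformly
#' without replacement; a short pool is taken whole with a warning.
#'
#' @param motif_set peak ids with the TF's motif.
#' @param seed_links the TF's seed-linked peak ids.
#' @param all_peaks all peak ids.
#' @param expanded feature-group-expanded candidates (exclusion a).
#' @param enriched_peaks peaks in enriched paired groups (exclusion b).
#' @param neighbors the seed kNN union (exclusion c).
#' @param n1 number of pseudo-positives selected.
#' @param r1,r2 negative:positive ratios for pools 1 and 2
#'   (defaults 0.25 / 1.5).
#' @param seed integer seed for the sampling.
#' @return List with `pool1`, `pool2` (sampled ids), `eligible1`,
#'   `eligible2` (pool sizes before sampling).
#' @export
select_pseudo_negatives <- function(motif_set, seed_links, all_peaks,
                                    expanded, enriched_peaks, neighbors,
                                    n1, r1 = 0.25, r2 = 1.5, seed = 1) {
  if (n1 < 1) stop("n1 must be >= 1")
  if (r1 <= 0 || r2 <= 0) stop("r1 and r2 must be positive")
  excl <- unique(c(expanded, enriched_peaks, neighbors, seed_links))
  pool1 <- setdiff(setdiff(motif_set, seed_links), excl)
  pool2 <- setdiff(setdiff(all_peaks, motif_set), excl)
  if (length(pool1) == 0 && length(pool2) == 0) {
    stop("both negative pools are empty; model cannot train")
  }
  n21 <- round_half_up(r1 * n1)
  n22 <- round_half_up(r2 * n1)
  take <- function(pool, n, label) {
    if (length(pool) < n) {
      warning("negative ", label, " has only ", length(pool),
              " eligible peaks (wanted ", n, "); taking all")
      return(pool)
    }
    pool[sample.int(length(pool), n)]
  }
  with_seed(seed, list(
    pool1 = take(pool1, n21, "pool 1"),
    pool2 = take(pool2, n22, "pool 2"),
    eligible1 = length(pool1), eligible2 = length(pool2)))
}

#' Train the per-TF classifier and predict binding genome-wide
#'
#' Features are the concatenated accessibility and sequence embeddings,
#' standardized per feature with training-sample statistics. An
#' L2-regularized logistic regression (glmnet, alpha = 0) is fit on the
#' pseudo-labels and applied to every peak.
#'
#' @param emb_atac,emb_seq the two embeddings (same peak order).
#' @param positives,negatives pseudo-labeled peak ids (disjoint).
#' @param l2 L2 penalty strength on the unscaled log-likelihood
#'   (glmnet lambda = `l2 / n_train`).
#' @param threshold probability cutoff for the binary call.
#' @return data.frame `peak_id`, `probability`, `call` over all peaks.
#' @export
train_predict <- function(emb_atac, emb_seq, positives, negatives,
                          l2 = 1, threshold = 0.5) {
  if (!identical(emb_atac$peak_ids, emb_seq$peak_ids)) {
    stop("peak orderings of the two embeddings differ")
  }
  if (length(intersect(positives, negatives))) {
    stop("positives and negatives overlap")
  }
  if (length(positives) == 0 || length(negatives) == 0) {
    stop("need both classes among the pseudo-labels")
  }
  ids <- emb_atac$peak_ids
  feats <- cbind(emb_atac$embedding, emb_seq$embedding)
  colnames(feats) <- c(paste0("atac", seq_len(ncol(emb_atac$embedding))),
                       paste0("seq", seq_len(ncol(emb_seq$embedding))))
  tr_idx <- c(match(positives, ids), match(negatives, ids))
  if (anyNA(tr_idx)) stop("pseudo-labeled peak not present in the embeddings")
  y <- rep(c(1, 0), c(length(positives), length(negatives)))
  mu <- colMeans(feats[tr_idx, , drop = FALSE])
  sd_ <- apply(feats[tr_idx, , drop = FALSE], 2, stats::sd)
  sd_[sd_ == 0] <- 1
  z <- sweep(sweep(feats, 2, mu), 2, sd_, "/")
  fit <- glmnet::glmnet(z[tr_idx, , drop = FALSE], y, family = "binomial",
                        alpha = 0, lambda = l2 / length(tr_idx),
                        standardize = FALSE)
  prob <- as.vector(stats::predict(fit, z, type = "response"))
  data.frame(peak_id = ids, probability = prob,
             call = as.integer(prob >= threshold),
             stringsAsFactors = FALSE)
}

#' Full binding-recovery pipeline for one TF
#'
#' Runs, for one TF: paired-group enrichment of the seed links, candidate
#' expansion, seed-neighbor search, pseudo-positive/negative selection, and
#' classifier training/prediction. Deterministic under a fixed seed.
#'
#' @param tf TF id.
#' @param seed_links the TF's seed peak set (triplet-scoring links by
#'   default, but any per-TF peak set — e.g. raw motif hits — works).
#' @param rho_peak_tf named correlation of each seed peak's accessibility
#'   with the TF's expression.
#' @param score1 named triplet binding score per seed peak (best over
#'   genes); pass `rho_peak_tf` again when seeds carry no triplet score.
#' @param emb_atac,emb_seq clustered embeddings.
#' @param groups a [pair_groups()] result.
#' @param scan a [motif_scan()].
#' @param K seed-neighbor count per space.
#' @param tau1,tau2 pseudo-positive thresholds.
#' @param r1,r2 negative sampling ratios.
#' @param alpha enrichment q-value cutoff.
#' @param l2 classifier penalty.
#' @param min_positives minimum usable pseudo-positive count; below it the
#'   TF is skipped (returns NULL with a message).
#' @param seed integer seed.
#' @return List of class `tf_binding`: `tf`, `prediction` (data.frame over
#'   all peaks), `pseudo` (selection audit), `enrichment` (per-group
#'   table), or NULL if the TF was skipped.
#' @export
recover_binding_tf <- function(tf, seed_links, rho_peak_tf, score1,
                               emb_atac, emb_seq, groups, scan,
                               K = 100, tau1 = 0.25, tau2 = 0.75,
                               r1 = 0.25, r2 = 1.5, alpha = 0.05, l2 = 1,
                               min_positives = 20, seed = 1) {
  if (tau2 <= tau1) stop("tau2 must be > tau1")
  all_peaks <- emb_atac$peak_ids
  motif_set <- motif_peaks(scan, tf)
  if (length(seed_links) < min_positives) {
    message("TF ", tf, " skipped: only ", length(seed_links), " seed peaks")
    return(NULL)
  }
  enr <- fisher_enrichment(groups, seed_links, alpha = alpha)
  enriched_groups <- enr$group[enr$enriched]
  assign_grp <- stats::setNames(groups$assignment$group,
                                groups$assignment$peak_id)
  enriched_peaks <- groups$assignment$peak_id[
    groups$assignment$group %in% enriched_groups]

  sc <- quantile_scores(rho_peak_tf[seed_links], score1[seed_links])
  pos <- select_pseudo_positives(
    sc, assign_grp[sc$peak_id] %in% enriched_groups, tau1, tau2)
  if (length(pos) < min_positives) {
    message("TF ", tf, " skipped: only ", length(pos), " pseudo-positives")
    return(NULL)
  }
  expanded <- expand_candidates(groups, seed_links,
                                setdiff(all_peaks, motif_set))
  nbr <- neighbor_union(emb_atac, emb_seq, seed_links, K = K)
  neg <- select_pseudo_negatives(
    motif_set, seed_links, all_peaks, expanded, enriched_peaks, nbr,
    n1 = length(pos), r1 = r1, r2 = r2,
    seed = derive_seed(seed, "negatives"))
  pred <- train_predict(emb_atac, emb_seq, pos, c(neg$pool1, neg$pool2),
                        l2 = l2)
  structure(list(tf = tf, prediction = pred,
                 pseudo = list(positives = pos, negatives_pool1 = neg$pool1,
                               negatives_pool2 = neg$pool2,
                               n1 = length(pos),
                               n2_1 = length(neg$pool1),
                               n2_2 = length(neg$pool2),
                               eligible1 = neg$eligible1,
                               eligible2 = neg$eligible2,
                               expanded = expanded, neighbors = nbr,
                               seed = seed),
                 enrichment = enr),
            class = "tf_binding")
}

#' Binding recovery across TFs
#'
#' Convenience driver: embeds and clusters the peaks once, then runs
#' [recover_binding_tf()] for every TF with enough seed links. Seed links
#' default to triplet-scoring output but any named list of per-TF peak
#' sets can be supplied.
#'
#' @param seed_links named list, TF id -> seed peak ids (e.g.
#'   [call_tf_links()] output).
#' @param triplets triplet table ([score_triplets()] output) used for the
#'   per-peak `score1`; NULL to reuse the accessibility correlation.
#' @param acc accessibility [metacell_matrix()] over all peaks.
#' @param tf_expr expression [metacell_matrix()] containing the TF rows.
#' @param scan a [motif_scan()].
#' @param d1,d2 embedding dimensions (defaults 50; capped at the matrix
#'   rank).
#' @param knn clustering neighbor count.
#' @param resolution Leiden resolution.
#' @param K,tau1,tau2,r1,r2,alpha,l2,min_positives see
#'   [recover_binding_tf()].
#' @param seed master seed; per-stage seeds are derived from it.
#' @return List of class `binding_recovery`: `results` (per-TF
#'   `tf_binding` objects), `emb_atac`, `emb_seq`, `groups`.
#' @export
recover_binding <- function(seed_links, triplets, acc, tf_expr, scan,
                            d1 = 50, d2 = 50, knn = 30, resolution = 1,
                            K = 100, tau1 = 0.25, tau2 = 0.75,
                            r1 = 0.25, r2 = 1.5, alpha = 0.05, l2 = 1,
                            min_positives = 20, seed = 1) {
  accm <- as.matrix(acc$values)
  d1 <- min(d1, dim(accm))
  d2 <- min(d2, dim(scan$presence))
  emb_atac <- embed_peaks(accm, d1, center = "row", space = "ATAC")
  emb_seq <- embed_peaks(scan$presence, d2, center = "none", space = "seq")
  emb_atac <- cluster_embedding(emb_atac, knn = knn, resolution = resolution,
                                seed = derive_seed(seed, "cluster_atac"))
  emb_seq <- cluster_embedding(emb_seq, knn = knn, resolution = resolution,
                               seed = derive_seed(seed, "cluster_seq"))
  groups <- pair_groups(emb_atac, emb_seq)

  rho_tp <- spearman_cor_rows(as.matrix(tf_expr$values)[
    intersect(names(seed_links), tf_expr$entity_ids), , drop = FALSE], accm)
  results <- list()
  for (tf in intersect(names(seed_links), rownames(rho_tp))) {
    links <- intersect(seed_links[[tf]], acc$entity_ids)
    rho_vec <- stats::setNames(rho_tp[tf, ], acc$entity_ids)
    s1_vec <- rho_vec
    if (!is.null(triplets)) {
      tt <- triplets[triplets$tf_id == tf, , drop = FALSE]
      if (nrow(tt)) {
        best <- tapply(tt$score1, tt$peak_id, max)
        s1_vec <- rho_vec * 0
        s1_vec[names(best)] <- best
      }
    }
    res <- recover_binding_tf(tf, links, rho_vec, s1_vec, emb_atac, emb_seq,
                              groups, scan, K = K, tau1 = tau1, tau2 = tau2,
                              r1 = r1, r2 = r2, alpha = alpha, l2 = l2,
                              min_positives = min_positives, seed = seed)
    if (!is.null(res)) results[[tf]] <- res
  }
  structure(list(results = results, emb_atac = emb_atac, emb_seq = emb_seq,
                 groups = groups),
            class = "binding_recovery")
}
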