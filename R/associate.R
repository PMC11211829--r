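# Downstream association discovery: expression-prediction gain from newly
# linked TFs, TF-pair interaction correlations on peak accessibility, and
# motif co-enrichment between peak groups.

# out-of-fold linear-regression predictions of y from columns X;
# singular normal equations fall back to a small ridge (1e-6)
oof_linear_predict <- function(y, X, cv_folds, seed) {
  n <- length(y)
  if (n < 2 * cv_folds) stop("need at least 2 observations per fold")
  if (ncol(X) > 0) {  # constant predictors carry no information; drop them
    keep <- apply(X, 2, function(col) stats::sd(col) > 0)
    X <- X[, keep, drop = FALSE]
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  pred <- numeric(n)
  for (f in seq_len(cv_folds)) {
    test <- folds == f
    Xtr <- cbind(1, X[!test, , drop = FALSE])
    Xte <- cbind(1, X[test, , drop = FALSE])
    xtx <- crossprod(Xtr)
    beta <- tryCatch(solve(xtx, crossprod(Xtr, y[!test])),
                     error = function(e) {
                       solve(xtx + 1e-6 * diag(nrow(xtx)),
                             crossprod(Xtr, y[!test]))
                     })
    pred[test] <- Xte %*% beta
  }
  pred
}

#' Expression-prediction gain from adding one TF
#'
#' Predicts a gene's expression across metacells from TF expression by
#' out-of-fold linear regression, with two nested predictor sets, and
#' reports the gain in Pearson correlation between observed and predicted
#' expression when the one extra TF is added. A gain of at least
#' `gain_threshold` (default 0.05) supports the new gene-TF link.
#'
#' @param gene gene id.
#' @param expr expression [metacell_matrix()] containing the gene.
#' @param tf_expr expression [metacell_matrix()] containing all TFs.
#' @param set1 baseline predictor TF ids (the gene's previously linked
#'   TFs; may be empty, giving an intercept-only baseline).
#' @param set2 augmented predictor set; must be `set1` plus exactly one
#'   new TF (or identical to `set1`, giving gain 0 exactly).
#' @param cv_folds number of folds (default 5).
#' @param gain_threshold support threshold on the gain.
#' @param seed integer seed for the fold split.
#' @return One-row data.frame: `gene_id`, `new_tf_id`, `baseline_r`,
#'   `augmented_r`, `gain`, `supported`.
#' @export
gene_tf_gain <- function(gene, expr, tf_expr, set1, set2, cv_folds = 5,
                         gain_threshold = 0.05, seed = 1) {
  if (!gene %in% expr$entity_ids) stop("gene not in expression matrix")
  extra <- setdiff(set2, set1)
  if (!all(set1 %in% set2) || length(extra) > 1) {
    stop("set2 must be set1 plus at most one new TF")
  }
  y <- as.numeric(as.matrix(expr$values)[gene, ])
  tfm <- as.matrix(tf_expr$values)
  miss <- setdiff(set2, rownames(tfm))
  if (length(miss)) stop("TF(s) missing from tf_expr: ",
                         paste(miss, collapse = ", "))
  X1 <- t(tfm[set1, , drop = FALSE])
  p1 <- oof_linear_predict(y, X1, cv_folds, seed)
  r1 <- if (stats::sd(p1) == 0 || stats::sd(y) == 0) 0 else stats::cor(y, p1)
  if (length(extra) == 0) {
    r2 <- r1
  } else {
    X2 <- t(tfm[set2, , drop = FALSE])
    p2 <- oof_linear_predict(y, X2, cv_folds, seed)
    r2 <- if (stats::sd(p2) == 0 || stats::sd(y) == 0) 0 else stats::cor(y, p2)
  }
  gain <- r2 - r1
  data.frame(gene_id = gene,
             new_tf_id = if (length(extra)) extra else NA_character_,
             baseline_r = r1, augmented_r = r2, gain = gain,
             supported = gain >= gain_threshold, stringsAsFactors = FALSE)
}

#' TF-pair interaction scores on a peak's accessibility
#'
#' For a peak with linked TF set `linked_tfs` plus the newly predicted TF
#' `new_tf`, computes (i) the correlation between peak accessibility and
#' each single TF's expression and (ii) the correlation between the
#' accessibility and the product of each unordered TF pair's expression.
#' The peak is flagged when the best pair correlation beats the best
#' single-TF correlation and that pair involves the new TF.
#'
#' @param acc_peak numeric accessibility vector of the peak.
#' @param tf_expr expression [metacell_matrix()] with the TF rows.
#' @param linked_tfs previously linked TF ids.
#' @param new_tf newly linked TF id.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List: `pairs` (data.frame `tf_a`, `tf_b`, `rho_pair`,
#'   `involves_new_tf`), `singles` (named rho), `rho_single_max`,
#'   `best_pair`, `flagged`.
#' @export
tf_pair_interaction <- function(acc_peak, tf_expr, linked_tfs, new_tf,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  tfs <- union(linked_tfs, new_tf)
  if (length(tfs) < 2) stop("need at least 2 TFs (linked set plus new TF)")
  tfm <- as.matrix(tf_expr$values)[tfs, , drop = FALSE]
  corf <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    if (method == "spearman") unclass(spearman_cor(a, b)) else stats::cor(a, b)
  }
  singles <- vapply(tfs, function(tf) corf(acc_peak, tfm[tf, ]), numeric(1))
  cmb <- utils::combn(sort(tfs), 2)
  pairs <- data.frame(tf_a = cmb[1, ], tf_b = cmb[2, ],
                      rho_pair = apply(cmb, 2, function(pr) {
                        corf(acc_peak, tfm[pr[1], ] * tfm[pr[2], ])
                      }), stringsAsFactors = FALSE)
  pairs$involves_new_tf <- pairs$tf_a == new_tf | pairs$tf_b == new_tf
  best <- which.max(pairs$rho_pair)
  flagged <- pairs$rho_pair[best] > max(singles) &&
    pairs$involves_new_tf[best]
  list(pairs = pairs, singles = singles, rho_single_max = max(singles),
       best_pair = pairs[best, c("tf_a", "tf_b")], flagged = flagged)
}

#' Motif co-enrichment between two peak groups
#'
#' For each TF motif, a one-sided Fisher exact test of motif presence in
#' the group versus all remaining peaks, run separately for group 1
#' (peaks with the query TF's motif and supporting signal) and group 2
#' (peaks without the detected motif but with binding recovered by the
#' classifier). Reports `-log10(p)`, `log10` odds ratio, and BH q-values
#' per group.
#'
#' @param group1,group2 disjoint peak id sets.
#' @param scan a [motif_scan()].
#' @param query_tf optional TF id removed from the reported motifs.
#' @return data.frame: `group`, `tf_id`, `in_group`, `group_size`,
#'   `total_with_motif`, `odds_ratio`, `log10_odds`, `p`, `neg_log10_p`,
#'   `q`.
#' @export
motif_coenrichment <- function(group1, group2, scan, query_tf = NULL) {
  stopifnot(inherits(scan, "motif_scan"))
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  tfs <- setdiff(scan$tf_ids, query_tf)
  L <- length(scan$peak_ids)
  one_group <- function(group, label) {
    idx <- scan$peak_ids %in% group
    a <- sum(idx)
    rows <- lapply(tfs, function(tf) {
      hasm <- scan$presence[, tf] == 1
      B <- sum(hasm)
      if (B == 0) return(NULL)  # motif absent everywhere
      b <- sum(idx & hasm)
      p <- stats::phyper(b - 1, B, L - B, a, lower.tail = FALSE)
      or <- (b * ((L - a) - (B - b))) / ((a - b) * (B - b))
      data.frame(group = label, tf_id = tf, in_group = b, group_size = a,
                 total_with_motif = B, odds_ratio = or,
                 log10_odds = log10(or), p = p,
                 neg_log10_p = -log10(p), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(out)) out$q <- stats::p.adjust(out$p, "BH")
    out
  }
  out <- rbind(one_group(group1, "group1"), one_group(group2, "group2"))
  rownames(out) <- NULL
  out
}
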