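# Triplet scoring: assign peaks to candidate target genes, then score each
# (peak, TF, gene) triplet with two complementary functions built from
# Spearman correlation and first-order Spearman partial correlation,
# damped by a motif-score x accessibility regularizer.
#
# With X_j = TF expression, C_i = peak accessibility, Y_g = gene expression:
#   score1 = (w1 * rho(X_j, C_i) + w2 * rho(X_j, Y_g ; C_i)) * reg_ij
#   score2 = (w1 * rho(Y_g, C_i) + w2 * rho(X_j, Y_g ; C_i)) * reg_ij
# where the weights are +0.5 for an inferred activation (rho(X_j, C_i) >= 0)
# and -0.5 for repression, and reg_ij = minmax(theta_ij * pi_i) in [0, 1].

# quantile transform used throughout: rank with ties sharing the upper
# quantile (ties.method = "max") divided by n, so the maximum maps to 1 and
# all-tied inputs map to 1
quantile_transform <- function(x) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  rank(x, ties.method = "max") / n
}

#' Normalize motif scores to per-TF quantiles
#'
#' Positive motif scores of each TF column are quantile-transformed to
#' (0, 1] (ties share the upper quantile; the best score maps to 1);
#' zeros (motif absent) stay 0.
#'
#' @param scan a [motif_scan()].
#' @return Numeric matrix (peaks x TFs) in `[0, 1]`.
#' @export
normalize_motif_scores <- function(scan) {
  stopifnot(inherits(scan, "motif_scan"))
  out <- scan$scores * 0
  for (j in seq_len(ncol(out))) {
    pos <- scan$scores[, j] > 0
    if (any(pos)) out[pos, j] <- quantile_transform(scan$scores[pos, j])
  }
  out
}

#' Transformed maximal peak accessibility
#'
#' Each peak's maximum accessibility over metacells, quantile-transformed
#' across peaks to `[0, 1]`.
#'
#' @param acc accessibility [metacell_matrix()] (peaks x metacells).
#' @return Named numeric vector over peaks.
#' @export
peak_max_accessibility <- function(acc) {
  stopifnot(inherits(acc, "metacell_matrix"))
  m <- as.matrix(acc$values)
  stats::setNames(quantile_transform(apply(m, 1, max)), acc$entity_ids)
}

#' Min-max scaled regularizer over a TF's candidate peaks
#'
#' The product of the normalized motif score and the transformed maximal
#' accessibility, min-max scaled across the peaks in `scope`. If all
#' products are equal the regularizer is 1 for every peak (no
#' discrimination implies no penalty).
#'
#' @param theta normalized motif scores for the scope peaks (in `[0, 1]`).
#' @param pi_max transformed maximal accessibility for the scope peaks.
#' @return Numeric vector in `[0, 1]`, same length as the scope.
#' @export
minmax_regularizer <- function(theta, pi_max) {
  if (length(theta) == 0) stop("empty regularizer scope")
  if (length(theta) != length(pi_max)) stop("theta and pi_max lengths differ")
  prod <- theta * pi_max
  rng <- max(prod) - min(prod)
  if (rng == 0) return(rep(1, length(prod)))
  (prod - min(prod)) / rng
}

#' Assign peaks to candidate target genes
#'
#' Hybrid search: peaks within `window_bp` of a gene's TSS whose
#' accessibility-expression Spearman correlation passes `rho_min` become
#' candidates; then, per peak, competing genes are compared and only those
#' within `delta_rho` of the peak's best `|rho|` stay retained, reducing
#' ambiguous assignment. Dropped competitors are kept with
#' `retained = FALSE`.
#'
#' @param peaks peak table (`peak_id`, `chrom`, `start`, `end`).
#' @param genes gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param acc accessibility [metacell_matrix()] over the peaks.
#' @param expr expression [metacell_matrix()] containing the genes.
#' @param window_bp max |TSS distance| in bp (default 500 kb).
#' @param rho_min minimum `|rho|` to become a candidate.
#' @param delta_rho ambiguity margin relative to the peak's best `|rho|`.
#' @return data.frame: `peak_id`, `gene_id`, `tss_distance` (signed bp from
#'   TSS to peak midpoint, upstream negative on the gene strand), `rho`,
#'   `retained`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, acc, expr,
                                  window_bp = 500000, rho_min = 0.1,
                                  delta_rho = 0.05) {
  validate_peaks(peaks); validate_genes(genes)
  if (!identical(acc$metacell_ids, expr$metacell_ids)) {
    shared <- intersect(acc$metacell_ids, expr$metacell_ids)
    if (length(shared) < 3) stop("no shared metacells between matrices")
    acc <- metacell_matrix(acc$values[, shared, drop = FALSE],
                           acc$entity_ids, shared)
    expr <- metacell_matrix(expr$values[, shared, drop = FALSE],
                            expr$entity_ids, shared)
  }
  genes <- genes[genes$gene_id %in% expr$entity_ids, , drop = FALSE]
  peaks <- peaks[peaks$peak_id %in% acc$entity_ids, , drop = FALSE]
  mid <- (peaks$start + peaks$end) / 2

  # candidate (peak, gene) pairs by distance, per chromosome
  pairs <- vector("list", nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    same <- peaks$chrom == genes$chrom[gi]
    d <- mid[same] - genes$tss[gi]
    if (genes$strand[gi] == "-") d <- -d
    hit <- abs(d) <= window_bp
    if (any(hit)) {
      pairs[[gi]] <- data.frame(peak_id = peaks$peak_id[same][hit],
                                gene_id = genes$gene_id[gi],
                                tss_distance = as.integer(round(d[hit])),
                                stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      tss_distance = integer(), rho = numeric(),
                      retained = logical(), stringsAsFactors = FALSE))
  }

  upeaks <- unique(pairs$peak_id)
  ugenes <- unique(pairs$gene_id)
  rho_mat <- spearman_cor_rows(as.matrix(acc$values)[upeaks, , drop = FALSE],
                               as.matrix(expr$values)[ugenes, , drop = FALSE])
  pairs$rho <- rho_mat[cbind(match(pairs$peak_id, upeaks),
                             match(pairs$gene_id, ugenes))]
  pairs <- pairs[abs(pairs$rho) >= rho_min, , drop = FALSE]
  if (nrow(pairs) == 0) {
    pairs$retained <- logical(0)
    rownames(pairs) <- NULL
    return(pairs)
  }
  best <- tapply(abs(pairs$rho), pairs$peak_id, max)
  pairs$retained <- abs(pairs$rho) >= best[pairs$peak_id] - delta_rho
  pairs <- pairs[order(pairs$peak_id, -abs(pairs$rho)), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Score peak-TF-gene triplets
#'
#' For every retained peak-gene candidate and every TF whose motif is
#' detected in the peak, computes the two complementary scores (see the
#' package vignette). Degenerate correlations (constant inputs) enter as
#' zeros, never NaN.
#'
#' @param candidates output of [assign_peaks_to_genes()] (only rows with
#'   `retained = TRUE` are scored).
#' @param scan a [motif_scan()].
#' @param acc accessibility [metacell_matrix()] (peaks).
#' @param expr expression [metacell_matrix()] (target genes).
#' @param tf_expr expression [metacell_matrix()] whose rows include the TF
#'   ids of `scan` (may be the same object as `expr`).
#' @param weight magnitude of the score weights (default 0.5; the sign is
#'   set per triplet by the inferred association type).
#' @return data.frame of triplets with rho components, `regularizer`,
#'   `sign`, `score1`, `score2`.
#' @export
score_triplets <- function(candidates, scan, acc, expr, tf_expr = expr,
                           weight = 0.5) {
  stopifnot(inherits(scan, "motif_scan"))
  cand <- candidates[candidates$retained, , drop = FALSE]
  if (nrow(cand) == 0) stop("no retained peak-gene candidates")
  tfs <- intersect(scan$tf_ids, tf_expr$entity_ids)
  if (length(tfs) == 0) stop("no scanned TF has an expression row")

  accm <- as.matrix(acc$values)
  exprm <- as.matrix(expr$values)
  tfm <- as.matrix(tf_expr$values)[tfs, , drop = FALSE]
  upeaks <- unique(cand$peak_id)
  ugenes <- unique(cand$gene_id)
  upeaks <- upeaks[upeaks %in% rownames(accm) & upeaks %in% scan$peak_ids]
  cand <- cand[cand$peak_id %in% upeaks, , drop = FALSE]

  # rank-correlation building blocks, computed once
  r_tp <- spearman_cor_rows(tfm, accm[upeaks, , drop = FALSE])   # TF x peak
  r_tg <- spearman_cor_rows(tfm, exprm[ugenes, , drop = FALSE])  # TF x gene
  r_pg <- spearman_cor_rows(accm[upeaks, , drop = FALSE],
                            exprm[ugenes, , drop = FALSE])       # peak x gene

  theta <- normalize_motif_scores(scan)
  pi_max <- peak_max_accessibility(acc)

  out <- vector("list", length(tfs))
  for (jj in seq_along(tfs)) {
    tf <- tfs[jj]
    with_motif <- scan$peak_ids[scan$presence[, tf] == 1]
    rows <- cand[cand$peak_id %in% with_motif, , drop = FALSE]
    if (nrow(rows) == 0) next
    pi_ <- match(rows$peak_id, upeaks)
    gi_ <- match(rows$gene_id, ugenes)
    rho_tp <- r_tp[jj, pi_]
    rho_pg <- r_pg[cbind(pi_, gi_)]
    rho_tg <- r_tg[jj, gi_]
    rho_partial <- pcor_from_cor(rho_tg, rho_tp, r_pg[cbind(pi_, gi_)])

    scope <- unique(rows$peak_id)
    reg_scope <- stats::setNames(
      minmax_regularizer(theta[scope, tf], pi_max[scope]), scope)
    sgn <- ifelse(rho_tp >= 0, 1, -1)
    w1 <- sgn * weight
    reg <- reg_scope[rows$peak_id]
    out[[jj]] <- data.frame(
      peak_id = rows$peak_id, tf_id = tf, gene_id = rows$gene_id,
      rho_tf_peak = rho_tp, rho_peak_gene = rho_pg,
      rho_partial = rho_partial, regularizer = unname(reg),
      sign = sgn,
      score1 = (w1 * rho_tp + w1 * rho_partial) * reg,
      score2 = (w1 * rho_pg + w1 * rho_partial) * reg,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) stop("no scoreable triplets")
  rownames(out) <- NULL
  out
}

#' Call high-confidence per-TF peak links from triplet scores
#'
#' A peak enters a TF's link set when its best `score1` over linked genes
#' reaches the per-TF quantile threshold (ties kept). The link set is by
#' construction a subset of the TF's motif-bearing peaks.
#'
#' @param triplets output of [score_triplets()].
#' @param score_quantile per-TF quantile of best scores used as threshold
#'   (default 0.5: top half); `1.0` keeps only the argmax peak(s).
#' @param min_score optional absolute threshold applied instead of the
#'   quantile when non-NULL.
#' @return Named list, TF id -> character vector of peak ids.
#' @export
call_tf_links <- function(triplets, score_quantile = 0.5, min_score = NULL) {
  out <- list()
  for (tf in unique(triplets$tf_id)) {
    tt <- triplets[triplets$tf_id == tf, , drop = FALSE]
    best <- tapply(tt$score1, tt$peak_id, max)
    thr <- if (!is.null(min_score)) min_score else
      stats::quantile(best, score_quantile, names = FALSE)
    sel <- names(best)[best >= thr]
    if (length(sel) == 0) {
      warning("no links called for TF ", tf)
    }
    out[[tf]] <- sel
  }
  out
}
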