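# Benchmarking of per-peak binding predictions against (real or simulated)
# ChIP-seq intervals: overlap labeling, AUPR as average precision,
# precision at fixed recall, F1, a shuffle null for the F1 of binary calls
# in a restricted peak domain, and 2x2 enrichment tests.

#' Label peaks by ChIP-seq overlap
#'
#' A peak is labeled 1 iff it overlaps any interval by at least 1 bp under
#' the half-open BED convention (an interval starting exactly at a peak's
#' end does not overlap).
#'
#' @param peaks peak table (`peak_id`, `chrom`, `start`, `end`).
#' @param chip interval data.frame (`chrom`, `start`, `end`), e.g. from
#'   [read_bed()] or [chipseq_from_truth()].
#' @return data.frame `peak_id`, `label`.
#' @export
label_by_overlap <- function(peaks, chip) {
  validate_peaks(peaks)
  label <- integer(nrow(peaks))
  if (!is.null(chip) && nrow(chip) > 0) {
    # BED half-open [start, end) -> 1-based closed [start+1, end]
    q <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$start + 1, peaks$end))
    s <- GenomicRanges::GRanges(chip$chrom,
                                IRanges::IRanges(chip$start + 1, chip$end))
    hits <- GenomicRanges::countOverlaps(q, s)
    label <- as.integer(hits > 0)
  }
  data.frame(peak_id = peaks$peak_id, label = label, stringsAsFactors = FALSE)
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed as the sum of precision times recall increments over
#' decreasing score thresholds, with tied scores grouped into a single
#' threshold. This is average precision, not trapezoidal interpolation.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (>= 1 positive and >= 1 negative).
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  pr <- pr_points(scores, labels)
  sum(pr$precision * diff(c(0, pr$recall)))
}

# precision/recall at each distinct score threshold, scores descending
pr_points <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) {
    stop("need at least one positive and one negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  data.frame(threshold = s[last],
             precision = tp[last] / (tp[last] + fp[last]),
             recall = tp[last] / npos)
}

#' Precision at a fixed recall level
#'
#' Precision at the smallest number of top-ranked peaks (largest score
#' threshold, ties grouped) whose recall reaches `r`.
#'
#' @param scores,labels as in [aupr()].
#' @param r target recall in (0, 1], e.g. 0.15 or 0.20.
#' @return Precision in `[0, 1]`.
#' @export
precision_at_recall <- function(scores, labels, r) {
  if (r <= 0 || r > 1) stop("r must be in (0, 1]")
  pr <- pr_points(scores, labels)
  pr$precision[which(pr$recall >= r)[1]]
}

#' F1 score of binary calls
#'
#' `2PR/(P+R)`; defined as 0 when there are no predicted positives, no
#' true positives to recall, or no overlap.
#'
#' @param pred,labels binary vectors of equal length.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(pred, labels) {
  if (length(pred) != length(labels)) stop("length mismatch")
  tp <- sum(pred == 1 & labels == 1)
  if (tp == 0) return(0)
  p <- tp / sum(pred == 1)
  r <- tp / sum(labels == 1)
  2 * p * r / (p + r)
}

#' Shuffle null for the F1 score within a peak domain
#'
#' Repeatedly reassigns the predicted positive calls uniformly at random
#' among the peaks of `domain` (keeping their number fixed) and recomputes
#' F1 against the labels, giving the expected F1 of an uninformed
#' predictor with the same call rate. Used with `domain` = peaks lacking
#' the TF's motif.
#'
#' @param pred named binary calls (peak ids as names).
#' @param labels named binary labels.
#' @param domain peak ids defining the evaluation domain.
#' @param n_shuffles number of shuffles (default 100).
#' @param seed integer seed.
#' @return List: `mean`, `sd`, `values` (per-shuffle F1), `observed`.
#' @export
shuffle_null_f1 <- function(pred, labels, domain, n_shuffles = 100,
                            seed = 1) {
  if (length(domain) == 0) stop("empty domain")
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  p <- pred[domain]; y <- labels[domain]
  if (anyNA(p) || anyNA(y)) stop("domain peaks missing from pred or labels")
  m <- sum(p == 1)
  obs <- f1_score(p, y)
  vals <- with_seed(seed, vapply(seq_len(n_shuffles), function(.) {
    sh <- integer(length(p))
    if (m > 0) sh[sample.int(length(p), m)] <- 1L
    f1_score(sh, y)
  }, numeric(1)))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals,
       observed = obs)
}

#' Enrichment of predicted calls in labeled peaks
#'
#' One-sided (greater) Fisher exact test and Pearson chi-squared test
#' (without continuity correction) on the 2x2 prediction-by-label table.
#' A zero margin makes the tests undefined; p = 1 is returned with
#' attribute `degenerate = TRUE`.
#'
#' @param pred,labels binary vectors of equal length.
#' @return List: `fisher_p`, `chisq_p`, `table`.
#' @export
prediction_enrichment <- function(pred, labels) {
  if (length(pred) != length(labels)) stop("length mismatch")
  tab <- table(factor(pred, levels = c(1, 0)),
               factor(labels, levels = c(1, 0)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(list(fisher_p = 1, chisq_p = 1, table = tab),
                     degenerate = TRUE))
  }
  fisher_p <- stats::fisher.test(tab, alternative = "greater")$p.value
  chisq_p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  list(fisher_p = fisher_p, chisq_p = chisq_p, table = tab)
}

#' Evaluate one TF's predictions against ChIP-seq style intervals
#'
#' @param prediction data.frame `peak_id`, `probability`, `call` (as from
#'   [recover_binding_tf()]).
#' @param peaks peak table.
#' @param chip interval data.frame for the TF.
#' @param scan optional [motif_scan()]; when given, the shuffle null and
#'   the motif-free metrics are computed on the peaks lacking the TF's
#'   motif.
#' @param tf TF id (needed with `scan`).
#' @param n_shuffles shuffle count for the F1 null.
#' @param seed integer seed.
#' @return One-row data.frame: `tf`, `aupr`, `f1`, `precision_at_15`,
#'   `precision_at_20`, `expected_f1_null`, `expected_f1_sd`, `fisher_p`,
#'   `chisq_p`, and (with `scan`) `aupr_nonmotif`, `prevalence_nonmotif`.
#' @export
evaluate_tf <- function(prediction, peaks, chip, scan = NULL, tf = NULL,
                        n_shuffles = 100, seed = 1) {
  lab <- label_by_overlap(peaks, chip)
  y <- stats::setNames(lab$label, lab$peak_id)[prediction$peak_id]
  s <- prediction$probability
  calls <- stats::setNames(prediction$call, prediction$peak_id)
  out <- data.frame(
    tf = if (is.null(tf)) NA_character_ else tf,
    aupr = aupr(s, y),
    f1 = f1_score(calls, y),
    precision_at_15 = precision_at_recall(s, y, 0.15),
    precision_at_20 = precision_at_recall(s, y, 0.20),
    stringsAsFactors = FALSE)
  enr <- prediction_enrichment(unname(calls), unname(y))
  out$fisher_p <- enr$fisher_p
  out$chisq_p <- enr$chisq_p
  if (!is.null(scan)) {
    stopifnot(!is.null(tf))
    domain <- setdiff(prediction$peak_id, motif_peaks(scan, tf))
    nul <- shuffle_null_f1(calls, stats::setNames(y, prediction$peak_id),
                           domain, n_shuffles = n_shuffles, seed = seed)
    out$expected_f1_null <- nul$mean
    out$expected_f1_sd <- nul$sd
    out$f1_nonmotif <- nul$observed
    yd <- y[match(domain, prediction$peak_id)]
    out$prevalence_nonmotif <- mean(yd)
    out$aupr_nonmotif <- if (sum(yd) > 0 && sum(yd) < length(yd)) {
      aupr(s[match(domain, prediction$peak_id)], yd)
    } else NA_real_
  }
  out
}
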