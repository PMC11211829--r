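# Dual latent representations of peaks: truncated SVD of the peak
# accessibility matrix (chromatin feature space) and of the binary
# peak-motif matrix (sequence feature space), followed by PhenoGraph-style
# clustering (kNN graph with shared-neighbor Jaccard weights + Leiden
# community detection) on each manifold.

#' Truncated SVD embedding of peaks
#'
#' Rows of the embedding are `U %*% diag(D)` truncated to `d` components.
#' A deterministic sign convention is applied: within each component the
#' largest-magnitude right-singular-vector loading is made positive.
#' Components beyond the numerical rank are zeroed with a warning.
#'
#' @param mat numeric matrix, peaks x features (metacells, or TF motifs for
#'   the binary sequence space); rownames are peak ids.
#' @param d number of components (must be <= `min(dim(mat))`).
#' @param center `"none"` (default, preserves sparsity of a binary motif
#'   matrix) or `"row"` (subtract per-peak means; used for accessibility).
#' @param space label for the feature space (`"ATAC"` or `"seq"`).
#' @return Object of class `peak_embedding`: list with `embedding`
#'   (L x d), `d`, `sdev` (singular values), `v` (feature loadings),
#'   `space`, `peak_ids`, and `cluster` (NULL until
#'   [cluster_embedding()]).
#' @export
embed_peaks <- function(mat, d, center = c("none", "row"), space = "ATAC") {
  center <- match.arg(center)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("peak ids required as rownames")
  if (d > min(dim(mat))) stop("d exceeds min(dim(mat))")
  x <- if (center == "row") mat - rowMeans(mat) else mat
  sv <- svd(x, nu = d, nv = d)
  dd <- sv$d[seq_len(d)]
  tol <- max(dim(x)) * max(sv$d) * .Machine$double.eps
  dead <- dd <= tol
  if (any(dead)) {
    warning(sum(dead), " component(s) beyond the numerical rank set to zero")
    dd[dead] <- 0
  }
  u <- sv$u; v <- sv$v
  for (k in seq_len(d)) {
    if (dd[k] == 0) { u[, k] <- 0; v[, k] <- 0; next }
    top <- which.max(abs(v[, k]))
    if (v[top, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  emb <- u %*% diag(dd, nrow = d)
  rownames(emb) <- rownames(mat)
  structure(list(embedding = emb, d = d, sdev = dd, v = v, space = space,
                 peak_ids = rownames(mat), cluster = NULL),
            class = "peak_embedding")
}

#' @export
print.peak_embedding <- function(x, ...) {
  cat(sprintf("peak_embedding [%s]: %d peaks x %d components%s\n", x$space,
              nrow(x$embedding), x$d,
              if (is.null(x$cluster)) "" else
                sprintf(", %d clusters", length(unique(x$cluster)))))
  invisible(x)
}

# brute-force Euclidean k nearest neighbors, computed blockwise to bound
# memory. query: row indices into x (default all). self matches (same index)
# are excluded. Returns integer matrix length(query) x k of row indices.
knn_indices <- function(x, k, query = seq_len(nrow(x)), block = 512L) {
  n <- nrow(x)
  if (k >= n) stop("k must be < number of points")
  xsq <- rowSums(x * x)
  out <- matrix(0L, length(query), k)
  for (s in seq(1, length(query), by = block)) {
    idx <- query[s:min(s + block - 1L, length(query))]
    d2 <- outer(xsq[idx], xsq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    ord <- apply(d2, 1L, function(r) order(r)[seq_len(k)])
    out[s:(s + length(idx) - 1L), ] <- t(ord)
  }
  out
}

#' Cluster a peak embedding (PhenoGraph-style)
#'
#' Builds a k-nearest-neighbor graph in the embedding, weights each edge by
#' the Jaccard overlap of the endpoints' neighbor sets, and partitions it
#' with Leiden community detection (modularity objective). Deterministic
#' under a fixed seed.
#'
#' @param emb a [embed_peaks()] result.
#' @param knn neighbors per peak (default 30).
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed.
#' @return The embedding with integer `cluster` labels (1-based) attached.
#' @export
cluster_embedding <- function(emb, knn = 30, resolution = 1, seed = 1) {
  stopifnot(inherits(emb, "peak_embedding"))
  n <- nrow(emb$embedding)
  if (knn >= n) stop("knn must be smaller than the number of peaks")
  nn <- knn_indices(emb$embedding, knn)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = knn),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(adj)          # |N_i intersect N_j|
  trip <- Matrix::summary(adj)
  lo <- pmin(trip$i, trip$j); hi <- pmax(trip$i, trip$j)
  keep <- !duplicated(lo * (n + 1) + hi)    # one record per undirected edge
  i <- lo[keep]; j <- hi[keep]
  ov <- inter[cbind(i, j)]
  w <- ov / (2 * knn - ov)                  # Jaccard of the two kNN sets
  w[w <= 0] <- .Machine$double.eps
  g <- igraph::graph_from_data_frame(
    data.frame(from = i, to = j, weight = w), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 3))
  })
  emb$cluster <- as.integer(memb[match(seq_len(n), as.integer(names(memb)))])
  emb
}

#' Pair the cluster labels of the two feature spaces
#'
#' Each peak receives the pair (k, l) of its accessibility-space and
#' sequence-space cluster labels; peaks sharing a pair form the group
#' S_kl. Non-empty groups partition the peaks.
#'
#' @param emb_atac clustered accessibility embedding.
#' @param emb_seq clustered sequence embedding (same peak order).
#' @return Object of class `paired_groups`: list with `assignment`
#'   (data.frame `peak_id`, `k`, `l`, `group`) and `groups` (named list,
#'   group label -> peak ids).
#' @export
pair_groups <- function(emb_atac, emb_seq) {
  stopifnot(inherits(emb_atac, "peak_embedding"),
            inherits(emb_seq, "peak_embedding"))
  if (!identical(emb_atac$peak_ids, emb_seq$peak_ids)) {
    stop("peak orderings of the two embeddings differ")
  }
  if (is.null(emb_atac$cluster) || is.null(emb_seq$cluster)) {
    stop("cluster both embeddings first (cluster_embedding)")
  }
  grp <- paste(emb_atac$cluster, emb_seq$cluster, sep = "_")
  assignment <- data.frame(peak_id = emb_atac$peak_ids,
                           k = emb_atac$cluster, l = emb_seq$cluster,
                           group = grp, stringsAsFactors = FALSE)
  structure(list(assignment = assignment,
                 groups = split(assignment$peak_id, grp)),
            class = "paired_groups")
}

#' Fisher enrichment of a peak set across paired groups
#'
#' For each paired group S_kl versus all remaining peaks, a one-sided
#' (greater) Fisher exact test of the 2x2 table of membership in
#' `positives`, i.e. the hypergeometric tail probability, with
#' Benjamini-Hochberg correction across groups.
#'
#' @param groups a [pair_groups()] result.
#' @param positives peak ids whose enrichment is tested (e.g. a TF's seed
#'   link set).
#' @param alpha BH q-value cutoff for the `enriched` call (default 0.05).
#' @return data.frame: `group`, `k`, `l`, `a` (group size), `b` (positives
#'   in group), `odds_ratio`, `p`, `q`, `enriched`.
#' @export
fisher_enrichment <- function(groups, positives, alpha = 0.05) {
  stopifnot(inherits(groups, "paired_groups"))
  L <- nrow(groups$assignment)
  B <- sum(groups$assignment$peak_id %in% positives)
  labs <- names(groups$groups)
  a <- lengths(groups$groups)
  b <- vapply(groups$groups, function(p) sum(p %in% positives), 0L)
  p <- stats::phyper(b - 1, B, L - B, a, lower.tail = FALSE)
  or <- (b * ((L - a) - (B - b))) / ((a - b) * (B - b))
  kl <- do.call(rbind, strsplit(labs, "_", fixed = TRUE))
  out <- data.frame(group = labs, k = as.integer(kl[, 1]),
                    l = as.integer(kl[, 2]), a = as.integer(a),
                    b = as.integer(b), odds_ratio = or, p = p,
                    q = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
  out$enriched <- out$q < alpha
  rownames(out) <- NULL
  out
}

#' Candidate expansion through paired feature groups
#'
#' Every paired group containing at least one seed-linked peak contributes
#' its motif-less members as new binding candidates ("seed links + feature
#' group"). The result is disjoint from the motif-bearing peak set by
#' construction.
#'
#' @param groups a [pair_groups()] result.
#' @param seed_links peak ids linked to the TF by triplet scoring.
#' @param nonmotif_peaks peak ids lacking the TF's motif.
#' @return Character vector of candidate peak ids.
#' @export
expand_candidates <- function(groups, seed_links, nonmotif_peaks) {
  stopifnot(inherits(groups, "paired_groups"))
  hit <- vapply(groups$groups, function(p) any(p %in% seed_links), logical(1))
  out <- unlist(groups$groups[hit], use.names = FALSE)
  intersect(out, nonmotif_peaks)
}

#' Union of K nearest neighbors of seed peaks on both manifolds
#'
#' Euclidean K nearest neighbors of every seed peak, in the accessibility
#' and in the sequence embedding, pooled. Seed peaks themselves may appear
#' (as neighbors of other seeds).
#'
#' @param emb_atac,emb_seq the two embeddings (same peak order).
#' @param seed_links seed peak ids.
#' @param K neighbors per peak per space (default 100).
#' @return Character vector of peak ids.
#' @export
neighbor_union <- function(emb_atac, emb_seq, seed_links, K = 100) {
  if (!identical(emb_atac$peak_ids, emb_seq$peak_ids)) {
    stop("peak orderings of the two embeddings differ")
  }
  ids <- emb_atac$peak_ids
  if (K >= length(ids)) stop("K must be < number of peaks")
  seeds <- which(ids %in% seed_links)
  if (length(seeds) == 0) return(character(0))
  nn1 <- knn_indices(emb_atac$embedding, K, query = seeds)
  nn2 <- knn_indices(emb_seq$embedding, K, query = seeds)
  ids[unique(c(as.vector(nn1), as.vector(nn2)))]
}
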