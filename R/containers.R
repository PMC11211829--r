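#' Metacell matrix container
#'
#' A light container for an entities-by-metacells matrix (genes x metacells
#' for expression, peaks x metacells for accessibility). Values are expected
#' on a normalized, log-scale per metacell (see [aggregate_metacells()]).
#' The matrix may be dense (`matrix`) or sparse (`Matrix::dgCMatrix`); all
#' package operations give identical results on either representation.
#'
#' @param values numeric matrix or sparse Matrix, entities in rows.
#' @param entity_ids character vector of row ids (genes or peaks).
#' @param metacell_ids character vector of column ids.
#' @return An object of class `metacell_matrix`: a list with elements
#'   `values`, `entity_ids`, `metacell_ids`.
#' @export
metacell_matrix <- function(values,
                            entity_ids = rownames(values),
                            metacell_ids = colnames(values)) {
  if (is.null(entity_ids) || is.null(metacell_ids)) {
    stop("entity_ids and metacell_ids are required (or set dimnames)")
  }
  entity_ids <- as.character(entity_ids)
  metacell_ids <- as.character(metacell_ids)
  if (nrow(values) != length(entity_ids)) {
    stop("entity_ids length (", length(entity_ids),
         ") does not match matrix rows (", nrow(values), ")")
  }
  if (ncol(values) != length(metacell_ids)) {
    stop("metacell_ids length (", length(metacell_ids),
         ") does not match matrix columns (", ncol(values), ")")
  }
  if (anyDuplicated(entity_ids)) stop("duplicated entity_ids")
  if (anyNA(values)) stop("metacell matrix must not contain NA/NaN")
  dimnames(values) <- list(entity_ids, metacell_ids)
  structure(list(values = values,
                 entity_ids = entity_ids,
                 metacell_ids = metacell_ids),
            class = "metacell_matrix")
}

#' @export
dim.metacell_matrix <- function(x) dim(x$values)

#' @export
print.metacell_matrix <- function(x, ...) {
  cat(sprintf("metacell_matrix: %d entities x %d metacells (%s)\n",
              nrow(x$values), ncol(x$values),
              if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
as.matrix.metacell_matrix <- function(x, ...) as.matrix(x$values)

#' Peak-by-motif scan container
#'
#' Holds the binary presence matrix and the continuous motif-score matrix
#' produced by an external motif scanner, both peaks x TF motifs.
#' Invariants: presence is 0/1; scores are nonnegative and zero wherever
#' presence is zero; a positive score implies presence.
#'
#' @param presence binary matrix, peaks x TF motifs.
#' @param scores nonnegative numeric matrix of the same shape (motif match
#'   scores); defaults to `presence` itself when the scanner reports no
#'   scores.
#' @param tf_ids character vector of motif/TF ids (columns).
#' @param peak_ids character vector of peak ids (rows).
#' @return An object of class `motif_scan`.
#' @export
motif_scan <- function(presence, scores = NULL,
                       tf_ids = colnames(presence),
                       peak_ids = rownames(presence)) {
  if (is.null(tf_ids) || is.null(peak_ids)) {
    stop("tf_ids and peak_ids are required (or set dimnames)")
  }
  if (is.null(scores)) scores <- presence
  presence <- as.matrix(presence)
  scores <- as.matrix(scores)
  if (!all(dim(presence) == dim(scores))) {
    stop("presence and scores dimensions differ")
  }
  if (!all(presence %in% c(0, 1))) stop("presence must be binary 0/1")
  if (any(scores < 0)) stop("motif scores must be nonnegative")
  if (any(scores > 0 & presence == 0)) {
    stop("positive score where presence is 0 violates the scan invariant")
  }
  tf_ids <- as.character(tf_ids)
  peak_ids <- as.character(peak_ids)
  if (length(tf_ids) != ncol(presence) || length(peak_ids) != nrow(presence)) {
    stop("id lengths do not match matrix dimensions")
  }
  dimnames(presence) <- dimnames(scores) <- list(peak_ids, tf_ids)
  structure(list(presence = presence, scores = scores,
                 tf_ids = tf_ids, peak_ids = peak_ids),
            class = "motif_scan")
}

#' @export
print.motif_scan <- function(x, ...) {
  cat(sprintf("motif_scan: %d peaks x %d TF motifs, %.1f%% presence\n",
              nrow(x$presence), ncol(x$presence), 100 * mean(x$presence)))
  invisible(x)
}

#' Peaks carrying a TF motif
#'
#' @param scan a [motif_scan()] object.
#' @param tf TF/motif id.
#' @return Character vector of peak ids with the motif detected.
#' @export
motif_peaks <- function(scan, tf) {
  stopifnot(inherits(scan, "motif_scan"))
  if (!tf %in% scan$tf_ids) stop("unknown TF: ", tf)
  scan$peak_ids[scan$presence[, tf] == 1]
}

# validate a peak table: data.frame(peak_id, chrom, start, end), BED-style
# 0-based half-open coordinates
validate_peaks <- function(peaks) {
  need <- c("peak_id", "chrom", "start", "end")
  if (!all(need %in% names(peaks))) {
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(peaks$start >= peaks$end)) stop("peak start must be < end")
  if (any(peaks$start < 0)) stop("negative peak start")
  if (anyDuplicated(peaks$peak_id)) stop("duplicated peak_id")
  invisible(peaks)
}

# validate a gene table: data.frame(gene_id, chrom, tss, strand)
validate_genes <- function(genes) {
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(genes))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id")
  if (any(genes$tss < 0)) stop("negative TSS")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(genes)
}
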