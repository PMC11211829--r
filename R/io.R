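#' Read a BED3/BED4 file of peaks or intervals
#'
#' Coordinates follow the BED convention: 0-based, half-open `[start, end)`.
#' When a fourth (name) column is absent, peak ids are auto-generated as
#' `"chrom:start-end"`.
#'
#' @param path file path.
#' @return data.frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   input order preserved.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3)) {
    stop("BED parse error at line ", lineno[which(nfield < 3)[1]],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1]], ": non-integer coordinates")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1]], ": start >= end")
  }
  id <- ifelse(nfield >= 4, vapply(parts, `[`, "", 4L),
               sprintf("%s:%d-%d", chrom, start, end))
  data.frame(peak_id = id, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Write intervals as BED4
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `peak_id` (written as the name column).
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  id <- if ("peak_id" %in% names(x)) x$peak_id else sprintf("%s:%d-%d", x$chrom, x$start, x$end)
  out <- data.frame(x$chrom, x$start, x$end, id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Accepts a TSV with header columns `gene_id`, `chrom`, `tss`, `strand`
#' (TSS 0-based), or a GTF file (`.gtf`; requires the rtracklayer package),
#' from which `gene` features are taken and the TSS derived from the strand
#' and converted to 0-based.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GTF requires the rtracklayer package; ",
           "provide a TSV (gene_id, chrom, tss, strand) instead")
    }
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    # GTF is 1-based closed; TSS as 0-based position
    tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                  GenomicRanges::end(gr) - 1L,
                  GenomicRanges::start(gr) - 1L)
    genes <- data.frame(gene_id = gr$gene_id,
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        tss = tss,
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  validate_genes(genes)
  genes
}

#' Write a gene annotation table (TSV)
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  validate_genes(genes)
  utils::write.table(genes[, c("gene_id", "chrom", "tss", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an entities-by-metacells matrix
#'
#' Two on-disk layouts are supported:
#' * `mtx`: MatrixMarket file plus sidecar id files `<path>.rownames` and
#'   `<path>.colnames` (one id per line), as written by [write_matrix()].
#' * `tsv`: tab-separated values with a header row of metacell ids and the
#'   first column holding entity ids.
#'
#' @param path matrix file path.
#' @param format `"auto"` (by extension), `"mtx"` or `"tsv"`.
#' @return A [metacell_matrix()]; MTX input is kept sparse when density
#'   is below 50%.
#' @export
read_matrix <- function(path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (length(rn) != nrow(m)) {
      stop("row-id file length (", length(rn), ") does not match matrix rows (",
           nrow(m), ")")
    }
    if (length(cn) != ncol(m)) {
      stop("column-id file length (", length(cn),
           ") does not match matrix columns (", ncol(m), ")")
    }
    m <- methods::as(m, "CsparseMatrix")
    if (Matrix::nnzero(m) / prod(dim(m)) >= 0.5) m <- as.matrix(m)
    metacell_matrix(m, rn, cn)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    rn <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    metacell_matrix(m, rn, colnames(m))
  }
}

#' Write an entities-by-metacells matrix
#'
#' Inverse of [read_matrix()]; `mtx` output writes sidecar
#' `<path>.rownames` / `<path>.colnames` id files.
#'
#' @param mm a [metacell_matrix()] (or plain matrix with dimnames).
#' @param path output path.
#' @param format `"mtx"` or `"tsv"`.
#' @export
write_matrix <- function(mm, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!inherits(mm, "metacell_matrix")) mm <- metacell_matrix(mm)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(mm$values, "dMatrix"),
                                "CsparseMatrix"), path)
    writeLines(mm$entity_ids, paste0(path, ".rownames"))
    writeLines(mm$metacell_ids, paste0(path, ".colnames"))
  } else {
    m <- as.matrix(mm$values)
    dt <- data.table::data.table(id = mm$entity_ids)
    dt <- cbind(dt, data.table::as.data.table(m))
    data.table::setnames(dt, c("id", mm$metacell_ids))
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

#' Read a cell-to-metacell assignment table
#'
#' @param path TSV with header columns `cell_id`, `metacell_id`.
#' @return data.frame with those two columns.
#' @export
read_cell_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "metacell_id") %in% names(map))) {
    stop("cell map must have columns cell_id, metacell_id")
  }
  if (anyDuplicated(map$cell_id)) stop("a cell maps to more than one metacell")
  map
}

#' Aggregate single-cell counts into normalized metacell profiles
#'
#' Member-cell counts are summed per metacell, each metacell column is
#' scaled to a fixed total (`scale`, default 1e4), and natural `log1p` is
#' applied — i.e. counts "normalized per metacell and log-transformed".
#' Metacells are ordered by first appearance in the map.
#'
#' @param counts raw count matrix, entities x cells, with cell ids as
#'   column names.
#' @param map data.frame with `cell_id`, `metacell_id` covering every
#'   counted cell.
#' @param scale target per-metacell total before log1p.
#' @return A [metacell_matrix()].
#' @export
aggregate_metacells <- function(counts, map, scale = 1e4) {
  counts <- as.matrix(counts)
  cells <- colnames(counts)
  if (is.null(cells)) stop("counts must have cell ids as column names")
  missing <- setdiff(cells, map$cell_id)
  if (length(missing)) {
    stop("cells not present in the cell->metacell map: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  mc <- map$metacell_id[match(cells, map$cell_id)]
  mc_order <- unique(mc)
  agg <- vapply(mc_order, function(m) {
    rowSums(counts[, mc == m, drop = FALSE])
  }, numeric(nrow(counts)))
  totals <- colSums(agg)
  if (any(totals == 0)) {
    stop("metacell with zero total count: ", mc_order[which(totals == 0)[1]])
  }
  norm <- log1p(sweep(agg, 2, totals / scale, "/"))
  if (is.null(rownames(counts))) rownames(norm) <- paste0("entity", seq_len(nrow(norm)))
  metacell_matrix(norm, rownames(norm), mc_order)
}
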