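# Synthetic multiome generator with planted peak-TF-gene ground truth.
# Latent cell-state activities drive TF expression and the accessibility of
# bound peaks; target gene expression is driven by its regulatory peaks'
# accessibility times the linked TF's expression; the motif presence matrix
# is the true binding matrix with a fraction of entries masked (hidden
# motifs) and spurious motifs added in unbound peaks.

# numerically stable softplus link; keeps accessibility nonnegative pre-log
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# evaluate expr under a fixed RNG seed without clobbering global RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a stage-specific 32-bit seed from a master seed
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, cluster_atac = 23L, cluster_seq = 29L,
               negatives = 37L, classifier = 41L, evaluate = 53L,
               associate = 59L, folds = 61L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage))
  # numeric arithmetic, then reduce: stays exact below 2^53 and the
  # result fits a 32-bit integer seed
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

#' Configuration for the synthetic multiome generator
#'
#' Defaults define the package's reference simulation: 10 TFs on 10 latent
#' cell states, 5000 peaks, 300 metacells, 5% of peaks bound per TF, 30%
#' of truly bound peaks with the motif hidden, and 5% spurious motifs in
#' unbound peaks.
#'
#' @param n_metacells number of metacells.
#' @param n_tfs number of TFs (each with a motif column).
#' @param n_peaks number of accessibility peaks.
#' @param n_genes number of target genes (TF genes are added on top).
#' @param n_states number of latent cell states (must be <= `n_tfs`).
#' @param bound_fraction fraction of peaks bound per TF.
#' @param motif_mask_rate fraction of truly bound peaks whose motif is
#'   hidden from the scan (Bernoulli per bound entry).
#' @param false_motif_rate fraction of unbound (peak, TF) entries given a
#'   spurious motif.
#' @param noise_sd Gaussian noise scale added to accessibility and
#'   expression.
#' @param repression_fraction fraction of TFs acting as repressors
#'   (accessibility of their bound peaks decreases with state activity).
#' @param peak_gene_window_bp bound peaks are placed within this distance
#'   of their target gene's TSS.
#' @param gene_spacing_bp TSS spacing on the synthetic chromosome.
#' @param peak_width_bp width of each peak.
#' @param link accessibility link function, `"softplus"` or `"linear"`.
#' @param co_binding if TRUE, TFs are paired on shared states and bound
#'   peaks of a pair carry both TFs (exercises TF-pair analyses).
#' @param seed integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_metacells = 300, n_tfs = 10, n_peaks = 5000,
                              n_genes = 500, n_states = n_tfs,
                              bound_fraction = 0.05, motif_mask_rate = 0.3,
                              false_motif_rate = 0.05, noise_sd = 0.3,
                              repression_fraction = 0.2,
                              peak_gene_window_bp = 50000,
                              gene_spacing_bp = 50000, peak_width_bp = 500,
                              link = c("softplus", "linear"),
                              co_binding = FALSE, seed = 1) {
  link <- match.arg(link)
  cfg <- list(n_metacells = n_metacells, n_tfs = n_tfs, n_peaks = n_peaks,
              n_genes = n_genes, n_states = n_states,
              bound_fraction = bound_fraction,
              motif_mask_rate = motif_mask_rate,
              false_motif_rate = false_motif_rate, noise_sd = noise_sd,
              repression_fraction = repression_fraction,
              peak_gene_window_bp = peak_gene_window_bp,
              gene_spacing_bp = gene_spacing_bp,
              peak_width_bp = peak_width_bp, link = link,
              co_binding = co_binding, seed = seed)
  fracs <- c(bound_fraction, motif_mask_rate, false_motif_rate,
             repression_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_states > n_tfs) stop("n_states must be <= n_tfs")
  if (n_states < 1 || n_metacells < 3) stop("infeasible config")
  n_bound <- n_tfs * round(bound_fraction * n_peaks)
  if (!co_binding && n_bound > n_peaks) {
    stop("infeasible config: more bound peaks than peaks (",
         n_bound, " > ", n_peaks, ")")
  }
  if (co_binding && n_tfs %% 2 != 0) {
    stop("co_binding requires an even number of TFs")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multiome dataset with planted TF-peak-gene ground truth
#'
#' @param cfg a [simulation_config()].
#' @return A list of class `sim_multiome` with elements:
#'   `expression` (genes + TF genes x metacells, [metacell_matrix()]),
#'   `accessibility` (peaks x metacells), `motifs` ([motif_scan()]),
#'   `peaks` (BED-style data.frame), `genes` (annotation data.frame,
#'   TF genes on a separate chromosome), `tf_ids`, and `truth`
#'   (list: `binding` L x M binary matrix, `peak_gene` named vector over
#'   bound peaks, `tf_sign` named +1/-1 vector).
#' @export
simulate_multiome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "simulate"), simulate_multiome_impl(cfg))
}

simulate_multiome_impl <- function(cfg) {
  N <- cfg$n_metacells; L <- cfg$n_peaks; M <- cfg$n_tfs; G <- cfg$n_genes
  link <- if (cfg$link == "softplus") softplus else identity
  tf_ids <- sprintf("TF%02d", seq_len(M))
  gene_ids <- sprintf("G%04d", seq_len(G))
  metacell_ids <- sprintf("mc%03d", seq_len(N))

  # latent state activities per metacell
  A <- matrix(stats::rnorm(cfg$n_states * N), cfg$n_states, N)
  state_of_tf <- if (cfg$co_binding) {
    rep(seq_len(cfg$n_states), each = 2, length.out = M)
  } else rep_len(seq_len(cfg$n_states), M)

  n_rep <- round(cfg$repression_fraction * M)
  tf_sign <- rep(1, M)
  if (n_rep > 0) tf_sign[sample.int(M, n_rep)] <- -1
  names(tf_sign) <- tf_ids

  # TF expression loads on its state
  X <- link(A[state_of_tf, , drop = FALSE]) +
    cfg$noise_sd * matrix(stats::rnorm(M * N), M, N)
  rownames(X) <- tf_ids

  # genome layout: target genes evenly spaced on chrS, TF genes on chrT;
  # peaks occupy distinct 1 kb bins so they never overlap each other
  genes <- data.frame(gene_id = gene_ids, chrom = "chrS",
                      tss = cfg$gene_spacing_bp * seq_len(G),
                      strand = rep_len(c("+", "-"), G),
                      stringsAsFactors = FALSE)
  tf_genes <- data.frame(gene_id = tf_ids, chrom = "chrT",
                         tss = 100000 * seq_len(M), strand = "+",
                         stringsAsFactors = FALSE)
  bin_bp <- 1000
  n_bins <- ceiling((G + 1) * cfg$gene_spacing_bp / bin_bp)
  n_per_tf <- round(cfg$bound_fraction * L)

  # bound peaks: pick a target gene, then a free bin within the window
  free <- rep(TRUE, n_bins)
  tf_of_peak <- integer(0); gene_of_peak <- integer(0); bins <- integer(0)
  bound_tfs <- if (cfg$co_binding) seq(1, M, by = 2) else seq_len(M)
  for (j in bound_tfs) {
    for (b in seq_len(n_per_tf)) {
      placed <- FALSE
      for (try in 1:50) {
        g <- sample.int(G, 1)
        lo <- max(1, floor((genes$tss[g] - cfg$peak_gene_window_bp) / bin_bp) + 1)
        hi <- min(n_bins, floor((genes$tss[g] + cfg$peak_gene_window_bp) / bin_bp))
        cand <- which(free[lo:hi]) + lo - 1L
        if (length(cand)) {
          bin <- if (length(cand) == 1) cand else sample(cand, 1)
          free[bin] <- FALSE
          bins <- c(bins, bin); tf_of_peak <- c(tf_of_peak, j)
          gene_of_peak <- c(gene_of_peak, g)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("infeasible config: no free bin near a sampled gene")
    }
  }
  n_bound <- length(bins)
  n_bg <- L - n_bound
  if (n_bg < 0) stop("infeasible config: bound peaks exceed n_peaks")
  bg_bins <- sample(which(free), n_bg)
  all_bins <- c(bins, bg_bins)
  tf_of_peak <- c(tf_of_peak, rep(NA_integer_, n_bg))
  gene_of_peak <- c(gene_of_peak, rep(NA_integer_, n_bg))

  # shuffle peak order so bound/unbound are interleaved
  ord <- sample.int(L)
  all_bins <- all_bins[ord]
  tf_of_peak <- tf_of_peak[ord]
  gene_of_peak <- gene_of_peak[ord]

  start <- (all_bins - 1L) * bin_bp + (bin_bp - cfg$peak_width_bp) %/% 2
  end <- start + cfg$peak_width_bp
  peak_ids <- sprintf("chrS:%d-%d", start, end)
  peaks <- data.frame(peak_id = peak_ids, chrom = "chrS",
                      start = start, end = end, stringsAsFactors = FALSE)

  # true binding matrix; co-binding pairs share their bound peaks
  binding <- matrix(0L, L, M, dimnames = list(peak_ids, tf_ids))
  is_bound <- !is.na(tf_of_peak)
  binding[cbind(which(is_bound), tf_of_peak[is_bound])] <- 1L
  if (cfg$co_binding) {
    binding[cbind(which(is_bound), tf_of_peak[is_bound] + 1L)] <- 1L
  }

  # accessibility: bound peaks follow their TF's (signed) state activity;
  # background peaks get an independent smooth profile
  C <- matrix(0, L, N, dimnames = list(peak_ids, metacell_ids))
  noise <- cfg$noise_sd * matrix(stats::rnorm(L * N), L, N)
  amp <- stats::runif(L, 0.5, 1.5)  # per-peak accessibility amplitude
  for (i in seq_len(L)) {
    if (is_bound[i]) {
      j <- tf_of_peak[i]
      base <- A[state_of_tf[j], ] * tf_sign[j]
      if (cfg$co_binding) base <- base * tf_sign[j + 1L]
      C[i, ] <- amp[i] * link(base)
    } else {
      C[i, ] <- amp[i] * link(stats::rnorm(N))
    }
  }
  C <- C + noise

  # gene expression: regulatory peaks' accessibility x linked TF expression
  Y <- matrix(0, G, N, dimnames = list(gene_ids, metacell_ids))
  for (g in seq_len(G)) {
    idx <- which(gene_of_peak == g)
    if (length(idx)) {
      w <- stats::runif(length(idx), 0.5, 1.5)
      contrib <- sweep(C[idx, , drop = FALSE] *
                         X[tf_of_peak[idx], , drop = FALSE], 1, w, "*")
      Y[g, ] <- colSums(contrib) / length(idx)
    } else {
      Y[g, ] <- link(stats::rnorm(N))
    }
  }
  Y <- Y + cfg$noise_sd * matrix(stats::rnorm(G * N), G, N)

  # motif scan: truth with hidden motifs and spurious extra motifs
  presence <- binding
  masked <- binding == 1L &
    matrix(stats::runif(L * M) < cfg$motif_mask_rate, L, M)
  presence[masked] <- 0L
  spurious <- binding == 0L &
    matrix(stats::runif(L * M) < cfg$false_motif_rate, L, M)
  presence[spurious] <- 1L
  scores <- matrix(0, L, M, dimnames = dimnames(presence))
  scores[presence == 1L] <- stats::runif(sum(presence), 1, 10)

  peak_gene <- stats::setNames(gene_ids[gene_of_peak[is_bound]],
                               peak_ids[is_bound])
  out <- list(
    expression = metacell_matrix(rbind(Y, X), c(gene_ids, tf_ids),
                                 metacell_ids),
    accessibility = metacell_matrix(C, peak_ids, metacell_ids),
    motifs = motif_scan(presence, scores, tf_ids, peak_ids),
    peaks = peaks,
    genes = rbind(genes, tf_genes),
    tf_ids = tf_ids,
    truth = list(binding = binding, peak_gene = peak_gene,
                 tf_sign = tf_sign),
    config = cfg
  )
  class(out) <- "sim_multiome"
  out
}

#' Emit ChIP-seq style intervals from the planted ground truth
#'
#' One interval per truly bound peak of the TF, spanning exactly that peak,
#' so that overlap labeling against the same peak set recovers the truth
#' column. These are synthetic evaluation labels standing in for real
#' ChIP-seq peak files.
#'
#' @param truth the `truth` element of a [simulate_multiome()] result.
#' @param peaks the matching peak table.
#' @param tf TF id.
#' @return data.frame of intervals (`chrom`, `start`, `end`, `peak_id`),
#'   writable with [write_bed()].
#' @export
chipseq_from_truth <- function(truth, peaks, tf) {
  if (!tf %in% colnames(truth$binding)) stop("unknown TF: ", tf)
  bound <- rownames(truth$binding)[truth$binding[, tf] == 1]
  out <- peaks[match(bound, peaks$peak_id), c("chrom", "start", "end", "peak_id"),
               drop = FALSE]
  rownames(out) <- NULL
  out
}
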