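# End-to-end orchestration: simulate -> triplet scoring -> binding
# recovery -> evaluation -> association discovery, under one flat config
# and a single master seed. Artifacts are TSV/BED files plus a manifest
# with per-file checksums so that reruns are verifiably reproducible.

#' Default pipeline configuration
#'
#' Flat key-value list consumed by [run_pipeline()]. Numeric defaults:
#' peak-gene window 500 kb, embedding dimensions d1 = d2 = 50, clustering
#' knn = 30, seed-neighbor K = 100, pseudo-positive thresholds tau1 = 0.25
#' / tau2 = 0.75, negative ratios r1 = 0.25 / r2 = 1.5, enrichment alpha =
#' 0.05, 100 F1-null shuffles, expression-gain threshold 0.05, minimum 20
#' seed peaks per TF. The demo simulation uses 10 TFs, 3000 peaks and 300
#' metacells.
#'
#' @param ... overrides of any default, by name.
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    # simulation
    n_metacells = 300, n_tfs = 10, n_peaks = 3000, n_genes = 300,
    bound_fraction = 0.05, motif_mask_rate = 0.3, false_motif_rate = 0.05,
    noise_sd = 0.3, repression_fraction = 0.2,
    # triplet scoring
    window_bp = 500000, rho_min = 0.1, delta_rho = 0.05, weight = 0.5,
    link_quantile = 0.5,
    # binding recovery
    d1 = 50, d2 = 50, knn = 30, resolution = 1, K = 100,
    tau1 = 0.25, tau2 = 0.75, r1 = 0.25, r2 = 1.5, alpha = 0.05, l2 = 1,
    min_positives = 20,
    # evaluation / association
    n_shuffles = 100, gain_threshold = 0.05, cv_folds = 5,
    max_genes_per_tf = 10, max_peaks_per_tf = 10,
    # master seed
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (cfg$tau2 <= cfg$tau1) stop("config error: tau2 must be > tau1")
  if (cfg$r1 <= 0 || cfg$r2 <= 0) stop("config error: r1, r2 must be > 0")
  if (cfg$n_shuffles < 1) stop("config error: n_shuffles must be >= 1")
  invisible(cfg)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  path
}

#' Run the full pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' under `out_dir` and finally a `manifest.tsv` (file, md5 checksum) plus
#' a `config.txt` dump. With the same config and master seed the written
#' prediction files are byte-identical across reruns.
#'
#' @param config a [default_config()] (possibly with overrides).
#' @param out_dir output directory (created if needed).
#' @param stages subset of
#'   `c("simulate", "triplets", "binding", "evaluate", "associate")`,
#'   honored in pipeline order; later stages require the earlier ones in
#'   the same call.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and artifact
#'   paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "triplets", "binding",
                                    "evaluate", "associate"),
                         quiet = FALSE) {
  validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  order_ <- c("simulate", "triplets", "binding", "evaluate", "associate")
  stages <- order_[order_ %in% stages]
  need <- function(stage, have) {
    if (!(stage %in% names(have)) || is.null(have[[stage]])) {
      stop("stage dependency missing: run '", stage, "' first")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  res <- list()

  for (stage in stages) {
    if (stage == "simulate") {
      say("[simulate] ", config$n_peaks, " peaks, ", config$n_tfs,
          " TFs, ", config$n_metacells, " metacells")
      sim <- simulate_multiome(simulation_config(
        n_metacells = config$n_metacells, n_tfs = config$n_tfs,
        n_peaks = config$n_peaks, n_genes = config$n_genes,
        bound_fraction = config$bound_fraction,
        motif_mask_rate = config$motif_mask_rate,
        false_motif_rate = config$false_motif_rate,
        noise_sd = config$noise_sd,
        repression_fraction = config$repression_fraction,
        seed = config$seed))
      res$simulate <- sim
      write_bed(sim$peaks, file.path(out_dir, "peaks.bed"))
      write_genes(sim$genes, file.path(out_dir, "genes.tsv"))
      write_matrix(sim$expression, file.path(out_dir, "expression.tsv"))
      write_matrix(sim$accessibility, file.path(out_dir, "accessibility.tsv"))
      write_matrix(metacell_matrix(sim$motifs$presence),
                   file.path(out_dir, "motif_presence.tsv"))
      write_matrix(metacell_matrix(sim$motifs$scores),
                   file.path(out_dir, "motif_scores.tsv"))
      chip_dir <- file.path(out_dir, "chip")
      dir.create(chip_dir, showWarnings = FALSE)
      for (tf in sim$tf_ids) {
        write_bed(chipseq_from_truth(sim$truth, sim$peaks, tf),
                  file.path(chip_dir, paste0(tf, ".bed")))
      }
    } else if (stage == "triplets") {
      need("simulate", res)
      sim <- res$simulate
      say("[triplets] peak-gene assignment and triplet scoring")
      cand <- assign_peaks_to_genes(sim$peaks, sim$genes, sim$accessibility,
                                    sim$expression,
                                    window_bp = config$window_bp,
                                    rho_min = config$rho_min,
                                    delta_rho = config$delta_rho)
      trip <- score_triplets(cand, sim$motifs, sim$accessibility,
                             sim$expression, sim$expression,
                             weight = config$weight)
      links <- call_tf_links(trip, score_quantile = config$link_quantile)
      res$triplets <- list(candidates = cand, triplets = trip, links = links)
      write_tsv(trip, file.path(out_dir, "triplets.tsv"))
      write_tsv(data.frame(
        tf_id = rep(names(links), lengths(links)),
        peak_id = unlist(links, use.names = FALSE)),
        file.path(out_dir, "tf_links.tsv"))
    } else if (stage == "binding") {
      need("simulate", res); need("triplets", res)
      sim <- res$simulate
      say("[binding] embeddings, clustering and per-TF classifiers")
      rec <- recover_binding(res$triplets$links, res$triplets$triplets,
                             sim$accessibility, sim$expression, sim$motifs,
                             d1 = config$d1, d2 = config$d2,
                             knn = config$knn,
                             resolution = config$resolution, K = config$K,
                             tau1 = config$tau1, tau2 = config$tau2,
                             r1 = config$r1, r2 = config$r2,
                             alpha = config$alpha, l2 = config$l2,
                             min_positives = config$min_positives,
                             seed = config$seed)
      res$binding <- rec
      pred_dir <- file.path(out_dir, "predictions")
      dir.create(pred_dir, showWarnings = FALSE)
      audit <- list(); enrich <- list()
      for (tf in names(rec$results)) {
        r <- rec$results[[tf]]
        write_tsv(r$prediction, file.path(pred_dir, paste0(tf, ".tsv")))
        audit[[tf]] <- data.frame(
          tf_id = tf, n1 = r$pseudo$n1, n2_1 = r$pseudo$n2_1,
          n2_2 = r$pseudo$n2_2, eligible1 = r$pseudo$eligible1,
          eligible2 = r$pseudo$eligible2,
          n_enriched_groups = sum(r$enrichment$enriched))
        e <- r$enrichment; e$tf_id <- tf
        enrich[[tf]] <- e
        say("  ", tf, ": n1=", r$pseudo$n1, " n2,1=", r$pseudo$n2_1,
            " n2,2=", r$pseudo$n2_2, " enriched groups=",
            sum(r$enrichment$enriched))
      }
      if (length(audit)) {
        write_tsv(do.call(rbind, audit),
                  file.path(out_dir, "pseudo_labels.tsv"))
        write_tsv(do.call(rbind, enrich), file.path(out_dir, "enrichment.tsv"))
      } else {
        say("  no TF passed min_positives = ", config$min_positives,
            "; nothing to train")
      }
    } else if (stage == "evaluate") {
      need("simulate", res); need("binding", res)
      sim <- res$simulate
      say("[evaluate] metrics against simulated ChIP-seq intervals")
      evals <- list()
      for (tf in names(res$binding$results)) {
        chip <- chipseq_from_truth(sim$truth, sim$peaks, tf)
        evals[[tf]] <- evaluate_tf(res$binding$results[[tf]]$prediction,
                                   sim$peaks, chip, scan = sim$motifs,
                                   tf = tf, n_shuffles = config$n_shuffles,
                                   seed = derive_seed(config$seed, "evaluate"))
      }
      ev <- do.call(rbind, evals)
      res$evaluate <- ev
      if (is.null(ev)) {
        say("  no predictions to evaluate")
        next
      }
      write_tsv(ev, file.path(out_dir, "evaluation.tsv"))
      summary <- data.frame(median_aupr = stats::median(ev$aupr),
                            median_f1 = stats::median(ev$f1),
                            median_precision_at_15 =
                              stats::median(ev$precision_at_15),
                            median_precision_at_20 =
                              stats::median(ev$precision_at_20),
                            n_tfs = nrow(ev))
      write_tsv(summary, file.path(out_dir, "evaluation_summary.tsv"))
      say(sprintf("  median AUPR %.3f, median F1 %.3f over %d TFs",
                  summary$median_aupr, summary$median_f1, summary$n_tfs))
    } else if (stage == "associate") {
      need("simulate", res); need("triplets", res); need("binding", res)
      sim <- res$simulate
      say("[associate] gene-TF gains, TF pairs and motif co-enrichment")
      res$associate <- run_association_stage(sim, res$triplets, res$binding,
                                             config, out_dir)
    }
  }

  # manifest: config dump + md5 of every artifact
  cfg_lines <- paste0(names(config), " = ",
                      vapply(config, function(v) paste(v, collapse = ","), ""))
  writeLines(cfg_lines, file.path(out_dir, "config.txt"))
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.tsv")
  md5 <- tools::md5sum(file.path(out_dir, files))
  write_tsv(data.frame(file = files, md5 = unname(md5)),
            file.path(out_dir, "manifest.tsv"))
  invisible(c(res, list(out_dir = out_dir, config = config)))
}

# association-discovery stage: for each TF, evaluate new gene links
# through motif-less predicted peaks, TF-pair interactions on those
# peaks, and motif co-enrichment of predicted motif-less binding
run_association_stage <- function(sim, triplets, binding, config, out_dir) {
  gains <- list(); pairs <- list(); coenr <- list()
  seed_a <- derive_seed(config$seed, "associate")
  for (tf in names(binding$results)) {
    pred <- binding$results[[tf]]$prediction
    nonmotif <- setdiff(pred$peak_id, motif_peaks(sim$motifs, tf))
    called <- pred$peak_id[pred$call == 1]
    new_peaks <- intersect(called, nonmotif)
    if (length(new_peaks) == 0) next

    # genes reachable from newly bound peaks via retained peak-gene links
    cand <- triplets$candidates
    cand <- cand[cand$retained & cand$peak_id %in% new_peaks, , drop = FALSE]
    trip_tf <- triplets$triplets[triplets$triplets$tf_id == tf, , drop = FALSE]
    new_genes <- setdiff(unique(cand$gene_id), unique(trip_tf$gene_id))
    new_genes <- utils::head(new_genes, config$max_genes_per_tf)
    for (g in new_genes) {
      base_tfs <- unique(triplets$triplets$tf_id[
        triplets$triplets$gene_id == g])
      base_tfs <- setdiff(base_tfs, tf)
      row <- gene_tf_gain(g, sim$expression, sim$expression,
                          set1 = base_tfs, set2 = c(base_tfs, tf),
                          cv_folds = config$cv_folds,
                          gain_threshold = config$gain_threshold,
                          seed = seed_a)
      row$tf_id <- tf
      gains[[length(gains) + 1]] <- row
    }

    # TF-pair interactions on newly bound peaks with >= 1 previously
    # linked TF
    accm <- as.matrix(sim$accessibility$values)
    for (pk in utils::head(new_peaks, config$max_peaks_per_tf)) {
      linked <- unique(triplets$triplets$tf_id[
        triplets$triplets$peak_id == pk])
      linked <- setdiff(linked, tf)
      if (length(linked) == 0) linked <- setdiff(sim$tf_ids, tf)[1]
      tp <- tf_pair_interaction(accm[pk, ], sim$expression, linked, tf)
      pairs[[length(pairs) + 1]] <- data.frame(
        tf_id = tf, peak_id = pk, rho_single_max = tp$rho_single_max,
        best_pair = paste(tp$best_pair, collapse = "*"),
        rho_pair_max = max(tp$pairs$rho_pair), flagged = tp$flagged,
        stringsAsFactors = FALSE)
    }

    group1 <- intersect(called, motif_peaks(sim$motifs, tf))
    if (length(group1) && length(new_peaks)) {
      ce <- motif_coenrichment(group1, new_peaks, sim$motifs, query_tf = tf)
      ce$query_tf <- tf
      coenr[[length(coenr) + 1]] <- ce
    }
  }
  gains <- if (length(gains)) do.call(rbind, gains) else NULL
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  coenr <- if (length(coenr)) do.call(rbind, coenr) else NULL
  if (!is.null(gains)) write_tsv(gains, file.path(out_dir, "gene_tf_gains.tsv"))
  if (!is.null(pairs)) write_tsv(pairs, file.path(out_dir, "tf_pairs.tsv"))
  if (!is.null(coenr)) write_tsv(coenr, file.path(out_dir,
                                                  "motif_coenrichment.tsv"))
  list(gains = gains, pairs = pairs, coenrichment = coenr)
}
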