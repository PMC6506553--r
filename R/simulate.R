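#' Configuration for the synthetic single-cell benchmark
#'
#' Describes a multi-state single-cell experiment with planted
#' co-expressed "oscillatory" modules: in the earliest state, module genes
#' share a per-cell latent factor (a uniform random phase mapped through a
#' sinusoid — a snapshot of unsynchronized oscillators), giving them both
#' high cross-cell variability and high pairwise correlation; in later
#' states the loading collapses and the genes harmonize. These module
#' genes are the planted DVC ground truth. A separate class of mean-shift
#' genes (conventional DEGs) is planted for contrast, and the remainder is
#' independent background. Counts are negative binomial with lognormal
#' library sizes.
#'
#' @param n_genes total genes (default 10000).
#' @param states named integer vector, cells per state in developmental
#'   order (default `c(NSC = 92, TAP = 27, astrocyte = 22)`, mirroring a
#'   typical sorted-population design).
#' @param modules data.frame with one row per planted module: `size`,
#'   `loading_early`, `loading_late` (log2-scale sinusoid amplitudes in
#'   the earliest vs the later states), `mean_early`, `mean_late`
#'   (log2-scale baseline expected counts at the reference library size).
#'   Default: 3 modules of 150 genes, loading 1.5 -> 0, equal baselines.
#' @param n_shift,shift_log2fc,shift_mean mean-shift gene class: count
#'   (default 300), log2 fold change applied in the later states (default
#'   -1.5), and baseline.
#' @param background_log2_mean,background_log2_sd lognormal (base-2)
#'   baseline distribution of background genes.
#' @param nb_dispersion negative binomial dispersion (1/size; default 0.1).
#' @param libsize_log_mean,libsize_log_sd natural-log parameters of the
#'   lognormal library sizes (defaults log(5e5), 0.3).
#' @param seed mandatory RNG seed.
#' @return a `dvc_sim_config` list.
#' @export
simulation_config <- function(n_genes = 10000,
                              states = c(NSC = 92, TAP = 27, astrocyte = 22),
                              modules = NULL,
                              n_shift = 300, shift_log2fc = -1.5,
                              shift_mean = 6,
                              background_log2_mean = log2(20),
                              background_log2_sd = 1.5,
                              nb_dispersion = 0.1,
                              libsize_log_mean = log(5e5),
                              libsize_log_sd = 0.3,
                              seed) {
  if (missing(seed)) .stopf("seed is mandatory")
  modules <- modules %||% data.frame(size = rep(150, 3),
                                     loading_early = 1.5, loading_late = 0,
                                     mean_early = 6, mean_late = 6)
  stopifnot(all(c("size", "loading_early", "loading_late",
                  "mean_early", "mean_late") %in% names(modules)))
  if (any(modules$size <= 0) || any(states <= 0) || n_genes <= 0)
    .stopf("sizes must be positive")
  if (sum(modules$size) + n_shift > n_genes)
    .stopf("planted genes exceed n_genes")
  if (is.null(names(states))) names(states) <- paste0("S", seq_along(states))
  structure(list(n_genes = n_genes, states = states, modules = modules,
                 n_shift = n_shift, shift_log2fc = shift_log2fc,
                 shift_mean = shift_mean,
                 background_log2_mean = background_log2_mean,
                 background_log2_sd = background_log2_sd,
                 nb_dispersion = nb_dispersion,
                 libsize_log_mean = libsize_log_mean,
                 libsize_log_sd = libsize_log_sd, seed = seed),
            class = "dvc_sim_config")
}

#' Simulate a multi-state count matrix with planted DVC structure
#'
#' See [simulation_config] for the generative model. Module genes are the
#' planted DVC truth (`truth$dvc_flag`); the latent per-module, per-cell
#' factors are returned for inspection.
#'
#' @param cfg a `dvc_sim_config`.
#' @return list with `counts` (a [dvc_counts]) and `truth` (list:
#'   `genes` data.frame with `gene, module, dvc_flag, shift_flag`;
#'   `factors` modules x cells matrix; `lib_sizes`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "dvc_sim_config"))
  set.seed(cfg$seed)
  n_cells <- sum(cfg$states)
  state_of <- factor(rep(names(cfg$states), cfg$states),
                     levels = names(cfg$states))
  cells <- paste0(as.character(state_of), "_",
                  unlist(lapply(cfg$states, function(k) sprintf("%03d", seq_len(k)))))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  early <- names(cfg$states)[1]
  is_early <- state_of == early

  mods <- cfg$modules
  n_mod <- nrow(mods)
  module_of <- rep("none", cfg$n_genes)
  idx <- 0
  mod_names <- sprintf("M%02d", seq_len(n_mod))
  for (m in seq_len(n_mod)) {
    module_of[idx + seq_len(mods$size[m])] <- mod_names[m]
    idx <- idx + mods$size[m]
  }
  shift_idx <- idx + seq_len(cfg$n_shift)
  bg_idx <- which(module_of == "none")
  bg_idx <- setdiff(bg_idx, shift_idx)

  # log2 baseline expected count at the reference library size
  base <- matrix(0, cfg$n_genes, n_cells)
  for (m in seq_len(n_mod)) {
    g <- which(module_of == mod_names[m])
    base[g, is_early] <- mods$mean_early[m]
    base[g, !is_early] <- mods$mean_late[m]
  }
  base[shift_idx, is_early] <- cfg$shift_mean
  base[shift_idx, !is_early] <- cfg$shift_mean + cfg$shift_log2fc
  bg_base <- stats::rnorm(length(bg_idx), cfg$background_log2_mean,
                          cfg$background_log2_sd)
  base[bg_idx, ] <- bg_base  # recycled column-wise: constant per gene

  # unsynchronized oscillation: uniform phase through a sinusoid
  factors <- matrix(sin(stats::runif(n_mod * n_cells, 0, 2 * pi)),
                    n_mod, n_cells, dimnames = list(mod_names, cells))
  eta <- base
  for (m in seq_len(n_mod)) {
    g <- which(module_of == mod_names[m])
    load <- ifelse(is_early, mods$loading_early[m], mods$loading_late[m])
    eta[g, ] <- eta[g, ] + rep(load * factors[m, ], each = length(g))
  }

  lib <- stats::rlnorm(n_cells, cfg$libsize_log_mean, cfg$libsize_log_sd)
  ref_lib <- exp(cfg$libsize_log_mean + cfg$libsize_log_sd^2 / 2)
  mu <- 2^eta * rep(lib / ref_lib, each = cfg$n_genes)
  counts <- if (cfg$nb_dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
           cfg$n_genes, n_cells)
  } else {
    matrix(stats::rpois(length(mu), mu), cfg$n_genes, n_cells)
  }
  dimnames(counts) <- list(genes, cells)
  truth_genes <- data.frame(
    gene = genes, module = module_of,
    dvc_flag = module_of != "none" &
      module_of %in% mod_names[mods$loading_early != mods$loading_late |
                               mods$mean_early != mods$mean_late],
    shift_flag = seq_len(cfg$n_genes) %in% shift_idx,
    stringsAsFactors = FALSE)
  list(counts = dvc_counts(counts, stats::setNames(as.character(state_of), cells),
                           state_order = names(cfg$states)),
       truth = list(genes = truth_genes, factors = factors, lib_sizes = lib))
}

#' Simulate regulatory-region tracks for the TF-enrichment route
#'
#' Lays the simulated genes out on synthetic chromosomes (widely spaced so
#' each regulatory region reaches exactly its intended gene at the default
#' 1 Mb window), emits open-chromatin (DNase-like) sites near every gene,
#' and for each transcription factor a peak track overlapping the
#' open-chromatin site of its target genes plus intergenic decoy peaks
#' that overlap no open chromatin. The designated regulator (first TF)
#' targets planted DVC genes; the remaining TFs target random genes.
#'
#' @param cfg the `dvc_sim_config` used for [simulate_counts].
#' @param truth the `truth` element returned by [simulate_counts].
#' @param n_tf number of TFs including the designated regulator
#'   (default 11).
#' @param n_targets target genes per TF (default 100).
#' @param gene_spacing distance between gene starts (default 2.5e6).
#' @param genes_per_chrom genes per synthetic chromosome (default 400).
#' @param seed RNG seed (default `cfg$seed + 1`).
#' @return list: `loci` (gene locus table), `dnase` (interval table),
#'   `peaks` (named list of per-TF interval tables), `tf_targets` (named
#'   list of ground-truth target gene sets), `regulator` (name of the
#'   designated TF).
#' @export
simulate_regulatory_tracks <- function(cfg, truth, n_tf = 11, n_targets = 100,
                                       gene_spacing = 2.5e6,
                                       genes_per_chrom = 400,
                                       seed = cfg$seed + 1) {
  stopifnot(inherits(cfg, "dvc_sim_config"))
  set.seed(seed)
  genes <- truth$genes$gene
  n <- length(genes)
  pos_in_chrom <- (seq_len(n) - 1) %% genes_per_chrom
  loci <- data.frame(gene = genes,
                     chrom = paste0("chr", (seq_len(n) - 1) %/% genes_per_chrom + 1),
                     start = pos_in_chrom * gene_spacing,
                     end = pos_in_chrom * gene_spacing + 2000,
                     strand = "+", stringsAsFactors = FALSE)
  # open chromatin at every promoter
  dnase <- data.frame(chrom = loci$chrom, start = loci$start + 300,
                      end = loci$start + 900, stringsAsFactors = FALSE)
  tfs <- sprintf("TF%02d", seq_len(n_tf))
  planted <- truth$genes$gene[truth$genes$dvc_flag]
  peaks <- list()
  tf_targets <- list()
  for (i in seq_len(n_tf)) {
    pool <- if (i == 1) planted else genes
    targets <- sort(sample(pool, min(n_targets, length(pool))))
    li <- loci[match(targets, loci$gene), ]
    peak <- data.frame(chrom = li$chrom, start = li$start + 100,
                       end = li$start + 600, stringsAsFactors = FALSE)
    # intergenic decoys, no open chromatin within reach of the intersection
    decoy_at <- loci[sample(n, min(50, n)), ]
    decoys <- data.frame(chrom = decoy_at$chrom,
                         start = decoy_at$start + round(gene_spacing / 2),
                         end = decoy_at$start + round(gene_spacing / 2) + 500,
                         stringsAsFactors = FALSE)
    peaks[[tfs[i]]] <- rbind(peak, decoys)
    tf_targets[[tfs[i]]] <- targets
  }
  list(loci = loci, dnase = dnase, peaks = peaks, tf_targets = tf_targets,
       regulator = tfs[1])
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Writes counts (TSV and MatrixMarket triplet with gene/cell annotation),
#' cell-state labels, ground-truth tables, optional regulatory tracks
#' (BED, gene loci, per-TF target GMT), and a provenance JSON echoing all
#' generation parameters.
#'
#' @param sim result of [simulate_counts].
#' @param dir output directory (created if needed).
#' @param cfg the `dvc_sim_config` used (for provenance).
#' @param tracks optional result of [simulate_regulatory_tracks].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, cfg, tracks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- sim$counts
  write_counts_tsv(cm, file.path(dir, "counts.tsv"))
  Matrix::writeMM(methods::as(methods::as(cm$counts, "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(cm$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(cm$counts), file.path(dir, "cells.tsv"))
  utils::write.table(data.frame(cell = colnames(cm$counts),
                                state = as.character(cm$states)),
                     file.path(dir, "states.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tracks)) {
    write_bed(tracks$dnase, file.path(dir, "dnase.bed"))
    for (tf in names(tracks$peaks))
      write_bed(tracks$peaks[[tf]], file.path(dir, sprintf("peaks_%s.bed", tf)))
    utils::write.table(tracks$loci, file.path(dir, "gene_loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(tracks$tf_targets, file.path(dir, "tf_targets.gmt"))
  }
  jsonlite::write_json(unclass(cfg), file.path(dir, "simulation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a count matrix as dense TSV
#' @param cm a [dvc_counts] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(cm, path) {
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an interval table as BED3
#' @param x data.frame with `chrom, start, end` (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  .check_bed(x)
  utils::write.table(x[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write named gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
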