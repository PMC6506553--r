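#' One-sided hypergeometric enrichment p-value
#'
#' Upper-tail probability `P(X >= overlap)` for `X ~ Hypergeometric`
#' (drawing `query_size` genes from a universe of `universe_size`
#' containing `target_size` marked genes), computed in log space for
#' numerical stability.
#'
#' @param overlap observed overlap.
#' @param query_size,target_size,universe_size set sizes.
#' @return the p-value.
#' @export
hypergeom_p <- function(overlap, query_size, target_size, universe_size) {
  if (any(c(overlap, query_size, target_size, universe_size) < 0))
    .stopf("sizes must be non-negative")
  if (overlap > min(query_size, target_size))
    .stopf("overlap (%d) exceeds min(query, target)", overlap)
  if (universe_size < query_size + target_size - overlap)
    .stopf("universe smaller than the union of query and target")
  if (overlap == 0) return(1)
  lp <- stats::phyper(overlap - 1, target_size, universe_size - target_size,
                      query_size, lower.tail = FALSE, log.p = TRUE)
  exp(lp)
}

#' Hypergeometric enrichment of a query gene set in a target gene set
#'
#' Both sets are intersected with the analyzed universe before testing
#' (the universe is the filtered analyzed genes, never the whole
#' annotation).
#'
#' @param query,target,universe character vectors of gene ids.
#' @param name optional label for the target set.
#' @return one-row data.frame: `set, query_size, target_size,
#'   universe_size, overlap, p, neg_log10_p`.
#' @export
hypergeom_test <- function(query, target, universe, name = NA_character_) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  target <- intersect(unique(target), universe)
  ov <- length(intersect(query, target))
  if (ov == 0) {
    p <- 1
  } else {
    lp <- stats::phyper(ov - 1, length(target),
                        length(universe) - length(target), length(query),
                        lower.tail = FALSE, log.p = TRUE)
    p <- exp(lp)
  }
  nl <- if (ov == 0) 0 else -stats::phyper(ov - 1, length(target),
                                           length(universe) - length(target),
                                           length(query), lower.tail = FALSE,
                                           log.p = TRUE) / log(10)
  data.frame(set = name, query_size = length(query),
             target_size = length(target), universe_size = length(universe),
             overlap = ov, p = p, neg_log10_p = nl,
             stringsAsFactors = FALSE)
}

#' Per-module enrichment of differential-variability calls
#'
#' For each co-expression module, counts the member genes whose
#' variability changed in the given direction (at the q threshold already
#' applied in [differential_variability]) and tests the overlap against
#' the universe-wide direction set with a one-sided hypergeometric test.
#' Up- and down-changes are counted separately.
#'
#' @param modules a `dvc_modules` assignment.
#' @param var a `dvc_variability` table.
#' @param direction `"decreased"` or `"increased"` (variability after the
#'   transition).
#' @return data.frame, one row per module: `module, module_size,
#'   direction_total, overlap, p, neg_log10_p`, sorted by p.
#' @export
module_variability_enrichment <- function(modules, var,
                                          direction = c("decreased", "increased")) {
  stopifnot(inherits(modules, "dvc_modules"), inherits(var, "dvc_variability"))
  direction <- match.arg(direction)
  universe <- intersect(modules$gene, var$gene)
  dir_set <- intersect(var$gene[var$direction == direction], universe)
  mods <- setdiff(unique(modules$module), "unassigned")
  rows <- lapply(mods, function(m) {
    members <- intersect(module_genes(modules, m), universe)
    if (length(members) == 0) {
      message(sprintf("module '%s' empty after universe intersection; skipped", m))
      return(NULL)
    }
    res <- hypergeom_test(members, dir_set, universe, name = m)
    data.frame(module = m, module_size = length(members),
               direction_total = length(dir_set), overlap = res$overlap,
               p = res$p, neg_log10_p = res$neg_log10_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$module), ]
  rownames(out) <- NULL
  attr(out, "direction") <- direction
  out
}

# --- genomic intervals (BED convention: 0-based, half-open) ---------------

.check_bed <- function(x, what = "intervals") {
  if (!all(c("chrom", "start", "end") %in% names(x)))
    .stopf("%s need columns chrom, start, end", what)
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    .stopf("malformed interval in %s at line %d (start %s, end %s)",
           what, bad[1], x$start[bad[1]], x$end[bad[1]])
  x
}

.bed_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
}

.granges_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a BED3+ file into an interval table
#'
#' @param path BED file (0-based, half-open).
#' @return data.frame with `chrom, start, end` (plus `name` if present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- .granges_to_bed(gr)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  .check_bed(out, path)
}

#' Intersect two interval tracks
#'
#' Set intersection of the genomic regions covered by the two tracks
#' (e.g. ChIP-seq peaks with DNase open-chromatin sites), under half-open
#' semantics: intervals sharing only a boundary do not overlap. Output is
#' sorted by (chrom, start) and merged per chromosome.
#'
#' @param a,b interval data.frames with `chrom, start, end` (0-based,
#'   half-open).
#' @return interval data.frame of the intersection segments.
#' @export
intersect_intervals <- function(a, b) {
  .check_bed(a, "track a"); .check_bed(b, "track b")
  ga <- .bed_to_granges(a); gb <- .bed_to_granges(b)
  lev <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lev
  GenomeInfoDb::seqlevels(gb) <- lev
  gr <- GenomicRanges::intersect(ga, gb)
  out <- .granges_to_bed(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes within a window of a set of regions
#'
#' A gene is included iff the minimum distance between its locus span and
#' any region is at most `window` bases (0 if overlapping; inclusive at
#' exactly `window`). Strand is ignored; distance is measured from the
#' gene span, not the TSS.
#'
#' @param regions interval data.frame (`chrom, start, end`).
#' @param loci gene locus table: `gene, chrom, start, end` (0-based,
#'   half-open), e.g. from [read_gene_loci].
#' @param window maximum distance in bases (default 1e6).
#' @return character vector of gene ids (a gene set).
#' @export
genes_near_regions <- function(regions, loci, window = 1e6) {
  .check_bed(regions, "regions")
  .check_bed(loci, "loci")
  missing_chr <- setdiff(unique(regions$chrom), unique(loci$chrom))
  if (length(missing_chr))
    .warnf("chromosomes present in regions but absent in loci: %s",
           paste(missing_chr, collapse = ", "))
  gr_r <- .bed_to_granges(regions)
  gr_l <- .bed_to_granges(loci)
  # seqlevel mismatches are already reported above in genomic terms
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(gr_l, gr_r, ignore.strand = TRUE))
  keep <- S4Vectors::queryHits(hits)[S4Vectors::mcols(hits)$distance <= window]
  sort(unique(loci$gene[keep]))
}

#' Read gene loci from BED6 or GFF/GTF
#'
#' @param path input file.
#' @param format `"bed"` or `"gff"` (auto from extension by default).
#' @param feature for GFF input, which feature type to keep (default
#'   `"gene"`).
#' @param attribute for GFF input, which attribute holds the gene id
#'   (default `"gene_id"`).
#' @return data.frame `gene, chrom, start, end, strand` (0-based,
#'   half-open). Duplicate gene ids are resolved to the widest span, with
#'   a message.
#' @export
read_gene_loci <- function(path, format = NULL, feature = "gene",
                           attribute = "gene_id") {
  format <- format %||%
    (if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff")
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- gr$name
  } else {
    gr <- rtracklayer::import(path)
    if (!is.null(gr$type) && any(gr$type == feature)) gr <- gr[gr$type == feature]
    ids <- S4Vectors::mcols(gr)[[attribute]]
  }
  if (is.null(ids)) .stopf("no gene identifiers found in %s", path)
  out <- data.frame(gene = as.character(ids),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) {
    message("duplicate gene loci resolved to the widest span")
    out <- out[order(out$gene, -(out$end - out$start)), ]
    out <- out[!duplicated(out$gene), ]
  }
  rownames(out) <- NULL
  .check_bed(out, path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, members per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Rank transcription-factor target sets by enrichment in DVC genes
#'
#' One one-sided hypergeometric test per transcription factor, against the
#' analyzed-gene universe; results sorted by ascending p. Raw p-values are
#' the ranking statistic (matching the original analysis); a BH-adjusted
#' column `bh_q` is additionally provided as an extension and is not used
#' for ranking.
#'
#' @param dvc_genes character vector of query (DVC) genes.
#' @param tf_sets named list of target gene sets, e.g. built with
#'   [intersect_intervals] + [genes_near_regions] per TF.
#' @param universe analyzed gene universe.
#' @return data.frame, one row per TF, sorted ascending by p, with columns
#'   of [hypergeom_test] plus `bh_q` and `rank`.
#' @export
tf_target_enrichment <- function(dvc_genes, tf_sets, universe) {
  rows <- lapply(names(tf_sets), function(tf)
    hypergeom_test(dvc_genes, tf_sets[[tf]], universe, name = tf))
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
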