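#' Pearson correlation of all gene pairs within one state
#'
#' @param em a `dvc_expr` object (either scale; Pearson correlation is
#'   identical on log2-CPM and its per-state z-scored view).
#' @param state state label; needs at least 3 cells.
#' @return An object of class `dvc_cor`: list with `r` (symmetric genes x
#'   genes matrix, unit diagonal), `state`, and `constant_genes` (genes
#'   with zero variance in this state; their correlations are set to 0).
#' @export
pairwise_pcc <- function(em, state) {
  stopifnot(inherits(em, "dvc_expr"))
  if (!state %in% levels(em$states)) .stopf("unknown state '%s'", state)
  x <- em$values[, em$states == state, drop = FALSE]
  if (ncol(x) < 3) .stopf("state '%s' has fewer than 3 cells", state)
  sds <- .row_sds(x)
  const <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(stats::cor(t(x)))
  if (any(const)) {
    r[const, ] <- 0
    r[, const] <- 0
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  structure(list(r = r, state = state,
                 constant_genes = rownames(x)[const]),
            class = "dvc_cor")
}

#' @export
print.dvc_cor <- function(x, ...) {
  cat(sprintf("dvc_cor: %d genes, state '%s' (%d constant genes)\n",
              nrow(x$r), x$state, length(x$constant_genes)))
  invisible(x)
}

#' Hierarchical co-expression tree
#'
#' Agglomerative clustering of genes on the dissimilarity `d = 1 - r`
#' (signed: anti-correlated genes are maximally distant) using Ward's
#' minimum-variance update, i.e. the Lance-Williams recurrence applied
#' directly to the precomputed dissimilarity.
#'
#' @param corr a `dvc_cor` object.
#' @param linkage currently `"ward"`.
#' @param dissimilarity `"signed"` (1 - r, default) or `"unsigned"`
#'   (1 - |r|).
#' @return an [stats::hclust] tree over the genes, with the dissimilarity
#'   convention recorded in `attr(, "dissimilarity")`.
#' @export
cluster_tree <- function(corr, linkage = c("ward"),
                         dissimilarity = c("signed", "unsigned")) {
  stopifnot(inherits(corr, "dvc_cor"))
  linkage <- match.arg(linkage)
  dissimilarity <- match.arg(dissimilarity)
  d <- if (dissimilarity == "signed") 1 - corr$r else 1 - abs(corr$r)
  h <- stats::hclust(stats::as.dist(d), method = "ward.D")
  attr(h, "dissimilarity") <- dissimilarity
  h
}

#' Export a clustering tree as Newick text
#'
#' @param tree an [stats::hclust] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

# leaves under node i of an hclust merge matrix (i indexes merges)
.branch_leaves <- function(merge, node) {
  stack <- node
  leaves <- integer(0)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    kids <- merge[top, ]
    for (k in kids) {
      if (k < 0) leaves <- c(leaves, -k) else stack <- c(stack, k)
    }
  }
  leaves
}

# mean within-branch dissimilarity, deterministically subsampled for
# large branches so evaluation cost stays bounded
.branch_scatter <- function(d, leaves, max_leaves = 200L) {
  if (length(leaves) > max_leaves) {
    idx <- leaves[round(seq(1, length(leaves), length.out = max_leaves))]
  } else idx <- leaves
  sub <- d[idx, idx]
  sum(sub) / (length(idx) * (length(idx) - 1))
}

#' Cut a co-expression tree into modules
#'
#' Hybrid mode (default) performs adaptive branch detection on the
#' dendrogram: branches are split top-down where the merge-height gap is
#' large, a branch is accepted as a module when its mean within-branch
#' dissimilarity is small relative to the matrix-wide mean (threshold set
#' by `deep_split`), and leftover genes are then assigned, PAM-like, to
#' the module with the highest mean correlation provided that correlation
#' exceeds `pam_frac` times the module's own mean intra-correlation.
#' Branches below `min_size` are dissolved to `"unassigned"`. Height mode
#' is a fixed-height cut with the same size filter. Module labels are
#' color names in decreasing size order (`"black"` = largest).
#'
#' @param tree [stats::hclust] tree from [cluster_tree].
#' @param corr the `dvc_cor` the tree was built from.
#' @param min_size minimum module size (default 100).
#' @param mode `"hybrid"` or `"height"`.
#' @param deep_split integer 0-4; larger values accept looser branches
#'   (default 2).
#' @param cut_height height for `mode = "height"`; default 0.99 of the top
#'   merge height.
#' @param pam_frac fraction of a module's mean intra-correlation a leftover
#'   gene must reach to be assigned in the PAM-like stage (default 0.7);
#'   `NA` disables the stage.
#' @param min_gap normalized merge-height gap above which a tight branch is
#'   still split into its children (default 0.1).
#' @return An object of class `dvc_modules`: data.frame with columns
#'   `gene` and `module` (color label or `"unassigned"`), with `min_size`
#'   and `source_state` attributes.
#' @export
cut_tree_dynamic <- function(tree, corr, min_size = 100,
                             mode = c("hybrid", "height"), deep_split = 2,
                             cut_height = NULL, pam_frac = 0.7,
                             min_gap = 0.1) {
  stopifnot(inherits(tree, "hclust"), inherits(corr, "dvc_cor"))
  mode <- match.arg(mode)
  genes <- tree$labels
  if (!identical(sort(genes), sort(rownames(corr$r))))
    .stopf("tree and correlation matrix cover different genes")
  n <- length(genes)
  labels <- rep("unassigned", n)
  names(labels) <- genes
  if (min_size > n) {
    .warnf("min_size (%d) exceeds the number of genes (%d); everything unassigned",
           min_size, n)
    return(.make_modules(labels, min_size, corr$state))
  }
  d <- if (attr(tree, "dissimilarity") %||% "signed" == "signed") 1 - corr$r else 1 - abs(corr$r)
  d <- d[genes, genes]

  if (mode == "height") {
    cut_height <- cut_height %||% (0.99 * max(tree$height))
    cl <- stats::cutree(tree, h = cut_height)
    groups <- split(names(cl), cl)
  } else {
    groups <- .hybrid_branches(tree, d, min_size, deep_split, min_gap)
  }
  groups <- Filter(function(g) length(g) >= min_size, groups)
  # deterministic ordering: size desc, ties by first gene position in input
  if (length(groups)) {
    first_pos <- vapply(groups, function(g) min(match(g, genes)), numeric(1))
    ord <- order(-vapply(groups, length, integer(1)), first_pos)
    groups <- groups[ord]
    cols <- .module_palette(length(groups))
    for (i in seq_along(groups)) labels[groups[[i]]] <- cols[i]
    if (mode == "hybrid" && !is.na(pam_frac))
      labels <- .pam_assign(labels, corr$r, pam_frac)
  }
  .make_modules(labels, min_size, corr$state)
}

# top-down branch detection (see cut_tree_dynamic)
.hybrid_branches <- function(tree, d, min_size, deep_split, min_gap) {
  merge <- tree$merge
  heights <- tree$height
  n <- length(tree$labels)
  sizes <- numeric(nrow(merge))
  for (i in seq_len(nrow(merge))) {
    sizes[i] <- sum(ifelse(merge[i, ] < 0, 1, sizes[pmax(merge[i, ], 1)]))
  }
  node_size <- function(k) if (k < 0) 1L else sizes[k]
  node_height <- function(k) if (k < 0) 0 else heights[k]
  ref_height <- stats::quantile(heights, 0.05, names = FALSE)
  scale_h <- max(0.99 * max(heights) - ref_height, .Machine$double.eps)
  # tightness threshold: fraction of the matrix-wide mean dissimilarity
  d_bar <- sum(d) / (nrow(d) * (nrow(d) - 1))  # diagonal is 0
  scatter_max <- c(0.50, 0.60, 0.70, 0.80, 0.875)[deep_split + 1] * d_bar

  tight <- function(node) {
    leaves <- .branch_leaves(merge, node)
    .branch_scatter(d, leaves, 200L) <= scatter_max
  }
  modules <- list()
  emit <- function(node) {
    modules[[length(modules) + 1]] <<- tree$labels[.branch_leaves(merge, node)]
  }
  stack <- nrow(merge)  # root
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (node < 0 || node_size(node) < min_size) next
    kids <- merge[node, ]
    s1 <- node_size(kids[1]); s2 <- node_size(kids[2])
    if (s1 >= min_size && s2 >= min_size) {
      gap <- (heights[node] - max(node_height(kids[1]), node_height(kids[2]))) / scale_h
      if (gap <= min_gap && tight(node)) emit(node)
      else stack <- c(stack, kids[1], kids[2])
    } else {
      if (tight(node)) emit(node)
      else {
        big <- kids[which.max(c(s1, s2))]
        if (node_size(big) >= min_size) stack <- c(stack, big)
      }
    }
  }
  modules
}

# PAM-like assignment of leftover genes to the closest module
.pam_assign <- function(labels, r, pam_frac) {
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) return(labels)
  un <- names(labels)[labels == "unassigned"]
  if (!length(un)) return(labels)
  mean_to <- sapply(mods, function(m) {
    members <- names(labels)[labels == m]
    rowMeans(r[un, members, drop = FALSE])
  })
  mean_to <- matrix(mean_to, nrow = length(un),
                    dimnames = list(un, mods))
  thresh <- vapply(mods, function(m) {
    members <- names(labels)[labels == m]
    sub <- r[members, members, drop = FALSE]
    pam_frac * (sum(sub) - length(members)) /
      (length(members) * (length(members) - 1))
  }, numeric(1))
  best <- max.col(mean_to, ties.method = "first")
  ok <- mean_to[cbind(seq_along(un), best)] >= thresh[best]
  labels[un[ok]] <- mods[best[ok]]
  labels
}

.module_palette <- function(k) {
  base <- c("black", "magenta", "red", "purple", "blue", "green", "yellow",
            "brown", "pink", "turquoise", "cyan", "orange", "salmon",
            "lightgreen", "midnightblue", "lightcyan", "grey60", "tan",
            "darkred", "darkgreen")
  if (k <= length(base)) base[seq_len(k)]
  else c(base, sprintf("module%02d", seq_len(k - length(base))))
}

.make_modules <- function(labels, min_size, state) {
  out <- data.frame(gene = names(labels), module = unname(labels),
                    stringsAsFactors = FALSE)
  class(out) <- c("dvc_modules", "data.frame")
  attr(out, "min_size") <- min_size
  attr(out, "source_state") <- state
  out
}

#' @export
print.dvc_modules <- function(x, ...) {
  tab <- sort(table(x$module[x$module != "unassigned"]), decreasing = TRUE)
  cat(sprintf("dvc_modules: %d genes, %d modules (state '%s', min size %d)\n",
              nrow(x), length(tab), attr(x, "source_state"), attr(x, "min_size")))
  if (length(tab))
    cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  cat(sprintf("  unassigned: %d\n", sum(x$module == "unassigned")))
  invisible(x)
}

#' Genes of one module
#' @param modules a `dvc_modules` object.
#' @param module module label.
#' @return character vector of gene ids.
#' @export
module_genes <- function(modules, module) {
  modules$gene[modules$module == module]
}
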