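#' Thresholded co-expression network
#'
#' Builds an undirected network over a gene subset with an edge wherever
#' the pairwise Pearson correlation is at least `threshold` (inclusive;
#' edge weight = correlation). Node attributes (e.g. STS, module, gene-set
#' membership flags) can be attached from a per-gene table.
#'
#' @param corr a `dvc_cor` object (typically the earliest state, where
#'   co-regulation is asserted).
#' @param genes optional subset of genes; default all genes in `corr`.
#' @param threshold minimum correlation for an edge (default 0.7).
#' @param node_attrs optional data.frame with a `gene` column; remaining
#'   columns become node attributes.
#' @return an [igraph] graph with edge attribute `weight` and graph
#'   attribute `threshold`.
#' @export
build_network <- function(corr, genes = NULL, threshold = 0.7,
                          node_attrs = NULL) {
  stopifnot(inherits(corr, "dvc_cor"))
  genes <- genes %||% rownames(corr$r)
  missing <- setdiff(genes, rownames(corr$r))
  if (length(missing))
    .stopf("genes not in the correlation matrix: %s",
           paste(utils::head(missing, 5), collapse = ", "))
  if (length(genes) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    r <- corr$r[genes, genes, drop = FALSE]
    adj <- (r >= threshold) * r
    diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
  }
  if (!is.null(node_attrs) && igraph::vcount(g) > 0) {
    idx <- match(igraph::V(g)$name, node_attrs$gene)
    for (col in setdiff(names(node_attrs), "gene")) {
      igraph::vertex_attr(g, col) <- node_attrs[[col]][idx]
    }
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Neighborhood subnetwork around a seed gene
#'
#' Induced subgraph on all nodes within `radius` hops of `seed`
#' (`radius = Inf` gives the connected component).
#'
#' @param net an [igraph] network from [build_network].
#' @param seed gene id present in the network.
#' @param radius number of hops (default 1).
#' @return an [igraph] subgraph.
#' @export
ego_subnetwork <- function(net, seed, radius = 1) {
  if (!seed %in% igraph::V(net)$name) .stopf("seed gene '%s' not in network", seed)
  order <- if (is.infinite(radius)) igraph::vcount(net) else radius
  igraph::make_ego_graph(net, order = order, nodes = seed)[[1]]
}

#' Export a co-expression network
#'
#' GraphML keeps node and edge attributes in one file; SIF writes the
#' Cytoscape simple-interaction format (`gene pp gene`) plus a separate
#' node-attribute TSV next to it.
#'
#' @param net an [igraph] network.
#' @param path output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net)
    lines <- if (nrow(el)) sprintf("%s\tpp\t%s", el[, 1], el[, 2]) else character(0)
    isolated <- setdiff(igraph::V(net)$name,
                        unique(c(el[, 1], el[, 2])))
    writeLines(c(lines, isolated), path)
    attrs <- as.data.frame(igraph::vertex_attr(net), stringsAsFactors = FALSE)
    if (nrow(attrs)) {
      names(attrs)[names(attrs) == "name"] <- "gene"
      utils::write.table(attrs, paste0(path, ".nodes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Re-import an exported network
#'
#' @param path file written by [export_network].
#' @param format `"graphml"` or `"sif"`.
#' @return an [igraph] graph.
#' @export
import_network <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  edges <- do.call(rbind, lapply(parts[lengths(parts) >= 3],
                                 function(p) c(p[1], p[3])))
  singles <- unlist(lapply(parts[lengths(parts) == 1], identity))
  g <- igraph::graph_from_edgelist(if (is.null(edges)) matrix(character(0), 0, 2) else edges,
                                   directed = FALSE)
  g + igraph::vertices(setdiff(singles, igraph::V(g)$name))
}
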