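#' Assemble a pipeline run configuration
#'
#' Collects input locations, the state ordering (earliest first; modules
#' are always detected in the earliest state), the state pairs to compare,
#' and every stage-level tuning key with its default. Accepts either file
#' paths (`counts`, `states_file`, ...) or an in-memory [dvc_counts]
#' object.
#'
#' @param counts path to a counts file or a [dvc_counts] object.
#' @param format `"tsv"` or `"mtx"` (when `counts` is a path).
#' @param states_file,genes_file,cells_file companion files for path input.
#' @param state_order state labels, earliest first (default: observed
#'   order).
#' @param pairs list of 2-element character vectors `(early, late)`;
#'   default: earliest vs every other state.
#' @param outdir output directory.
#' @param seed integer seed recorded in provenance and used for any
#'   stochastic step.
#' @param filter.min_mean,filter.rule gene filter (see
#'   [filter_low_expression]).
#' @param norm.pseudo,norm.trim_m,norm.trim_a normalization (see
#'   [tmm_factors], [cpm_log2]).
#' @param pca.n_pc,pca.mad_k,pca.remove cell outlier handling (see
#'   [pca_outlier_cells]); `pca.remove = TRUE` drops flagged cells.
#' @param coexpr.min_module_size,coexpr.cut_mode,coexpr.deep_split,coexpr.dissimilarity
#'   module detection (see [cut_tree_dynamic]).
#' @param dvc.alpha,dvc.levene_center,dvc.combiner,dvc.top_n,dvc.cap
#'   DVC scoring (see [differential_variability], [compute_sts],
#'   [select_dvc_genes]).
#' @param net.threshold,net.state network stage (see [build_network]);
#'   `net.state = NULL` uses the earliest state.
#' @return a `dvc_run_config` list.
#' @export
run_config <- function(counts, format = "tsv", states_file = NULL,
                       genes_file = NULL, cells_file = NULL,
                       state_order = NULL, pairs = NULL,
                       outdir = tempfile("dvcscan_run_"), seed = 1,
                       filter.min_mean = 2, filter.rule = "mean",
                       norm.pseudo = 1, norm.trim_m = 0.30, norm.trim_a = 0.05,
                       pca.n_pc = 2, pca.mad_k = 5, pca.remove = TRUE,
                       coexpr.min_module_size = 100, coexpr.cut_mode = "hybrid",
                       coexpr.deep_split = 2, coexpr.dissimilarity = "signed",
                       dvc.alpha = 0.001, dvc.levene_center = "mean",
                       dvc.combiner = "rank_sum", dvc.top_n = 500, dvc.cap = 20,
                       net.threshold = 0.7, net.state = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "dvc_run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Keys are the argument names of [run_config] (dots allowed in YAML).
#'
#' @param path YAML file.
#' @return a `dvc_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$pairs)) vals$pairs <- lapply(vals$pairs, as.character)
  do.call(run_config, vals)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full DVC analysis pipeline
#'
#' Executes preprocess -> co-expression module detection (earliest state)
#' -> differential variability / correlation and STS ranking (each state
#' pair) -> module-level variability enrichment -> thresholded network
#' export, writing every table plus a machine-readable provenance JSON to
#' `cfg$outdir`. Any stage error aborts with the stage name.
#'
#' @param cfg a `dvc_run_config` from [run_config] or [read_run_config].
#' @return invisibly, a list with the in-memory results: `counts`
#'   (filtered), `expr`, `modules`, `sts` (named list per pair),
#'   `dvc_genes` (named list), `enrichment` (named list), `network`,
#'   `outputs` (paths), `provenance`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "dvc_run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  prov <- list(package = "dvcscan",
               version = as.character(utils::packageVersion("dvcscan")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               seed = cfg$seed,
               config = lapply(unclass(cfg), function(x)
                 if (inherits(x, "dvc_counts")) "<in-memory counts>" else x))
  set.seed(cfg$seed)
  outputs <- character(0)

  cm <- stage("read", {
    if (inherits(cfg$counts, "dvc_counts")) cfg$counts
    else read_counts(cfg$counts, format = cfg$format,
                     states_file = cfg$states_file, genes_file = cfg$genes_file,
                     cells_file = cfg$cells_file, state_order = cfg$state_order)
  })
  prov$n_genes_input <- nrow(cm$counts)
  prov$n_cells_input <- ncol(cm$counts)
  message(sprintf("input: %d genes x %d cells", nrow(cm$counts), ncol(cm$counts)))

  cm <- stage("filter", filter_low_expression(cm, cfg$filter.min_mean,
                                              cfg$filter.rule))
  prov$n_genes_filtered <- nrow(cm$counts)

  em <- stage("normalize", {
    f <- tmm_factors(cm, trim_m = cfg$norm.trim_m, trim_a = cfg$norm.trim_a)
    cpm_log2(cm, factors = f, pseudo = cfg$norm.pseudo)
  })
  outputs <- c(outputs, .write_tsv(
    data.frame(cell = colnames(cm$counts), state = as.character(cm$states),
               lib_size = em$lib_sizes, tmm_factor = em$norm_factors),
    file.path(cfg$outdir, "normalization.tsv")))

  flagged <- stage("pca_outliers",
                   pca_outlier_cells(em, cfg$pca.n_pc, cfg$pca.mad_k))
  prov$outlier_cells <- as.character(flagged)
  if (cfg$pca.remove && length(flagged)) {
    message(sprintf("removing %d outlier cells: %s", length(flagged),
                    paste(flagged, collapse = ", ")))
    cm <- stage("drop_outliers", drop_cells(cm, flagged))
    em <- stage("renormalize", {
      f <- tmm_factors(cm, trim_m = cfg$norm.trim_m, trim_a = cfg$norm.trim_a)
      cpm_log2(cm, factors = f, pseudo = cfg$norm.pseudo)
    })
  }
  prov$n_cells_analyzed <- ncol(cm$counts)
  outputs <- c(outputs, {
    write_counts_tsv(cm, file.path(cfg$outdir, "filtered_counts.tsv"))
    file.path(cfg$outdir, "filtered_counts.tsv")
  })
  outputs <- c(outputs, .write_tsv(
    data.frame(gene = rownames(em$values), round(em$values, 6),
               check.names = FALSE),
    file.path(cfg$outdir, "log2cpm.tsv")))

  early <- levels(cm$states)[1]
  zs <- stage("zscore", zscore_per_state(em))
  corr_early <- stage("coexpression", pairwise_pcc(zs, early))
  tree <- stage("coexpression",
                cluster_tree(corr_early, dissimilarity = cfg$coexpr.dissimilarity))
  modules <- stage("coexpression",
                   cut_tree_dynamic(tree, corr_early,
                                    min_size = cfg$coexpr.min_module_size,
                                    mode = cfg$coexpr.cut_mode,
                                    deep_split = cfg$coexpr.deep_split))
  prov$n_modules <- length(setdiff(unique(modules$module), "unassigned"))
  message(sprintf("coexpression: %d modules in state '%s'", prov$n_modules, early))
  outputs <- c(outputs,
               .write_tsv(as.data.frame(modules), file.path(cfg$outdir, "modules.tsv")),
               write_tree_newick(tree, file.path(cfg$outdir, "dendrogram.nwk")))

  pairs <- cfg$pairs %||% lapply(levels(cm$states)[-1], function(s) c(early, s))
  bad <- vapply(pairs, function(p) !all(p %in% levels(cm$states)), logical(1))
  if (any(bad)) .stopf("pipeline stage 'dvc' failed: pair references unknown state")
  sts_list <- list(); dvc_list <- list(); enr_list <- list()
  for (p in pairs) {
    key <- paste(p, collapse = "_vs_")
    var <- stage("dvc", differential_variability(em, p[1], p[2],
                                                 alpha = cfg$dvc.alpha,
                                                 center = cfg$dvc.levene_center,
                                                 cap = cfg$dvc.cap))
    cc <- stage("dvc", differential_correlation(em, modules, p[1], p[2]))
    sts <- stage("dvc", compute_sts(var, cc, combiner = cfg$dvc.combiner))
    sts <- stage("dvc", select_dvc_genes(sts, top_n = min(cfg$dvc.top_n, nrow(sts))))
    sts_list[[key]] <- sts
    dvc_list[[key]] <- attr(sts, "dvc_genes")
    outputs <- c(outputs,
                 .write_tsv(as.data.frame(sts), file.path(cfg$outdir, sprintf("sts_%s.tsv", key))))
    writeLines(dvc_list[[key]], file.path(cfg$outdir, sprintf("dvc_genes_%s.txt", key)))
    outputs <- c(outputs, file.path(cfg$outdir, sprintf("dvc_genes_%s.txt", key)))
    enr <- stage("enrichment", rbind(
      cbind(direction = "decreased",
            module_variability_enrichment(modules, var, "decreased")),
      cbind(direction = "increased",
            module_variability_enrichment(modules, var, "increased"))))
    enr_list[[key]] <- enr
    outputs <- c(outputs,
                 .write_tsv(enr, file.path(cfg$outdir, sprintf("module_enrichment_%s.tsv", key))))
  }

  net_state <- cfg$net.state %||% early
  net_corr <- if (identical(net_state, early)) corr_early
              else stage("network", pairwise_pcc(zs, net_state))
  net_genes <- modules$gene[modules$module != "unassigned"]
  first_sts <- sts_list[[1]]
  attrs <- data.frame(gene = first_sts$gene, sts = first_sts$sts,
                      module = first_sts$module, stringsAsFactors = FALSE)
  net <- stage("network", build_network(net_corr, genes = net_genes,
                                        threshold = cfg$net.threshold,
                                        node_attrs = attrs))
  outputs <- c(outputs,
               export_network(net, file.path(cfg$outdir, "network.graphml"), "graphml"))

  prov$outputs <- basename(outputs)
  jsonlite::write_json(prov, file.path(cfg$outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(counts = cm, expr = em, modules = modules, sts = sts_list,
                 dvc_genes = dvc_list, enrichment = enr_list, network = net,
                 outputs = outputs, provenance = prov))
}

#' Overlap significance of two DVC rankings
#'
#' Overlap of the top-`top_n` gene sets of two STS tables (e.g. from two
#' independent datasets), with a one-sided hypergeometric p on the shared
#' gene universe.
#'
#' @param sts_a,sts_b `dvc_sts` tables.
#' @param top_n how many top-ranked genes from each table (either one
#'   number or a length-2 vector).
#' @param universe gene universe for the test; default the genes shared by
#'   the two tables. Pass the full analyzed-gene universe when the tables
#'   only score a subset (e.g. module-assigned genes).
#' @return one-row data.frame as [hypergeom_test].
#' @export
compare_dvc_overlap <- function(sts_a, sts_b, top_n, universe = NULL) {
  stopifnot(inherits(sts_a, "dvc_sts"), inherits(sts_b, "dvc_sts"))
  top_n <- rep(top_n, length.out = 2)
  shared <- intersect(sts_a$gene, sts_b$gene)
  if (length(shared) == 0) .stopf("the two tables share no genes")
  universe <- universe %||% shared
  ta <- intersect(sts_a$gene[sts_a$rank <= top_n[1]], universe)
  tb <- intersect(sts_b$gene[sts_b$rank <= top_n[2]], universe)
  hypergeom_test(ta, tb, universe, name = "dvc_overlap")
}
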