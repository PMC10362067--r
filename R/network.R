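#' Build the gene graph from significant gene-variant pairs
#'
#' Genes are nodes; for every variant significantly associated with k >= 2
#' genes, each of the C(k, 2) gene pairs gains edge weight 1, so an edge
#' weight counts the variants shared by two genes. A per-variant gene-count
#' histogram is also emitted.
#'
#' @param pairs data.frame with columns `gene` and `variant` (the
#'   significant pairs of a scan).
#' @return An object of class `gene_graph`: list with `edges` (gene_a,
#'   gene_b, weight; gene_a < gene_b), `nodes`, and `variant_gene_counts`.
#' @export
build_gene_graph <- function(pairs) {
  dt <- unique(data.table::as.data.table(pairs)[, .(gene, variant)])
  per_var <- dt[, .(genes = list(sort(gene)), k = .N), by = variant]
  shared <- per_var[k >= 2]
  edge_list <- if (nrow(shared)) shared[, {
    g <- genes[[1]]
    cmb <- utils::combn(g, 2)
    .(gene_a = cmb[1, ], gene_b = cmb[2, ])
  }, by = variant] else data.table::data.table()
  edges <- if (nrow(edge_list)) {
    edge_list[, .(weight = .N), by = .(gene_a, gene_b)][order(gene_a, gene_b)]
  } else {
    data.table::data.table(gene_a = character(), gene_b = character(),
                           weight = integer())
  }
  structure(list(edges = edges, nodes = sort(unique(dt$gene)),
                 variant_gene_counts = per_var[, .(variant, n_genes = k)]),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph> %d nodes, %d edges (weights %s)\n",
              length(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) paste(range(x$edges$weight), collapse = "-")
              else "-"))
  invisible(x)
}

#' Enumerate maximal cliques of genes sharing associated variants
#'
#' Prunes edges with weight below `min_weight` (the default 3 encodes
#' "edge weight > 2", i.e. more than two shared variants) and returns the
#' maximal cliques of the pruned graph. Cliques are sorted by decreasing
#' size then lexicographically by member genes; singletons are suppressed,
#' pairs are kept.
#'
#' @param graph a `gene_graph`.
#' @param min_weight minimum retained edge weight (default 3).
#' @return List with `cliques` (list of sorted gene vectors) and `table`
#'   (clique id, size, genes, min/max edge weight within the clique).
#' @export
find_gene_cliques <- function(graph, min_weight = 3) {
  ed <- graph$edges[weight >= min_weight]
  if (!nrow(ed)) {
    return(list(cliques = list(),
                table = data.table::data.table(clique = integer(),
                                               size = integer(),
                                               genes = character(),
                                               min_weight = integer(),
                                               max_weight = integer())))
  }
  g <- igraph::graph_from_data_frame(ed[, .(gene_a, gene_b, weight)],
                                     directed = FALSE)
  cl <- igraph::max_cliques(g, min = 2)
  cl <- lapply(cl, function(v) sort(names(v)))
  ord <- order(-lengths(cl), vapply(cl, paste, "", collapse = "|"))
  cl <- cl[ord]
  wt <- vapply(cl, function(genes) {
    sub <- ed[gene_a %in% genes & gene_b %in% genes]
    c(min(sub$weight), max(sub$weight))
  }, numeric(2))
  list(cliques = cl,
       table = data.table::data.table(
         clique = seq_along(cl), size = lengths(cl),
         genes = vapply(cl, paste, "", collapse = ","),
         min_weight = wt[1, ], max_weight = wt[2, ]))
}
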