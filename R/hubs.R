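#' Build an interaction graph from an edge list
#'
#' Canonicalizes a weighted undirected edge list: self-loops are dropped and
#' duplicate undirected edges collapsed (keeping the maximum weight), with a
#' warning in either case.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` and optionally
#'   `weight` (confidence in \[0, 1\]; defaults to 1).
#' @return Object of class `interaction_graph`: `edges`, `nodes`, and the
#'   per-node `degree` and `weighted_degree` tables.
#' @export
interaction_graph <- function(edges) {
  if (!all(c("gene_a", "gene_b") %in% names(edges)))
    stop("`edges` needs columns gene_a and gene_b")
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (nrow(edges) == 0)
    return(structure(list(edges = data.frame(gene_a = character(),
                                             gene_b = character(),
                                             weight = numeric()),
                          nodes = character(),
                          degree = integer(), weighted_degree = numeric()),
                     class = "interaction_graph"))
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate undirected edge(s) collapsed")
    keep <- !duplicated(key)
    w <- tapply(edges$weight, key, max)
    edges <- data.frame(gene_a = a[keep], gene_b = b[keep],
                        weight = as.numeric(w[key[keep]]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene_a = a, gene_b = b, weight = edges$weight,
                        stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  ends <- c(edges$gene_a, edges$gene_b)
  degree <- table(factor(ends, levels = nodes))
  wdeg <- tapply(c(edges$weight, edges$weight), factor(ends, levels = nodes),
                 sum, default = 0)
  structure(list(edges = edges, nodes = nodes,
                 degree = stats::setNames(as.integer(degree), nodes),
                 weighted_degree = stats::setNames(as.numeric(wdeg), nodes)),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a TSV edge list (gene_a, gene_b, weight)
#'
#' @param path TSV file with a header row.
#' @return an [interaction_graph()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  interaction_graph(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Hub ranking by interaction degree
#'
#' Ranks nodes (optionally restricted to one module's genes) by the number of
#' interaction partners — the degree-centrality definition of hub genes —
#' with deterministic tie-breaking by weighted degree, then gene id. The
#' study convention keeps the top 50.
#'
#' @param graph an [interaction_graph()].
#' @param top_n how many hubs to return (default 50).
#' @param module_filter optional character vector of gene ids (e.g. one
#'   module's members) to restrict the ranking to.
#' @return data.frame: rank, gene_id, degree, weighted_degree.
#' @export
degree_rank <- function(graph, top_n = 50, module_filter = NULL) {
  stopifnot(inherits(graph, "interaction_graph"))
  nodes <- graph$nodes
  if (!is.null(module_filter)) nodes <- intersect(nodes, module_filter)
  if (!length(nodes))
    return(data.frame(rank = integer(), gene_id = character(),
                      degree = integer(), weighted_degree = numeric(),
                      stringsAsFactors = FALSE))
  deg <- graph$degree[nodes]
  wdeg <- graph$weighted_degree[nodes]
  ord <- order(-deg, -wdeg, nodes)[seq_len(min(top_n, length(nodes)))]
  data.frame(rank = seq_along(ord), gene_id = nodes[ord],
             degree = as.integer(deg[ord]),
             weighted_degree = as.numeric(wdeg[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intramodular connectivity
#'
#' kIM(i) = sum of gene i's co-expression adjacency to the genes sharing its
#' module label. Grey (unassigned) genes get their connectivity among grey
#' peers, flagged `in_module = FALSE`.
#'
#' @param adjacency symmetric adjacency from [adjacency_matrix()] (zero
#'   diagonal).
#' @param labels gene -> module labels covering the adjacency's rownames.
#' @return data.frame: gene_id, module, kim, in_module.
#' @export
intramodular_connectivity <- function(adjacency, labels) {
  genes <- rownames(adjacency)
  if (is.null(genes)) stop("adjacency must carry gene ids as dimnames")
  if (!all(genes %in% names(labels)))
    stop("labels missing for some adjacency genes")
  lab <- labels[genes]
  kim <- vapply(seq_along(genes), function(i) {
    peers <- which(lab == lab[i])
    sum(adjacency[i, setdiff(peers, i)])
  }, numeric(1))
  data.frame(gene_id = genes, module = unname(lab), kim = kim,
             in_module = unname(lab) != "grey",
             row.names = NULL, stringsAsFactors = FALSE)
}
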