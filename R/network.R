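#' Build an interaction graph from a weighted edge table
#'
#' Edges are undirected gene pairs with confidence weights in \[0, 1\].
#' Self-loops are dropped (with a message), and duplicate pairs — in either
#' order — collapse to the maximum weight seen.
#'
#' @param edges Tibble or data frame with columns `gene_a`, `gene_b`,
#'   `weight`.
#' @return An undirected [igraph::igraph] with a `weight` edge attribute.
#' @export
#' @examples
#' g <- interaction_graph(tibble::tibble(
#'   gene_a = c("A", "B"), gene_b = c("B", "A"), weight = c(0.9, 0.5)
#' ))
#' igraph::E(g)$weight
interaction_graph <- function(edges) {
  edges <- tibble::as_tibble(edges)
  needed <- c("gene_a", "gene_b", "weight")
  if (!all(needed %in% names(edges))) {
    abort_data("edge table needs columns gene_a, gene_b, weight")
  }
  bad <- which(!is.finite(edges$weight) | edges$weight < 0 | edges$weight > 1)
  if (length(bad)) {
    abort_data(sprintf("edge weight outside [0, 1] at line %d", bad[1]))
  }
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    rlang::inform(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  edges <- edges |>
    dplyr::mutate(a = pmin(.data$gene_a, .data$gene_b),
                  b = pmax(.data$gene_a, .data$gene_b)) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(weight = max(.data$weight), .groups = "drop")
  igraph::graph_from_data_frame(
    data.frame(from = edges$a, to = edges$b, weight = edges$weight),
    directed = FALSE
  )
}

#' Load a weighted edge list TSV
#'
#' @param path TSV with header columns `gene_a`, `gene_b`, `weight`.
#' @return An undirected weighted [igraph::igraph]; an empty file yields an
#'   empty graph.
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("edge list not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          gene_a = readr::col_character(),
                          gene_b = readr::col_character(),
                          weight = readr::col_double()
                        ))
  interaction_graph(df)
}

#' Extract the dominant interaction subcluster of a query gene set
#'
#' Induces the subgraph on the query genes, keeps edges at or above the
#' confidence cutoff, and returns the largest connected component — the
#' "CLUp"-style subcluster. Ties in component size break deterministically
#' toward the lexicographically smallest member set. Singletons are never a
#' cluster: if every query gene is isolated at the cutoff, the result is an
#' empty set with a warning.
#'
#' @param graph An [interaction_graph()] / [load_edge_list()] result.
#' @param query_genes Nonempty character vector of gene ids.
#' @param confidence_min Minimum edge confidence kept (default 0.4, the
#'   conventional medium-confidence interaction cutoff).
#' @return Sorted character vector of cluster genes (possibly empty).
#' @export
#' @examples
#' g <- interaction_graph(tibble::tibble(
#'   gene_a = c("A", "B", "D"), gene_b = c("B", "C", "E"),
#'   weight = c(0.9, 0.8, 0.9)
#' ))
#' extract_subcluster(g, c("A", "B", "C", "D", "E"))
extract_subcluster <- function(graph, query_genes, confidence_min = 0.4) {
  if (length(query_genes) == 0) abort_config("`query_genes` must be nonempty")
  check_scalar_number(confidence_min, "confidence_min", lower = 0, upper = 1)
  present <- intersect(query_genes, igraph::V(graph)$name)
  if (length(present) == 0) {
    rlang::warn("no query gene has any qualifying edge; returning empty cluster")
    return(character(0))
  }
  sub <- igraph::induced_subgraph(graph, present)
  sub <- igraph::subgraph_from_edges(
    sub, igraph::E(sub)[igraph::E(sub)$weight >= confidence_min],
    delete.vertices = FALSE
  )
  comp <- igraph::components(sub)
  sizes <- comp$csize
  if (max(sizes) <= 1) {
    rlang::warn("all query genes are isolated at this confidence cutoff")
    return(character(0))
  }
  big <- which(sizes == max(sizes))
  members <- lapply(big, function(k) igraph::V(sub)$name[comp$membership == k])
  sort(lexicographic_min_set(members))
}
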