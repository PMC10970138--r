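#' Upper-tail hypergeometric overlap probability
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: the chance of observing
#' at least `k` of the `K` term genes in a query of size `n` drawn from a
#' universe of `N`. Vectorized over its arguments.
#'
#' @param k Observed overlap.
#' @param K Term size (within the universe).
#' @param n Query size (within the universe).
#' @param N Universe size.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' hypergeom_p(2, 3, 5, 20)
hypergeom_p <- function(k, K, n, N) {
  ok <- k >= 0 & k <= pmin(K, n) & K <= N & n <= N & K >= 0 & n >= 0
  if (!all(ok)) abort_data("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis against a gene-set library
#'
#' Tests every library term with at least one query gene in it for
#' over-representation, with Benjamini-Hochberg adjustment applied within
#' each namespace (BP/CC/MF) separately. Query genes outside the universe
#' are dropped with a message; term genes are intersected with the universe
#' before counting. Terms with zero overlap are omitted — they carry no
#' evidence and would inflate the BH test count.
#'
#' @param query Character vector of gene ids.
#' @param library A `geneset_library` tibble (`term`, `namespace`, `genes`).
#' @param universe Background gene set; defaults to the union of all library
#'   genes and the query.
#' @param alpha Enrichment threshold on q-values.
#' @return An `ora_result` tibble sorted by q, then p, then term: `term`,
#'   `namespace`, `k`, `K`, `n`, `N`, `overlap` (the "k/K" display string),
#'   `p`, `q`, `enriched`, `overlap_genes` (list-column).
#' @export
#' @examples
#' lib <- generate_geneset_library(planted_truth(200), n_sets = 20, seed = 1)
#' run_ora(lib$genes[[1]], lib)
run_ora <- function(query, library, universe = NULL, alpha = 0.05) {
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  stopifnot(is.data.frame(library),
            all(c("term", "namespace", "genes") %in% names(library)))
  if (is.null(universe)) {
    universe <- union(unique(unlist(library$genes)), query)
  }
  universe <- unique(universe)
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    rlang::inform(sprintf("dropping %d query gene(s) outside the universe",
                          length(dropped)))
  }
  query <- intersect(query, universe)
  if (length(query) == 0) abort_data("query is empty after universe intersection")
  n <- length(query)
  nn <- length(universe)
  rec <- library |>
    dplyr::mutate(
      genes = purrr::map(.data$genes, ~ intersect(unique(.x), universe)),
      K = lengths(.data$genes),
      overlap_genes = purrr::map(.data$genes, ~ sort(intersect(.x, query))),
      k = lengths(.data$overlap_genes)
    ) |>
    dplyr::filter(.data$k >= 1)
  if (nrow(rec) == 0) {
    out <- tibble::tibble(term = character(), namespace = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), overlap = character(), p = numeric(),
                          q = numeric(), enriched = logical(),
                          overlap_genes = list())
    return(structure(out, class = c("ora_result", class(out)),
                     query_size = n, universe_size = nn, alpha = alpha))
  }
  out <- rec |>
    dplyr::mutate(
      n = n, N = nn,
      p = hypergeom_p(.data$k, .data$K, n, nn)
    ) |>
    dplyr::group_by(.data$namespace) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      enriched = .data$q < alpha,
      overlap = sprintf("%d/%d", .data$k, .data$K)
    ) |>
    dplyr::select("term", "namespace", "k", "K", "n", "N", "overlap",
                  "p", "q", "enriched", "overlap_genes") |>
    dplyr::arrange(.data$q, .data$p, .data$term)
  structure(out, class = c("ora_result", class(out)),
            query_size = n, universe_size = nn, alpha = alpha)
}

#' Term-overlap network with automatic fusion of redundant terms
#'
#' Connects enriched terms by the Jaccard similarity of their overlapping
#' query genes and transitively merges terms at or above `fuse_jaccard`
#' into fused nodes — collapsing near-duplicate ontology terms that share
#' most of their hit genes. A fused node is labeled by its most significant
#' member (smallest q) and carries the union of the members' genes.
#'
#' @param records An [run_ora()] result (only `enriched` terms are used).
#' @param fuse_jaccard Jaccard threshold for merging terms.
#' @return List with `nodes` (tibble: `label`, `members` list, `genes`
#'   list, `q`) and `edges` (tibble: `term_a`, `term_b`, `jaccard`).
#' @export
term_network <- function(records, fuse_jaccard = 0.5) {
  check_scalar_number(fuse_jaccard, "fuse_jaccard", lower = 0, upper = 1)
  rec <- dplyr::filter(tibble::as_tibble(records), .data$enriched)
  empty_nodes <- tibble::tibble(label = character(), members = list(),
                                genes = list(), q = numeric())
  empty_edges <- tibble::tibble(term_a = character(), term_b = character(),
                                jaccard = numeric())
  if (nrow(rec) == 0) return(list(nodes = empty_nodes, edges = empty_edges))
  gene_sets <- stats::setNames(rec$overlap_genes, rec$term)
  pairs <- if (nrow(rec) >= 2) utils::combn(rec$term, 2) else
    matrix(character(0), nrow = 2)
  jac <- apply(pairs, 2, function(pr) {
    a <- gene_sets[[pr[1]]]
    b <- gene_sets[[pr[2]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  edges <- tibble::tibble(term_a = pairs[1, ], term_b = pairs[2, ],
                          jaccard = as.numeric(jac))
  edges <- dplyr::filter(edges, .data$jaccard > 0)
  fuse <- dplyr::filter(edges, .data$jaccard >= fuse_jaccard)
  g <- igraph::graph_from_data_frame(fuse[, c("term_a", "term_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = rec$term))
  comp <- igraph::components(g)
  nodes <- purrr::map_dfr(seq_len(comp$no), function(i) {
    member_terms <- igraph::V(g)$name[comp$membership == i]
    sub <- rec[rec$term %in% member_terms, ]
    best <- sub[order(sub$q, sub$p, sub$term), ][1, ]
    union_genes <- sort(unique(unlist(gene_sets[member_terms])))
    tibble::tibble(label = best$term, members = list(sort(member_terms)),
                   genes = list(union_genes), q = best$q)
  })
  list(nodes = dplyr::arrange(nodes, .data$q, .data$label), edges = edges)
}
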