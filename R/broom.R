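#' Tidy and summarize fitted pipeline objects
#'
#' `tidy()` returns the per-unit result table of a fit as a tibble;
#' `glance()` a one-row summary.
#'
#' @param x An `rp_dea`, `ora_result`, `specificity_partition` or `ms_run`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name msc_broom
NULL

#' @rdname msc_broom
#' @exportS3Method generics::tidy
tidy.rp_dea <- function(x, ...) x$table

#' @rdname msc_broom
#' @exportS3Method generics::glance
glance.rp_dea <- function(x, ...) {
  tibble::tibble(
    dataset_id = x$dataset_id,
    tissue = x$tissue,
    contrast = paste(x$contrast, collapse = " vs "),
    n_genes = nrow(x$table),
    n_up = sum(x$table$direction == "up"),
    n_down = sum(x$table$direction == "down"),
    alpha = x$config$alpha,
    n_permutations = x$config$n_permutations
  )
}

#' @rdname msc_broom
#' @exportS3Method generics::tidy
tidy.ora_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(overlap_genes = purrr::map_chr(.data$overlap_genes,
                                                 paste, collapse = ";"))
}

#' @rdname msc_broom
#' @exportS3Method generics::glance
glance.ora_result <- function(x, ...) {
  tibble::tibble(
    n_terms_tested = nrow(x),
    n_enriched = sum(x$enriched),
    n_enriched_bp = sum(x$enriched & x$namespace == "BP"),
    n_enriched_cc = sum(x$enriched & x$namespace == "CC"),
    n_enriched_mf = sum(x$enriched & x$namespace == "MF"),
    query_size = attr(x, "query_size"),
    universe_size = attr(x, "universe_size"),
    alpha = attr(x, "alpha")
  )
}

#' @rdname msc_broom
#' @exportS3Method generics::tidy
tidy.specificity_partition <- function(x, ...) {
  tibble::as_tibble(x)[, c("gene", "spms_direction", "rrms_direction", "category")]
}

#' @rdname msc_broom
#' @exportS3Method generics::glance
glance.specificity_partition <- function(x, ...) {
  n <- table(factor(x$category, c("same", "opposite", "specific")))
  tibble::tibble(
    n_genes = nrow(x),
    n_same = n[["same"]],
    n_opposite = n[["opposite"]],
    n_specific = n[["specific"]],
    n_candidates = n[["opposite"]] + n[["specific"]]
  )
}

#' @rdname msc_broom
#' @exportS3Method generics::glance
glance.ms_run <- function(x, ...) {
  cts <- x$manifest$counts
  tibble::tibble(
    seed = x$manifest$seed,
    consensus_pool = cts$consensus_pool,
    rulu = cts$rulu,
    clup = cts$clup,
    candidates = cts$candidates,
    final_bps = cts$final_bps
  )
}
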