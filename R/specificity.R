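#' Consensus RRMS-vs-HC direction across blood datasets
#'
#' Applies the same directional-consistency rule as the cross-tissue
#' consensus, restricted to blood (the tissue where candidate biomarkers
#' must be detectable): a gene gets an RRMS direction when it is a DEG with
#' the modal direction in at least `blood_min_fraction` of the blood
#' datasets measuring it; otherwise its RRMS direction is `none`.
#'
#' @param rrms_deg_tables List of [rank_product_test()] fits for the
#'   RRMS-vs-HC contrast (blood only), or a long tibble with `dataset_id`,
#'   `tissue`, `gene`, `direction`.
#' @param blood_min_fraction Consistency threshold.
#' @return Tibble `gene`, `rrms_direction` (`up`, `down` or `none`).
#' @export
rrms_consensus <- function(rrms_deg_tables, blood_min_fraction = 0.75) {
  check_scalar_number(blood_min_fraction, "blood_min_fraction", lower = 0, upper = 1)
  long <- as_deg_long(rrms_deg_tables)
  if (nrow(long) == 0) {
    return(tibble::tibble(gene = character(), rrms_direction = character()))
  }
  if (any(long$tissue != "blood", na.rm = TRUE)) {
    abort_config("the RRMS comparison is blood-only; brain tables are not allowed")
  }
  long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n = dplyr::n(),
      up = sum(.data$direction == "up"),
      down = sum(.data$direction == "down"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      modal = modal_direction(.data$up, .data$down),
      frac = pmax(.data$up, .data$down) / .data$n,
      rrms_direction = ifelse(.data$modal %in% c("up", "down") &
                                .data$frac >= blood_min_fraction,
                              .data$modal, "none")
    ) |>
    dplyr::select("gene", "rrms_direction") |>
    dplyr::arrange(.data$gene)
}

#' Partition a target gene set by its RRMS behavior
#'
#' Classifies each target gene (e.g. the CLUp or RuLu set, with its SPMS
#' consensus direction) against the blood RRMS-vs-HC consensus:
#' `same` when the RRMS direction equals the SPMS direction, `opposite`
#' when it is the reverse, and `specific` when the gene is not an RRMS DEG.
#' The three categories partition the target set exactly. Genes missing
#' from the RRMS tables are treated as RRMS direction `none` (logged).
#' The biomarker `candidates` are `specific` plus `opposite` — everything
#' whose behavior differs from the relapsing-remitting subtype.
#'
#' @param target Tibble with columns `gene` and `spms_direction` (`up` or
#'   `down`), or a character vector of genes (then all `spms_direction =
#'   "up"`).
#' @param rrms_directions A [rrms_consensus()] table.
#' @return A `specificity_partition` tibble: `gene`, `spms_direction`,
#'   `rrms_direction`, `category`; attribute `candidates` holds the
#'   specific-plus-opposite gene vector.
#' @export
partition_by_rrms <- function(target, rrms_directions) {
  if (is.character(target)) {
    target <- tibble::tibble(gene = target, spms_direction = "up")
  }
  stopifnot(is.data.frame(target),
            all(c("gene", "spms_direction") %in% names(target)))
  if (!all(target$spms_direction %in% c("up", "down"))) {
    abort_data("every target gene needs an SPMS direction of 'up' or 'down'")
  }
  out <- target |>
    dplyr::left_join(rrms_directions, by = "gene")
  n_missing <- sum(is.na(out$rrms_direction))
  if (n_missing > 0) {
    rlang::inform(sprintf(
      "%d target gene(s) absent from the RRMS tables; treated as not DEG in RRMS",
      n_missing))
  }
  out <- out |>
    dplyr::mutate(
      rrms_direction = dplyr::coalesce(.data$rrms_direction, "none"),
      category = dplyr::case_when(
        .data$rrms_direction == .data$spms_direction ~ "same",
        .data$rrms_direction %in% c("up", "down") ~ "opposite",
        TRUE ~ "specific"
      )
    ) |>
    dplyr::arrange(.data$gene)
  structure(out, class = c("specificity_partition", class(out)),
            candidates = sort(out$gene[out$category %in% c("specific", "opposite")]))
}

#' @export
print.specificity_partition <- function(x, ...) {
  n <- table(factor(x$category, c("same", "opposite", "specific")))
  cat(sprintf("<specificity_partition> %d genes: %d same + %d opposite + %d specific (%d candidates)\n",
              nrow(x), n[["same"]], n[["opposite"]], n[["specific"]],
              n[["opposite"]] + n[["specific"]]))
  invisible(x)
}

#' Candidate biomarkers from a specificity partition
#'
#' @param partition A [partition_by_rrms()] result.
#' @return Sorted character vector: genes whose behavior differs from RRMS
#'   (`specific` plus `opposite`).
#' @export
candidate_genes <- function(partition) {
  attr(partition, "candidates")
}

layer_sides <- function(partition, mode = c("specific", "different")) {
  mode <- match.arg(mode)
  spec_cats <- if (mode == "specific") "specific" else c("specific", "opposite")
  list(specific = sort(partition$gene[partition$category %in% spec_cats]),
       shared = sort(partition$gene[partition$category == "same"]))
}

#' Three-layered SPMS-specific biological-process comparison
#'
#' Runs paired over-representation analyses at three granularities —
#' the network subcluster (CLUp), the up/up consensus set (RuLu), and all
#' consensus DEGs — each contrasting the genes whose behavior differs from
#' RRMS against the genes shared with RRMS. A layer's "difference" is the
#' set of BP terms enriched (q < alpha) on the differing side but not on
#' the shared side. The final SPMS-specific BP set combines the layer
#' differences by the chosen rule (strict intersection by default).
#'
#' Layers 1 and 2 contrast the strictly `specific` genes against the `same`
#' genes; layer 3 contrasts all different-behavior genes (`specific` plus
#' `opposite`) against the `same` genes. A layer whose differing side is
#' empty is skipped (logged); a layer whose shared side is empty contributes
#' its enrichment without exclusions.
#'
#' @param partitions Named list of [partition_by_rrms()] results:
#'   `clup`, `rulu`, `all`.
#' @param library A `geneset_library`.
#' @param universe Background gene set for the ORA.
#' @param alpha Enrichment threshold.
#' @param layer_rule `"intersection"` (default), `"union"`, or
#'   `"per-layer"` (no combination; `final` is `NULL`).
#' @return A `layered_bp` list: per-layer `specific_terms`, `shared_terms`,
#'   `difference`, plus `final` (character vector of BP terms).
#' @export
layered_bp_comparison <- function(partitions, library, universe = NULL,
                                  alpha = 0.05,
                                  layer_rule = c("intersection", "union",
                                                 "per-layer")) {
  layer_rule <- match.arg(layer_rule)
  stopifnot(all(c("clup", "rulu", "all") %in% names(partitions)))
  modes <- c(clup = "specific", rulu = "specific", all = "different")
  bp_terms <- function(genes) {
    if (length(genes) == 0) return(character(0))
    res <- run_ora(genes, library, universe = universe, alpha = alpha)
    sort(res$term[res$enriched & res$namespace == "BP"])
  }
  layers <- purrr::imap(modes, function(mode, name) {
    sides <- layer_sides(partitions[[name]], mode)
    if (length(sides$specific) == 0) {
      rlang::inform(sprintf("layer '%s': empty differing side, layer skipped", name))
      return(list(specific_terms = character(0), shared_terms = character(0),
                  difference = character(0), skipped = TRUE))
    }
    spec_terms <- bp_terms(sides$specific)
    if (length(sides$shared) == 0) {
      rlang::inform(sprintf("layer '%s': empty shared side, no exclusions", name))
      shared_terms <- character(0)
    } else {
      shared_terms <- bp_terms(sides$shared)
    }
    list(specific_terms = spec_terms, shared_terms = shared_terms,
         difference = setdiff(spec_terms, shared_terms), skipped = FALSE)
  })
  active <- purrr::keep(layers, ~ !.x$skipped)
  final <- switch(layer_rule,
    intersection = if (length(active)) {
      Reduce(intersect, purrr::map(active, "difference"))
    } else character(0),
    union = sort(unique(unlist(purrr::map(active, "difference")))),
    `per-layer` = NULL
  )
  structure(list(layers = layers, final = final, layer_rule = layer_rule,
                 alpha = alpha),
            class = "layered_bp")
}

#' @export
print.layered_bp <- function(x, ...) {
  cat(sprintf("<layered_bp> rule = %s\n", x$layer_rule))
  for (nm in names(x$layers)) {
    ly <- x$layers[[nm]]
    cat(sprintf("  %s: %d enriched (differing) / %d (shared) -> %d retained%s\n",
                nm, length(ly$specific_terms), length(ly$shared_terms),
                length(ly$difference), if (ly$skipped) " [skipped]" else ""))
  }
  if (!is.null(x$final)) {
    cat(sprintf("  final SPMS-specific BPs: %d\n", length(x$final)))
  }
  invisible(x)
}
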