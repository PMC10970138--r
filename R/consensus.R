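as_deg_long <- function(deg_tables) {
  if (inherits(deg_tables, "rp_dea")) deg_tables <- list(deg_tables)
  if (is.data.frame(deg_tables)) {
    needed <- c("dataset_id", "tissue", "gene", "direction")
    if (!all(needed %in% names(deg_tables))) {
      abort_config("long DEG table needs columns dataset_id, tissue, gene, direction")
    }
    return(tibble::as_tibble(deg_tables))
  }
  purrr::map_dfr(deg_tables, function(x) {
    if (!inherits(x, "rp_dea")) {
      abort_config("`deg_tables` must be rp_dea objects or one long tibble")
    }
    dplyr::mutate(x$table[, c("gene", "direction")],
                  dataset_id = x$dataset_id, tissue = x$tissue,
                  .before = 1)
  })
}

# modal direction among DEG calls: "none" if no DEG, "mixed" on an exact tie
modal_direction <- function(n_up, n_down) {
  dplyr::case_when(
    n_up == 0 & n_down == 0 ~ "none",
    n_up > n_down ~ "up",
    n_down > n_up ~ "down",
    TRUE ~ "mixed"
  )
}

#' Cross-tissue consensus filter over per-dataset DEG tables
#'
#' A gene passes when (a) it is a DEG in at least `brain_min_fraction` of
#' the brain datasets that measure it, with an unambiguous modal direction,
#' and (b) it is a DEG with that same direction in at least
#' `blood_min_fraction` of the blood datasets that measure it. Genes absent
#' from a dataset's platform are excluded from that dataset's denominator.
#'
#' Under the default `blood_rule = "strict"`, the blood fraction counts only
#' datasets where the gene is significant in the modal direction. The
#' `"lenient"` alternative treats non-significant blood datasets as
#' non-contradictory: the fraction counts datasets that are either
#' significant in the modal direction or not significant at all, and at
#' least one blood dataset must still call the gene in that direction.
#'
#' @param deg_tables List of [rank_product_test()] fits (brain and blood
#'   mixed), or one long tibble with columns `dataset_id`, `tissue`, `gene`,
#'   `direction`.
#' @param brain_min_fraction Minimum fraction of brain datasets calling the
#'   gene a DEG.
#' @param blood_min_fraction Minimum fraction of blood datasets consistent
#'   with the brain direction.
#' @param blood_rule `"strict"` (default) or `"lenient"`; see Details.
#' @return A `consensus_table` tibble with one row per gene:
#'   `brain_deg_fraction`, `blood_direction_fraction`, `brain_direction`,
#'   `blood_direction`, `passes_filter`, `rulu`.
#' @export
#' @examples
#' study <- generate_study(study_design(seed = 7))
#' cfg <- rp_config(n_permutations = 50)
#' fits <- lapply(study$datasets, rank_product_test, config = cfg)
#' cons <- consensus_filter(fits)
#' sum(cons$passes_filter)
consensus_filter <- function(deg_tables, brain_min_fraction = 0.5,
                             blood_min_fraction = 0.75,
                             blood_rule = c("strict", "lenient")) {
  blood_rule <- match.arg(blood_rule)
  check_scalar_number(brain_min_fraction, "brain_min_fraction", lower = 0, upper = 1)
  check_scalar_number(blood_min_fraction, "blood_min_fraction", lower = 0, upper = 1)
  long <- as_deg_long(deg_tables)
  if (!any(long$tissue == "brain") || !any(long$tissue == "blood")) {
    abort_config("consensus needs at least one brain and one blood DEG table")
  }
  per_gene <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_brain = sum(.data$tissue == "brain"),
      brain_up = sum(.data$tissue == "brain" & .data$direction == "up"),
      brain_down = sum(.data$tissue == "brain" & .data$direction == "down"),
      n_blood = sum(.data$tissue == "blood"),
      blood_up = sum(.data$tissue == "blood" & .data$direction == "up"),
      blood_down = sum(.data$tissue == "blood" & .data$direction == "down"),
      .groups = "drop"
    )
  out <- per_gene |>
    dplyr::mutate(
      brain_direction = modal_direction(.data$brain_up, .data$brain_down),
      blood_direction = modal_direction(.data$blood_up, .data$blood_down),
      brain_deg_fraction = ifelse(.data$n_brain > 0,
                                  (.data$brain_up + .data$brain_down) / .data$n_brain, 0),
      blood_modal_n = pmax(.data$blood_up, .data$blood_down),
      blood_ns_n = .data$n_blood - .data$blood_up - .data$blood_down,
      blood_direction_fraction = ifelse(
        .data$n_blood > 0,
        if (blood_rule == "strict") {
          .data$blood_modal_n / .data$n_blood
        } else {
          (.data$blood_modal_n + .data$blood_ns_n) / .data$n_blood
        },
        0
      ),
      passes_filter =
        .data$n_brain > 0 & .data$n_blood > 0 &
        .data$brain_deg_fraction >= brain_min_fraction &
        .data$brain_direction %in% c("up", "down") &
        .data$blood_direction == .data$brain_direction &
        .data$blood_modal_n >= 1 &
        .data$blood_direction_fraction >= blood_min_fraction,
      rulu = .data$passes_filter &
        .data$brain_direction == "up" & .data$blood_direction == "up"
    ) |>
    dplyr::select("gene", "brain_deg_fraction", "blood_direction_fraction",
                  "brain_direction", "blood_direction", "passes_filter", "rulu") |>
    dplyr::arrange(.data$gene)
  structure(out, class = c("consensus_table", class(out)),
            blood_rule = blood_rule,
            brain_min_fraction = brain_min_fraction,
            blood_min_fraction = blood_min_fraction)
}

#' Up-regulated cross-tissue consensus genes (the "RuLu" set)
#'
#' Refines the consensus pool to genes up-regulated in both brain and blood
#' — the robust up/up biomarker shortlist fed to the network stage.
#'
#' @param consensus A [consensus_filter()] table.
#' @return Sorted character vector of gene ids.
#' @export
derive_rulu <- function(consensus) {
  stopifnot(is.data.frame(consensus), all(c("gene", "rulu") %in% names(consensus)))
  sort(consensus$gene[consensus$rulu])
}
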