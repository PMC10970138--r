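#' Planted ground truth for a synthetic multi-dataset study
#'
#' Assigns each gene in the universe to one of five differential-expression
#' classes relative to the healthy-control baseline:
#'
#' * `null` — no shift in any arm;
#' * `spms_up_specific` — up in the SPMS arm only;
#' * `spms_down_specific` — down in the SPMS arm only;
#' * `shared_up` — up in both the SPMS and RRMS arms;
#' * `opposite` — up in SPMS, down in RRMS.
#'
#' The classes partition the gene universe, so downstream sensitivity and
#' precision can be scored exactly.
#'
#' @param n_genes Size of the gene universe (>= 50).
#' @param n_per_class Named counts of planted genes per non-null class.
#' @param effect_size Log2 fold-change magnitude applied to planted arms
#'   (single non-negative number).
#' @param seed Integer seed used to assign genes to classes.
#' @return A `planted_truth` tibble with columns `gene`, `class`,
#'   `spms_shift`, `rrms_shift` (signed log2 shifts applied to the SPMS and
#'   RRMS arms respectively).
#' @export
#' @examples
#' truth <- planted_truth(200, seed = 1)
#' dplyr::count(truth, class)
planted_truth <- function(n_genes = 200,
                          n_per_class = c(spms_up_specific = 20,
                                          spms_down_specific = 5,
                                          shared_up = 5,
                                          opposite = 3),
                          effect_size = 1.5,
                          seed = 1L) {
  check_scalar_number(n_genes, "n_genes", lower = 50)
  check_scalar_number(effect_size, "effect_size", lower = 0)
  classes <- c("spms_up_specific", "spms_down_specific", "shared_up", "opposite")
  if (!all(names(n_per_class) %in% classes)) {
    abort_config("`n_per_class` names must be planted class labels")
  }
  full <- stats::setNames(rep(0L, length(classes)), classes)
  full[names(n_per_class)] <- as.integer(n_per_class)
  if (sum(full) > n_genes) {
    abort_config("planted class counts exceed the gene universe")
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  class <- rep("null", n_genes)
  idx <- withr::with_seed(as.integer(seed), sample.int(n_genes, sum(full)))
  class[idx] <- rep(classes, times = full)
  e <- effect_size
  shift <- list(
    null = c(0, 0),
    spms_up_specific = c(e, 0),
    spms_down_specific = c(-e, 0),
    shared_up = c(e, e),
    opposite = c(e, -e)
  )
  out <- tibble::tibble(
    gene = genes,
    class = class,
    spms_shift = vapply(class, function(cl) shift[[cl]][1], numeric(1), USE.NAMES = FALSE),
    rrms_shift = vapply(class, function(cl) shift[[cl]][2], numeric(1), USE.NAMES = FALSE)
  )
  structure(out, class = c("planted_truth", class(out)), effect_size = e)
}

#' Describe a synthetic multi-dataset case/control study
#'
#' The default layout mirrors the cross-tissue design the pipeline targets:
#' two brain datasets (SPMS vs HC only) and four blood datasets (SPMS, RRMS
#' and HC arms), each with its own multiplicative batch scale, log-normal
#' expression and a shared per-gene baseline so that a gene's planted class
#' is consistent across datasets.
#'
#' @param n_genes Gene universe size (>= 50).
#' @param datasets Tibble with columns `dataset_id`, `tissue` ("brain" or
#'   "blood"), `n_spms`, `n_rrms`, `n_hc`, `batch_scale`. RRMS arms are
#'   blood-only; brain rows must have `n_rrms = 0`.
#' @param planted A [planted_truth()] table; defaults to one over `n_genes`.
#' @param noise_sd Gaussian noise SD on the log2 scale (> 0); the 0.5
#'   default matches the typical residual spread of expressed microarray
#'   genes after normalization.
#' @param seed Integer seed controlling every random draw in generation.
#' @param ... Passed to [planted_truth()] when `planted` is `NULL`.
#' @return A `study_design` list with elements `n_genes`, `datasets`,
#'   `planted`, `noise_sd`, `seed`.
#' @export
#' @examples
#' design <- study_design(seed = 7)
#' design$datasets
study_design <- function(n_genes = 200,
                         datasets = NULL,
                         planted = NULL,
                         noise_sd = 0.5,
                         seed = 1L,
                         ...) {
  check_scalar_number(n_genes, "n_genes", lower = 50)
  check_scalar_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  check_scalar_number(seed, "seed")
  if (is.null(datasets)) {
    datasets <- tibble::tribble(
      ~dataset_id, ~tissue, ~n_spms, ~n_rrms, ~n_hc, ~batch_scale,
      "brain1", "brain", 10L, 0L, 10L, 1.0,
      "brain2", "brain", 10L, 0L, 10L, 1.6,
      "blood1", "blood", 10L, 10L, 10L, 0.7,
      "blood2", "blood", 10L, 10L, 10L, 1.2,
      "blood3", "blood", 10L, 10L, 10L, 2.0,
      "blood4", "blood", 10L, 10L, 10L, 0.9
    )
  }
  datasets <- tibble::as_tibble(datasets)
  needed <- c("dataset_id", "tissue", "n_spms", "n_rrms", "n_hc", "batch_scale")
  if (!all(needed %in% names(datasets))) {
    abort_config("`datasets` must have columns dataset_id, tissue, n_spms, n_rrms, n_hc, batch_scale")
  }
  if (anyDuplicated(datasets$dataset_id)) abort_config("dataset_id values must be unique")
  if (!all(datasets$tissue %in% c("brain", "blood"))) {
    abort_config("tissue must be 'brain' or 'blood'")
  }
  if (!any(datasets$tissue == "brain") || !any(datasets$tissue == "blood")) {
    abort_config("the design needs at least one brain and one blood dataset")
  }
  if (any(datasets$n_spms < 2) || any(datasets$n_hc < 2)) {
    abort_config("every SPMS and HC arm needs at least 2 samples")
  }
  if (any(datasets$n_rrms != 0 & datasets$n_rrms < 2)) {
    abort_config("RRMS arms must be absent (0) or have at least 2 samples")
  }
  if (any(datasets$n_rrms > 0 & datasets$tissue == "brain")) {
    abort_config("RRMS arms are blood-only in this design")
  }
  if (any(datasets$batch_scale <= 0)) abort_config("batch_scale must be positive")
  if (is.null(planted)) planted <- planted_truth(n_genes, seed = seed, ...)
  if (nrow(planted) != n_genes) {
    abort_config("`planted` must cover exactly the n_genes gene universe")
  }
  structure(
    list(n_genes = as.integer(n_genes), datasets = datasets,
         planted = planted, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d genes, %d datasets (%d brain / %d blood), seed %d\n",
              x$n_genes, nrow(x$datasets), sum(x$datasets$tissue == "brain"),
              sum(x$datasets$tissue == "blood"), x$seed))
  print(x$datasets)
  invisible(x)
}

new_expression_dataset <- function(dataset_id, tissue, matrix, samples) {
  stopifnot(is.matrix(matrix), nrow(samples) == ncol(matrix))
  if (anyDuplicated(rownames(matrix))) abort_data("gene ids must be unique")
  if (any(!is.finite(matrix))) abort_data("expression values must be finite")
  if (!all(samples$group %in% c("SPMS", "RRMS", "HC"))) {
    abort_data("sample groups must be SPMS, RRMS or HC")
  }
  structure(
    list(dataset_id = dataset_id, tissue = tissue,
         matrix = matrix, samples = tibble::as_tibble(samples)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  grp <- table(x$samples$group)
  cat(sprintf("<expression_dataset> %s (%s): %d genes x %d samples [%s]\n",
              x$dataset_id, x$tissue, nrow(x$matrix), ncol(x$matrix),
              paste(names(grp), grp, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic multi-dataset expression study
#'
#' Draws one log2 baseline per gene (Uniform(4, 12), shared across datasets),
#' then builds each dataset as baseline + log2(batch scale) + planted arm
#' shift + independent Gaussian noise. The result is a list of per-dataset
#' genes-by-samples matrices on the log2-intensity scale, fully determined by
#' the design seed.
#'
#' @param design A [study_design()].
#' @return A list with `datasets` (named list of `expression_dataset`) and
#'   `truth` (the design's [planted_truth()] table).
#' @export
#' @examples
#' study <- generate_study(study_design(seed = 7))
#' study$datasets$brain1
generate_study <- function(design) {
  if (!inherits(design, "study_design")) {
    abort_config("`design` must be a study_design object")
  }
  truth <- design$planted
  withr::with_seed(design$seed, {
    mu <- stats::runif(design$n_genes, 4, 12)
    datasets <- purrr::pmap(design$datasets, function(dataset_id, tissue, n_spms,
                                                      n_rrms, n_hc, batch_scale) {
      groups <- c(rep("SPMS", n_spms), rep("RRMS", n_rrms), rep("HC", n_hc))
      n <- length(groups)
      sample_id <- sprintf("%s_%s_%02d", dataset_id, groups,
                           stats::ave(seq_len(n), groups, FUN = seq_along))
      shift <- cbind(SPMS = truth$spms_shift, RRMS = truth$rrms_shift,
                     HC = rep(0, design$n_genes))
      m <- mu + log2(batch_scale) + shift[, groups, drop = FALSE] +
        matrix(stats::rnorm(design$n_genes * n, sd = design$noise_sd),
               design$n_genes, n)
      dimnames(m) <- list(truth$gene, sample_id)
      new_expression_dataset(dataset_id, tissue, m,
                             tibble::tibble(sample_id = sample_id, group = groups))
    })
  })
  names(datasets) <- design$datasets$dataset_id
  list(datasets = datasets, truth = truth)
}

#' Generate a gene-set library with known enriched sets
#'
#' Builds a GMT-writable library over the truth table's gene universe.
#' `enriched_sets` of the terms are seeded predominantly (a configurable
#' fraction) with the planted SPMS-up-specific genes, giving known positives
#' for over-representation recovery; the remaining terms are drawn uniformly
#' from the universe. Seeded terms are tagged namespace `BP`; background
#' terms cycle through BP/CC/MF.
#'
#' @param truth A [planted_truth()] table.
#' @param n_sets Number of terms (> 0).
#' @param set_size_range Length-2 integer range of term sizes.
#' @param enriched_sets How many terms to seed with planted specific genes.
#' @param enriched_fraction Fraction of a seeded term drawn from the planted
#'   SPMS-up-specific genes.
#' @param seed Integer seed.
#' @return A `geneset_library` tibble with columns `term`, `namespace`,
#'   `genes` (list-column); attribute `enriched_terms` names the seeded terms.
#' @export
#' @examples
#' lib <- generate_geneset_library(planted_truth(200), n_sets = 10, seed = 1)
#' attr(lib, "enriched_terms")
generate_geneset_library <- function(truth, n_sets = 50,
                                     set_size_range = c(10, 40),
                                     enriched_sets = 3,
                                     enriched_fraction = 0.8,
                                     seed = 1L) {
  check_scalar_number(n_sets, "n_sets", lower = 1)
  check_scalar_number(enriched_sets, "enriched_sets", lower = 0, upper = n_sets)
  check_scalar_number(enriched_fraction, "enriched_fraction", lower = 0, upper = 1)
  universe <- truth$gene
  if (max(set_size_range) > length(universe)) {
    abort_config("set sizes cannot exceed the gene universe")
  }
  specific <- truth$gene[truth$class == "spms_up_specific"]
  withr::with_seed(as.integer(seed), {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets, replace = TRUE)
    genes <- purrr::map(seq_len(n_sets), function(i) {
      s <- sizes[i]
      if (i <= enriched_sets && length(specific) > 0) {
        k <- min(round(enriched_fraction * s), length(specific))
        seeded <- sample(specific, k)
        rest <- sample(setdiff(universe, seeded), s - k)
        sort(c(seeded, rest))
      } else {
        sort(sample(universe, s))
      }
    })
  })
  namespace <- rep(c("BP", "CC", "MF"), length.out = n_sets)
  if (enriched_sets > 0) namespace[seq_len(enriched_sets)] <- "BP"
  out <- tibble::tibble(
    term = sprintf("TERM_%03d", seq_len(n_sets)),
    namespace = namespace,
    genes = genes
  )
  structure(out, class = c("geneset_library", class(out)),
            enriched_terms = out$term[seq_len(enriched_sets)])
}

#' Generate a weighted gene-gene interaction graph with a planted module
#'
#' Background edges are Erdos-Renyi with weights Uniform(0, 1). When
#' `clique_on_specific` is set, the planted SPMS-up-specific genes form a
#' fully connected high-confidence module (weights Uniform(0.7, 1)), so
#' subcluster extraction at the default 0.4 confidence cutoff has a known
#' answer.
#'
#' @param truth A [planted_truth()] table.
#' @param clique_on_specific Plant a high-confidence clique on the
#'   SPMS-up-specific genes?
#' @param background_edge_prob Erdos-Renyi background edge probability.
#' @param seed Integer seed.
#' @return An edge tibble `gene_a`, `gene_b`, `weight` (one row per
#'   unordered pair, `gene_a < gene_b`).
#' @export
#' @examples
#' edges <- generate_interaction_graph(planted_truth(200), seed = 1)
#' head(edges)
generate_interaction_graph <- function(truth, clique_on_specific = TRUE,
                                       background_edge_prob = 0.01,
                                       seed = 1L) {
  check_scalar_number(background_edge_prob, "background_edge_prob",
                      lower = 0, upper = 1)
  genes <- truth$gene
  specific <- truth$gene[truth$class == "spms_up_specific"]
  pairs <- utils::combn(sort(genes), 2L)
  withr::with_seed(as.integer(seed), {
    keep <- stats::runif(ncol(pairs)) < background_edge_prob
    bg <- tibble::tibble(
      gene_a = pairs[1, keep], gene_b = pairs[2, keep],
      weight = stats::runif(sum(keep))
    )
    mod <- tibble::tibble(gene_a = character(), gene_b = character(),
                          weight = numeric())
    if (clique_on_specific && length(specific) >= 2) {
      mp <- utils::combn(sort(specific), 2L)
      mod <- tibble::tibble(
        gene_a = mp[1, ], gene_b = mp[2, ],
        weight = stats::runif(ncol(mp), 0.7, 1)
      )
    }
  })
  edges <- dplyr::bind_rows(mod, bg)
  # collapse duplicate pairs, keeping the strongest (module) edge
  edges <- edges |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(weight = max(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  edges
}
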