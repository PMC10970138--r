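#' Configure an end-to-end pipeline run
#'
#' In simulation mode (the default) the pipeline generates a synthetic
#' study, gene-set library and interaction graph from `design`; in file
#' mode it reads them from `data_dir` (a [write_study()] layout), a GMT at
#' `gmt_path` and an edge list at `edges_path`. All stage thresholds
#' default to the pipeline's published operating point: brain 0.5 / blood
#' 0.75 consensus fractions, interaction confidence 0.4, q-value alpha
#' 0.05.
#'
#' @param design A [study_design()] (simulation mode) or `NULL`.
#' @param data_dir,gmt_path,edges_path File-mode inputs; `data_dir` must
#'   exist when `design` is `NULL`.
#' @param rp An [rp_config()]; its seed is overridden by the fanned-out
#'   stage seed.
#' @param brain_min_fraction,blood_min_fraction Consensus thresholds.
#' @param blood_rule Consensus blood rule, `"strict"` or `"lenient"`.
#' @param confidence_min Interaction confidence cutoff.
#' @param alpha Enrichment threshold.
#' @param layer_rule Combination rule for the three-layer BP comparison.
#' @param library_params,graph_params Lists of extra arguments to
#'   [generate_geneset_library()] / [generate_interaction_graph()]
#'   (simulation mode).
#' @param seed Global seed fanned out to per-stage seeds via
#'   [derive_seeds()].
#' @param out_dir Optional directory for per-stage TSV outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design = NULL,
                            data_dir = NULL, gmt_path = NULL, edges_path = NULL,
                            rp = rp_config(),
                            brain_min_fraction = 0.5,
                            blood_min_fraction = 0.75,
                            blood_rule = "strict",
                            confidence_min = 0.4,
                            alpha = 0.05,
                            layer_rule = "intersection",
                            library_params = list(),
                            graph_params = list(),
                            seed = 1L,
                            out_dir = NULL) {
  if (is.null(design)) {
    if (is.null(data_dir) || !dir.exists(data_dir)) {
      abort_config("file mode needs an existing `data_dir`")
    }
    if (is.null(gmt_path) || !file.exists(gmt_path)) {
      abort_config("file mode needs an existing `gmt_path`")
    }
    if (is.null(edges_path) || !file.exists(edges_path)) {
      abort_config("file mode needs an existing `edges_path`")
    }
  }
  check_scalar_number(confidence_min, "confidence_min", lower = 0, upper = 1)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  structure(
    list(design = design, data_dir = data_dir, gmt_path = gmt_path,
         edges_path = edges_path, rp = rp,
         brain_min_fraction = brain_min_fraction,
         blood_min_fraction = blood_min_fraction,
         blood_rule = blood_rule, confidence_min = confidence_min,
         alpha = alpha, layer_rule = layer_rule,
         library_params = library_params, graph_params = graph_params,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

MANIFEST_SCHEMA_VERSION <- "1.0"

#' Run the full biomarker-discovery pipeline
#'
#' Executes, in order: study generation (or loading), quantile
#' normalization, per-dataset SPMS-vs-HC Rank Product DEA, the brain/blood
#' consensus filter and its up/up refinement (RuLu), interaction-network
#' subcluster extraction (CLUp), over-representation analysis of RuLu and
#' CLUp, blood-only RRMS-vs-HC DEA with its own consensus, the three-way
#' specificity partitions, and the three-layered BP comparison. The run is
#' fully deterministic given the config seed, which fans out to one seed
#' per stage.
#'
#' @param config A [pipeline_config()].
#' @return An `ms_run` list with the per-stage results (`dea`, `consensus`,
#'   `rulu`, `clup`, `ora_rulu`, `ora_clup`, `rrms`, `partitions`,
#'   `layered`, `candidates`, `truth`) and a `manifest` of stage counts
#'   suitable for [write_manifest()].
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(design = study_design(seed = 3), seed = 3))
#' run$manifest$counts
#' }
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort_config("`config` must come from pipeline_config()")
  }
  seeds <- derive_seeds(config$seed,
                        c("simulate", "library", "graph", "dea", "rrms_dea"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "msc_stage_error", stage = name)
    })
  }

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$design)) {
    design <- config$design
    study <- stage("simulate", generate_study(design))
    library <- stage("library", do.call(generate_geneset_library, c(
      list(truth = study$truth, seed = seeds[["library"]]),
      config$library_params
    )))
    edges <- stage("graph", do.call(generate_interaction_graph, c(
      list(truth = study$truth, seed = seeds[["graph"]]),
      config$graph_params
    )))
    graph <- interaction_graph(edges)
    truth <- study$truth
  } else {
    study <- stage("load", read_study(config$data_dir))
    library <- stage("load", read_gmt(config$gmt_path))
    graph <- stage("load", load_edge_list(config$edges_path))
    truth <- study$truth
  }
  datasets <- stage("preprocess", preprocess_datasets(study$datasets))

  # --- SPMS-vs-HC DEA per dataset -------------------------------------------
  dea_seeds <- derive_seeds(seeds[["dea"]], names(datasets))
  dea <- stage("dea", purrr::imap(datasets, function(ds, id) {
    cfg <- config$rp
    cfg$seed <- dea_seeds[[id]]
    rank_product_test(ds, c("SPMS", "HC"), cfg)
  }))

  # --- consensus + RuLu ------------------------------------------------------
  consensus <- stage("consensus", consensus_filter(
    dea, config$brain_min_fraction, config$blood_min_fraction,
    config$blood_rule))
  pool <- consensus$gene[consensus$passes_filter]
  rulu <- derive_rulu(consensus)

  # --- network subcluster ----------------------------------------------------
  clup <- stage("cluster", if (length(rulu)) {
    suppressWarnings(extract_subcluster(graph, rulu, config$confidence_min))
  } else character(0))

  # --- ORA -------------------------------------------------------------------
  universe <- sort(unique(unlist(purrr::map(datasets, ~ rownames(.x$matrix)))))
  universe <- intersect(universe, unique(unlist(library$genes)))
  ora_rulu <- stage("ora", if (length(rulu)) {
    run_ora(rulu, library, universe, config$alpha)
  } else NULL)
  ora_clup <- stage("ora", if (length(clup)) {
    run_ora(clup, library, universe, config$alpha)
  } else NULL)

  # --- RRMS pruning ----------------------------------------------------------
  blood <- purrr::keep(datasets, ~ .x$tissue == "blood" &&
                         sum(.x$samples$group == "RRMS") >= 2)
  rrms_dir <- if (length(blood)) {
    rrms_seeds <- derive_seeds(seeds[["rrms_dea"]], names(blood))
    rrms_dea <- stage("rrms_dea", purrr::imap(blood, function(ds, id) {
      cfg <- config$rp
      cfg$seed <- rrms_seeds[[id]]
      rank_product_test(ds, c("RRMS", "HC"), cfg)
    }))
    stage("rrms_consensus", rrms_consensus(rrms_dea, config$blood_min_fraction))
  } else {
    tibble::tibble(gene = character(), rrms_direction = character())
  }

  spms_dir <- consensus[, c("gene", "brain_direction")] |>
    dplyr::rename(spms_direction = "brain_direction")
  target_tbl <- function(genes) {
    dplyr::filter(spms_dir, .data$gene %in% genes)
  }
  partitions <- stage("specificity", list(
    clup = suppressMessages(partition_by_rrms(target_tbl(clup), rrms_dir)),
    rulu = suppressMessages(partition_by_rrms(target_tbl(rulu), rrms_dir)),
    all = suppressMessages(partition_by_rrms(target_tbl(pool), rrms_dir))
  ))
  candidates <- candidate_genes(partitions$clup)

  layered <- stage("layered_bp", suppressMessages(layered_bp_comparison(
    partitions, library, universe, config$alpha, config$layer_rule)))

  # --- manifest --------------------------------------------------------------
  cat_counts <- function(p) {
    as.list(table(factor(p$category, c("same", "opposite", "specific"))))
  }
  manifest <- list(
    schema_version = MANIFEST_SCHEMA_VERSION,
    seed = config$seed,
    params = list(
      brain_min_fraction = config$brain_min_fraction,
      blood_min_fraction = config$blood_min_fraction,
      blood_rule = config$blood_rule,
      confidence_min = config$confidence_min,
      alpha = config$alpha,
      rp_alpha = config$rp$alpha,
      n_permutations = config$rp$n_permutations,
      max_pairs = unname(config$rp$max_pairs),
      layer_rule = config$layer_rule
    ),
    counts = list(
      degs_per_dataset = purrr::map(dea, ~ sum(.x$table$direction != "ns")),
      consensus_pool = length(pool),
      rulu = length(rulu),
      clup = length(clup),
      clup_partition = cat_counts(partitions$clup),
      candidates = length(candidates),
      final_bps = length(layered$final %||% character(0))
    ),
    candidates = as.list(candidates),
    final_bps = as.list(layered$final %||% character(0))
  )

  run <- structure(
    list(manifest = manifest, dea = dea, consensus = consensus, rulu = rulu,
         clup = clup, ora_rulu = ora_rulu, ora_clup = ora_clup,
         rrms_directions = rrms_dir, partitions = partitions,
         layered = layered, candidates = candidates, truth = truth),
    class = "ms_run"
  )
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

#' @export
print.ms_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat(sprintf(
    "<ms_run> seed %d: pool %d -> RuLu %d -> CLUp %d -> candidates %d; final BPs %d\n",
    x$manifest$seed, cts$consensus_pool, cts$rulu, cts$clup, cts$candidates,
    cts$final_bps))
  invisible(x)
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fit in run$dea) {
    readr::write_tsv(fit$table, file.path(dir, sprintf("dea_%s.tsv", fit$dataset_id)))
  }
  readr::write_tsv(run$consensus, file.path(dir, "consensus.tsv"))
  write_gene_list(run$rulu, file.path(dir, "rulu.txt"))
  write_gene_list(run$clup, file.path(dir, "clup.txt"))
  readr::write_tsv(
    tibble::as_tibble(run$partitions$clup)[, c("gene", "spms_direction",
                                               "rrms_direction", "category")],
    file.path(dir, "clup_partition.tsv"))
  if (!is.null(run$ora_rulu)) {
    tab <- dplyr::select(tibble::as_tibble(run$ora_rulu), -"overlap_genes")
    readr::write_tsv(tab, file.path(dir, "ora_rulu.tsv"))
  }
  write_manifest(run, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Write / read the run manifest
#'
#' The manifest is a JSON record of the run: schema version, seed, the
#' thresholds in force, gene counts at every stage, and the candidate list.
#' The round-trip through disk is lossless, and a schema-version mismatch
#' on read is an explicit error.
#'
#' @param run An `ms_run` or a bare manifest list.
#' @param path JSON file path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   the manifest list.
#' @export
write_manifest <- function(run, path) {
  manifest <- if (inherits(run, "ms_run")) run$manifest else run
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("manifest not found: %s", path))
  m <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) abort_data("malformed manifest JSON"))
  if (!identical(m$schema_version, MANIFEST_SCHEMA_VERSION)) {
    abort_data(sprintf("manifest schema version '%s' does not match '%s'",
                       m$schema_version %||% "<missing>",
                       MANIFEST_SCHEMA_VERSION))
  }
  m
}
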