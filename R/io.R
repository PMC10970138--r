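#' Read and write the pipeline's plain-text interchange formats
#'
#' Expression matrices travel as TSV with a `gene` id column and one column
#' per sample (log2 intensities); sample sheets as TSV with `sample_id`,
#' `group`, `tissue`, `dataset_id`; gene-set libraries as standard GMT
#' (term, description, then member genes, tab-separated — the description
#' slot carries the BP/CC/MF namespace); interaction graphs as a three-column
#' edge list TSV.
#'
#' @param mat Genes-by-samples numeric matrix with rownames.
#' @param path File path.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name msc_io
NULL

#' @rdname msc_io
#' @export
write_expression_tsv <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname msc_io
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname msc_io
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if missing).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in study$datasets) {
    write_expression_tsv(ds$matrix, file.path(dir, paste0(ds$dataset_id, ".tsv")))
  }
  sheet <- purrr::map_dfr(study$datasets, function(ds) {
    dplyr::mutate(ds$samples, tissue = ds$tissue, dataset_id = ds$dataset_id)
  })
  readr::write_tsv(sheet, file.path(dir, "samples.tsv"))
  readr::write_tsv(study$truth[, c("gene", "class")], file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname msc_io
#' @export
read_study <- function(dir) {
  sheet <- readr::read_tsv(file.path(dir, "samples.tsv"), show_col_types = FALSE)
  ids <- unique(sheet$dataset_id)
  datasets <- purrr::map(ids, function(id) {
    m <- read_expression_tsv(file.path(dir, paste0(id, ".tsv")))
    s <- dplyr::filter(sheet, .data$dataset_id == id)
    new_expression_dataset(id, s$tissue[1], m[, s$sample_id, drop = FALSE],
                           s[, c("sample_id", "group")])
  })
  names(datasets) <- ids
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, show_col_types = FALSE)
  } else NULL
  list(datasets = datasets, truth = truth)
}

#' @rdname msc_io
#' @param library A `geneset_library` tibble (`term`, `namespace`, `genes`).
#' @export
write_gmt <- function(library, path) {
  lines <- purrr::pmap_chr(library[, c("term", "namespace", "genes")],
                           function(term, namespace, genes) {
    paste(c(term, namespace, unique(genes)), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname msc_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    abort_data(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  }
  out <- tibble::tibble(
    term = vapply(parts, `[[`, character(1), 1L),
    namespace = vapply(parts, `[[`, character(1), 2L),
    genes = purrr::map(parts, function(p) unique(p[-(1:2)]))
  )
  if (anyDuplicated(out$term)) abort_data("duplicate term names in GMT")
  structure(out, class = c("geneset_library", class(out)))
}

#' @rdname msc_io
#' @param edges Edge tibble `gene_a`, `gene_b`, `weight`.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges[, c("gene_a", "gene_b", "weight")], path)
  invisible(path)
}

#' @rdname msc_io
#' @param genes Character vector of gene ids.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
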