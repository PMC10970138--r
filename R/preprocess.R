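#' Log2-transform raw intensities
#'
#' Applies `log2(x + 1)` elementwise unless the matrix is already on the log
#' scale, in which case it is returned unchanged. Negative raw intensities
#' are a data error and are reported by gene and sample.
#'
#' @param mat Genes-by-samples numeric matrix.
#' @param already_logged Is the matrix already log2-scale?
#' @return Matrix on the log2 scale.
#' @export
#' @examples
#' log2_transform(matrix(c(0, 1, 3, 7), 2, dimnames = list(c("g1", "g2"), NULL)))
log2_transform <- function(mat, already_logged = FALSE) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (already_logged) return(mat)
  if (any(mat < 0, na.rm = TRUE)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1, ]
    abort_data(sprintf(
      "negative intensity for gene '%s', sample '%s'; raw intensities must be >= 0",
      rownames(mat)[idx[1]] %||% as.character(idx[1]),
      colnames(mat)[idx[2]] %||% as.character(idx[2])
    ))
  }
  log2(mat + 1)
}

#' Quantile-normalize a log2 expression matrix
#'
#' Forces every sample (column) onto the identical empirical distribution:
#' after normalization, the sorted values of each column equal the
#' across-column means of the order statistics. Ties within a column receive
#' the mean of the reference values at the tied positions. The operation is
#' idempotent.
#'
#' @param mat Genes-by-samples numeric matrix with no missing values.
#' @return Matrix of the same shape; a single-column matrix is returned
#'   unchanged with a warning.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (anyNA(mat)) abort_data("quantile normalization requires a complete matrix")
  if (ncol(mat) < 2) {
    rlang::warn("single-column matrix: quantile normalization is a no-op")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Collapse many-to-one probe rows to gene rows
#'
#' Summarizes all probe rows mapping to a gene into one row. Probes without
#' a mapping are dropped (their count is reported via a message and the
#' `n_unmapped` attribute). Each probe may map to at most one gene.
#'
#' @param mat Probes-by-samples numeric matrix with probe rownames.
#' @param probe_to_gene Mapping: a data frame with columns `probe`, `gene`,
#'   or a named character vector (names = probes, values = genes).
#' @param strategy How to summarize multi-probe genes: `"mean"` (default)
#'   or `"median"` of the probe rows per sample, or `"max-mean-probe"`
#'   (keep verbatim the probe row with the highest overall mean).
#' @return Genes-by-samples matrix; one row per distinct mapped gene.
#' @export
#' @examples
#' m <- matrix(c(1, 3, 3, 5), 2, byrow = TRUE,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' collapse_probes(m, c(p1 = "gA", p2 = "gA"))
collapse_probes <- function(mat, probe_to_gene,
                            strategy = c("mean", "median", "max-mean-probe")) {
  strategy <- match.arg(strategy)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene$gene),
                           as.character(probe_to_gene$probe))
  } else {
    map <- probe_to_gene
  }
  if (length(map) == 0) abort_config("empty probe-to-gene mapping")
  if (anyDuplicated(names(map))) {
    abort_data("a probe maps to more than one gene")
  }
  mapped <- intersect(rownames(mat), names(map))
  n_unmapped <- nrow(mat) - length(mapped)
  if (n_unmapped > 0) {
    rlang::inform(sprintf("dropping %d unmapped probe(s)", n_unmapped))
  }
  m <- mat[mapped, , drop = FALSE]
  gene <- map[mapped]
  out <- switch(strategy,
    mean = {
      s <- rowsum(m, gene)
      s / as.vector(table(gene)[rownames(s)])
    },
    median = {
      genes <- sort(unique(gene))
      t(vapply(genes, function(g) {
        apply(m[gene == g, , drop = FALSE], 2, stats::median)
      }, numeric(ncol(m))))
    },
    `max-mean-probe` = {
      genes <- sort(unique(gene))
      picked <- vapply(genes, function(g) {
        rows <- which(gene == g)
        rows[which.max(rowMeans(m[rows, , drop = FALSE]))]
      }, integer(1))
      out <- m[picked, , drop = FALSE]
      rownames(out) <- genes
      out
    }
  )
  out <- out[sort(unique(gene)), , drop = FALSE]
  colnames(out) <- colnames(mat)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Normalize every dataset of a study in place
#'
#' Convenience wrapper applying background correction (a no-op unless a
#' function is supplied — synthetic data is generated background-free),
#' [log2_transform()] and [quantile_normalize()] to each dataset matrix.
#'
#' @param datasets Named list of `expression_dataset` objects.
#' @param already_logged Are the matrices already log2-scale?
#' @param background_correct Optional function `matrix -> matrix` applied
#'   to the raw matrix before the log transform.
#' @return The list with normalized matrices.
#' @export
preprocess_datasets <- function(datasets, already_logged = TRUE,
                                background_correct = NULL) {
  purrr::map(datasets, function(ds) {
    m <- ds$matrix
    if (!is.null(background_correct)) m <- background_correct(m)
    ds$matrix <- quantile_normalize(log2_transform(m, already_logged))
    ds
  })
}
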