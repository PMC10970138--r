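#' Configuration for the Rank Product test
#'
#' @param alpha Significance threshold on q-values (DEG call: q < alpha).
#' @param n_permutations Number of label permutations for the pooled null
#'   (>= 50 for reportable q-values).
#' @param max_pairs Cap on the number of case-control sample pairs used; when
#'   the full grid exceeds it, a seeded uniform subsample of pairs is taken.
#' @param seed Integer seed for pair subsampling and permutations.
#' @return An `rp_config` list.
#' @export
#' @examples
#' rp_config(alpha = 0.05, n_permutations = 200)
rp_config <- function(alpha = 0.05, n_permutations = 200, max_pairs = 400,
                      seed = 1L) {
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_number(n_permutations, "n_permutations", lower = 1)
  if (n_permutations < 50) {
    rlang::warn("fewer than 50 permutations: q-values will be coarse")
  }
  check_scalar_number(max_pairs, "max_pairs", lower = 1)
  check_scalar_number(seed, "seed")
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 max_pairs = max_pairs, seed = as.integer(seed)),
            class = "rp_config")
}

# average-rank column ranking; rank_up = G + 1 - rank_down holds under
# average ties, so one pass serves both orientations
col_ranks <- function(m) {
  r <- m
  for (j in seq_len(ncol(m))) r[, j] <- rank(m[, j])
  r
}

# fixed case-control pair grid, subsampled once when it exceeds max_pairs
choose_pairs <- function(n_case, n_control, max_pairs = Inf) {
  ci <- rep(seq_len(n_case), each = n_control)
  hi <- rep(seq_len(n_control), times = n_case)
  k <- length(ci)
  if (k > max_pairs) {
    keep <- sample.int(k, max_pairs)
    ci <- ci[keep]
    hi <- hi[keep]
  }
  list(case = ci, control = hi)
}

#' Per-pair rank matrix for the two-sample Rank Product
#'
#' For every (case, control) sample pair, genes are ranked by the per-gene
#' expression difference: orientation `"up"` gives rank 1 to the most
#' up-regulated gene (largest difference), `"down"` to the most
#' down-regulated. Ties receive average ranks.
#'
#' @param case_matrix,control_matrix Genes-by-samples matrices over the same
#'   gene rows.
#' @param orientation `"up"` or `"down"`.
#' @param max_pairs Cap on the pair grid (seeded subsample beyond it).
#' @param seed Optional seed for the pair subsample; `NULL` uses the current
#'   RNG state.
#' @return Genes-by-pairs matrix of ranks.
#' @export
#' @examples
#' ca <- matrix(c(3, 1.5, 0), 3, dimnames = list(c("g1", "g2", "g3"), "c1"))
#' co <- matrix(c(1, 1, 1), 3, dimnames = list(c("g1", "g2", "g3"), "h1"))
#' pairwise_rank_matrix(ca, co, "up")
pairwise_rank_matrix <- function(case_matrix, control_matrix,
                                 orientation = c("up", "down"),
                                 max_pairs = Inf, seed = NULL) {
  orientation <- match.arg(orientation)
  if (!identical(rownames(case_matrix), rownames(control_matrix))) {
    abort_data("case and control matrices must share identical gene rows")
  }
  run <- function() {
    p <- choose_pairs(ncol(case_matrix), ncol(control_matrix), max_pairs)
    d <- case_matrix[, p$case, drop = FALSE] -
      control_matrix[, p$control, drop = FALSE]
    r <- col_ranks(d)
    if (orientation == "up") r <- nrow(d) + 1 - r
    colnames(r) <- NULL
    r
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Rank Product statistic
#'
#' Geometric mean of a gene's ranks across case-control pairs, computed in
#' log space for numerical stability. Rank 1 in every pair gives the best
#' possible value, 1.
#'
#' @param ranks Genes-by-pairs matrix of positive ranks.
#' @return Numeric vector of rank products, one per gene.
#' @export
#' @examples
#' rank_product(cbind(c(1, 3), c(2, 2)))
rank_product <- function(ranks) {
  ranks <- as.matrix(ranks)
  if (ncol(ranks) < 1) abort_data("need at least one pair of ranks")
  if (any(ranks <= 0)) abort_data("ranks must be positive")
  exp(rowMeans(log(ranks)))
}

#' Permutation p-values for the Rank Product, pooled across genes
#'
#' Shuffles group labels over the pooled samples `n_permutations` times,
#' recomputes the rank product for every gene in both orientations, and
#' reports the plus-one-corrected pooled empirical tail:
#' `p_g = (1 + #\{(b, g') : rp*_\{g'b\} <= rp_g\}) / (1 + B * G)`.
#' Permuted values equal to the observed one up to a 1e-9 relative
#' tolerance count as ties, so the tail count does not depend on
#' floating-point evaluation order. With `exhaustive = TRUE` all distinct
#' case/control relabelings are enumerated instead of sampled (feasible
#' for small designs).
#'
#' @inheritParams pairwise_rank_matrix
#' @param config An [rp_config()].
#' @param exhaustive Enumerate all `choose(n, n_case)` relabelings?
#' @return A tibble with per-gene `gene`, `rp_up`, `rp_down`, `p_up`,
#'   `p_down`.
#' @export
rp_permutation_pvalues <- function(case_matrix, control_matrix,
                                   config = rp_config(),
                                   exhaustive = FALSE) {
  if (!identical(rownames(case_matrix), rownames(control_matrix))) {
    abort_data("case and control matrices must share identical gene rows")
  }
  n_case <- ncol(case_matrix)
  n_control <- ncol(control_matrix)
  if (n_case < 1 || n_control < 1) abort_data("need >= 1 case and >= 1 control")
  g <- nrow(case_matrix)
  pool <- cbind(case_matrix, control_matrix)
  n <- ncol(pool)

  withr::with_seed(config$seed, {
    pairs <- choose_pairs(n_case, n_control, config$max_pairs)
    rp_of <- function(cs, ct) {
      d <- cs[, pairs$case, drop = FALSE] - ct[, pairs$control, drop = FALSE]
      r_down <- col_ranks(d)
      list(down = exp(rowMeans(log(r_down))),
           up = exp(rowMeans(log(g + 1 - r_down))))
    }
    obs <- rp_of(case_matrix, control_matrix)
    if (exhaustive) {
      sel <- utils::combn(n, n_case)
      b <- ncol(sel)
    } else {
      b <- config$n_permutations
      sel <- vapply(seq_len(b), function(i) sample.int(n, n_case), integer(n_case))
      sel <- matrix(sel, nrow = n_case)
    }
    null_up <- vector("list", b)
    null_down <- vector("list", b)
    for (i in seq_len(b)) {
      idx <- sel[, i]
      rp <- rp_of(pool[, idx, drop = FALSE], pool[, -idx, drop = FALSE])
      null_up[[i]] <- rp$up
      null_down[[i]] <- rp$down
    }
  })
  null_up <- sort(unlist(null_up, use.names = FALSE))
  null_down <- sort(unlist(null_down, use.names = FALSE))
  denom <- 1 + as.numeric(b) * g
  # rank products of different rank multisets can be mathematically equal
  # (2*3 = 1*6); a small relative tolerance makes the tie count invariant
  # to floating-point evaluation order
  tail_count <- function(obs, null_sorted) {
    findInterval(obs * (1 + 1e-9), null_sorted)
  }
  tibble::tibble(
    gene = rownames(case_matrix) %||% sprintf("g%d", seq_len(g)),
    rp_up = unname(obs$up),
    rp_down = unname(obs$down),
    p_up = (1 + tail_count(obs$up, null_up)) / denom,
    p_down = (1 + tail_count(obs$down, null_down)) / denom
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: sort p ascending, `q_(i) = min_(j>=i) m p_(j)/j`
#' clipped to 1, returned in the input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort_data("p-values must be numbers in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differential-expression directions from q-values
#'
#' A gene is `up` when `q_up < alpha` and `q_up <= q_down`, `down` when
#' `q_down < alpha` and `q_down < q_up`, otherwise `ns`. A gene significant
#' in both orientations with identical q-values is called `up` (documented
#' deterministic tie rule; the downstream selection focuses on
#' up-regulation). No fold-change filter is applied.
#'
#' @param deg_table Tibble with columns `q_up` and `q_down`.
#' @param alpha Significance threshold.
#' @return The table with a `direction` column added.
#' @export
call_degs <- function(deg_table, alpha = 0.05) {
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  dplyr::mutate(deg_table, direction = dplyr::case_when(
    .data$q_up < alpha & .data$q_up <= .data$q_down ~ "up",
    .data$q_down < alpha & .data$q_down < .data$q_up ~ "down",
    TRUE ~ "ns"
  ))
}

#' Two-sample Rank Product differential expression test
#'
#' Runs the full Rank Product analysis for one dataset and contrast:
#' all case-control pairwise expression differences are ranked per pair in
#' both orientations, the per-gene geometric mean rank (the rank product) is
#' compared against a pooled label-permutation null, and
#' Benjamini-Hochberg q-values are computed per orientation. Because the
#' statistic is rank-based it is invariant under monotone transforms of the
#' expression values. The log2 fold change (mean case minus mean control)
#' accompanies each call as the authoritative direction report.
#'
#' @param dataset An `expression_dataset` (see [generate_study()]), or a
#'   plain genes-by-samples matrix together with `groups`.
#' @param contrast Length-2 character: case group, control group (e.g.
#'   `c("SPMS", "HC")`).
#' @param config An [rp_config()].
#' @param groups Optional sample group vector when `dataset` is a matrix.
#' @return An `rp_dea` object; `tidy()` returns the per-gene table with
#'   columns `gene`, `log2fc`, `rp_up`, `rp_down`, `p_up`, `p_down`,
#'   `q_up`, `q_down`, `direction`.
#' @export
#' @examples
#' study <- generate_study(study_design(seed = 7))
#' fit <- rank_product_test(study$datasets$brain1, c("SPMS", "HC"),
#'                          rp_config(n_permutations = 50, seed = 1))
#' glance(fit)
rank_product_test <- function(dataset, contrast = c("SPMS", "HC"),
                              config = rp_config(), groups = NULL) {
  if (inherits(dataset, "expression_dataset")) {
    mat <- dataset$matrix
    groups <- dataset$samples$group
    dataset_id <- dataset$dataset_id
    tissue <- dataset$tissue
  } else {
    mat <- dataset
    if (is.null(groups)) abort_config("`groups` is required for a plain matrix")
    dataset_id <- "dataset"
    tissue <- NA_character_
  }
  stopifnot(length(contrast) == 2)
  case <- mat[, groups == contrast[1], drop = FALSE]
  control <- mat[, groups == contrast[2], drop = FALSE]
  if (ncol(case) < 2 || ncol(control) < 2) {
    abort_data(sprintf("need >= 2 samples per group for contrast %s vs %s",
                       contrast[1], contrast[2]))
  }
  tab <- rp_permutation_pvalues(case, control, config)
  tab <- dplyr::mutate(tab,
    log2fc = rowMeans(case) - rowMeans(control),
    q_up = bh_adjust(.data$p_up),
    q_down = bh_adjust(.data$p_down),
    .after = "gene"
  )
  tab <- call_degs(tab, config$alpha)
  tab <- tab[, c("gene", "log2fc", "rp_up", "rp_down", "p_up", "p_down",
                 "q_up", "q_down", "direction")]
  structure(
    list(table = tab, dataset_id = dataset_id, tissue = tissue,
         contrast = contrast, config = config),
    class = "rp_dea"
  )
}

#' @export
print.rp_dea <- function(x, ...) {
  n <- table(factor(x$table$direction, c("up", "down", "ns")))
  cat(sprintf("<rp_dea> %s (%s), %s vs %s: %d genes, %d up / %d down at q < %g\n",
              x$dataset_id, x$tissue, x$contrast[1], x$contrast[2],
              nrow(x$table), n[["up"]], n[["down"]], x$config$alpha))
  invisible(x)
}
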