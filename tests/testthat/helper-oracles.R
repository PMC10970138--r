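# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the package's code paths: plain loops, direct
# formulas, no shared helpers.

# Exhaustive two-sample rank-product p-values: enumerate every distinct
# case/control relabeling, compute the rank product as prod(ranks)^(1/K),
# and take the plus-one-corrected pooled tail.
oracle_exhaustive_rp_p <- function(case, control) {
  g <- nrow(case)
  nc <- ncol(case)
  pool <- cbind(case, control)
  n <- ncol(pool)
  nh <- n - nc
  rp_for <- function(cs, ct) {
    K <- ncol(cs) * ncol(ct)
    ru <- matrix(0, g, K)
    rd <- matrix(0, g, K)
    k <- 0
    for (ci in seq_len(ncol(cs))) {
      for (hi in seq_len(ncol(ct))) {
        k <- k + 1
        d <- cs[, ci] - ct[, hi]
        rd[, k] <- rank(d)
        ru[, k] <- rank(-d)
      }
    }
    list(up = apply(ru, 1, function(r) prod(r)^(1 / K)),
         down = apply(rd, 1, function(r) prod(r)^(1 / K)))
  }
  obs <- rp_for(case, control)
  sel <- combn(n, nc)
  b <- ncol(sel)
  null_up <- numeric(0)
  null_down <- numeric(0)
  for (i in seq_len(b)) {
    rp <- rp_for(pool[, sel[, i], drop = FALSE], pool[, -sel[, i], drop = FALSE])
    null_up <- c(null_up, rp$up)
    null_down <- c(null_down, rp$down)
  }
  # ties (equal rank products from different relabelings) are counted with
  # the same relative tolerance the package documents
  list(
    p_up = vapply(obs$up, function(x) {
      (1 + sum(null_up <= x * (1 + 1e-9))) / (1 + b * g)
    }, numeric(1)),
    p_down = vapply(obs$down, function(x) {
      (1 + sum(null_down <= x * (1 + 1e-9))) / (1 + b * g)
    }, numeric(1)),
    n_relabelings = b
  )
}

# Direct combinatorial-sum upper-tail hypergeometric probability.
oracle_hypergeom_p <- function(k, K, n, N) {
  i <- seq(k, min(K, n))
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Literal Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}

# Union-find connected components over a node set and an edge list
# (data.frame with columns a, b). Returns a list of sorted member vectors.
oracle_components <- function(nodes, edges) {
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      ia <- find(match(edges$a[r], nodes))
      ib <- find(match(edges$b[r], nodes))
      if (ia != ib) parent[[ia]] <- ib
    }
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  unname(lapply(split(nodes, roots), sort))
}

# Largest component with the package's documented tie-break, recomputed
# independently from the oracle components.
oracle_largest_component <- function(comps) {
  sizes <- lengths(comps)
  big <- comps[sizes == max(sizes)]
  keys <- vapply(big, paste, character(1), collapse = "\r")
  big[[order(keys)[1]]]
}

# Small labeled matrix fixtures ------------------------------------------

make_dataset <- function(n_genes = 30, n_spms = 5, n_rrms = 0, n_hc = 5,
                         tissue = "blood", effect_genes = character(0),
                         effect = 0, noise_sd = 0.5, seed = 1,
                         dataset_id = "ds1") {
  groups <- c(rep("SPMS", n_spms), rep("RRMS", n_rrms), rep("HC", n_hc))
  genes <- sprintf("G%04d", seq_len(n_genes))
  m <- withr::with_seed(seed, {
    base <- runif(n_genes, 4, 12)
    mm <- base + matrix(rnorm(n_genes * length(groups), sd = noise_sd),
                        n_genes, length(groups))
    mm[genes %in% effect_genes, groups == "SPMS"] <-
      mm[genes %in% effect_genes, groups == "SPMS"] + effect
    mm
  })
  dimnames(m) <- list(genes, sprintf("s%02d", seq_along(groups)))
  structure(
    list(dataset_id = dataset_id, tissue = tissue, matrix = m,
         samples = tibble::tibble(sample_id = colnames(m), group = groups)),
    class = "expression_dataset"
  )
}

# Long DEG tibble shorthand for consensus tests: spec like
# list(b1 = c(tissue = "brain", gA = "up", gB = "ns"), ...)
deg_long <- function(spec) {
  purrr::imap_dfr(spec, function(x, id) {
    tibble::tibble(
      dataset_id = id,
      tissue = x[["tissue"]],
      gene = setdiff(names(x), "tissue"),
      direction = unname(x[setdiff(names(x), "tissue")])
    )
  })
}

fast_rp <- function(seed = 1, B = 100) rp_config(n_permutations = B, seed = seed)

# Memoized default pipeline runs so several test files can share one
# (deterministic) end-to-end result without re-running the pipeline.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(seed) {
  key <- as.character(seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_pipeline(
      pipeline_config(design = study_design(seed = seed), seed = seed))
  }
  .run_cache[[key]]
}
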