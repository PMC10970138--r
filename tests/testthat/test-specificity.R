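test_that("RRMS consensus applies the 75% blood rule", {
  long <- deg_long(list(
    r1 = c(tissue = "blood", g1 = "up", g2 = "up", g3 = "down"),
    r2 = c(tissue = "blood", g1 = "up", g2 = "up", g3 = "down"),
    r3 = c(tissue = "blood", g1 = "up", g2 = "ns", g3 = "down"),
    r4 = c(tissue = "blood", g1 = "ns", g2 = "ns", g3 = "up")
  ))
  out <- rrms_consensus(long)
  expect_equal(out$rrms_direction[out$gene == "g1"], "up")    # 3/4
  expect_equal(out$rrms_direction[out$gene == "g2"], "none")  # 2/4
  expect_equal(out$rrms_direction[out$gene == "g3"], "down")  # 3/4
  # brain tables are rejected
  brain <- deg_long(list(b1 = c(tissue = "brain", g1 = "up")))
  expect_error(rrms_consensus(brain), class = "msc_config_error")
  # empty input: no directions
  empty <- tibble::tibble(dataset_id = character(), tissue = character(),
                          gene = character(), direction = character())
  expect_equal(nrow(rrms_consensus(empty)), 0)
})

test_that("the partition is exact and categories follow the direction algebra", {
  target <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    spms_direction = c("up", "up", "up", "down")
  )
  rrms <- tibble::tibble(
    gene = c("a", "b", "d"),
    rrms_direction = c("up", "down", "none")
  )
  expect_message(part <- partition_by_rrms(target, rrms), "absent")
  expect_equal(nrow(part), 4)
  got <- setNames(part$category, part$gene)
  expect_equal(got[["a"]], "same")
  expect_equal(got[["b"]], "opposite")
  expect_equal(got[["c"]], "specific")  # missing from RRMS -> none
  expect_equal(got[["d"]], "specific")
  n <- table(part$category)
  expect_equal(sum(n), nrow(part))
  expect_setequal(candidate_genes(part), c("b", "c", "d"))
  g <- glance(part)
  expect_equal(g$n_same + g$n_opposite + g$n_specific, g$n_genes)
})

test_that("partition exactness holds on random inputs", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(1:40, 1)
      target <- tibble::tibble(
        gene = sprintf("g%02d", seq_len(n)),
        spms_direction = sample(c("up", "down"), n, replace = TRUE)
      )
      m <- sample(0:n, 1)
      rrms <- tibble::tibble(
        gene = sample(target$gene, m),
        rrms_direction = sample(c("up", "down", "none"), m, replace = TRUE)
      )
    })
    part <- suppressMessages(partition_by_rrms(target, rrms))
    n_cat <- table(factor(part$category, c("same", "opposite", "specific")))
    expect_equal(unname(sum(n_cat)), nrow(target))
    expect_setequal(part$gene, target$gene)
  }
})

test_that("with no RRMS signal every target gene is a candidate", {
  target <- tibble::tibble(gene = c("a", "b"), spms_direction = c("up", "up"))
  rrms <- tibble::tibble(gene = c("a", "b"), rrms_direction = c("none", "none"))
  part <- partition_by_rrms(target, rrms)
  expect_true(all(part$category == "specific"))
  expect_equal(candidate_genes(part), c("a", "b"))
})

test_that("planted classes land in the right partition categories", {
  run <- cached_run(42)
  part <- run$partitions$rulu
  truth <- run$truth
  cls <- setNames(truth$class, truth$gene)[part$gene]
  acc <- function(category, class) {
    got <- part$category[cls == class]
    if (!length(got)) return(NA_real_)
    mean(got == category)
  }
  expect_gte(acc("specific", "spms_up_specific"), 0.8)
  same_acc <- acc("same", "shared_up")
  if (!is.na(same_acc)) expect_gte(same_acc, 0.5)
  opp_acc <- acc("opposite", "opposite")
  if (!is.na(opp_acc)) expect_gte(opp_acc, 0.5)
})

test_that("the three-layer comparison recovers the seeded process and degenerates safely", {
  universe <- sprintf("U%03d", 1:80)
  spec_genes <- universe[1:10]
  shared_genes <- universe[11:20]
  lib <- tibble::tibble(
    term = c("spec_bp", "shared_bp", "noise_bp"),
    namespace = "BP",
    genes = list(spec_genes, shared_genes, universe[41:60])
  )
  mk_part <- function(spec, shared) {
    suppressMessages(partition_by_rrms(
      tibble::tibble(gene = c(spec, shared),
                     spms_direction = "up"),
      tibble::tibble(gene = shared, rrms_direction = "up")
    ))
  }
  parts <- list(
    clup = mk_part(spec_genes[1:8], shared_genes[1:8]),
    rulu = mk_part(spec_genes, shared_genes),
    all = mk_part(spec_genes, shared_genes)
  )
  res <- layered_bp_comparison(parts, lib, universe, alpha = 0.05)
  expect_equal(res$final, "spec_bp")
  expect_false("shared_bp" %in% res$final)
  # identical specific and shared sets: every difference empty
  same <- partition_by_rrms(
    tibble::tibble(gene = spec_genes, spms_direction = "up"),
    tibble::tibble(gene = spec_genes, rrms_direction = "up"))
  degenerate <- suppressMessages(layered_bp_comparison(
    list(clup = same, rulu = same, all = same), lib, universe))
  expect_length(degenerate$final, 0)
  # empty shared side: final equals the intersection of specific enrichments
  all_spec <- partition_by_rrms(
    tibble::tibble(gene = spec_genes, spms_direction = "up"),
    tibble::tibble(gene = spec_genes, rrms_direction = "none"))
  open <- suppressMessages(layered_bp_comparison(
    list(clup = all_spec, rulu = all_spec, all = all_spec), lib, universe))
  expect_equal(open$final, "spec_bp")
  # union and per-layer modes
  uni <- layered_bp_comparison(parts, lib, universe, layer_rule = "union")
  expect_true("spec_bp" %in% uni$final)
  per <- layered_bp_comparison(parts, lib, universe, layer_rule = "per-layer")
  expect_null(per$final)
})

test_that("the final BP set shrinks or stays equal as alpha decreases", {
  run <- cached_run(42)
  lib <- generate_geneset_library(run$truth, seed = derive_seeds(42, c(
    "simulate", "library", "graph", "dea", "rrms_dea"))[["library"]])
  universe <- intersect(run$truth$gene, unique(unlist(lib$genes)))
  loose <- suppressMessages(layered_bp_comparison(run$partitions, lib, universe,
                                                  alpha = 0.05))
  tight <- suppressMessages(layered_bp_comparison(run$partitions, lib, universe,
                                                  alpha = 0.01))
  expect_true(all(tight$final %in% loose$final))
})
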