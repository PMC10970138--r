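test_that("study generation is deterministic under a fixed seed", {
  design <- study_design(n_genes = 60, seed = 7,
                         n_per_class = c(spms_up_specific = 5))
  s1 <- generate_study(design)
  s2 <- generate_study(design)
  expect_identical(s1$datasets$brain1$matrix, s2$datasets$brain1$matrix)
  expect_identical(
    purrr::map(s1$datasets, "matrix"),
    purrr::map(s2$datasets, "matrix")
  )
  expect_identical(s1$truth, s2$truth)
})

test_that("planted truth partitions the gene universe with the requested counts", {
  truth <- planted_truth(100, n_per_class = c(spms_up_specific = 10,
                                              shared_up = 4, opposite = 2),
                         seed = 3)
  expect_equal(nrow(truth), 100)
  counts <- table(truth$class)
  expect_equal(unname(counts[["spms_up_specific"]]), 10)
  expect_equal(unname(counts[["shared_up"]]), 4)
  expect_equal(unname(counts[["opposite"]]), 2)
  expect_equal(unname(counts[["null"]]), 84)
  # signed shifts follow the class semantics
  expect_true(all(truth$spms_shift[truth$class == "opposite"] > 0))
  expect_true(all(truth$rrms_shift[truth$class == "opposite"] < 0))
  expect_true(all(truth$rrms_shift[truth$class == "spms_up_specific"] == 0))
})

test_that("invalid designs are rejected with configuration errors", {
  expect_error(study_design(n_genes = 10), class = "msc_config_error")
  expect_error(study_design(noise_sd = 0), class = "msc_config_error")
  bad_arm <- tibble::tibble(dataset_id = c("b", "l"),
                            tissue = c("brain", "blood"),
                            n_spms = c(1L, 5L), n_rrms = c(0L, 0L),
                            n_hc = c(5L, 5L), batch_scale = c(1, 1))
  expect_error(study_design(datasets = bad_arm), class = "msc_config_error")
  no_brain <- dplyr::mutate(bad_arm, tissue = "blood", n_spms = 5L)
  expect_error(study_design(datasets = no_brain), class = "msc_config_error")
  rrms_in_brain <- dplyr::mutate(bad_arm, n_spms = 5L, n_rrms = c(5L, 0L))
  expect_error(study_design(datasets = rrms_in_brain), class = "msc_config_error")
})

test_that("zero effect size makes planted genes indistinguishable from null", {
  design <- study_design(n_genes = 100, seed = 11, effect_size = 0,
                         n_per_class = c(spms_up_specific = 20))
  study <- generate_study(design)
  fit <- rank_product_test(study$datasets$blood1, c("SPMS", "HC"), fast_rp(5))
  tab <- tidy(fit)
  planted <- study$truth$gene[study$truth$class != "null"]
  rate_planted <- mean(tab$direction[tab$gene %in% planted] != "ns")
  rate_null <- mean(tab$direction[!tab$gene %in% planted] != "ns")
  # both at (or below) the type-I level
  expect_lte(rate_planted, 0.1)
  expect_lte(abs(rate_planted - rate_null), 0.1)
})

test_that("planted classes are recoverable by an oracle t-test at large n", {
  arms <- tibble::tibble(
    dataset_id = c("brain1", "blood1"), tissue = c("brain", "blood"),
    n_spms = c(40L, 40L), n_rrms = c(0L, 40L), n_hc = c(40L, 40L),
    batch_scale = c(1, 1)
  )
  design <- study_design(n_genes = 100, datasets = arms, seed = 5,
                         n_per_class = c(spms_up_specific = 8,
                                         spms_down_specific = 4))
  study <- generate_study(design)
  m <- study$datasets$blood1$matrix
  g <- study$datasets$blood1$samples$group
  p <- apply(m, 1, function(x) stats::t.test(x[g == "SPMS"], x[g == "HC"])$p.value)
  fc <- rowMeans(m[, g == "SPMS"]) - rowMeans(m[, g == "HC"])
  q <- p.adjust(p, "BH")
  up <- study$truth$gene[study$truth$class == "spms_up_specific"]
  dn <- study$truth$gene[study$truth$class == "spms_down_specific"]
  expect_true(all(q[up] < 0.05 & fc[up] > 0))
  expect_true(all(q[dn] < 0.05 & fc[dn] < 0))
})

test_that("batch scale shifts a whole dataset on the log2 scale", {
  truth <- planted_truth(60, n_per_class = c(), seed = 2)
  arms <- tibble::tibble(
    dataset_id = c("brain1", "blood1"), tissue = c("brain", "blood"),
    n_spms = c(5L, 5L), n_rrms = c(0L, 0L), n_hc = c(5L, 5L),
    batch_scale = c(1, 4)
  )
  study <- generate_study(study_design(n_genes = 60, datasets = arms,
                                       planted = truth, seed = 2,
                                       noise_sd = 0.1))
  gap <- mean(study$datasets$blood1$matrix) - mean(study$datasets$brain1$matrix)
  expect_equal(gap, log2(4), tolerance = 0.1)
})

test_that("gene-set library generation seeds known positives and round-trips GMT", {
  truth <- planted_truth(200, seed = 1)
  lib <- generate_geneset_library(truth, n_sets = 12, enriched_sets = 2, seed = 4)
  expect_equal(nrow(lib), 12)
  enr <- attr(lib, "enriched_terms")
  expect_length(enr, 2)
  specific <- truth$gene[truth$class == "spms_up_specific"]
  for (tm in enr) {
    genes <- lib$genes[[match(tm, lib$term)]]
    expect_gte(mean(genes %in% specific), 0.5)
  }
  expect_error(generate_geneset_library(truth, n_sets = 0),
               class = "msc_config_error")
  expect_error(generate_geneset_library(truth, set_size_range = c(10, 500)),
               class = "msc_config_error")
  # GMT write-then-read returns the identical library content
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(lib, path)
  back <- read_gmt(path)
  expect_equal(back$term, lib$term)
  expect_equal(back$namespace, lib$namespace)
  expect_equal(back$genes, lib$genes)
})

test_that("duplicate genes inside a GMT set are deduplicated on write", {
  lib <- tibble::tibble(term = "T1", namespace = "BP",
                        genes = list(c("A", "B", "A")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(lib, path)
  expect_equal(read_gmt(path)$genes[[1]], c("A", "B"))
})

test_that("interaction graph construction plants the promised module", {
  truth <- planted_truth(80, n_per_class = c(spms_up_specific = 10), seed = 9)
  specific <- truth$gene[truth$class == "spms_up_specific"]
  # no background: the module is the only structure
  edges <- generate_interaction_graph(truth, background_edge_prob = 0, seed = 2)
  expect_setequal(unique(c(edges$gene_a, edges$gene_b)), specific)
  expect_true(all(edges$weight >= 0.7))
  clu <- extract_subcluster(interaction_graph(edges), truth$gene, 0.4)
  expect_setequal(clu, specific)
  # full background: complete graph at cutoff 0
  full <- generate_interaction_graph(truth, clique_on_specific = FALSE,
                                     background_edge_prob = 1, seed = 2)
  expect_equal(nrow(full), choose(80, 2))
})

test_that("study round-trips through the TSV layout", {
  design <- study_design(n_genes = 60, seed = 13,
                         n_per_class = c(spms_up_specific = 5))
  study <- generate_study(design)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  back <- read_study(dir)
  expect_equal(names(back$datasets), names(study$datasets))
  expect_equal(back$datasets$blood2$matrix, study$datasets$blood2$matrix,
               tolerance = 1e-12)
  expect_equal(back$datasets$blood2$samples$group,
               study$datasets$blood2$samples$group)
  expect_equal(back$truth$class, study$truth$class)
})
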