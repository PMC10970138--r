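test_that("pairwise rank matrix ranks differences per orientation with average ties", {
  ca <- matrix(c(3, 1.5, 0), 3, dimnames = list(c("g1", "g2", "g3"), "c1"))
  co <- matrix(c(1, 1, 1), 3, dimnames = list(c("g1", "g2", "g3"), "h1"))
  # differences are [2.0, 0.5, -1.0]
  expect_equal(unname(pairwise_rank_matrix(ca, co, "up")[, 1]), c(1, 2, 3))
  expect_equal(unname(pairwise_rank_matrix(ca, co, "down")[, 1]), c(3, 2, 1))
  # two genes tied at d = 0.5 occupying positions 2 and 3
  ca2 <- matrix(c(3, 1.5, 1.5), 3, dimnames = list(paste0("g", 1:3), "c1"))
  co2 <- matrix(c(1, 1, 1), 3, dimnames = list(paste0("g", 1:3), "h1"))
  expect_equal(unname(pairwise_rank_matrix(ca2, co2, "up")[, 1]), c(1, 2.5, 2.5))
  # orientation antisymmetry for a single pair without ties
  up <- pairwise_rank_matrix(ca, co, "up")
  down <- pairwise_rank_matrix(ca, co, "down")
  expect_equal(up + down, matrix(4, 3, 1, dimnames = dimnames(up)))
  # row mismatch is an error
  co_bad <- co
  rownames(co_bad) <- c("g1", "g2", "gX")
  expect_error(pairwise_rank_matrix(ca, co_bad, "up"), class = "msc_data_error")
})

test_that("the pair grid is capped by a seeded subsample", {
  ca <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(sprintf("g%d", 1:10), NULL))
  co <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(sprintf("g%d", 1:10), NULL))
  r <- pairwise_rank_matrix(ca, co, "up", max_pairs = 7, seed = 3)
  expect_equal(ncol(r), 7)
  expect_identical(r, pairwise_rank_matrix(ca, co, "up", max_pairs = 7, seed = 3))
})

test_that("rank product is the geometric mean of ranks", {
  expect_equal(rank_product(matrix(c(1, 2), 1)), sqrt(2))
  expect_equal(rank_product(matrix(c(5, 5, 5), 1)), 5)
  expect_equal(rank_product(matrix(rep(1, 8), 1)), 1)
  expect_error(rank_product(matrix(c(1, 0), 1)), class = "msc_data_error")
})

test_that("rank product depends on expression only through difference ranks", {
  ca <- withr::with_seed(31, matrix(rexp(20 * 4) + 1, 20, 4,
                                    dimnames = list(sprintf("g%d", 1:20), NULL)))
  co <- withr::with_seed(32, matrix(rexp(20 * 4) + 1, 20, 4,
                                    dimnames = list(sprintf("g%d", 1:20), NULL)))
  r1 <- pairwise_rank_matrix(ca, co, "up")
  # increasing affine transforms of the values leave every difference rank,
  # hence the statistic, unchanged
  r2 <- pairwise_rank_matrix(2.5 * ca + 7, 2.5 * co + 7, "up")
  expect_equal(rank_product(r2), rank_product(r1))
})

test_that("permutation p-values match the exhaustive relabeling oracle", {
  for (cfg in list(list(g = 5, nc = 3, nh = 3, seed = 1),
                   list(g = 8, nc = 4, nh = 4, seed = 2))) {
    ca <- withr::with_seed(cfg$seed,
      matrix(rnorm(cfg$g * cfg$nc), cfg$g,
             dimnames = list(sprintf("g%d", seq_len(cfg$g)), NULL)))
    co <- withr::with_seed(cfg$seed + 100,
      matrix(rnorm(cfg$g * cfg$nh), cfg$g,
             dimnames = list(sprintf("g%d", seq_len(cfg$g)), NULL)))
    got <- rp_permutation_pvalues(ca, co, rp_config(n_permutations = 50, seed = 9),
                                  exhaustive = TRUE)
    want <- oracle_exhaustive_rp_p(ca, co)
    expect_equal(got$p_up, want$p_up, tolerance = 1e-12)
    expect_equal(got$p_down, want$p_down, tolerance = 1e-12)
  }
})

test_that("the best observed rank product attains the boundary p-value", {
  # gene 1 is shifted so far up in every case sample that only the exact
  # observed labeling could reproduce its rank product; with C(16,8) =
  # 12870 relabelings and a fixed seed, none of the 200 sampled
  # permutations does, so its p sits exactly on the floor 1/(1 + B*G)
  g <- 20
  ca <- withr::with_seed(41, matrix(rnorm(g * 8), g,
                                    dimnames = list(sprintf("g%d", 1:g), NULL)))
  co <- withr::with_seed(42, matrix(rnorm(g * 8), g,
                                    dimnames = list(sprintf("g%d", 1:g), NULL)))
  ca[1, ] <- ca[1, ] + 1000
  res <- rp_permutation_pvalues(ca, co, rp_config(n_permutations = 200, seed = 2))
  expect_equal(res$rp_up[1], 1)  # rank 1 in every pair
  expect_equal(res$p_up[1], 1 / (1 + 200 * g))
  expect_equal(res$p_up[1], min(res$p_up))
})

test_that("null p-values are approximately uniform", {
  ks <- vapply(1:20, function(s) {
    ca <- withr::with_seed(s, matrix(rnorm(100 * 6), 100,
                                     dimnames = list(sprintf("g%d", 1:100), NULL)))
    co <- withr::with_seed(s + 500, matrix(rnorm(100 * 6), 100,
                                           dimnames = list(sprintf("g%d", 1:100), NULL)))
    res <- rp_permutation_pvalues(ca, co, rp_config(n_permutations = 200, seed = s))
    p <- res$p_up
    max(abs(seq_along(p) / length(p) - sort(p)))
  }, numeric(1))
  expect_lt(mean(ks), 0.1)
})

test_that("BH adjustment matches the hand-applied step-up on the worked example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(1), 1)
  expect_error(bh_adjust(c(0.1, 1.2)), class = "msc_data_error")
  expect_error(bh_adjust(c(0.1, NA)), class = "msc_data_error")
  # order equivariance
  p <- withr::with_seed(4, runif(50))
  perm <- withr::with_seed(5, sample(50))
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("DEG calls follow the q-threshold and the documented tie rule", {
  tab <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    q_up = c(0.01, 0.2, 0.01, 0.9),
    q_down = c(0.9, 0.2, 0.01, 0.01)
  )
  out <- call_degs(tab, 0.05)
  expect_equal(out$direction, c("up", "ns", "up", "down"))
})

test_that("rank_product_test detects a planted shift and reports coherent fields", {
  ds <- make_dataset(n_genes = 50, n_spms = 8, n_hc = 8,
                     effect_genes = sprintf("G%04d", 1:6), effect = 1.5,
                     noise_sd = 0.5, seed = 21)
  fit <- rank_product_test(ds, c("SPMS", "HC"), fast_rp(seed = 8, B = 100))
  tab <- tidy(fit)
  expect_named(tab, c("gene", "log2fc", "rp_up", "rp_down", "p_up", "p_down",
                      "q_up", "q_down", "direction"))
  expect_true(all(tab$p_up > 0 & tab$p_up <= 1))
  planted <- sprintf("G%04d", 1:6)
  expect_gte(mean(tab$direction[tab$gene %in% planted] == "up"), 0.5)
  expect_true(all(tab$log2fc[tab$gene %in% planted] > 0))
  g <- glance(fit)
  expect_equal(g$n_genes, 50)
  expect_equal(g$n_up + g$n_down, sum(tab$direction != "ns"))
  # two-sample guard
  expect_error(rank_product_test(ds, c("RRMS", "HC"), fast_rp()),
               class = "msc_data_error")
})
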