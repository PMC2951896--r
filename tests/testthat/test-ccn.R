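test_that("background sampling is seed-reproducible and skips degenerates", {
  m <- rand_expr(20, 6, 111)
  b1 <- background_correlations(m, 500, seed = 3)
  b2 <- background_correlations(m, 500, seed = 3)
  expect_identical(b1$samples, b2$samples)
  expect_true(all(b1$samples >= -1 & b1$samples <= 1))
  expect_equal(length(b1$samples) + b1$n_degenerate, 500)

  m2 <- m
  m2[5, ] <- 7
  b3 <- background_correlations(m2, 2000, seed = 1)
  expect_gt(b3$n_degenerate, 0)
  expect_equal(length(b3$samples) + b3$n_degenerate, 2000)

  m3 <- m[1:2, ]
  m3[1, ] <- 3
  expect_error(background_correlations(m3, 10, seed = 1), "non-constant")
})

test_that("background correlations match direct per-pair computation", {
  m <- rand_expr(15, 5, 112)
  bg <- background_correlations(m, 50, seed = 9)
  # redraw the same pairs with the same generator contract
  set.seed(9)
  i <- sample.int(15, 50, replace = TRUE)
  j0 <- sample.int(14, 50, replace = TRUE)
  j <- j0 + (j0 >= i)
  expect_true(all(i != j))
  direct <- vapply(seq_len(50), function(q) o_pearson(m[i[q], ], m[j[q], ]),
                   numeric(1))
  expect_equal(bg$samples, direct, tolerance = 1e-12)
})

test_that("background of independent noise genes is centered at zero", {
  cfg <- sim_config(k = 500, t_a = 20, t_b = 20, n_common = 20, m = 1,
                    p_cons = 1, noise_sd = 3, seed = 13)
  # with noise_sd >> module signal the profiles are essentially independent
  sim <- simulate_paired_expression(cfg)
  bg <- background_correlations(sim$paired$A, 20000, seed = 14)
  se <- sd(bg$samples) / sqrt(length(bg$samples))
  expect_lt(abs(mean(bg$samples)), 3 * se)
})

test_that("correlation threshold is the linear-interpolation quantile", {
  bg <- structure(list(samples = c(-1, 0, 1), n_pairs = 3L,
                       n_degenerate = 0L, seed = 1L, species_tag = ""),
                  class = "background_distribution")
  expect_equal(correlation_threshold(bg, 0.5), 0)
  expect_equal(correlation_threshold(bg, 0), -1)
  expect_equal(correlation_threshold(bg, 1), 1)

  m <- rand_expr(50, 6, 113)
  big <- background_correlations(m, 20000, seed = 8)
  for (x in c(0.95, 0.975, 0.99)) {
    expect_equal(correlation_threshold(big, x), o_quantile7(big$samples, x),
                 tolerance = 1e-12)
  }
  empty <- structure(list(samples = numeric(0)),
                     class = "background_distribution")
  expect_error(correlation_threshold(empty, 0.5), "empty")
})

test_that("CCN nodes match exhaustive enumeration of all pairs", {
  pp <- rand_pcm_pair(6, 5, 121)
  for (thr in list(c(0.3, 0.2), c(0, 0), c(-0.5, 0.6))) {
    got <- identify_ccn_nodes(pp$pa, pp$pb, thr[1], thr[2])
    want <- o_ccn_nodes(pp$pa, pp$pb, thr[1], thr[2])
    expect_equal(got$node_indices, want$nodes)
    expect_equal(got$n_conserved_edges, want$n_edges)
  }

  # boundary thresholds: strict inequality
  top <- identify_ccn_nodes(pp$pa, pp$pb, 1, 1)
  expect_equal(length(top$node_indices), 0)
  expect_equal(top$n_conserved_edges, 0)
  bottom <- identify_ccn_nodes(pp$pa, pp$pb, -1, -1)
  expect_equal(bottom$node_indices, 1:6)
  expect_equal(bottom$n_conserved_edges, choose(6, 2))
})

test_that("CCN node identification is invariant to consistent relabeling", {
  pp <- rand_pcm_pair(8, 6, 122)
  set.seed(6)
  perm <- sample.int(8)
  base <- identify_ccn_nodes(pp$pa, pp$pb, 0.2, 0.2)
  rel <- identify_ccn_nodes(pp$pa[perm, perm], pp$pb[perm, perm], 0.2, 0.2)
  # node set maps through the permutation
  expect_equal(sort(perm[rel$node_indices]), base$node_indices)
  expect_equal(rel$n_conserved_edges, base$n_conserved_edges)
})

test_that("raising the quantile never adds CCN nodes", {
  cfg <- sim_config(k = 150, t_a = 14, t_b = 14, n_common = 10, seed = 19)
  sim <- simulate_paired_expression(cfg)
  pa <- pairwise_correlation_matrix(sim$paired$A)
  pb <- pairwise_correlation_matrix(sim$paired$B)
  bga <- background_correlations(sim$paired$A, 5000, seed = 20)
  bgb <- background_correlations(sim$paired$B, 5000, seed = 21)
  sets <- lapply(c(0.95, 0.975, 0.99), function(x) {
    identify_ccn_nodes(pa, pb, correlation_threshold(bga, x),
                       correlation_threshold(bgb, x), x)$node_indices
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})
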