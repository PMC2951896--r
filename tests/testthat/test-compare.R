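test_that("EC summaries use valid scores only, sample sd", {
  ec <- ec_result("m", ec = c(0.5, 0.5, 0.5), valid = rep(TRUE, 3))
  s <- summarize_ec(ec)
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0)
  expect_equal(s$n_valid, 3)

  ec2 <- ec_result("m", ec = c(1, -1), valid = c(TRUE, TRUE))
  s2 <- summarize_ec(ec2, "random_pairs")
  expect_equal(s2$mean, 0)
  expect_equal(s2$sd, sqrt(2))

  # invalid entries are excluded
  ec3 <- ec_result("m", ec = c(0.2, NA, 0.8, 0.9),
                   valid = c(TRUE, FALSE, TRUE, FALSE))
  s3 <- summarize_ec(ec3)
  expect_equal(s3$n_valid, 2)
  expect_equal(s3$mean, 0.5)

  set.seed(33)
  v <- runif(1000, -1, 1)
  ec4 <- ec_result("m", ec = v, valid = rep(TRUE, 1000))
  ms <- o_mean_sd(v)
  s4 <- summarize_ec(ec4)
  expect_equal(s4$mean, unname(ms["mean"]), tolerance = 1e-12)
  expect_equal(s4$sd, unname(ms["sd"]), tolerance = 1e-12)

  expect_error(summarize_ec(ec_result("m", ec = 1, valid = TRUE)),
               "at least 2")
})

test_that("random pairing with the identity permutation reproduces ortholog ECs", {
  pe <- rand_paired(10, 6, 6, seed = 201)
  rp <- random_pair_ec(pe, seed = 1, perm = 1:10)
  expect_equal(rp$ec, liao_zhang_ec(pe)$ec, tolerance = 1e-14)

  pp <- rand_pcm_pair(10, 6, 202)
  rp2 <- random_pair_ec(pp$pa, pp$pb, seed = 1, perm = 1:10)
  expect_equal(rp2$ec, dutilh_ec(pp$pa, pp$pb)$ec, tolerance = 1e-14)

  nodes <- c(1L, 3L, 5L, 7L, 9L)
  rp3 <- random_pair_ec(pp$pa, pp$pb, seed = 1, perm = 1:10,
                        node_indices = nodes)
  expect_equal(rp3$ec, essien_ec(pp$pa, pp$pb, nodes)$ec, tolerance = 1e-14)

  fit <- icc(pp$pa, pp$pb)
  rp4 <- random_pair_ec(pp$pa, pp$pb, seed = 1, perm = 1:10,
                        weights = fit$weights)
  expect_equal(rp4$ec, fit$result$ec, tolerance = 1e-14)
})

test_that("random pairing is seed-reproducible and counts fixed points", {
  pp <- rand_pcm_pair(12, 6, 203)
  r1 <- random_pair_ec(pp$pa, pp$pb, seed = 77)
  r2 <- random_pair_ec(pp$pa, pp$pb, seed = 77)
  expect_identical(r1$ec, r2$ec)
  expect_identical(r1$params$perm, r2$params$perm)
  expect_equal(r1$params$n_fixed_points,
               sum(r1$params$perm == seq_len(12)))
})

test_that("permuting reference orthology is a seeded group action", {
  pp <- rand_pcm_pair(9, 6, 204)
  idp <- permute_reference_orthology(pp$pb, seed = 1, perm = 1:9)
  attr(idp, "perm") <- NULL
  expect_equal(unname(idp), unname(pp$pb))

  pm <- permute_reference_orthology(pp$pb, seed = 5)
  perm <- attr(pm, "perm")
  back <- pm[, order(perm)]
  expect_equal(unname(back), unname(pp$pb))

  # same seed, same permutation
  pm2 <- permute_reference_orthology(pp$pb, seed = 5)
  expect_identical(unname(pm), unname(pm2))
})

test_that("method agreement matches definitional rank and moment sums", {
  set.seed(41)
  v1 <- runif(50, -1, 1)
  v2 <- 0.5 * v1 + 0.3 * runif(50, -1, 1)
  e1 <- ec_result("m1", ec = v1, valid = rep(TRUE, 50))
  e2 <- ec_result("m2", ec = v2, valid = rep(TRUE, 50))
  ag <- method_agreement(e1, e2)
  want <- o_agreement(v1, v2)
  expect_equal(ag$pearson_r, unname(want["pearson"]), tolerance = 1e-12)
  expect_equal(ag$spearman_rho, unname(want["spearman"]), tolerance = 1e-12)
  expect_equal(ag$n_pairs_used, 50)

  # self-agreement and rank reversal
  expect_equal(method_agreement(e1, e1)$pearson_r, 1, tolerance = 1e-12)
  e3 <- ec_result("m3", ec = -tanh(v1), valid = rep(TRUE, 50))
  expect_equal(method_agreement(e1, e3)$spearman_rho, -1, tolerance = 1e-12)

  # complete cases only
  e4 <- ec_result("m4", ec = replace(v2, 1:10, NA),
                  valid = c(rep(FALSE, 10), rep(TRUE, 40)))
  expect_equal(method_agreement(e1, e4)$n_pairs_used, 40)

  # symmetry in arguments
  ag_rev <- method_agreement(e2, e1)
  expect_equal(ag_rev$pearson_r, ag$pearson_r, tolerance = 1e-14)

  few <- ec_result("m", ec = c(1, 1, NA), valid = c(TRUE, TRUE, FALSE))
  expect_error(method_agreement(few, few), "at least 3")
})

test_that("distance agreement uses the distance fields", {
  set.seed(42)
  d1 <- runif(30)
  d2 <- d1 + 0.1 * runif(30)
  e1 <- ec_result("m1", distance = d1, valid = rep(TRUE, 30))
  e2 <- ec_result("m2", distance = d2, valid = rep(TRUE, 30))
  da <- distance_agreement(e1, e2)
  expect_equal(da$pearson_r, o_pearson(d1, d2), tolerance = 1e-12)
  expect_equal(distance_agreement(e1, e1)$pearson_r, 1)

  const <- ec_result("m3", distance = rep(0.5, 30), valid = rep(TRUE, 30))
  expect_warning(out <- distance_agreement(e1, const), "zero variance")
  expect_true(is.na(out$pearson_r))
})

test_that("identity tissue subset yields identical ECs and a null test", {
  pe <- rand_paired(20, 8, 8, seed = 205)
  cmp <- compare_tissue_subsets(pe, colnames(pe$A), colnames(pe$B),
                                method = "dutilh")
  expect_equal(cmp$agreement$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$full$ec, cmp$common$ec, tolerance = 1e-14)
})
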