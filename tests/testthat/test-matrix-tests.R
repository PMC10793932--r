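test_that("dietz_r is Spearman over dyadic values with its invariances", {
  set.seed(21)
  a <- random_weight_matrix(6L)
  expect_equal(dietz_r(a, a), 1)

  b4 <- a4 <- matrix(0, 4L, 4L)
  ut <- upper.tri(a4)
  a4[ut] <- 1:6; b4[ut] <- 6:1
  a4 <- a4 + t(a4); b4 <- b4 + t(b4)
  expect_equal(dietz_r(a4, b4), -1)

  b <- random_weight_matrix(6L)
  r0 <- dietz_r(a, b)
  expect_equal(dietz_r(exp(3 * a), b), r0)  # monotone-transform invariance
  p <- sample.int(6L)
  expect_equal(dietz_r(a[p, p], b[p, p]), r0)  # joint label invariance
  expect_equal(r0, suppressWarnings(
    cor(upper_tri(a), upper_tri(b), method = "spearman")))

  cst <- matrix(0.5, 6L, 6L); diag(cst) <- 0
  expect_warning(rc <- dietz_r(cst, b), "constant")
  expect_true(is.na(rc))
})

test_that("node permutation test is exact for small N and matches enumeration", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(4:5, 1L)
    a <- random_weight_matrix(n, density = 1)
    b <- random_weight_matrix(n, density = 1)
    tt <- node_permutation_test(a, b, n_perm = 1000L, seed = i)
    expect_true(tt$exact)
    expect_equal(tt$n_perm, factorial(n))
    expect_equal(tt$p_two_sided, oracle_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical matrices give r = 1 at the minimum attainable p", {
  set.seed(41)
  a <- random_weight_matrix(14L, density = 1)
  tt <- node_permutation_test(a, a, n_perm = 1000L, seed = 9L)
  expect_false(tt$exact)
  expect_equal(tt$r_obs, 1)
  expect_equal(tt$p_two_sided, 1 / 1001)
  expect_true(tt$significant)
  expect_gte(tt$p_two_sided, 1 / (tt$n_perm + 1))
})

test_that("significance flag follows the 2.5%/97.5% null-quantile rule", {
  set.seed(51)
  a <- random_weight_matrix(10L, density = 1)
  b <- random_weight_matrix(10L, density = 1)
  tt <- node_permutation_test(a, b, n_perm = 500L, seed = 3L)
  expect_equal(unname(tt$significant),
               tt$r_obs < tt$null_quantiles[[1L]] ||
                 tt$r_obs > tt$null_quantiles[[2L]])
  expect_warning(node_permutation_test(a, b, n_perm = 50L, seed = 1L),
                 "coarse")
})

test_that("attribute matrices score shared attributes from the roster", {
  r <- grace_roster()
  or <- attribute_matrix(r, "origin")
  expect_equal(or$values["AMA", "KIG"], 1)  # Goma-Goma
  expect_equal(or$values["AMA", "ISA"], 0)  # Goma-Single
  sx <- attribute_matrix(r, "sex")
  expect_equal(sx$values["LUB", "SHA"], 1)  # M-M
  expect_equal(sx$values["KIG", "KAL"], 0)  # M-F
  expect_true(all(diag(or$values) == 0))
  expect_equal(unname(or$values), unname(t(or$values)))

  same <- attribute_matrix(r, values = rep("x", 14L))
  expect_warning(tt <- node_permutation_test(same, sx, seed = 1L),
                 "constant")
  expect_true(tt$degenerate)

  expect_error(attribute_matrix(r, "height"), "unknown attribute")
  expect_error(attribute_matrix(r, values = c("a", NA)[c(1, 2, 1)][
    rep(1:3, length.out = 14)]), "missing")
})

test_that("context consistency runs all pairs with Bonferroni flags", {
  set.seed(61)
  m <- assoc_matrix(random_weight_matrix(8L) / 2, context = "nesting")
  mats <- list(nesting = m, mixing = m, shifting = m)
  cc <- context_consistency(mats, n_perm = 300L, seed = 5L)
  expect_equal(nrow(cc), 3L)
  expect_equal(cc$r, rep(1, 3L))
  expect_true(all(cc$significant_bonferroni))
  expect_length(attr(cc, "tests"), 3L)
})

test_that("temporal stability detects persistence and regime switches", {
  one_ctx_cfg <- function(seed, start = as.Date("2022-05-02")) {
    sim_config(n_individuals = 10L, n_days = 70L,
               contexts = c(nesting = 1L),
               n_obs_days = c(nesting = 70L),
               context_effect = c(nesting = 1),
               base_p = 0.1, block = NULL, visibility = 1,
               gregariousness_sdlog = 0.8,
               start_date = start, seed = seed)
  }
  # stationary: same individuals/propensities in both halves
  sim <- simulate_scans(sim_config(
    n_individuals = 10L, n_days = 140L, contexts = c(nesting = 1L),
    n_obs_days = c(nesting = 140L), context_effect = c(nesting = 1),
    base_p = 0.1, block = NULL, visibility = 1,
    gregariousness_sdlog = 0.8, seed = 71L))
  ts <- temporal_stability(sim$scans, sim$roster, "nesting",
                           n_perm = 400L, seed = 8L)
  expect_gt(ts$r_obs, 0.3)
  expect_true(ts$significant)

  # regime switch: second half generated with independent propensities
  s1 <- simulate_scans(one_ctx_cfg(81L))
  s2 <- simulate_scans(one_ctx_cfg(82L, start = as.Date("2022-05-02") + 70L))
  joined <- scan_records(rbind(as.data.frame(s1$scans),
                               as.data.frame(s2$scans)), s1$roster)
  ts2 <- temporal_stability(joined, s1$roster, "nesting",
                            n_perm = 400L, seed = 8L)
  expect_lt(abs(ts2$r_obs), 0.35)  # R centred on 0 under independence
})
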