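test_that("simulator is reproducible and honours the scan design", {
  cfg <- sim_config(seed = 11L)
  sim1 <- simulate_scans(cfg)
  sim2 <- simulate_scans(cfg)
  expect_identical(sim1$scans, sim2$scans)  # byte-identical under a seed
  expect_identical(sim1$truth$gregariousness, sim2$truth$gregariousness)

  sc <- sim1$scans
  expect_equal(sort(unique(sc$context)),
               c("mixing", "nesting", "shifting"))
  expect_equal(max(sc$scan[sc$context == "mixing"]), 3L)
  expect_equal(max(sc$scan[sc$context == "nesting"]), 1L)
  expect_equal(length(unique(sc$date[sc$context == "nesting"])), 192L)
  expect_equal(length(unique(sc$date[sc$context == "mixing"])), 157L)
  expect_equal(length(unique(sc$date[sc$context == "shifting"])), 159L)
  expect_lte(as.numeric(max(sc$date) - min(sc$date)) + 1, 224)
  expect_equal(nrow(sim1$roster), 14L)
  expect_equal(sum(sim1$roster$sex == "M"), 3L)

  # p_eff >= p, equality iff one scan per day
  expect_true(all(sim1$truth$p_eff$mixing >=
                    sim1$truth$p$mixing - 1e-15))
  expect_equal(sim1$truth$p_eff$nesting, {
    p <- sim1$truth$p$nesting; diag(p) <- 0; p
  })
  expect_gt(max(sim1$truth$p_eff$mixing - sim1$truth$p$mixing), 0)
})

test_that("uniform propensity, full visibility: SRI converges to 1-(1-p)^s", {
  cfg <- sim_config(
    n_individuals = 6L, n_days = 1200L, contexts = c(mixing = 3L),
    n_obs_days = c(mixing = 1200L), context_effect = c(mixing = 1),
    base_p = 0.06, block = NULL, gregariousness = rep(1, 6L),
    visibility = 1, seed = 12L)
  sim <- simulate_scans(cfg)
  m <- build_association_matrix(sim$scans, sim$roster, "mixing")
  p_eff <- 1 - (1 - 0.06)^3
  expect_equal(mean(upper_tri(m)), p_eff, tolerance = 0.05)
  # under v = 1 every dyad's denominator equals the day count
  counts <- tally_counts(daily_states(sim$scans), sim$roster)
  expect_true(all(rowSums(counts[, c("X", "Y_A", "Y_B", "Y_AB")]) ==
                    1200L))
})

test_that("recovery_report measures estimation error against truth", {
  cfg <- sim_config(n_individuals = 8L, n_days = 300L,
                    contexts = c(nesting = 1L),
                    n_obs_days = c(nesting = 300L),
                    context_effect = c(nesting = 1), base_p = 0.08,
                    block = NULL, visibility = 1, seed = 13L)
  sim <- simulate_scans(cfg)
  m <- build_association_matrix(sim$scans, sim$roster, "nesting")
  rr <- recovery_report(m, sim$truth)
  expect_false(rr$empty)
  expect_equal(rr$n_dyads, 28L)
  expect_lt(rr$max_abs_error, 0.1)
  expect_lte(rr$rmse, rr$max_abs_error)
  expect_error(recovery_report(m, sim$truth, "mixing"), "no truth")
})

test_that("attribute labels independent of propensity keep type-I near 5%", {
  # scaled-down calibration (the full 500-replicate version lives in the
  # acceptance suite)
  set.seed(14)
  rej <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    v <- random_weight_matrix(12L, density = 0.9)
    r <- tiny_roster(12L)
    r$origin <- sample(c("Goma", "Kinigi", "Single"), 12L, replace = TRUE)
    tt <- node_permutation_test(v, attribute_matrix(r, "origin")$values,
                                n_perm = 300L, seed = i)
    if (isTRUE(tt$significant)) rej <- rej + 1L
  }
  expect_lte(rej, qbinom(0.9995, n_rep, 0.05) + 1L)
})

test_that("raising p_within raises detected modularity (monotone in blocks)", {
  qs <- vapply(c(0.1, 0.3, 0.5), function(pw) {
    cfg <- sim_config(n_individuals = 10L, n_days = 150L,
                      contexts = c(nesting = 1L),
                      n_obs_days = c(nesting = 150L),
                      context_effect = c(nesting = 1),
                      block = list(contexts = "nesting", p_within = pw,
                                   p_between = 0.05,
                                   membership = rep(1:2, each = 5L)),
                      gregariousness = rep(1, 10L), visibility = 1,
                      seed = 15L)
    sim <- simulate_scans(cfg)
    m <- build_association_matrix(sim$scans, sim$roster, "nesting")
    detect_communities(m)$Q
  }, numeric(1L))
  expect_true(all(diff(qs) > -0.02))  # weakly increasing, MC tolerance
  expect_gt(qs[3L], qs[1L])
})

test_that("simulated scan files round-trip through the CSV dialect", {
  cfg <- sim_config(n_individuals = 5L, n_days = 10L,
                    contexts = c(shifting = 1L),
                    n_obs_days = c(shifting = 10L),
                    context_effect = c(shifting = 1), block = NULL,
                    seed = 16L)
  sim <- simulate_scans(cfg)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_scans(sim$scans, tmp)
  back <- read_scans(tmp, sim$roster)
  expect_equal(back, sim$scans)
})
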