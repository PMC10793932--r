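make_scans <- function(rows, roster) {
  df <- do.call(rbind, lapply(rows, function(x) {
    data.frame(date = as.Date(x[[1L]]), context = x[[2L]],
               scan = as.integer(x[[3L]]), id_a = x[[4L]], id_b = x[[5L]],
               state = suppressWarnings(as.integer(x[[6L]])),
               stringsAsFactors = FALSE)
  }))
  scan_records(df, roster)
}

test_that("daily collapsing follows the at-least-one-scan / all-unseen rules", {
  r <- tiny_roster(3L)
  day <- function(states) {
    make_scans(lapply(seq_along(states), function(s) {
      list("2022-05-02", "mixing", s, "A", "B", states[s])
    }), r)
  }
  expect_equal(collapse_daily(day(c("0", "1", "0")))$state, 1L)
  expect_equal(collapse_daily(day(c("0", "0", "0")))$state, 0L)
  expect_true(is.na(collapse_daily(day(c("NA", "NA", "NA")))$state))
  expect_equal(collapse_daily(day(c("NA", "0", "NA")))$state, 0L)
  two_days <- make_scans(list(
    list("2022-05-02", "mixing", 1, "A", "B", "1"),
    list("2022-05-03", "mixing", 1, "A", "B", "0")), r)
  expect_error(collapse_daily(two_days), "single date")
})

test_that("tally_counts applies the visibility rules per day", {
  r <- tiny_roster(3L)
  # dyad A-B over 5 days: 1, 1, 0, NA (A seen via A-C, B unseen),
  # NA (both unseen: all rows NA)
  sc <- make_scans(list(
    list("2022-05-01", "nesting", 1, "A", "B", "1"),
    list("2022-05-02", "nesting", 1, "A", "B", "1"),
    list("2022-05-03", "nesting", 1, "A", "B", "0"),
    list("2022-05-04", "nesting", 1, "A", "B", "NA"),
    list("2022-05-04", "nesting", 1, "A", "C", "0"),
    list("2022-05-04", "nesting", 1, "B", "C", "NA"),
    list("2022-05-05", "nesting", 1, "A", "B", "NA"),
    list("2022-05-05", "nesting", 1, "A", "C", "NA"),
    list("2022-05-05", "nesting", 1, "B", "C", "NA")), r)
  counts <- tally_counts(daily_states(sc), r)
  ab <- counts[counts$id_a == "A" & counts$id_b == "B", ]
  expect_equal(ab$X, 2L)
  expect_equal(ab$Y_AB, 1L)
  expect_equal(ab$Y_A, 1L)
  expect_equal(ab$Y_B, 0L)
  # empty input -> all-zero counts
  empty <- tally_counts(daily_states(sc)[0L, ], r)
  expect_true(all(empty[, c("X", "Y_A", "Y_B", "Y_AB")] == 0L))
})

test_that("simple_ratio matches the closed form and its bounds", {
  expect_equal(simple_ratio(3, 1, 1, 5), 0.3)
  expect_equal(simple_ratio(0, Y_AB = 10), 0)
  expect_equal(simple_ratio(7), 1)
  expect_warning(zero <- simple_ratio(0, 0, 0, 0), "denominator")
  expect_equal(zero, 0)
  expect_error(simple_ratio(-1), "non-negative")
  # index is 1 iff X > 0 and all other terms 0
  set.seed(1)
  for (i in 1:50) {
    c4 <- rpois(4L, 2)
    idx <- suppressWarnings(simple_ratio(c4[1], c4[2], c4[3], c4[4]))
    expect_gte(idx, 0); expect_lte(idx, 1)
    expect_equal(idx == 1, c4[1] > 0 && all(c4[2:4] == 0))
  }
})

test_that("build_association_matrix computes indices and is order-invariant", {
  r <- tiny_roster(3L)
  sc <- make_scans(list(
    list("2022-05-01", "nesting", 1, "A", "B", "1"),
    list("2022-05-02", "nesting", 1, "A", "B", "1"),
    list("2022-05-03", "nesting", 1, "A", "B", "0"),
    list("2022-05-04", "nesting", 1, "A", "B", "1")), r)
  m <- suppressWarnings(build_association_matrix(sc, r, "nesting"))
  expect_equal(m$values["A", "B"], 0.75)
  expect_equal(m$n_observations, 4L)
  expect_error(build_association_matrix(sc, r, "mixing"), "no records")

  set.seed(7)
  sc2 <- random_scanset(tiny_roster(5L), 12L)
  m1 <- suppressWarnings(
    build_association_matrix(sc2, tiny_roster(5L), "nesting"))
  perm <- sc2[sample.int(nrow(sc2)), ]
  m2 <- suppressWarnings(
    build_association_matrix(perm, tiny_roster(5L), "nesting"))
  expect_equal(m1$values, m2$values)
})

test_that("matrix construction equals the brute-force recount (oracle)", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(4:6, 1L)
    r <- tiny_roster(n)
    sc <- random_scanset(r, n_days = sample(8:30, 1L))
    m <- suppressWarnings(build_association_matrix(sc, r, "nesting"))
    expect_equal(m$values, brute_sri(sc, r, "nesting"), tolerance = 1e-12)
  }
})

test_that("adding associated days never decreases the index (monotonicity)", {
  set.seed(3)
  r <- tiny_roster(4L)
  sc <- random_scanset(r, 15L)
  m0 <- suppressWarnings(build_association_matrix(sc, r, "nesting"))
  add_day <- function(st) {
    extra <- scan_records(data.frame(
      date = max(sc$date) + 1L, context = "nesting", scan = 1L,
      id_a = "A", id_b = "B", state = st, stringsAsFactors = FALSE), r)
    suppressWarnings(
      build_association_matrix(rbind(sc, extra), r, "nesting"))
  }
  expect_gte(add_day(1L)$values["A", "B"], m0$values["A", "B"])
  expect_lte(add_day(0L)$values["A", "B"], m0$values["A", "B"])
})

test_that("preferred_dyads: means over all dyads, top-3 with tie flag", {
  r <- tiny_roster(4L)
  v <- matrix(0, 4L, 4L, dimnames = list(r$id, r$id))
  v[1, 2] <- v[2, 1] <- 0.5
  v[1, 3] <- v[3, 1] <- 0.3
  v[1, 4] <- v[4, 1] <- 0.2
  v[2, 3] <- v[3, 2] <- 0.2
  m <- assoc_matrix(v, context = "nesting")
  pd <- preferred_dyads(m)
  expect_equal(pd$mean_index, mean(c(0.5, 0.3, 0.2, 0.2, 0, 0)))
  expect_equal(sum(pd$dyads$above_mean), 2L)  # 0.5 and 0.3 beat 0.2
  expect_equal(sum(pd$dyads$top3), 4L)        # tie at third (0.2, 0.2)
  expect_true(pd$ties_at_third)
  expect_equal(pd$dyads$ratio_to_mean[1L], 0.5 / pd$mean_index)

  u <- matrix(0.4, 4L, 4L); diag(u) <- 0
  dimnames(u) <- list(r$id, r$id)
  pdu <- preferred_dyads(assoc_matrix(u))
  expect_equal(sum(pdu$dyads$above_mean), 0L)  # nothing strictly > mean
})

test_that("split_periods counts 7-day blocks and flags overlap", {
  r <- tiny_roster(3L)
  span_scans <- function(weeks) {
    dates <- as.Date("2022-05-02") + seq_len(weeks * 7L) - 1L
    scan_records(data.frame(
      date = dates, context = "nesting", scan = 1L, id_a = "A",
      id_b = "B", state = 1L, stringsAsFactors = FALSE), r)
  }
  sp <- split_periods(span_scans(32L))
  expect_equal(as.numeric(diff(sp$early_window)) + 1, 70)
  expect_equal(as.numeric(diff(sp$late_window)) + 1, 70)
  expect_false(sp$overlap)
  expect_true(max(sp$early$date) < min(sp$late$date))

  sp20 <- split_periods(span_scans(20L))
  expect_false(sp20$overlap)
  expect_equal(sort(unique(c(sp20$early$date, sp20$late$date))),
               sort(unique(span_scans(20L)$date)))  # exact partition

  sp12 <- split_periods(span_scans(12L))
  expect_true(sp12$overlap)

  expect_error(split_periods(span_scans(8L)), "span")
})

test_that("mean-strength identity holds for every matrix", {
  set.seed(5)
  for (n in c(5L, 9L, 14L)) {
    v <- random_weight_matrix(n)
    expect_equal(mean(rowSums(v)), (n - 1) * mean(upper_tri(v)))
  }
})
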