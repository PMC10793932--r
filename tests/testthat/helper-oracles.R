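# Independent oracles and small fixtures. Everything here is deliberately
# written along a different path than the package code it checks: direct
# per-dyad filtering, power iteration, exhaustive enumeration.

tiny_roster <- function(n = 4L) {
  roster(data.frame(
    id = LETTERS[seq_len(n)],
    sex = rep(c("F", "M"), length.out = n),
    origin = rep(c("Goma", "Kinigi", "Single"), length.out = n),
    estimated_age = seq_len(n) + 6L,
    status = c("Silverback", rep("Adult", n - 1L)),
    stringsAsFactors = FALSE))
}

# Random small scan set as a plain data.frame (independent of the
# package simulator): per day one scan, random subset of dyad rows with
# random states including NA.
random_scanset <- function(roster, n_days, p_assoc = 0.3, p_na = 0.2,
                           p_missing_row = 0.1) {
  dy <- t(combn(sort(roster$id), 2L))
  rows <- list()
  for (d in seq_len(n_days)) {
    keep <- runif(nrow(dy)) > p_missing_row
    if (!any(keep)) next
    st <- ifelse(runif(nrow(dy)) < p_na, NA_integer_,
                 as.integer(runif(nrow(dy)) < p_assoc))
    rows[[d]] <- data.frame(
      date = as.Date("2022-05-02") + d - 1L, context = "nesting",
      scan = 1L, id_a = dy[keep, 1L], id_b = dy[keep, 2L],
      state = st[keep], stringsAsFactors = FALSE)
  }
  scan_records(do.call(rbind, rows), roster)
}

# Brute-force simple-ratio recount: direct filtering per dyad and per day,
# no matrices, no data.table.
brute_sri <- function(records, roster, context) {
  rec <- records[records$context == context, , drop = FALSE]
  days <- sort(unique(rec$date))
  ids <- roster$id
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
      X <- yab <- ya <- yb <- 0L
      for (d in days) {
        day <- rec[rec$date == d, , drop = FALSE]
        mine <- day[day$id_a == a & day$id_b == b, , drop = FALSE]
        st <- mine$state
        if (any(st == 1L, na.rm = TRUE)) { X <- X + 1L; next }
        if (any(st == 0L, na.rm = TRUE)) { yab <- yab + 1L; next }
        seen <- function(id) {
          rel <- day[(day$id_a == id | day$id_b == id) &
                       !is.na(day$state), , drop = FALSE]
          nrow(rel) > 0L
        }
        sa <- seen(a); sb <- seen(b)
        if (sa && !sb) ya <- ya + 1L
        if (sb && !sa) yb <- yb + 1L
      }
      den <- X + ya + yb + yab
      val <- if (den > 0) X / den else 0
      # a/b are lexicographic; map back to roster positions i/j
      out[i, j] <- out[j, i] <- val
    }
  }
  out
}

# Power-iteration eigenvector oracle.
power_iter_centrality <- function(v, iters = 10000L, tol = 1e-14) {
  x <- rep(1 / sqrt(nrow(v)), nrow(v))
  for (k in seq_len(iters)) {
    y <- v %*% x
    y <- y / sqrt(sum(y^2))
    if (sqrt(sum((y - x)^2)) < tol) break
    x <- y
  }
  as.numeric(abs(y))
}

# Exhaustive modularity oracle: enumerate all set partitions (restricted
# growth strings, iterative) and score each by the textbook formula
# Q = sum_c (e_c - a_c^2) over community totals.
oracle_best_q <- function(v) {
  n <- nrow(v)
  w <- sum(v) / 2
  best <- -Inf
  part <- rep(1L, n)
  kmax <- rep(1L, n)
  repeat {
    q <- oracle_q(v, part, w)
    if (q > best) best <- q
    # next restricted growth string
    i <- n
    repeat {
      if (i == 1L) return(best)
      if (part[i] < kmax[i - 1L] + 1L) break
      i <- i - 1L
    }
    part[i] <- part[i] + 1L
    kmax[i] <- max(kmax[i - 1L], part[i])
    if (i < n) {
      part[(i + 1L):n] <- 1L
      for (j in (i + 1L):n) kmax[j] <- kmax[j - 1L]
    }
  }
}

oracle_q <- function(v, part, w = sum(v) / 2) {
  q <- 0
  for (c in unique(part)) {
    inc <- part == c
    e_c <- sum(v[inc, inc]) / (2 * w)
    a_c <- sum(v[inc, ]) / (2 * w)
    q <- q + e_c - a_c^2
  }
  q
}

# All permutations, iteratively (independent of the package's generator).
oracle_perms <- function(n) {
  out <- list(1L)
  for (k in 2:n) {
    nxt <- vector("list", length(out) * k)
    i <- 0L
    for (p in out) {
      for (pos in seq_len(k)) {
        i <- i + 1L
        nxt[[i]] <- append(p, k, after = pos - 1L)
      }
    }
    out <- nxt
  }
  out
}

# Exhaustive two-sided permutation p for the Spearman matrix correlation.
oracle_exact_p <- function(va, vb) {
  n <- nrow(va)
  ut <- upper.tri(va)
  r_obs <- suppressWarnings(cor(va[ut], vb[ut], method = "spearman"))
  rs <- vapply(oracle_perms(n), function(p) {
    vp <- vb[p, p]
    suppressWarnings(cor(va[ut], vp[ut], method = "spearman"))
  }, numeric(1L))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# Random symmetric non-negative weight matrix.
random_weight_matrix <- function(n, density = 0.7) {
  v <- matrix(0, n, n)
  ut <- upper.tri(v)
  v[ut] <- (runif(sum(ut)) < density) * runif(sum(ut))
  v + t(v)
}

grace_roster <- function() {
  read_roster(system.file("extdata", "grace_roster.csv",
                          package = "proxnet"))
}

grace_metrics <- function() {
  read.csv(system.file("extdata", "grace_metrics.csv",
                       package = "proxnet"), stringsAsFactors = FALSE)
}
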