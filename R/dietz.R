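#' Dietz R rank matrix correlation
#'
#' Rank-based correlation between two symmetric matrices over their
#' N(N-1)/2 dyadic (upper-triangle, off-diagonal) entries: Pearson
#' correlation of the midrank-transformed values, i.e. the Spearman
#' correlation of the dyadic values. Invariant under strictly monotone
#' transforms of either matrix's entries, and under applying one node
#' permutation to both matrices.
#'
#' @param a,b `assoc_matrix` objects or symmetric matrices with the same
#'   labels/order, N >= 4.
#' @return R in [-1, 1], or NA (with a warning) when either matrix is
#'   constant across dyads.
#' @export
dietz_r <- function(a, b) {
  ua <- upper_tri(a)
  ub <- upper_tri(b)
  if (length(ua) != length(ub)) stop("matrices must have the same size")
  if (length(ua) < 6L) stop("need at least 4 individuals")
  .dietz_r_vec(rank(ua), rank(ub))
}

.dietz_r_vec <- function(ra, rb) {
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    warning("constant matrix: Dietz R undefined")
    return(NA_real_)
  }
  cor(ra, rb)
}

#' Node-label permutation test for matrix correlation
#'
#' Tests the observed Dietz R against a null built by jointly permuting
#' the row/column labels of one matrix `n_perm` times (identity
#' permutation of the other held fixed) and recomputing R. Two-sided
#' p-value with the add-one rule, p = (1 + #\{|R_null| >= |R_obs|\}) /
#' (n_perm + 1), so p is never 0. The `significant` flag follows the
#' two-tailed quantile rule: the observed R lies above the 97.5% or below
#' the 2.5% quantile of the null. When N! <= `n_perm` the test is exact:
#' all N! node permutations are enumerated instead of sampled.
#'
#' @param a,b as in [dietz_r()].
#' @param n_perm number of random permutations (default 1000).
#' @param seed integer seed for reproducibility.
#' @param alpha significance level for the quantile rule (default 0.05).
#' @return A `perm_test` list: `r_obs`, `n_perm`, `p_two_sided`,
#'   `null_quantiles` (2.5%, 97.5%), `significant`, `exact`, `seed`.
#' @export
node_permutation_test <- function(a, b, n_perm = 1000L, seed = NULL,
                                  alpha = 0.05) {
  va <- if (inherits(a, "assoc_matrix")) a$values else as.matrix(a)
  vb <- if (inherits(b, "assoc_matrix")) b$values else as.matrix(b)
  n <- nrow(va)
  if (n < 4L) stop("need at least 4 individuals")
  if (!all(dim(vb) == n)) stop("matrices must have the same size")
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse null")
  # Ranks commute with node permutation (the multiset of dyadic values is
  # permutation-invariant), so rank once and index thereafter.
  ra <- rank(upper_tri(va))
  rb_ut <- rank(upper_tri(vb))
  if (stats::sd(ra) == 0 || stats::sd(rb_ut) == 0) {
    warning("constant matrix: Dietz R undefined; degenerate test")
    return(structure(list(r_obs = NA_real_, n_perm = 0L,
                          p_two_sided = NA_real_,
                          null_quantiles = c(`2.5%` = NA_real_,
                                             `97.5%` = NA_real_),
                          significant = NA, exact = FALSE,
                          seed = seed, degenerate = TRUE),
                     class = "perm_test"))
  }
  rb_mat <- matrix(0, n, n)
  iu <- which(upper.tri(rb_mat), arr.ind = TRUE)
  iu <- iu[order(iu[, 1L], iu[, 2L]), , drop = FALSE]  # canonical order
  rb_mat[iu] <- rb_ut
  rb_mat <- rb_mat + t(rb_mat)
  r_obs <- cor(ra, rb_ut)

  exact <- factorial(n) <= n_perm
  if (exact) {
    perms <- .all_perms(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  }
  za <- (ra - mean(ra)) / stats::sd(ra)
  ii <- iu[, 1L]
  jj <- iu[, 2L]
  m1 <- length(ra) - 1L
  null_r <- vapply(perms, function(p) {
    rbp <- rb_mat[cbind(p[ii], p[jj])]
    sum(za * (rbp - mean(rbp))) / (stats::sd(rbp) * m1)
  }, numeric(1L))
  if (exact) {
    p <- mean(abs(null_r) >= abs(r_obs) - 1e-12)
  } else {
    p <- (1 + sum(abs(null_r) >= abs(r_obs) - 1e-12)) / (length(null_r) + 1)
  }
  q <- quantile(null_r, c(1 - (1 - alpha / 2), 1 - alpha / 2),
                names = FALSE, type = 7)
  names(q) <- c("2.5%", "97.5%")
  structure(list(r_obs = r_obs, n_perm = length(null_r),
                 p_two_sided = p, null_quantiles = q,
                 significant = r_obs < q[[1L]] | r_obs > q[[2L]],
                 exact = exact, seed = seed, degenerate = FALSE),
            class = "perm_test")
}

.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' @export
print.perm_test <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Degenerate matrix-correlation test (constant matrix)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Dietz R = %.3f, P = %.4g (%s, %d permutations)%s\n",
    x$r_obs, x$p_two_sided, if (x$exact) "exact" else "Monte Carlo",
    x$n_perm, if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Same-attribute adjacency matrix
#'
#' A binary symmetric matrix scoring each dyad 1 if the two individuals
#' share the attribute value (same origin, same sex, same community) and
#' 0 otherwise; the diagonal is 0 and is ignored by all dyadic tests.
#'
#' @param roster a [roster()].
#' @param attribute `"origin"`, `"sex"` or `"status"`; alternatively pass
#'   `values` directly.
#' @param values optional explicit per-individual labels (e.g. community
#'   ids) overriding `attribute`.
#' @return An `assoc_matrix`-like binary matrix object (class
#'   `attr_matrix`) with `$values`, `$labels`, `$attribute`.
#' @export
attribute_matrix <- function(roster, attribute = NULL, values = NULL) {
  if (is.null(values)) {
    if (is.null(attribute) || !attribute %in% names(roster)) {
      stop("unknown attribute: ", attribute)
    }
    values <- roster[[attribute]]
  }
  if (anyNA(values)) stop("missing attribute value(s)")
  if (length(values) != nrow(roster)) {
    stop("attribute values must match roster length")
  }
  v <- outer(values, values, "==") * 1
  diag(v) <- 0
  dimnames(v) <- list(roster$id, roster$id)
  structure(list(values = v, labels = roster$id,
                 attribute = if (is.null(attribute)) "custom" else attribute),
            class = c("attr_matrix", "assoc_matrix"))
}

#' Between-context consistency tests
#'
#' All pairwise Dietz node-permutation tests between the contexts'
#' association matrices; with three contexts the conventional Bonferroni
#' level alpha = 0.016 is applied to the reported `significant_bonferroni`
#' flag (the quantile-rule `significant` flag is kept at 0.05).
#'
#' @param matrices named list of [assoc_matrix()] per context.
#' @param n_perm,seed as in [node_permutation_test()].
#' @param alpha_bonferroni corrected level (default 0.016 for 3 pairs).
#' @return data.frame, one row per context pair, with R, p, and
#'   significance flags; the `perm_test` objects attached as
#'   `attr(, "tests")`.
#' @export
context_consistency <- function(matrices, n_perm = 1000L, seed = NULL,
                                alpha_bonferroni = 0.016) {
  stopifnot(length(matrices) >= 2L)
  cxs <- names(matrices)
  prs <- combn(cxs, 2L)
  tests <- list()
  rows <- vector("list", ncol(prs))
  for (k in seq_len(ncol(prs))) {
    c1 <- prs[1L, k]; c2 <- prs[2L, k]
    sk <- if (is.null(seed)) NULL else seed + k
    tt <- node_permutation_test(matrices[[c1]], matrices[[c2]],
                                n_perm = n_perm, seed = sk)
    tests[[paste(c1, c2, sep = "-")]] <- tt
    rows[[k]] <- data.frame(
      context_a = c1, context_b = c2, r = tt$r_obs, p = tt$p_two_sided,
      significant = tt$significant,
      significant_bonferroni = !is.na(tt$p_two_sided) &&
        tt$p_two_sided <= alpha_bonferroni,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "tests") <- tests
  out
}

#' Temporal stability of the association network
#'
#' Dietz node-permutation test between the association matrices of the
#' first and last study weeks within one context (default 10 + 10 weeks).
#'
#' @param records `proxnet_scans` table.
#' @param roster a [roster()].
#' @param context context to analyse.
#' @param first_weeks,last_weeks window lengths (see [split_periods()]).
#' @param n_perm,seed as in [node_permutation_test()].
#' @return A `perm_test` with the two period matrices attached as
#'   `$early_matrix` / `$late_matrix`.
#' @export
temporal_stability <- function(records, roster, context,
                               first_weeks = 10L, last_weeks = 10L,
                               n_perm = 1000L, seed = NULL) {
  rec <- records[records$context == context, , drop = FALSE]
  sp <- split_periods(rec, first_weeks, last_weeks)
  m_early <- build_association_matrix(sp$early, roster, context)
  m_late <- build_association_matrix(sp$late, roster, context)
  tt <- node_permutation_test(m_early, m_late, n_perm = n_perm, seed = seed)
  tt$early_matrix <- m_early
  tt$late_matrix <- m_late
  tt$overlap <- sp$overlap
  tt
}
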