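#' Weighted Newman modularity of a partition
#'
#' Q = (1 / 2W) * sum_ij (A_ij - s_i s_j / 2W) * delta(c_i, c_j), with
#' A the (weighted) association matrix, s its row sums (strengths) and W
#' the total upper-triangle weight. Q is 0 for the single-community
#' partition by construction and at most 1; Q >= 0.30 is the conventional
#' subgrouping threshold.
#'
#' @param m an [assoc_matrix()] or non-negative symmetric matrix with
#'   positive total weight.
#' @param membership integer/character vector assigning each individual a
#'   community.
#' @return Q (numeric scalar).
#' @export
modularity_q <- function(m, membership) {
  v <- if (inherits(m, "assoc_matrix")) m$values else as.matrix(m)
  if (any(v < 0)) stop("weights must be non-negative")
  w2 <- sum(v)
  if (w2 <= 0) stop("empty network: total weight is zero")
  if (length(membership) != nrow(v)) {
    stop("membership length must equal the number of individuals")
  }
  s <- rowSums(v)
  b <- v - outer(s, s) / w2
  same <- outer(membership, membership, "==")
  sum(b[same]) / w2
}

.modularity_from_B <- function(b, w2, membership) {
  sum(b[outer(membership, membership, "==")]) / w2
}

#' Detect communities by leading-eigenvector bisection
#'
#' Newman's spectral method on the weighted modularity matrix: the network
#' is recursively bisected along the sign pattern of the leading
#' eigenvector of the (generalised) modularity matrix, each bisection is
#' fine-tuned by Kernighan-Lin style single-node moves (vertices moved at
#' most once per pass, best prefix kept, lowest index first on ties), and
#' a subgroup is left intact when its modularity matrix has no positive
#' eigenvalue or when no split increases Q. Fully deterministic.
#'
#' @param m an [assoc_matrix()] or non-negative symmetric matrix.
#' @param exhaustive if TRUE (N <= 12 only) search all set partitions for
#'   the global maximum-Q partition instead; intended as a check.
#' @return A `partition` list: `membership` (integer, 1..K, named by id),
#'   `K`, `Q`, `method`.
#' @export
detect_communities <- function(m, exhaustive = FALSE) {
  v <- if (inherits(m, "assoc_matrix")) m$values else as.matrix(m)
  n <- nrow(v)
  labels <- rownames(v)
  if (is.null(labels)) labels <- paste0("V", seq_len(n))
  w2 <- sum(v)
  if (w2 <= 0) stop("empty network: total weight is zero")
  if (exhaustive) {
    if (n > 10L) stop("exhaustive search is limited to N <= 10")
    best <- .best_partition_exhaustive(v)
    return(.partition(best, labels, modularity_q(v, best), "exhaustive"))
  }
  s <- rowSums(v)
  b <- v - outer(s, s) / w2
  membership <- rep(1L, n)
  queue <- list(seq_len(n))
  while (length(queue)) {
    g <- queue[[1L]]
    queue <- queue[-1L]
    if (length(g) < 2L) next
    bg <- b[g, g, drop = FALSE]
    diag(bg) <- diag(bg) - rowSums(bg)  # generalised modularity matrix
    eg <- eigen(bg, symmetric = TRUE)
    if (eg$values[1L] <= 1e-10) next  # indivisible
    side <- ifelse(eg$vectors[, 1L] >= 0, 1L, 2L)
    if (length(unique(side)) < 2L) next
    side <- .kl_refine(bg, side)
    if (length(unique(side)) < 2L) next
    # accept the split only if it increases global Q
    dq <- .split_gain(bg, side) / w2
    if (dq <= 1e-12) next
    new_id <- max(membership) + 1L
    membership[g[side == 2L]] <- new_id
    queue <- c(queue, list(g[side == 1L]), list(g[side == 2L]))
  }
  membership <- .global_refine(b, w2, membership)
  membership <- match(membership, unique(membership))  # compact 1..K
  .partition(membership, labels, modularity_q(v, membership),
             "leading-eigenvector")
}

# Gain in (unnormalised) modularity from splitting a subgroup along `side`,
# relative to leaving it whole: sum of B^g over same-side pairs minus sum
# over all pairs.
.split_gain <- function(bg, side) {
  same <- outer(side, side, "==")
  sum(bg[same]) - sum(bg)
}

# Kernighan-Lin style fine-tuning of a bisection of one subgroup.
# Repeated passes; within a pass every vertex is moved exactly once (the
# move with the largest gain first, lowest index breaking ties), the gain
# trajectory is tracked and the best prefix kept. Stops when a full pass
# yields no improvement.
.kl_refine <- function(bg, side) {
  ng <- length(side)
  repeat {
    cur <- side
    gain <- numeric(ng)
    moved_order <- integer(ng)
    g_cum <- 0
    score <- .split_gain(bg, cur)
    traj <- numeric(ng)
    free <- rep(TRUE, ng)
    work <- cur
    for (step in seq_len(ng)) {
      # gain of flipping vertex i: delta of sum(bg[same]) when i switches
      gains <- rep(-Inf, ng)
      for (i in which(free)) {
        same_i <- work == work[i]
        # flipping i: pairs (i, j) j != i change membership agreement
        delta <- 2 * (sum(bg[i, !same_i]) - sum(bg[i, same_i]) + bg[i, i])
        gains[i] <- delta
      }
      i_best <- which.max(gains)  # lowest index wins ties
      work[i_best] <- 3L - work[i_best]
      free[i_best] <- FALSE
      g_cum <- g_cum + gains[i_best]
      traj[step] <- g_cum
      moved_order[step] <- i_best
    }
    best_step <- which.max(traj)
    if (traj[best_step] > 1e-10) {
      flips <- moved_order[seq_len(best_step)]
      side[flips] <- 3L - side[flips]
    } else {
      return(side)
    }
  }
}

# Final tuning over the whole partition: greedy single-node moves between
# existing communities (bisection alone cannot shift a node across an
# earlier split). Applies the single best positive move until none is
# left; lowest node index breaks ties. Deterministic.
.global_refine <- function(b, w2, membership) {
  n <- length(membership)
  repeat {
    comms <- unique(membership)
    if (length(comms) < 2L) return(membership)
    # S[i, c] = sum of B_ij over j != i in community c
    s_ic <- vapply(comms, function(c) {
      out <- rowSums(b[, membership == c, drop = FALSE])
      out - ifelse(membership == c, diag(b), 0)
    }, numeric(n))
    own <- s_ic[cbind(seq_len(n), match(membership, comms))]
    gain <- 2 * (s_ic - own) / w2
    gain[cbind(seq_len(n), match(membership, comms))] <- 0
    best <- which(gain == max(gain), arr.ind = TRUE)[1L, ]
    if (gain[best[1L], best[2L]] <= 1e-10) return(membership)
    membership[best[1L]] <- comms[best[2L]]
  }
}

.partition <- function(membership, labels, q, method) {
  names(membership) <- labels
  structure(list(membership = membership,
                 K = length(unique(membership)), Q = q, method = method),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition into K = %d communities, Q = %.3f (%s)\n",
              x$K, x$Q, x$method))
  for (k in sort(unique(x$membership))) {
    cat(sprintf("  [%d] %s\n", k,
                paste(names(x$membership)[x$membership == k],
                      collapse = " ")))
  }
  invisible(x)
}

# Exhaustive maximum-modularity search over all set partitions (small N),
# enumerated as restricted-growth strings.
.best_partition_exhaustive <- function(v) {
  n <- nrow(v)
  w2 <- sum(v)
  s <- rowSums(v)
  b <- v - outer(s, s) / w2
  best_q <- -Inf
  best <- rep(1L, n)
  part <- integer(n)
  recurse <- function(i, k) {
    if (i > n) {
      q <- .modularity_from_B(b, w2, part)
      if (q > best_q) {
        best_q <<- q
        best <<- part[seq_len(n)]
      }
      return(invisible(NULL))
    }
    for (c in seq_len(k + 1L)) {
      part[i] <<- c
      recurse(i + 1L, max(k, c))
    }
  }
  recurse(1L, 0L)
  best
}

#' Subgrouping verdict from a partition's modularity
#'
#' TRUE iff Q >= 0.30 (inclusive boundary), the conventional indication of
#' subgrouping in a population.
#'
#' @param partition a `partition` from [detect_communities()].
#' @param threshold modularity threshold (default 0.30).
#' @return list: `subgrouping` (logical), `Q`, `K`, `threshold`.
#' @export
subgrouping_verdict <- function(partition, threshold = 0.30) {
  list(subgrouping = partition$Q >= threshold, Q = partition$Q,
       K = partition$K, threshold = threshold)
}

#' Test community membership against a demographic attribute
#'
#' Builds the binary same-community matrix from a partition and runs the
#' Dietz node-permutation test against the same-attribute matrix (shared
#' origin, shared sex, ...), asking whether subgroup membership is defined
#' by the attribute.
#'
#' @param partition a `partition` with K >= 2.
#' @param roster a [roster()].
#' @param attribute attribute name (see [attribute_matrix()]).
#' @param n_perm,seed as in [node_permutation_test()].
#' @return A `perm_test`.
#' @export
membership_attribute_test <- function(partition, roster, attribute,
                                      n_perm = 1000L, seed = NULL) {
  if (partition$K < 2L) {
    warning("single-community partition: degenerate membership test")
  }
  same_comm <- attribute_matrix(roster,
                                values = partition$membership[roster$id])
  attrm <- attribute_matrix(roster, attribute)
  node_permutation_test(same_comm, attrm, n_perm = n_perm, seed = seed)
}
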