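#' Binary network density
#'
#' The fraction of the N(N-1)/2 dyads with a nonzero association index.
#' Density is deliberately binary (presence/absence of any association);
#' it depends only on the zero pattern, not on edge weights.
#'
#' @param m an [assoc_matrix()] or symmetric matrix.
#' @return proportion in [0, 1].
#' @export
net_density <- function(m) {
  ut <- upper_tri(m)
  if (length(ut) == 0L) stop("need at least 2 individuals")
  mean(ut > 0)
}

#' Node strength (weighted degree)
#'
#' The sum of an individual's association indices — its "gregariousness".
#' Row sums of the index matrix, in roster order. The group identity
#' mean(strength) = (N-1) * mean(dyadic index) holds exactly.
#'
#' @param m an [assoc_matrix()] or symmetric matrix.
#' @return named numeric vector.
#' @export
node_strength <- function(m) {
  v <- if (inherits(m, "assoc_matrix")) m$values else as.matrix(m)
  rowSums(v)
}

#' Weighted eigenvector centrality
#'
#' Entries of the principal eigenvector of the association matrix: an
#' individual scores high when it and its partners are strongly connected.
#' Computed by deterministic symmetric eigendecomposition, oriented
#' non-negative and scaled to unit Euclidean norm (the convention under
#' which the per-individual values' squares sum to 1); `normalize =
#' "max"` rescales so the largest entry is 1 instead.
#'
#' For a disconnected network the leading eigenvector localises on the
#' component with the largest eigenvalue; the value is still returned,
#' with a warning.
#'
#' @param m an [assoc_matrix()] or non-negative symmetric matrix.
#' @param normalize `"euclidean"` (default) or `"max"`.
#' @return named numeric vector, non-negative.
#' @export
eig_centrality <- function(m, normalize = c("euclidean", "max")) {
  normalize <- match.arg(normalize)
  v <- if (inherits(m, "assoc_matrix")) m$values else as.matrix(m)
  if (any(v < 0)) stop("matrix must be non-negative")
  if (.n_components(v) > 1L) {
    warning("network is disconnected; leading eigenvector localises on ",
            "the dominant component")
  }
  e <- eigen(v, symmetric = TRUE)
  vec <- e$vectors[, 1L]
  if (sum(vec) < 0) vec <- -vec
  vec[vec < 0 & vec > -1e-10] <- 0  # zap numerical negatives
  if (any(vec < 0)) {
    warning("leading eigenvector has mixed signs (disconnected network); ",
            "negative entries truncated to 0")
    vec[vec < 0] <- 0
  }
  vec <- switch(normalize,
                euclidean = vec / sqrt(sum(vec^2)),
                max = vec / max(vec))
  names(vec) <- rownames(v)
  vec
}

.n_components <- function(v) {
  n <- nrow(v)
  adj <- v > 0
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    k <- k + 1L
    frontier <- i
    comp[i] <- k
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- k
      frontier <- nb
    }
  }
  k
}

#' Per-individual network metrics table
#'
#' @param m an [assoc_matrix()].
#' @param roster optional [roster()] to join demographic columns.
#' @return data.frame: `id`, `context`, `strength`,
#'   `eigenvector_centrality` (+ roster columns if given).
#' @export
network_metrics <- function(m, roster = NULL) {
  out <- data.frame(id = m$labels, context = m$context,
                    strength = unname(node_strength(m)),
                    eigenvector_centrality = unname(eig_centrality(m)),
                    stringsAsFactors = FALSE)
  if (!is.null(roster)) {
    out <- merge(out, as.data.frame(roster), by = "id", sort = FALSE)
    out <- out[match(m$labels, out$id), ]
    rownames(out) <- NULL
  }
  out
}

#' Spearman correlation of network metrics with age
#'
#' Rank correlation (midranks for ties) of estimated age against strength
#' and against eigenvector centrality, two-sided p from the standard t
#' approximation. A constant metric vector yields an undefined rho,
#' reported as NA.
#'
#' @param metrics data.frame from [network_metrics()] (or with columns
#'   `id`, `strength`, `eigenvector_centrality`).
#' @param roster a [roster()] supplying `estimated_age`.
#' @return data.frame: `metric`, `rho`, `p_value`, `n`.
#' @export
metric_age_correlation <- function(metrics, roster) {
  stopifnot(nrow(metrics) >= 4L)
  age <- roster$estimated_age[match(metrics$id, roster$id)]
  one <- function(metric) {
    y <- metrics[[metric]]
    if (length(unique(y)) < 2L || length(unique(age)) < 2L) {
      return(data.frame(metric = metric, rho = NA_real_,
                        p_value = NA_real_, n = length(y)))
    }
    ct <- suppressWarnings(
      cor.test(age, y, method = "spearman", exact = FALSE))
    data.frame(metric = metric, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(y))
  }
  rbind(one("strength"), one("eigenvector_centrality"))
}
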