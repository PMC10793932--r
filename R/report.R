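#' Run the full association-network analysis
#'
#' Orchestrates the whole pipeline per observation context — association
#' matrix, summary statistics, network metrics, preferred dyads,
#' origin/sex attribute tests, community detection with the subgrouping
#' verdict (and attribute follow-up when subgrouping is indicated),
#' the random-vs-scale-free assessment — followed by cross-context
#' consistency and within-context temporal-stability tests. Contexts are
#' never mixed in one matrix. Every stochastic result carries its seed
#' and permutation count.
#'
#' @param scans a `proxnet_scans` table (or path to a scan CSV).
#' @param roster a [roster()] (or path to a roster CSV).
#' @param n_perm permutations per test (default 1000).
#' @param seed base seed; each test derives its own offset from it.
#' @param alpha significance level (default 0.05).
#' @param alpha_bonferroni level for the 3 cross-context comparisons.
#' @param first_weeks,last_weeks temporal-stability windows.
#' @return A `proxnet_report` list with `contexts` (per-context results),
#'   `consistency`, `temporal`, and `meta`.
#' @export
run_full_analysis <- function(scans, roster, n_perm = 1000L, seed = 1L,
                              alpha = 0.05, alpha_bonferroni = 0.016,
                              first_weeks = 10L, last_weeks = 10L) {
  if (is.character(roster)) roster <- read_roster(roster)
  if (is.character(scans)) scans <- read_scans(scans, roster)
  present <- intersect(c("nesting", "mixing", "shifting"),
                       unique(scans$context))
  if (length(present) == 0L) stop("association stage: no records")
  if (length(present) < 3L) {
    warning("context(s) missing from the data; report covers: ",
            paste(present, collapse = ", "))
  }
  per_ctx <- list()
  matrices <- list()
  off <- 0L
  for (ctx in present) {
    res <- tryCatch({
      m <- build_association_matrix(scans, roster, ctx)
      ut <- upper_tri(m)
      metrics <- network_metrics(m, roster)
      pd <- preferred_dyads(m)
      t_origin <- node_permutation_test(
        m, attribute_matrix(roster, "origin"),
        n_perm = n_perm, seed = seed + off + 1L, alpha = alpha)
      t_sex <- node_permutation_test(
        m, attribute_matrix(roster, "sex"),
        n_perm = n_perm, seed = seed + off + 2L, alpha = alpha)
      part <- detect_communities(m)
      verdict <- subgrouping_verdict(part)
      follow <- NULL
      if (verdict$subgrouping && part$K >= 2L) {
        follow <- list(
          origin = membership_attribute_test(part, roster, "origin",
                                             n_perm = n_perm,
                                             seed = seed + off + 3L),
          sex = membership_attribute_test(part, roster, "sex",
                                          n_perm = n_perm,
                                          seed = seed + off + 4L))
      }
      sf <- scale_free_assessment(metrics$eigenvector_centrality)
      age_cor <- metric_age_correlation(metrics, roster)
      matrices[[ctx]] <- m
      list(matrix = m,
           summary = list(mean_index = mean(ut), sd_index = stats::sd(ut),
                          density = net_density(m),
                          n_observations = m$n_observations),
           metrics = metrics, preferred = pd,
           tests = list(origin = t_origin, sex = t_sex),
           age_correlation = age_cor,
           partition = part, subgrouping = verdict,
           membership_tests = follow, scale_free = sf)
    }, error = function(e) {
      stop("context '", ctx, "' stage failed: ", conditionMessage(e),
           call. = FALSE)
    })
    per_ctx[[ctx]] <- res
    off <- off + 10L
  }
  consistency <- if (length(matrices) >= 2L) {
    context_consistency(matrices, n_perm = n_perm, seed = seed + 100L,
                        alpha_bonferroni = alpha_bonferroni)
  } else NULL
  temporal <- list()
  for (ctx in present) {
    temporal[[ctx]] <- tryCatch(
      temporal_stability(scans, roster, ctx, first_weeks, last_weeks,
                         n_perm = n_perm, seed = seed + 200L),
      error = function(e) {
        warning("temporal stability skipped for '", ctx, "': ",
                conditionMessage(e))
        NULL
      })
  }
  structure(list(contexts = per_ctx, consistency = consistency,
                 temporal = temporal,
                 meta = list(seed = seed, n_perm = n_perm, alpha = alpha,
                             alpha_bonferroni = alpha_bonferroni,
                             n_individuals = nrow(roster),
                             package_version =
                               as.character(utils::packageVersion("proxnet")))),
            class = "proxnet_report")
}

#' @export
print.proxnet_report <- function(x, ...) {
  cat("proxnet analysis report —", length(x$contexts), "context(s),",
      x$meta$n_individuals, "individuals\n")
  for (ctx in names(x$contexts)) {
    r <- x$contexts[[ctx]]
    cat(sprintf(
      "\n[%s] d = %.2f, mean index = %.2f (SD %.2f), Q = %.3f (K = %d)%s, %s network\n",
      ctx, r$summary$density, r$summary$mean_index, r$summary$sd_index,
      r$partition$Q, r$partition$K,
      if (r$subgrouping$subgrouping) " [subgrouping]" else "",
      r$scale_free$verdict))
    cat(sprintf("  origin: R = %.3f, P = %.3f | sex: R = %.3f, P = %.3f\n",
                r$tests$origin$r_obs, r$tests$origin$p_two_sided,
                r$tests$sex$r_obs, r$tests$sex$p_two_sided))
  }
  if (!is.null(x$consistency)) {
    cat("\nCross-context consistency:\n")
    print(x$consistency, digits = 3)
  }
  invisible(x)
}

#' Export an association network for visualisation
#'
#' Writes GraphML (via igraph) and/or a weighted edge list
#' (`source,target,weight` CSV). Nodes carry strength, eigenvector
#' centrality and any roster/community attributes supplied; edges carry
#' the association index as weight, and zero-index dyads are omitted.
#'
#' @param m an [assoc_matrix()].
#' @param path output path (extension replaced per format).
#' @param roster optional [roster()] for node attributes.
#' @param partition optional `partition` for a community node attribute.
#' @param format `"graphml"`, `"edgelist"` or both.
#' @return (invisibly) the paths written.
#' @export
export_graph <- function(m, path, roster = NULL, partition = NULL,
                         format = c("graphml", "edgelist")) {
  format <- match.arg(format, several.ok = TRUE)
  gr <- igraph::graph_from_adjacency_matrix(m$values, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::V(gr)$strength <- unname(node_strength(m))
  igraph::V(gr)$eigenvector_centrality <- unname(eig_centrality(m))
  if (!is.null(roster)) {
    idx <- match(m$labels, roster$id)
    igraph::V(gr)$sex <- roster$sex[idx]
    igraph::V(gr)$origin <- roster$origin[idx]
    igraph::V(gr)$status <- roster$status[idx]
  }
  if (!is.null(partition)) {
    igraph::V(gr)$community <- unname(partition$membership[m$labels])
  }
  base <- sub("\\.(graphml|csv)$", "", path)
  out <- character()
  if ("graphml" %in% format) {
    f <- paste0(base, ".graphml")
    igraph::write_graph(gr, f, format = "graphml")
    out <- c(out, f)
  }
  if ("edgelist" %in% format) {
    f <- paste0(base, ".csv")
    el <- igraph::as_data_frame(gr, what = "edges")
    names(el) <- c("source", "target", "weight")
    write.csv(el, f, row.names = FALSE, quote = FALSE)
    out <- c(out, f)
  }
  invisible(out)
}
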