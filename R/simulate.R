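#' Configuration for the synthetic scan-data generator
#'
#' Defaults emulate a 32-week group-scan study of a 14-member gorilla
#' group observed in three daily contexts: `nesting` (1 scan/day, 192
#' observation days), `mixing` (3 scans/day OR-collapsed to one daily
#' score, 157 days) and `shifting` (1 scan/day, 159 days). The per-scan
#' association propensity of a dyad is
#' `p_ij = clamp(base * g_i * g_j * context_effect)`, where `base` is
#' `p_within`/`p_between` for contexts with block (community) structure
#' and `base_p` otherwise, and `g_i` are per-individual gregariousness
#' multipliers (lognormal, mean 1). Each individual is visible in a scan
#' independently with probability `visibility`; a dyad with an unseen
#' member is recorded not-visible (`NA`) for that scan.
#'
#' Default magnitudes are pinned to the study design they emulate: daily
#' association probabilities near 0.05 in mixing/shifting, a sex-assorted
#' 4-block structure in nesting (`p_within` 0.18, `p_between` 0.045,
#' giving a mean daily index near 0.07), and near-total density.
#'
#' @param n_individuals group size (default 14).
#' @param n_days study span in days (default 224 = 32 weeks).
#' @param contexts named integer vector of scans per day.
#' @param n_obs_days named integer vector of observation days per context
#'   (sampled uniformly from the study span).
#' @param context_effect named multiplier per context (mixing default
#'   0.34 so that the OR-collapsed daily probability of three scans is
#'   about `base_p`).
#' @param base_p baseline per-scan dyadic propensity.
#' @param block list with `contexts` (character), `p_within`, `p_between`,
#'   optional `membership` (integer per individual); `NULL` disables
#'   block structure.
#' @param gregariousness optional numeric vector of multipliers `g_i`;
#'   drawn lognormal(`sdlog = gregariousness_sdlog`), normalised to mean
#'   1, when `NULL`.
#' @param gregariousness_sdlog spread of the gregariousness draw.
#' @param visibility per-scan visibility probability in (0, 1].
#' @param roster optional [roster()]; synthesised when `NULL`.
#' @param start_date first study date.
#' @param seed integer seed; the generated dataset is byte-identical for
#'   a given config + seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 14L,
                       n_days = 224L,
                       contexts = c(nesting = 1L, mixing = 3L,
                                    shifting = 1L),
                       n_obs_days = c(nesting = 192L, mixing = 157L,
                                      shifting = 159L),
                       context_effect = c(nesting = 1, mixing = 0.34,
                                          shifting = 1),
                       base_p = 0.05,
                       block = list(contexts = "nesting",
                                    p_within = 0.18, p_between = 0.045,
                                    membership = NULL),
                       gregariousness = NULL,
                       gregariousness_sdlog = 0.35,
                       visibility = 0.95,
                       roster = NULL,
                       start_date = as.Date("2022-05-02"),
                       seed = NULL) {
  stopifnot(n_individuals >= 3L, n_days >= 1L, all(contexts >= 1L),
            visibility > 0, visibility <= 1, base_p >= 0, base_p <= 1)
  if (!all(names(contexts) %in% c("nesting", "mixing", "shifting"))) {
    stop("context names must be nesting/mixing/shifting")
  }
  if (!setequal(names(n_obs_days), names(contexts)) ||
      !setequal(names(context_effect), names(contexts))) {
    stop("n_obs_days and context_effect must name the same contexts")
  }
  if (any(n_obs_days > n_days)) stop("n_obs_days cannot exceed n_days")
  if (!is.null(block)) {
    stopifnot(block$p_within >= 0, block$p_within <= 1,
              block$p_between >= 0, block$p_between <= 1,
              all(block$contexts %in% names(contexts)))
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_days = as.integer(n_days), contexts = contexts,
                 n_obs_days = n_obs_days, context_effect = context_effect,
                 base_p = base_p, block = block,
                 gregariousness = gregariousness,
                 gregariousness_sdlog = gregariousness_sdlog,
                 visibility = visibility, roster = roster,
                 start_date = start_date, seed = seed),
            class = "sim_config")
}

# Synthetic roster mirroring the demographic make-up of a sanctuary
# group: ~3/14 males (one silverback, rest blackbacks), origins split
# roughly 4/4/6 Goma/Kinigi/Single, ages 7-21.
.synth_roster <- function(n) {
  ids <- sprintf("SYN%02d", seq_len(n))
  n_m <- max(1L, round(n * 3 / 14))
  sex <- c(rep("M", n_m), rep("F", n - n_m))
  status <- c("Silverback", rep("Blackback", n_m - 1L),
              "Subadult", rep("Adult", n - n_m - 1L))[seq_len(n)]
  origin <- rep(c("Goma", "Kinigi", "Single"),
                c(round(n * 4 / 14), round(n * 4 / 14),
                  n - 2L * round(n * 4 / 14)))
  age <- sample(7:21, n, replace = TRUE)
  roster(data.frame(id = ids, sex = sex, origin = origin,
                    estimated_age = age, status = status,
                    stringsAsFactors = FALSE))
}

# Default 4-block, sex-assorted community layout: the blackbacks form one
# block, the silverback nests with two females (mixed block), remaining
# females split into two blocks.
.default_communities <- function(r) {
  n <- nrow(r)
  if (n < 8L) {
    return(rep(1:2, length.out = n)[order(order(seq_len(n)))])
  }
  memb <- integer(n)
  bb <- which(r$status == "Blackback")
  sb <- which(r$status == "Silverback")
  if (length(bb) == 0L) bb <- n
  if (length(sb) == 0L) sb <- n - 1L
  females <- setdiff(seq_len(n), c(bb, sb))
  memb[bb] <- 4L
  mixed_f <- females[seq_len(min(2L, length(females)))]
  memb[c(sb, mixed_f)] <- 3L
  rest <- setdiff(females, mixed_f)
  half <- ceiling(length(rest) / 2)
  memb[rest[seq_len(half)]] <- 1L
  memb[rest[-seq_len(half)]] <- 2L
  memb
}

#' Generate a synthetic scan dataset with known ground truth
#'
#' @param config a [sim_config()].
#' @return list: `roster`, `scans` (a `proxnet_scans` table in the same
#'   dialect [read_scans()] reads), `truth` (per-context per-scan
#'   propensity matrices `p`, daily OR-collapsed `p_eff = 1 - (1-p)^s`,
#'   `communities`, `gregariousness`, `obs_dates`).
#' @export
simulate_scans <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_individuals
  r <- if (is.null(config$roster)) .synth_roster(n) else config$roster
  if (nrow(r) != n) stop("roster size does not match n_individuals")
  g <- config$gregariousness
  if (is.null(g)) {
    g <- exp(rnorm(n, 0, config$gregariousness_sdlog))
    g <- g / mean(g)
  }
  if (any(g <= 0)) stop("gregariousness multipliers must be positive")
  block <- config$block
  memb <- NULL
  if (!is.null(block)) {
    memb <- block$membership
    if (is.null(memb)) memb <- .default_communities(r)
  }
  dy <- dyads(r)
  ia <- match(dy$id_a, r$id)
  ib <- match(dy$id_b, r$id)
  gg <- g[ia] * g[ib]

  truth_p <- list()
  truth_peff <- list()
  obs_dates <- list()
  recs <- list()
  for (ctx in names(config$contexts)) {
    s <- config$contexts[[ctx]]
    base <- rep(config$base_p, nrow(dy))
    if (!is.null(block) && ctx %in% block$contexts) {
      base <- ifelse(memb[ia] == memb[ib], block$p_within, block$p_between)
    }
    p <- pmin(1, pmax(0, base * gg * config$context_effect[[ctx]]))
    pm <- matrix(0, n, n, dimnames = list(r$id, r$id))
    pm[cbind(ia, ib)] <- p
    pm[cbind(ib, ia)] <- p
    truth_p[[ctx]] <- pm
    peff <- 1 - (1 - pm)^s
    diag(peff) <- 0
    truth_peff[[ctx]] <- peff
    days <- sort(sample.int(config$n_days, config$n_obs_days[[ctx]]))
    dates <- config$start_date + days - 1L
    obs_dates[[ctx]] <- dates
    nsc <- length(dates) * s
    vis <- matrix(runif(nsc * n) < config$visibility, nsc, n)
    both <- vis[, ia, drop = FALSE] & vis[, ib, drop = FALSE]
    st <- matrix(NA_integer_, nsc, nrow(dy))
    draw <- matrix(runif(nsc * nrow(dy)), nsc, nrow(dy))
    st[both] <- as.integer(draw < matrix(p, nsc, nrow(dy),
                                         byrow = TRUE))[both]
    recs[[ctx]] <- data.frame(
      date = rep(rep(dates, each = s), times = nrow(dy)),
      context = ctx,
      scan = rep(rep(seq_len(s), times = length(dates)),
                 times = nrow(dy)),
      id_a = rep(pmin(dy$id_a, dy$id_b), each = nsc),
      id_b = rep(pmax(dy$id_a, dy$id_b), each = nsc),
      state = as.integer(st),
      stringsAsFactors = FALSE)
  }
  scans <- scan_records(do.call(rbind, recs), r)
  truth <- list(p = truth_p, p_eff = truth_peff, communities = memb,
                gregariousness = setNames(g, r$id),
                obs_dates = obs_dates)
  list(roster = r, scans = scans, truth = truth)
}

#' Compare an estimated association matrix with simulation truth
#'
#' Per-dyad error of the simple-ratio estimates against the true daily
#' (OR-collapsed) association probabilities of the generating process.
#'
#' @param estimate an [assoc_matrix()].
#' @param truth the `truth` element of [simulate_scans()] output.
#' @param context context whose `p_eff` to compare against.
#' @return list: `max_abs_error`, `rmse`, `mean_signed_error`, `n_dyads`,
#'   `empty` flag.
#' @export
recovery_report <- function(estimate, truth, context = estimate$context) {
  peff <- truth$p_eff[[context]]
  if (is.null(peff)) stop("no truth for context '", context, "'")
  if (!identical(rownames(peff), estimate$labels)) {
    stop("labels of estimate and truth differ")
  }
  est <- upper_tri(estimate)
  tru <- upper_tri(peff)
  if (isTRUE(estimate$n_observations == 0L) || length(est) == 0L) {
    return(list(max_abs_error = NA_real_, rmse = NA_real_,
                mean_signed_error = NA_real_, n_dyads = length(est),
                empty = TRUE))
  }
  err <- est - tru
  list(max_abs_error = max(abs(err)), rmse = sqrt(mean(err^2)),
       mean_signed_error = mean(err), n_dyads = length(err),
       empty = FALSE)
}
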