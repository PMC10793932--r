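#' Collapse repeated scans into one daily dyadic state
#'
#' Mixing-yard days carry up to three scans; to limit autocorrelation a
#' single daily one/zero score is used: a dyad is associated for the day if
#' it was associated in at least one scan, not associated if both members
#' were seen apart in at least one scan and never seen together, and
#' not-visible (`NA`) only if no scan of the day yielded a determinate
#' state (an individual counts as not visible for the day only when unseen
#' in every scan).
#'
#' @param records `proxnet_scans` rows sharing a single date and context.
#' @return data.frame with one row per dyad: `date`, `context`, `id_a`,
#'   `id_b`, `state`.
#' @export
collapse_daily <- function(records) {
  if (length(unique(records$date)) > 1L ||
      length(unique(records$context)) > 1L) {
    stop("collapse_daily expects records from a single date and context")
  }
  dt <- data.table::as.data.table(records)
  out <- dt[, .(state = .collapse_states(state)),
            by = .(date, context, id_a, id_b)]
  as.data.frame(out)
}

.collapse_states <- function(s) {
  if (any(s == 1L, na.rm = TRUE)) 1L
  else if (any(s == 0L, na.rm = TRUE)) 0L
  else NA_integer_
}

#' @rdname collapse_daily
#' @details `daily_states()` applies the same collapsing to a whole record
#'   set (any number of dates) within one context.
#' @export
daily_states <- function(records) {
  if (length(unique(records$context)) > 1L) {
    stop("daily_states expects a single context")
  }
  .daily_states(records)
}

# Daily collapsing for a whole record set (any dates), one context.
.daily_states <- function(records) {
  dt <- data.table::as.data.table(records)
  out <- dt[, .(state = .collapse_states(state)),
            by = .(date, context, id_a, id_b)]
  data.table::setorder(out, date, id_a, id_b)
  as.data.frame(out)
}

#' Visibility-aware dyad counts for the simple-ratio index
#'
#' From one context's daily dyadic states, tallies for each dyad the four
#' terms of the simple-ratio denominator: `X` days both seen and
#' associated, `Y_AB` days both seen but apart, `Y_A` days only the first
#' member seen, `Y_B` days only the second. Per-day visibility of an
#' individual is derived from the data: seen on a day iff it has a
#' determinate (non-NA) state in at least one of its dyad rows that day.
#' Days with both members unseen contribute to no term.
#'
#' @param daily daily dyadic states (from [collapse_daily()] /
#'   internally from [build_association_matrix()]), one context.
#' @param roster a [roster()].
#' @return data.frame, one row per canonical dyad: `id_a`, `id_b`, `X`,
#'   `Y_A`, `Y_B`, `Y_AB`.
#' @export
tally_counts <- function(daily, roster) {
  ids <- roster$id
  dy <- dyads(roster)
  n_d <- nrow(dy)
  if (nrow(daily) == 0L) {
    return(cbind(dy, X = 0L, Y_A = 0L, Y_B = 0L, Y_AB = 0L))
  }
  if (length(unique(daily$context)) > 1L) {
    stop("tally_counts expects a single context")
  }
  days <- sort(unique(daily$date))
  nd <- length(days)
  # state array: days x dyads (NA where no record)
  di <- match(daily$date, days)
  ki <- match(paste(daily$id_a, daily$id_b),
              paste(pmin(dy$id_a, dy$id_b), pmax(dy$id_a, dy$id_b)))
  if (anyNA(ki)) stop("record ids not covered by roster dyads")
  st <- matrix(NA_integer_, nd, n_d)
  st[cbind(di, ki)] <- daily$state
  # seen[d, i]: individual i has a determinate state on day d
  seen <- matrix(FALSE, nd, length(ids), dimnames = list(NULL, ids))
  det <- !is.na(daily$state)
  for (col in c("id_a", "id_b")) {
    idx <- cbind(di[det], match(daily[[col]][det], ids))
    seen[idx] <- TRUE
  }
  ia <- match(dy$id_a, ids)
  ib <- match(dy$id_b, ids)
  sa <- seen[, ia, drop = FALSE]
  sb <- seen[, ib, drop = FALSE]
  na_st <- is.na(st)
  cbind(dy,
        X    = colSums(st == 1L, na.rm = TRUE),
        Y_A  = colSums(na_st & sa & !sb),
        Y_B  = colSums(na_st & !sa & sb),
        Y_AB = colSums(st == 0L, na.rm = TRUE))
}

#' Simple-ratio association index
#'
#' `X / (X + Y_A + Y_B + Y_AB)`: the proportion of observation days on
#' which a dyad was associated, out of the days on which its association
#' state could have been determined. A dyad whose denominator is zero
#' (never jointly observable) gets index 0 with a warning, so matrices
#' stay total.
#'
#' @param X,Y_A,Y_B,Y_AB non-negative counts (vectorised).
#' @return numeric index/indices in [0, 1].
#' @export
simple_ratio <- function(X, Y_A = 0, Y_B = 0, Y_AB = 0) {
  if (any(c(X, Y_A, Y_B, Y_AB) < 0)) stop("counts must be non-negative")
  den <- X + Y_A + Y_B + Y_AB
  out <- ifelse(den > 0, X / den, 0)
  if (any(den == 0)) {
    warning("zero denominator for ", sum(den == 0),
            " dyad(s); index set to 0")
  }
  out
}

#' Build the association matrix for one context
#'
#' Collapses scans to daily states, tallies visibility-aware counts and
#' fills a symmetric matrix of simple-ratio indices in roster order.
#'
#' @param records `proxnet_scans` table (any contexts; filtered here).
#' @param roster a [roster()].
#' @param context context to use.
#' @param dates optional vector/range of dates to keep (e.g. from
#'   [split_periods()]).
#' @return An [assoc_matrix()] with `n_observations` = number of
#'   observation days used.
#' @export
build_association_matrix <- function(records, roster, context,
                                     dates = NULL) {
  rec <- records[records$context == context, , drop = FALSE]
  if (!is.null(dates)) rec <- rec[rec$date %in% dates, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for context '", context, "'")
  daily <- .daily_states(rec)
  counts <- tally_counts(daily, roster)
  idx <- withCallingHandlers(
    simple_ratio(counts$X, counts$Y_A, counts$Y_B, counts$Y_AB),
    warning = function(w) invokeRestart("muffleWarning"))
  den0 <- with(counts, X + Y_A + Y_B + Y_AB) == 0
  if (any(den0)) {
    warning(sum(den0), " dyad(s) never jointly observable in '", context,
            "'; index set to 0")
  }
  n <- nrow(roster)
  v <- matrix(0, n, n, dimnames = list(roster$id, roster$id))
  ia <- match(counts$id_a, roster$id)
  ib <- match(counts$id_b, roster$id)
  v[cbind(ia, ib)] <- idx
  v[cbind(ib, ia)] <- idx
  assoc_matrix(v, roster$id, context = context,
               n_observations = length(unique(daily$date)))
}

#' Preferred-relationship report
#'
#' Flags dyads whose association index exceeds the context mean (mean over
#' all N(N-1)/2 dyads, zeros included) and the three largest-index dyads;
#' ties at the third-largest value are all reported and flagged.
#'
#' @param m an [assoc_matrix()] with at least 3 individuals.
#' @return A `preferred_dyads` list: `mean_index`, `dyads` (data.frame
#'   with `id_a`, `id_b`, `index`, `ratio_to_mean`, `above_mean`, `top3`),
#'   `ties_at_third` flag.
#' @export
preferred_dyads <- function(m) {
  stopifnot(inherits(m, "assoc_matrix"), length(m$labels) >= 3L)
  dy <- dyads(m$labels)
  dy$index <- upper_tri(m)
  mu <- mean(dy$index)
  dy$ratio_to_mean <- if (mu > 0) dy$index / mu else NA_real_
  dy$above_mean <- dy$index > mu
  ord <- order(-dy$index)
  third <- dy$index[ord][min(3L, nrow(dy))]
  dy$top3 <- dy$index >= third & dy$index > 0
  ties <- sum(dy$top3) > 3L
  dy <- dy[ord, ]
  rownames(dy) <- NULL
  structure(list(mean_index = mu, dyads = dy, ties_at_third = ties),
            class = "preferred_dyads")
}

#' @export
print.preferred_dyads <- function(x, ...) {
  cat(sprintf("Mean dyadic index %.4f; %d of %d dyads above mean\n",
              x$mean_index, sum(x$dyads$above_mean), nrow(x$dyads)))
  cat("Top dyads:\n")
  print(head(x$dyads, sum(x$dyads$top3)), digits = 3)
  if (x$ties_at_third) cat("(ties at the third-largest value)\n")
  invisible(x)
}

#' Split records into first and last study weeks
#'
#' Weeks are consecutive 7-day blocks counted from the earliest
#' observation date; the early period covers weeks 1..`first_weeks` and
#' the late period the final `last_weeks` blocks ending at the latest
#' date. If the record span is shorter than their sum the two windows
#' overlap; that is permitted but flagged.
#'
#' @param records `proxnet_scans` table.
#' @param first_weeks,last_weeks window lengths in weeks (default 10).
#' @return list with `early` and `late` record subsets, the date windows,
#'   and an `overlap` flag.
#' @export
split_periods <- function(records, first_weeks = 10L, last_weeks = 10L) {
  if (nrow(records) == 0L) stop("no records to split")
  d0 <- min(records$date)
  d1 <- max(records$date)
  span_weeks <- as.numeric(d1 - d0 + 1L) / 7
  if (span_weeks < max(first_weeks, last_weeks)) {
    stop("records span ", round(span_weeks, 1), " weeks; need at least ",
         max(first_weeks, last_weeks))
  }
  early_end <- d0 + first_weeks * 7L - 1L
  late_start <- d1 - last_weeks * 7L + 1L
  overlap <- late_start <= early_end
  list(
    early = records[records$date <= early_end, , drop = FALSE],
    late = records[records$date >= late_start, , drop = FALSE],
    early_window = c(d0, early_end),
    late_window = c(late_start, d1),
    overlap = overlap
  )
}
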