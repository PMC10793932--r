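#' Read dyadic scan records from CSV
#'
#' One row per dyad per scan, columns `date,context,scan,id1,id2,state`.
#' `date` is ISO-8601 (`YYYY-MM-DD`); `context` is one of `nesting`,
#' `mixing`, `shifting`; `scan` is a positive integer (1..3 for mixing, 1
#' otherwise); `state` is `1` (associated, within the proximity criterion),
#' `0` (both visible, not associated) or `NA` (at least one member not
#' visible). Ids are canonicalised so that `id_a < id_b` lexicographically;
#' records are returned sorted by (date, context, scan, id_a, id_b).
#'
#' Dyads absent from a scan's rows are treated as not-visible (`NA`) by all
#' downstream tallies, never as 0: absence of evidence is not evidence of
#' non-association.
#'
#' @param path CSV file path.
#' @param roster a [roster()]; all ids must belong to it.
#' @return A `proxnet_scans` data.frame with columns
#'   `date` (Date), `context`, `scan` (integer), `id_a`, `id_b`,
#'   `state` (integer, NA allowed).
#' @export
read_scans <- function(path, roster) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(state = "character"))
  if (nrow(raw) == 0L) {
    warning("scan file is empty: ", path)
    return(scan_records(data.frame(
      date = as.Date(character()), context = character(),
      scan = integer(), id_a = character(), id_b = character(),
      state = integer()), roster))
  }
  names(raw) <- tolower(names(raw))
  need <- c("date", "context", "scan", "id1", "id2", "state")
  if (!all(need %in% names(raw))) {
    stop("scan file must have columns ", paste(need, collapse = ","))
  }
  st <- trimws(raw$state)
  st[st %in% c("NA", "")] <- NA_character_
  state <- suppressWarnings(as.integer(st))
  bad <- !is.na(st) & (is.na(state) | !state %in% c(0L, 1L))
  if (any(bad)) {
    stop("unparseable state value(s): ",
         paste(unique(st[bad]), collapse = ", "))
  }
  scan_records(data.frame(
    date = raw$date, context = raw$context,
    scan = as.integer(raw$scan), id_a = raw$id1, id_b = raw$id2,
    state = state, stringsAsFactors = FALSE), roster)
}

#' Validate and canonicalise a table of scan records
#'
#' @param x data.frame with columns `date`, `context`, `scan`, `id_a`,
#'   `id_b`, `state`.
#' @param roster a [roster()].
#' @return A `proxnet_scans` data.frame (see [read_scans()]).
#' @export
scan_records <- function(x, roster) {
  stopifnot(inherits(roster, "proxnet_roster"))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  d <- as.Date(as.character(x$date), format = "%Y-%m-%d")
  bad_date <- is.na(d) & !is.na(x$date)
  if (any(bad_date)) {
    stop("unparseable date(s): ",
         paste(unique(x$date[bad_date]), collapse = ", "))
  }
  x$date <- d
  x$context <- as.character(x$context)
  .check_vocab(x$context, c("nesting", "mixing", "shifting"), "context")
  x$scan <- as.integer(x$scan)
  if (nrow(x) && any(is.na(x$scan) | x$scan < 1L)) {
    stop("scan index must be a positive integer")
  }
  unknown <- setdiff(unique(c(x$id_a, x$id_b)), roster$id)
  if (length(unknown)) {
    stop("id(s) not in roster: ", paste(unknown, collapse = ", "))
  }
  if (nrow(x) && any(x$id_a == x$id_b)) stop("self-dyads are not allowed")
  swap <- x$id_a > x$id_b
  if (any(swap)) {
    tmp <- x$id_a[swap]
    x$id_a[swap] <- x$id_b[swap]
    x$id_b[swap] <- tmp
  }
  x$state <- as.integer(x$state)
  if (nrow(x) && any(!x$state %in% c(0L, 1L) & !is.na(x$state))) {
    stop("state must be 0, 1 or NA")
  }
  key <- paste(x$date, x$context, x$scan, x$id_a, x$id_b, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate scan record(s) for key(s): ",
         paste(head(unique(gsub("\r", "/", key[duplicated(key)])), 3L),
               collapse = "; "))
  }
  x <- x[order(x$date, x$context, x$scan, x$id_a, x$id_b),
         c("date", "context", "scan", "id_a", "id_b", "state")]
  rownames(x) <- NULL
  class(x) <- c("proxnet_scans", "data.frame")
  x
}

#' @rdname read_scans
#' @param scans a `proxnet_scans` table.
#' @export
write_scans <- function(scans, path) {
  out <- data.frame(date = format(scans$date, "%Y-%m-%d"),
                    context = scans$context, scan = scans$scan,
                    id1 = scans$id_a, id2 = scans$id_b,
                    state = ifelse(is.na(scans$state), "NA", scans$state),
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.proxnet_scans <- function(x, ...) {
  cat("Scan records:", nrow(x), "dyad-scan rows,",
      length(unique(x$date)), "dates,",
      "contexts:", paste(sort(unique(x$context)), collapse = "/"), "\n")
  print(head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
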