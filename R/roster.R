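#' Roster construction and I/O
#'
#' A roster is the ordered table of study individuals; its row order fixes
#' the row/column order of every matrix produced downstream. Required
#' columns: `id` (short unique label), `sex` (`F`/`M`), `origin`
#' (`Goma`/`Kinigi`/`Single`), `estimated_age` (integer years, >= 0) and
#' `status` (`Adult`/`Subadult`/`Silverback`/`Blackback`).
#'
#' @param x data.frame with the five roster columns.
#' @return A `proxnet_roster`: a validated data.frame with those columns.
#' @examples
#' roster(data.frame(
#'   id = c("A", "B", "C"), sex = c("F", "F", "M"),
#'   origin = c("Goma", "Single", "Goma"),
#'   estimated_age = c(10L, 12L, 14L),
#'   status = c("Adult", "Adult", "Silverback")
#' ))
#' @export
roster <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("id", "sex", "origin", "estimated_age", "status")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("roster is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- x[, need]
  x$id <- as.character(x$id)
  x$sex <- as.character(x$sex)
  x$origin <- as.character(x$origin)
  x$status <- as.character(x$status)
  x$estimated_age <- as.integer(x$estimated_age)
  if (nrow(x) < 3L) {
    stop("a roster needs at least 3 individuals, got ", nrow(x))
  }
  dup <- unique(x$id[duplicated(x$id)])
  if (length(dup)) {
    stop("duplicate individual id(s) in roster: ", paste(dup, collapse = ", "))
  }
  .check_vocab(x$sex, c("F", "M"), "sex")
  .check_vocab(x$origin, c("Goma", "Kinigi", "Single"), "origin")
  .check_vocab(x$status, c("Adult", "Subadult", "Silverback", "Blackback"),
               "status")
  if (anyNA(x$estimated_age) || any(x$estimated_age < 0L)) {
    stop("estimated_age must be a non-negative integer for every individual")
  }
  rownames(x) <- NULL
  class(x) <- c("proxnet_roster", "data.frame")
  x
}

.check_vocab <- function(values, vocab, field) {
  bad <- unique(values[!values %in% vocab])
  if (length(bad)) {
    stop("unknown ", field, " value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(vocab, collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Read a roster from CSV
#'
#' The file must carry a header naming the five roster fields
#' (`id,sex,origin,estimated_age,status`, any column order); file row order
#' is preserved and fixes matrix ordering downstream.
#'
#' @param path path to a CSV file.
#' @return A [roster()] object.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("roster file not found: ", path)
  roster(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_roster
#' @param r a roster.
#' @export
write_roster <- function(r, path) {
  stopifnot(inherits(r, "proxnet_roster"))
  write.csv(as.data.frame(r), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.proxnet_roster <- function(x, ...) {
  cat("Roster of", nrow(x), "individuals (",
      sum(x$sex == "F"), "F /", sum(x$sex == "M"), "M )\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

n_dyads <- function(n) n * (n - 1L) / 2L

#' All unordered dyads of a roster, in canonical order
#'
#' Canonical order: pairs `(i, j)` with `i < j` by roster position, so for
#' N individuals there are exactly N(N-1)/2 dyads.
#'
#' @param r a roster or character vector of ids.
#' @return data.frame with columns `id_a`, `id_b`.
#' @export
dyads <- function(r) {
  ids <- if (is.character(r)) r else r$id
  p <- combn(seq_along(ids), 2L)
  data.frame(id_a = ids[p[1L, ]], id_b = ids[p[2L, ]],
             stringsAsFactors = FALSE)
}
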