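#' Association matrix container
#'
#' A symmetric N x N matrix of association indices in [0, 1] with a zero
#' diagonal, carrying its context label and the number of observation days
#' behind it. Row/column order is the roster order.
#'
#' @param values numeric symmetric matrix, entries in [0,1], diagonal 0.
#' @param labels character vector of ids (defaults to dimnames).
#' @param context context label.
#' @param n_observations number of observation days used.
#' @return An `assoc_matrix` object.
#' @export
assoc_matrix <- function(values, labels = NULL, context = NA_character_,
                         n_observations = NA_integer_) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(values)))
  n <- length(labels)
  if (!all(dim(values) == c(n, n))) {
    stop("matrix dimensions do not match the ", n, " labels")
  }
  if (anyNA(values)) stop("association matrix must not contain NA")
  if (max(abs(values - t(values))) > 1e-12) {
    stop("association matrix must be symmetric")
  }
  values <- (values + t(values)) / 2  # exact symmetry
  if (any(values < 0) || any(values > 1)) {
    stop("association indices must lie in [0, 1]")
  }
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, context = context,
                 n_observations = as.integer(n_observations)),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat("Association matrix (", x$context, "): ", length(x$labels),
      " individuals, ", x$n_observations, " observation days\n", sep = "")
  ut <- upper_tri(x)
  cat(sprintf("mean index %.3f, SD %.3f, range [%.3f, %.3f]\n",
              mean(ut), stats::sd(ut), min(ut), max(ut)))
  invisible(x)
}

#' Upper-triangle dyadic values of a symmetric matrix
#'
#' Returns the N(N-1)/2 off-diagonal dyadic values (each unordered dyad
#' once), in canonical dyad order.
#'
#' @param m an `assoc_matrix` or plain symmetric matrix.
#' @return numeric vector of length N(N-1)/2.
#' @export
upper_tri <- function(m) {
  v <- if (inherits(m, "assoc_matrix")) m$values else as.matrix(m)
  t(v)[lower.tri(v)]  # row-major upper triangle = canonical dyad order
}

#' Write / read an association matrix as CSV
#'
#' Full square matrix with id header row and id first column; symmetry,
#' range and zero diagonal are re-checked on read. Round trip is exact to
#' stored precision (17 significant digits).
#'
#' @param m an `assoc_matrix`.
#' @param path file path.
#' @export
write_assoc_matrix <- function(m, path) {
  stopifnot(inherits(m, "assoc_matrix"))
  v <- m$values
  lines <- c(
    paste(c("id", m$labels), collapse = ","),
    vapply(seq_along(m$labels), function(i) {
      paste(c(m$labels[i], format(v[i, ], digits = 17, trim = TRUE,
                                  scientific = FALSE)),
            collapse = ",")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_assoc_matrix
#' @param roster optional [roster()]; labels must match if given.
#' @param context,n_observations metadata for the returned object.
#' @export
read_assoc_matrix <- function(path, roster = NULL,
                              context = NA_character_,
                              n_observations = NA_integer_) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(x[[1L]])
  v <- as.matrix(x[, -1L, drop = FALSE])
  if (!identical(colnames(v), labels)) {
    stop("matrix header ids do not match row ids")
  }
  if (!is.null(roster)) {
    if (!identical(labels, roster$id)) {
      stop("matrix labels do not match the roster (order matters)")
    }
  }
  storage.mode(v) <- "double"
  assoc_matrix(v, labels, context = context, n_observations = n_observations)
}
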