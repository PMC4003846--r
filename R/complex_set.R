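#' Complex sets
#'
#' A *complex* is a non-empty set of protein identifiers (opaque,
#' case-sensitive strings); a *complex set* is an ordered collection of
#' complexes — either the predictions of [detect_complexes()] or a reference
#' catalogue such as a CYC2008-style benchmark. A complex set is represented
#' as a tibble with one row per complex and columns
#'
#' * `complex_id` — integer position (insertion order is meaningful and
#'   preserved),
#' * `size` — number of distinct members,
#' * `members` — list-column of character vectors, each sorted and unique.
#'
#' `complex_set()` builds one from a list of character vectors;
#' `as_complex_set()` coerces a list, a `data.frame` with a `members`
#' list-column, or a long tibble with `complex_id` + `protein` columns.
#'
#' @param members A list of character vectors, one per complex.
#' @param x Object to coerce.
#' @return A `complex_set` tibble.
#' @examples
#' cs <- complex_set(list(c("B", "A"), c("C", "D", "E")))
#' cs$size
#' @export
complex_set <- function(members = list()) {
  stopifnot(is.list(members))
  members <- lapply(unname(members), function(m) {
    m <- as.character(m)
    if (length(m) == 0 || anyNA(m)) {
      abort("every complex must be a non-empty set of protein identifiers")
    }
    sort(unique(m), method = "radix")
  })
  out <- tibble(
    complex_id = seq_along(members),
    size = if (length(members)) vapply(members, length, 1L) else integer(),
    members = members
  )
  class(out) <- c("complex_set", class(out))
  out
}

#' @rdname complex_set
#' @export
as_complex_set <- function(x) {
  if (inherits(x, "complex_set")) return(complex_set(x$members))
  if (is.list(x) && !is.data.frame(x)) return(complex_set(x))
  if (is.data.frame(x)) {
    if ("members" %in% names(x)) return(complex_set(x$members))
    if (all(c("complex_id", "protein") %in% names(x))) {
      return(complex_set(unname(split(x$protein, x$complex_id))))
    }
  }
  abort("cannot interpret `x` as a complex set")
}

#' @rdname complex_set
#' @export
is_complex_set <- function(x) inherits(x, "complex_set")

# strip members down to plain list of character vectors
members_list <- function(x) {
  if (is_complex_set(x) || (is.data.frame(x) && "members" %in% names(x))) {
    x <- x$members
  }
  if (!is.list(x)) abort("expected a complex set or list of member vectors")
  x
}

#' @export
print.complex_set <- function(x, ...) {
  cat(sprintf("# A complex set: %d complexes\n", nrow(x)))
  NextMethod()
  invisible(x)
}

#' Turn a complex set into a long tidy table
#'
#' One row per (complex, member) pair — convenient for joins against
#' per-protein annotation tables.
#'
#' @param x A `complex_set`.
#' @param ... Unused.
#' @return A tibble with columns `complex_id`, `size`, `protein`.
#' @export
tidy.complex_set <- function(x, ...) {
  tidyr::unnest(
    tibble(complex_id = x$complex_id, size = x$size, protein = x$members),
    "protein"
  )
}
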