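#' Weighted PPI networks
#'
#' A weighted protein-protein interaction network is an undirected graph with
#' a confidence weight `0 < w <= 1` on every edge; a pair of proteins without
#' a stored edge has weight exactly 0. The tabular representation is a tibble
#' with columns `protein_a`, `protein_b`, `weight`, canonicalized so that
#' `protein_a < protein_b` within each row and rows are sorted — two networks
#' with the same edges compare identical regardless of input row order.
#'
#' `ppi_network()` validates and canonicalizes a data frame of edges.
#' Isolated vertices (degree 0) cannot be carried by an edge list; they may be
#' supplied through `vertices` and are kept as an attribute so that seeding
#' and density lookups still see them.
#'
#' @param edges A data frame whose first three columns are interpreted as
#'   protein a, protein b and the confidence weight.
#' @param on_duplicate Policy when the same unordered pair appears more than
#'   once: `"error"` (default; duplicates with *equal* weights collapse
#'   silently, conflicting weights are an error), `"max"`, or `"mean"`.
#' @param vertices Optional character vector of vertex identifiers to include
#'   in addition to edge endpoints (e.g. isolated proteins).
#' @return A `ppi_network` tibble.
#' @examples
#' net <- ppi_network(data.frame(a = "A", b = "B", w = 0.75))
#' edge_weight(net, "A", "B")
#' edge_weight(net, "A", "Z") # non-edge: exactly 0
#' @export
ppi_network <- function(edges, on_duplicate = c("error", "max", "mean"),
                        vertices = NULL) {
  on_duplicate <- match.arg(on_duplicate)
  if (!is.data.frame(edges) || ncol(edges) < 3) {
    abort("`edges` must be a data frame with >= 3 columns (a, b, weight)")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  w <- edges[[3]]
  if (!is.numeric(w)) {
    w <- suppressWarnings(as.numeric(w))
    if (anyNA(w)) abort("malformed weight column: non-numeric values")
  }
  bad <- which(!is.finite(w) | w <= 0 | w > 1)
  if (length(bad)) {
    abort(sprintf(
      "edge weight must lie in (0, 1]; offending row(s): %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  loops <- which(a == b)
  if (length(loops)) {
    abort(sprintf(
      "self-loops are not allowed; offending row(s): %s",
      paste(head(loops, 5), collapse = ", ")
    ))
  }
  # canonical unordered pair: lexicographically smaller endpoint first
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    grp <- factor(match(key, key), levels = unique(match(key, key)))
    rng <- tapply(w, grp, function(x) diff(range(x)))
    if (on_duplicate == "error" && any(rng > 0)) {
      abort(paste(
        "duplicate edges with conflicting weights;",
        'use on_duplicate = "max" or "mean" to resolve'
      ))
    }
    agg <- switch(on_duplicate, error = , max = max, mean = mean)
    w <- as.numeric(tapply(w, grp, agg))
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
  }
  out <- tibble(protein_a = a, protein_b = b, weight = w)
  out <- out[order(out$protein_a, out$protein_b, method = "radix"), ]
  verts <- sort(unique(c(a, b, as.character(vertices %||% character()))),
                method = "radix")
  new_tibble(out, vertices = verts, class = "ppi_network")
}

#' @rdname ppi_network
#' @export
is_ppi_network <- function(x) inherits(x, "ppi_network")

#' @rdname ppi_network
#' @param net A `ppi_network`.
#' @export
network_vertices <- function(net) {
  v <- attr(net, "vertices")
  if (is.null(v)) v <- sort(unique(c(net[[1]], net[[2]])), method = "radix")
  v
}

#' @rdname ppi_network
#' @param u,v Vertex identifiers.
#' @export
edge_weight <- function(net, u, v) {
  stopifnot(length(u) == length(v))
  a <- pmin(as.character(u), as.character(v))
  b <- pmax(as.character(u), as.character(v))
  i <- match(paste(a, b, sep = "\r"),
             paste(net$protein_a, net$protein_b, sep = "\r"))
  w <- net$weight[i]
  w[is.na(w) | a == b] <- 0
  w
}

#' Read and write weighted edge lists
#'
#' The on-disk dialect is the de facto format of affinity-scored interaction
#' maps (and of MCL `.abc` inputs): three whitespace- or tab-separated
#' columns `id_a id_b weight`, `#` comment lines ignored. Weights must lie in
#' `(0, 1]` and self-loop rows are rejected; both errors name the offending
#' line. Duplicate rows for the same unordered pair are resolved per
#' `on_duplicate` (see [ppi_network()]).
#'
#' @param path File path.
#' @inheritParams ppi_network
#' @return `read_ppi_network()` returns a `ppi_network`;
#'   `write_ppi_network()` invisibly returns `net`.
#' @export
read_ppi_network <- function(path, on_duplicate = c("error", "max", "mean")) {
  on_duplicate <- match.arg(on_duplicate)
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(ppi_network(tibble(protein_a = character(),
                              protein_b = character(),
                              weight = numeric())))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 3)) {
    abort(sprintf("malformed row (expected 3 columns) at line %d of %s",
                  lineno[which(nf != 3)[1]], path))
  }
  m <- matrix(unlist(fields), ncol = 3, byrow = TRUE)
  w <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(w)) {
    abort(sprintf("non-numeric weight at line %d of %s",
                  lineno[which(is.na(w))[1]], path))
  }
  bad <- which(!is.finite(w) | w <= 0 | w > 1)
  if (length(bad)) {
    abort(sprintf("edge weight outside (0, 1] at line %d of %s",
                  lineno[bad[1]], path))
  }
  loops <- which(m[, 1] == m[, 2])
  if (length(loops)) {
    abort(sprintf("self-loop at line %d of %s", lineno[loops[1]], path))
  }
  ppi_network(tibble(protein_a = m[, 1], protein_b = m[, 2], weight = w),
              on_duplicate = on_duplicate)
}

#' @rdname read_ppi_network
#' @param net A `ppi_network`.
#' @export
write_ppi_network <- function(net, path) {
  readr::write_tsv(as_tibble(net)[, c("protein_a", "protein_b", "weight")],
                   path, col_names = FALSE)
  invisible(net)
}

#' Read and write complex-set files
#'
#' One complex per line, members tab-separated (MCL-style cluster output;
#' also fits CYC2008-style reference catalogues). Reading preserves file
#' order, collapses duplicate members within a line (with a warning) and
#' skips empty lines (with a warning). Writing sorts members
#' lexicographically within each line, so write-then-read round-trips any
#' complex set exactly.
#'
#' @param path File path.
#' @return `read_complexes()` returns a [complex_set()];
#'   `write_complexes()` invisibly returns `cs`.
#' @export
read_complexes <- function(path) {
  lines <- readr::read_lines(path)
  empty <- grepl("^\\s*$", lines)
  if (any(empty)) {
    warn(sprintf("%d empty line(s) skipped in %s", sum(empty), path))
    lines <- lines[!empty]
  }
  members <- strsplit(lines, "\t", fixed = TRUE)
  members <- lapply(members, function(m) m[nzchar(m)])
  if (any(vapply(members, anyDuplicated, 1L) > 0)) {
    warn(sprintf("duplicate members within a complex collapsed in %s", path))
  }
  complex_set(members)
}

#' @rdname read_complexes
#' @param cs A [complex_set()] (or anything [as_complex_set()] accepts).
#' @export
write_complexes <- function(cs, path) {
  cs <- as_complex_set(cs)
  lines <- vapply(cs$members, paste, "", collapse = "\t")
  readr::write_lines(lines, path)
  invisible(cs)
}
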