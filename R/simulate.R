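#' Simulate a weighted network with planted protein complexes
#'
#' Generates a confidence-weighted network containing vertex-disjoint
#' planted complexes over a background of noise vertices, together with the
#' ground-truth complex set, so that detection and evaluation can be
#' exercised end-to-end with no external data. Each within-complex pair is
#' joined with probability `p_in` and a weight drawn uniformly from `w_in`;
#' every other pair (background-background, background-complex and
#' cross-complex) is joined with probability `p_out` and a weight from
#' `w_out`.
#'
#' The defaults describe a strong-signal regime — near-clique complexes with
#' high confidence weights over sparse, low-confidence noise — emulating the
#' character of high-confidence affinity-scored interaction maps: bounded
#' confidence weights with a clear separation between true-complex edges and
#' residual noise. They do not emulate any particular dataset's degree or
#' score distribution.
#'
#' @param n_complexes Number of planted complexes (default 5).
#' @param size_range Inclusive `(min, max)` complex size; minimum `>= 2`
#'   (default 4 to 8).
#' @param p_in Within-complex edge probability (default 1: planted cliques).
#' @param p_out Background edge probability; must be `< p_in`
#'   (default 0.01).
#' @param w_in,w_out Length-2 weight ranges within `(0, 1]` for uniform
#'   draws (defaults `c(0.8, 1)` and `c(0.05, 0.15)`).
#' @param n_background Number of extra noise vertices (default 50).
#' @param seed Integer RNG seed; the generated instance is a pure function
#'   of it. `NULL` uses the current RNG state.
#' @return A list of class `planted_network` with elements `network` (a
#'   [ppi_network()], isolated vertices retained as network vertices) and
#'   `truth` (a [complex_set()] of the planted complexes).
#' @examples
#' sim <- simulate_planted_network(seed = 1)
#' sim$truth$size
#' @export
simulate_planted_network <- function(n_complexes = 5,
                                     size_range = c(4, 8),
                                     p_in = 1,
                                     p_out = 0.01,
                                     w_in = c(0.8, 1),
                                     w_out = c(0.05, 0.15),
                                     n_background = 50,
                                     seed = NULL) {
  stopifnot(
    n_complexes >= 1, length(size_range) == 2,
    size_range[1] >= 2, size_range[2] >= size_range[1],
    p_in > 0, p_in <= 1, p_out >= 0, p_out < p_in,
    length(w_in) == 2, all(w_in > 0), all(w_in <= 1), w_in[1] <= w_in[2],
    length(w_out) == 2, all(w_out > 0), all(w_out <= 1), w_out[1] <= w_out[2],
    n_background >= 0
  )
  gen <- function() {
    sizes <- sample(size_range[1]:size_range[2], n_complexes, replace = TRUE)
    n <- sum(sizes) + n_background
    verts <- sprintf("P%04d", seq_len(n))
    assignment <- rep(c(seq_len(n_complexes), NA_integer_),
                      c(sizes, n_background))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pairs[, 1]; j <- pairs[, 2]
    same <- !is.na(assignment[i]) & !is.na(assignment[j]) &
      assignment[i] == assignment[j]
    u <- runif(length(i))
    keep <- ifelse(same, u < p_in, u < p_out)
    w <- ifelse(same,
                runif(length(i), w_in[1], w_in[2]),
                runif(length(i), w_out[1], w_out[2]))
    edges <- tibble(
      protein_a = verts[i][keep],
      protein_b = verts[j][keep],
      weight = w[keep]
    )
    truth <- complex_set(split(verts[!is.na(assignment)],
                               assignment[!is.na(assignment)]))
    list(
      network = ppi_network(edges, vertices = verts),
      truth = truth
    )
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  class(out) <- "planted_network"
  out
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf(
    "# Planted-complex network: %d vertices, %d edges, %d planted complexes (sizes %s)\n",
    length(network_vertices(x$network)), nrow(x$network), nrow(x$truth),
    paste(x$truth$size, collapse = ", ")
  ))
  invisible(x)
}
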