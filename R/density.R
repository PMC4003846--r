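#' Weighted density of a vertex set
#'
#' The weighted density of a set of proteins `S` in a confidence-weighted
#' network is the sum of the weights of the edges among members of `S`
#' divided by the number of possible pairs, `|S| * (|S| - 1) / 2`. It ranges
#' from 0 (no internal edges) to 1 (a clique with every weight 1) and
#' measures how close the induced subgraph is to a unit-weight clique.
#'
#' A singleton has no pairs; its density is defined as 1 so that a bare seed
#' never fails its own density threshold during expansion (singletons are
#' later dropped by the minimum-size filter of [detect_complexes()]).
#'
#' @param network A [ppi_network()] (any 3-column edge data frame is
#'   coerced).
#' @param members Character vector of protein identifiers, all present in
#'   the network.
#' @return A single number in `[0, 1]`.
#' @examples
#' net <- ppi_network(data.frame(a = "0", b = "1", w = 0.75))
#' weighted_density(net, c("0", "1")) # 0.75
#' @export
weighted_density <- function(network, members) {
  if (!is_ppi_network(network)) network <- ppi_network(network)
  members <- unique(as.character(members))
  if (length(members) == 0) abort("`members` must be non-empty")
  missing <- setdiff(members, network_vertices(network))
  if (length(missing)) {
    abort(sprintf("member(s) not in network: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (length(members) == 1) return(1)
  inside <- network$protein_a %in% members & network$protein_b %in% members
  n <- length(members)
  sum(network$weight[inside]) / (n * (n - 1) / 2)
}
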