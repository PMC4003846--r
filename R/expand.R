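# adjacency: named list, adj[[v]] = named numeric vector of neighbour weights
build_adjacency <- function(net) {
  from <- c(net$protein_a, net$protein_b)
  to <- c(net$protein_b, net$protein_a)
  w <- rep.int(net$weight, 2)
  idx <- split(seq_along(from), from)
  adj <- lapply(idx, function(i) setNames(w[i], to[i]))
  # isolated vertices get an empty neighbourhood
  iso <- setdiff(network_vertices(net), names(adj))
  if (length(iso)) adj[iso] <- list(setNames(numeric(), character()))
  adj
}

# Candidate-loop expansion from one seed over a prebuilt adjacency.
# Frontier = unclustered, not-yet-rejected vertices adjacent to the cluster;
# priority = maximum edge weight connecting the candidate to any cluster
# member, ties broken by lexicographically smallest identifier. The highest
# priority candidate is tentatively added; it stays iff the cluster's
# weighted density remains >= td, otherwise it is permanently rejected for
# this cluster. A running edge-weight sum makes each density update O(deg).
expand_impl <- function(adj, seed, td, trace = FALSE) {
  cluster <- seed
  rejected <- character()
  wsum <- 0
  pri <- adj[[seed]]
  pri <- pri[order(names(pri), method = "radix")]
  steps <- if (trace) list() else NULL

  while (length(pri)) {
    top <- which(pri == max(pri))[1] # names sorted, so first max is lex-min
    v <- names(pri)[top]
    conn <- adj[[v]]
    new_sum <- wsum + sum(conn[names(conn) %in% cluster])
    n <- length(cluster) + 1
    dens <- if (n == 1) 1 else new_sum / (n * (n - 1) / 2)
    ok <- dens >= td
    if (trace) {
      steps[[length(steps) + 1]] <- tibble(
        vertex = v, priority = unname(pri[top]),
        density = dens, accepted = ok
      )
    }
    pri <- pri[-top]
    if (ok) {
      cluster <- c(cluster, v)
      wsum <- new_sum
      nb <- conn[!(names(conn) %in% c(cluster, rejected))]
      if (length(nb)) {
        known <- names(nb) %in% names(pri)
        if (any(known)) {
          k <- names(nb)[known]
          pri[k] <- pmax(pri[k], nb[known])
        }
        if (any(!known)) {
          add <- nb[!known]
          pri <- c(pri, add)
          pri <- pri[order(names(pri), method = "radix")]
        }
      }
    } else {
      rejected <- c(rejected, v)
    }
  }
  members <- sort(cluster, method = "radix")
  if (trace) {
    empty <- tibble(vertex = character(), priority = numeric(),
                    density = numeric(), accepted = logical())
    attr(members, "trace") <- bind_rows(c(list(empty), steps))
  }
  members
}

#' Grow one cluster from a seed protein
#'
#' Breadth-first seed expansion under a weighted-density floor: starting from
#' the singleton `{seed}`, the unclustered neighbour with the highest edge
#' weight to any current member is repeatedly tried; it is kept if the
#' cluster's [weighted_density()] stays at or above `td`, and otherwise
#' permanently rejected for this cluster. Expansion continues after a
#' rejection and stops only when no candidate remains, so the returned
#' cluster always has weighted density `>= td` (vacuously for a singleton).
#'
#' A rejected vertex remains available as a seed of its own and as a member
#' of clusters grown from other seeds; expansions from different seeds may
#' therefore overlap (the redundancy filter of [detect_complexes()] prunes
#' near-duplicates).
#'
#' @param network A [ppi_network()].
#' @param seed A vertex identifier present in the network.
#' @param td Weighted density threshold in `[0, 1]`; with `td = 0` the
#'   expansion returns the seed's entire connected component.
#' @param trace If `TRUE`, attach a `"trace"` attribute: a tibble with one
#'   row per candidate decision (`vertex`, `priority`, `density`,
#'   `accepted`).
#' @return Character vector of member identifiers, sorted.
#' @examples
#' net <- ppi_network(data.frame(
#'   a = c("s", "s", "s"), b = c("x", "y", "z"), w = c(0.9, 0.8, 0.1)
#' ))
#' expand_cluster(net, "s", td = 0.5) # keeps x and y, rejects z
#' @export
expand_cluster <- function(network, seed, td = 0.1, trace = FALSE) {
  if (!is_ppi_network(network)) network <- ppi_network(network)
  seed <- as.character(seed)
  stopifnot(length(seed) == 1, td >= 0, td <= 1)
  if (!seed %in% network_vertices(network)) {
    abort(sprintf("seed '%s' is not a vertex of the network", seed))
  }
  expand_impl(build_adjacency(network), seed, td, trace = trace)
}
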