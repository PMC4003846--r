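# Independent oracles and fixture builders shared across the suite.

# brute-force weighted density: explicit double loop over unordered pairs
density_oracle <- function(net, members) {
  members <- unique(members)
  if (length(members) == 1) return(1)
  s <- 0
  for (i in seq_along(members)) {
    for (j in seq_len(i - 1)) {
      s <- s + edge_weight(net, members[i], members[j])
    }
  }
  s / (length(members) * (length(members) - 1) / 2)
}

# all permutations of a vector (n <= 6 in the suite)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# brute-force MMR: enumerate every one-to-one mapping via permutations of a
# zero-padded square overlap-score matrix
mmr_oracle <- function(pred, ref) {
  pred <- as_complex_set(pred)
  ref <- as_complex_set(ref)
  np <- nrow(pred)
  nr <- nrow(ref)
  k <- max(np, nr)
  m <- matrix(0, k, k)
  for (i in seq_len(np)) {
    for (j in seq_len(nr)) {
      m[i, j] <- overlap_score(pred$members[[i]], ref$members[[j]])
    }
  }
  best <- 0
  for (p in all_perms(seq_len(k))) {
    best <- max(best, sum(m[cbind(seq_len(k), p)]))
  }
  best / nr
}

# random Erdos-Renyi weighted network; weights in (0, 1]
rand_network <- function(n, p = 0.3) {
  v <- sprintf("v%02d", seq_len(n))
  pr <- t(combn(v, 2))
  keep <- stats::runif(nrow(pr)) < p
  if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
  ppi_network(
    data.frame(
      a = pr[keep, 1], b = pr[keep, 2],
      w = round(stats::runif(sum(keep), 0.01, 1), 4)
    ),
    vertices = v
  )
}

# random complex set over a small protein universe
rand_complex_set <- function(n_complexes, universe = sprintf("p%02d", 1:20),
                             max_size = 8) {
  complex_set(lapply(seq_len(n_complexes), function(i) {
    sample(universe, sample(2:max_size, 1))
  }))
}

# 12-vertex reconstruction of the worked seed-expansion example: a chain
# 0-1-2-3-4-5 closed by a weak 0-5 edge, with rejected branches hanging off
# vertices 4, 3, 2, 5 and an unreachable tail 6-7-8. From seed "00" at
# Td = 0.2 the expansion accepts 1..5 in order (final density 3.45/15 =
# 0.23), then rejects 6 (tentative density 3.97/21 ~ 0.19), 9, 10 and 11.
walkthrough_network <- function() {
  ppi_network(data.frame(
    a = c("00", "01", "02", "03", "04", "00", "04", "03", "02", "05", "06", "07"),
    b = c("01", "02", "03", "04", "05", "05", "06", "09", "10", "11", "07", "08"),
    w = c(0.75, 0.70, 0.65, 0.60, 0.55, 0.20, 0.52, 0.51, 0.45, 0.40, 0.80, 0.76)
  ))
}

two_triangles <- function() {
  ppi_network(data.frame(
    a = c("A", "B", "C", "X", "Y", "Z"),
    b = c("B", "C", "A", "Y", "Z", "X"),
    w = 1
  ))
}

write_edge_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
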