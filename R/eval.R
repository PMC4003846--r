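# overlap score on two plain member vectors
os_members <- function(a, b) {
  i <- length(intersect(a, b))
  if (i == 0) return(0)
  i^2 / (length(a) * length(b))
}

#' Overlap score between two complexes
#'
#' `OS(A, B) = i^2 / (g * h)` where `i` is the number of shared proteins and
#' `g`, `h` the two complex sizes. The score is symmetric, lies in
#' `[0, 1]`, equals 1 iff the two complexes contain exactly the same
#' proteins, and is positive iff they share at least one protein. It is the
#' standard neighbourhood-affinity criterion for deciding whether a
#' predicted complex matches a reference complex.
#'
#' @param a,b Non-empty character vectors of protein identifiers.
#' @return A single number in `[0, 1]`.
#' @examples
#' overlap_score(letters[1:14], c(letters[1:4], LETTERS[1:6])) # 16/140
#' @export
overlap_score <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0 || length(b) == 0) abort("complexes must be non-empty")
  os_members(a, b)
}

# all-pairs overlap score matrix (|pred| x |ref|) via sparse incidence
os_matrix <- function(pred, ref) {
  pred <- members_list(pred)
  ref <- members_list(ref)
  prot <- unique(c(unlist(pred), unlist(ref)))
  mk <- function(sets) {
    Matrix::sparseMatrix(
      i = match(unlist(sets), prot),
      j = rep.int(seq_along(sets), lengths(sets)),
      x = 1,
      dims = c(length(prot), length(sets))
    )
  }
  if (length(pred) == 0 || length(ref) == 0) {
    return(matrix(0, length(pred), length(ref)))
  }
  inter <- as.matrix(Matrix::crossprod(mk(pred), mk(ref)))
  inter^2 / outer(lengths(pred), lengths(ref))
}

#' Complex-level confusion counts at an overlap-score threshold
#'
#' A predicted complex is a true positive if its best overlap score against
#' the reference catalogue reaches `os_threshold` (inclusive); the remaining
#' predictions are false positives. A reference complex not reached at the
#' threshold by any prediction is a false negative.
#'
#' @param pred,ref [complex_set()]s (anything [as_complex_set()] accepts):
#'   predictions and reference catalogue. `ref` must be non-empty.
#' @param os_threshold Overlap-score threshold in `[0, 1]`; default 0.2, the
#'   conventional benchmark match level.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, ref, os_threshold = 0.2) {
  pred <- as_complex_set(pred)
  ref <- as_complex_set(ref)
  stopifnot(os_threshold >= 0, os_threshold <= 1)
  if (nrow(ref) == 0) abort("reference complex set is empty: metrics undefined")
  if (nrow(pred) == 0) {
    return(tibble(tp = 0L, fp = 0L, fn = nrow(ref)))
  }
  os <- os_matrix(pred, ref)
  tp <- sum(apply(os, 1, max) >= os_threshold)
  fn <- sum(apply(os, 2, max) < os_threshold)
  tibble(tp = as.integer(tp), fp = nrow(pred) - as.integer(tp),
         fn = as.integer(fn))
}

#' Precision, recall and F-measure from confusion counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)` and the F-measure
#' is their harmonic mean `2 * R * P / (R + P)`. Any 0/0 evaluates to 0.
#'
#' @param counts A data frame or named list with elements `tp`, `fp`, `fn`
#'   (as produced by [confusion_counts()]).
#' @return A one-row tibble with columns `recall`, `precision`, `f_measure`.
#' @examples
#' precision_recall_f(list(tp = 2, fp = 1, fn = 2))
#' @export
precision_recall_f <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  safe <- function(num, den) if (den == 0) 0 else num / den
  recall <- safe(tp, tp + fn)
  precision <- safe(tp, tp + fp)
  f <- safe(2 * recall * precision, recall + precision)
  tibble(recall = recall, precision = precision, f_measure = f)
}

#' Maximum matching ratio
#'
#' Build the bipartite graph joining every prediction-reference pair with a
#' positive overlap score, each edge weighted by that score; compute an
#' exact maximum-total-weight one-to-one matching; return the matched weight
#' divided by the number of reference complexes. MMR rewards a clean
#' one-to-one correspondence with the reference catalogue: no reference
#' complex can absorb credit from more than one prediction.
#'
#' @inheritParams confusion_counts
#' @return A single number in `[0, 1]`.
#' @export
max_matching_ratio <- function(pred, ref) {
  pred <- as_complex_set(pred)
  ref <- as_complex_set(ref)
  if (nrow(ref) == 0) abort("reference complex set is empty: MMR undefined")
  if (nrow(pred) == 0) return(0)
  os <- os_matrix(pred, ref)
  if (all(os == 0)) return(0)
  dimnames(os) <- list(paste0("p", seq_len(nrow(os))),
                       paste0("r", seq_len(ncol(os))))
  g <- igraph::graph_from_biadjacency_matrix(os, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  m$matching_weight / nrow(ref)
}

#' Match counts over a grid of overlap-score thresholds
#'
#' For each threshold `t` in 0, 0.1, ..., 1.0, count (a) the predictions
#' whose best overlap score against the reference reaches `t` and (b) the
#' reference complexes whose best overlap score against the predictions
#' reaches `t` (both inclusive). The row at `t = 0` always equals the two
#' set sizes, and both columns are non-increasing in the threshold.
#'
#' @inheritParams confusion_counts
#' @param thresholds Numeric grid of thresholds; default `seq(0, 1, 0.1)`.
#' @return A tibble with columns `os_threshold`, `n_pred_matched`,
#'   `n_ref_matched`.
#' @export
match_count_table <- function(pred, ref, thresholds = seq(0, 1, by = 0.1)) {
  pred <- as_complex_set(pred)
  ref <- as_complex_set(ref)
  if (nrow(pred) == 0 || nrow(ref) == 0) {
    abort("both complex sets must be non-empty")
  }
  os <- os_matrix(pred, ref)
  best_pred <- apply(os, 1, max)
  best_ref <- apply(os, 2, max)
  tibble(
    os_threshold = thresholds,
    n_pred_matched = vapply(thresholds, function(t) sum(best_pred >= t), 1L),
    n_ref_matched = vapply(thresholds, function(t) sum(best_ref >= t), 1L)
  )
}

#' Evaluate predicted complexes against a reference catalogue
#'
#' The full evaluation report: confusion counts and precision / recall /
#' F-measure at `os_threshold`, the maximum matching ratio, and the match
#' count table over thresholds 0 to 1. Reference complexes with fewer than
#' `min_ref_size` members are removed before any metric is computed
#' (benchmark catalogues are conventionally restricted to complexes of two
#' or more proteins).
#'
#' @inheritParams confusion_counts
#' @param min_ref_size Minimum reference complex size retained; default 2.
#' @return A `complex_eval` object (a list). [glance()] gives the one-row
#'   metric summary, [tidy()] the match count table, [autoplot()] the match
#'   curves.
#' @examples
#' pred <- complex_set(list(c("A", "B", "C"), c("D", "E")))
#' evaluate_complexes(pred, pred)
#' @export
evaluate_complexes <- function(pred, ref, os_threshold = 0.2,
                               min_ref_size = 2) {
  pred <- as_complex_set(pred)
  ref <- as_complex_set(ref)
  ref <- complex_set(ref$members[ref$size >= min_ref_size])
  if (nrow(ref) == 0) {
    abort("reference complex set is empty after size filtering")
  }
  counts <- confusion_counts(pred, ref, os_threshold)
  prf <- precision_recall_f(counts)
  out <- list(
    counts = counts,
    recall = prf$recall,
    precision = prf$precision,
    f_measure = prf$f_measure,
    mmr = max_matching_ratio(pred, ref),
    os_threshold = os_threshold,
    n_pred = nrow(pred),
    n_ref = nrow(ref),
    match_table = if (nrow(pred)) match_count_table(pred, ref) else NULL
  )
  class(out) <- "complex_eval"
  out
}

#' @export
print.complex_eval <- function(x, ...) {
  cat(sprintf(
    paste0(
      "# Complex evaluation (%d predicted vs %d reference, OS >= %g)\n",
      "  TP %d  FP %d  FN %d\n",
      "  recall %.3f  precision %.3f  F-measure %.3f  MMR %.3f\n"
    ),
    x$n_pred, x$n_ref, x$os_threshold,
    x$counts$tp, x$counts$fp, x$counts$fn,
    x$recall, x$precision, x$f_measure, x$mmr
  ))
  invisible(x)
}

#' @rdname evaluate_complexes
#' @param x,object A `complex_eval` object.
#' @param ... Unused.
#' @export
glance.complex_eval <- function(x, ...) {
  tibble(
    n_pred = x$n_pred, n_ref = x$n_ref,
    tp = x$counts$tp, fp = x$counts$fp, fn = x$counts$fn,
    recall = x$recall, precision = x$precision,
    f_measure = x$f_measure, mmr = x$mmr,
    os_threshold = x$os_threshold
  )
}

#' @rdname evaluate_complexes
#' @export
tidy.complex_eval <- function(x, ...) {
  x$match_table %||%
    tibble(os_threshold = numeric(), n_pred_matched = integer(),
           n_ref_matched = integer())
}

#' @rdname evaluate_complexes
#' @export
autoplot.complex_eval <- function(object, ...) {
  tab <- tidy(object)
  long <- tidyr::pivot_longer(tab, -"os_threshold",
                              names_to = "side", values_to = "n")
  long$side <- ifelse(long$side == "n_pred_matched",
                      "predictions matching a reference",
                      "references matched by a prediction")
  ggplot2::ggplot(long, ggplot2::aes(.data$os_threshold, .data$n,
                                     colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "overlap-score threshold", y = "count", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
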