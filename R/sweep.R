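#' Sweep the weighted-density threshold
#'
#' Runs [detect_complexes()] and [evaluate_complexes()] once per value of
#' `td` on a grid and collects the metrics, to examine how the density
#' threshold trades cluster granularity against benchmark agreement. On
#' affinity-scored yeast maps the F-measure is typically flat and maximal on
#' an interior plateau of thresholds (around 0.1), which motivates the
#' package default.
#'
#' @inheritParams detect_complexes
#' @param reference Reference [complex_set()].
#' @param td_grid Numeric vector of density thresholds; default
#'   `seq(0.01, 0.30, by = 0.01)`.
#' @inheritParams evaluate_complexes
#' @return A tibble with one row per grid value: `td`, `n_complexes`, `tp`,
#'   `fp`, `fn`, `recall`, `precision`, `f_measure`, `mmr`.
#' @export
sweep_td <- function(network, reference, td_grid = seq(0.01, 0.30, by = 0.01),
                     r = 0.8, min_size = 2, os_threshold = 0.2,
                     min_ref_size = 2) {
  if (length(td_grid) == 0) abort("`td_grid` must be non-empty")
  stopifnot(all(td_grid >= 0), all(td_grid <= 1))
  if (!is_ppi_network(network)) network <- ppi_network(network)
  reference <- as_complex_set(reference)
  rows <- map(td_grid, function(td) {
    cs <- detect_complexes(network, td = td, r = r, min_size = min_size)
    ev <- evaluate_complexes(cs, reference, os_threshold = os_threshold,
                             min_ref_size = min_ref_size)
    dplyr::bind_cols(
      tibble(td = td, n_complexes = nrow(cs)),
      glance(ev)[c("tp", "fp", "fn", "recall", "precision",
                   "f_measure", "mmr")]
    )
  })
  bind_rows(rows)
}

#' Plot a density-threshold sweep
#'
#' @param sweep A tibble from [sweep_td()].
#' @return A ggplot of F-measure and MMR against the density threshold.
#' @export
plot_td_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep[, c("td", "f_measure", "mmr")],
                              -"td", names_to = "metric", values_to = "value")
  long$metric <- ifelse(long$metric == "f_measure", "F-measure", "MMR")
  ggplot2::ggplot(long, ggplot2::aes(.data$td, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "weighted-density threshold Td", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
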