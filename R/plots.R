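## Figure analogues: barrier time by inhibition level (log10 median with
## bootstrap CI, faceted by population size) and mean-vs-SD scatter with
## optional animal points.

#' Plot barrier time against inhibition level
#'
#' One panel per population size: log10 of the median barrier-zone time
#' with a seeded percentile-bootstrap confidence interval for the median,
#' and the individual trial times as pale points. Zero medians are
#' guarded by the 0.1 s step resolution before taking logs.
#'
#' @param trials A [run_sweep()] trial table (successful trials are
#'   used).
#' @param n_boot,conf Bootstrap parameters for the median CI.
#' @param seed Seed for the bootstrap resamples.
#' @return A ggplot object.
#' @export
plot_barrier_times <- function(trials, n_boot = 1000, conf = 0.95,
                               seed = 1) {
  keep <- trials[!is.na(trials$success) & trials$success, ]
  keep$barrier_seconds <- pmax(keep$barrier_seconds, 0.1)
  set.seed(seed)
  cells <- unique(keep[, c("pop_size", "inhibition")])
  ci <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    x <- keep$barrier_seconds[keep$pop_size == cells$pop_size[i] &
                                keep$inhibition == cells$inhibition[i]]
    b <- median_boot_ci(x, n_boot, conf)
    data.frame(pop_size = cells$pop_size[i],
               inhibition = cells$inhibition[i],
               median = median(x), lower = b[1], upper = b[2])
  }))
  ggplot2::ggplot(ci, ggplot2::aes(x = factor(inhibition))) +
    ggplot2::geom_jitter(
      data = keep,
      ggplot2::aes(y = log10(barrier_seconds)),
      width = 0.15, alpha = 0.35, color = "steelblue", size = 1) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = log10(median),
                   ymin = log10(pmax(lower, 0.1)),
                   ymax = log10(upper))) +
    ggplot2::facet_wrap(~pop_size, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "inhibition level",
                  y = "log10 median time in barrier zone (s)") +
    ggplot2::theme_minimal()
}

#' Plot mean vs SD of barrier time
#'
#' Scatter of per-cell mean against SD of barrier-zone time, with animal
#' points (if any) labelled by species.
#'
#' @param merged A [compare_animals()] table.
#' @return A ggplot object.
#' @export
plot_mean_sd <- function(merged) {
  ggplot2::ggplot(merged,
                  ggplot2::aes(x = mean_s, y = sd_s,
                               color = source)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(
      data = merged[merged$source == "animal", ],
      ggplot2::aes(label = label),
      vjust = -0.8, show.legend = FALSE) +
    ggplot2::labs(x = "mean time in barrier zone (s)",
                  y = "SD of time in barrier zone (s)") +
    ggplot2::theme_minimal()
}
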