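## Inhibition x population-size sweep and summary statistics.

#' Sweep configuration
#'
#' @param inhibition_levels Ordered inhibition weights in `[0, 1]`.
#' @param population_sizes Ordered population sizes.
#' @param trials_per_cell Trials per (size, level) pair (>= 1).
#' @param master_seed Master seed; per-trial seeds are drawn from it and
#'   recorded, so any single trial can be replayed exactly.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(inhibition_levels = c(0, 0.1, 0.2, 0.4, 0.6, 0.8, 1),
                         population_sizes = c(1, 2, 5, 10),
                         trials_per_cell = 15, master_seed = 42) {
  if (any(inhibition_levels < 0 | inhibition_levels > 1)) {
    stop("inhibition levels must lie in [0, 1]", call. = FALSE)
  }
  if (trials_per_cell < 1) stop("`trials_per_cell` must be >= 1",
                                call. = FALSE)
  structure(list(inhibition_levels = inhibition_levels,
                 population_sizes = as.integer(population_sizes),
                 trials_per_cell = as.integer(trials_per_cell),
                 master_seed = as.integer(master_seed)),
            class = "sweep_config")
}

#' Run the inhibition-by-population-size sweep
#'
#' Runs `trials_per_cell` trials for every (population size, inhibition
#' level) pair with deterministic per-trial seeds derived from the master
#' seed. Per-trial errors are recorded in the `error` column rather than
#' aborting the sweep.
#'
#' @param sweep A [sweep_config()].
#' @param arena The arena (default the canonical V arena).
#' @param config_base A [network_config()] supplying everything except
#'   `n` and `w`.
#' @param protocol,camera,agent Passed to [run_trial()].
#' @param verbose Print a line per cell.
#' @return A data.frame with one row per trial: `pop_size`, `inhibition`,
#'   `trial`, `seed`, `success`, `steps`, `barrier_steps`,
#'   `barrier_seconds`, `error`.
#' @export
run_sweep <- function(sweep = sweep_config(), arena = default_arena(),
                      config_base = network_config(),
                      protocol = trial_protocol(),
                      camera = camera_config(), agent = agent_config(),
                      verbose = FALSE) {
  grid_n <- length(sweep$population_sizes) *
    length(sweep$inhibition_levels) * sweep$trials_per_cell
  set.seed(sweep$master_seed)
  seeds <- sample.int(.Machine$integer.max, grid_n)
  rows <- vector("list", grid_n)
  k <- 0L
  for (n in sweep$population_sizes) {
    for (w in sweep$inhibition_levels) {
      cfg <- config_base
      cfg$n <- as.integer(n)
      cfg$w <- w
      if (verbose) {
        message(sprintf("cell n=%d w=%.2f", n, w))
      }
      for (trial in seq_len(sweep$trials_per_cell)) {
        k <- k + 1L
        res <- tryCatch(
          run_trial(arena, cfg, protocol, seed = seeds[k],
                    camera = camera, agent = agent),
          error = function(e) e
        )
        rows[[k]] <- if (inherits(res, "error")) {
          data.frame(pop_size = n, inhibition = w, trial = trial,
                     seed = seeds[k], success = NA, steps = NA_integer_,
                     barrier_steps = NA_integer_,
                     barrier_seconds = NA_real_,
                     error = conditionMessage(res))
        } else {
          data.frame(pop_size = n, inhibition = w, trial = trial,
                     seed = seeds[k], success = res$success,
                     steps = res$steps, barrier_steps = res$barrier_steps,
                     barrier_seconds = res$barrier_seconds,
                     error = NA_character_)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summary statistics per sweep cell
#'
#' Computes, per (population size, inhibition level) cell, the mean, SD
#' (sample, n-1 denominator; 0 for a single trial), median, IQR
#' (interpolated quartiles, `Q3 - Q1`), minimum and maximum of
#' `barrier_seconds`. Timed-out trials are excluded with a warning;
#' errored trials are always excluded.
#'
#' @param trials A [run_sweep()] trial table.
#' @return A data.frame with columns `pop_size`, `inhibition`, `mean`,
#'   `sd`, `median`, `iqr`, `min`, `max`, `n_trials`.
#' @export
summarize_trials <- function(trials) {
  bad <- !is.na(trials$error) & nzchar(trials$error)
  timeouts <- !bad & !is.na(trials$success) & !trials$success
  if (any(timeouts)) {
    warning(sum(timeouts),
            " timed-out trial(s) excluded from summary statistics",
            call. = FALSE)
  }
  keep <- trials[!bad & !timeouts & !is.na(trials$barrier_seconds), ]
  cells <- unique(keep[, c("pop_size", "inhibition")])
  cells <- cells[order(cells$pop_size, cells$inhibition), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    x <- keep$barrier_seconds[keep$pop_size == cells$pop_size[i] &
                                keep$inhibition == cells$inhibition[i]]
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(pop_size = cells$pop_size[i],
               inhibition = cells$inhibition[i],
               mean = mean(x),
               sd = if (length(x) > 1) sd(x) else 0,
               median = q[2], iqr = q[3] - q[1],
               min = min(x), max = max(x), n_trials = length(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trend diagnostics over the sweep summary
#'
#' Reports, per population size, the sequence of medians over the
#' inhibition levels together with the number of adjacent increases
#' (0 = monotone non-increasing); the Pearson correlation between the
#' per-cell mean and SD across all cells; and, per inhibition level, the
#' SD sequence over population sizes.
#'
#' @param summary A [summarize_trials()] table.
#' @return A `trend_report` list with `median_by_inhibition` (data.frame
#'   `pop_size`, `inversions`, plus the median sequence as a list
#'   column), `mean_sd_pearson`, and `sd_by_size`.
#' @export
trend_report <- function(summary) {
  sizes <- sort(unique(summary$pop_size))
  levels <- sort(unique(summary$inhibition))
  med <- lapply(sizes, function(n) {
    s <- summary[summary$pop_size == n, ]
    s <- s[order(s$inhibition), ]
    s$median
  })
  inversions <- vapply(med, function(m) sum(diff(m) > 0), integer(1))
  sd_by_size <- lapply(levels, function(w) {
    s <- summary[summary$inhibition == w, ]
    s <- s[order(s$pop_size), ]
    stats::setNames(s$sd, s$pop_size)
  })
  names(sd_by_size) <- levels
  structure(list(
    median_by_inhibition = data.frame(pop_size = sizes,
                                      inversions = inversions),
    medians = stats::setNames(med, sizes),
    mean_sd_pearson = if (nrow(summary) > 1) cor(summary$mean, summary$sd)
                      else NA_real_,
    sd_by_size = sd_by_size
  ), class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("<trend_report>\n")
  cat(" adjacent median increases over inhibition, per population size:\n")
  print(x$median_by_inhibition, row.names = FALSE)
  cat(sprintf(" Pearson r (cell mean vs SD): %.3f\n", x$mean_sd_pearson))
  invisible(x)
}

#' Merge simulation summaries with animal barrier-time statistics
#'
#' The animal table is user-supplied (`species`, `mean_s`, `sd_s` columns)
#' and is merged with the per-cell simulation summaries into one
#' mean-vs-SD table for plotting.
#'
#' @param summary A [summarize_trials()] table.
#' @param animal_csv Path to the animal CSV, or `NULL` for simulation
#'   rows only.
#' @return A data.frame with `source` ("simulation"/"animal"), `label`,
#'   `mean_s`, `sd_s`.
#' @export
compare_animals <- function(summary, animal_csv = NULL) {
  sim <- data.frame(
    source = "simulation",
    label = sprintf("n=%d w=%.2f", summary$pop_size, summary$inhibition),
    mean_s = summary$mean,
    sd_s = summary$sd
  )
  if (is.null(animal_csv)) return(sim)
  an <- read.csv(animal_csv, stringsAsFactors = FALSE)
  need <- c("species", "mean_s", "sd_s")
  if (nrow(an) == 0) return(sim)
  if (!all(need %in% names(an))) {
    stop("animal CSV must have columns species, mean_s, sd_s",
         call. = FALSE)
  }
  if (anyDuplicated(an$species)) {
    stop("duplicate species in animal CSV: ",
         an$species[duplicated(an$species)][1], call. = FALSE)
  }
  bad <- which(!is.finite(an$mean_s) | !is.finite(an$sd_s) |
                 !nzchar(an$species))
  if (length(bad)) {
    stop("malformed animal CSV row ", bad[1], call. = FALSE)
  }
  rbind(sim, data.frame(source = "animal", label = an$species,
                        mean_s = an$mean_s, sd_s = an$sd_s))
}

#' Bootstrap confidence interval for the median
#'
#' Percentile bootstrap (1000 resamples by default) of the median, used
#' for the barrier-time figure.
#'
#' @param x Numeric sample.
#' @param n_boot Number of resamples.
#' @param conf Confidence level.
#' @return `c(lower, upper)`.
#' @export
median_boot_ci <- function(x, n_boot = 1000, conf = 0.95) {
  if (length(x) < 2) return(c(lower = min(x), upper = max(x)))
  meds <- vapply(seq_len(n_boot),
                 function(i) median(sample(x, replace = TRUE)),
                 numeric(1))
  a <- (1 - conf) / 2
  q <- quantile(meds, c(a, 1 - a), names = FALSE)
  c(lower = q[1], upper = q[2])
}
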