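#' Regular-spiking unit parameters
#'
#' Returns the parameter quadruple (a, b, c, d) of a regular-spiking
#' Izhikevich unit, with the post-spike reset potential `c` and recovery
#' increment `d` jittered by a noise term `gamma`:
#' `c = -65 + 15 gamma^2` (mV) and `d = 8 - 6 gamma^2`. `gamma = 0` gives
#' the canonical regular-spiking cell; larger values shade the unit toward
#' faster, chattering-like recovery. The jitter is what decorrelates units
#' within a population.
#'
#' @param gamma Noise term in `[0, 1]`; may be a vector.
#' @return A list with numeric fields `a`, `b`, `c`, `d` (each the length
#'   of `gamma`).
#' @examples
#' rs_params(0)    # canonical regular spiking: c = -65, d = 8
#' rs_params(0.5)
#' @export
rs_params <- function(gamma) {
  if (!is.numeric(gamma) || anyNA(gamma) || any(gamma < 0 | gamma > 1)) {
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  }
  list(
    a = rep(0.02, length(gamma)),
    b = rep(0.2, length(gamma)),
    c = -65.0 + 15 * gamma^2,
    d = 8 - 6 * gamma^2
  )
}

#' Create a single spiking unit
#'
#' @param gamma Noise term in `[0, 1]` used to draw the (c, d) parameters.
#' @param v,u Optional initial state; default is rest at `v = c`,
#'   `u = b * v`.
#' @return A `spiking_unit` list with fields `v`, `u`, `a`, `b`, `c`, `d`.
#' @export
spiking_unit <- function(gamma = 0, v = NULL, u = NULL) {
  p <- rs_params(gamma)
  if (is.null(v)) v <- p$c
  if (is.null(u)) u <- p$b * v
  structure(list(v = v, u = u, a = p$a, b = p$b, c = p$c, d = p$d),
            class = "spiking_unit")
}

#' One forward-Euler substep of a spiking unit
#'
#' Integrates `dv/dt = 0.04 v^2 + 5 v + 140 - u + I` and
#' `du/dt = a (b v - u)` over `dt` milliseconds. The voltage is advanced in
#' two half-steps of `dt/2` (the standard stabilisation for the quadratic
#' voltage term); the recovery variable is updated once from the new
#' voltage. If the unit is at or above the 30 mV threshold it is reset:
#' `v <- c`, `u <- u + d`, exactly and with no further integration within
#' that substep.
#'
#' This is the plain-R reference path; [population_step()] runs the same
#' arithmetic in compiled code.
#'
#' @param unit A [spiking_unit()].
#' @param I Input current (dimensionless, canonical units of the model).
#' @param dt Substep duration in ms (> 0).
#' @return A list with `unit` (updated), `spiked` (logical), and
#'   `at_spike` — the `(v, u)` pair immediately before the reset was
#'   applied, or `NULL` when no spike occurred.
#' @export
izhikevich_substep <- function(unit, I, dt = 1) {
  stopifnot(inherits(unit, "spiking_unit"))
  if (!is.finite(I) || !is.finite(unit$v) || !is.finite(unit$u)) {
    stop("non-finite state or input current", call. = FALSE)
  }
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  v <- unit$v; u <- unit$u
  if (v >= 30) {
    pre <- c(v = v, u = u)
    unit$v <- unit$c
    unit$u <- u + unit$d
    return(list(unit = unit, spiked = TRUE, at_spike = pre))
  }
  v <- v + 0.5 * dt * (0.04 * v * v + 5 * v + 140 - u + I)
  v <- v + 0.5 * dt * (0.04 * v * v + 5 * v + 140 - u + I)
  u <- u + dt * unit$a * (unit$b * v - u)
  if (v >= 30) {
    pre <- c(v = v, u = u)
    unit$v <- unit$c
    unit$u <- u + unit$d
    return(list(unit = unit, spiked = TRUE, at_spike = pre))
  }
  unit$v <- v
  unit$u <- u
  list(unit = unit, spiked = FALSE, at_spike = NULL)
}

#' Create a population of spiking units
#'
#' Each unit's `gamma` is drawn independently (uniform on `[0, 1]` by
#' default, from the current RNG stream), so units share the regular-
#' spiking class but differ in reset depth and recovery increment, which
#' desynchronises their spike phases.
#'
#' @param n Population size (>= 1).
#' @param gamma Optional vector of length `n` of noise terms; drawn
#'   uniformly when omitted.
#' @return A `spiking_population` list with vector fields `v`, `u`, `a`,
#'   `b`, `c`, `d`, `gamma` and size `n`.
#' @export
spiking_population <- function(n, gamma = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("`n` must be a positive integer", call. = FALSE)
  if (is.null(gamma)) gamma <- runif(n)
  if (length(gamma) != n) stop("`gamma` must have length `n`", call. = FALSE)
  p <- rs_params(gamma)
  structure(list(v = p$c, u = p$b * p$c, a = p$a, b = p$b, c = p$c, d = p$d,
                 gamma = gamma, n = n),
            class = "spiking_population")
}

#' @export
print.spiking_population <- function(x, ...) {
  cat("<spiking_population> n =", x$n,
      " v in [", round(min(x$v), 2), ",", round(max(x$v), 2), "]\n")
  invisible(x)
}

#' Advance a population over one world step
#'
#' Bridges the millisecond-scale unit dynamics to the 10 Hz world loop:
#' every unit receives the same input current `I` and is advanced
#' `substeps` Euler substeps of `dt` ms (defaults give a 100 ms world
#' step). Returns the total spike count across units and substeps, which
#' is the population's raw output for this world step.
#'
#' @param pop A [spiking_population()].
#' @param I Input current applied identically to every unit.
#' @param substeps Number of substeps (>= 1).
#' @param dt Substep duration in ms.
#' @return A list with `pop` (updated) and `spikes` (non-negative integer).
#' @export
population_step <- function(pop, I, substeps = 100L, dt = 1) {
  stopifnot(inherits(pop, "spiking_population"))
  substeps <- as.integer(substeps)
  if (is.na(substeps) || substeps < 1) {
    stop("`substeps` must be >= 1", call. = FALSE)
  }
  if (!is.finite(I)) stop("non-finite input current", call. = FALSE)
  res <- izhi_population_steps(pop$v, pop$u, pop$a, pop$b, pop$c, pop$d,
                               I, substeps, dt)
  pop$v <- res$v
  pop$u <- res$u
  list(pop = pop, spikes = res$spikes)
}

#' Normalized population drive
#'
#' Maps a world-step spike count to a drive in `[0, 1]`:
#' `min(1, spike_count / (n * s_max))`. Dividing by the population size
#' keeps the mean drive approximately independent of `n` while the
#' trial-to-trial variability shrinks roughly as `1/sqrt(n)` — the
#' precision gain that larger populations buy.
#'
#' @param spike_count Non-negative spike count for the world step.
#' @param n Population size (>= 1).
#' @param s_max Per-unit spike cap per world step (>= 1); the default 5
#'   is a tight upper bound on regular-spiking rates over a 100 ms world
#'   step (sustained input at the full gain yields about 4 spikes), so
#'   drives span most of [0, 1] in the operating regime.
#' @return Drive in `[0, 1]`.
#' @export
normalized_drive <- function(spike_count, n, s_max = 5) {
  if (any(spike_count < 0)) stop("negative spike count", call. = FALSE)
  if (n < 1 || s_max < 1) stop("`n` and `s_max` must be >= 1", call. = FALSE)
  pmin(1, spike_count / (n * s_max))
}

#' Create a leaky integrator
#'
#' The integrator turns a spike-train drive into a scalar evidence value.
#' With input `x` and decay threshold `tau` the direct-assignment update
#' is `y' = epsilon * (x - (1 - lambda) * y)` when `x >= tau` (growth mode)
#' and `y' = omega * (x - y)` when `x < tau` (decay mode). Note the decay
#' mode is non-accumulating and flips sign around zero input; an
#' alternative incremental update `y' = y + e * (x - (1 - l) * y)` is
#' available via `mode = "incremental"` but is off by default.
#'
#' @param y Initial value.
#' @param omega Decay-mode rate (default 0.024).
#' @param epsilon Growth-mode rate (default 0.1).
#' @param lambda Leakage factor in growth mode (default 0.9).
#' @param tau Decay threshold on the input (default 1).
#' @param mode `"replace"` (direct assignment) or `"incremental"`.
#' @return A `leaky_integrator` list.
#' @export
leaky_integrator <- function(y = 0, omega = 0.024, epsilon = 0.1,
                             lambda = 0.9, tau = 1,
                             mode = c("replace", "incremental")) {
  mode <- match.arg(mode)
  structure(list(y = y, omega = omega, epsilon = epsilon, lambda = lambda,
                 tau = tau, mode = mode),
            class = "leaky_integrator")
}

#' One integrator update
#'
#' @param intg A [leaky_integrator()].
#' @param x Input value.
#' @return The updated integrator.
#' @export
integrator_step <- function(intg, x) {
  stopifnot(inherits(intg, "leaky_integrator"))
  if (x < intg$tau) {
    e <- intg$omega
    l <- 0
  } else {
    e <- intg$epsilon
    l <- intg$lambda
  }
  upd <- e * (x - (1 - l) * intg$y)
  intg$y <- if (intg$mode == "incremental") intg$y + upd else upd
  intg
}

#' Fixed point of the growth-mode integrator
#'
#' For a constant input `x >= tau` the printed update converges
#' geometrically (contraction factor `epsilon * (1 - lambda)`) to
#' `epsilon * x / (1 + epsilon * (1 - lambda))`.
#'
#' @param x Constant input (>= `tau` for the formula to apply).
#' @param intg A [leaky_integrator()] supplying the rates.
#' @return The fixed-point value.
#' @export
integrator_fixed_point <- function(x, intg = leaky_integrator()) {
  intg$epsilon * x / (1 + intg$epsilon * (1 - intg$lambda))
}

#' Drive-noise scaling across population sizes
#'
#' Runs isolated populations of each size under a fixed input current for
#' a number of world steps (after a burn-in) and reports the mean and
#' standard deviation of the normalized drive. Used to check that the mean
#' drive is approximately size-invariant while its step-to-step SD shrinks
#' with population size.
#'
#' @param n_values Population sizes to probe.
#' @param I Input current.
#' @param steps Number of measured world steps.
#' @param burn_in World steps discarded before measuring.
#' @param substeps,dt,s_max World-step bridging parameters.
#' @param replicates Independent population draws per size; the reported
#'   mean and SD are averaged over draws, since a single draw's temporal
#'   SD is dominated by that draw's particular unit parameters.
#' @return A data.frame with columns `n`, `mean_drive`, `sd_drive`.
#' @export
drive_precision <- function(n_values = c(1, 2, 5, 10), I = 10, steps = 200,
                            burn_in = 10, substeps = 100L, dt = 1,
                            s_max = 5, replicates = 1) {
  one <- function(n) {
    pop <- spiking_population(n)
    drives <- numeric(steps)
    for (k in seq_len(burn_in)) {
      pop <- population_step(pop, I, substeps, dt)$pop
    }
    for (k in seq_len(steps)) {
      st <- population_step(pop, I, substeps, dt)
      pop <- st$pop
      drives[k] <- normalized_drive(st$spikes, n, s_max)
    }
    c(mean(drives), sd(drives))
  }
  out <- lapply(n_values, function(n) {
    reps <- vapply(seq_len(replicates), function(r) one(n), numeric(2))
    data.frame(n = n, mean_drive = mean(reps[1, ]),
               sd_drive = mean(reps[2, ]))
  })
  do.call(rbind, out)
}
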