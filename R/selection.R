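## Strategy-selection network: barrier and reward-proximity input
## populations, allocentric and egocentric strategy populations, a single
## one-way inhibitory connection from the barrier channel onto the
## egocentric channel, leaky-integrator readouts, argmax selection.

#' Selection-network configuration
#'
#' @param n Size of every population (>= 1; the sweep uses 1, 2, 5, 10).
#' @param w Inhibitory weight in `[0, 1]` from the barrier channel onto
#'   the egocentric (direct approach) channel.
#' @param gain Sensory-drive-to-current scale; 15 places a maximal drive
#'   in the reliably spiking range of a regular-spiking unit.
#' @param s_max Per-unit spike cap used by [normalized_drive()].
#' @param substeps,dt Millisecond substeps per 10 Hz world step.
#' @param integrator_gain Scale from a strategy population's normalized
#'   drive to its integrator input; 10 lets active populations cross the
#'   integrator's decay threshold `tau = 1`.
#' @param integrator_mode `"incremental"` (default for the closed-loop
#'   readout: `y' = y + e (x - (1 - l) y)`, a smoothly decaying
#'   accumulator that preserves the ordering of the two channels between
#'   evidence bursts) or `"replace"` (the bare direct-assignment rule,
#'   [leaky_integrator()]'s own default; its decay branch flips sign
#'   around zero input, which makes the argmax alternate strategies on
#'   every world step once both populations fall quiet).
#' @param omega,epsilon,lambda,tau Integrator rates; see
#'   [leaky_integrator()].
#' @param mutual_inhibition Optional symmetric inhibition weight between
#'   the two strategy populations (0 disables it; the default network has
#'   only the single barrier-to-egocentric inhibitory connection, and
#'   competition is realized by the argmax over the integrators).
#' @return A `network_config` list.
#' @export
network_config <- function(n = 10, w = 0, gain = 15, s_max = 5,
                           substeps = 100L, dt = 1, integrator_gain = 10,
                           integrator_mode = "incremental",
                           omega = 0.024, epsilon = 0.1, lambda = 0.9,
                           tau = 1, mutual_inhibition = 0) {
  if (w < 0 || w > 1) stop("`w` must lie in [0, 1]", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  structure(list(n = as.integer(n), w = w, gain = gain, s_max = s_max,
                 substeps = as.integer(substeps), dt = dt,
                 integrator_gain = integrator_gain,
                 integrator_mode = integrator_mode,
                 omega = omega, epsilon = epsilon, lambda = lambda,
                 tau = tau, mutual_inhibition = mutual_inhibition),
            class = "network_config")
}

#' Initialize the selection network
#'
#' Draws every unit's noise term `gamma` independently (uniform on
#' `[0, 1]`, from the current RNG stream) for all four populations, as
#' happens at every trial reset. The initial choice is egocentric — the
#' direct approach is the prepotent response the inhibition must
#' overcome.
#'
#' @param config A [network_config()].
#' @return A `network_state` list.
#' @export
network_init <- function(config) {
  mk <- function() spiking_population(config$n)
  intg <- function() {
    leaky_integrator(0, config$omega, config$epsilon, config$lambda,
                     config$tau, config$integrator_mode)
  }
  structure(list(
    barrier_pop = mk(), reward_pop = mk(),
    allo_pop = mk(), ego_pop = mk(),
    allo_intg = intg(), ego_intg = intg(),
    nb = 0, nr = 0, na = 0, ne = 0,
    choice = "egocentric"
  ), class = "network_state")
}

# argmax over the two integrator values; exact ties retain the previous
# choice
.select_choice <- function(y_allo, y_ego, prev) {
  if (y_allo > y_ego) "allocentric"
  else if (y_ego > y_allo) "egocentric"
  else prev
}

#' One world step of the selection network
#'
#' The barrier and reward populations are driven by the current sensory
#' drives (`gain * drive`). The strategy populations are driven by the
#' input populations' normalized drives *measured on the previous world
#' step* (a one-world-step synaptic delay): the allocentric population by
#' `gain * nb`, the egocentric population by `gain * (nr - w * nb)`, which
#' may be negative (hyperpolarizing; no rectification). Each strategy
#' population's normalized drive, scaled by `integrator_gain`, feeds its
#' leaky integrator, and the choice is the argmax of the two integrator
#' values (exact ties retain the previous choice).
#'
#' @param state A [network_init()] state.
#' @param barrier_drive,reward_drive Sensory drives in `[0, 1]`.
#' @param config The [network_config()].
#' @return A list with the updated `state` and the `choice` label.
#' @export
network_step <- function(state, barrier_drive, reward_drive, config) {
  if (barrier_drive < 0 || barrier_drive > 1 ||
      reward_drive < 0 || reward_drive > 1) {
    stop("drives must lie in [0, 1]", call. = FALSE)
  }
  g <- config$gain; ss <- config$substeps; dt <- config$dt
  n <- config$n; smax <- config$s_max; mi <- config$mutual_inhibition

  rb <- population_step(state$barrier_pop, g * barrier_drive, ss, dt)
  rr <- population_step(state$reward_pop, g * reward_drive, ss, dt)

  I_allo <- g * (state$nb - mi * state$ne)
  I_ego <- g * (state$nr - config$w * state$nb - mi * state$na)
  ra <- population_step(state$allo_pop, I_allo, ss, dt)
  re <- population_step(state$ego_pop, I_ego, ss, dt)

  na <- normalized_drive(ra$spikes, n, smax)
  ne <- normalized_drive(re$spikes, n, smax)
  state$allo_intg <- integrator_step(state$allo_intg,
                                     config$integrator_gain * na)
  state$ego_intg <- integrator_step(state$ego_intg,
                                    config$integrator_gain * ne)

  choice <- .select_choice(state$allo_intg$y, state$ego_intg$y,
                           state$choice)

  state$barrier_pop <- rb$pop
  state$reward_pop <- rr$pop
  state$allo_pop <- ra$pop
  state$ego_pop <- re$pop
  state$nb <- normalized_drive(rb$spikes, n, smax)
  state$nr <- normalized_drive(rr$spikes, n, smax)
  state$na <- na
  state$ne <- ne
  state$choice <- choice
  list(state = state, choice = choice)
}

#' Trial protocol
#'
#' @param max_steps Step limit per trial (default 1200).
#' @param hz World-loop rate (default 10 Hz), so the default trial
#'   ceiling is 120 s.
#' @param goal_radius Reach radius around the goal center (default 5
#'   world units).
#' @return A `trial_protocol` list; `ceiling_s = max_steps / hz`.
#' @export
trial_protocol <- function(max_steps = 1200, hz = 10, goal_radius = 5) {
  structure(list(max_steps = as.integer(max_steps), hz = hz,
                 goal_radius = goal_radius,
                 ceiling_s = max_steps / hz),
            class = "trial_protocol")
}

#' Run one detour trial
#'
#' Seeds the RNG, randomizes all unit parameters (`gamma ~ U[0, 1]` per
#' unit), plans the wavefront map once (the arena is static, so per-step
#' replanning reduces to a memoized lookup), then loops:
#' render the camera, extract the red and barrier signals, step the
#' selection network, execute the chosen policy's heading command, move
#' with collision resolution, and accumulate barrier-zone time from the
#' post-move pose. The trial ends on goal contact or at the step limit.
#'
#' @param arena An arena (see [default_arena()]).
#' @param config A [network_config()].
#' @param protocol A [trial_protocol()].
#' @param seed Integer seed for exact replay; `NULL` continues the
#'   current RNG stream.
#' @param camera A [camera_config()].
#' @param agent An [agent_config()].
#' @param trace When `TRUE`, attach a per-step data.frame (`step`, `x`,
#'   `y`, `heading`, `red_count`, `barrier_signal`, `ego_y`, `allo_y`,
#'   `choice`, `in_zone`) as the `"trace"` attribute.
#' @return A `trial_result` list: `success`, `steps`, `barrier_steps`,
#'   `barrier_seconds`, `seed`, `n`, `w`.
#' @export
run_trial <- function(arena, config = network_config(),
                      protocol = trial_protocol(), seed = NULL,
                      camera = camera_config(), agent = agent_config(),
                      trace = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  state <- network_init(config)

  grid <- rasterize(arena, resolution = 1, agent_radius = agent$radius)
  goal_cell <- cell_of(grid, arena$goal)
  wmap <- wavefront(grid, goal_cell)
  start_cell <- cell_of(grid, c(arena$start_pose$x, arena$start_pose$y))
  if (is.na(wmap$dist[start_cell[1], start_cell[2]])) {
    stop("goal is unreachable from the start in the rasterized arena",
         call. = FALSE)
  }

  pose <- arena$start_pose
  barrier_steps <- 0L
  success <- FALSE
  steps <- 0L
  tr <- if (trace) vector("list", protocol$max_steps) else NULL

  for (step in seq_len(protocol$max_steps)) {
    steps <- step
    frame <- render_camera(arena, pose, camera)
    rs <- red_signal(frame)
    bs <- barrier_signal(frame$depth, camera$band_edges,
                         camera$band_weights)
    reward_drive <- min(1, rs$count / camera$red_saturation)

    ns <- network_step(state, bs, reward_drive, config)
    state <- ns$state

    if (ns$choice == "allocentric") {
      cmd <- allocentric_heading(wmap, grid, pose, arena)
      if (isTRUE(cmd$error)) {
        cmd <- egocentric_heading(pose, rs$centroid, camera$n_rays,
                                  camera$fov, agent$k_turn,
                                  agent$search_rate)
      }
    } else {
      cmd <- egocentric_heading(pose, rs$centroid, camera$n_rays,
                                camera$fov, agent$k_turn,
                                agent$search_rate)
    }
    pose <- move_agent(pose, cmd$heading,
                       if (isTRUE(cmd$move)) agent$speed else 0,
                       arena, agent$radius)

    in_zone <- in_barrier_zone(pose, arena)
    if (in_zone) barrier_steps <- barrier_steps + 1L

    if (trace) {
      tr[[step]] <- data.frame(
        step = step, x = pose$x, y = pose$y, heading = pose$heading,
        red_count = rs$count, barrier_signal = bs,
        ego_y = state$ego_intg$y, allo_y = state$allo_intg$y,
        choice = ns$choice, in_zone = in_zone
      )
    }
    if (goal_reached(pose, arena, protocol$goal_radius)) {
      success <- TRUE
      break
    }
  }

  res <- structure(list(
    success = success, steps = steps, barrier_steps = barrier_steps,
    barrier_seconds = barrier_steps / protocol$hz,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    n = config$n, w = config$w
  ), class = "trial_result")
  if (trace) attr(res, "trace") <- do.call(rbind, tr[seq_len(steps)])
  res
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf(
    "<trial_result> n=%d w=%.2f %s in %d steps, %.1f s in barrier zone\n",
    x$n, x$w, if (x$success) "goal reached" else "timed out",
    x$steps, x$barrier_seconds))
  invisible(x)
}
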