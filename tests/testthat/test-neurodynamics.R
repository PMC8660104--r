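test_that("regular-spiking parameters follow the gamma-jitter formulas", {
  p0 <- rs_params(0)
  expect_equal(c(p0$a, p0$b, p0$c, p0$d), c(0.02, 0.2, -65, 8))
  p1 <- rs_params(1)
  expect_equal(c(p1$c, p1$d), c(-50, 2))
  ph <- rs_params(0.5)
  expect_equal(c(ph$c, ph$d), c(-61.25, 6.5))
  expect_error(rs_params(-0.01), "gamma")
  expect_error(rs_params(1.2), "gamma")
})

test_that("the canonical rest state is a fixed point at zero current", {
  u <- spiking_unit(0, v = -70, u = -14)
  for (i in 1:100) {
    st <- izhikevich_substep(u, I = 0)
    expect_false(st$spiked)
    u <- st$unit
  }
  expect_lt(abs(u$v + 70), 1e-9)
  expect_lt(abs(u$u + 14), 1e-9)
})

test_that("threshold reset is applied exactly", {
  u <- spiking_unit(0, v = 30, u = -10)
  st <- izhikevich_substep(u, I = 0)
  expect_true(st$spiked)
  expect_identical(st$unit$v, -65)
  expect_identical(st$unit$u, -10 + 8)
})

test_that("the substep does two half-steps of v and one u update", {
  # independent hand-coded arithmetic for v=-65, u=-13, I=10, dt=1
  v <- -65; u <- -13; I <- 10
  v1 <- v + 0.5 * (0.04 * v^2 + 5 * v + 140 - u + I)
  v2 <- v1 + 0.5 * (0.04 * v1^2 + 5 * v1 + 140 - u + I)
  u2 <- u + 0.02 * (0.2 * v2 - u)
  st <- izhikevich_substep(spiking_unit(0, v = -65, u = -13), I = 10)
  expect_false(st$spiked)
  expect_equal(st$unit$v, v2, tolerance = 1e-12)
  expect_equal(st$unit$u, u2, tolerance = 1e-12)
  expect_equal(st$unit$v, -58.105, tolerance = 1e-3)
})

test_that("every spike along a driven trajectory resets exactly", {
  u <- spiking_unit(0)
  spikes <- 0
  for (i in 1:1500) {
    st <- izhikevich_substep(u, I = 10)
    if (st$spiked) {
      spikes <- spikes + 1
      expect_identical(st$unit$v, -65)
      expect_identical(st$unit$u, st$at_spike[["u"]] + 8)
    }
    u <- st$unit
  }
  expect_gt(spikes, 5)
})

test_that("compiled population stepping matches the R reference exactly", {
  gam <- c(0, 0.3, 0.8)
  pop <- spiking_population(3, gamma = gam)
  ref <- lapply(gam, spiking_unit)
  for (i in seq_along(ref)) {       # same rest initialisation as the pop
    ref[[i]]$v <- pop$v[i]
    ref[[i]]$u <- pop$u[i]
  }
  n_spikes_ref <- 0
  for (k in 1:250) {
    for (i in seq_along(ref)) {
      st <- izhikevich_substep(ref[[i]], I = 10)
      ref[[i]] <- st$unit
      n_spikes_ref <- n_spikes_ref + st$spiked
    }
  }
  out <- population_step(pop, I = 10, substeps = 250)
  expect_identical(out$pop$v, vapply(ref, `[[`, numeric(1), "v"))
  expect_identical(out$pop$u, vapply(ref, `[[`, numeric(1), "u"))
  expect_identical(out$spikes, as.integer(n_spikes_ref))
})

test_that("population spike counts add over units and stay at fixed points", {
  # stationary point: no spikes ever
  pop <- spiking_population(1, gamma = 0)
  pop$v <- -70; pop$u <- -14
  expect_identical(population_step(pop, I = 0, substeps = 100)$spikes, 0L)
  # three units held at threshold each reset exactly once in one substep
  pop3 <- spiking_population(3, gamma = c(0, 0, 0))
  pop3$v <- rep(30, 3)
  expect_identical(population_step(pop3, I = 0, substeps = 1)$spikes, 3L)
  # sustained drive makes a regular-spiking population fire
  set.seed(1)
  pop10 <- spiking_population(10)
  expect_gt(population_step(pop10, I = 10, substeps = 100)$spikes, 0)
})

test_that("normalized drive divides by population size and caps at one", {
  expect_equal(normalized_drive(0, 7), 0)
  expect_equal(normalized_drive(40, 10, s_max = 10), 0.4)
  expect_equal(normalized_drive(200, 1, s_max = 10), 1)
  expect_error(normalized_drive(-1, 5), "negative")
})

test_that("integrator updates follow the two-branch rule", {
  it <- leaky_integrator()
  expect_equal(integrator_step(it, 0)$y, 0)          # zero fixed point
  expect_equal(integrator_step(it, 2)$y, 0.2)        # growth: 0.1*(2-0.1*0)
  it$y <- 0.5
  expect_equal(integrator_step(it, 0)$y, 0.024 * (0 - 0.5))  # decay branch
  inc <- leaky_integrator(y = 1, mode = "incremental")
  expect_equal(integrator_step(inc, 2)$y, 1 + 0.1 * (2 - 0.1 * 1))
})

test_that("constant supra-threshold input converges to the closed form", {
  for (x in c(1, 2, 5)) {
    it <- leaky_integrator()
    for (k in 1:500) it <- integrator_step(it, x)
    expect_lt(abs(it$y - integrator_fixed_point(x)), 1e-9)
  }
})

test_that("identical seeds give bit-identical spike trains", {
  run <- function() {
    set.seed(99)
    pop <- spiking_population(5)
    counts <- integer(20)
    for (k in 1:20) {
      st <- population_step(pop, I = 8)
      pop <- st$pop
      counts[k] <- st$spikes
    }
    list(counts = counts, v = pop$v, u = pop$u)
  }
  expect_identical(run(), run())
})

test_that("mean drive is size-invariant while its variability shrinks", {
  set.seed(5)
  d <- drive_precision(c(1, 10), I = 10, steps = 100, replicates = 5)
  rel <- abs(d$mean_drive[1] - d$mean_drive[2]) / d$mean_drive[1]
  expect_lt(rel, 0.2)
  expect_gt(d$sd_drive[1], d$sd_drive[2])
})
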