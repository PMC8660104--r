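test_that("rasterizing an empty arena blocks only the perimeter", {
  a <- no_barrier_arena(border_half = 5, start_dist = 3, goal_behind = 1)
  g <- rasterize(a, resolution = 1, agent_radius = 0.5)
  expect_equal(dim(g$blocked), c(10, 10))
  ring <- row(g$blocked) %in% c(1, 10) | col(g$blocked) %in% c(1, 10)
  expect_true(all(g$blocked[ring]))
  expect_false(any(g$blocked[!ring]))
  expect_error(rasterize(a, resolution = 20), "larger")
})

test_that("the default arena rasterizes with start and goal connected", {
  a <- default_arena()
  g <- rasterize(a)
  sc <- cell_of(g, c(a$start_pose$x, a$start_pose$y))
  gc <- cell_of(g, a$goal)
  expect_false(g$blocked[sc[1], sc[2]])
  expect_false(g$blocked[gc[1], gc[2]])
  wm <- wavefront(g, gc)
  expect_false(is.na(wm$dist[sc[1], sc[2]]))
})

test_that("a full wall splits the grid for the wavefront", {
  blocked <- matrix(FALSE, 9, 9)
  blocked[, 5] <- TRUE
  g <- occupancy_grid(blocked)
  wm <- wavefront(g, c(5, 8))
  expect_true(all(is.na(wm$dist[, 1:4])))
  expect_false(any(is.na(wm$dist[, 6:9])))
  expect_error(wavefront(g, c(1, 5)), "blocked")
})

test_that("wavefront distances are exact on small grids", {
  g <- occupancy_grid(matrix(FALSE, 3, 3))
  wm <- wavefront(g, c(1, 1))
  expect_identical(wm$dist[1, 1], 0L)
  expect_identical(wm$dist[3, 3], 2L)   # one diagonal + one step
  wm4 <- wavefront(g, c(1, 1), connectivity = 4)
  expect_identical(wm4$dist[3, 3], 4L)
})

test_that("wavefront matches an independent shortest-path oracle", {
  skip_if_not_installed("igraph")
  set.seed(2024)
  for (rep in 1:100) {
    rg <- random_grid(20, 20, 0.35)
    wm <- wavefront(rg$grid, rg$goal)
    oracle <- grid_dist_oracle(rg$grid$blocked, rg$goal)
    got <- ifelse(is.na(wm$dist), Inf, wm$dist)
    expect_true(all(got == oracle))
  }
})

test_that("gradient descent on the distance field needs exactly dist steps", {
  set.seed(7)
  offs <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1), c(0, -1), c(-1, -1),
                c(-1, 0), c(-1, 1))
  for (rep in 1:20) {
    rg <- random_grid(15, 15, 0.3)
    wm <- wavefront(rg$grid, rg$goal)
    reach <- which(!is.na(wm$dist) & wm$dist > 0, arr.ind = TRUE)
    if (nrow(reach) == 0) next
    for (s in sample(nrow(reach), min(5, nrow(reach)))) {
      cell <- as.integer(reach[s, ])
      d0 <- wm$dist[cell[1], cell[2]]
      steps <- 0L
      while (wm$dist[cell[1], cell[2]] > 0 && steps <= d0) {
        cand <- t(t(offs) + cell)
        ok <- cand[, 1] >= 1 & cand[, 1] <= 15 & cand[, 2] >= 1 &
          cand[, 2] <= 15
        dd <- rep(NA_integer_, 8)
        dd[ok] <- wm$dist[cand[ok, , drop = FALSE]]
        cell <- cand[which.min(dd), ]
        steps <- steps + 1L
      }
      # no local minima: the greedy walk needs exactly d0 steps
      expect_identical(steps, d0)
    }
  }
})

test_that("replanning a static arena reproduces the identical map", {
  a <- default_arena()
  g <- rasterize(a)
  gc <- cell_of(g, a$goal)
  expect_identical(wavefront(g, gc), wavefront(g, gc))
})

test_that("the allocentric command heads for the lowest-distance neighbor", {
  g <- occupancy_grid(matrix(FALSE, 11, 11), resolution = 1,
                      origin = c(0, 0))
  wm <- wavefront(g, c(5, 5))
  # one cell east of the goal: command points west
  pose <- agent_pose(5.5, 4.5, 0)
  cmd <- allocentric_heading(wm, g, pose)
  expect_true(cmd$move)
  expect_equal(cmd$heading, pi)
  # at the goal cell: stop
  stop_cmd <- allocentric_heading(wm, g, agent_pose(4.5, 4.5, 1))
  expect_false(stop_cmd$move)
  # behind a wall with an opening to the north: head north-ish
  blocked <- matrix(FALSE, 11, 11)
  blocked[6, 1:8] <- TRUE
  gw <- occupancy_grid(blocked, resolution = 1, origin = c(0, 0))
  wmw <- wavefront(gw, c(9, 3))
  cmdw <- allocentric_heading(wmw, gw, agent_pose(2.5, 2.5, 0))
  expect_gt(sin(cmdw$heading), 0)
  # fully walled-in agent: navigation error flag
  boxed <- matrix(FALSE, 11, 11)
  boxed[3:5, 3:5] <- TRUE
  boxed[4, 4] <- FALSE
  gb <- occupancy_grid(boxed, resolution = 1, origin = c(0, 0))
  wmb <- wavefront(gb, c(9, 9))
  cmdb <- allocentric_heading(wmb, gb, agent_pose(3.5, 3.5, 0))
  expect_true(cmdb$error)
})

test_that("egocentric homing is a proportional controller on the centroid", {
  pose <- agent_pose(0, 0, 1)
  # centered centroid: heading unchanged
  c0 <- egocentric_heading(pose, centroid = 33, n_rays = 65)
  expect_equal(c0$heading, 1)
  # rightmost ray at 120 degree fov: turn clockwise by 60 degrees
  cr <- egocentric_heading(pose, centroid = 64, n_rays = 64,
                           fov = 2 * pi / 3, k_turn = 1)
  expect_equal(cr$heading, 1 - pi / 3)
  # no red: rotate in place at the search rate
  cs <- egocentric_heading(pose, centroid = NA)
  expect_false(cs$move)
  expect_equal(cs$heading, 1 + pi / 12)
})

test_that("pure egocentric homing reaches the goal in an open arena", {
  a <- no_barrier_arena()
  cam <- camera_config()
  pose <- a$start_pose
  reached <- FALSE
  dist0 <- sqrt(sum((c(pose$x, pose$y) - a$goal)^2))
  bound <- ceiling((dist0 - 5) / 0.5) + 10
  for (k in seq_len(bound)) {
    rs <- red_signal(render_camera(a, pose, cam))
    cmd <- egocentric_heading(pose, rs$centroid, cam$n_rays, cam$fov)
    pose <- move_agent(pose, cmd$heading, if (cmd$move) 0.5 else 0, a)
    if (goal_reached(pose, a, 5)) {
      reached <- TRUE
      break
    }
  }
  expect_true(reached)
})
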