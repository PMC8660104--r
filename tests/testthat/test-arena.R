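# independent segment-intersection check used to probe constructed geometry
segs_cross <- function(p, q, segs) {
  any(vapply(seq_len(nrow(segs)), function(j) {
    a <- segs[j, 1:2]; b <- segs[j, 3:4]
    d1 <- q - p; d2 <- b - a
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / den
    s <- ((a[1] - p[1]) * d1[2] - (a[2] - p[2]) * d1[1]) / den
    t >= 0 && t <= 1 && s >= -1e-9 && s <= 1 + 1e-9
  }, logical(1)))
}

test_that("the default arena realises the detour conflict", {
  a <- default_arena()
  start <- c(a$start_pose$x, a$start_pose$y)
  # start faces the apex
  expect_lt(abs(a$start_pose$heading -
                  atan2(a$apex[2] - start[2], a$apex[1] - start[1])), 1e-9)
  # the straight start-to-goal segment is blocked by the barrier
  expect_true(segs_cross(start, a$goal, a$solid_segs))
  expect_false(in_barrier_zone(a$start_pose, a))
  # goal inside the V, between the arms
  expect_gt(a$goal[2], a$apex[2])
  # interior points of the V are not barrier zone
  expect_false(in_barrier_zone(agent_pose(0, 3, 0), a))
  expect_false(in_barrier_zone(agent_pose(2, 4, 0), a))
})

test_that("fixture variants behave as advertised", {
  nb <- no_barrier_arena()
  expect_false(segs_cross(c(nb$start_pose$x, nb$start_pose$y), nb$goal,
                          nb$solid_segs))
  fr <- render_camera(nb, nb$start_pose)
  expect_gt(red_signal(fr)$count, 0)               # goal visible
  expect_equal(barrier_signal(fr$depth), 0)        # nothing within bands
  co <- corridor_arena()
  expect_true(segs_cross(c(co$start_pose$x, co$start_pose$y), co$goal,
                         co$solid_segs))
})

test_that("inconsistent geometry is rejected", {
  expect_error(default_arena(goal_behind = 40), "border")
  expect_error(default_arena(goal_behind = -1), "behind the apex")
  expect_error(default_arena(border_half = -1), "positive")
})

test_that("rendering is pure and respects occlusion semantics", {
  a <- default_arena()
  cam <- camera_config(n_rays = 65)          # odd: ray 33 is the center
  f1 <- render_camera(a, a$start_pose, cam)
  f2 <- render_camera(a, a$start_pose, cam)
  expect_identical(f1, f2)

  # facing the bottom border wall: no red anywhere, finite depth
  down <- agent_pose(0, -25, -pi / 2)
  fd <- render_camera(a, down, cam)
  expect_true(all(fd$red == 0))
  expect_true(all(fd$depth > 0 & fd$depth <= cam$max_depth))

  # central ray onto the opaque apex stripe: depth = 2, no red
  f <- render_camera(a, agent_pose(0, -2, pi / 2), cam)
  expect_equal(f$depth[33], 2, tolerance = 1e-9)
  expect_equal(f$red[33], 0)

  # looking at the goal through a transparent stripe interval: the red
  # disc is seen through the glass while the same surface sets the depth
  gap_mid <- 1.5 / sqrt(2) * c(1, 1)          # arm interval [1,2] midpoint
  dir_out <- (gap_mid - a$goal) / sqrt(sum((gap_mid - a$goal)^2))
  pos <- gap_mid + 3 * dir_out
  pose <- agent_pose(pos[1], pos[2],
                     atan2(a$goal[2] - pos[2], a$goal[1] - pos[1]))
  fg <- render_camera(a, pose, cam)
  expect_equal(fg$red[33], 1)
  expect_equal(fg$depth[33], 3, tolerance = 1e-6)
  expect_error(render_camera(a, agent_pose(40, 0, 0), cam), "border")
})

test_that("red signal counts rays and averages their indices", {
  mk <- function(red) structure(list(red = red), class = "camera_frame")
  expect_equal(red_signal(mk(rep(0, 9))), list(count = 0, centroid = NA_real_))
  expect_equal(red_signal(mk(c(0, 0, 0, 1, 1, 1, 0, 0, 0))),
               list(count = 3, centroid = 5))
  expect_equal(red_signal(mk(c(1, rep(0, 8)))), list(count = 1, centroid = 1))
})

test_that("barrier signal bins depths and normalizes to [0, 1]", {
  expect_equal(barrier_signal(rep(50, 64)), 0)
  expect_equal(barrier_signal(rep(1, 64)), 1)
  expect_equal(barrier_signal(c(rep(1, 32), rep(50, 32))), 0.5)
  # weights divide out only for the nearest band
  expect_equal(barrier_signal(rep(3, 64)), 0.3 / 0.4)
  expect_error(barrier_signal(rep(1, 64), band_edges = c(4, 2, 6, 8)),
               "increasing")
})

test_that("movement slides along obstacles and never penetrates", {
  a <- default_arena()
  # free motion is exact
  p1 <- move_agent(a$start_pose, 0, 0.5, a)
  expect_equal(c(p1$x, p1$y), c(0.5, -20))
  # head-on into the border wall: zero displacement
  at_wall <- agent_pose(29.5, 0, 0)
  p2 <- move_agent(at_wall, 0, 0.5, a)
  expect_equal(c(p2$x, p2$y), c(29.5, 0))
  # 45 degree approach against the wall slides with speed * cos(45)
  p3 <- move_agent(at_wall, pi / 4, 0.5, a)
  expect_equal(c(p3$x, p3$y), c(29.5, 0.5 * cos(pi / 4)))
  expect_error(move_agent(at_wall, 0, -1, a), "speed")
})

test_that("random motion stays inside the border and outside the barrier", {
  a <- default_arena()
  set.seed(123)
  pose <- a$start_pose
  for (k in 1:300) {
    pose <- move_agent(pose, runif(1, -pi, pi), 0.5, a)
    expect_lte(max(abs(pose$x), abs(pose$y)), 29.5 + 1e-6)
    expect_gte(min(detoursim:::.point_seg_dist(pose$x, pose$y, a$solid_segs)),
               0.5 - 1e-4)
  }
})

test_that("zone and goal tests use closed boundaries", {
  a <- default_arena()
  expect_true(goal_reached(agent_pose(a$goal[1], a$goal[2], 0), a))
  expect_true(goal_reached(agent_pose(a$goal[1], a$goal[2] - 5, 0), a))
  expect_false(goal_reached(agent_pose(a$goal[1], a$goal[2] - 5.001, 0), a))
  # apex cap and mid-arm band are both zone; the V interior is not
  expect_true(in_barrier_zone(agent_pose(0, -1, 0), a))
  mid <- 7 / sqrt(2) * c(1, 1) + 2 * c(1, -1) / sqrt(2)
  expect_true(in_barrier_zone(agent_pose(mid[1], mid[2], 0), a))
  expect_false(in_barrier_zone(agent_pose(0, 5, 0), a))
})
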