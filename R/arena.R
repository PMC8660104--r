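## 2D world: border, striped V-barrier, goal disc, barrier zone, ray camera.
## Coordinates are continuous world units, origin at the arena center,
## angles in radians (0 = +x, counter-clockwise positive). Containment
## tests use closed boundaries.

#' Agent pose
#'
#' @param x,y Position in world units.
#' @param heading Angle in radians (0 = +x axis, counter-clockwise).
#' @return An `agent_pose` list.
#' @export
agent_pose <- function(x, y, heading) {
  structure(list(x = x, y = y, heading = heading), class = "agent_pose")
}

#' Camera parameters
#'
#' @param n_rays Number of rays (>= 3); ray 1 is the leftmost
#'   (counter-clockwise-most) ray.
#' @param fov Field of view in radians, centered on the heading.
#' @param max_depth Depth reported when a ray hits nothing (world units).
#' @param band_edges Outer edges of the four obstacle distance bands.
#' @param band_weights Positive weights, decreasing with distance.
#' @param red_saturation Red-ray count at which the reward drive saturates
#'   at 1; default `n_rays / 4`. Together with the rendered goal-disc
#'   radius this calibrates the reward channel's three operating points:
#'   weakly driving on approach (the direct approach is prepotent), an
#'   even noise-decided contest with the barrier channel when pressed at
#'   the apex, and below the barrier channel along the flat arm faces so
#'   that a detour always completes within the trial ceiling.
#' @return A `camera_config` list.
#' @export
camera_config <- function(n_rays = 64, fov = 2 * pi / 3, max_depth = 50,
                          band_edges = c(2, 4, 6, 8),
                          band_weights = c(0.4, 0.3, 0.2, 0.1),
                          red_saturation = NULL) {
  if (n_rays < 3) stop("`n_rays` must be >= 3", call. = FALSE)
  if (fov <= 0 || fov > 2 * pi) stop("`fov` must be in (0, 2*pi]", call. = FALSE)
  if (is.null(red_saturation)) red_saturation <- n_rays / 4
  structure(list(n_rays = as.integer(n_rays), fov = fov,
                 max_depth = max_depth, band_edges = band_edges,
                 band_weights = band_weights,
                 red_saturation = red_saturation),
            class = "camera_config")
}

#' Agent body and motor parameters
#'
#' @param radius Body radius (world units).
#' @param speed Forward speed per world step (world units); 0.5 at 10 Hz
#'   is 5 units/s, so an unobstructed start-to-goal run takes a few
#'   seconds.
#' @param k_turn Proportional gain of the homing controller (per step).
#' @param search_rate Rotation per step when no red is visible (radians).
#' @return An `agent_config` list.
#' @export
agent_config <- function(radius = 0.5, speed = 0.5, k_turn = 1,
                         search_rate = pi / 12) {
  structure(list(radius = radius, speed = speed, k_turn = k_turn,
                 search_rate = search_rate),
            class = "agent_config")
}

## ---- internal geometry helpers ------------------------------------------

# segments are matrices with columns x1, y1, x2, y2 (one row per segment)
.seg_mat <- function(...) {
  m <- rbind(...)
  if (is.null(m)) m <- matrix(numeric(0), ncol = 4)
  colnames(m) <- c("x1", "y1", "x2", "y2")
  m
}

.border_segs <- function(h) {
  .seg_mat(
    c(-h, -h,  h, -h),
    c( h, -h,  h,  h),
    c( h,  h, -h,  h),
    c(-h,  h, -h, -h)
  )
}

# min distance from point (px, py) to each segment row of `segs`
.point_seg_dist <- function(px, py, segs) {
  if (nrow(segs) == 0) return(numeric(0))
  sx <- segs[, 3] - segs[, 1]
  sy <- segs[, 4] - segs[, 2]
  len2 <- sx * sx + sy * sy
  t <- ((px - segs[, 1]) * sx + (py - segs[, 2]) * sy) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  cx <- segs[, 1] + t * sx
  cy <- segs[, 2] + t * sy
  sqrt((px - cx)^2 + (py - cy)^2)
}

# does the open segment (ax,ay)-(bx,by) properly cross any row of `segs`?
.seg_crosses <- function(ax, ay, bx, by, segs) {
  if (nrow(segs) == 0) return(FALSE)
  dx <- bx - ax; dy <- by - ay
  sx <- segs[, 3] - segs[, 1]
  sy <- segs[, 4] - segs[, 2]
  wx <- segs[, 1] - ax
  wy <- segs[, 2] - ay
  den <- dx * sy - dy * sx
  ok <- abs(den) > 1e-12
  if (!any(ok)) return(FALSE)
  t <- (wx * sy - wy * sx)[ok] / den[ok]
  s <- (wx * dy - wy * dx)[ok] / den[ok]
  any(t > 1e-9 & t < 1 - 1e-9 & s >= -1e-9 & s <= 1 + 1e-9)
}

# counter-clockwise-orient a convex polygon given as an n x 2 matrix
.orient_ccw <- function(poly) {
  n <- nrow(poly)
  area <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  if (area < 0) poly[n:1, , drop = FALSE] else poly
}

.point_in_convex <- function(px, py, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  ex <- poly[nxt, 1] - poly[, 1]
  ey <- poly[nxt, 2] - poly[, 2]
  all(ex * (py - poly[, 2]) - ey * (px - poly[, 1]) >= -1e-9)
}

# opaque stripe sub-segments along an arm from `from` to `to`:
# alternating intervals of `stripe_len`, the interval touching `from`
# opaque ("anchored at the apex"). duty = 1 makes the whole arm opaque.
.stripe_segs <- function(from, to, stripe_len, duty = 0.5) {
  len <- sqrt(sum((to - from)^2))
  dir <- (to - from) / len
  if (duty >= 1) {
    return(.seg_mat(c(from, to)))
  }
  starts <- seq(0, len, by = 2 * stripe_len)
  rows <- lapply(starts, function(s0) {
    s1 <- min(s0 + stripe_len, len)
    if (s1 <= s0) return(NULL)
    c(from + s0 * dir, from + s1 * dir)
  })
  do.call(.seg_mat, rows[!vapply(rows, is.null, logical(1))])
}

## ---- arena constructors ---------------------------------------------------

#' Build the detour-task arena
#'
#' The canonical inward-V world: a square border, a V-shaped barrier whose
#' apex points at the agent, a red goal disc inside the V behind the apex,
#' and a barrier zone band along the outer (agent-facing) faces of the two
#' arms. The barrier arms carry alternating opaque/transparent stripes of
#' one world unit each, anchored opaque at the apex. Transparent stripes
#' are see-through for the camera (the red goal shows through) but the
#' whole V is solid for movement — the conflict that defines the task.
#'
#' @param border_half Half-size of the square border (world units).
#' @param arm_len Length of each barrier arm.
#' @param arm_half_angle Half the opening angle of the V (radians);
#'   `pi/4` gives a 90 degree V.
#' @param start_dist Distance from the apex to the start position.
#' @param goal_behind Distance from the apex to the goal center, inside
#'   the V. The default 8 keeps the whole 5-unit reach disc strictly
#'   inside the 90 degree V (8/sqrt(2) > 5), so the goal cannot be
#'   reached from outside the barrier.
#' @param zone_width Width of the barrier zone band along the outer arm
#'   faces.
#' @param stripe_len Length of each opaque and each transparent stripe.
#' @param goal_visual_radius Radius of the rendered red disc (the goal
#'   *reach* radius is a separate trial-protocol parameter, default 5).
#'   The default 3 keeps the goal visible from the start pose yet stops
#'   the disc from filling the whole field of view at the wall, where an
#'   over-saturated reward channel would make the direct approach
#'   unconditionally dominant.
#' @param variant `"default"` (the V), `"no_barrier"` (goal directly
#'   approachable), or `"corridor"` (a full wall with a single gap, so a
#'   detour is forced).
#' @return An `arena` object.
#' @export
default_arena <- function(border_half = 30, arm_len = 20,
                          arm_half_angle = pi / 4, start_dist = 20,
                          goal_behind = 8, zone_width = 4, stripe_len = 1,
                          goal_visual_radius = 3,
                          variant = c("default", "no_barrier", "corridor")) {
  variant <- match.arg(variant)
  if (border_half <= 0 || arm_len <= 0 || start_dist <= 0) {
    stop("arena geometry values must be positive", call. = FALSE)
  }
  if (variant != "no_barrier" && goal_behind <= 0) {
    stop("the goal must lie behind the apex (goal_behind > 0)", call. = FALSE)
  }
  apex <- c(0, 0)
  start <- c(0, -start_dist)
  goal <- c(0, goal_behind)
  heading <- atan2(apex[2] - start[2], apex[1] - start[1])

  arms <- .seg_mat()
  opaque <- .seg_mat()
  zone <- list()

  if (variant == "default") {
    tips <- list(
      c(-sin(arm_half_angle), cos(arm_half_angle)) * arm_len,
      c(sin(arm_half_angle), cos(arm_half_angle)) * arm_len
    )
    arms <- .seg_mat(c(apex, tips[[1]]), c(apex, tips[[2]]))
    opaque <- rbind(.stripe_segs(apex, tips[[1]], stripe_len),
                    .stripe_segs(apex, tips[[2]], stripe_len))
    nrms <- list()
    for (tip in tips) {
      dir <- (tip - apex) / sqrt(sum((tip - apex)^2))
      nrm <- c(dir[2], -dir[1])               # candidate outward normal
      if (sum(nrm * (start - apex)) < 0) nrm <- -nrm
      nrms <- c(nrms, list(nrm))
      quad <- rbind(apex, tip, tip + zone_width * nrm, apex + zone_width * nrm)
      zone <- c(zone, list(.orient_ccw(quad)))
    }
    # cap the band around the vertex so the region directly in front of
    # the apex counts as barrier zone too
    cap <- rbind(apex, apex + zone_width * nrms[[1]],
                 apex + zone_width * nrms[[2]])
    zone <- c(zone, list(.orient_ccw(cap)))
  } else if (variant == "corridor") {
    # full wall across the arena with a gap on the right side
    gap <- c(border_half - 10, border_half)
    wall <- .seg_mat(c(-border_half, 0, gap[1], 0))
    arms <- wall
    opaque <- wall
  }

  arena <- structure(list(
    border_half = border_half,
    border_segs = .border_segs(border_half),
    arms = arms,
    opaque_segs = rbind(opaque, .border_segs(border_half)),
    depth_segs = rbind(arms, .border_segs(border_half)),
    solid_segs = arms,
    goal = goal,
    goal_visual_radius = goal_visual_radius,
    zone = zone,
    start_pose = agent_pose(start[1], start[2], heading),
    apex = apex,
    variant = variant
  ), class = "arena")

  .validate_arena(arena, arm_half_angle)
  arena
}

.validate_arena <- function(arena, arm_half_angle) {
  h <- arena$border_half
  g <- arena$goal
  s <- c(arena$start_pose$x, arena$start_pose$y)
  if (any(abs(g) >= h) || any(abs(s) >= h)) {
    stop("goal and start must lie inside the border", call. = FALSE)
  }
  if (arena$variant == "default") {
    # goal inside the V: within the wedge opened by the arms, behind apex
    ang <- atan2(g[1] - arena$apex[1], g[2] - arena$apex[2]) # from +y axis
    if (g[2] <= arena$apex[2] || abs(ang) >= arm_half_angle) {
      stop("goal must lie inside the V, behind the apex", call. = FALSE)
    }
    if (in_barrier_zone(arena$start_pose, arena)) {
      stop("start pose must lie outside the barrier zone", call. = FALSE)
    }
  }
  invisible(arena)
}

#' @rdname default_arena
#' @param ... Passed on to [default_arena()].
#' @export
no_barrier_arena <- function(...) default_arena(variant = "no_barrier", ...)

#' @rdname default_arena
#' @export
corridor_arena <- function(...) default_arena(variant = "corridor", ...)

#' @export
print.arena <- function(x, ...) {
  cat("<arena>", x$variant,
      " border", 2 * x$border_half, "x", 2 * x$border_half,
      " goal (", x$goal[1], ",", x$goal[2], ")\n")
  invisible(x)
}

#' Export arena geometry as JSON
#'
#' @param arena An [default_arena()] object.
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
arena_geometry_json <- function(arena, path = NULL) {
  doc <- list(
    variant = arena$variant,
    border_half = arena$border_half,
    arms = arena$arms,
    opaque_segments = arena$opaque_segs,
    goal = list(center = arena$goal,
                visual_radius = arena$goal_visual_radius),
    zone = arena$zone,
    start = unclass(arena$start_pose)
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

## ---- camera ---------------------------------------------------------------

# smallest positive ray parameter t of intersections with segment rows;
# Inf where a ray hits nothing. dx, dy: unit ray directions.
.ray_seg_tmin <- function(ox, oy, dx, dy, segs) {
  nr <- length(dx)
  if (nrow(segs) == 0) return(rep(Inf, nr))
  sx <- segs[, 3] - segs[, 1]
  sy <- segs[, 4] - segs[, 2]
  wx <- segs[, 1] - ox
  wy <- segs[, 2] - oy
  cross_ws <- wx * sy - wy * sx                     # per segment
  den <- outer(dx, sy) - outer(dy, sx)              # rays x segments
  tt <- sweep(1 / den, 2, cross_ws, `*`)
  ss <- (outer(dy, wx) - outer(dx, wy)) / den
  bad <- abs(den) < 1e-12 | tt <= 1e-9 | ss < -1e-9 | ss > 1 + 1e-9
  tt[bad] <- Inf
  if (ncol(tt) == 1) as.vector(tt) else apply(tt, 1, min)
}

# smallest positive ray parameter of intersection with a circle
.ray_circle_tmin <- function(ox, oy, dx, dy, cx, cy, r) {
  fx <- ox - cx
  fy <- oy - cy
  b <- 2 * (dx * fx + dy * fy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * cc
  t <- rep(Inf, length(dx))
  hit <- disc >= 0
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    t1 <- (-b[hit] - sq) / 2
    t2 <- (-b[hit] + sq) / 2
    tbest <- ifelse(t1 > 1e-9, t1, ifelse(t2 > 1e-9, t2, Inf))
    t[hit] <- tbest
  }
  t
}

#' Render the ray-cast camera
#'
#' Casts `n_rays` rays spread uniformly over the field of view centered on
#' the agent's heading (ray 1 leftmost). The depth channel reports the
#' distance to the nearest physically solid surface — border wall or any
#' part of a barrier arm, transparent stripes included, since the whole
#' barrier is an obstacle. The red channel is 1 on a ray whose first
#' *visual* obstruction is the goal disc — the goal is closer along the
#' ray than any opaque surface, so the red goal shows through transparent
#' stripes while the same surface still registers as an obstacle in
#' depth.
#'
#' @param arena An arena.
#' @param pose The agent pose (must be inside the border).
#' @param camera A [camera_config()].
#' @return A `camera_frame` list with `red` (0/1 per ray), `depth`
#'   (world units, `max_depth` when nothing is hit) and `angles`.
#' @export
render_camera <- function(arena, pose, camera = camera_config()) {
  h <- arena$border_half
  if (abs(pose$x) > h || abs(pose$y) > h) {
    stop("pose outside the border", call. = FALSE)
  }
  n <- camera$n_rays
  ang <- pose$heading + camera$fov / 2 -
    (seq_len(n) - 1) * camera$fov / (n - 1)
  dx <- cos(ang)
  dy <- sin(ang)
  t_occ <- .ray_seg_tmin(pose$x, pose$y, dx, dy, arena$opaque_segs)
  t_solid <- .ray_seg_tmin(pose$x, pose$y, dx, dy, arena$depth_segs)
  t_goal <- .ray_circle_tmin(pose$x, pose$y, dx, dy,
                             arena$goal[1], arena$goal[2],
                             arena$goal_visual_radius)
  red <- as.numeric(t_goal < t_occ & t_goal <= camera$max_depth)
  depth <- pmin(t_solid, camera$max_depth)
  structure(list(red = red, depth = depth, angles = ang),
            class = "camera_frame")
}

#' Red homing signal
#'
#' Counts the pure-red rays and returns their centroid ray index
#' (1-based; `NA` when no ray is red).
#'
#' @param frame A [render_camera()] frame.
#' @return A list with `count` and `centroid`.
#' @export
red_signal <- function(frame) {
  idx <- which(frame$red > 0)
  list(count = length(idx),
       centroid = if (length(idx)) mean(idx) else NA_real_)
}

#' Barrier proximity signal
#'
#' Bins each ray's depth into one of four distance bands (nothing beyond
#' the farthest edge), sums the band weights over rays and normalizes by
#' `n_rays * max(weights)`, so a frame with every ray in the nearest band
#' yields 1.
#'
#' @param depth Per-ray depth vector.
#' @param band_edges Increasing outer band edges (4 values).
#' @param band_weights Positive weights, decreasing with distance.
#' @return A value in `[0, 1]`.
#' @export
barrier_signal <- function(depth, band_edges = c(2, 4, 6, 8),
                           band_weights = c(0.4, 0.3, 0.2, 0.1)) {
  if (length(band_edges) != 4 || is.unsorted(band_edges, strictly = TRUE)) {
    stop("`band_edges` must be 4 strictly increasing values", call. = FALSE)
  }
  if (length(band_weights) != 4 || any(band_weights <= 0) ||
      is.unsorted(rev(band_weights))) {
    stop("`band_weights` must be 4 positive, non-increasing values",
         call. = FALSE)
  }
  band <- findInterval(depth, c(0, band_edges), left.open = TRUE)
  inband <- band >= 1 & band <= 4
  sum(band_weights[band[inband]]) / (length(depth) * max(band_weights))
}

## ---- movement and regions -------------------------------------------------

# is q an acceptable post-move position, moving from p?
.move_ok <- function(px, py, qx, qy, arena, radius) {
  h <- arena$border_half - radius
  if (abs(qx) > h + 1e-9 || abs(qy) > h + 1e-9) return(FALSE)
  segs <- arena$solid_segs
  if (nrow(segs) > 0) {
    dq <- .point_seg_dist(qx, qy, segs)
    dp <- .point_seg_dist(px, py, segs)
    # never deeper into a wall than before (allows grazing contact)
    if (any(dq < radius - 1e-9 & dq < dp - 1e-9)) return(FALSE)
    if (.seg_crosses(px, py, qx, qy, segs)) return(FALSE)
  }
  TRUE
}

#' Move the agent with collision resolution
#'
#' Sets the heading to `heading_command` and advances `speed` world units.
#' If the motion runs into a solid element (border wall or any barrier
#' segment — transparent stripes are physically solid), the motion
#' component into the surface is cancelled and the agent slides along it;
#' it never penetrates.
#'
#' @param pose Current [agent_pose()].
#' @param heading_command New heading (radians).
#' @param speed Distance to advance (>= 0).
#' @param arena The arena.
#' @param radius Agent body radius.
#' @return The new pose.
#' @export
move_agent <- function(pose, heading_command, speed, arena, radius = 0.5) {
  if (speed < 0) stop("`speed` must be >= 0", call. = FALSE)
  h <- arena$border_half - radius
  px <- pose$x; py <- pose$y
  dxy <- speed * c(cos(heading_command), sin(heading_command))
  qx <- min(max(px + dxy[1], -h), h)
  qy <- min(max(py + dxy[2], -h), h)
  if (.move_ok(px, py, qx, qy, arena, radius)) {
    return(agent_pose(qx, qy, heading_command))
  }
  # slide along the nearest blocking segment
  segs <- arena$solid_segs
  if (nrow(segs) > 0) {
    dists <- .point_seg_dist(qx, qy, segs)
    j <- which.min(dists)
    tx <- segs[j, 3] - segs[j, 1]
    ty <- segs[j, 4] - segs[j, 2]
    tl <- sqrt(tx * tx + ty * ty)
    tx <- tx / tl; ty <- ty / tl
    along <- dxy[1] * tx + dxy[2] * ty
    q2x <- min(max(px + along * tx, -h), h)
    q2y <- min(max(py + along * ty, -h), h)
    if (.move_ok(px, py, q2x, q2y, arena, radius)) {
      return(agent_pose(q2x, q2y, heading_command))
    }
  }
  agent_pose(px, py, heading_command)
}

#' Barrier-zone membership
#'
#' @param pose An [agent_pose()].
#' @param arena The arena.
#' @return `TRUE` when the position lies in the barrier zone (closed
#'   boundaries).
#' @export
in_barrier_zone <- function(pose, arena) {
  for (quad in arena$zone) {
    if (.point_in_convex(pose$x, pose$y, quad)) return(TRUE)
  }
  FALSE
}

#' Goal-reach test
#'
#' @param pose An [agent_pose()].
#' @param arena The arena.
#' @param radius Reach radius (default 5 world units); the boundary
#'   counts.
#' @return `TRUE` when the agent is within `radius` of the goal center.
#' @export
goal_reached <- function(pose, arena, radius = 5) {
  sqrt((pose$x - arena$goal[1])^2 + (pose$y - arena$goal[2])^2) <= radius
}
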