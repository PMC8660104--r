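## Allocentric wavefront planning and egocentric homing control.

#' Occupancy grid constructor
#'
#' @param blocked Logical matrix, `blocked[ix, iy]` is `TRUE` where the
#'   cell is not traversable; `ix` indexes x, `iy` indexes y.
#' @param resolution World units per cell.
#' @param origin World coordinate of the corner of cell (1, 1).
#' @return An `occupancy_grid` object.
#' @export
occupancy_grid <- function(blocked, resolution = 1, origin = c(0, 0)) {
  stopifnot(is.matrix(blocked))
  structure(list(blocked = blocked, resolution = resolution,
                 origin = origin, nx = nrow(blocked), ny = ncol(blocked)),
            class = "occupancy_grid")
}

#' Grid cell containing a world point
#'
#' @param grid An [occupancy_grid()].
#' @param p World point `c(x, y)`.
#' @return Integer cell index `c(ix, iy)`, clamped to the grid.
#' @export
cell_of <- function(grid, p) {
  ij <- floor((p - grid$origin) / grid$resolution) + 1L
  c(min(max(ij[1], 1L), grid$nx), min(max(ij[2], 1L), grid$ny))
}

#' World coordinates of a cell center
#'
#' @param grid An [occupancy_grid()].
#' @param cell Integer cell index `c(ix, iy)`.
#' @return World point `c(x, y)`.
#' @export
cell_center <- function(grid, cell) {
  grid$origin + (cell - 0.5) * grid$resolution
}

#' Rasterize an arena into an occupancy grid
#'
#' Marks as blocked every cell overlapping a border wall or a barrier
#' segment after inflation by the agent radius (cell overlap is tested
#' against the cell center with a half-cell margin). The goal cell is
#' always kept free.
#'
#' @param arena An arena.
#' @param resolution Cell size in world units (> 0, smaller than the
#'   arena).
#' @param agent_radius Obstacle inflation radius.
#' @return An [occupancy_grid()].
#' @export
rasterize <- function(arena, resolution = 1, agent_radius = 0.5) {
  h <- arena$border_half
  if (resolution <= 0) stop("`resolution` must be positive", call. = FALSE)
  if (resolution > 2 * h) {
    stop("`resolution` is larger than the arena", call. = FALSE)
  }
  n <- as.integer(round(2 * h / resolution))
  centers <- -h + (seq_len(n) - 0.5) * resolution
  inflate <- agent_radius + resolution / 2
  cx <- rep(centers, times = n)
  cy <- rep(centers, each = n)
  blocked <- abs(cx) > h - inflate | abs(cy) > h - inflate
  segs <- arena$solid_segs
  if (nrow(segs) > 0) {
    for (j in seq_len(nrow(segs))) {
      sx <- segs[j, 3] - segs[j, 1]
      sy <- segs[j, 4] - segs[j, 2]
      len2 <- max(sx * sx + sy * sy, 1e-300)
      t <- ((cx - segs[j, 1]) * sx + (cy - segs[j, 2]) * sy) / len2
      t <- pmin(pmax(t, 0), 1)
      dd <- sqrt((cx - (segs[j, 1] + t * sx))^2 +
                 (cy - (segs[j, 2] + t * sy))^2)
      blocked <- blocked | dd < inflate
    }
  }
  grid <- occupancy_grid(matrix(blocked, n, n), resolution, c(-h, -h))
  gc <- cell_of(grid, arena$goal)
  grid$blocked[gc[1], gc[2]] <- FALSE
  grid
}

# 8-connected neighbor offsets in the deterministic preference order
# N, NE, E, SE, S, SW, W, NW (N = +y)
.nbr_offsets <- matrix(c(0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1, -1, 0,
                         -1, 1), ncol = 2, byrow = TRUE)

#' Wavefront distance map
#'
#' Breadth-first expansion from the goal cell over free cells with
#' 8-connectivity and unit cost per move. `dist` is 0 at the goal and
#' `NA` (unreachable) on blocked or disconnected cells; every reachable
#' non-goal cell has a neighbor whose distance is exactly one less, so
#' gradient descent on `dist` reaches the goal without local minima.
#'
#' @param grid An [occupancy_grid()].
#' @param goal_cell Integer cell index `c(ix, iy)`; must be free.
#' @param connectivity 8 (default) or 4.
#' @return A `wavefront_map` with the integer `dist` matrix.
#' @export
wavefront <- function(grid, goal_cell, connectivity = 8) {
  nx <- grid$nx; ny <- grid$ny
  if (grid$blocked[goal_cell[1], goal_cell[2]]) {
    stop("goal cell is blocked", call. = FALSE)
  }
  offs <- if (connectivity == 8) .nbr_offsets else
    .nbr_offsets[c(1, 3, 5, 7), , drop = FALSE]
  dist <- matrix(NA_integer_, nx, ny)
  dist[goal_cell[1], goal_cell[2]] <- 0L
  fx <- goal_cell[1]; fy <- goal_cell[2]
  d <- 0L
  while (length(fx)) {
    d <- d + 1L
    nxt_x <- integer(0); nxt_y <- integer(0)
    for (k in seq_len(nrow(offs))) {
      qx <- fx + offs[k, 1]
      qy <- fy + offs[k, 2]
      ok <- qx >= 1 & qx <= nx & qy >= 1 & qy <= ny
      qx <- qx[ok]; qy <- qy[ok]
      lin <- qx + (qy - 1L) * nx
      new <- is.na(dist[lin]) & !grid$blocked[lin]
      if (any(new)) {
        lin <- lin[new]
        keep <- !duplicated(lin)
        dist[lin[keep]] <- d
        nxt_x <- c(nxt_x, qx[new][keep])
        nxt_y <- c(nxt_y, qy[new][keep])
      }
    }
    if (length(nxt_x)) {
      lin <- nxt_x + (nxt_y - 1L) * nx
      keep <- !duplicated(lin)
      fx <- nxt_x[keep]; fy <- nxt_y[keep]
    } else {
      fx <- integer(0); fy <- integer(0)
    }
  }
  structure(list(dist = dist, goal_cell = as.integer(goal_cell),
                 connectivity = connectivity),
            class = "wavefront_map")
}

#' Export a wavefront distance matrix as a plain-text CSV grid
#'
#' @param wmap A [wavefront()] map.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_wavefront_csv <- function(wmap, path) {
  write.csv(wmap$dist, path, row.names = FALSE)
  invisible(path)
}

#' Allocentric heading from the wavefront map
#'
#' Returns the world heading toward the center of the 8-neighbor cell
#' with minimal wavefront distance (ties broken in the fixed order N, NE,
#' E, SE, S, SW, W, NW). The agent's own cell may be blocked — the
#' continuous agent can stand closer to a wall than the inflated raster
#' admits — in which case the neighbor minimum still applies. At the goal
#' cell the command is "stop". When no neighbor has a finite distance the
#' command carries `error = TRUE` and the caller is expected to fall back
#' to egocentric control.
#'
#' @param wmap A [wavefront()] map.
#' @param grid The matching [occupancy_grid()].
#' @param pose Current [agent_pose()].
#' @param arena Optional arena; when supplied, a neighbor cell is only
#'   eligible if the straight segment from the pose to its center does
#'   not cross a solid barrier segment (the agent's own cell can straddle
#'   a thin diagonal wall, in which case the raw distance minimum can lie
#'   on the far, unreachable side).
#' @return A list with `heading`, `move` (logical) and `error`.
#' @export
allocentric_heading <- function(wmap, grid, pose, arena = NULL) {
  cell <- cell_of(grid, c(pose$x, pose$y))
  d0 <- wmap$dist[cell[1], cell[2]]
  if (!is.na(d0) && d0 == 0L) {
    return(list(heading = pose$heading, move = FALSE, error = FALSE))
  }
  segs <- if (!is.null(arena)) arena$solid_segs else NULL
  best <- NULL
  best_d <- Inf
  for (k in seq_len(nrow(.nbr_offsets))) {
    q <- cell + .nbr_offsets[k, ]
    if (q[1] < 1 || q[1] > grid$nx || q[2] < 1 || q[2] > grid$ny) next
    dq <- wmap$dist[q[1], q[2]]
    if (is.na(dq) || dq >= best_d) next
    if (!is.null(segs) && nrow(segs) > 0) {
      ctr <- cell_center(grid, q)
      if (.seg_crosses(pose$x, pose$y, ctr[1], ctr[2], segs)) next
    }
    best_d <- dq
    best <- q
  }
  if (is.null(best)) {
    return(list(heading = pose$heading, move = FALSE, error = TRUE))
  }
  ctr <- cell_center(grid, best)
  list(heading = atan2(ctr[2] - pose$y, ctr[1] - pose$x),
       move = TRUE, error = FALSE)
}

#' Egocentric homing heading
#'
#' Proportional controller on the red centroid: the new heading is the
#' current heading plus `k_turn` times the angular offset of the centroid
#' ray from the camera center (ray 1 is the leftmost ray, at `+fov/2`).
#' With no red in view the agent rotates in place by `search_rate` per
#' step with zero forward speed.
#'
#' @param pose Current [agent_pose()].
#' @param centroid Red centroid ray index (1-based, possibly fractional),
#'   or `NA` when no red is visible.
#' @param n_rays,fov Camera geometry.
#' @param k_turn Proportional gain.
#' @param search_rate Search rotation per step (radians).
#' @return A list with `heading` and `move` (logical).
#' @export
egocentric_heading <- function(pose, centroid, n_rays = 64, fov = 2 * pi / 3,
                               k_turn = 1, search_rate = pi / 12) {
  if (is.na(centroid)) {
    return(list(heading = pose$heading + search_rate, move = FALSE))
  }
  offset <- fov / 2 - (centroid - 1) * fov / (n_rays - 1)
  list(heading = pose$heading + k_turn * offset, move = TRUE)
}
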