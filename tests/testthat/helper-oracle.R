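# Independent shortest-path oracle for wavefront tests: build the
# 8-connected lattice over free cells as an igraph graph and use
# igraph::distances() — a completely separate code path from the
# package's breadth-first implementation.
grid_dist_oracle <- function(blocked, goal_cell, connectivity = 8) {
  nx <- nrow(blocked)
  ny <- ncol(blocked)
  id <- function(ix, iy) (iy - 1L) * nx + ix
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  if (connectivity == 4) offs <- offs[1:2]
  from <- integer(0)
  to <- integer(0)
  for (o in offs) {
    ix <- rep(seq_len(nx), times = ny)
    iy <- rep(seq_len(ny), each = nx)
    jx <- ix + o[1]
    jy <- iy + o[2]
    ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
    ix <- ix[ok]; iy <- iy[ok]; jx <- jx[ok]; jy <- jy[ok]
    free <- !blocked[cbind(ix, iy)] & !blocked[cbind(jx, jy)]
    from <- c(from, id(ix, iy)[free])
    to <- c(to, id(jx, jy)[free])
  }
  g <- igraph::make_empty_graph(n = nx * ny, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  d <- igraph::distances(g, v = id(goal_cell[1], goal_cell[2]))
  matrix(as.vector(d), nx, ny)
}

# random occupancy grid with free goal cell
random_grid <- function(nx = 20, ny = 20, p_block = 0.35) {
  blocked <- matrix(runif(nx * ny) < p_block, nx, ny)
  free <- which(!blocked, arr.ind = TRUE)
  goal <- free[sample(nrow(free), 1), ]
  list(grid = occupancy_grid(blocked), goal = as.integer(goal))
}
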