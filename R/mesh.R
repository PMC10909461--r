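# Structured hexahedral mesh generation: rectangular blocks with an
# optional zero-thickness cohesive plane (duplicated node layer).

.grid_nodes <- function(xs, ys, zs, offset = 0L) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nodes <- cbind(rep(xs, times = ny * nz),
                 rep(rep(ys, each = nx), times = nz),
                 rep(zs, each = nx * ny))
  idx <- array(offset + seq_len(nx * ny * nz), dim = c(nx, ny, nz))
  list(nodes = nodes, idx = idx)
}

.grid_hex <- function(idx) {
  d <- dim(idx)
  nx <- d[1] - 1; ny <- d[2] - 1; nz <- d[3] - 1
  if (nx < 1 || ny < 1 || nz < 1) return(matrix(integer(0), 0, 8))
  out <- matrix(0L, nx * ny * nz, 8)
  e <- 0L
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    e <- e + 1L
    out[e, ] <- c(idx[ix, iy, iz], idx[ix + 1, iy, iz],
                  idx[ix + 1, iy + 1, iz], idx[ix, iy + 1, iz],
                  idx[ix, iy, iz + 1], idx[ix + 1, iy, iz + 1],
                  idx[ix + 1, iy + 1, iz + 1], idx[ix, iy + 1, iz + 1])
  }
  out
}

# Rectangular block with an optional cohesive plane at y = iface_y.
# Returns nodes, hexes (with centroids), cohesive connectivity (ordered so
# the interface normal points +y, mode II along +x, mode III along z) and
# the lower/upper grid index arrays for boundary selection.
.mesh_block <- function(xs, ys, zs, iface_y = NULL) {
  if (is.null(iface_y)) {
    g <- .grid_nodes(xs, ys, zs)
    hex <- .grid_hex(g$idx)
    return(list(nodes = g$nodes, hex = hex, coh = matrix(integer(0), 0, 8),
                idxL = g$idx, idxU = g$idx, coh_cent = NULL))
  }
  i0 <- which(abs(ys - iface_y) < 1e-12)
  if (length(i0) != 1 || i0 == 1 || i0 == length(ys)) {
    stop("iface_y must be an interior entry of ys")
  }
  gL <- .grid_nodes(xs, ys[1:i0], zs)
  gU <- .grid_nodes(xs, ys[i0:length(ys)], zs, offset = nrow(gL$nodes))
  nodes <- rbind(gL$nodes, gU$nodes)
  hex <- rbind(.grid_hex(gL$idx), .grid_hex(gU$idx))
  nx <- length(xs) - 1; nz <- length(zs) - 1
  coh <- matrix(0L, nx * nz, 8)
  cent <- matrix(0, nx * nz, 2)
  iyL <- i0
  e <- 0L
  for (iz in seq_len(nz)) for (ix in seq_len(nx)) {
    e <- e + 1L
    bot <- c(gL$idx[ix, iyL, iz + 1], gL$idx[ix + 1, iyL, iz + 1],
             gL$idx[ix + 1, iyL, iz], gL$idx[ix, iyL, iz])
    top <- c(gU$idx[ix, 1, iz + 1], gU$idx[ix + 1, 1, iz + 1],
             gU$idx[ix + 1, 1, iz], gU$idx[ix, 1, iz])
    coh[e, ] <- c(bot, top)
    cent[e, ] <- c((xs[ix] + xs[ix + 1]) / 2, (zs[iz] + zs[iz + 1]) / 2)
  }
  list(nodes = nodes, hex = hex, coh = coh, idxL = gL$idx, idxU = gU$idx,
       coh_cent = cent)
}

.hex_centroids <- function(nodes, hex) {
  t(apply(hex, 1, function(h) colMeans(nodes[h, , drop = FALSE])))
}
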