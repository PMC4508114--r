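# Lattice geometry helpers shared by the agent modules.  Agents and fields
# live on one lattice; an occupancy array maps each voxel to the id of the
# agent sitting there (0 = free).  Face-neighbor lookups are precomputed
# once per grid as an (n_voxels x 6) table of linear indices, ordered by
# ascending linear index (-z, -y, -x, +x, +y, +z) so that "lowest voxel
# index" tie-breaks fall out of a plain which.max.

make_lattice <- function(dims) {
  dims <- as.integer(dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nvox <- nx * ny * nz
  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  lin <- seq_len(nvox)
  nb <- matrix(NA_integer_, nrow = nvox, ncol = 6L)
  nb[, 1] <- ifelse(iz > 1L, lin - nx * ny, NA_integer_)
  nb[, 2] <- ifelse(iy > 1L, lin - nx, NA_integer_)
  nb[, 3] <- ifelse(ix > 1L, lin - 1L, NA_integer_)
  nb[, 4] <- ifelse(ix < nx, lin + 1L, NA_integer_)
  nb[, 5] <- ifelse(iy < ny, lin + nx, NA_integer_)
  nb[, 6] <- ifelse(iz < nz, lin + nx * ny, NA_integer_)
  list(dims = dims, nvox = nvox, nb = nb)
}

vox_to_lin <- function(voxel, dims) {
  voxel[1] + (voxel[2] - 1L) * dims[1] + (voxel[3] - 1L) * dims[1] * dims[2]
}

lin_to_vox <- function(lin, dims) {
  lin0 <- lin - 1L
  x <- lin0 %% dims[1]
  y <- (lin0 %/% dims[1]) %% dims[2]
  z <- lin0 %/% (dims[1] * dims[2])
  c(x + 1L, y + 1L, z + 1L)
}

# in-bounds neighbor linear indices of a voxel, ascending
lattice_neighbors <- function(lattice, lin) {
  nbs <- lattice$nb[lin, ]
  nbs[!is.na(nbs)]
}

# free (occupancy == 0) neighbor linear indices, ascending
free_neighbors <- function(lattice, occ, lin) {
  nbs <- lattice_neighbors(lattice, lin)
  nbs[occ[nbs] == 0L]
}
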