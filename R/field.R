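#' Lattice concentration fields
#'
#' Oxygen and VEGF are represented as continuum concentration fields on the
#' same 3D lattice the agents live on (spacing = one cell diameter, all
#' quantities in relative units).  Transport is explicit forward-Euler
#' diffusion with a 6-point stencil and zero-flux (reflecting) boundaries,
#' followed by multiplicative first-order decay.  The explicit scheme is
#' stable for `D * dt / h^2 <= 1/6`, which is enforced when simulation
#' configurations are validated.
#'
#' @name microenvironment
NULL

#' Create a scalar concentration field
#'
#' @param dims integer 3-vector `(nx, ny, nz)`, each at least 3
#' @param h lattice spacing (relative units; one cell diameter)
#' @param D diffusion coefficient (relative units)
#' @param k_decay first-order decay rate, `>= 0`
#' @param values initial values: a scalar or an array of dimension `dims`;
#'   must be finite and non-negative
#' @return a `scalar_field`
#' @export
scalar_field <- function(dims, h = 1, D = 0, k_decay = 0, values = 0) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 3L)) {
    stop("dims must be three integers, each >= 3", call. = FALSE)
  }
  if (h <= 0) stop("spacing h must be positive", call. = FALSE)
  if (D < 0 || k_decay < 0) stop("D and k_decay must be >= 0", call. = FALSE)
  if (length(values) == 1L) {
    vals <- array(as.numeric(values), dim = dims)
  } else {
    vals <- array(as.numeric(values), dim = dims)
    if (!identical(dim(vals), dims) && !identical(as.integer(dim(values)), dims)) {
      stop("values must match dims", call. = FALSE)
    }
  }
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("field values must be finite and non-negative", call. = FALSE)
  }
  structure(list(dims = dims, h = h, D = D, k_decay = k_decay, values = vals),
            class = "scalar_field")
}

field_check_voxel <- function(field, voxel) {
  voxel <- as.integer(voxel)
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > field$dims)) {
    stop(sprintf("voxel (%s) is outside the %s grid",
                 paste(voxel, collapse = ","),
                 paste(field$dims, collapse = "x")), call. = FALSE)
  }
  voxel
}

#' Deposit an amount at one voxel
#'
#' @param field a `scalar_field`
#' @param voxel integer 3-vector (1-based lattice indices)
#' @param amount non-negative amount added to that voxel
#' @export
add_source <- function(field, voxel, amount) {
  voxel <- field_check_voxel(field, voxel)
  if (amount < 0) stop("amount must be >= 0", call. = FALSE)
  field$values[voxel[1], voxel[2], voxel[3]] <-
    field$values[voxel[1], voxel[2], voxel[3]] + amount
  field
}

#' One explicit diffusion-and-decay step
#'
#' Applies the 6-neighbor Laplacian update with zero-flux boundaries
#' (out-of-domain neighbors replicate the boundary value, so no mass crosses
#' the boundary), then multiplies by `(1 - k_decay * dt)`.  With zero decay,
#' total mass is conserved to floating-point rounding.
#'
#' @param field a `scalar_field`
#' @param dt time step; `field$D * dt / h^2` must not exceed 1/6
#' @export
diffuse_decay_step <- function(field, dt) {
  lam <- field$D * dt / field$h^2
  if (lam > 1 / 6 + 1e-12) {
    stop(sprintf("unstable diffusion step: D*dt/h^2 = %.4g > 1/6", lam),
         call. = FALSE)
  }
  if (field$k_decay * dt > 1) {
    stop("k_decay * dt exceeds 1; decay factor would be negative", call. = FALSE)
  }
  v <- field$values
  if (lam > 0) {
    nx <- field$dims[1]; ny <- field$dims[2]; nz <- field$dims[3]
    nb <- v[c(1L, seq_len(nx - 1L)), , , drop = FALSE] +
          v[c(seq_len(nx - 1L) + 1L, nx), , , drop = FALSE] +
          v[, c(1L, seq_len(ny - 1L)), , drop = FALSE] +
          v[, c(seq_len(ny - 1L) + 1L, ny), , drop = FALSE] +
          v[, , c(1L, seq_len(nz - 1L)), drop = FALSE] +
          v[, , c(seq_len(nz - 1L) + 1L, nz), drop = FALSE]
    v <- v + lam * (nb - 6 * v)
  }
  if (field$k_decay > 0) v <- v * (1 - field$k_decay * dt)
  field$values <- v
  field
}

#' Consume (remove) an amount at one voxel, clamped at zero
#'
#' @param field a `scalar_field`
#' @param voxel integer 3-vector
#' @param rate consumption rate `>= 0`
#' @param dt time step
#' @export
consume <- function(field, voxel, rate, dt) {
  voxel <- field_check_voxel(field, voxel)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  cur <- field$values[voxel[1], voxel[2], voxel[3]]
  field$values[voxel[1], voxel[2], voxel[3]] <- max(0, cur - rate * dt)
  field
}

#' Concentration gradient at a voxel
#'
#' Central differences in the interior, one-sided differences on boundary
#' faces; returned in units of concentration per unit length (`1/h` scaling).
#'
#' @param field a `scalar_field`
#' @param voxel integer 3-vector
#' @return numeric 3-vector
#' @export
gradient_at <- function(field, voxel) {
  voxel <- field_check_voxel(field, voxel)
  g <- numeric(3)
  v <- field$values
  for (ax in 1:3) {
    i <- voxel[ax]; n <- field$dims[ax]
    at <- function(j) { w <- voxel; w[ax] <- j; v[w[1], w[2], w[3]] }
    g[ax] <- if (i > 1L && i < n) {
      (at(i + 1L) - at(i - 1L)) / (2 * field$h)
    } else if (i == 1L) {
      (at(2L) - at(1L)) / field$h
    } else {
      (at(n) - at(n - 1L)) / field$h
    }
  }
  g
}

#' Total amount in a field
#' @param field a `scalar_field`
#' @export
total_mass <- function(field) sum(field$values)

# voxel centers along one axis, in length units
voxel_centers <- function(n, h) (seq_len(n) - 0.5) * h

#' Radial shell totals around a center
#'
#' Voxels are binned by the Euclidean distance of their centers from
#' `center` into `n_bins` equal-width shells spanning `[0, max distance]`;
#' the shell totals partition the field, so they sum to [total_mass()]
#' exactly.  This is the "amount per sphere from the tumor center" display
#' summary.
#'
#' @param field a `scalar_field`
#' @param center numeric 3-vector in length units (voxel centers sit at
#'   `(i - 0.5) * h`)
#' @param n_bins number of shells, `>= 1`
#' @return data.frame with columns `shell` (1-based index) and `amount`
#' @export
radial_profile <- function(field, center, n_bins) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  d <- field$dims
  cx <- voxel_centers(d[1], field$h) - center[1]
  cy <- voxel_centers(d[2], field$h) - center[2]
  cz <- voxel_centers(d[3], field$h) - center[3]
  dist <- sqrt(outer(outer(cx^2, cy^2, `+`), cz^2, `+`))
  dmax <- max(dist)
  bin <- if (dmax == 0) {
    array(1L, dim = d)
  } else {
    pmin(n_bins, floor(dist / (dmax / n_bins)) + 1L)
  }
  amount <- vapply(seq_len(n_bins), function(b) sum(field$values[bin == b]),
                   numeric(1))
  data.frame(shell = seq_len(n_bins), amount = amount)
}

#' Coarse cube totals
#'
#' Tiles the lattice into `block^3` cubes (edge cubes may be smaller) and
#' sums each cube — the "amount per cube throughout the space" display
#' summary.  The grand total equals [total_mass()].
#'
#' @param field a `scalar_field`
#' @param block cube edge in voxels, `>= 1`
#' @return 3D numeric array of cube sums
#' @export
cube_histogram <- function(field, block) {
  block <- as.integer(block)
  if (block < 1L) stop("block must be >= 1", call. = FALSE)
  d <- field$dims
  od <- as.integer(ceiling(d / block))
  gx <- ceiling(seq_len(d[1]) / block)
  gy <- ceiling(seq_len(d[2]) / block)
  gz <- ceiling(seq_len(d[3]) / block)
  # group linear index per voxel
  gi <- gx[slice.index(field$values, 1)] +
        (gy[slice.index(field$values, 2)] - 1L) * od[1] +
        (gz[slice.index(field$values, 3)] - 1L) * od[1] * od[2]
  out <- array(0, dim = od)
  sums <- rowsum(as.vector(field$values), group = as.vector(gi))
  out[as.integer(rownames(sums))] <- sums[, 1]
  out
}

#' Write a field snapshot as CSV
#'
#' One row per voxel with 1-based indices: `x,y,z,value`.
#'
#' @param field a `scalar_field`
#' @param path output file
#' @export
write_field_csv <- function(field, path) {
  d <- field$dims
  df <- data.frame(
    x = rep(seq_len(d[1]), times = d[2] * d[3]),
    y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    z = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(field$values)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field %s, h=%g, D=%g, k_decay=%g, mass=%g>\n",
              paste(x$dims, collapse = "x"), x$h, x$D, x$k_decay, total_mass(x)))
  invisible(x)
}
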