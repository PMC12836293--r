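# Shared fixtures: a coarse (4 mm) phantom keeps unit tests fast; the
# full-resolution 2 mm phantom is reserved for the acceptance checks.

coarse_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(48, 48, 100), spacing_mm = c(4, 4, 4),
               spine_length_mm = 150, seed = seed, ...)
}

coarse_phantom <- function(seed = 1L, ...) generate_phantom(coarse_spec(seed, ...))

# Dose grid holding a linear ramp lo -> hi along x, plus a box structure
# covering the central region.
ramp_fixture <- function(n = 21, lo = 0, hi = 20) {
  vals <- array(rep(seq(lo, hi, length.out = n), times = n * 5),
                dim = c(n, n, 5))
  dose <- dose_grid(vals, spacing_mm = c(2, 2, 2))
  box <- array(TRUE, dim = c(n, n, 5))
  list(dose = dose,
       structure = structure_mask("box", box, c(2, 2, 2)))
}

uniform_grid <- function(value, dim3 = c(8, 8, 8), spacing = c(2, 2, 2)) {
  dose_grid(array(value, dim = dim3), spacing)
}

full_mask <- function(dim3 = c(8, 8, 8), spacing = c(2, 2, 2),
                      name = "all") {
  structure_mask(name, array(TRUE, dim = dim3), spacing)
}

# Static rectangular beam: n_pairs open pairs with the given gap, two CPs.
static_beam <- function(gap_mm = 40, n_pairs = 10, leaf_width_mm = 5,
                        n_cp = 2, mu = 100, id = "beam01",
                        isocenter = "iso1") {
  left <- matrix(-gap_mm / 2, n_cp, n_pairs)
  right <- matrix(gap_mm / 2, n_cp, n_pairs)
  list(id = id, isocenter = isocenter, mu = mu,
       gantry_deg = seq(0, 10, length.out = n_cp), collimator_deg = 0,
       leaf_width_mm = leaf_width_mm, left = left, right = right,
       jaw_x = c(-200, 200),
       cum_mu_frac = seq(0, 1, length.out = n_cp))
}

# Axis-aligned rasterised perimeter oracle: draw the aperture on a fine
# pixel raster and count exposed pixel faces. Exact for integer-mm leaf
# positions with a 1 mm raster.
raster_perimeter <- function(left, right, leaf_width_mm, px = 1) {
  x0 <- min(left) - 2 * px; x1 <- max(right) + 2 * px
  nx <- round((x1 - x0) / px)
  ny <- length(left) * round(leaf_width_mm / px)
  img <- matrix(FALSE, nx, ny)
  for (i in seq_along(left)) {
    if (right[i] <= left[i]) next
    cols <- ((i - 1) * round(leaf_width_mm / px) + 1):(i * round(leaf_width_mm / px))
    rows <- which((x0 + (seq_len(nx) - 0.5) * px) > left[i] &
                    (x0 + (seq_len(nx) - 0.5) * px) < right[i])
    img[rows, cols] <- TRUE
  }
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- img
  edges <- sum(pad[-1, ] != pad[-nrow(pad), ]) + sum(pad[, -1] != pad[, -ncol(pad)])
  edges * px
}
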