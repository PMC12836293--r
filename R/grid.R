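#' Dose grid
#'
#' A 3-D scalar dose field on a regular grid. Axes are ordered
#' (x = left-right, y = anterior-posterior, z = superior-inferior), in
#' patient-space millimetres; voxel centres lie at
#' `origin_mm + (index - 1) * spacing_mm`.
#'
#' @param values 3-D numeric array of dose in Gy; finite and non-negative.
#' @param spacing_mm numeric(3), voxel size per axis in mm, all > 0.
#' @param origin_mm numeric(3), position of the first voxel centre in mm.
#' @param frame_id text label identifying the frame of reference.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                      frame_id = "phantom") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (any(!is.finite(values))) stop("dose values must be finite")
  if (any(values < 0)) stop("dose values must be non-negative")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive numbers")
  if (length(origin_mm) != 3L) stop("`origin_mm` must have length 3")
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm,
         frame_id = as.character(frame_id)),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<dose_grid '%s'> %d x %d x %d voxels, spacing %s mm, dose %.2f-%.2f Gy\n",
    x$frame_id, d[1], d[2], d[3],
    paste(format(x$spacing_mm, trim = TRUE), collapse = "x"),
    min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel-centre coordinates of a grid axis
#'
#' @param grid a `dose_grid` (or anything with `spacing_mm`, `origin_mm` and
#'   3-D `values`/`mask`).
#' @param axis integer 1..3.
#' @return numeric vector of coordinates in mm.
#' @export
grid_axis_mm <- function(grid, axis) {
  arr <- if (!is.null(grid$values)) grid$values else grid$mask
  n <- dim(arr)[axis]
  grid$origin_mm[axis] + (seq_len(n) - 1) * grid$spacing_mm[axis]
}

#' Voxel volume in cubic centimetres
#' @param grid a `dose_grid` or `structure_mask`.
#' @return scalar cc.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing_mm) / 1000

same_geometry <- function(a, b, tol = 1e-6) {
  da <- dim(if (!is.null(a$values)) a$values else a$mask)
  db <- dim(if (!is.null(b$values)) b$values else b$mask)
  identical(da, db) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

#' Structure mask
#'
#' Named boolean voxel set aligned to a dose grid. Volumes are whole-voxel:
#' `volume_cc = true-voxel count x voxel volume` (no partial-volume
#' weighting).
#'
#' @param name structure name.
#' @param mask logical 3-D array, same shape as the grid it belongs to.
#' @param spacing_mm,origin_mm,frame_id geometry, as for [dose_grid()].
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, mask, spacing_mm, origin_mm = c(0, 0, 0),
                           frame_id = "phantom") {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a logical 3-D array")
  structure(
    list(name = as.character(name), mask = mask,
         spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm), frame_id = as.character(frame_id)),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask '%s'> %d voxels, %.2f cc\n",
              x$name, sum(x$mask), structure_volume_cc(x)))
  invisible(x)
}

#' Structure volume (cc)
#' @param structure a `structure_mask`.
#' @return volume in cc (true-voxel count times voxel volume).
#' @export
structure_volume_cc <- function(structure) {
  sum(structure$mask) * voxel_volume_cc(structure)
}

#' Doses of the voxels inside a structure
#'
#' @param dose a `dose_grid`.
#' @param structure a `structure_mask` on the same grid.
#' @return numeric vector of in-structure voxel doses (Gy), unordered.
#' @export
structure_doses <- function(dose, structure) {
  if (!same_geometry(dose, structure))
    stop("dose grid and structure mask geometries differ")
  if (!any(structure$mask))
    stop(sprintf("structure '%s' is empty", structure$name))
  dose$values[structure$mask]
}

#' Coordinates (mm) of the voxel centres inside a mask
#' @param structure a `structure_mask`.
#' @return n x 3 matrix of mm coordinates.
#' @export
mask_coords_mm <- function(structure) {
  idx <- which(structure$mask, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, structure$spacing_mm, "*"),
        2, structure$origin_mm, "+")
}

# Vectorised trilinear interpolation of a 3-D array at arbitrary points.
# Points outside the grid are clamped to the nearest edge value; the
# fraction of clamped points is returned as attribute "out_of_field".
interp_trilinear <- function(values, spacing_mm, origin_mm, pts) {
  d <- dim(values)
  # fractional (0-based) index per axis
  fx <- (pts[, 1] - origin_mm[1]) / spacing_mm[1]
  fy <- (pts[, 2] - origin_mm[2]) / spacing_mm[2]
  fz <- (pts[, 3] - origin_mm[3]) / spacing_mm[3]
  oob <- fx < 0 | fx > d[1] - 1 | fy < 0 | fy > d[2] - 1 | fz < 0 | fz > d[3] - 1
  clamp <- function(f, n) pmin(pmax(f, 0), n - 1)
  fx <- clamp(fx, d[1]); fy <- clamp(fy, d[2]); fz <- clamp(fz, d[3])
  i0 <- pmin(floor(fx), d[1] - 2); j0 <- pmin(floor(fy), d[2] - 2)
  k0 <- pmin(floor(fz), d[3] - 2)
  if (d[1] < 2) i0 <- rep(0, length(fx))
  if (d[2] < 2) j0 <- rep(0, length(fy))
  if (d[3] < 2) k0 <- rep(0, length(fz))
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  at <- function(di, dj, dk) {
    ii <- pmin(i0 + di, d[1] - 1); jj <- pmin(j0 + dj, d[2] - 1)
    kk <- pmin(k0 + dk, d[3] - 1)
    values[1 + ii + d[1] * (jj + d[2] * kk)]
  }
  v <-
    at(0, 0, 0) * (1 - tx) * (1 - ty) * (1 - tz) +
    at(1, 0, 0) * tx       * (1 - ty) * (1 - tz) +
    at(0, 1, 0) * (1 - tx) * ty       * (1 - tz) +
    at(1, 1, 0) * tx       * ty       * (1 - tz) +
    at(0, 0, 1) * (1 - tx) * (1 - ty) * tz +
    at(1, 0, 1) * tx       * (1 - ty) * tz +
    at(0, 1, 1) * (1 - tx) * ty       * tz +
    at(1, 1, 1) * tx       * ty       * tz
  attr(v, "out_of_field") <- mean(oob)
  v
}

#' Sample a dose grid at arbitrary points
#'
#' Trilinear interpolation of the dose field at mm coordinates. Points
#' outside the grid take the nearest-edge value; the clamped fraction is
#' attached as attribute `"out_of_field"`.
#'
#' @param dose a `dose_grid`.
#' @param pts n x 3 matrix of mm coordinates.
#' @return numeric vector of interpolated doses.
#' @export
sample_dose <- function(dose, pts) {
  interp_trilinear(dose$values, dose$spacing_mm, dose$origin_mm, pts)
}
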