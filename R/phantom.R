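# Synthetic head-and-spine phantom: geometry, dose, plans, delivery logs.
# Everything is a pure function of (spec, recipe, seed); RNG state is saved
# and restored around every draw so no global state leaks.

local_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

default_structure_params <- function() {
  list(
    ptv_cranial_margin_mm = 10,     # cranial PTV radius = head radius - margin
    spine_radius_mm = 12.5,         # spinal PTV cylinder radius
    spine_post_offset_mm = 20,      # AP offset of the spinal canal axis
    spine_field_radius_mm = 40,     # radius of the spinal dose bath
    hippocampus = list(lat_mm = 28, post_mm = 5, dz_mm = 0,
                       semi_mm = c(6, 12, 5)),
    hypothalamus = list(lat_mm = 0, post_mm = 0, dz_mm = -8,
                        semi_mm = c(6, 6, 4)),
    pituitary = list(lat_mm = 0, post_mm = 2, dz_mm = -18,
                     semi_mm = c(4, 4, 4)),
    cochlea = list(lat_mm = 55, post_mm = 10, dz_mm = -8,
                   semi_mm = c(5, 5, 5)),
    scalp_thickness_mm = 5,
    scalp_min_dz_mm = -40,          # scalp kept above the skull base
    vertebra_halfwidth_mm = 15,
    vertebra_depth_mm = 20,
    jitter_sd_mm = 1                # per-structure centre jitter across seeds
  )
}

#' Phantom specification
#'
#' Describes the synthetic pediatric head + spine geometry: a spherical head
#' holding the cranial PTV and the functional structures (paired
#' hippocampi, hypothalamus, pituitary, paired cochleae, a 5 mm scalp
#' shell), and a spinal-canal cylinder with a vertebral column abutting it
#' posteriorly.
#'
#' @param grid_shape integer(3) voxel counts per axis (x, y, z).
#' @param spacing_mm numeric(3) voxel size in mm.
#' @param head_radius_mm head sphere radius (mm).
#' @param spine_length_mm spinal PTV length (mm).
#' @param structure_params named list overriding entries of the default
#'   per-structure size/position descriptors (see
#'   `csieval:::default_structure_params`).
#' @param seed integer seed controlling the (small) anatomical jitter.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(100, 100, 250),
                         spacing_mm = c(2, 2, 2),
                         head_radius_mm = 80,
                         spine_length_mm = 300,
                         structure_params = list(),
                         seed = 1L) {
  if (any(spacing_mm <= 0)) stop("spacings must be > 0")
  if (any(grid_shape < 2)) stop("grid_shape must be at least 2 per axis")
  sp <- utils::modifyList(default_structure_params(), structure_params)
  structure(
    list(grid_shape = as.integer(grid_shape),
         spacing_mm = as.numeric(spacing_mm),
         head_radius_mm = head_radius_mm,
         spine_length_mm = spine_length_mm,
         structure_params = sp, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# 3-D logical mask of an axis-aligned ellipsoid, by voxel-centre-in-region.
ellipsoid_mask_arr <- function(x, y, z, centre, semi) {
  ex <- ((x - centre[1]) / semi[1])^2
  ey <- ((y - centre[2]) / semi[2])^2
  ez <- ((z - centre[3]) / semi[3])^2
  outer(outer(ex, ey, "+"), ez, "+") <= 1
}

#' Generate the phantom geometry
#'
#' Voxelises the phantom structures (voxel-centre-in-region) on the grid
#' defined by the spec. The returned structure set contains `ptv`,
#' `ptv_cranial`, `ptv_spinal`, `hippocampus`, `hypothalamus`, `pituitary`,
#' `cochlea`, `scalp` and `vertebrae`; the scalp is a shell of the
#' configured thickness, the interior functional structures lie inside the
#' cranial PTV, and the vertebrae abut the spinal PTV posteriorly.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom`: list with `template` (all-zero [dose_grid()]),
#'   `structures` (named list of [structure_mask()]), `geometry` (derived
#'   mm-space landmarks used by [generate_dose()]), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$structure_params
  shape <- spec$grid_shape
  spacing <- spec$spacing_mm
  # x and y centred on the head axis, z from 0 (inferior) upward
  origin <- c(-(shape[1] - 1) * spacing[1] / 2,
              -(shape[2] - 1) * spacing[2] / 2, 0)
  x <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  z <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]

  z_top <- max(z)
  head_c <- c(0, 0, z_top - spec$head_radius_mm - 8)
  r_cran <- spec$head_radius_mm - sp$ptv_cranial_margin_mm
  spine_z1 <- head_c[3] - spec$head_radius_mm
  spine_z0 <- spine_z1 - spec$spine_length_mm
  if (spine_z0 < min(z))
    stop("spine does not fit inside the grid; enlarge grid_shape[3]")
  spine_y <- sp$spine_post_offset_mm

  jit <- local_rng(spec$seed, function() {
    matrix(stats::rnorm(8 * 3, 0, sp$jitter_sd_mm), ncol = 3)
  })
  if (sp$jitter_sd_mm == 0) jit[] <- 0

  masks <- list()
  masks$ptv_cranial <- ellipsoid_mask_arr(x, y, z, head_c, rep(r_cran, 3))
  rad2 <- outer((x - 0)^2, (y - spine_y)^2, "+")
  zin <- z >= spine_z0 & z <= spine_z1
  masks$ptv_spinal <- outer(rad2 <= sp$spine_radius_mm^2, zin, "&")
  masks$ptv <- masks$ptv_cranial | masks$ptv_spinal

  bilateral <- function(p, jrow_l, jrow_r) {
    cl <- head_c + c(-p$lat_mm, p$post_mm, p$dz_mm) + jit[jrow_l, ]
    cr <- head_c + c(p$lat_mm, p$post_mm, p$dz_mm) + jit[jrow_r, ]
    list(ellipsoid_mask_arr(x, y, z, cl, p$semi_mm),
         ellipsoid_mask_arr(x, y, z, cr, p$semi_mm),
         centres = rbind(cl, cr), semi = p$semi_mm)
  }
  hip <- bilateral(sp$hippocampus, 1, 2)
  masks$hippocampus <- hip[[1]] | hip[[2]]
  coc <- bilateral(sp$cochlea, 3, 4)
  masks$cochlea <- coc[[1]] | coc[[2]]
  hy_c <- head_c + c(sp$hypothalamus$lat_mm, sp$hypothalamus$post_mm,
                     sp$hypothalamus$dz_mm) + jit[5, ]
  masks$hypothalamus <- ellipsoid_mask_arr(x, y, z, hy_c, sp$hypothalamus$semi_mm)
  pi_c <- head_c + c(sp$pituitary$lat_mm, sp$pituitary$post_mm,
                     sp$pituitary$dz_mm) + jit[6, ]
  masks$pituitary <- ellipsoid_mask_arr(x, y, z, pi_c, sp$pituitary$semi_mm)

  r2_head <- outer(outer((x - head_c[1])^2, (y - head_c[2])^2, "+"),
                   (z - head_c[3])^2, "+")
  shell <- r2_head <= spec$head_radius_mm^2 &
    r2_head >= (spec$head_radius_mm - sp$scalp_thickness_mm)^2
  masks$scalp <- shell & outer(array(TRUE, dim = shape[1:2]),
                               z >= head_c[3] + sp$scalp_min_dz_mm, "&")

  vy0 <- spine_y + sp$spine_radius_mm          # abuts the spinal PTV
  vy1 <- vy0 + sp$vertebra_depth_mm
  vx <- abs(x) <= sp$vertebra_halfwidth_mm
  masks$vertebrae <- outer(outer(vx, y >= vy0 & y <= vy1, "&"), zin, "&")

  for (nm in names(masks)) {
    if (!any(masks[[nm]]))
      stop(sprintf("structure '%s' is empty at this resolution", nm))
  }
  structures <- lapply(names(masks), function(nm)
    structure_mask(nm, masks[[nm]], spacing, origin))
  names(structures) <- names(masks)

  template <- dose_grid(array(0, dim = shape), spacing, origin)
  geometry <- list(
    origin_mm = origin, head_centre_mm = head_c, r_cranial_mm = r_cran,
    spine_axis_xy_mm = c(0, spine_y), spine_radius_mm = sp$spine_radius_mm,
    spine_field_radius_mm = sp$spine_field_radius_mm,
    spine_z_mm = c(spine_z0, spine_z1),
    vertebra_y_mm = c(vy0, vy1),
    well_centres = list(
      hippocampus = hip$centres, cochlea = coc$centres,
      hypothalamus = rbind(hy_c), pituitary = rbind(pi_c)),
    well_semi = list(
      hippocampus = sp$hippocampus$semi_mm, cochlea = sp$cochlea$semi_mm,
      hypothalamus = sp$hypothalamus$semi_mm, pituitary = sp$pituitary$semi_mm)
  )
  structure(list(template = template, structures = structures,
                 geometry = geometry, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels @ %s mm, %d structures\n",
              paste(dim(x$template$values), collapse = "x"),
              paste(format(x$spec$spacing_mm, trim = TRUE), collapse = "x"),
              length(x$structures)))
  for (s in x$structures)
    cat(sprintf("  %-12s %8.2f cc\n", s$name, structure_volume_cc(s)))
  invisible(x)
}

#' Dose recipe
#'
#' Parameters of the synthetic dose distribution: the CSI prescription
#' (23.4 Gy in 13 fractions by default), the plan style, and the sparing
#' targets. `mode = "standard"` emulates a plan with no functional-organ
#' constraints: the whole PTV and every interior functional structure sit
#' at the prescription. `mode = "functional_sparing"` carves smooth
#' Gaussian avoidance dips so each entry of `avoidance_targets` is met in
#' structure-mean dose while target coverage is retained.
#'
#' @param prescription_Gy total prescription dose (Gy).
#' @param n_fractions number of fractions.
#' @param mode `"standard"` or `"functional_sparing"`.
#' @param avoidance_targets named numeric, structure -> target mean dose
#'   (Gy). Defaults: none for standard mode; hippocampus 12.4,
#'   hypothalamus 14.7, pituitary 15.4, cochlea 21.4 for functional
#'   sparing (the sparing levels the technique is designed to reach).
#' @param penumbra_sigma_mm Gaussian width of the dose fall-off outside the
#'   target (mm).
#' @param noise_sd_Gy additive Gaussian dose noise (Gy), emulating Monte
#'   Carlo calculation noise.
#' @param vertebral_gradient_Gy imposed anterior-posterior D2%-D98% spread
#'   across the vertebrae (Gy). Defaults 8.7 (standard) / 4.7 (sparing),
#'   the spread each technique produces.
#' @return An object of class `dose_recipe`.
#' @export
dose_recipe <- function(prescription_Gy = 23.4, n_fractions = 13,
                        mode = c("standard", "functional_sparing"),
                        avoidance_targets = NULL,
                        penumbra_sigma_mm = 6,
                        noise_sd_Gy = 0.05,
                        vertebral_gradient_Gy = NULL) {
  mode <- match.arg(mode)
  if (prescription_Gy <= 0) stop("prescription must be > 0")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  if (is.null(avoidance_targets)) {
    avoidance_targets <- if (mode == "functional_sparing")
      c(hippocampus = 12.4, hypothalamus = 14.7,
        pituitary = 15.4, cochlea = 21.4)
    else numeric(0)
  }
  if (length(avoidance_targets) &&
      any(avoidance_targets >= prescription_Gy))
    stop("avoidance target means must be below the prescription")
  if (is.null(vertebral_gradient_Gy))
    vertebral_gradient_Gy <- if (mode == "functional_sparing") 4.7 else 8.7
  structure(
    list(prescription_Gy = prescription_Gy, n_fractions = n_fractions,
         mode = mode, avoidance_targets = avoidance_targets,
         penumbra_sigma_mm = penumbra_sigma_mm, noise_sd_Gy = noise_sd_Gy,
         vertebral_gradient_Gy = vertebral_gradient_Gy),
    class = "dose_recipe"
  )
}

# Anisotropic super-Gaussian well centred at `centre`, widths sigma (mm):
# exp(-u^2/2) with u the squared scaled radius. Flat over the structure,
# near-Gaussian shoulder, but a much faster tail than a plain Gaussian, so
# the dip stays local and target coverage outside the avoidance region is
# preserved.
gaussian_well_arr <- function(x, y, z, centre, sigma) {
  u <- outer(outer((x - centre[1])^2 / sigma[1]^2,
                   (y - centre[2])^2 / sigma[2]^2, "+"),
             (z - centre[3])^2 / sigma[3]^2, "+")
  exp(-u^2 / 2)
}

#' Generate a synthetic CSI dose distribution
#'
#' Builds the dose as prescription inside the target envelope with a
#' Gaussian penumbra outside it, a linear anterior-posterior ramp across
#' the vertebral column whose amplitude is solved so the vertebral
#' D2%-D98% equals `vertebral_gradient_Gy`, and (in functional-sparing
#' mode) one anisotropic Gaussian avoidance dip per target structure.
#' The dip amplitudes are obtained by solving the small linear system
#' relating well amplitudes to structure-mean doses, so every
#' `avoidance_targets` entry is met exactly before noise; overlapping wells
#' (hypothalamus/pituitary) are thereby handled jointly.
#'
#' @param phantom a `phantom` from [generate_phantom()].
#' @param recipe a [dose_recipe()].
#' @param seed integer seed for the additive noise.
#' @return A [dose_grid()].
#' @export
generate_dose <- function(phantom, recipe, seed = 1L) {
  stopifnot(inherits(phantom, "phantom"), inherits(recipe, "dose_recipe"))
  g <- phantom$geometry
  shape <- dim(phantom$template$values)
  spacing <- phantom$spec$spacing_mm
  origin <- g$origin_mm
  x <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  z <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  rx <- recipe$prescription_Gy
  sig <- recipe$penumbra_sigma_mm

  # --- distance outside the target envelope (analytic SDFs) -------------
  hc <- g$head_centre_mm
  d_sph <- sqrt(outer(outer((x - hc[1])^2, (y - hc[2])^2, "+"),
                      (z - hc[3])^2, "+")) - g$r_cranial_mm
  rad <- sqrt(outer((x - g$spine_axis_xy_mm[1])^2,
                    (y - g$spine_axis_xy_mm[2])^2, "+")) -
    g$spine_field_radius_mm
  dz_out <- pmax(g$spine_z_mm[1] - z, z - g$spine_z_mm[2], 0)
  d_cyl <- sqrt(outer(pmax(rad, 0)^2, dz_out^2, "+"))
  d_cyl[outer(rad <= 0, dz_out <= 0, "&")] <- 0
  d_out <- pmax(pmin(d_sph, d_cyl), 0)
  dose <- rx * exp(-d_out^2 / (2 * sig^2))
  rm(d_sph, d_cyl, d_out)

  # --- vertebral anterior-posterior ramp --------------------------------
  vert <- phantom$structures$vertebrae$mask
  depth_y <- pmin(pmax((y - g$vertebra_y_mm[1]) /
                         diff(g$vertebra_y_mm), 0), 1)
  in_slab <- outer(outer(rep(TRUE, shape[1]), depth_y > 0, "&"),
                   z >= g$spine_z_mm[1] & z <= g$spine_z_mm[2], "&")
  depth <- array(rep(rep(depth_y, each = shape[1]), shape[3]), dim = shape)
  depth[!in_slab] <- 0
  vd <- dose[vert]; vdep <- depth[vert]
  grad_of <- function(a) {
    dd <- vd * (1 - a * vdep)
    unname(stats::quantile(dd, 0.98, type = 7) -
             stats::quantile(dd, 0.02, type = 7))
  }
  target_grad <- recipe$vertebral_gradient_Gy
  if (grad_of(0) >= target_grad) {
    a <- 0
    warning("baseline vertebral spread already exceeds the requested gradient")
  } else if (grad_of(1) <= target_grad) {
    a <- 1
  } else {
    a <- stats::uniroot(function(a) grad_of(a) - target_grad,
                        c(0, 1), tol = 1e-6)$root
  }
  dose <- dose * (1 - a * depth)
  rm(depth, in_slab)

  # --- functional-sparing avoidance dips --------------------------------
  targets <- recipe$avoidance_targets
  if (recipe$mode == "functional_sparing" && length(targets)) {
    ptv_mask <- phantom$structures$ptv$mask
    for (nm in names(targets)) {
      st <- phantom$structures[[nm]]
      if (is.null(st)) stop(sprintf("no structure '%s' for avoidance", nm))
      if (!any(xor(st$mask, ptv_mask)))
        stop(sprintf("avoidance structure '%s' is identical to the PTV", nm))
    }
    wells <- lapply(names(targets), function(nm) {
      ctrs <- g$well_centres[[nm]]
      sigma <- g$well_semi[[nm]] + 3
      w <- 0
      for (i in seq_len(nrow(ctrs)))
        w <- w + gaussian_well_arr(x, y, z, ctrs[i, ], sigma)
      w
    })
    names(wells) <- names(targets)
    k <- length(targets)
    M <- matrix(0, k, k, dimnames = list(names(targets), names(targets)))
    b <- numeric(k)
    for (i in seq_len(k)) {
      m <- phantom$structures[[names(targets)[i]]]$mask
      for (j in seq_len(k)) M[i, j] <- mean(wells[[j]][m])
      b[i] <- mean(dose[m]) - targets[i]
    }
    amp <- solve(M, b)
    amp[amp < 0] <- 0
    for (j in seq_len(k)) if (amp[j] > 0) dose <- dose - amp[j] * wells[[j]]
    rm(wells)
  }

  if (recipe$noise_sd_Gy > 0) {
    noise <- local_rng(seed, function()
      stats::rnorm(length(dose), 0, recipe$noise_sd_Gy))
    dose <- dose + noise
  }
  dose[dose < 0] <- 0
  dose_grid(dose, spacing, origin, frame_id = phantom$template$frame_id)
}
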