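# Setup-uncertainty robustness: rigid perturbation scenarios, perturbed
# dose resampling, DVH bands, and the robustness index lambda.
#
# The perturbed dose is the static planned dose field rigidly transformed
# relative to the structure frame (the standard isocenter-shift surrogate
# for a full perturbed recomputation); surface-curvature dose changes are
# deliberately ignored.

#' Perturbation scenario
#'
#' @param translation_mm signed shift (x = LR, y = AP, z = SI), mm.
#' @param rotation_deg signed (pitch, yaw, roll) in degrees; pitch about
#'   the LR axis, yaw about the AP axis, roll about the SI axis.
#' @param label scenario label.
#' @param group magnitude group label (e.g. `"±2 mm"`).
#' @return object of class `perturbation_scenario`.
#' @export
perturbation_scenario <- function(translation_mm = c(0, 0, 0),
                                  rotation_deg = c(0, 0, 0),
                                  label = "", group = "") {
  if (any(abs(translation_mm) > 10))
    stop("translations above 10 mm are outside the supported range")
  if (any(abs(rotation_deg) > 5))
    stop("rotations above 5 degrees are outside the supported range")
  structure(list(translation_mm = as.numeric(translation_mm),
                 rotation_deg = as.numeric(rotation_deg),
                 label = label, group = group),
            class = "perturbation_scenario")
}

#' Canonical 30-scenario setup-error set
#'
#' 18 translational shifts (±2, ±3 and ±5 mm along each of the LR, AP and
#' SI axes) and 12 rotational errors (±1.0° and ±2.0° in pitch, yaw and
#' roll), grouped by magnitude. Exactly one of translation/rotation is
#' non-zero per scenario.
#'
#' @return list of 30 [perturbation_scenario()] objects.
#' @export
canonical_scenarios <- function() {
  axes <- c("LR", "AP", "SI")
  out <- list()
  for (mag in c(2, 3, 5)) for (ax in 1:3) for (sgn in c(1, -1)) {
    tr <- c(0, 0, 0); tr[ax] <- sgn * mag
    out[[length(out) + 1]] <- perturbation_scenario(
      translation_mm = tr,
      label = sprintf("%+g mm %s", sgn * mag, axes[ax]),
      group = sprintf("±%g mm", mag))
  }
  rots <- c("pitch", "yaw", "roll")
  for (mag in c(1, 2)) for (ax in 1:3) for (sgn in c(1, -1)) {
    ro <- c(0, 0, 0); ro[ax] <- sgn * mag
    out[[length(out) + 1]] <- perturbation_scenario(
      rotation_deg = ro,
      label = sprintf("%+g° %s", sgn * mag, rots[ax]),
      group = sprintf("±%g°", mag))
  }
  out
}

# Rotation matrix for intrinsic rotations applied in roll -> pitch -> yaw
# order; pitch about x (LR), yaw about y (AP), roll about z (SI).
scenario_rotation <- function(rotation_deg) {
  th <- rotation_deg * pi / 180
  cp <- cos(th[1]); sp <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cr <- cos(th[3]); sr <- sin(th[3])
  Rx <- rbind(c(1, 0, 0), c(0, cp, -sp), c(0, sp, cp))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cr, -sr, 0), c(sr, cr, 0), c(0, 0, 1))
  Ry %*% Rx %*% Rz
}

# Map evaluation points (mm) to the dose-field coordinates they see under
# a rigid setup error: rotate about the isocenter, then translate.
perturbed_coords <- function(pts, scenario, isocenter_mm) {
  R <- scenario_rotation(scenario$rotation_deg)
  ctr <- sweep(pts, 2, isocenter_mm)
  sweep(ctr %*% t(R), 2, isocenter_mm + scenario$translation_mm, "+")
}

#' Rigidly perturbed dose distribution
#'
#' Resamples the dose field under a rigid setup error (translation, then
#' intrinsic rotations about the isocenter) with trilinear interpolation.
#' Voxels mapping outside the original grid take the nearest-edge value
#' and are counted in the `out_of_field` attribute of the result.
#'
#' @param dose a [dose_grid()].
#' @param scenario a [perturbation_scenario()].
#' @param isocenter_mm rotation centre (mm), typically the cranial plan
#'   isocenter.
#' @return A [dose_grid()] with attribute `out_of_field` (fraction of
#'   grid voxels that sampled outside the original field).
#' @export
perturb_dose <- function(dose, scenario, isocenter_mm) {
  d <- dim(dose$values)
  ax <- lapply(1:3, function(a) grid_axis_mm(dose, a))
  pts <- cbind(rep(ax[[1]], times = d[2] * d[3]),
               rep(rep(ax[[2]], each = d[1]), times = d[3]),
               rep(ax[[3]], each = d[1] * d[2]))
  v <- sample_dose(dose, perturbed_coords(pts, scenario, isocenter_mm))
  oof <- attr(v, "out_of_field")
  out <- dose_grid(array(pmax(v, 0), dim = d), dose$spacing_mm,
                   dose$origin_mm, dose$frame_id)
  attr(out, "out_of_field") <- oof
  out
}

#' Robustness index lambda
#'
#' `lambda = (best - worst) / nominal * 100` where best/worst are the
#' extreme metric values over a scenario group. Smaller lambda means a
#' more robust plan.
#'
#' @param nominal_value metric value of the unperturbed plan (> 0).
#' @param scenario_values metric values across the group's scenarios.
#' @return lambda in percent (>= 0).
#' @export
lambda_index <- function(nominal_value, scenario_values) {
  if (nominal_value <= 0) stop("nominal value must be > 0")
  if (!length(scenario_values)) stop("no scenario values")
  (max(scenario_values) - min(scenario_values)) / nominal_value * 100
}

#' Default structure -> DVH-metric map for robustness evaluation
#'
#' D95% for the PTV, D40% for the hippocampus, D50% for hypothalamus,
#' pituitary, scalp and cochlea.
#' @return named character vector.
#' @export
default_metric_map <- function() {
  c(ptv = "D95%", hippocampus = "D40%", hypothalamus = "D50%",
    pituitary = "D50%", cochlea = "D50%", scalp = "D50%")
}

#' Setup-uncertainty robustness study
#'
#' Evaluates every structure's DVH metric under each perturbation
#' scenario and summarises per (structure, magnitude group): the
#' robustness index lambda and the band width (max - min of the metric).
#' The nominal value is excluded from the extremes.
#'
#' The perturbed metric is computed by sampling the dose field at the
#' rigidly transformed structure-voxel coordinates, which is exactly the
#' in-structure restriction of [perturb_dose()] but avoids resampling the
#' full grid per scenario.
#'
#' @param dose nominal [dose_grid()].
#' @param structures named list of [structure_mask()].
#' @param metric_map named character vector, structure -> metric label;
#'   defaults to [default_metric_map()] restricted to the structures
#'   present.
#' @param scenarios list of scenarios; default [canonical_scenarios()].
#' @param isocenter_mm rotation centre (mm).
#' @param oof_warn_fraction warn when a structure samples outside the
#'   grid in more than this fraction of its voxels under any scenario.
#' @return list of class `robustness_study`: `values` (long data.frame:
#'   structure, metric, group, scenario, value), `summary` (data.frame:
#'   structure, metric, group, nominal, best, worst, band_width,
#'   lambda_percent), `nominal` (named nominal metric values).
#' @export
robustness_study <- function(dose, structures, metric_map = NULL,
                             scenarios = canonical_scenarios(),
                             isocenter_mm, oof_warn_fraction = 0.05) {
  if (is.null(metric_map)) {
    mm <- default_metric_map()
    metric_map <- mm[names(mm) %in% names(structures)]
  }
  if (!all(names(metric_map) %in% names(structures)))
    stop("metric_map names missing from `structures`: ",
         paste(setdiff(names(metric_map), names(structures)), collapse = ", "))
  rows <- list()
  nominal <- numeric(0)
  for (snm in names(metric_map)) {
    st <- structures[[snm]]
    pts <- mask_coords_mm(st)
    metric <- metric_map[[snm]]
    nom <- dose_metric(dvh_from_doses(sample_dose(dose, pts),
                                      total_volume_cc = structure_volume_cc(st)),
                       metric)
    nominal[snm] <- nom
    for (sc in scenarios) {
      v <- sample_dose(dose, perturbed_coords(pts, sc, isocenter_mm))
      if (attr(v, "out_of_field") > oof_warn_fraction)
        warning(sprintf(
          "structure '%s', scenario '%s': %.1f%% of voxels sampled outside the grid",
          snm, sc$label, 100 * attr(v, "out_of_field")))
      val <- dose_metric(dvh_from_doses(pmax(v, 0),
                                        total_volume_cc = structure_volume_cc(st)),
                         metric)
      rows[[length(rows) + 1]] <- data.frame(
        structure = snm, metric = metric, group = sc$group,
        scenario = sc$label, value = val, stringsAsFactors = FALSE)
    }
  }
  values <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(
    values, list(values$structure, values$group), drop = TRUE),
    function(df) {
      data.frame(structure = df$structure[1], metric = df$metric[1],
                 group = df$group[1], nominal = nominal[df$structure[1]],
                 best = max(df$value), worst = min(df$value),
                 band_width = max(df$value) - min(df$value),
                 lambda_percent = lambda_index(nominal[df$structure[1]],
                                               df$value),
                 stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$structure, summ$group), ]
  structure(list(values = values, summary = summ, nominal = nominal),
            class = "robustness_study")
}

#' @export
print.robustness_study <- function(x, ...) {
  cat("<robustness_study>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
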