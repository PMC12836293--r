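# Planned-versus-delivered comparison: global gamma analysis, DVH-metric
# deviations, delivery-log RMS mechanical errors, and the log-derived
# delivered-dose surrogate.

# Interpolate an array sampled at a constant fractional voxel shift,
# clamping to the nearest edge. Works for 2-D (bilinear) and 3-D
# (trilinear) arrays; the shift is in voxel units per axis.
shift_sample <- function(arr, shift_vox) {
  d <- dim(arr)
  nd <- length(d)
  i0 <- floor(shift_vox)
  fr <- shift_vox - i0
  idx <- function(axis, extra) pmin(pmax(seq_len(d[axis]) + i0[axis] + extra,
                                         1L), d[axis])
  out <- array(0, dim = d)
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (r in seq_len(nrow(corners))) {
    cr <- corners[r, ]
    w <- prod(ifelse(cr == 1, fr, 1 - fr))
    if (w == 0) next
    piece <- if (nd == 2) arr[idx(1, cr[1]), idx(2, cr[2])]
    else arr[idx(1, cr[1]), idx(2, cr[2]), idx(3, cr[3])]
    out <- out + w * piece
  }
  out
}

#' Global gamma-index comparison
#'
#' For every evaluated point above the low-dose threshold,
#' `gamma = min over the search neighborhood of
#' sqrt((dose difference / dose criterion)^2 + (distance / DTA)^2)`,
#' with the dose difference normalised to the global maximum of the
#' reference distribution. The search is exhaustive over a local
#' neighborhood of radius `search_factor * DTA`, linearly upsampled
#' `local_upsample`-fold, visited in order of increasing distance with
#' early termination. Gamma is asymmetric in its arguments: swap them to
#' compute the other direction.
#'
#' @param reference,evaluated co-registered dose distributions: two
#'   [dose_grid()]s, or two matrices/3-D arrays (then `spacing_mm` is
#'   required).
#' @param dose_percent dose-difference criterion (% of global reference
#'   maximum).
#' @param distance_mm distance-to-agreement criterion (mm).
#' @param spacing_mm per-axis spacing for bare-array input.
#' @param low_dose_threshold_percent evaluated points below this percent
#'   of the reference maximum are excluded.
#' @param local_upsample subsampling factor of the spatial search
#'   (search step = DTA / local_upsample).
#' @param search_factor search radius in units of DTA.
#' @return list of class `gamma_result`: `gamma` (array, NA below
#'   threshold), `pass_rate_percent` (percent of evaluated points with
#'   gamma <= 1), `n_evaluated`, `criteria`.
#' @export
gamma_index <- function(reference, evaluated, dose_percent = 3,
                        distance_mm = 3, spacing_mm = NULL,
                        low_dose_threshold_percent = 10,
                        local_upsample = 10, search_factor = 3) {
  if (inherits(reference, "dose_grid")) {
    if (!inherits(evaluated, "dose_grid") ||
        !same_geometry(reference, evaluated))
      stop("reference and evaluated grids are not co-registered")
    spacing_mm <- reference$spacing_mm
    reference <- reference$values
    evaluated <- evaluated$values
  }
  if (is.null(dim(reference)) || !identical(dim(reference), dim(evaluated)))
    stop("reference and evaluated must share one geometry")
  if (is.null(spacing_mm)) stop("spacing_mm required for array input")
  nd <- length(dim(reference))
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = nd)
  ref_max <- max(reference)
  if (ref_max <= 0) stop("reference distribution has no positive dose")
  dd <- dose_percent / 100 * ref_max
  eval_mask <- evaluated >= low_dose_threshold_percent / 100 * ref_max
  n_eval <- sum(eval_mask)
  if (n_eval == 0)
    stop("no evaluated points above the low-dose threshold")

  step <- distance_mm / local_upsample
  radius <- search_factor * distance_mm
  k <- floor(radius / step)
  offs <- as.matrix(expand.grid(rep(list((-k):k), nd))) * step
  dist2 <- rowSums(offs^2)
  keep <- dist2 <= radius^2
  offs <- offs[keep, , drop = FALSE]
  dist2 <- dist2[keep]
  ord <- order(dist2)
  offs <- offs[ord, , drop = FALSE]
  dist2 <- dist2[ord]

  ev <- evaluated[eval_mask]
  g2 <- rep(Inf, n_eval)
  for (r in seq_len(nrow(offs))) {
    dterm <- dist2[r] / distance_mm^2
    if (dterm >= max(g2)) break
    refs <- shift_sample(reference, offs[r, ] / spacing_mm)[eval_mask]
    cand <- ((refs - ev) / dd)^2 + dterm
    g2 <- pmin(g2, cand)
  }
  gamma <- array(NA_real_, dim = dim(reference))
  gamma[eval_mask] <- sqrt(g2)
  structure(
    list(gamma = gamma,
         pass_rate_percent = 100 * mean(g2 <= 1 + 1e-12),
         n_evaluated = n_eval,
         criteria = list(dose_percent = dose_percent,
                         distance_mm = distance_mm,
                         low_dose_threshold_percent = low_dose_threshold_percent)),
    class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: pass rate %.1f%% (%d points)\n",
              x$criteria$dose_percent, x$criteria$distance_mm,
              x$pass_rate_percent, x$n_evaluated))
  invisible(x)
}

#' Default structure -> metric map for planned-vs-delivered DVH deviations
#' @return named list: structure -> character vector of metric labels.
#' @export
default_delta_metric_map <- function() {
  list(ptv = c("D95%", "D98%", "D2%", "Dmean"),
       hippocampus = "D40%", hypothalamus = "D50%", pituitary = "D50%",
       cochlea = "D50%", scalp = "D50%")
}

#' DVH-metric deviations between planned and delivered dose
#'
#' `delta = delivered - planned` per structure/metric; exactly
#' antisymmetric under swapping the inputs.
#'
#' @param planned,delivered [dose_grid()]s in the same frame.
#' @param structures named list of [structure_mask()].
#' @param metric_map named list, structure -> metric labels; defaults to
#'   [default_delta_metric_map()] restricted to structures present.
#' @return data.frame: structure, metric, planned, delivered, delta_Gy.
#' @export
delta_dvh <- function(planned, delivered, structures, metric_map = NULL) {
  if (!same_geometry(planned, delivered))
    stop("planned and delivered grids are not in the same frame")
  if (is.null(metric_map)) {
    mm <- default_delta_metric_map()
    metric_map <- mm[names(mm) %in% names(structures)]
  }
  rows <- list()
  for (snm in names(metric_map)) {
    dvh_p <- compute_dvh(planned, structures[[snm]])
    dvh_d <- compute_dvh(delivered, structures[[snm]])
    for (metric in metric_map[[snm]]) {
      p <- dose_metric(dvh_p, metric)
      d <- dose_metric(dvh_d, metric)
      rows[[length(rows) + 1]] <- data.frame(
        structure = snm, metric = metric, planned = p, delivered = d,
        delta_Gy = d - p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' RMS mechanical errors from a delivery log
#'
#' Root-mean-square of actual minus planned over all leaves and control
#' points (MLC, mm) and over all control points (gantry, deg), per beam
#' and overall.
#'
#' @param plan a [beam_plan()].
#' @param log a [delivery_log()] for that plan.
#' @return list of class `log_rms_report`: `mlc_mm`, `gantry_deg`,
#'   `per_beam` (data.frame).
#' @export
log_rms <- function(plan, log) {
  if (length(log$beams) != length(plan$beams))
    stop("log beam count does not match plan")
  rms <- function(x) sqrt(mean(x^2))
  per <- list()
  mlc_all <- c(); gan_all <- c()
  for (i in seq_along(plan$beams)) {
    pb <- plan$beams[[i]]; lb <- log$beams[[i]]
    if (!identical(dim(pb$left), dim(lb$left)) ||
        length(pb$gantry_deg) != length(lb$gantry_deg))
      stop("CP count mismatch between plan and log")
    em <- c(lb$left - pb$left, lb$right - pb$right)
    eg <- lb$gantry_deg - pb$gantry_deg
    mlc_all <- c(mlc_all, em); gan_all <- c(gan_all, eg)
    per[[i]] <- data.frame(beam = pb$id, mlc_rms_mm = rms(em),
                           gantry_rms_deg = rms(eg),
                           stringsAsFactors = FALSE)
  }
  structure(list(mlc_mm = rms(mlc_all), gantry_deg = rms(gan_all),
                 per_beam = do.call(rbind, per)),
            class = "log_rms_report")
}

#' @export
print.log_rms_report <- function(x, ...) {
  cat(sprintf("<log_rms_report> MLC %.3f mm, gantry %.3f deg\n",
              x$mlc_mm, x$gantry_deg))
  invisible(x)
}

#' Delivered-dose surrogate from a delivery log
#'
#' Desk-scale stand-in for a full Monte Carlo dose reconstruction: the
#' MU-weighted mean signed leaf-gap error of each beam, relative to the
#' beam's mean planned gap, scales the planned dose as a global output
#' factor. This captures the first-order output effect of systematic MLC
#' gap errors and nothing else (no spatial redistribution); it is a
#' stated modelling limitation, not an emulation of a reconstruction
#' engine.
#'
#' @param dose planned [dose_grid()].
#' @param plan a [beam_plan()].
#' @param log a [delivery_log()].
#' @param sensitivity dimensionless scaling of the relative gap error
#'   into a relative output change.
#' @return A [dose_grid()] of the surrogate delivered dose.
#' @export
reconstruct_delivered_dose <- function(dose, plan, log, sensitivity = 1) {
  mus <- vapply(plan$beams, function(b) b$mu, 0)
  rel <- vapply(seq_along(plan$beams), function(i) {
    pb <- plan$beams[[i]]; lb <- log$beams[[i]]
    gap_p <- pb$right - pb$left
    gap_l <- lb$right - lb$left
    open <- gap_p > 1
    if (!any(open)) return(0)
    mean(gap_l[open] - gap_p[open]) / mean(gap_p[open])
  }, 0)
  scale <- 1 + sensitivity * sum(rel * mus) / sum(mus)
  dose_grid(pmax(dose$values * scale, 0), dose$spacing_mm, dose$origin_mm,
            dose$frame_id)
}
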