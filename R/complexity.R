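# MLC aperture complexity metrics for VMAT control-point sequences:
# aperture irregularity (PI), modulation complexity score (MCS), small
# aperture score (SAS10), mean field area (MFA), mean leaf gap (MLG) and
# mean leaf travel (MLT), reported per beam, per isocenter group and per
# plan. Leaf pairs with a gap at or below the closed threshold (default
# 1 mm, the practical leaf-gap minimum of 5 mm-leaf MLCs) count as closed;
# jaw clipping is applied before all gap/area computations.

# Per-CP MU weights from the cumulative meterset: each CP carries half of
# its adjacent segments. Weights sum to 1.
cp_mu_weights <- function(cum_mu_frac) {
  s <- diff(cum_mu_frac)
  (c(0, s) + c(s, 0)) / 2
}

#' Aperture geometry of one control point
#'
#' Clips leaf positions to the x jaws, marks pairs with gap at or below
#' `closed_threshold_mm` as closed, and traces each connected run of open
#' pairs: area is the sum of gap x leaf width; the perimeter accumulates
#' the left/right edge steps between adjacent open pairs, both side edges
#' of each pair, and the end caps.
#'
#' @param left,right leaf-bank positions (mm), one value per pair.
#' @param leaf_width_mm leaf width at isocenter.
#' @param jaw_x `c(lo, hi)` x-jaw positions (mm), or NULL for no clip.
#' @param closed_threshold_mm gap at or below this counts as closed.
#' @return list with `open_pairs` (indices), `gap_mm` (clipped gaps),
#'   `area_mm2`, `perimeter_mm`, and `components` (data.frame with one
#'   row per connected run: start, end, area_mm2, perimeter_mm).
#' @export
aperture_geometry <- function(left, right, leaf_width_mm = 5,
                              jaw_x = NULL, closed_threshold_mm = 1) {
  if (any(left > right + 1e-6)) stop("leaf crossing: left > right")
  if (!is.null(jaw_x)) {
    left <- pmax(left, jaw_x[1])
    right <- pmin(right, jaw_x[2])
  }
  gap <- pmax(right - left, 0)
  open <- gap > closed_threshold_mm
  comps <- list()
  if (any(open)) {
    r <- rle(open)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i <- starts[k]:ends[k]
      area <- sum(gap[i]) * leaf_width_mm
      steps <- if (length(i) > 1)
        sum(abs(diff(left[i]))) + sum(abs(diff(right[i]))) else 0
      perim <- 2 * leaf_width_mm * length(i) + steps +
        gap[i[1]] + gap[i[length(i)]]
      comps[[length(comps) + 1]] <-
        data.frame(start = i[1], end = i[length(i)],
                   area_mm2 = area, perimeter_mm = perim)
    }
  }
  components <- if (length(comps)) do.call(rbind, comps) else
    data.frame(start = integer(0), end = integer(0),
               area_mm2 = numeric(0), perimeter_mm = numeric(0))
  list(open_pairs = which(open), gap_mm = gap,
       area_mm2 = sum(components$area_mm2),
       perimeter_mm = sum(components$perimeter_mm),
       components = components)
}

# Aperture irregularity of one CP: perimeter^2 / (4 pi area) per connected
# component, area-weighted. 1 for a circle, 4/pi for a square.
cp_irregularity <- function(geom) {
  cc <- geom$components
  if (!nrow(cc)) return(NA_real_)
  ai <- cc$perimeter_mm^2 / (4 * pi * cc$area_mm2)
  sum(ai * cc$area_mm2) / sum(cc$area_mm2)
}

beam_cp_geoms <- function(beam, closed_threshold_mm) {
  lapply(seq_len(nrow(beam$left)), function(j)
    aperture_geometry(beam$left[j, ], beam$right[j, ], beam$leaf_width_mm,
                      beam$jaw_x, closed_threshold_mm))
}

#' Beam aperture irregularity
#'
#' Per control point the aperture irregularity `AI = perimeter^2 /
#' (4 pi area)` (area-weighted over disjoint components); the beam value
#' is the MU-weighted mean over control points. The plan-averaged value
#' (PI) is the MU-weighted mean over beams.
#'
#' @param beam one element of `plan$beams`.
#' @param closed_threshold_mm closed-leaf gap threshold (mm).
#' @return beam irregularity (dimensionless, >= 1 for rasterised
#'   single-component apertures).
#' @export
beam_irregularity <- function(beam, closed_threshold_mm = 1) {
  geoms <- beam_cp_geoms(beam, closed_threshold_mm)
  ai <- vapply(geoms, cp_irregularity, 0)
  w <- cp_mu_weights(beam$cum_mu_frac)
  ok <- !is.na(ai)
  if (!any(ok)) stop(sprintf("beam %s: no open aperture at any CP", beam$id))
  sum(ai[ok] * w[ok]) / sum(w[ok])
}

# Leaf sequence variability of one bank over the open pairs of a CP.
lsv_bank <- function(pos) {
  n <- length(pos)
  if (n <= 1) return(1)
  pos_max <- max(pos) - min(pos)
  if (pos_max <= 0) return(1)
  sum(pos_max - abs(diff(pos))) / ((n - 1) * pos_max)
}

#' Modulation complexity score of a beam
#'
#' Per control point: leaf sequence variability (LSV) per bank over the
#' open pairs, combined multiplicatively, and aperture area variability
#' (AAV) = aperture area over the area of the beam's per-pair maximal
#' openings. The beam MCS sums `mean(AAV) * mean(LSV) * segment-MU
#' fraction` over adjacent control-point pairs. 1 for a static field
#' fully open to its own maximum; lower values mean more modulation.
#'
#' @inheritParams beam_irregularity
#' @return MCS in (0, 1].
#' @export
mcs <- function(beam, closed_threshold_mm = 1) {
  n_cp <- nrow(beam$left)
  geoms <- beam_cp_geoms(beam, closed_threshold_mm)
  gaps <- do.call(rbind, lapply(geoms, function(g) {
    gg <- g$gap_mm
    gg[setdiff(seq_along(gg), g$open_pairs)] <- 0
    gg
  }))
  max_gap <- apply(gaps, 2, max)
  denom <- sum(max_gap)
  aav <- if (denom > 0) rowSums(gaps) / denom else rep(1, n_cp)
  lsv <- vapply(seq_len(n_cp), function(j) {
    op <- geoms[[j]]$open_pairs
    if (!length(op)) return(1)
    lsv_bank(beam$left[j, op]) * lsv_bank(beam$right[j, op])
  }, 0)
  seg <- diff(beam$cum_mu_frac)
  sum(((aav[-n_cp] + aav[-1]) / 2) * ((lsv[-n_cp] + lsv[-1]) / 2) * seg)
}

#' Small aperture score
#'
#' MU-weighted fraction of open leaf pairs whose gap is below
#' `threshold_mm` (default 10 mm, the SAS10 of the complexity
#' literature).
#'
#' @inheritParams beam_irregularity
#' @param threshold_mm small-aperture gap threshold (mm).
#' @return fraction in \[0, 1\].
#' @export
small_aperture_score <- function(beam, threshold_mm = 10,
                                 closed_threshold_mm = 1) {
  geoms <- beam_cp_geoms(beam, closed_threshold_mm)
  frac <- vapply(geoms, function(g) {
    if (!length(g$open_pairs)) return(NA_real_)
    mean(g$gap_mm[g$open_pairs] < threshold_mm)
  }, 0)
  w <- cp_mu_weights(beam$cum_mu_frac)
  ok <- !is.na(frac)
  if (!any(ok)) return(0)
  sum(frac[ok] * w[ok]) / sum(w[ok])
}

beam_metrics_row <- function(beam, closed_threshold_mm, sas_threshold_mm) {
  geoms <- beam_cp_geoms(beam, closed_threshold_mm)
  w <- cp_mu_weights(beam$cum_mu_frac)
  area <- vapply(geoms, function(g) g$area_mm2, 0)
  mlg <- vapply(geoms, function(g) {
    if (!length(g$open_pairs)) return(NA_real_)
    mean(g$gap_mm[g$open_pairs])
  }, 0)
  ok <- !is.na(mlg)
  travel <- sum(abs(diff(beam$left))) + sum(abs(diff(beam$right)))
  n_leaves <- 2 * ncol(beam$left)
  data.frame(
    scope = "beam", id = beam$id, isocenter = beam$isocenter,
    MU = beam$mu, CPs = nrow(beam$left),
    PI = beam_irregularity(beam, closed_threshold_mm),
    MCS = mcs(beam, closed_threshold_mm),
    SAS10 = small_aperture_score(beam, sas_threshold_mm, closed_threshold_mm),
    MFA_cm2 = sum(area * w) / 100,
    MLG_cm = sum(mlg[ok] * w[ok]) / sum(w[ok]) / 10,
    MLT_cm = travel / n_leaves / 10,
    stringsAsFactors = FALSE)
}

#' Plan complexity report
#'
#' Computes MU, control-point count, PI, MCS, SAS10, MFA, MLG and MLT per
#' beam, then aggregates per isocenter group and for the whole plan
#' (MU-weighted for the MU-normalised metrics; MU and CPs summed).
#'
#' @param plan a [beam_plan()].
#' @param closed_threshold_mm closed-leaf gap threshold (mm).
#' @param sas_threshold_mm small-aperture threshold (mm).
#' @return data.frame of class `complexity_report`: one row per beam,
#'   per isocenter group and for the plan.
#' @export
aggregate_metrics <- function(plan, closed_threshold_mm = 1,
                              sas_threshold_mm = 10) {
  rows <- do.call(rbind, lapply(plan$beams, beam_metrics_row,
                                closed_threshold_mm = closed_threshold_mm,
                                sas_threshold_mm = sas_threshold_mm))
  roll <- function(df, scope, id) {
    w <- df$MU / sum(df$MU)
    data.frame(scope = scope, id = id, isocenter = id,
               MU = sum(df$MU), CPs = sum(df$CPs),
               PI = sum(df$PI * w), MCS = sum(df$MCS * w),
               SAS10 = sum(df$SAS10 * w), MFA_cm2 = sum(df$MFA_cm2 * w),
               MLG_cm = sum(df$MLG_cm * w), MLT_cm = sum(df$MLT_cm * w),
               stringsAsFactors = FALSE)
  }
  isos <- lapply(split(rows, rows$isocenter), function(df)
    roll(df, "isocenter", df$isocenter[1]))
  out <- rbind(rows, do.call(rbind, isos), roll(rows, "plan", "plan"))
  rownames(out) <- NULL
  class(out) <- c("complexity_report", "data.frame")
  out
}
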