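# VMAT plan model: ordered control points with MU weights and MLC/jaw
# geometry, plus the seeded plan/delivery-log generators used to exercise
# the complexity and QA layers at controllable modulation.

#' Beam plan
#'
#' @param beams list of beams; each beam is a list with `id`, `isocenter`
#'   (label, e.g. `"iso1"`), `mu` (total beam MU), `gantry_deg` (per-CP),
#'   `collimator_deg`, `leaf_width_mm`, `left`/`right` (n_cp x n_pairs
#'   matrices of leaf-bank positions in mm at isocenter; `left <= right`
#'   per pair), `jaw_x` (c(lo, hi), mm), `cum_mu_frac` (per-CP cumulative
#'   meterset fraction, 0 to 1).
#' @param max_leaf_travel_mm maximum allowed per-CP leaf travel (mm).
#' @return validated object of class `beam_plan`.
#' @export
beam_plan <- function(beams, max_leaf_travel_mm = 10) {
  for (b in beams) {
    n_cp <- nrow(b$left)
    if (n_cp < 2) stop(sprintf("beam %s: dynamic beams need >= 2 CPs", b$id))
    if (!identical(dim(b$left), dim(b$right)))
      stop("left/right bank shapes differ")
    if (any(b$left > b$right + 1e-6))
      stop(sprintf("beam %s: leaf crossing (left > right)", b$id))
    if (b$mu <= 0) stop("beam MU must be positive")
    cmf <- b$cum_mu_frac
    if (length(cmf) != n_cp || abs(cmf[1]) > 1e-9 ||
        abs(cmf[n_cp] - 1) > 1e-9 || any(diff(cmf) < -1e-12))
      stop(sprintf("beam %s: cum_mu_frac must rise monotonically 0 -> 1", b$id))
    trav <- max(abs(diff(b$left)), abs(diff(b$right)))
    if (trav > max_leaf_travel_mm + 1e-6)
      stop(sprintf("beam %s: per-CP leaf travel %.2f mm exceeds limit %g mm",
                   b$id, trav, max_leaf_travel_mm))
  }
  structure(list(beams = beams, max_leaf_travel_mm = max_leaf_travel_mm),
            class = "beam_plan")
}

#' @export
print.beam_plan <- function(x, ...) {
  cat(sprintf("<beam_plan> %d beams, %d CPs, %.0f MU\n",
              length(x$beams),
              sum(vapply(x$beams, function(b) nrow(b$left), 0)),
              sum(vapply(x$beams, function(b) b$mu, 0))))
  invisible(x)
}

# Reflected uniform random walk in [lo, hi], n steps, step half-width h.
reflected_walk <- function(n, lo, hi, h, start) {
  out <- numeric(n)
  out[1] <- start
  for (j in seq_len(n - 1)) {
    v <- out[j] + stats::runif(1, -h, h)
    if (v > hi) v <- 2 * hi - v
    if (v < lo) v <- 2 * lo - v
    out[j + 1] <- min(max(v, lo), hi)
  }
  out
}

#' Generate a synthetic VMAT plan
#'
#' Builds an arc per beam whose aperture sequence interpolates between a
#' static rectangular field (`modulation_level = 0`) and a heavily
#' modulated sequence (`modulation_level = 1`). Per active leaf pair the
#' gap shrinks as `base_gap * (1 - level * beta)` and the aperture centre
#' wanders as `level * 15 mm * gamma`, with `beta`/`gamma` smooth random
#' walks across control points drawn once from the seed, so plans at
#' different modulation levels under the same seed differ only by the
#' level scaling. Beam MU grows with modulation as `base_mu * (1 + level)`.
#'
#' @param n_beams number of beams.
#' @param n_cp_per_beam control points per beam (>= 2).
#' @param modulation_level modulation in \[0, 1\].
#' @param seed integer seed.
#' @param n_pairs total MLC leaf pairs.
#' @param active_pairs centrally open pairs (the rest stay closed).
#' @param leaf_width_mm leaf width at isocenter.
#' @param base_gap_mm unmodulated leaf gap.
#' @param base_mu unmodulated beam MU.
#' @param isocenter_labels per-beam isocenter labels; default `"iso1"` for
#'   the first beam and `"iso2"` for the rest (cranial / spinal split).
#' @return A [beam_plan()].
#' @export
generate_plan <- function(n_beams = 2, n_cp_per_beam = 60,
                          modulation_level = 0.5, seed = 1L,
                          n_pairs = 40, active_pairs = 20,
                          leaf_width_mm = 5, base_gap_mm = 40,
                          base_mu = 300, isocenter_labels = NULL) {
  if (modulation_level < 0 || modulation_level > 1)
    stop("modulation_level must be in [0, 1]")
  if (active_pairs > n_pairs) stop("active_pairs must be <= n_pairs")
  if (is.null(isocenter_labels))
    isocenter_labels <- c("iso1", rep("iso2", max(0, n_beams - 1)))
  m <- modulation_level
  act <- seq.int((n_pairs - active_pairs) %/% 2 + 1,
                 (n_pairs - active_pairs) %/% 2 + active_pairs)
  beams <- local_rng(seed, function() {
    lapply(seq_len(n_beams), function(bi) {
      n_cp <- n_cp_per_beam
      beta <- sapply(seq_along(act), function(i)
        reflected_walk(n_cp, 0, 0.95, 0.15, stats::runif(1, 0, 0.95)))
      gam <- sapply(seq_along(act), function(i)
        reflected_walk(n_cp, -1, 1, 0.2, stats::runif(1, -1, 1)))
      gap <- base_gap_mm * (1 - m * beta)          # n_cp x active
      ctr <- m * 15 * gam
      left <- matrix(0, n_cp, n_pairs)
      right <- matrix(0, n_cp, n_pairs)
      left[, act] <- ctr - gap / 2
      right[, act] <- ctr + gap / 2
      seg <- stats::runif(n_cp - 1, 0.5, 1.5)
      gantry0 <- stats::runif(1, 0, 360)
      list(id = sprintf("beam%02d", bi),
           isocenter = isocenter_labels[bi],
           mu = base_mu * (1 + m),
           gantry_deg = (gantry0 + seq(0, 358, length.out = n_cp)) %% 360,
           collimator_deg = 0,
           leaf_width_mm = leaf_width_mm,
           left = left, right = right,
           jaw_x = c(-100, 100),
           cum_mu_frac = c(0, cumsum(seg) / sum(seg)))
    })
  })
  beam_plan(beams)
}

#' Delivery log
#'
#' Per-control-point actual leaf and gantry values for a plan.
#'
#' @param plan the planned [beam_plan()].
#' @param beams list mirroring `plan$beams`, each with `left`, `right`
#'   (matrices) and `gantry_deg` of actual values.
#' @return object of class `delivery_log`.
#' @export
delivery_log <- function(plan, beams) {
  if (length(beams) != length(plan$beams))
    stop("log beam count does not match plan")
  for (i in seq_along(beams)) {
    if (!identical(dim(beams[[i]]$left), dim(plan$beams[[i]]$left)))
      stop("log CP/leaf shape does not match plan")
  }
  structure(list(beams = beams), class = "delivery_log")
}

#' Generate a synthetic delivery log
#'
#' Actual values are planned values plus independent zero-mean Gaussian
#' noise per leaf position and per gantry angle; with zero standard
#' deviations the log equals the plan exactly.
#'
#' @param plan a [beam_plan()].
#' @param mlc_sd_mm leaf-position error SD (mm).
#' @param gantry_sd_deg gantry-angle error SD (deg).
#' @param seed integer seed.
#' @return A [delivery_log()].
#' @export
generate_log <- function(plan, mlc_sd_mm = 0.5, gantry_sd_deg = 0.3,
                         seed = 1L) {
  if (mlc_sd_mm < 0 || gantry_sd_deg < 0) stop("error SDs must be >= 0")
  beams <- local_rng(seed, function() {
    lapply(plan$beams, function(b) {
      list(id = b$id,
           left = b$left + stats::rnorm(length(b$left), 0, mlc_sd_mm),
           right = b$right + stats::rnorm(length(b$right), 0, mlc_sd_mm),
           gantry_deg = b$gantry_deg +
             stats::rnorm(length(b$gantry_deg), 0, gantry_sd_deg))
    })
  })
  delivery_log(plan, beams)
}
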