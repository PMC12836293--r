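test_that("canonical scenario set has the 18 + 12 magnitude-group structure", {
  sc <- canonical_scenarios()
  expect_length(sc, 30)
  groups <- vapply(sc, function(s) s$group, "")
  expect_equal(sum(groups == "±2 mm"), 6)
  expect_equal(sum(groups == "±3 mm"), 6)
  expect_equal(sum(groups == "±5 mm"), 6)
  expect_equal(sum(groups == "±1°"), 6)
  expect_equal(sum(groups == "±2°"), 6)
  for (s in sc) {
    has_t <- any(s$translation_mm != 0)
    has_r <- any(s$rotation_deg != 0)
    expect_true(xor(has_t, has_r))
  }
})

test_that("lambda index matches its definition and is order-invariant", {
  expect_equal(lambda_index(23.4, c(23.4, 23.4, 23.4)), 0)
  expect_equal(lambda_index(23.4, c(24.0, 22.0, 23.1)),
               (24 - 22) / 23.4 * 100)
  set.seed(5)
  v <- stats::runif(12, 10, 20)
  expect_equal(lambda_index(15, v), lambda_index(15, sample(v)))
  expect_error(lambda_index(0, v))
})

test_that("zero perturbation reproduces the dose field exactly", {
  fx <- ramp_fixture()
  zero <- perturbation_scenario()
  out <- perturb_dose(fx$dose, zero, isocenter_mm = c(20, 20, 4))
  expect_equal(out$values, fx$dose$values, tolerance = 1e-12)

  # translating a uniform field changes nothing (edge values clamp)
  uni <- uniform_grid(10)
  sh <- perturb_dose(uni, perturbation_scenario(translation_mm = c(3, 0, 0)),
                     isocenter_mm = c(7, 7, 7))
  expect_equal(sh$values, uni$values, tolerance = 1e-12)
})

test_that("opposite translations round-trip a smooth field", {
  n <- 25
  ax <- (seq_len(n) - 1) * 2.5   # 2.5 mm grid so a 2 mm shift is fractional
  ctr <- mean(ax)
  g <- exp(-outer(outer((ax - ctr)^2, (ax - ctr)^2, "+"),
                  (ax - ctr)^2, "+") / 1800)
  dose <- dose_grid(20 * g, c(2.5, 2.5, 2.5))
  iso <- rep(ctr, 3)
  p1 <- perturb_dose(dose, perturbation_scenario(translation_mm = c(2, 0, 0)),
                     isocenter_mm = iso)
  p2 <- perturb_dose(p1, perturbation_scenario(translation_mm = c(-2, 0, 0)),
                     isocenter_mm = iso)
  expect_gt(max(abs(p1$values - dose$values)), 0)  # the shift did something
  # compare away from the grid boundary, where the nearest-edge extension
  # (not interpolation) dominates
  inner <- 3:(n - 2)
  expect_lt(max(abs(p2$values[inner, inner, inner] -
                      dose$values[inner, inner, inner])),
            0.02 * max(dose$values))
})

test_that("trilinear sampling matches an independent loop interpolator", {
  # independent oracle: direct per-point 8-corner interpolation
  loop_trilinear <- function(vals, sp, org, p) {
    f <- (p - org) / sp
    i <- pmin(pmax(floor(f), 0), dim(vals) - 2)
    t <- f - i
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, t, 1 - t))
      v <- v + w * vals[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1]
    }
    v
  }
  set.seed(8)
  vals <- array(stats::runif(6 * 7 * 8, 0, 10), dim = c(6, 7, 8))
  dose <- dose_grid(vals, c(2, 3, 4), origin_mm = c(1, -2, 5))
  pts <- cbind(stats::runif(50, 1, 11), stats::runif(50, -2, 16),
               stats::runif(50, 5, 33))
  mine <- sample_dose(dose, pts)
  oracle <- vapply(seq_len(nrow(pts)), function(r)
    loop_trilinear(vals, c(2, 3, 4), c(1, -2, 5), pts[r, ]), 0)
  expect_equal(as.numeric(mine), oracle, tolerance = 1e-12)

  # trilinear interpolation is exact on trilinear polynomials
  ax <- list(1 + (0:5) * 2, -2 + (0:6) * 3, 5 + (0:7) * 4)
  poly <- function(x, y, z) 2 + 0.3 * x - 0.2 * y + 0.1 * z +
    0.05 * x * y - 0.02 * y * z + 0.01 * x * z + 0.005 * x * y * z
  pv <- array(0, dim = c(6, 7, 8))
  for (i in 1:6) for (j in 1:7) for (k in 1:8)
    pv[i, j, k] <- poly(ax[[1]][i], ax[[2]][j], ax[[3]][k])
  pdose <- dose_grid(pv - min(pv), c(2, 3, 4), origin_mm = c(1, -2, 5))
  got <- sample_dose(pdose, pts)
  want <- poly(pts[, 1], pts[, 2], pts[, 3]) - min(pv)
  expect_equal(as.numeric(got), want, tolerance = 1e-9)
})

test_that("rotation convention: a roll about the SI axis moves lateral points", {
  # point 10 mm lateral of the isocenter, rolled 90 deg, lands on the AP axis
  sc <- perturbation_scenario(rotation_deg = c(0, 0, 2))
  R <- csieval:::scenario_rotation(c(0, 0, 90))
  p <- as.numeric(R %*% c(10, 0, 0))
  expect_equal(p, c(0, 10, 0), tolerance = 1e-9)
  # small rotations leave the isocenter fixed
  iso <- c(5, 5, 5)
  moved <- csieval:::perturbed_coords(rbind(iso), sc, iso)
  expect_equal(as.numeric(moved), iso, tolerance = 1e-12)
})

test_that("study fast path equals full-grid perturbation metrics", {
  ph <- coarse_phantom(seed = 21)
  d <- generate_dose(ph, dose_recipe(mode = "functional_sparing"), seed = 21)
  iso <- ph$geometry$head_centre_mm
  sc <- perturbation_scenario(translation_mm = c(0, 3, 0), group = "±3 mm")
  full <- perturb_dose(d, sc, iso)
  d40_full <- dose_metric(compute_dvh(full, ph$structures$hippocampus), "D40%")
  st <- robustness_study(d, ph$structures,
                         metric_map = c(hippocampus = "D40%"),
                         scenarios = list(sc), isocenter_mm = iso)
  expect_equal(st$values$value, d40_full, tolerance = 1e-9)
})

test_that("all-zero scenarios give lambda = 0 and bands of zero width", {
  ph <- coarse_phantom(seed = 22)
  d <- generate_dose(ph, dose_recipe(mode = "standard"), seed = 22)
  zeros <- lapply(1:6, function(i)
    perturbation_scenario(label = paste0("z", i), group = "null"))
  st <- robustness_study(d, ph$structures,
                         metric_map = c(ptv = "D95%", hippocampus = "D40%"),
                         scenarios = zeros,
                         isocenter_mm = ph$geometry$head_centre_mm)
  expect_true(all(st$summary$lambda_percent == 0))
  expect_true(all(st$summary$band_width == 0))
  # nominal lies inside [worst, best] by construction
  expect_true(all(st$summary$worst <= st$summary$nominal + 1e-9 &
                    st$summary$nominal <= st$summary$best + 1e-9))
})

test_that("steep sparing gradients cost robustness at the hippocampus", {
  ph <- coarse_phantom(seed = 23)
  iso <- ph$geometry$head_centre_mm
  d_fp <- generate_dose(ph, dose_recipe(mode = "functional_sparing"), seed = 23)
  d_s <- generate_dose(ph, dose_recipe(mode = "standard"), seed = 23)
  st_fp <- robustness_study(d_fp, ph$structures,
                            metric_map = c(hippocampus = "D40%"),
                            isocenter_mm = iso)
  st_s <- robustness_study(d_s, ph$structures,
                           metric_map = c(hippocampus = "D40%"),
                           isocenter_mm = iso)
  m_fp <- st_fp$summary[order(st_fp$summary$group), ]
  m_s <- st_s$summary[order(st_s$summary$group), ]
  expect_true(all(m_fp$lambda_percent > m_s$lambda_percent))
  # lambda grows with translation magnitude for the steep plan
  lam <- function(st, g) st$summary$lambda_percent[st$summary$group == g]
  expect_lt(lam(st_fp, "±2 mm"), lam(st_fp, "±3 mm"))
  expect_lt(lam(st_fp, "±3 mm"), lam(st_fp, "±5 mm"))
})
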