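test_that("phantom generation is deterministic and anatomically sane", {
  ph1 <- coarse_phantom(seed = 11)
  ph2 <- coarse_phantom(seed = 11)
  for (nm in names(ph1$structures))
    expect_identical(ph1$structures[[nm]]$mask, ph2$structures[[nm]]$mask)

  # interior functional structures sit inside the cranial PTV
  cran <- ph1$structures$ptv_cranial$mask
  for (nm in c("hippocampus", "hypothalamus", "pituitary", "cochlea"))
    expect_true(all(cran[ph1$structures[[nm]]$mask]), label = nm)
  # scalp shell is disjoint from the cranial PTV
  expect_false(any(ph1$structures$scalp$mask & cran))
  # vertebrae abut the spinal PTV posteriorly but do not overlap it
  expect_false(any(ph1$structures$vertebrae$mask & ph1$structures$ptv_spinal$mask))
  expect_gt(sum(ph1$structures$vertebrae$mask), 0)
})

test_that("hippocampus volume lands in the pediatric range on the default grid", {
  ph <- generate_phantom(phantom_spec())
  v <- structure_volume_cc(ph$structures$hippocampus)
  expect_gt(v, 1)
  expect_lt(v, 6)
})

test_that("mask volumes are stable when the grid is coarsened", {
  fine <- generate_phantom(phantom_spec(grid_shape = c(100, 100, 250),
                                        spacing_mm = c(2, 2, 2), seed = 5))
  coarse <- generate_phantom(phantom_spec(grid_shape = c(50, 50, 125),
                                          spacing_mm = c(4, 4, 4), seed = 5))
  for (nm in names(fine$structures)) {
    vf <- structure_volume_cc(fine$structures[[nm]])
    vc <- structure_volume_cc(coarse$structures[[nm]])
    expect_lt(abs(vc - vf) / vf, 0.15, label = nm)
  }
})

test_that("a structure that voxelises to nothing raises a named error", {
  sp <- coarse_spec(structure_params = list(
    pituitary = list(lat_mm = 0, post_mm = 2, dz_mm = -18,
                     semi_mm = c(0.1, 0.1, 0.1)),
    jitter_sd_mm = 0))
  expect_error(generate_phantom(sp), "pituitary")
})

test_that("standard-mode dose puts target and interior organs at prescription", {
  ph <- coarse_phantom(seed = 2)
  d <- generate_dose(ph, dose_recipe(mode = "standard"), seed = 2)
  rx <- 23.4
  expect_true(all(is.finite(d$values)) && all(d$values >= 0))
  expect_lt(abs(mean(structure_doses(d, ph$structures$ptv)) - rx) / rx, 0.02)
  for (nm in c("hippocampus", "hypothalamus", "pituitary", "cochlea"))
    expect_lt(abs(mean(structure_doses(d, ph$structures[[nm]])) - rx) / rx,
              0.05, label = nm)
})

test_that("noise-free standard dose is exactly constant inside the PTV", {
  ph <- coarse_phantom(seed = 3)
  d <- generate_dose(ph, dose_recipe(mode = "standard", noise_sd_Gy = 0),
                     seed = 3)
  v <- structure_doses(d, ph$structures$ptv)
  expect_equal(max(v), min(v))
  expect_equal(max(v), 23.4)
})

test_that("functional-sparing dose hits avoidance targets with coverage kept", {
  for (s in c(4, 9)) {
    ph <- coarse_phantom(seed = s)
    rec <- dose_recipe(mode = "functional_sparing")
    d <- generate_dose(ph, rec, seed = s)
    for (nm in names(rec$avoidance_targets)) {
      got <- mean(structure_doses(d, ph$structures[[nm]]))
      expect_lt(abs(got - rec$avoidance_targets[[nm]]) /
                  rec$avoidance_targets[[nm]], 0.10, label = nm)
    }
    d95 <- unname(stats::quantile(structure_doses(d, ph$structures$ptv), 0.05))
    expect_gte(d95, 0.95 * rec$prescription_Gy)
  }
})

test_that("imposed vertebral gradient is recovered in D2%-D98%", {
  ph <- coarse_phantom(seed = 6)
  d <- generate_dose(ph, dose_recipe(mode = "functional_sparing",
                                     noise_sd_Gy = 0), seed = 6)
  g <- dose_metric(compute_dvh(d, ph$structures$vertebrae), "gradient")
  expect_lt(abs(g - 4.7), 0.2)
  ds <- generate_dose(ph, dose_recipe(mode = "standard", noise_sd_Gy = 0),
                      seed = 6)
  gs <- dose_metric(compute_dvh(ds, ph$structures$vertebrae), "gradient")
  expect_lt(abs(gs - 8.7), 0.2)
})

test_that("dose generation is seed-deterministic and recipe validation bites", {
  ph <- coarse_phantom(seed = 7)
  rec <- dose_recipe(mode = "functional_sparing")
  expect_identical(generate_dose(ph, rec, seed = 42)$values,
                   generate_dose(ph, rec, seed = 42)$values)
  expect_error(dose_recipe(prescription_Gy = -1))
  expect_error(dose_recipe(avoidance_targets = c(hippocampus = 30)),
               "below the prescription")
  expect_error(generate_dose(ph, dose_recipe(
    mode = "functional_sparing", avoidance_targets = c(ptv = 12))),
    "identical to the PTV")
})

test_that("plan generator spans static to modulated apertures", {
  p0 <- generate_plan(modulation_level = 0, seed = 8)
  r0 <- aggregate_metrics(p0)
  plan_row <- r0[r0$scope == "plan", ]
  expect_equal(plan_row$MLT_cm, 0)
  expect_equal(plan_row$MCS, 1)
  # same seed reproduces the plan exactly
  p0b <- generate_plan(modulation_level = 0, seed = 8)
  expect_identical(p0$beams[[1]]$left, p0b$beams[[1]]$left)
  # SAS10 strictly larger at full modulation than at low modulation
  s_hi <- aggregate_metrics(generate_plan(modulation_level = 1, seed = 8))
  s_lo <- aggregate_metrics(generate_plan(modulation_level = 0.2, seed = 8))
  expect_gt(s_hi$SAS10[s_hi$scope == "plan"],
            s_lo$SAS10[s_lo$scope == "plan"])
  # bank ordering and MU bookkeeping hold by construction
  for (b in generate_plan(modulation_level = 1, seed = 13)$beams) {
    expect_true(all(b$left <= b$right + 1e-9))
    expect_gt(b$mu, 0)
  }
})

test_that("delivery log equals the plan at zero error and matches injected noise", {
  plan <- generate_plan(n_beams = 3, n_cp_per_beam = 200,
                        modulation_level = 0.5, seed = 10)
  log0 <- generate_log(plan, mlc_sd_mm = 0, gantry_sd_deg = 0, seed = 1)
  r0 <- log_rms(plan, log0)
  expect_equal(r0$mlc_mm, 0)
  expect_equal(r0$gantry_deg, 0)

  logn <- generate_log(plan, mlc_sd_mm = 0.5, gantry_sd_deg = 0.3, seed = 2)
  rn <- log_rms(plan, logn)
  expect_lt(abs(rn$mlc_mm - 0.5) / 0.5, 0.10)
  expect_lt(abs(rn$gantry_deg - 0.3) / 0.3, 0.10)
})
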