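test_that("aperture geometry reproduces analytic rectangles and empty fields", {
  g <- aperture_geometry(rep(-20, 10), rep(20, 10), leaf_width_mm = 5)
  expect_equal(g$area_mm2, 2000)
  expect_equal(g$perimeter_mm, 2 * (50 + 40))
  expect_equal(nrow(g$components), 1)

  closed <- aperture_geometry(rep(0, 10), rep(0, 10), leaf_width_mm = 5)
  expect_equal(closed$area_mm2, 0)
  expect_equal(nrow(closed$components), 0)

  expect_error(aperture_geometry(c(5, 0), c(0, 5)), "crossing")
})

test_that("staircase perimeter matches the rasterised tracing oracle", {
  set.seed(41)
  for (k in 1:5) {
    n <- 12
    left <- -sample(5:30, n, replace = TRUE)
    right <- sample(5:30, n, replace = TRUE)
    g <- aperture_geometry(left, right, leaf_width_mm = 5,
                           closed_threshold_mm = 1)
    expect_equal(g$perimeter_mm, raster_perimeter(left, right, 5),
                 label = paste("staircase", k))
  }
})

test_that("jaw clipping and disjoint components are handled", {
  # two open runs separated by a closed pair
  left <- c(-20, -20, 0, -10, -10)
  right <- c(20, 20, 0, 10, 10)
  g <- aperture_geometry(left, right, leaf_width_mm = 5)
  expect_equal(nrow(g$components), 2)
  expect_equal(g$area_mm2, 2 * 40 * 5 + 2 * 20 * 5)
  gj <- aperture_geometry(left, right, leaf_width_mm = 5, jaw_x = c(-5, 5))
  expect_equal(gj$area_mm2, 4 * 10 * 5)
})

test_that("aperture irregularity hits the analytic square and circle limits", {
  # 40 mm square from 8 pairs of 5 mm leaves
  beam <- static_beam(gap_mm = 40, n_pairs = 8, leaf_width_mm = 5)
  expect_equal(beam_irregularity(beam), 4 / pi, tolerance = 1e-12)

  # rasterised circle at 1 mm leaves: the staircase (MLC-edge) perimeter
  # converges to the Manhattan length 8r, so AI approaches 16/pi^2, the
  # staircase isoperimetric limit for a disc
  r <- 30
  yc <- (seq_len(60) - 0.5) - r
  half <- sqrt(pmax(r^2 - yc^2, 0))
  circ <- static_beam(n_pairs = 60, leaf_width_mm = 1)
  circ$left <- matrix(rep(-half, each = 2), 2, 60)
  circ$right <- matrix(rep(half, each = 2), 2, 60)
  ai <- beam_irregularity(circ)
  expect_gte(ai, 1)
  expect_lt(abs(ai - 16 / pi^2) / (16 / pi^2), 0.05)

  # isoperimetric inequality on random single-run apertures
  set.seed(42)
  for (k in 1:10) {
    n <- 15
    b <- static_beam(n_pairs = n, leaf_width_mm = 5)
    l <- -stats::runif(n, 2, 40); rr <- stats::runif(n, 2, 40)
    b$left <- matrix(rep(l, each = 2), 2, n)
    b$right <- matrix(rep(rr, each = 2), 2, n)
    expect_gte(beam_irregularity(b), 1 - 0.01)
  }
})

test_that("MCS is 1 for a static open field and falls with modulation", {
  expect_equal(mcs(static_beam()), 1)
  hi <- generate_plan(modulation_level = 0.9, seed = 44)
  lo <- generate_plan(modulation_level = 0.1, seed = 44)
  expect_lt(mcs(hi$beams[[1]]), mcs(lo$beams[[1]]))
  for (m in c(mcs(hi$beams[[1]]), mcs(lo$beams[[1]]))) {
    expect_gt(m, 0); expect_lte(m, 1)
  }
})

test_that("small aperture score counts MU-weighted sub-threshold gaps", {
  all5 <- static_beam(gap_mm = 5)
  expect_equal(small_aperture_score(all5), 1)
  all20 <- static_beam(gap_mm = 20)
  expect_equal(small_aperture_score(all20), 0)
  # half the MU at 5 mm gaps, half at 20 mm
  mix <- static_beam(n_cp = 2)
  mix$left <- rbind(rep(-2.5, 10), rep(-10, 10))
  mix$right <- rbind(rep(2.5, 10), rep(10, 10))
  expect_equal(small_aperture_score(mix), 0.5)
})

test_that("aggregate metrics recover the static-field values and scale in MU", {
  plan <- beam_plan(list(static_beam(gap_mm = 30)))
  rep1 <- aggregate_metrics(plan)
  row <- rep1[rep1$scope == "plan", ]
  expect_equal(row$MLG_cm, 3)
  expect_equal(row$MFA_cm2, 15)
  expect_equal(row$MLT_cm, 0)
  expect_equal(row$MCS, 1)

  # merging two identical beams doubles MU, leaves normalised metrics put
  b2 <- static_beam(gap_mm = 30, id = "beam02")
  rep2 <- aggregate_metrics(beam_plan(list(static_beam(gap_mm = 30), b2)))
  row2 <- rep2[rep2$scope == "plan", ]
  expect_equal(row2$MU, 2 * row$MU)
  for (m in c("PI", "MCS", "SAS10", "MFA_cm2", "MLG_cm", "MLT_cm"))
    expect_equal(row2[[m]], row[[m]], label = m)

  # MU rescaling leaves every MU-normalised metric unchanged
  b10 <- static_beam(gap_mm = 30); b10$mu <- b10$mu * 10
  rep10 <- aggregate_metrics(beam_plan(list(b10)))
  row10 <- rep10[rep10$scope == "plan", ]
  for (m in c("PI", "MCS", "SAS10", "MFA_cm2", "MLG_cm", "MLT_cm"))
    expect_equal(row10[[m]], row[[m]], label = m)
})

test_that("isocenter grouping mirrors the cranial/spinal split", {
  plan <- generate_plan(n_beams = 3, modulation_level = 0.5, seed = 45)
  rep <- aggregate_metrics(plan)
  expect_setequal(rep$id[rep$scope == "isocenter"], c("iso1", "iso2"))
  iso2 <- rep[rep$scope == "isocenter" & rep$id == "iso2", ]
  beams2 <- rep[rep$scope == "beam" & rep$isocenter == "iso2", ]
  expect_equal(iso2$MU, sum(beams2$MU))
  expect_equal(iso2$CPs, sum(beams2$CPs))
})

test_that("modulation level moves every complexity metric the right way", {
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  for (seed in 1:10) {
    reps <- lapply(levels, function(m)
      aggregate_metrics(generate_plan(n_beams = 1, n_cp_per_beam = 30,
                                      modulation_level = m, seed = seed)))
    get <- function(col) vapply(reps, function(r) r[r$scope == "plan", col], 0)
    expect_true(all(diff(get("PI")) >= -1e-9), label = paste("PI seed", seed))
    expect_true(all(diff(get("SAS10")) >= -1e-9),
                label = paste("SAS10 seed", seed))
    expect_true(all(diff(get("MCS")) <= 1e-9),
                label = paste("MCS seed", seed))
  }
})
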