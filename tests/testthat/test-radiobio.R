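test_that("EQD2 matches the per-fraction BED summation oracle exactly", {
  bed_oracle <- function(total, n, ab) {
    d <- total / n
    bed <- 0
    for (k in seq_len(n)) bed <- bed + d * (1 + d / ab)  # fraction by fraction
    bed / (1 + 2 / ab)
  }
  for (case in list(c(24, 13, 2), c(12.7, 13, 2), c(50, 25, 3), c(8, 1, 10))) {
    s <- fractionation_scheme(case[2], case[3])
    expect_equal(eqd2(case[1], s), bed_oracle(case[1], case[2], case[3]),
                 tolerance = 1e-12)
  }
  # 2 Gy per fraction is the fixed point, independent of alpha/beta
  expect_equal(eqd2(26, fractionation_scheme(13, 2)), 26)
  expect_equal(eqd2(26, fractionation_scheme(13, 10)), 26)
  expect_equal(eqd2(0, fractionation_scheme(13, 2)), 0)
  expect_error(eqd2(-1, fractionation_scheme(13, 2)))
})

test_that("gEUD reduces to the mean at n = 1 and is dose-bounded", {
  set.seed(3)
  x <- stats::runif(200, 2, 30)
  expect_equal(geud(x, 1), mean(x), tolerance = 1e-12)
  expect_equal(geud(rep(7.5, 50), 0.14), 7.5, tolerance = 1e-9)
  for (n in c(0.05, 0.14, 0.5, 1, 2)) {
    g <- geud(x, n)
    expect_gte(g, min(x)); expect_lte(g, max(x))
  }
  # two-bin fixture: small n approaches the maximum dose
  two_bin <- dvh_from_doses(c(rep(10, 500), rep(20, 500)))
  expect_lt(abs(geud(two_bin, 0.01) - 20) / 20, 0.01)
  expect_error(geud(x, 0), "n = 0")
})

test_that("gEUD through the DVH path agrees with direct two-bin summation", {
  two_bin <- dvh_from_doses(c(rep(10, 500), rep(20, 500)))
  for (n in c(0.14, 0.5, 2)) {
    oracle <- (0.5 * 10^(1 / n) + 0.5 * 20^(1 / n))^n
    expect_lt(abs(geud(two_bin, n) - oracle) / oracle, 1e-3, label = n)
  }
})

test_that("LKB probit behaves at its anchor points", {
  expect_equal(lkb_ntcp(22, 22, 0.54), 0.5)
  expect_equal(lkb_ntcp(14.88, 14.88, 0.54), 0.5)
  # zero-dose scalp closes at Phi(-1/m)
  expect_equal(scalp_ntcp(geud_Gy = 0), stats::pnorm(-1 / 0.54),
               tolerance = 1e-12)
  expect_lt(abs(scalp_ntcp(geud_Gy = 0) - 0.032), 5e-4)
})

test_that("hippocampal model chains EQD2 into the probit", {
  s <- fractionation_scheme(13, 2)
  # EQD2 equal to TD50 sits exactly at 50% risk
  d <- stats::uniroot(function(x) eqd2(x, s) - 14.88, c(1, 30))$root
  expect_equal(hippocampal_ntcp(d, s), 0.5, tolerance = 1e-9)
  expect_equal(hippocampal_ntcp(24.0, s),
               lkb_ntcp(eqd2(24.0, s), 14.88, 0.54))
})

test_that("endocrine model is zero at t = 0 and increases with dose", {
  expect_equal(endocrine_ntcp(14.6, 15.2, 10, t_years = 0), 0)
  # frozen direct evaluation at the cohort-mean inputs (age 10, t = 5)
  expect_equal(endocrine_ntcp(14.6, 15.2, 10), 0.3167642, tolerance = 1e-6)
  doses <- seq(0, 40, by = 2)
  p <- vapply(doses, function(dd) endocrine_ntcp(dd, dd, 10), 0)
  expect_true(all(diff(p) > 0))
  expect_error(endocrine_ntcp(14.6, 15.2, 10, t_years = -1))
})

test_that("cochlear logistic model crosses 0.5 at its midpoint", {
  expect_equal(cochlear_ntcp(-(-5.3) / 0.085), 0.5, tolerance = 1e-12)
  expect_equal(cochlear_ntcp(21.4),
               exp(-5.3 + 0.085 * 21.4) / (1 + exp(-5.3 + 0.085 * 21.4)))
})

test_that("all four NTCP models stay in [0,1] and are monotone in dose", {
  doses <- seq(0, 60, by = 1)
  s <- fractionation_scheme(13, 2)
  curves <- list(
    hippocampus = vapply(doses, function(d) hippocampal_ntcp(d, s), 0),
    scalp = vapply(doses, function(d) scalp_ntcp(geud_Gy = d), 0),
    hpa = vapply(doses, function(d) endocrine_ntcp(d, d, 10), 0),
    cochlea = vapply(doses, function(d) cochlear_ntcp(d), 0))
  for (nm in names(curves)) {
    p <- curves[[nm]]
    expect_true(all(p >= 0 & p <= 1), label = nm)
    expect_true(all(diff(p) >= 0), label = nm)
  }
})

test_that("target EUD/TCP: uniform fixed point, TCD50 midpoint, spread invariance", {
  uni <- dvh_from_doses(rep(23.4, 400))
  out <- ptv_eud_tcp(uni, eud_exponent_a = -10, TCD50_Gy = 30, gamma50 = 2)
  expect_equal(out$EUD_Gy, 23.4, tolerance = 1e-9)
  out50 <- ptv_eud_tcp(uni, eud_exponent_a = -10, TCD50_Gy = 23.4, gamma50 = 2)
  expect_equal(out50$TCP, 0.5, tolerance = 1e-9)
  expect_error(ptv_eud_tcp(uni), "TCP parameters")

  # two distributions moment-matched in gEUD share the TCP exactly
  a <- -10; n <- 1 / a
  d1 <- 19
  target <- geud(rep(20, 10), n)
  d2 <- (2 * target^(1 / n) - d1^(1 / n))^n
  mix <- dvh_from_doses(c(rep(d1, 300), rep(d2, 300)))
  expect_equal(geud(mix, n), 20, tolerance = 1e-9)
  t1 <- ptv_eud_tcp(dvh_from_doses(rep(20, 600)), a, 30, 2)$TCP
  t2 <- ptv_eud_tcp(mix, a, 30, 2)$TCP
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("parameter registry ships the documented organ models", {
  reg <- load_ntcp_registry()
  expect_equal(reg$hippocampus$TD50_Gy, 14.88)
  expect_equal(reg$hippocampus$m, 0.54)
  expect_equal(reg$hippocampus$alpha_beta_Gy, 2)
  expect_equal(reg$scalp$TD50_Gy, 22)
  expect_equal(reg$scalp$n, 0.14)
  expect_equal(reg$hpa$gamma, 0.56)
  expect_equal(reg$hpa$const, 3.13)
  expect_equal(reg$cochlea$b0, -5.3)
  expect_equal(reg$cochlea$b1, 0.085)
  expect_error(load_ntcp_registry("does/not/exist.yaml"), "not found")
})
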