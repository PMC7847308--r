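test_that("stack reflection vanishes without index contrast and matches Fresnel at a single interface", {
  ww <- opticalStack(list(opticalLayer("water", 1.33),
                          opticalLayer("water", 1.33)), 518)
  for (u in c(0, 0.3, 0.99, 1.5, 10)) {
    expect_equal(Mod(stackReflection(ww, "s", u)), 0, tolerance = 1e-12)
    expect_equal(Mod(stackReflection(ww, "p", u)), 0, tolerance = 1e-12)
  }
  wg <- opticalStack(list(opticalLayer("glass", 1.52),
                          opticalLayer("water", 1.33)), 518)
  r0 <- (1.33 - 1.52) / (1.33 + 1.52)
  expect_equal(Re(stackReflection(wg, "s", 0)), r0, tolerance = 1e-12)
  # p-polarization at normal incidence in the mirror-positive convention
  expect_equal(Re(stackReflection(wg, "p", 0)), -r0, tolerance = 1e-12)
  expect_error(stackReflection(wg, "s", -0.1), "non-negative")
})

test_that("full-stack reflection matches the independently coded recursive oracle", {
  st <- gietStack("giet520", 518)
  n_list <- list(as.complex(1.33), as.complex(1.44),
                 complex(real = 2.68, imaginary = 1.21), as.complex(1.52))
  t_list <- list(2.5, 0.34)
  for (u in c(0, 0.5, 0.9, 1.0001, 2, 20, 200)) {
    for (pol in c("s", "p")) {
      got <- stackReflection(st, pol, u)
      want <- oracleReflection(u, pol, 518, n_list, t_list)
      expect_lt(Mod(got - want), 1e-10)
    }
  }
})

test_that("a homogeneous medium leaves the emission power unchanged", {
  ws <- waterStack()
  for (ori in c("isotropic", "perpendicular", "parallel")) {
    expect_equal(relativeEmissionPower(ws, c(3, 10, 25), ori),
                 c(1, 1, 1), tolerance = 1e-9)
  }
  expect_equal(lifetimeRatio(gietFluorophore("FAM"), ws, 10), 1,
               tolerance = 1e-9)
})

test_that("the quenching vanishes in the far field for every bundled fluorophore", {
  for (nm in c("FAM", "EGFP", "mNeonGreen", "Dy647P1")) {
    fl <- gietFluorophore(nm)
    expect_lt(abs(lifetimeRatio(fl, d = 1000) - 1), 0.02)
  }
})

test_that("adaptive quadrature agrees with brute-force fixed-grid integration", {
  st <- gietStack("giet520", 518)
  for (d in c(3, 5, 10, 20)) {
    adaptive <- relativeEmissionPower(st, d)
    brute <- bruteForcePower(st, d)
    expect_lt(abs(adaptive - brute) / abs(brute), 1e-5)
  }
})

test_that("emitters below the monolayer surface are rejected", {
  st <- gietStack("giet520", 518)
  expect_error(relativeEmissionPower(st, 1.0), "monolayer")
  expect_error(gietCurve(gietFluorophore("FAM"), d_min = 1), "monolayer")
})

test_that("lifetime ratio approaches one as the quantum yield vanishes", {
  dark <- fluorophore("dark", 518, 1e-9, 3.0)
  st <- gietStack("giet520", 518)
  expect_equal(lifetimeRatio(dark, st, 5), 1, tolerance = 1e-6)
})

test_that("efficiency is the complement of the ratio and increases with quantum yield", {
  st <- gietStack("giet520", 518)
  d <- 5
  effs <- vapply(c(0.2, 0.5, 0.8), function(phi) {
    fl <- fluorophore("x", 518, phi, 3.0)
    expect_equal(gietEfficiency(fl, st, d) + lifetimeRatio(fl, st, d), 1,
                 tolerance = 1e-12)
    gietEfficiency(fl, st, d)
  }, numeric(1))
  expect_true(all(diff(effs) > 0))
})

test_that("calibration curves are strictly increasing for all bundled fluorophores", {
  for (nm in c("FAM", "EGFP", "mNeonGreen", "Dy647P1")) {
    cv <- cachedCurve(nm)
    expect_true(all(diff(cv$ratio) > 0))
    expect_true(all(cv$ratio > 0 & cv$ratio < 1))
  }
})

test_that("curve interpolation reproduces direct recomputation at off-grid distances", {
  cv <- cachedCurve("FAM")
  fam <- gietFluorophore("FAM")
  st <- defaultStackFor(fam)
  for (d in c(3.333, 7.77, 14.05, 26.9)) {
    direct <- lifetimeRatio(fam, st, d)
    expect_lt(abs(predict(cv, d) - direct) / direct, 0.005)
  }
})

test_that("ratio inversion round-trips across the curve range and rejects out-of-range ratios", {
  cv <- cachedCurve("FAM")
  for (d0 in seq(2.6, 29.5, length.out = 12)) {
    est <- invertRatio(cv, predict(cv, d0))
    expect_lt(abs(est$d - d0), 1e-3)
    expect_equal(est$h, est$d - 2.5)
  }
  expect_error(invertRatio(cv, 0.9999), "attainable interval")
  expect_error(invertRatio(cv, 1e-9), "attainable interval")
})

test_that("uncertainty intervals bracket the point estimate and clip at the curve range", {
  cv <- cachedCurve("Dy647P1")
  est <- invertRatio(cv, 0.25, 0.06)
  expect_lte(est$d_low, est$d)
  expect_lte(est$d, est$d_high)
  wide <- invertRatio(cv, 0.05, 0.2)
  expect_equal(wide$d_low, min(cv$d))
})

test_that("curve construction validates its grid arguments", {
  fam <- gietFluorophore("FAM")
  expect_error(gietCurve(fam, step = 0.2), "step")
  expect_error(gietCurve(fam, d_min = 10, d_max = 5), "smaller")
  expect_error(gietCurve(fam, d_max = 60), "50")
})
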