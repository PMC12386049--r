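test_that("series oracle roots are genuine roots, confirmed by bisection", {
  # independent bisection locates the first eigenvalue before the package's
  # root finder is trusted
  for (alpha in c(1, 5, 10)) {
    f <- function(q) tan(q) - 3 * q / (3 + alpha * q^2)
    lo <- pi + 1e-9; hi <- 3 * pi / 2 - 1e-9
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    q1_bisect <- (lo + hi) / 2
    q1_pkg <- phenolflux:::crank_roots(alpha, 20)[1]
    expect_gt(q1_pkg, pi / 2)
    expect_lt(q1_pkg, 3 * pi / 2)
    expect_equal(q1_pkg, q1_bisect, tolerance = 1e-10)
    expect_lt(abs(f(q1_pkg)), 1e-8)
  }
})

test_that("series fraction has the right limits and monotonicity", {
  expect_identical(crank_series_fraction(5, 0), 0)
  for (alpha in c(1, 10, 50)) {
    expect_equal(crank_series_fraction(alpha, 10), 1, tolerance = 1e-9)
    taus <- seq(0, 2, length.out = 40)
    fr <- crank_series_fraction(alpha, taus)
    expect_true(all(diff(fr) >= -1e-12))
    expect_true(all(fr >= 0 & fr <= 1))
  }
  expect_error(crank_series_fraction(-1, 1), "alpha")
  expect_error(crank_series_fraction(1, 1, n_roots = 5), "n_roots")
})

test_that("numerical solver matches the series oracle across alpha and tau", {
  taus <- c(0, 1e-3, 5e-3, 0.01, 0.05, 0.1, 0.5, 1, 2, 5)
  for (alpha in c(1, 5, 10, 50)) {
    prof <- quick_profile(alpha = alpha, taus = taus)
    frac <- profile_fraction(prof)
    oracle <- crank_series_fraction(alpha, taus, n_roots = 500)
    expect_lt(max(abs(frac - oracle)), 1e-3)
  }
})

test_that("initial condition and equilibrium limits hold", {
  prof <- quick_profile(alpha = 10, taus = c(0, 0.5, 12))
  expect_equal(prof$CL_series[1], 0)
  expect_true(all(prof$Cs_field[1, ] == prof$cs0_g_cm3))
  # tau >= 10: extracted fraction reaches alpha/(1+alpha); CL at the
  # equilibrium mass balance Cs0 Vs/(Vs + VL) for K = 1
  expect_equal(prof$extracted_fraction[3], 10 / 11, tolerance = 1e-6)
  susp <- prof$suspension
  expect_equal(prof$CL_series[3],
               prof$cs0_g_cm3 * solid_volume(susp) /
                 (solid_volume(susp) + susp$liquid_volume_ml),
               tolerance = 1e-6)
})

test_that("mass is conserved and fields stay within physical bounds", {
  for (alpha in c(1, 10)) {
    for (K in c(1, 2)) {
      prof <- quick_profile(alpha = alpha, K = K,
                            taus = c(0, 0.01, 0.1, 0.5, 2))
      mb <- mass_balance(prof)
      expect_lt(max(abs(mb$total_g / mb$total_g[1] - 1)), 1e-6)
      expect_true(all(prof$Cs_field >= -1e-9))
      expect_true(all(prof$Cs_field <= prof$cs0_g_cm3 + 1e-9))
      expect_true(all(diff(prof$CL_series) >= -1e-12))
      # Cs nonincreasing in time through the particle core; the outer
      # shell legitimately re-equilibrates upward as the bath fills
      core <- prof$xi_grid <= 0.8
      expect_true(all(apply(prof$Cs_field[, core, drop = FALSE], 2,
                            function(col) all(diff(col) <= 1e-9))))
    }
  }
})

test_that("grid refinement changes CL by less than 1e-4 relative", {
  taus <- c(0, 0.02, 0.1, 0.5, 1)
  p1 <- quick_profile(taus = taus, n_nodes = 101)
  p2 <- quick_profile(taus = taus, n_nodes = 202)
  rel <- abs(p2$CL_series[-1] - p1$CL_series[-1]) / p2$CL_series[-1]
  expect_lt(max(rel), 1e-4)
})

test_that("solutions depend only on the dimensionless groups", {
  taus <- c(0, 0.05, 0.2, 1)
  # same (tau, alpha, K), different dimensional parameterizations
  a <- solve_extraction(diffusion_params(0.01, rate_per_min = 2, K = 1),
                        particle_spec(24.5), suspension_spec(6, 60, 1),
                        taus / 2)
  b <- solve_extraction(diffusion_params(0.04, rate_per_min = 0.5, K = 1),
                        particle_spec(100), suspension_spec(3, 30, 1),
                        taus / 0.5)
  expect_equal(a$extracted_fraction, b$extracted_fraction, tolerance = 1e-9)
})

test_that("yield curve maps the bath series to mg/g and hits its asymptote", {
  susp <- suspension_spec(6, 60, 1)
  # Cs0 from a 7.90 mg/g total content; with alpha = 10 the long-time
  # yield is 7.90 * 10/11
  par <- diffusion_params(cs0_from_content(7.90), rate_per_min = 1, K = 1)
  prof <- solve_extraction(par, default_particle, susp, c(0, 1, 12))
  yc <- yield_curve(prof)
  expect_equal(yc$yield_mg_per_g[1], 0)
  expect_true(all(diff(yc$yield_mg_per_g) >= 0))
  expect_equal(yc$yield_mg_per_g[3], 7.90 * 10 / 11, tolerance = 1e-4)
  expect_true(all(yc$yield_mg_per_g <=
                    1000 * par$cs0_g_cm3 * solid_volume(susp) /
                      susp$solid_mass_g + 1e-9))
  # the alpha -> infinity limit recovers the full 7.90 mg/g content
  big <- suspension_spec(6, 6e4, 1)
  prof_inf <- solve_extraction(par, default_particle, big, c(0, 12))
  expect_equal(yield_curve(prof_inf)$yield_mg_per_g[2], 7.90,
               tolerance = 1e-2)
})

test_that("snapshots are flat at the ends and monotone mid-extraction", {
  prof <- quick_profile(alpha = 10, taus = c(0, 0.05, 12))
  s0 <- extraction_snapshot(prof, 0)
  expect_true(all(s0$Cs == prof$cs0_g_cm3))
  mid <- extraction_snapshot(prof, prof$times_min[2])
  expect_true(all(diff(mid$Cs) <= 1e-12))  # nonincreasing centre -> surface
  expect_lt(mid$Cs[length(mid$Cs)], mid$Cs[1])
  late <- extraction_snapshot(prof, prof$times_min[3])
  expect_equal(max(late$Cs) - min(late$Cs), 0, tolerance = 1e-6 * prof$cs0_g_cm3)
  expect_equal(late$Cs[length(late$Cs)], prof$K * late$CL, tolerance = 1e-6)
  # nearest-time lookup reports what it used
  expect_message(s <- extraction_snapshot(prof, 0.7 * prof$times_min[3]),
                 "nearest")
  expect_equal(s$time_used_min, prof$times_min[3])
})

test_that("invalid inputs are rejected loudly", {
  expect_error(particle_spec(-1), "positive")
  expect_error(suspension_spec(0, 60), "positive")
  expect_error(diffusion_params(0.01), "exactly one")
  expect_error(diffusion_params(-0.01, rate_per_min = 1), "cs0")
  expect_error(diffusion_params(0.01, rate_per_min = Inf), "finite")
  expect_error(quick_profile(taus = c(0.1, 0.2)), "start at 0")
  expect_error(quick_profile(taus = c(0, 0.1), n_nodes = 5), "n_nodes")
})
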