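ct <- huddle_constants()

test_that("constants constructor validates and carries the calibrated defaults", {
  expect_equal(ct$k, 8.31)
  expect_equal(ct$c, 19)
  expect_equal(ct$c1, 3)
  expect_equal(ct$c2, 0.025)
  expect_equal(ct$Tp, 36)
  expect_equal(ct$beta, 0.2)
  expect_equal(ct$gamma, 0.001)
  expect_equal(ct$n, 7L)
  expect_error(huddle_constants(k = -1), "k must")
  expect_error(huddle_constants(gamma = 1), "gamma")
  expect_error(huddle_constants(n = 1), "n must")
})

test_that("BAT depletion, entropy and metabolic rate match closed-form values", {
  # frozen values computed independently with 30-digit arithmetic (mpmath)
  expect_equal(bat_fraction(0), 1)
  expect_equal(bat_fraction(8.31), exp(-1))
  expect_equal(bat_fraction(60), 7.31643922887399e-4, tolerance = 1e-12)
  expect_equal(bat_entropy(0), 0)
  expect_equal(bat_entropy(8.31), 3.05707815613469, tolerance = 1e-12)
  expect_equal(metabolic_rate(0), 8.31)
  expect_equal(metabolic_rate(8.31), 33.7143194774792, tolerance = 1e-12)
  expect_error(bat_fraction(-0.1), "non-negative")
})

test_that("entropy computed as -kP log P equals its simplification t exp(-t/k)", {
  t <- seq(0, 60, by = 0.05)
  expect_equal(bat_entropy(t), t * exp(-t / ct$k), tolerance = 1e-12)
})

test_that("metabolic rate peaks at the BAT time constant for any k", {
  for (k in c(5, 8.31, 12)) {
    peak <- metabolic_peak_day(huddle_constants(k = k))
    expect_equal(peak, k, tolerance = 1e-6 / k)
  }
})

test_that("growth curves obey their defining rate identities", {
  # masses and asymptotes
  expect_equal(muscle_mass(0), 0)
  expect_equal(muscle_mass(8.31), 8.31 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(muscle_mass(1000), 8.31, tolerance = 1e-9)
  expect_equal(body_mass(1000), 8.31 + 19, tolerance = 1e-9)
  # conservation W = M + N on a dense grid
  t <- seq(0, 60, by = 0.1)
  expect_identical(body_mass(t), muscle_mass(t) + nonmuscle_mass(t))
  # muscle growth relaxes towards its asymptote k: dM/dt = (k - M) / k by
  # central differences (the closed form M = k(1 - e^(-t/k)) fixes the time
  # constant at k, so the deficit k - M decays at rate 1/k)
  h <- 1e-4
  t <- seq(0.5, 59.5, by = 0.5)
  dM <- (muscle_mass(t + h) - muscle_mass(t - h)) / (2 * h)
  expect_equal(dM, (ct$k - muscle_mass(t)) / ct$k, tolerance = 1e-3)
  # dN/dM = c1 * N at day 10, by finite differences of N against M
  t0 <- 10
  dN <- nonmuscle_mass(t0 + h) - nonmuscle_mass(t0 - h)
  dM1 <- muscle_mass(t0 + h) - muscle_mass(t0 - h)
  expect_equal(dN / dM1, ct$c1 * nonmuscle_mass(t0), tolerance = 1e-3)
})

test_that("physiology curves are monotone where development demands it", {
  t <- seq(0, 60, by = 0.1)
  expect_true(all(diff(bat_fraction(t)) < 0))
  expect_true(all(diff(muscle_mass(t)) > 0))
  expect_true(all(diff(nonmuscle_mass(t)) > 0))
  expect_true(all(diff(warm_deviation(t)) < 0))
})

test_that("preferred temperature switches from warm-seeking to cool-seeking", {
  expect_equal(warm_deviation(0), 3)
  expect_equal(warm_deviation(8.31), 3 * exp(-1), tolerance = 1e-12)
  expect_lt(cool_deviation(0), 1e-9)
  expect_equal(cool_deviation(1000), 0.025 * 8.31 * 19, tolerance = 1e-9)
  expect_equal(cool_deviation(60), 4.04605221141393, tolerance = 1e-12)
  expect_equal(selected_temperature(0), 39)
  expect_equal(selected_temperature(60), 31.9539477885861, tolerance = 1e-12)
  sw <- temperature_switch_day()
  expect_gt(sw, 16)
  expect_lt(sw, 17)
  # oracle: sign change located on a 0.01-day grid brackets the root
  grid <- seq(0, 60, by = 0.01)
  f <- warm_deviation(grid) - cool_deviation(grid)
  i <- which(diff(sign(f)) != 0)[1]
  expect_gte(sw, grid[i])
  expect_lte(sw, grid[i + 1])
})

test_that("the thermal huddling drive starts positive, ends negative, flips once", {
  expect_equal(huddling_drive(0), 0.6, tolerance = 1e-9)
  expect_equal(huddling_drive(60), -0.808771455929054, tolerance = 1e-12)
  # the sign change coincides with the preferred-temperature switch
  root <- stats::uniroot(huddling_drive, c(0, 60), tol = 1e-10)$root
  expect_equal(root, temperature_switch_day(), tolerance = 1e-6)
  t <- seq(0, 60, by = 0.1)
  expect_equal(sum(diff(sign(huddling_drive(t))) != 0), 1)
})

test_that("the curve table carries every quantity consistently", {
  cv <- physiology_curves(days = 0:60)
  expect_s3_class(cv, "huddle_curves")
  expect_named(cv, c("day", "P", "S", "G", "M", "N", "W", "T1", "T2",
                     "selected_temp", "drive"))
  expect_identical(cv$W, cv$M + cv$N)
  expect_equal(cv$drive, ct$beta * (cv$T1 - cv$T2))
  expect_equal(cv$selected_temp,
               ifelse(cv$T1 >= cv$T2, ct$Tp + cv$T1, ct$Tp - cv$T2))
})
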