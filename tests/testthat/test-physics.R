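# Relativistic kinematics, gyroradius/step formulas, stopping power,
# scattering width and rotation primitives.

test_that("lorentz kinematics satisfies the closed-form relations", {
  k0 <- lorentz_kinematics(0)
  expect_equal(k0$gamma, 1)
  expect_equal(k0$beta, 0)
  expect_equal(k0$momentum_c, 0)

  k <- lorentz_kinematics(0.5110)  # T = m0c^2
  expect_equal(k$gamma, 2)
  expect_equal(k$beta, 0.866025, tolerance = 1e-6)

  expect_equal(lorentz_kinematics(1.0)$momentum_c, 1.42197, tolerance = 1e-5)

  # invariants over a grid
  T <- c(1e-3, 0.05, 0.1, 0.5110, 1, 6)
  k <- lorentz_kinematics(T)
  expect_equal(k$gamma, 1 + T / 0.5110)
  expect_equal(k$beta, sqrt(1 - 1 / k$gamma^2))
  expect_equal(k$momentum_c, sqrt(T * (T + 2 * 0.5110)))
  expect_true(all(k$beta >= 0 & k$beta < 1))

  expect_error(lorentz_kinematics(-0.1), "non-negative")
})

test_that("gyroradius matches the momentum formula and sentinel cases", {
  expect_equal(gyroradius(1.0, 1.5, 1.0), 0.31621, tolerance = 1e-4)
  expect_equal(gyroradius(0.1, 1.5, 1.0), 0.074485, tolerance = 1e-4)
  expect_identical(gyroradius(1.0, 1.5, 0.0), Inf)   # motion parallel to B
  expect_identical(gyroradius(1.0, 0, 1.0), Inf)     # field off
  # stronger field, tighter radius; higher energy, larger radius
  expect_lt(gyroradius(1, 3, 1), gyroradius(1, 1.5, 1))
  expect_gt(gyroradius(6, 1.5, 1), gyroradius(1, 1.5, 1))
})

test_that("max_em_step is the em_estepe fraction of the gyroradius and linear", {
  B <- c(0, 0, 1.5); u <- c(1, 0, 0)  # u perpendicular to B
  expect_equal(max_em_step(1.0, B, u, 0.01), 3.1621e-3, tolerance = 1e-4)
  expect_equal(max_em_step(1.0, B, u, 0.25), 0.079052, tolerance = 1e-4)
  # exact linearity in em_estepe
  expect_identical(max_em_step(1.0, B, u, 0.2), 2 * max_em_step(1.0, B, u, 0.1))
  expect_identical(max_em_step(1.0, c(0, 0, 0), u, 0.25), Inf)
  expect_identical(max_em_step(1.0, B, c(0, 0, 1), 0.25), Inf)  # u parallel B
})

test_that("collision stopping power matches its formula and published-table band", {
  # frozen value from independent evaluation of the Moller/ICRU form
  expect_equal(collision_stopping_power(1.0), 1.872485, tolerance = 1e-5)
  # sanity band: within 3% of published water collision stopping power
  expect_lt(abs(collision_stopping_power(1.0) - 1.849) / 1.849, 0.03)
  # decreasing between 0.1 and 1 MeV, positive everywhere
  expect_gt(collision_stopping_power(0.1), collision_stopping_power(1.0))
  grid <- exp(seq(log(1e-3), log(10), length.out = 50))
  expect_true(all(collision_stopping_power(grid) > 0))
  expect_error(collision_stopping_power(1e-4), "cutoff")
})

test_that("multiple scattering width is variance-additive with Highland scale", {
  expect_identical(multiple_scattering_sigma(1.0, 0), 0)
  # independent re-evaluation of the stated formula
  t_ref <- 0.25 * 1.0 / collision_stopping_power(1.0)
  k <- lorentz_kinematics(1.0)
  bracket <- max(0.25, 1 + 0.038 * log(t_ref / 36.08))
  expect_equal(multiple_scattering_sigma(1.0, 0.01),
               13.6 / (k$beta * k$momentum_c) * sqrt(0.01 / 36.08) * bracket,
               tolerance = 1e-12)
  # exact sqrt scaling below the clamp
  expect_equal(multiple_scattering_sigma(1.0, 0.004),
               2 * multiple_scattering_sigma(1.0, 0.001), tolerance = 1e-12)
  # clamp at 0.5 rad for extreme thickness
  expect_identical(multiple_scattering_sigma(0.05, 1), 0.5)
  # scattering power is additive by construction
  expect_equal(multiple_scattering_sigma(1, 0.002)^2 +
                 multiple_scattering_sigma(1, 0.003)^2,
               multiple_scattering_sigma(1, 0.005)^2, tolerance = 1e-12)
})

test_that("Rodrigues rotation handles identity, full and quarter turns", {
  u <- c(1, 0, 0); a <- c(0, 0, 1)
  expect_equal(rotate_about_axis(u, a, 0), u)
  expect_equal(rotate_about_axis(u, a, 2 * pi), u, tolerance = 1e-12)
  expect_equal(rotate_about_axis(u, a, pi / 2), c(0, 1, 0), tolerance = 1e-12)
  expect_error(rotate_about_axis(c(1, 1, 0), a, 1), "unit")
  set.seed(42)
  for (i in 1:20) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    w <- rnorm(3); w <- w / sqrt(sum(w^2))
    out <- rotate_about_axis(v, w, runif(1, -5, 5))
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
  }
})

test_that("magnetic deflection is an exact transverse rotation", {
  B <- c(0, 0, 1.5); u <- c(1, 0, 0); E <- 1.0
  rg <- gyroradius(E, 1.5, 1)
  # full gyration returns the direction
  expect_equal(magnetic_deflection(u, B, 2 * pi * rg, E), u, tolerance = 1e-9)
  # quarter gyration rotates 90 degrees about B
  q <- magnetic_deflection(u, B, (pi / 2) * rg, E)
  expect_equal(abs(sum(q * u)), 0, tolerance = 1e-9)
  expect_equal(q[3], 0, tolerance = 1e-12)
  # first-order Taylor agreement: du ~ (s/r_G) * (u x Bhat)
  s <- 1e-4 * rg
  d <- magnetic_deflection(u, B, s, E) - u
  cross <- c(u[2], -u[1], 0)  # u x Bhat with Bhat = zhat
  expect_equal(d, (s / rg) * cross, tolerance = 1e-4)
  # parallel component and norm preserved for oblique directions
  set.seed(7)
  for (i in 1:20) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    out <- magnetic_deflection(v, B, runif(1, 0, 1), E)
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
    expect_equal(out[3], v[3], tolerance = 1e-12)  # component along B
  }
  expect_equal(magnetic_deflection(u, c(0, 0, 0), 1, E), u)
})

test_that("vacuum helix: composed small steps reverse the transverse direction", {
  E <- 1.0; B <- c(0, 0, 1.5)
  rg <- gyroradius(E, 1.5, 1)
  u <- c(1, 0, 0)
  n <- 1000
  s <- pi * rg / n
  for (i in seq_len(n)) u <- magnetic_deflection(u, B, s, E)
  expect_equal(u, c(-1, 0, 0), tolerance = 1e-6)
})

test_that("CSDA range table of the engine agrees with quadrature", {
  T <- c(0.002, 0.01, 0.1, 0.5, 1, 3, 5.9)
  m <- .engine_range_map(T, 6)
  r <- csda_range(T)
  expect_equal(m$range, r, tolerance = 5e-6)
  expect_equal(m$T_back, T, tolerance = 5e-6)
  # spot value: 1 MeV electron range in water ~ 0.437 g/cm^2
  expect_equal(csda_range(1), 0.437, tolerance = 1e-3)
})
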