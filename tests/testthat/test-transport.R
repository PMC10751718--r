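# The condensed-history stepper: step-length selection, energy
# bookkeeping, helix convergence, and agreement between the plain-R
# reference stepper and the compiled engine.

test_that("propose_step picks the limiting process correctly", {
  sl <- fixture_geometry("slab")
  # deep in water, no field: energy limit 0.25*T/(S*rho)
  st <- electron_state(c(0, 0, -2), c(0, 0, 1), 1, geom = sl)
  p0 <- transport_params()
  pr <- propose_step(st, sl, p0)
  expect_identical(pr$limiter, "energy")
  expect_equal(pr$length, 0.25 / collision_stopping_power(1), tolerance = 1e-9)
  expect_equal(pr$length, 0.1335, tolerance = 1e-3)

  # inside the air gap with a strong field: field limit em_estepe * r_G
  pB <- transport_params(em_estepe = 0.01, B_field = c(1.5, 0, 0))
  stg <- electron_state(c(0, 0.3, 0), c(0, 0, 1), 1, geom = sl)  # u  |  B
  prB <- propose_step(stg, sl, pB)
  expect_identical(prB$limiter, "field")
  expect_equal(prB$length, 3.1621e-3, tolerance = 1e-4)

  # just below a surface: geometry limited
  stn <- electron_state(c(0, 0, -0.251), c(0, 0, 1), 1, geom = sl)
  prn <- propose_step(stn, sl, p0)
  expect_identical(prn$limiter, "geometry")
  expect_equal(prn$length, 1e-3, tolerance = 1e-6)
})

test_that("field-limited step length is independent of the medium density", {
  sl <- fixture_geometry("slab")
  pB <- transport_params(em_estepe = 0.01, B_field = c(1.5, 0, 0))
  in_air <- electron_state(c(0, 0.3, 0), c(0, 0, 1), 1, geom = sl)
  in_water <- electron_state(c(0, 0.3, -2), c(0, 0, 1), 1, geom = sl)
  expect_identical(in_air$region_id == in_water$region_id, FALSE)
  expect_equal(propose_step(in_air, sl, pB)$length,
               propose_step(in_water, sl, pB)$length, tolerance = 1e-12)
})

test_that("a full history conserves energy exactly (R reference)", {
  sl <- fixture_geometry("slab")
  set.seed(31)
  p0 <- transport_params()
  for (i in 1:5) {
    em <- list(x = runif(1, -1, 1), y = runif(1, -1, 1), z = runif(1, -1, 1),
               ux = 0, uy = 0, uz = 1, region_id = NULL)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    em$ux <- u[1]; em$uy <- u[2]; em$uz <- u[3]
    em$region_id <- locate(sl, c(em$x, em$y, em$z))
    dep <- transport_history(em, sl, p0, 0.3)
    expect_equal(sum(dep), 0.3, tolerance = 1e-12)
  }
})

test_that("immediate absorption below and just above the cutoff", {
  g <- geom_uniform()
  em <- list(x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1, region_id = 0L)
  dep <- transport_history(em, g, transport_params(), 1.01e-3)
  expect_equal(unname(dep["0"]), 1.01e-3, tolerance = 1e-15)
  # a 1 MeV history deep inside a huge homogeneous phantom stays put
  g2 <- geom_uniform(size = 8)
  dep2 <- transport_history(em, g2, transport_params(), 1)
  expect_equal(unname(dep2["0"]), 1, tolerance = 1e-12)
})

test_that("CSDA path length matches quadrature through the range map", {
  g <- geom_uniform(size = 8)
  for (estepe in c(0.25, 0.005)) {
    p <- transport_params(estepe = estepe, disable_scatter = TRUE)
    st <- electron_state(c(0, 0, -3), c(0, 0, 1), 0.5, geom = g)
    total <- 0
    while (st$alive) {
      res <- do_step(st, g, p)
      total <- total + res$length
      st <- res$state
    }
    # the history dies at the cutoff, absorbing the remainder locally
    expected <- csda_range(0.5) - csda_range(1e-3)
    expect_lt(abs(total - expected) / expected,
              if (estepe == 0.005) 1e-4 else 1e-2)
  }
})

test_that("compiled engine reproduces the R reference step by step", {
  ch <- fixture_geometry("chamber_like")
  p <- transport_params(em_estepe = 0.05, B_field = c(1.5, 0, 0),
                        disable_scatter = TRUE)
  starts <- list(
    list(pos = c(0, 0, -0.9), dir = c(0, 0, 1)),    # up the axis into the wall
    list(pos = c(0.1, 0.05, 0), dir = c(0, 1, 0)),  # out through the cavity
    list(pos = c(0.3, 0, 2.0), dir = c(-0.3, 0.2, 0.933))
  )
  for (s0 in starts) {
    dir <- s0$dir / sqrt(sum(s0$dir^2))
    tr <- .engine_trace(fanocavity:::.geom_matrix(ch), ch$phantom / 2,
                        s0$pos, dir, 1.0, p$B_field, p$em_estepe, p$estepe,
                        p$ecut, TRUE, 1.0, FALSE, 1, 2e6)
    st <- electron_state(s0$pos, dir, 1.0, geom = ch)
    i <- 0
    ok <- TRUE
    while (st$alive && i < nrow(tr)) {
      i <- i + 1
      res <- do_step(st, ch, p)
      st <- res$state
      # compare positions and energy (range-map interpolation differs at 1e-5)
      if (max(abs(st$position - tr[i, c("x", "y", "z")])) > 1e-5 ||
          abs(st$kinetic_energy - tr[i, "T"]) > 2e-5) ok <- FALSE
    }
    expect_true(ok)
    expect_equal(i, nrow(tr))  # both engines take the same number of steps
  }
})

test_that("engine helix: transverse displacement converges to 2 r_G", {
  g <- geom_vacuum()
  rg <- gyroradius(1, 1.5, 1)
  for (f in c(0.05, 0.005)) {
    tr <- .engine_trace(fanocavity:::.geom_matrix(g), g$phantom / 2,
                        c(0, 0, 0), c(0, 0, 1), 1.0, c(1.5, 0, 0), f, 0.25,
                        1e-3, TRUE, 1.0, FALSE, 1, 5000)
    path <- cumsum(tr[, "s"])
    i <- which(path >= pi * rg)[1]
    expect_false(is.na(i))
    disp <- unname(sqrt(tr[i, "y"]^2 + tr[i, "z"]^2))
    tol <- if (f == 0.005) 1e-3 else 0.1
    expect_equal(disp, 2 * rg, tolerance = tol)
  }
  # energy unchanged over the near-vacuum flight
  expect_gt(min(tr[, "T"]), 1 - 1e-6)
})

test_that("first-order deflection agrees with the exact rotation for small steps", {
  u <- c(0, 1, 0); B <- c(1.5, 0, 0)
  s <- 1e-4 * gyroradius(1, 1.5, 1)
  expect_equal(magnetic_deflection(u, B, s, 1, first_order = TRUE),
               magnetic_deflection(u, B, s, 1, first_order = FALSE),
               tolerance = 1e-7)
})

test_that("run_transport tallies are reproducible and conserve energy", {
  sl <- fixture_geometry("slab")
  p <- transport_params(em_estepe = 0.1, B_field = c(1.5, 0, 0))
  a <- run_transport(sl, 1, 5000, p, seed = 77)
  b <- run_transport(sl, 1, 5000, p, seed = 77)
  expect_identical(a$sum_deposit, b$sum_deposit)
  expect_identical(a$n_emitted, b$n_emitted)
  expect_equal(a$total_deposit, 5000 * 1, tolerance = 1e-9)
  expect_lte(a$max_history_conservation_error, 1e-12)
  expect_identical(a$escapes, 0L)
  # recorded field-limited steps never exceed em_estepe * r_G
  expect_lte(a$max_field_step_ratio, 1 + 1e-9)
})
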