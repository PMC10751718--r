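# Geometry construction, volumes/masses, point location and chords.

test_that("fixtures load with the pinned detector dimensions and tile exactly", {
  ch <- fixture_geometry("chamber_like")
  rm <- region_masses(ch)
  cav <- rm[rm$name == "air_cavity", ]
  expect_equal(cav$volume, 0.07, tolerance = 1e-4)
  expect_equal(cav$mass, 8.434e-5, tolerance = 1e-3)
  expect_equal(ch$regions[[5]]$radius, 0.04)  # aluminium electrode

  di <- fixture_geometry("diode_like")
  rmd <- region_masses(di)
  expect_equal(rmd$volume[rmd$name == "silicon_chip"], 3.4e-4, tolerance = 1e-4)

  for (g in list(ch, di, fixture_geometry("slab"))) {
    expect_equal(sum(g$volume), prod(g$phantom), tolerance = 1e-9)
    expect_true(all(g$mass > 0))
    expect_equal(g$mass, g$volume * g$density)
  }
})

test_that("cylindrical shell volume is closed-form (outer minus inner)", {
  g <- geom_shell()
  rm <- region_masses(g)
  expect_equal(rm$volume[rm$name == "outer"], 3 * pi, tolerance = 1e-12)
  expect_equal(rm$volume[rm$name == "inner"], pi, tolerance = 1e-12)
})

test_that("invalid geometries are rejected", {
  # overlapping siblings
  expect_error(geometry(c(4, 4, 4), list(
    region_box(0, "base", c(0, 0, 0), c(4, 4, 4), 1),
    region_box(1, "a", c(0, 0, 0), c(2, 2, 2), 1),
    region_box(2, "b", c(0.5, 0, 0), c(2, 2, 2), 1)
  )), "overlapping")
  # region sticking out of every earlier region
  expect_error(geometry(c(4, 4, 4), list(
    region_box(0, "base", c(0, 0, 0), c(4, 4, 4), 1),
    region_box(1, "out", c(2, 0, 0), c(2, 2, 2), 1)
  )), "not contained")
  # first region must be the phantom box
  expect_error(geometry(c(4, 4, 4), list(
    region_box(0, "base", c(0, 0, 0), c(2, 2, 2), 1)
  )), "phantom")
})

test_that("locate respects carve-out priority and boundary resolution", {
  ch <- fixture_geometry("chamber_like")
  expect_identical(locate(ch, c(0, 0, 0)), 4L)          # electrode at origin
  expect_identical(locate(ch, c(0.1, 0, 0)), 3L)        # cavity annulus
  expect_identical(locate(ch, c(0, 0, 1.0)), 6L)        # stem air gap
  expect_identical(locate(ch, c(0, 0, 1.3)), 5L)        # stem body
  expect_identical(locate(ch, c(3, 3, -4)), 0L)         # far water
  # a point exactly on the electrode surface resolves to the electrode
  expect_identical(locate(ch, c(0.04, 0, 0)), 4L)
  expect_error(locate(ch, c(0, 0, 7)), "outside")
})

test_that("hit-or-miss volumes agree with the closed forms", {
  g <- fixture_geometry("slab")
  set.seed(101)
  n <- 40000
  pts <- cbind(runif(n, -3, 3), runif(n, -3, 3), runif(n, -3, 3))
  ids <- apply(pts, 1, function(p) locate(g, p))
  vol <- prod(g$phantom)
  for (j in seq_along(g$ids)) {
    p_hat <- mean(ids == g$ids[j])
    p_exp <- g$volume[j] / vol
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(p_hat - p_exp), 4 * se + 1e-12)
  }
})

test_that("chord distances are exact for on-axis and box cases", {
  ch <- fixture_geometry("chamber_like")
  # from the electrode centre along +z to the electrode end cap
  expect_equal(chord_distance(ch, c(0, 0, 0), c(0, 0, 1)), 0.1989435,
               tolerance = 1e-9)
  # radially outward from the centre: electrode side wall at r = 0.04
  expect_equal(chord_distance(ch, c(0, 0, 0), c(1, 0, 0)), 0.04,
               tolerance = 1e-9)
  sl <- fixture_geometry("slab")
  # from the gap centre along +z to the gap face
  expect_equal(chord_distance(sl, c(0, 0, 0), c(0, 0, 1)), 0.25,
               tolerance = 1e-9)
  # from deep water to the phantom wall
  expect_equal(chord_distance(sl, c(0, 0, 2), c(0, 0, 1)), 1, tolerance = 1e-9)
})

test_that("no tunnelling: locate is constant along the open chord", {
  ch <- fixture_geometry("chamber_like")
  set.seed(202)
  for (i in 1:150) {
    p <- c(runif(1, -0.6, 0.6), runif(1, -0.6, 0.6), runif(1, -1, 3))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    r0 <- locate(ch, p)
    t <- chord_distance(ch, p, u)
    expect_gt(t, 0)
    for (frac in c(0.15, 0.4, 0.65, 0.9)) {
      expect_identical(locate(ch, p + frac * t * u), r0)
    }
  }
})

test_that("chord agrees with a brute-force bisection oracle on random rays", {
  g <- fixture_geometry("slab")
  set.seed(303)
  for (i in 1:40) {
    p <- runif(3, -1.4, 1.4)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    r0 <- locate(g, p)
    t <- chord_distance(g, p, u)
    # bisect for the first region change along the ray (oracle); leaving
    # the phantom counts as a change
    f <- function(x) tryCatch(locate(g, p + x * u) != r0, error = function(e) TRUE)
    t_max <- min(t * 4, 2)
    if (!f(t_max)) next  # ray ends in the same region beyond the chord
    lo <- 0; hi <- t_max
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid)) hi <- mid else lo <- mid
    }
    # the returned chord never overestimates the true crossing distance
    expect_lte(t, hi + 1e-9)
  }
})
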