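# The density-proportional isotropic Fano source.

test_that("homogeneous medium gives uniform positions (chi-square, 8 octants)", {
  g <- geom_uniform()
  cfg <- fano_source_config(1, c(4, 4, 4), seed = 5)
  em <- sample_emission(g, cfg, 2e4)
  octant <- 1 + (em$x > 0) + 2 * (em$y > 0) + 4 * (em$z > 0)
  tab <- tabulate(octant, nbins = 8)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("emission density is proportional to mass density (10:1 half boxes)", {
  g <- geom_half(rho_light = 0.1)
  cfg <- fano_source_config(1, c(4, 4, 4), seed = 6)
  n <- 5e4
  em <- sample_emission(g, cfg, n)
  n_light <- sum(em$region_id == 1)
  p_exp <- 0.1 / 1.1   # rho-weighted half volumes
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(n_light / n - p_exp), 4 * se)
  # realized counts attribute matches the table
  expect_equal(unname(attr(em, "n_emitted")["1"]), n_light)
})

test_that("directions are isotropic", {
  g <- geom_uniform()
  cfg <- fano_source_config(1, c(4, 4, 4), seed = 7)
  n <- 5e4
  em <- sample_emission(g, cfg, n)
  for (comp in list(em$ux, em$uy, em$uz)) {
    expect_lt(abs(mean(comp)), 4 / sqrt(3 * n) * sqrt(3))
    expect_equal(stats::sd(comp), 1 / sqrt(3), tolerance = 0.02)
  }
  expect_equal(em$ux^2 + em$uy^2 + em$uz^2, rep(1, n), tolerance = 1e-12)
  # polar cosine uniform on [-1, 1]
  ks <- suppressWarnings(stats::ks.test(em$uz, "punif", -1, 1))
  expect_gt(ks$p.value, 0.001)
})

test_that("identical seed reproduces the emission stream exactly", {
  g <- fixture_geometry("slab")
  cfg <- fano_source_config(1, g$source_box, seed = 11)
  a <- sample_emission(g, cfg, 500)
  b <- sample_emission(g, cfg, 500)
  expect_identical(a, b)
})

test_that("compiled-engine emission counts follow the rho*V weights", {
  g <- fixture_geometry("slab")
  p <- transport_params(ecut = 0.9)  # near-immediate absorption, cheap
  tal <- run_transport(g, 1, 4e4, p, seed = 13)
  N <- tal$histories
  w <- fanocavity:::.analytic_weights(g, g$source_box)
  for (j in seq_along(g$ids)) {
    se <- sqrt(w[j] * (1 - w[j]) / N)
    expect_lt(abs(tal$n_emitted[j] / N - w[j]), 4 * se + 2e-4)
  }
})
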