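# Small geometries built in code for the unit tests.

# single homogeneous water box
geom_uniform <- function(size = 4, density = 1.0) {
  geometry(rep(size, 3),
           list(region_box(0, "water", c(0, 0, 0), rep(size, 3), density)),
           name = "uniform", source_box = rep(size / 2, 3))
}

# two half-boxes of different density (base water + carved light half)
geom_half <- function(rho_light = 0.1) {
  geometry(c(4, 4, 4), list(
    region_box(0, "dense", c(0, 0, 0), c(4, 4, 4), 1.0),
    region_box(1, "light", c(0, 0, 1), c(4, 4, 2), rho_light)
  ), name = "half", source_box = c(4, 4, 4))
}

# cylindrical shell: outer cylinder minus inner cylinder
geom_shell <- function() {
  geometry(c(10, 10, 10), list(
    region_box(0, "water", c(0, 0, 0), c(10, 10, 10), 1.0),
    region_cylinder(1, "outer", c(0, 0, 0), radius = 2, half_height = 0.5,
                    density = 1.19),
    region_cylinder(2, "inner", c(0, 0, 0), radius = 1, half_height = 0.5,
                    density = 0.5)
  ), name = "shell")
}

# near-vacuum box for field-only trajectory tests
geom_vacuum <- function(size = 40) {
  geometry(rep(size, 3),
           list(region_box(0, "thin_gas", c(0, 0, 0), rep(size, 3), 1e-9)),
           name = "vacuum", source_box = rep(1, 3))
}

run_histories_R <- function(geom, params, energy, n, seed) {
  cfg <- fano_source_config(energy, geom$source_box, seed = seed)
  em <- sample_emission(geom, cfg, n)
  dep <- matrix(0, n, length(geom$ids), dimnames = list(NULL, geom$ids))
  for (i in seq_len(n)) {
    dep[i, ] <- transport_history(em[i, ], geom, params, energy)
  }
  dep
}
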