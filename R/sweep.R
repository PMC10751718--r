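# Orchestration of the step-size studies: a grid over fixtures, energies,
# magnetic step-size fractions and field magnitudes, with per-cell Fano
# results collected into one long table plus a compact report.

#' Specify a Fano sweep
#'
#' @param fixture Fixture name (see [fixture_geometry()]) or a
#'   `fano_geometry`.
#' @param energies Initial electron energies in MeV.
#' @param em_estepe Grid of magnetic step-size fractions in `(0, 1]`.
#' @param B_magnitudes Field magnitudes in tesla (applied along x).
#' @param histories Histories per grid cell.
#' @param base_seed Base seed; each cell derives its own seed from it by a
#'   fixed rule, so cells are independent and can run in any order.
#' @param estepe,ecut Shared transport parameters.
#' @param expectation Expectation convention, see [fano_test()].
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(fixture = "slab", energies = c(0.1, 1, 6),
                       em_estepe = c(0.25, 0.1, 0.05, 0.025, 0.01, 0.005),
                       B_magnitudes = c(0, 1.5), histories = 1e5,
                       base_seed = 1L, estepe = 0.25, ecut = 1e-3,
                       expectation = "realized") {
  stopifnot(all(em_estepe > 0), all(em_estepe <= 1), all(energies > ecut))
  structure(list(fixture = fixture, energies = energies,
                 em_estepe = em_estepe, B_magnitudes = B_magnitudes,
                 histories = histories, base_seed = as.integer(base_seed),
                 estepe = estepe, ecut = ecut, expectation = expectation),
            class = "sweep_spec")
}

# deterministic per-cell seed derivation (kept below 2^31)
.cell_seed <- function(base_seed, cell_index) {
  (as.double(base_seed) * 2654435761 + 104729 * as.double(cell_index)) %%
    2147483629
}

# phantom / source-box sizing per energy: electrons above 1 MeV have ranges
# of several cm, which needs the larger phantom and emission volume
.sizes_for_energy <- function(energy) {
  if (energy > 1) {
    list(phantom = c(20, 20, 20), source_box = c(9, 9, 10))
  } else {
    list(phantom = NULL, source_box = NULL)  # fixture defaults
  }
}

#' Run a Fano sweep
#'
#' Executes [fano_test()] for every grid cell; cells are deterministic
#' given the base seed and mutually independent. Any cell failing the
#' energy-conservation or escape check aborts the sweep with diagnostics.
#'
#' @param spec A [sweep_spec()].
#' @param verbose Print one line per completed cell.
#' @return A long-format data.frame: one row per region per cell, with
#'   cell metadata columns (`energy`, `em_estepe`, `B`, `histories`,
#'   `seed`, `cell`) plus all `fano_result` columns; per-cell efficiency
#'   and wall time in columns `efficiency` and `wall_time_hours`.
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(energy = spec$energies, em_estepe = spec$em_estepe,
                      B = spec$B_magnitudes, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sz <- .sizes_for_energy(g$energy)
    geom <- if (inherits(spec$fixture, "fano_geometry")) spec$fixture
            else fixture_geometry(spec$fixture, phantom = sz$phantom,
                                  source_box = sz$source_box)
    seed <- .cell_seed(spec$base_seed, i)
    res <- fano_test(geom, energy = g$energy, n_histories = spec$histories,
                     B = g$B, em_estepe = g$em_estepe, estepe = spec$estepe,
                     ecut = spec$ecut, seed = seed,
                     expectation = spec$expectation)
    meta <- attr(res, "meta")
    if (meta$escapes > 0) {
      stop(sprintf("cell %d (E=%g, em_estepe=%g, B=%g): %d escaped histories",
                   i, g$energy, g$em_estepe, g$B, meta$escapes))
    }
    if (meta$conservation_error > 1e-9) {
      stop(sprintf("cell %d: energy conservation violated (%.3e)",
                   i, meta$conservation_error))
    }
    df <- as.data.frame(res)
    attr(df, "meta") <- NULL
    df$energy <- g$energy; df$em_estepe <- g$em_estepe; df$B <- g$B
    df$histories <- spec$histories; df$seed <- seed; df$cell <- i
    df$wall_time_hours <- meta$wall_time_hours
    df$efficiency <- if (is.null(meta$efficiency)) NA_real_ else meta$efficiency
    out[[i]] <- df
    if (verbose) {
      h <- fano_headline(res)
      message(sprintf(
        "cell %d/%d E=%g MeV f=%g B=%g T: max|delta| %.3f%% (region %s)",
        i, nrow(grid), g$energy, g$em_estepe, g$B,
        h$max_abs_deviation_percent, h$argmax_name))
    }
  }
  do.call(rbind, out)
}

#' Summarise a sweep into a per-cell report
#'
#' @param results Long table from [run_sweep()].
#' @param sensitive Region ids of the sensitive volume (defaults to the
#'   per-row `pass`-independent fixture annotation when present in
#'   `results`; otherwise supply explicitly).
#' @param k Guard multiplier of the pass rule.
#' @return A data.frame with one row per cell: `energy`, `em_estepe`, `B`,
#'   max significant and max absolute deviation (percent), the argmax
#'   region and whether it is the sensitive volume, the number of failing
#'   regions, and the cell efficiency.
#' @export
sweep_report <- function(results, sensitive = NULL, k = 2) {
  cells <- unique(results$cell)
  rows <- lapply(cells, function(ci) {
    d <- results[results$cell == ci & results$testable %in% TRUE, ]
    excess <- pmax(0, abs(d$delta_rel) - k * d$sigma_dev)
    i <- which.max(abs(d$delta_rel))
    data.frame(
      cell = ci, energy = d$energy[1], em_estepe = d$em_estepe[1],
      B = d$B[1],
      max_significant_deviation_percent = 100 * max(excess),
      max_abs_deviation_percent = 100 * abs(d$delta_rel[i]),
      argmax_region = d$region_id[i], argmax_name = d$name[i],
      sensitive_is_argmax = if (is.null(sensitive)) NA else
        d$region_id[i] %in% sensitive,
      n_fail = sum(!d$pass), n_testable = nrow(d),
      efficiency = d$efficiency[1]
    )
  })
  do.call(rbind, rows)
}

#' Plot per-region deviations of one or more Fano results
#'
#' Base-graphics convenience plot: deviation (percent) against region id
#' with `k`-sigma error bars, one series per cell.
#'
#' @param results A `fano_result` or a long table from [run_sweep()].
#' @param k Error-bar multiplier.
#' @param ... Passed to [plot()].
#' @return Invisibly `NULL`.
#' @export
plot_deviation <- function(results, k = 2, ...) {
  df <- as.data.frame(results)
  if (is.null(df$cell)) df$cell <- 1
  df <- df[df$testable %in% TRUE, ]
  ylim <- range(c(100 * (df$delta_rel - k * df$sigma_dev),
                  100 * (df$delta_rel + k * df$sigma_dev)))
  cells <- unique(df$cell)
  cols <- seq_along(cells)
  plot(NA, xlim = range(df$region_id), ylim = ylim,
       xlab = "region id", ylab = "deviation from Fano dose [%]", ...)
  abline(h = 0, lty = 2, col = "grey50")
  for (j in seq_along(cells)) {
    d <- df[df$cell == cells[j], ]
    off <- (j - (length(cells) + 1) / 2) * 0.06
    points(d$region_id + off, 100 * d$delta_rel, col = cols[j], pch = 19)
    arrows(d$region_id + off, 100 * (d$delta_rel - k * d$sigma_dev),
           d$region_id + off, 100 * (d$delta_rel + k * d$sigma_dev),
           angle = 90, code = 3, length = 0.02, col = cols[j])
  }
  invisible(NULL)
}
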