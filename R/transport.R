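# The condensed-history stepping engine. Each step: pick the step length
# (geometry chord, fractional-energy-loss limit ESTEPE, magnetic limit
# EM ESTEPE), deposit the continuous-slowing-down energy loss in the
# current region, advance along the straight pre-step chord, rotate the
# direction in the field, apply a Gaussian multiple-scattering deflection,
# relocate across boundaries, and terminate below the cutoff.
#
# The functions in this file are the plain-R reference implementation used
# by the oracle tests; production runs go through the compiled engine via
# run_transport(), which executes the identical algorithm.

#' Transport parameters for the condensed-history stepper
#'
#' @param em_estepe Maximum step length as a fraction of the local
#'   gyroradius, in `(0, 1]`. Only active with a nonzero field.
#' @param estepe Maximum fractional energy loss per step, in `(0, 1)`.
#' @param ecut Kinetic-energy transport cutoff in MeV; sub-cutoff energy is
#'   deposited locally.
#' @param B_field Magnetic field 3-vector in tesla (the package convention
#'   puts the field along x, perpendicular to the detector axis z).
#' @param boundary_nudge Distance in cm by which a particle landing on a
#'   surface is pushed along its post-deflection direction before
#'   relocation (deterministic tie-breaking).
#' @param disable_scatter Turn off multiple scattering (oracle runs).
#' @param sp_scale Global scale factor on the stopping power; Fano
#'   consistency must hold for any strictly positive value, which the test
#'   suite exercises with `sp_scale = 2`.
#' @param first_order Use the first-order direction update instead of the
#'   exact transverse rotation (comparison studies).
#' @param max_steps Step-count circuit breaker per history.
#' @return A `transport_params` list.
#' @export
transport_params <- function(em_estepe = 0.25, estepe = 0.25, ecut = 1e-3,
                             B_field = c(0, 0, 0), boundary_nudge = 1e-8,
                             disable_scatter = FALSE, sp_scale = 1,
                             first_order = FALSE, max_steps = 1e7) {
  stopifnot(em_estepe > 0, em_estepe <= 1, estepe > 0, estepe < 1,
            ecut > 0, sp_scale > 0, length(B_field) == 3)
  structure(list(em_estepe = em_estepe, estepe = estepe, ecut = ecut,
                 B_field = as.numeric(B_field),
                 boundary_nudge = boundary_nudge,
                 disable_scatter = disable_scatter, sp_scale = sp_scale,
                 first_order = first_order, max_steps = max_steps),
            class = "transport_params")
}

#' Electron in flight
#'
#' @param position Position in cm (3-vector).
#' @param direction Unit direction.
#' @param kinetic_energy Kinetic energy in MeV.
#' @param region_id Region id of the current position (located if missing).
#' @param geom Geometry, used to locate the region if `region_id` missing.
#' @return An `electron_state` list with an `alive` flag.
#' @export
electron_state <- function(position, direction, kinetic_energy,
                           region_id = NULL, geom = NULL) {
  direction <- as.numeric(direction)
  direction <- direction / sqrt(sum(direction^2))
  if (is.null(region_id)) {
    if (is.null(geom)) stop("either region_id or geom must be given")
    region_id <- locate(geom, position)
  }
  structure(list(position = as.numeric(position), direction = direction,
                 kinetic_energy = kinetic_energy,
                 region_id = as.integer(region_id), alive = TRUE),
            class = "electron_state")
}

#' Propose the next condensed-history step length
#'
#' The step is the minimum of the geometric chord to the nearest surface,
#' the energy-loss limit `estepe * T / (S(T) * rho)` and the magnetic limit
#' `em_estepe * r_G`.
#'
#' @param state An `electron_state`.
#' @param geom A `fano_geometry`.
#' @param params A [transport_params()].
#' @return A list with `length` (cm) and `limiter` (one of `"geometry"`,
#'   `"energy"`, `"field"`).
#' @export
propose_step <- function(state, geom, params) {
  stopifnot(state$alive, state$kinetic_energy > params$ecut)
  rho <- geom$density[match(state$region_id, geom$ids)]
  s_geo <- chord_distance(geom, state$position, state$direction)
  S <- params$sp_scale * collision_stopping_power(state$kinetic_energy)
  s_E <- params$estepe * state$kinetic_energy / (S * rho)
  s_B <- max_em_step(state$kinetic_energy, params$B_field, state$direction,
                     params$em_estepe)
  len <- s_geo; limiter <- "geometry"
  if (s_E < len) { len <- s_E; limiter <- "energy" }
  if (s_B < len) { len <- s_B; limiter <- "field" }
  list(length = len, limiter = limiter)
}

#' Execute one condensed-history step
#'
#' In order: step-length selection; advance to a uniformly random hinge
#' point where the magnetic rotation and the variance-additive Gaussian
#' scattering deflection are applied; geometry-checked advance of the
#' remainder along the new direction; exact CSDA energy loss over the
#' traversed mass thickness (range-map based) deposited in the current
#' region; boundary nudge and relocation; termination below the cutoff
#' with local absorption of the remainder. With scattering disabled the
#' step is a single deterministic segment with deflection at the end.
#' Uses R's RNG for the hinge fraction and scattering angles.
#'
#' @inheritParams propose_step
#' @return A list with the new `state` and `deposits`, a data.frame of
#'   `(region_id, energy)` rows booked during the step.
#' @export
do_step <- function(state, geom, params) {
  prop <- propose_step(state, geom, params)
  s <- prop$length
  rho <- geom$density[match(state$region_id, geom$ids)]
  T0 <- state$kinetic_energy
  geom_end <- prop$limiter == "geometry"

  if (params$disable_scatter) {
    # single straight segment, deflections at the end (deterministic)
    pos <- state$position + s * state$direction
    u <- magnetic_deflection(state$direction, params$B_field, s, T0,
                             first_order = params$first_order)
    s_tot <- s
  } else {
    # random hinge for the scattering deflection: advance a uniform
    # fraction of the step, scatter there, finish the remainder along the
    # new direction with a geometry re-check. Reproduces the lateral and
    # longitudinal scattering moments that end-of-step deflection misses;
    # the magnetic rotation stays a single end-of-step update (see below).
    xi <- runif(1)
    s1 <- xi * s
    pos <- state$position + s1 * state$direction
    u <- state$direction
    # variance-additive scattering: sub-rotations whose width is adjusted
    # so E[cos(theta)] composes exactly as exp(-v) (see the engine notes)
    v <- scattering_power(T0) * rho * s
    if (v > 0) {
      m <- 1 + floor(v / 0.05)
      w <- v / m
      sigma <- sqrt(0.5 * (3 - sqrt(9 - 12 * (1 - exp(-w)))))
      for (i in seq_len(m)) {
        theta <- min(sigma * sqrt(-2 * log(runif(1))), pi)
        phi <- runif(1, 0, 2 * pi)
        e1 <- if (abs(u[3]) < 0.99) c(-u[2], u[1], 0) else c(0, -u[3], u[2])
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
                u[1] * e1[2] - u[2] * e1[1])
        u <- cos(theta) * u + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
        u <- u / sqrt(sum(u^2))
      }
    }
    s2 <- (1 - xi) * s
    if (s2 > 0) {
      cap <- chord_distance(geom, pos, u)
      geom_end <- FALSE
      if (cap <= s2) { s2 <- cap; geom_end <- TRUE }
      pos <- pos + s2 * u
    }
    s_tot <- s1 + s2
    # single end-of-step magnetic rotation over the traversed path: the
    # straight-chord field approximation whose curvature resolution the
    # em_estepe restriction controls
    u <- magnetic_deflection(u, params$B_field, s_tot, T0,
                             first_order = params$first_order)
  }

  # exact CSDA loss over the traversed mass thickness through the range
  # map; sp_scale compresses the range (equivalent to scaling S)
  res_range <- csda_range(T0) - params$sp_scale * rho * s_tot
  T_after <- if (res_range <= 0) 1e-4 else .inv_csda_range(res_range)
  dE <- min(max(T0 - T_after, 0), T0)
  deposits <- data.frame(region_id = state$region_id, energy = dE)

  T1 <- T0 - dE
  region <- state$region_id
  alive <- TRUE
  # relocate after any boundary contact: hinge segment ended on a surface,
  # or the proposed step was geometry-limited (incl. exit-floor steps)
  if (geom_end || prop$limiter == "geometry") {
    pos <- pos + params$boundary_nudge * u
    if (any(abs(pos) > geom$phantom / 2 + .geom_tol)) {
      # escaped the phantom: absorb the remainder in the last region
      deposits <- rbind(deposits, data.frame(region_id = region, energy = T1))
      attr(deposits, "escaped") <- TRUE
      T1 <- 0; alive <- FALSE
    } else {
      region <- locate(geom, pos)
    }
  }
  if (alive && T1 <= params$ecut) {
    deposits <- rbind(deposits, data.frame(region_id = region, energy = T1))
    T1 <- 0; alive <- FALSE
  }
  new_state <- state
  new_state$position <- pos
  new_state$direction <- u
  new_state$kinetic_energy <- T1
  new_state$region_id <- region
  new_state$alive <- alive
  list(state = new_state, deposits = deposits, limiter = prop$limiter,
       length = s_tot)
}

#' Transport one history to completion (reference implementation)
#'
#' @param emission A list or one-row data.frame with `x, y, z, ux, uy, uz`
#'   and optionally `region_id` (as produced by [sample_emission()]).
#' @param geom A `fano_geometry`.
#' @param params A [transport_params()].
#' @param energy Initial kinetic energy in MeV.
#' @return Named numeric vector: deposited energy (MeV) per region id.
#'   The entries sum to `energy` up to accumulation precision.
#' @export
transport_history <- function(emission, geom, params, energy) {
  state <- electron_state(c(emission$x, emission$y, emission$z),
                          c(emission$ux, emission$uy, emission$uz),
                          energy,
                          region_id = emission$region_id, geom = geom)
  dep <- setNames(numeric(length(geom$ids)), geom$ids)
  nstep <- 0
  while (state$alive) {
    res <- do_step(state, geom, params)
    state <- res$state
    for (i in seq_len(nrow(res$deposits))) {
      id <- as.character(res$deposits$region_id[i])
      dep[id] <- dep[id] + res$deposits$energy[i]
    }
    nstep <- nstep + 1
    if (nstep > params$max_steps) {
      stop("step-count circuit breaker tripped in transport_history")
    }
  }
  dep
}

#' Run a full Fano transport calculation (compiled engine)
#'
#' Samples `n_histories` emissions from the Fano source and transports each
#' to completion, accumulating per-region emission counts, deposits and
#' history-by-history variance sums. Each history uses its own RNG
#' sub-stream derived from `seed` by a fixed splitting rule, so results do
#' not depend on batching or execution order.
#'
#' @param geom A `fano_geometry`.
#' @param energy Initial kinetic energy `E0` in MeV.
#' @param n_histories Number of primary histories.
#' @param params A [transport_params()].
#' @param seed Integer seed for the run.
#' @param source_box Full source-box dimensions in cm; defaults to the
#'   geometry's recommended box.
#' @return A `fano_tally` list: per-region vectors `n_emitted`,
#'   `sum_deposit`, `sum_deposit_sq`, `sum_excess`, `sum_excess_sq` (the
#'   excess is the per-history deposit minus `E0` times the emission
#'   indicator, the accumulator behind the deviation uncertainty), plus
#'   step/limiter statistics, escape counter, conservation diagnostics and
#'   the wall time in hours.
#' @export
run_transport <- function(geom, energy, n_histories, params = transport_params(),
                          seed = 1L, source_box = NULL) {
  if (is.null(source_box)) source_box <- geom$source_box
  if (is.null(source_box)) stop("no source box given and none in geometry")
  source_box <- as.numeric(source_box)
  if (any(source_box > geom$phantom + 1e-12)) {
    stop("source box extends outside the phantom")
  }
  rho_max <- .rho_max_in_box(geom, source_box)
  t0 <- proc.time()[["elapsed"]]
  raw <- .engine_run(.geom_matrix(geom), geom$phantom / 2, energy,
                     source_box / 2, rho_max, params$B_field,
                     params$em_estepe, params$estepe, params$ecut,
                     n_histories, seed,
                     params$disable_scatter, params$sp_scale,
                     params$first_order, params$max_steps)
  wall_h <- (proc.time()[["elapsed"]] - t0) / 3600
  names(raw$n_emitted) <- names(raw$sum_deposit) <- names(raw$sum_deposit_sq) <-
    names(raw$sum_excess) <- names(raw$sum_excess_sq) <- as.character(geom$ids)
  structure(c(raw, list(
    energy = energy, seed = as.integer(seed), source_box = source_box,
    params = params, geometry_name = geom$name, wall_time_hours = wall_h
  )), class = "fano_tally")
}

#' @export
print.fano_tally <- function(x, ...) {
  cat(sprintf(
    "<fano_tally> %s: %.3g histories of %.4g MeV, %d escapes, conservation %.2e\n",
    x$geometry_name, x$histories, x$energy, x$escapes,
    x$max_history_conservation_error))
  lims <- x$steps_by_limiter / sum(x$steps_by_limiter)
  cat(sprintf("  steps: %.3g (geometry %.1f%% | energy %.1f%% | field %.1f%%)\n",
              sum(x$steps_by_limiter), 100 * lims[1], 100 * lims[2],
              100 * lims[3]))
  invisible(x)
}
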