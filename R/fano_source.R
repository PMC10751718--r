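# The Fano radiation source: monoenergetic electrons emitted with position
# density proportional to the local mass density and isotropic direction,
# inside a source box centred on the detector. With such a source the
# charged-particle fluence is independent of the density distribution even
# in a uniform external magnetic field, so the absorbed dose in region i
# has the closed form D_i = n_i * E0 / m_i.

#' Fano source configuration
#'
#' @param energy Initial kinetic energy `E0` in MeV (monoenergetic;
#'   must exceed the transport cutoff).
#' @param source_box Full dimensions of the emission box in cm (3-vector,
#'   centred at the origin; must lie inside the phantom).
#' @param seed Integer RNG seed.
#' @return A `fano_source_config` list.
#' @export
fano_source_config <- function(energy, source_box, seed = 1L) {
  stopifnot(energy > 1e-3, length(source_box) == 3, all(source_box > 0))
  structure(list(energy = energy, source_box = as.numeric(source_box),
                 seed = as.integer(seed)),
            class = "fano_source_config")
}

# density of regions whose bounding box intersects the source box; the
# rejection sampler needs their maximum
.rho_max_in_box <- function(geom, source_box) {
  half <- source_box / 2
  rho <- geom$density[1]
  for (j in seq_along(geom$regions)[-1]) {
    bb <- .aabb(geom$regions[[j]])
    if (all(bb$lo < half) && all(bb$hi > -half)) {
      rho <- max(rho, geom$density[j])
    }
  }
  if (rho <= 0) stop("maximum density in the source box is not positive")
  rho
}

#' Sample emissions from the Fano source
#'
#' Positions are drawn by rejection sampling (uniform proposal over the
#' source box, accepted with probability `rho(x) / rho_max`), which realises
#' the density-proportional emission law pointwise without precomputing
#' box-region intersection volumes; directions are isotropic (uniform
#' cosine of the polar angle, uniform azimuth). Uses R's RNG; the compiled
#' transport engine contains an independent implementation of the same
#' sampler with its own per-history sub-streams.
#'
#' @param geom A `fano_geometry`.
#' @param config A [fano_source_config()].
#' @param n Number of emissions to draw.
#' @return A data.frame with columns `x, y, z` (cm), `ux, uy, uz` and
#'   `region_id`; the per-region emission counts are attached as attribute
#'   `n_emitted` (a named vector over all region ids).
#' @export
sample_emission <- function(geom, config, n) {
  stopifnot(inherits(config, "fano_source_config"), n >= 1)
  half <- config$source_box / 2
  if (any(half > geom$phantom / 2 + 1e-12)) {
    stop("source box extends outside the phantom")
  }
  set.seed(config$seed)
  rho_max <- .rho_max_in_box(geom, config$source_box)
  pos <- matrix(NA_real_, n, 3)
  reg <- integer(n)
  got <- 0L
  while (got < n) {
    m <- max(1000L, ceiling((n - got) / 0.9 * rho_max / mean(geom$density)))
    m <- min(m, 10L * (n - got) + 1000L)
    cand <- cbind(runif(m, -half[1], half[1]),
                  runif(m, -half[2], half[2]),
                  runif(m, -half[3], half[3]))
    r <- apply(cand, 1, function(p) locate(geom, p))
    rho <- geom$density[match(r, geom$ids)]
    keep <- runif(m) < rho / rho_max
    k <- which(keep)
    if (length(k)) {
      take <- k[seq_len(min(length(k), n - got))]
      idx <- got + seq_along(take)
      pos[idx, ] <- cand[take, , drop = FALSE]
      reg[idx] <- r[take]
      got <- got + length(take)
    }
  }
  cz <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  sxy <- sqrt(pmax(0, 1 - cz^2))
  out <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    ux = sxy * cos(phi), uy = sxy * sin(phi), uz = cz,
                    region_id = reg)
  counts <- table(factor(reg, levels = geom$ids))
  attr(out, "n_emitted") <- setNames(as.numeric(counts), names(counts))
  out
}
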