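# Analytic multi-region geometry: a box phantom containing nested
# axis-aligned boxes and z-axis finite cylinders, each with its own mass
# density. Later-listed regions carve volume out of earlier ones
# ("last-listed wins"), which is the simplest unambiguous tiling for nested
# detector shapes. The detector symmetry axis is z and the magnetic field
# is conventionally applied along x (perpendicular to the detector axis);
# the origin sits at the centre of the sensitive volume.

.geom_tol <- 1e-10   # points within this distance of a surface resolve to
                     # the higher-priority region

#' Construct a box region
#'
#' @param id Small non-negative integer region id (unique within a geometry).
#' @param name Human-readable region name.
#' @param center Centre of the box in cm (3-vector).
#' @param size Full edge lengths in cm (3-vector).
#' @param density Mass density in g/cm^3 (`> 0`).
#' @return A `fano_region` list.
#' @export
region_box <- function(id, name, center, size, density) {
  stopifnot(id >= 0, density > 0, all(size > 0))
  structure(list(id = as.integer(id), name = name, shape = "box",
                 center = as.numeric(center), size = as.numeric(size),
                 density = density),
            class = "fano_region")
}

#' Construct a finite-cylinder region (axis along z)
#'
#' @inheritParams region_box
#' @param radius Cylinder radius in cm.
#' @param half_height Half of the cylinder height in cm.
#' @return A `fano_region` list.
#' @export
region_cylinder <- function(id, name, center, radius, half_height, density) {
  stopifnot(id >= 0, density > 0, radius > 0, half_height > 0)
  structure(list(id = as.integer(id), name = name, shape = "cylinder",
                 center = as.numeric(center), radius = radius,
                 half_height = half_height, density = density),
            class = "fano_region")
}

.gross_volume <- function(r) {
  if (r$shape == "box") prod(r$size) else pi * r$radius^2 * 2 * r$half_height
}

.aabb <- function(r) {
  if (r$shape == "box") {
    list(lo = r$center - r$size / 2, hi = r$center + r$size / 2)
  } else {
    list(lo = r$center + c(-r$radius, -r$radius, -r$half_height),
         hi = r$center + c(r$radius, r$radius, r$half_height))
  }
}

# exact shape-in-shape containment for axis-aligned boxes / z-cylinders
.contains_shape <- function(a, b, tol = 1e-9) {
  ba <- .aabb(a); bb <- .aabb(b)
  if (a$shape == "box") {
    all(bb$lo >= ba$lo - tol) && all(bb$hi <= ba$hi + tol)
  } else if (b$shape == "cylinder") {       # cylinder in cylinder
    dxy <- sqrt(sum((a$center[1:2] - b$center[1:2])^2))
    dxy + b$radius <= a$radius + tol &&
      bb$lo[3] >= ba$lo[3] - tol && bb$hi[3] <= ba$hi[3] + tol
  } else {                                  # box in cylinder
    hx <- b$size[1] / 2; hy <- b$size[2] / 2
    corner <- sqrt((abs(b$center[1] - a$center[1]) + hx)^2 +
                   (abs(b$center[2] - a$center[2]) + hy)^2)
    corner <= a$radius + tol &&
      bb$lo[3] >= ba$lo[3] - tol && bb$hi[3] <= ba$hi[3] + tol
  }
}

# provable disjointness of two shapes (interiors); used for sibling checks
.disjoint_shape <- function(a, b, tol = 1e-9) {
  ba <- .aabb(a); bb <- .aabb(b)
  if (any(ba$hi <= bb$lo + tol) || any(bb$hi <= ba$lo + tol)) return(TRUE)
  if (a$shape == "cylinder" && b$shape == "cylinder") {
    dxy <- sqrt(sum((a$center[1:2] - b$center[1:2])^2))
    return(dxy >= a$radius + b$radius - tol)
  }
  if (a$shape != b$shape) {
    cyl <- if (a$shape == "cylinder") a else b
    box <- if (a$shape == "cylinder") b else a
    dx <- max(abs(cyl$center[1] - box$center[1]) - box$size[1] / 2, 0)
    dy <- max(abs(cyl$center[2] - box$center[2]) - box$size[2] / 2, 0)
    return(sqrt(dx^2 + dy^2) >= cyl$radius - tol)
  }
  FALSE
}

#' Assemble and validate a multi-region geometry
#'
#' The first region must be a box coinciding with the phantom (the base
#' water region); every later region must be fully contained in some
#' earlier region and carves its volume out of the innermost such parent.
#' Sibling regions sharing a parent must be disjoint. Net volumes are
#' computed in closed form (gross volume minus the gross volumes of direct
#' children), so the regions tile the phantom exactly.
#'
#' @param phantom Full phantom box dimensions in cm (3-vector, centred at
#'   the origin).
#' @param regions List of `fano_region` objects in carve-out priority order
#'   (later entries carve out earlier ones).
#' @param name Optional geometry name.
#' @param source_box Recommended Fano source-box full dimensions in cm.
#' @param sensitive Integer ids of the sensitive-volume region(s).
#' @return A `fano_geometry` object with per-region net volumes and masses.
#' @export
geometry <- function(phantom, regions, name = "geometry",
                     source_box = NULL, sensitive = integer()) {
  phantom <- as.numeric(phantom)
  stopifnot(length(phantom) == 3, all(phantom > 0), length(regions) >= 1)
  ids <- vapply(regions, function(r) r$id, integer(1))
  if (anyDuplicated(ids)) stop("region ids must be unique")
  base <- regions[[1]]
  if (base$shape != "box" || any(abs(base$size - phantom) > 1e-9) ||
      any(abs(base$center) > 1e-9)) {
    stop("the first region must be a box coinciding with the phantom")
  }
  n <- length(regions)
  parent <- rep(NA_integer_, n)
  if (n > 1) {
    for (j in 2:n) {
      for (i in (j - 1):1) {
        if (.contains_shape(regions[[i]], regions[[j]])) { parent[j] <- i; break }
      }
      if (is.na(parent[j])) {
        stop(sprintf("region %d is not contained in any earlier region", ids[j]))
      }
    }
    # siblings must be provably disjoint
    for (j in 2:n) for (k in seq_len(j - 1)[-1]) {
      if (!is.na(parent[j]) && parent[j] == parent[k] &&
          !.disjoint_shape(regions[[j]], regions[[k]])) {
        stop(sprintf("overlapping same-priority regions %d and %d",
                     ids[j], ids[k]))
      }
    }
  }
  gross <- vapply(regions, .gross_volume, numeric(1))
  net <- gross
  if (n > 1) for (j in 2:n) net[parent[j]] <- net[parent[j]] - gross[j]
  if (any(net <= 0)) stop("a region has non-positive net volume")
  dens <- vapply(regions, function(r) r$density, numeric(1))
  structure(list(
    name = name, phantom = phantom, regions = regions, ids = ids,
    parent = parent, volume = net, density = dens, mass = net * dens,
    source_box = if (is.null(source_box)) NULL else as.numeric(source_box),
    sensitive = as.integer(sensitive)
  ), class = "fano_geometry")
}

#' @export
print.fano_geometry <- function(x, ...) {
  cat(sprintf("<fano_geometry> %s: phantom %.4g x %.4g x %.4g cm, %d regions\n",
              x$name, x$phantom[1], x$phantom[2], x$phantom[3],
              length(x$regions)))
  print(region_masses(x), row.names = FALSE)
  invisible(x)
}

.inside_shape <- function(r, p, tol = .geom_tol) {
  if (r$shape == "box") {
    all(abs(p - r$center) <= r$size / 2 + tol)
  } else {
    abs(p[3] - r$center[3]) <= r$half_height + tol &&
      (p[1] - r$center[1])^2 + (p[2] - r$center[2])^2 <= (r$radius + tol)^2
  }
}

#' Locate the region containing a point
#'
#' Deterministic point location using the carve-out priority order: regions
#' are scanned from the last-listed (highest priority) down, and points
#' within `1e-10` cm of a surface resolve to the higher-priority region.
#'
#' @param geom A `fano_geometry`.
#' @param point Position in cm (3-vector), inside the phantom.
#' @return The region id (integer).
#' @export
locate <- function(geom, point) {
  point <- as.numeric(point)
  if (any(abs(point) > geom$phantom / 2 + .geom_tol)) {
    stop("point lies outside the phantom")
  }
  for (j in rev(seq_along(geom$regions))) {
    if (.inside_shape(geom$regions[[j]], point)) return(geom$ids[j])
  }
  geom$ids[1]
}

# exit distance from the tolerance-expanded shape along a ray (point
# assumed inside the expanded shape); floored so progress is always made
.exit_expanded <- function(r, p, u, tol = 1e-9) {
  t <- Inf
  if (r$shape == "box") {
    h <- r$size / 2 + tol
    for (ax in 1:3) {
      if (abs(u[ax]) < 1e-14) next
      face <- r$center[ax] + if (u[ax] > 0) h[ax] else -h[ax]
      t <- min(t, (face - p[ax]) / u[ax])
    }
  } else {
    if (abs(u[3]) > 1e-14) {
      face <- r$center[3] + if (u[3] > 0) r$half_height + tol else
        -(r$half_height + tol)
      t <- min(t, (face - p[3]) / u[3])
    }
    a <- u[1]^2 + u[2]^2
    if (a > 1e-28) {
      dx <- p[1] - r$center[1]; dy <- p[2] - r$center[2]
      R <- r$radius + tol
      b <- dx * u[1] + dy * u[2]
      disc <- b^2 - a * (dx^2 + dy^2 - R^2)
      if (disc > 0) t <- min(t, (-b + sqrt(disc)) / a)
    }
  }
  max(t, 2e-10)
}

# candidate boundary-crossing distances of one shape along a ray
.shape_crossings <- function(r, p, u, eps = 1e-10) {
  ts <- numeric(0)
  if (r$shape == "box") {
    lo <- r$center - r$size / 2; hi <- r$center + r$size / 2
    for (ax in 1:3) {
      if (abs(u[ax]) < 1e-14) next
      for (face in c(lo[ax], hi[ax])) {
        t <- (face - p[ax]) / u[ax]
        if (t <= eps) next
        q <- p + t * u
        oth <- setdiff(1:3, ax)
        if (all(q[oth] >= lo[oth] - 1e-9) && all(q[oth] <= hi[oth] + 1e-9)) {
          ts <- c(ts, t)
        }
      }
    }
  } else {
    zlo <- r$center[3] - r$half_height; zhi <- r$center[3] + r$half_height
    dx <- p[1] - r$center[1]; dy <- p[2] - r$center[2]
    a <- u[1]^2 + u[2]^2
    if (a > 1e-28) {
      b <- dx * u[1] + dy * u[2]
      cc <- dx^2 + dy^2 - r$radius^2
      disc <- b^2 - a * cc
      if (disc > 0) {
        sq <- sqrt(disc)
        for (t in c((-b - sq) / a, (-b + sq) / a)) {
          if (t > eps) {
            z <- p[3] + t * u[3]
            if (z >= zlo - 1e-9 && z <= zhi + 1e-9) ts <- c(ts, t)
          }
        }
      }
    }
    if (abs(u[3]) > 1e-14) {
      for (zface in c(zlo, zhi)) {
        t <- (zface - p[3]) / u[3]
        if (t > eps) {
          q <- p + t * u
          if ((q[1] - r$center[1])^2 + (q[2] - r$center[2])^2 <=
              (r$radius + 1e-9)^2) ts <- c(ts, t)
        }
      }
    }
  }
  ts
}

#' Straight-ray distance to the nearest region surface
#'
#' Exact distance along the straight ray from `point` in direction
#' `direction` to the nearest surface of any region (including surfaces of
#' higher-priority regions embedded in the current one) or of the phantom
#' itself. The returned distance never overestimates the chord of the
#' current region, so stepping by it can never tunnel through a boundary.
#'
#' @param geom A `fano_geometry`.
#' @param point Position in cm, inside the phantom.
#' @param direction Unit direction 3-vector.
#' @return Positive distance in cm.
#' @export
chord_distance <- function(geom, point, direction) {
  p <- as.numeric(point); u <- as.numeric(direction)
  half <- geom$phantom / 2
  # never outrun the shape of the region the point is located in: a point
  # sitting in the boundary skin of a shape could otherwise take a long
  # step at that region's density while geometrically outside it
  cur <- match(locate(geom, p), geom$ids)
  best <- if (cur > 1) .exit_expanded(geom$regions[[cur]], p, u) else Inf
  for (ax in 1:3) {        # phantom walls
    if (abs(u[ax]) < 1e-14) next
    for (face in c(-half[ax], half[ax])) {
      t <- (face - p[ax]) / u[ax]
      if (t > 1e-10 && t < best) best <- t
    }
  }
  for (r in geom$regions[-1]) {
    ts <- .shape_crossings(r, p, u)
    if (length(ts) && min(ts) < best) best <- min(ts)
  }
  best
}

#' Region volume and mass table
#'
#' Closed-form net volumes (after carve-outs) and masses of every region.
#' The volumes sum to the phantom volume exactly; these masses are the
#' denominators of the analytic Fano dose.
#'
#' @param geom A `fano_geometry`.
#' @return A data.frame with columns `region_id`, `name`, `density`
#'   (g/cm^3), `volume` (cm^3) and `mass` (g).
#' @export
region_masses <- function(geom) {
  data.frame(
    region_id = geom$ids,
    name = vapply(geom$regions, function(r) r$name, character(1)),
    density = geom$density,
    volume = geom$volume,
    mass = geom$mass
  )
}

#' Load a geometry from a YAML description
#'
#' The structured-text format is documented in
#' `system.file("extdata", "geometry-schema.md", package = "fanocavity")`.
#' All invariants (containment, sibling disjointness, tiling) are validated
#' on load.
#'
#' @param path Path to a YAML geometry file.
#' @param phantom Optional override of the phantom dimensions (cm); the
#'   base region is resized with it (used e.g. to enlarge the phantom for
#'   high-energy sources).
#' @param source_box Optional override of the recommended source-box
#'   dimensions (cm).
#' @return A `fano_geometry`.
#' @export
load_geometry <- function(path, phantom = NULL, source_box = NULL) {
  spec <- yaml::read_yaml(path)
  phan <- if (is.null(phantom)) as.numeric(spec$phantom) else as.numeric(phantom)
  regs <- lapply(spec$regions, function(r) {
    if (identical(r$shape, "box")) {
      size <- as.numeric(r$size)
      if (isTRUE(r$base)) size <- phan
      region_box(r$id, r$name, as.numeric(r$center), size, r$density)
    } else if (identical(r$shape, "cylinder")) {
      region_cylinder(r$id, r$name, as.numeric(r$center), r$radius,
                      r$half_height, r$density)
    } else stop("unknown shape: ", r$shape)
  })
  geometry(phan, regs, name = spec$name,
           source_box = if (is.null(source_box)) as.numeric(spec$source_box)
                        else as.numeric(source_box),
           sensitive = as.integer(spec$sensitive))
}

#' Built-in fixture geometries
#'
#' Three water-equivalent fixtures ship with the package (all media share
#' the water mass stopping power and differ only in density, as the Fano
#' substitution requires):
#' \describe{
#'   \item{`chamber_like`}{A simplified thimble ionization chamber: PMMA
#'     wall, graphite liner, a 0.07 cm^3 air cavity around a 0.04 cm radius
#'     aluminium electrode, and a PMMA stem containing three small air
#'     gaps. Nine regions in a 10 x 10 x 12 cm^3 water phantom.}
#'   \item{`diode_like`}{A simplified silicon diode: PMMA housing, epoxy
#'     body, a 3.4e-4 cm^3 silicon chip and one air gap; five regions.}
#'   \item{`slab`}{A three-layer sandwich (water / low-density gap / water)
#'     used as the oracle geometry for transport and Fano property tests.}
#' }
#'
#' @param name One of `"chamber_like"`, `"diode_like"`, `"slab"`.
#' @param ... Passed to [load_geometry()] (e.g. `phantom` override).
#' @return A `fano_geometry`.
#' @export
fixture_geometry <- function(name = c("chamber_like", "diode_like", "slab"),
                             ...) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "fanocavity")
  if (!nzchar(path)) stop("fixture file not found: ", name)
  load_geometry(path, ...)
}

# serialize a geometry for the compiled transport engine
.geom_matrix <- function(geom) {
  n <- length(geom$regions)
  m <- matrix(0, n, 8)
  for (j in seq_len(n)) {
    r <- geom$regions[[j]]
    if (r$shape == "box") {
      m[j, ] <- c(0, r$center, r$size / 2, r$density)
    } else {
      m[j, ] <- c(1, r$center, r$radius, r$half_height, 0, r$density)
    }
  }
  m
}
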