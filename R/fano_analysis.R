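# Per-region tallies to doses: the analytic Fano expectation
# D_i = n_i * E0 / m_i, the Monte Carlo dose with history-by-history
# type-A uncertainty, the relative deviation with its pass rule, and the
# efficiency figure of merit 1/(T * sigma^2).

#' Analytic Fano dose expectation
#'
#' Under Fano conditions (density-proportional isotropic source,
#' water-equivalent media) the absorbed dose in region `i` is
#' `n_i * E0 / m_i`, independent of the magnetic field strength.
#'
#' @param n_emitted Number of source particles emitted in the region.
#' @param energy_E0 Initial particle energy in MeV.
#' @param mass Region mass in g (`> 0`).
#' @return Expected dose in MeV/g; `0` for `n_emitted = 0`, in which case
#'   the region is flagged untestable downstream.
#' @export
expected_dose <- function(n_emitted, energy_E0, mass) {
  if (any(mass <= 0)) stop("mass must be > 0")
  n_emitted * energy_E0 / mass
}

#' Monte Carlo dose and history-by-history relative uncertainty
#'
#' `D_MC` is the total deposited energy divided by the region mass. The
#' relative type-A standard uncertainty uses the history-by-history
#' estimator: with per-history deposits `d_h`,
#' \deqn{\sigma_{rel} = \frac{\sqrt{(\sum d_h^2 - (\sum d_h)^2/N) /
#'   (N(N-1))}}{\sum d_h / N}.}
#'
#' @param sum_deposit Sum of per-history deposits in the region, MeV.
#' @param sum_deposit_sq Sum of squared per-history deposits, MeV^2.
#' @param histories Number of histories `N` (`>= 2`).
#' @param mass Region mass in g.
#' @return A list with `D_MC` (MeV/g) and `sigma_rel` (fraction; `NA` for
#'   a zero-deposit region, which is flagged downstream).
#' @export
mc_dose_and_sigma <- function(sum_deposit, sum_deposit_sq, histories, mass) {
  stopifnot(histories >= 2, all(mass > 0))
  var_sum <- pmax(0, sum_deposit_sq - sum_deposit^2 / histories)
  sigma_mean <- sqrt(var_sum / (histories * (histories - 1)))
  mean_dep <- sum_deposit / histories
  list(D_MC = sum_deposit / mass,
       sigma_rel = ifelse(mean_dep > 0, sigma_mean / mean_dep, NA_real_))
}

#' Relative deviation from the Fano expectation with pass rule
#'
#' Adds `delta_rel = D_MC / D_expected - 1` and a per-region pass flag
#' `|delta_rel| <= max(tolerance, k * sigma)` to a result table. Regions
#' with no emissions (zero expectation) or no deposit are marked
#' untestable and excluded from pass/fail.
#'
#' @param rows A data.frame with columns `D_MC`, `D_expected` and a
#'   statistical uncertainty column named by `sigma_col` (relative,
#'   fraction).
#' @param tolerance Absolute deviation tolerance (fraction; default 1e-3,
#'   the conventional 0.1% pass level of the Fano test).
#' @param k Statistical guard multiplier (default 2).
#' @param sigma_col Which uncertainty column guards the pass rule.
#' @return The input with `delta_rel`, `testable` and `pass` columns.
#' @export
fano_deviation <- function(rows, tolerance = 1e-3, k = 2,
                           sigma_col = "sigma_dev") {
  stopifnot(all(c("D_MC", "D_expected", sigma_col) %in% names(rows)))
  rows$delta_rel <- ifelse(rows$D_expected > 0,
                           rows$D_MC / rows$D_expected - 1, NA_real_)
  rows$testable <- rows$D_expected > 0 & is.finite(rows[[sigma_col]]) &
    rows$D_MC > 0
  guard <- pmax(tolerance, k * rows[[sigma_col]])
  rows$pass <- ifelse(rows$testable, abs(rows$delta_rel) <= guard, NA)
  rows
}

#' Monte Carlo efficiency figure of merit
#'
#' \eqn{\epsilon = 1/(T \sigma^2)} with the CPU time `T` in hours and the
#' type-A relative standard uncertainty `sigma` in percent (the
#' conventional unit pairing for reporting simulation efficiency).
#'
#' @param wall_time_hours CPU/wall time in hours (`> 0`).
#' @param sigma_rel_percent Relative standard uncertainty in percent
#'   (`> 0`).
#' @return Efficiency in 1/(h %^2).
#' @examples
#' efficiency(2656, 0.009)  # 4.65
#' @export
efficiency <- function(wall_time_hours, sigma_rel_percent) {
  stopifnot(wall_time_hours > 0, sigma_rel_percent > 0)
  1 / (wall_time_hours * sigma_rel_percent^2)
}

# expected emission weights rho_i * V(i intersect box) / sum_j ...
# requires every non-base region to lie fully inside the source box
.analytic_weights <- function(geom, source_box) {
  half <- source_box / 2
  w <- numeric(length(geom$ids))
  vol_in <- geom$volume
  for (j in seq_along(geom$regions)[-1]) {
    bb <- .aabb(geom$regions[[j]])
    if (!(all(bb$lo >= -half - 1e-9) && all(bb$hi <= half + 1e-9))) {
      stop("analytic expectation needs all detector regions inside the ",
           "source box; region ", geom$ids[j], " is not")
    }
  }
  vol_in[1] <- prod(source_box) - sum(vol_in[-1])
  w <- geom$density * vol_in
  w / sum(w)
}

#' Run the Fano cavity test on a geometry
#'
#' Runs the full pipeline — Fano source, condensed-history transport,
#' per-region tallies — and compares the Monte Carlo dose in every region
#' with the analytic expectation `n_i * E0 / m_i`.
#'
#' Two expectation conventions are available. `"realized"` (default) uses
#' the realised emission counts `n_i` of the run; its deviation
#' uncertainty `sigma_dev` comes from the history-by-history excess
#' accumulator `d_h - E0 * 1(emitted in i)`, which correctly folds the
#' correlation between the numerator and the realised counts (for large
#' self-absorbing regions most source noise cancels; for small regions fed
#' from outside the emission-count noise dominates). `"analytic"` uses the
#' expected counts `N * rho_i V_i / sum_j rho_j V_j` (all detector regions
#' must then lie inside the source box) and `sigma_dev` reduces to the
#' dose uncertainty.
#'
#' @param geom A `fano_geometry`.
#' @param energy Initial electron energy `E0` in MeV.
#' @param n_histories Number of primary histories.
#' @param B Magnetic field: a scalar magnitude (applied along x,
#'   perpendicular to the detector axis) or a 3-vector in tesla.
#' @param em_estepe,estepe,ecut Transport parameters, see
#'   [transport_params()].
#' @param seed Integer seed.
#' @param source_box Source-box dimensions (cm); default from the geometry.
#' @param expectation `"realized"` or `"analytic"` emission counts in the
#'   expectation (see Details).
#' @param tolerance,k Pass rule `|delta| <= max(tolerance, k * sigma_dev)`.
#' @param params Optionally a full [transport_params()] (overrides the
#'   individual transport arguments).
#' @return A `fano_result`: a per-region data.frame (`region_id`, `name`,
#'   `density`, `mass`, `n_emitted`, `D_expected`, `D_MC`, `sigma_rel`,
#'   `sigma_dev`, `delta_rel`, `testable`, `pass`) with run metadata in
#'   `attr(, "meta")` (config echo, conservation check, escape count,
#'   limiter statistics, wall time, efficiency of the sensitive volume).
#' @export
fano_test <- function(geom, energy, n_histories, B = 0, em_estepe = 0.25,
                      estepe = 0.25, ecut = 1e-3, seed = 1L,
                      source_box = NULL,
                      expectation = c("realized", "analytic"),
                      tolerance = 1e-3, k = 2, params = NULL) {
  expectation <- match.arg(expectation)
  if (length(B) == 1) B <- c(B, 0, 0)
  if (is.null(params)) {
    params <- transport_params(em_estepe = em_estepe, estepe = estepe,
                               ecut = ecut, B_field = B)
  }
  tally <- run_transport(geom, energy, n_histories, params, seed, source_box)
  result_from_tally(tally, geom, expectation = expectation,
                    tolerance = tolerance, k = k)
}

#' Assemble a Fano result table from a transport tally
#'
#' @param tally A `fano_tally` from [run_transport()].
#' @param geom The geometry the tally was run on.
#' @inheritParams fano_test
#' @return A `fano_result`, see [fano_test()].
#' @export
result_from_tally <- function(tally, geom,
                              expectation = c("realized", "analytic"),
                              tolerance = 1e-3, k = 2) {
  expectation <- match.arg(expectation)
  N <- tally$histories
  E0 <- tally$energy
  tab <- region_masses(geom)
  tab$n_emitted <- as.numeric(tally$n_emitted)
  n_exp <- if (expectation == "analytic") {
    N * .analytic_weights(geom, tally$source_box)
  } else tab$n_emitted
  tab$D_expected <- expected_dose(n_exp, E0, tab$mass)
  mc <- mc_dose_and_sigma(as.numeric(tally$sum_deposit),
                          as.numeric(tally$sum_deposit_sq), N, tab$mass)
  tab$D_MC <- mc$D_MC
  tab$sigma_rel <- mc$sigma_rel
  if (expectation == "realized") {
    # history-by-history sigma of the deviation via the excess accumulator
    sy <- as.numeric(tally$sum_excess)
    sy2 <- as.numeric(tally$sum_excess_sq)
    sd_sum <- sqrt(pmax(0, sy2 - sy^2 / N) * N / (N - 1))
    tab$sigma_dev <- ifelse(n_exp > 0, sd_sum / (n_exp * E0), NA_real_)
  } else {
    tab$sigma_dev <- tab$sigma_rel
  }
  tab <- fano_deviation(tab, tolerance = tolerance, k = k)
  meta <- list(
    geometry = geom$name, energy = E0, histories = N,
    B_field = tally$params$B_field, em_estepe = tally$params$em_estepe,
    estepe = tally$params$estepe, ecut = tally$params$ecut,
    seed = tally$seed, source_box = tally$source_box,
    expectation = expectation, tolerance = tolerance, k = k,
    escapes = tally$escapes,
    conservation_error = abs(tally$total_deposit - N * E0) / (N * E0),
    max_history_conservation_error = tally$max_history_conservation_error,
    steps_by_limiter = tally$steps_by_limiter,
    max_field_step_ratio = tally$max_field_step_ratio,
    wall_time_hours = tally$wall_time_hours,
    sensitive = geom$sensitive
  )
  sens <- match(geom$sensitive, tab$region_id)
  sens <- sens[!is.na(sens)]
  if (length(sens) && all(is.finite(tab$sigma_rel[sens])) &&
      tally$wall_time_hours > 0) {
    # root-sum-square combination of the absolute dose uncertainties
    sens_sigma_pct <- 100 * sqrt(sum((tab$sigma_rel[sens] *
                                        tab$D_MC[sens])^2)) /
      sum(tab$D_MC[sens])
    meta$sensitive_sigma_percent <- sens_sigma_pct
    meta$efficiency <- efficiency(tally$wall_time_hours, sens_sigma_pct)
  }
  structure(tab, meta = meta, class = c("fano_result", "data.frame"))
}

#' Headline deviation of a Fano result
#'
#' The scalar the Fano test reports: the largest statistically significant
#' relative deviation over the testable regions,
#' `max_i max(0, |delta_i| - z * sigma_dev,i)`, in percent. A region whose
#' deviation lies inside its guard band contributes zero — the test cannot
#' distinguish it from perfect agreement at the statistics used, so the
#' headline is a conservative lower bound on the true maximum deviation.
#'
#' With `family_wise = TRUE` the guard multiplier is widened from `k` to
#' the Sidak-corrected quantile for the number of testable regions, so the
#' family-wise false-alarm rate of the maximum equals the per-region rate
#' of a single `k`-sigma test. Taking a maximum over many noisy regions at
#' a fixed per-region guard would otherwise flag pure statistical noise in
#' roughly `m` times the per-region rate.
#'
#' @param result A `fano_result`.
#' @param k Guard multiplier (default 2, matching the per-region pass
#'   rule).
#' @param family_wise Correct the guard for the number of regions tested.
#' @return A list: `max_significant_deviation_percent`,
#'   `max_abs_deviation_percent`, `argmax_region` and `argmax_name` (region
#'   with the largest guarded excess, falling back to largest `|delta|`),
#'   `guard_multiplier`, `n_testable`, `all_pass`.
#' @export
fano_headline <- function(result, k = 2, family_wise = FALSE) {
  t <- result[result$testable %in% TRUE, ]
  if (!nrow(t)) stop("no testable regions in result")
  z <- if (family_wise) {
    stats::qnorm(1 - stats::pnorm(-k) / nrow(t))
  } else k
  excess <- pmax(0, abs(t$delta_rel) - z * t$sigma_dev)
  i <- if (any(excess > 0)) which.max(excess) else which.max(abs(t$delta_rel))
  list(
    max_significant_deviation_percent = 100 * max(excess),
    max_abs_deviation_percent = 100 * max(abs(t$delta_rel)),
    argmax_region = t$region_id[i],
    argmax_name = t$name[i],
    guard_multiplier = z,
    n_testable = nrow(t),
    all_pass = all(t$pass)
  )
}

#' @export
print.fano_result <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf(
    "<fano_result> %s: E0 = %.4g MeV, |B| = %.3g T, em_estepe = %.3g, N = %.3g\n",
    m$geometry, m$energy, sqrt(sum(m$B_field^2)), m$em_estepe, m$histories))
  cat(sprintf("  conservation %.2e, escapes %d, expectation: %s\n",
              m$conservation_error, m$escapes, m$expectation))
  df <- as.data.frame(x)
  df$delta_pct <- 100 * df$delta_rel
  df$sigma_pct <- 100 * df$sigma_dev
  print(df[, c("region_id", "name", "density", "mass", "n_emitted",
               "delta_pct", "sigma_pct", "pass")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a Fano result as CSV plus JSON metadata sidecar
#'
#' The CSV holds one row per region with 17 significant digits (so
#' identical runs are bit-identical); the JSON sidecar echoes the run
#' configuration, conservation check, escape count, wall time and
#' efficiency.
#'
#' @param result A `fano_result`.
#' @param path Output CSV path; the sidecar is written next to it with
#'   extension `.json`.
#' @return Invisibly, the two paths.
#' @export
write_fano_result <- function(result, path) {
  df <- as.data.frame(result)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jpath <- sub("\\.csv$", ".json", path)
  if (identical(jpath, path)) jpath <- paste0(path, ".json")
  jsonlite::write_json(attr(result, "meta"), jpath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(path, jpath))
}
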