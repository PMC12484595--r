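#' Gridded volume backscattering strength
#'
#' Container for an echo-integration grid: a depth-by-time matrix of
#' volume backscattering strength Sv (dB re 1 m^-1) with bin centers and
#' an exclusion mask. Depth is positive downward from the surface; bins
#' are half-open `[z, z + dz)` with centers reported. Masked cells retain
#' their values but are skipped by all indicator computations.
#'
#' @param sv_db Matrix [depth bin x time bin] of Sv (dB re 1 m^-1).
#' @param depth_centers Strictly increasing, uniformly spaced depth bin
#'   centers (m).
#' @param time_centers Uniformly spaced time bin centers (s).
#' @param mask Logical matrix, same shape; `TRUE` = excluded.
#' @return An object of class `sv_grid`.
#' @export
sv_grid <- function(sv_db, depth_centers, time_centers,
                    mask = matrix(FALSE, nrow(sv_db), ncol(sv_db))) {
  sv_db <- as.matrix(sv_db)
  if (nrow(sv_db) != length(depth_centers) || ncol(sv_db) != length(time_centers))
    stop_invalid("sv_db must be [depth x time]: got %d x %d for %d depths, %d times",
                 nrow(sv_db), ncol(sv_db), length(depth_centers), length(time_centers))
  dz <- diff(depth_centers)
  if (length(dz) > 0 && (any(dz <= 0) || max(abs(dz - dz[1])) > 1e-9 * dz[1]))
    stop_invalid("depth_centers must be strictly increasing and uniform")
  if (!identical(dim(mask), dim(sv_db)))
    stop_invalid("mask must have the same shape as sv_db")
  structure(list(sv_db = sv_db, depth_centers = depth_centers,
                 time_centers = time_centers, mask = mask),
            class = "sv_grid")
}

#' @export
print.sv_grid <- function(x, ...) {
  cat(sprintf("sv_grid: %d depth bins (%g-%g m) x %d time bins; %d cells masked\n",
              length(x$depth_centers), min(x$depth_centers),
              max(x$depth_centers), length(x$time_centers), sum(x$mask)))
  invisible(x)
}

grid_dz <- function(grid) {
  if (length(grid$depth_centers) > 1) diff(grid$depth_centers[1:2]) else 1
}

#' Convert between Sv (dB) and sv (linear)
#'
#' `sv = 10^(Sv/10)`; the pair are exact inverses.
#'
#' @param sv_db Sv values (dB re 1 m^-1).
#' @param sv_linear sv values (m^-1).
#' @return The converted values.
#' @export
db_to_linear <- function(sv_db) 10^(sv_db / 10)

#' @rdname db_to_linear
#' @export
linear_to_db <- function(sv_linear) 10 * log10(sv_linear)

#' Mask surface and near-transducer layers
#'
#' Excludes cells shallower than `surface_depth` (the wind-mixed surface
#' layer is unusable for zooplankton backscatter) and cells within
#' `bottom_clearance` of the deepest bin (the echosounder's near-field,
#' mounted above the seafloor). Values under the mask are retained.
#'
#' @param grid An [sv_grid()].
#' @param surface_depth Exclusion depth from the surface (m).
#' @param bottom_clearance Exclusion band above the deepest bin (m).
#' @return The grid with an updated mask.
#' @export
apply_exclusions <- function(grid, surface_depth, bottom_clearance = 5) {
  stopifnot(inherits(grid, "sv_grid"))
  if (surface_depth < 0 || surface_depth >= max(grid$depth_centers))
    stop_invalid("surface_depth must be in [0, deepest bin)")
  z <- grid$depth_centers
  excl <- z < surface_depth | z > max(z) - bottom_clearance
  mask <- grid$mask | matrix(excl, nrow(grid$sv_db), ncol(grid$sv_db))
  if (all(mask)) stop_invalid("exclusions mask every cell")
  grid$mask <- mask
  grid
}

#' Vertical distribution indicators of one profile
#'
#' Echo-integration moments of a single linear-domain backscatter profile:
#' center of mass (backscatter-weighted mean depth), inertia
#' (backscatter-weighted variance of depth about the center of mass) and
#' the nautical area scattering coefficient `s_A = 4 pi 1852^2 *
#' sum(sv * dz)`. Weighting is by linear sv times the bin height; masked
#' cells are excluded.
#'
#' @param sv_linear Linear-domain sv profile (m^-1), one value per depth
#'   bin.
#' @param depth Depth bin centers (m).
#' @param dz Depth bin height (m).
#' @param mask Logical; `TRUE` = excluded.
#' @return `center_of_mass` and `inertia` return `NA` for a profile with
#'   no positive unmasked backscatter; `area_scattering` returns 0.
#' @export
center_of_mass <- function(sv_linear, depth, dz = 1, mask = NULL) {
  w <- profile_weights(sv_linear, mask) * dz
  tot <- sum(w)
  if (tot <= 0) return(NA_real_)
  sum(depth * w) / tot
}

#' @rdname center_of_mass
#' @export
inertia <- function(sv_linear, depth, dz = 1, mask = NULL) {
  w <- profile_weights(sv_linear, mask) * dz
  tot <- sum(w)
  if (tot <= 0) return(NA_real_)
  cm <- sum(depth * w) / tot
  sum((depth - cm)^2 * w) / tot
}

#' @rdname center_of_mass
#' @export
area_scattering <- function(sv_linear, dz = 1, mask = NULL) {
  w <- profile_weights(sv_linear, mask)
  4 * pi * 1852^2 * sum(w) * dz
}

profile_weights <- function(sv_linear, mask) {
  w <- sv_linear
  if (!is.null(mask)) w[mask] <- 0
  w[!is.finite(w)] <- 0
  w
}

#' Indicators for every time bin of a grid
#'
#' Converts each unmasked column to the linear domain and computes center
#' of mass, inertia and s_A per time bin. Time bins with no usable
#' backscatter (all cells masked or zero) yield `NA` indicators and are
#' excluded from downstream fits.
#'
#' @param grid An [sv_grid()], normally after [apply_exclusions()].
#' @return Data frame: `time_s`, `cm_m`, `inertia_m2`, `sa`, `n_cells`.
#' @export
indicators_by_time <- function(grid) {
  stopifnot(inherits(grid, "sv_grid"))
  dz <- grid_dz(grid)
  z <- grid$depth_centers
  sv <- db_to_linear(grid$sv_db)
  sv[grid$mask | !is.finite(sv)] <- 0
  w <- sv * dz
  tot <- colSums(w)
  usable <- tot > 0
  cm <- ifelse(usable, colSums(z * w) / tot, NA_real_)
  # second moment about the column's own center of mass
  m2 <- colSums(z^2 * w) / ifelse(usable, tot, NA_real_)
  inert <- ifelse(usable, pmax(m2 - cm^2, 0), NA_real_)
  data.frame(time_s = grid$time_centers,
             cm_m = cm, inertia_m2 = inert,
             sa = 4 * pi * 1852^2 * tot,
             n_cells = colSums(sv > 0))
}

#' Join indicators to source distance
#'
#' Interpolates the approach track at each indicator time bin.
#'
#' @param indicators Output of [indicators_by_time()].
#' @param track Data frame with `time_s`, `distance_m`.
#' @return The indicators with a `distance_m` column.
#' @export
add_distance <- function(indicators, track) {
  indicators$distance_m <- stats::approx(track$time_s, track$distance_m,
                                         xout = indicators$time_s, rule = 2)$y
  indicators
}

#' Aggregate indicators into distance bins
#'
#' Bins per-time-bin indicators into half-open distance intervals
#' `[k*w, (k+1)*w)` up to `max_distance` and reports per-bin means. This
#' is the reporting view; regressions run on the per-time-bin records.
#'
#' @param indicators Indicators with `distance_m` (see [add_distance()]).
#' @param bin_width Bin width (m).
#' @param max_distance Largest distance retained (m).
#' @return Data frame: `distance_bin_m` (bin center), `cm_m`,
#'   `inertia_m2`, `sa`, `n`.
#' @export
bin_by_distance <- function(indicators, bin_width = 1000, max_distance = 9000) {
  ok <- is.finite(indicators$cm_m) & indicators$distance_m < max_distance
  x <- indicators[ok, , drop = FALSE]
  if (nrow(x) == 0) stop_invalid("no usable indicator records below max_distance")
  bin <- floor(x$distance_m / bin_width)
  agg <- lapply(split(x, bin), function(b) {
    data.frame(distance_bin_m = (floor(b$distance_m[1] / bin_width) + 0.5) * bin_width,
               cm_m = mean(b$cm_m), inertia_m2 = mean(b$inertia_m2),
               sa = mean(b$sa), n = nrow(b))
  })
  out <- do.call(rbind, agg)
  out[order(out$distance_bin_m), , drop = FALSE]
}

#' Regress an indicator on source distance
#'
#' Gaussian identity-link linear model (ordinary least squares) of an
#' indicator against distance, the standard "general linear model" with a
#' continuous covariate. Records with `NA` response or distance are
#' dropped.
#'
#' @param indicators Indicators with `distance_m`.
#' @param response `"cm"` or `"inertia"`.
#' @return An object of class `indicator_fit`: list with `response`,
#'   `slope` (per m), `intercept`, `se`, `p_value`, `n`, and the `lm` fit.
#' @export
fit_indicator_glm <- function(indicators, response = c("cm", "inertia")) {
  response <- match.arg(response)
  col <- if (response == "cm") "cm_m" else "inertia_m2"
  d <- indicators[is.finite(indicators[[col]]) & is.finite(indicators$distance_m),
                  c(col, "distance_m")]
  if (nrow(d) < 3) stop_invalid("need >= 3 records with finite %s and distance", col)
  if (stats::sd(d$distance_m) == 0)
    stop_invalid("distance is constant; slope is not identifiable")
  fit <- stats::lm(d[[col]] ~ d$distance_m)
  cf <- summary(fit)$coefficients
  structure(list(response = response,
                 slope = cf[2, 1], intercept = cf[1, 1],
                 se = cf[2, 2], p_value = cf[2, 4],
                 n = nrow(d), fit = fit),
            class = "indicator_fit")
}

#' @export
print.indicator_fit <- function(x, ...) {
  cat(sprintf("indicator fit: %s ~ distance (n = %d)\n", x$response, x$n))
  cat(sprintf("  slope %.4g per m (se %.3g), intercept %.4g, p = %.3g\n",
              x$slope, x$se, x$intercept, x$p_value))
  invisible(x)
}

#' Simulate a gridded echogram of a Gaussian scattering layer
#'
#' The water column holds a single scattering layer whose linear-domain sv
#' profile is Gaussian in depth: `sv(z, t) = sv_peak * exp(-(z - mu(t))^2 /
#' (2 sigma(t)^2))`, multiplied by lognormal cell noise with a standard
#' deviation of `noise_sd_db` dB. The grid covers bin centers from
#' `grid_dz/2` down to 5 m above the seafloor (the echosounder sits 5 m
#' off the bottom and cannot see below itself).
#'
#' When the scenario plants a distance response, the layer mean and/or
#' variance at each time bin are shifted in proportion to the source
#' distance interpolated from `track`; the returned ground truth columns
#' `cm_true_m` and `inertia_true_m2` are the continuous-limit moments
#' `mu(t)` and `sigma(t)^2` after that perturbation, which downstream
#' indicator recovery is measured against.
#'
#' @param scenario A [layer_scenario()].
#' @param track Data frame with `time_s`, `distance_m`; its time span
#'   defines the echogram time axis.
#' @param noise Set `FALSE` to disable cell noise regardless of the
#'   scenario (for exact-recovery checks).
#' @return A list of class `echogram_sim` with `grid` (an [sv_grid()])
#'   and `truth` (data frame: `time_s`, `distance_m`, `cm_true_m`,
#'   `inertia_true_m2`).
#' @export
gen_echogram <- function(scenario, track, noise = TRUE) {
  stopifnot(inherits(scenario, "layer_scenario"))
  t_cent <- seq(min(track$time_s) + scenario$grid_dt / 2, max(track$time_s),
                by = scenario$grid_dt)
  z_max <- scenario$water_depth - 5
  z_cent <- seq(scenario$grid_dz / 2, z_max, by = scenario$grid_dz)
  dist <- stats::approx(track$time_s, track$distance_m, xout = t_cent, rule = 2)$y
  d_km <- dist / 1000

  mu <- if (is.function(scenario$layer_mean_depth))
    vapply(t_cent, scenario$layer_mean_depth, numeric(1)) else
      rep(scenario$layer_mean_depth, length(t_cent))
  sdv <- if (is.function(scenario$layer_sd))
    vapply(t_cent, scenario$layer_sd, numeric(1)) else
      rep(scenario$layer_sd, length(t_cent))
  mu <- mu + scenario$cm_response_slope * d_km
  var <- sdv^2 + scenario$inertia_response_slope * d_km
  if (any(var <= 0)) stop_invalid("planted response drives layer variance <= 0")
  sdv <- sqrt(var)
  if (any(mu <= 0) || any(mu >= scenario$water_depth))
    stop_invalid("layer mean escapes the water column")

  sv_peak <- db_to_linear(scenario$layer_strength)
  sv <- sv_peak * exp(-outer(z_cent, mu, "-")^2 /
                        (2 * matrix(sdv^2, length(z_cent), length(t_cent),
                                    byrow = TRUE)))
  if (noise && scenario$noise_sd_db > 0) {
    noise_fac <- with_seed(scenario$seed,
      10^(matrix(stats::rnorm(length(sv), sd = scenario$noise_sd_db),
                 nrow(sv)) / 10))
    sv <- sv * noise_fac
  }
  grid <- sv_grid(linear_to_db(sv), z_cent, t_cent)
  truth <- data.frame(time_s = t_cent, distance_m = dist,
                      cm_true_m = mu, inertia_true_m2 = sdv^2)
  structure(list(grid = grid, truth = truth), class = "echogram_sim")
}
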