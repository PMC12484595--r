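#' Scenario constructors for the synthetic experiment generators
#'
#' A scenario object bundles every parameter of one simulated component of
#' an airgun-approach field experiment: the vessel approach and airgun
#' source, the scattering layer seen by a bottom-mounted echosounder, the
#' bag/net mortality experiment, and the stained-organism photographs.
#' Generators take a scenario and nothing else, so a run is fully
#' reproducible from its scenario (each scenario carries its own seed; no
#' global random state is consulted or modified).
#'
#' @name scenarios
NULL

# Evaluate expr with a local RNG seeded at `seed`; the caller's RNG state
# is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Airgun approach scenario
#'
#' Describes a seismic vessel steaming toward a stationary hydrophone while
#' discharging an airgun array at fixed intervals over a constant vessel
#' noise floor. Distances are slant-range-free along-track distances in
#' metres; the default speed of 2.315 m/s is 4.5 knots.
#'
#' @param start_distance Initial source-receiver distance (m).
#' @param vessel_speed Vessel speed (m/s); 2.315 m/s = 4.5 knots.
#' @param shot_interval Time between airgun discharges (s). Treated as an
#'   independent parameter: it is not derived from the shot spacing and
#'   vessel speed.
#' @param source_sel_at_1m Per-shot sound exposure level at 1 m
#'   (dB re 1 uPa^2 s).
#' @param noise_floor_sel Broadband SEL of the vessel noise floor in one
#'   analysis window (dB re 1 uPa^2 s per 10 s window), measured over the
#'   analysis band.
#' @param band Analysis band edges (Hz) over which `noise_floor_sel` is
#'   defined.
#' @param spreading_exponent Transmission-loss coefficient k in
#'   k*log10(r); 20 is spherical spreading.
#' @param sample_rate Recording sample rate (Hz); must support the 20 kHz
#'   upper analysis band edge, i.e. be at least 40 kHz.
#' @param duration Recording duration (s). Defaults to the time for the
#'   vessel to cover `start_distance`.
#' @param pulse_frequency Carrier frequency of the damped airgun pulse
#'   (Hz); airgun energy is concentrated below ~100 Hz.
#' @param pulse_decay Exponential amplitude decay time constant of the
#'   pulse (s).
#' @param seed Integer RNG seed.
#' @return An object of class `approach_scenario`.
#' @export
approach_scenario <- function(start_distance = 10000,
                              vessel_speed = 2.315,
                              shot_interval = 10.7,
                              source_sel_at_1m = 222,
                              noise_floor_sel = 158,
                              spreading_exponent = 20,
                              band = c(10, 20000),
                              sample_rate = 44100,
                              duration = NULL,
                              pulse_frequency = 60,
                              pulse_decay = 0.05,
                              seed = 1L) {
  if (start_distance <= 0) stop_invalid("start_distance must be > 0")
  if (vessel_speed <= 0) stop_invalid("vessel_speed must be > 0")
  if (shot_interval <= 0) stop_invalid("shot_interval must be > 0")
  if (sample_rate < 2 * band[2])
    stop_invalid("sample_rate must be at least twice the upper band edge")
  if (is.null(duration)) duration <- start_distance / vessel_speed
  structure(list(
    start_distance = start_distance, vessel_speed = vessel_speed,
    shot_interval = shot_interval, source_sel_at_1m = source_sel_at_1m,
    noise_floor_sel = noise_floor_sel,
    spreading_exponent = spreading_exponent, band = band,
    sample_rate = sample_rate,
    duration = duration, pulse_frequency = pulse_frequency,
    pulse_decay = pulse_decay, seed = seed
  ), class = "approach_scenario")
}

#' Scattering layer scenario
#'
#' Describes a Gaussian-in-depth zooplankton scattering layer in a shallow
#' water column, observed by an upward-looking echosounder mounted 5 m
#' above the seafloor, gridded as volume backscattering strength.
#'
#' `layer_mean_depth` and `layer_sd` may be constants or functions of time
#' (s), so diel-migration ramps can be expressed. `cm_response_slope` and
#' `inertia_response_slope` plant a distance-dependent effect: at source
#' distance d (km) the layer mean is shifted by `cm_response_slope * d`
#' (m) and the layer variance by `inertia_response_slope * d` (m^2), which
#' is what a regression of the recovered indicators on distance should
#' detect.
#'
#' @param water_depth Water column depth (m).
#' @param layer_mean_depth Mean depth of the layer (m), constant or
#'   function of time (s).
#' @param layer_sd Standard deviation of the layer (m), constant or
#'   function of time (s).
#' @param layer_strength Volume backscattering strength Sv at the layer
#'   core (dB re 1 m^-1).
#' @param noise_sd_db Multiplicative lognormal cell noise, expressed as a
#'   standard deviation in dB.
#' @param grid_dt Time resolution of the grid (s).
#' @param grid_dz Depth resolution of the grid (m).
#' @param surface_exclusion Depth above which cells are excluded (m);
#'   surface turbulence makes this zone unusable in the field.
#' @param cm_response_slope Planted shift of layer mean depth per km of
#'   source distance (m/km); 0 disables.
#' @param inertia_response_slope Planted increase of layer variance per km
#'   of source distance (m^2/km); 0 disables.
#' @param seed Integer RNG seed.
#' @return An object of class `layer_scenario`.
#' @export
layer_scenario <- function(water_depth = 70,
                           layer_mean_depth = 25,
                           layer_sd = 5,
                           layer_strength = -70,
                           noise_sd_db = 3,
                           grid_dt = 2,
                           grid_dz = 2,
                           surface_exclusion = 5,
                           cm_response_slope = 0,
                           inertia_response_slope = 0,
                           seed = 1L) {
  if (grid_dt <= 0 || grid_dz <= 0) stop_invalid("grid_dt and grid_dz must be > 0")
  if (water_depth <= 0) stop_invalid("water_depth must be > 0")
  mu0 <- if (is.function(layer_mean_depth)) layer_mean_depth(0) else layer_mean_depth
  if (mu0 <= 0 || mu0 >= water_depth)
    stop_invalid("layer_mean_depth must lie strictly inside the water column")
  sd0 <- if (is.function(layer_sd)) layer_sd(0) else layer_sd
  if (sd0 <= 0) stop_invalid("layer_sd must be > 0")
  structure(list(
    water_depth = water_depth, layer_mean_depth = layer_mean_depth,
    layer_sd = layer_sd, layer_strength = layer_strength,
    noise_sd_db = noise_sd_db, grid_dt = grid_dt, grid_dz = grid_dz,
    surface_exclusion = surface_exclusion,
    cm_response_slope = cm_response_slope,
    inertia_response_slope = inertia_response_slope, seed = seed
  ), class = "layer_scenario")
}

#' Mortality experiment scenario
#'
#' Describes the bag-exposure experiment (cultured copepods in sealed bags
#' at known distances, inspected daily for 7 days) and the net-haul
#' sampling of wild zooplankton during the approach.
#'
#' Each treatment is a list with elements `name`, `n_bags`,
#' `n_individuals`, `day0_death_prob` (probability an individual is dead
#' immediately after treatment) and `daily_hazard` (daily death
#' probability of a survivor over the follow-up). Expected cumulative
#' mortality at day d is `1 - (1 - p0) * (1 - h)^d`.
#'
#' The default treatments follow the field design: 12 control bags, 18
#' handling-control bags, 9 far-exposure bags (>6 km) and 36
#' close-exposure bags (89-1192 m), 10 individuals each, with hazards
#' calibrated so expected day-7 cumulative mortality is 25.1% for close
#' exposure, 22.3% far, 12.7% control and 11.7% handling control, and
#' expected immediate mortality 5.4% (close) and 2.3% (far).
#'
#' @param treatments List of treatment descriptors (see Details).
#' @param follow_up_days Length of the daily follow-up (days).
#' @param net_mortality_curve Function distance (m) -> expected dead
#'   fraction in a net haul.
#' @param net_dispersion Beta-binomial intra-haul correlation rho in
#'   [0, 1); 0 gives plain binomial sampling.
#' @param net_n_individuals Individuals scored per net haul.
#' @param seed Integer RNG seed.
#' @return An object of class `mortality_scenario`.
#' @export
mortality_scenario <- function(treatments = default_bag_treatments(),
                               follow_up_days = 7,
                               net_mortality_curve = function(d) rep(0.15, length(d)),
                               net_dispersion = 0.05,
                               net_n_individuals = 100,
                               seed = 1L) {
  for (tr in treatments) {
    if (tr$n_bags < 1 || tr$n_individuals < 1)
      stop_invalid("n_bags and n_individuals must be >= 1 (treatment %s)", tr$name)
    if (tr$day0_death_prob < 0 || tr$day0_death_prob > 1 ||
        tr$daily_hazard < 0 || tr$daily_hazard > 1)
      stop_invalid("probabilities must be in [0,1] (treatment %s)", tr$name)
  }
  if (net_dispersion < 0 || net_dispersion >= 1)
    stop_invalid("net_dispersion must be in [0,1)")
  structure(list(
    treatments = treatments, follow_up_days = follow_up_days,
    net_mortality_curve = net_mortality_curve,
    net_dispersion = net_dispersion,
    net_n_individuals = net_n_individuals, seed = seed
  ), class = "mortality_scenario")
}

# Daily hazard giving expected cumulative mortality `target` at day
# `days` when immediate mortality is p0: 1-(1-p0)(1-h)^days = target.
hazard_for_day7 <- function(target, p0, days = 7) {
  1 - ((1 - target) / (1 - p0))^(1 / days)
}

#' Default bag treatment set
#'
#' Four treatments matching the field design: per-bag sample sizes and
#' counts from the exposure experiment, hazards calibrated to the observed
#' day-7 cumulative mortality means (see [mortality_scenario()]).
#'
#' @param n_individuals Individuals per bag.
#' @return List of treatment descriptors.
#' @export
default_bag_treatments <- function(n_individuals = 10) {
  list(
    list(name = "control", n_bags = 12, n_individuals = n_individuals,
         day0_death_prob = 0.02,
         daily_hazard = hazard_for_day7(0.127, 0.02)),
    list(name = "handling_control", n_bags = 18, n_individuals = n_individuals,
         day0_death_prob = 0.02,
         daily_hazard = hazard_for_day7(0.117, 0.02)),
    list(name = "exposure_far", n_bags = 9, n_individuals = n_individuals,
         day0_death_prob = 0.023,
         daily_hazard = hazard_for_day7(0.223, 0.023)),
    list(name = "exposure_close", n_bags = 36, n_individuals = n_individuals,
         day0_death_prob = 0.054,
         daily_hazard = hazard_for_day7(0.251, 0.054))
  )
}

#' Stained-organism image scenario
#'
#' Describes synthetic photographs of Neutral Red stained zooplankton:
#' dark elliptical organisms on a light background (the dishes are lit
#' from below), where living animals take up the red stain strongly and
#' dead animals only diffusively. Stain intensity is expressed as the
#' red-channel saturation of the organism body; the live intensity range
#' must stochastically exceed the dead range.
#'
#' @param n_organisms Number of organisms per image.
#' @param live_fraction Fraction of organisms that are alive.
#' @param organism_size_px Length-2 range of semi-major axis (px).
#' @param live_stain_range Length-2 range of body saturation for live
#'   animals.
#' @param dead_stain_range Length-2 range of body saturation for dead
#'   animals (diffusive uptake only).
#' @param background_level Background gray value in [0, 1].
#' @param body_value HSV value (brightness) of the organism body.
#' @param noise_sd Gaussian pixel noise standard deviation (on [0,1]
#'   channel values).
#' @param width,height Image dimensions (px).
#' @param seed Integer RNG seed.
#' @return An object of class `image_scenario`.
#' @export
image_scenario <- function(n_organisms = 40,
                           live_fraction = 0.7,
                           organism_size_px = c(8, 14),
                           live_stain_range = c(0.65, 0.95),
                           dead_stain_range = c(0.05, 0.25),
                           background_level = 0.92,
                           body_value = 0.45,
                           noise_sd = 0.02,
                           width = 400, height = 400,
                           seed = 1L) {
  if (live_fraction < 0 || live_fraction > 1)
    stop_invalid("live_fraction must be in [0,1]")
  if (min(live_stain_range) < max(dead_stain_range) &&
      mean(live_stain_range) <= mean(dead_stain_range))
    stop_invalid("live stain distribution must stochastically exceed dead")
  if (n_organisms < 0) stop_invalid("n_organisms must be >= 0")
  structure(list(
    n_organisms = n_organisms, live_fraction = live_fraction,
    organism_size_px = organism_size_px,
    live_stain_range = live_stain_range,
    dead_stain_range = dead_stain_range,
    background_level = background_level, body_value = body_value,
    noise_sd = noise_sd, width = width, height = height, seed = seed
  ), class = "image_scenario")
}
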