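test_that("approach track follows linear kinematics and validates input", {
  sc <- approach_scenario(start_distance = 10000, vessel_speed = 2.315,
                          duration = 2000)
  tr <- gen_approach_track(sc)
  expect_equal(tr$distance_m[tr$time_s == 0], 10000)
  expect_equal(tr$distance_m[tr$time_s == 1000], 7685)
  before_pass <- tr$distance_m[tr$time_s < 10000 / 2.315]
  expect_true(all(diff(before_pass) < 0))
  expect_error(approach_scenario(vessel_speed = 0), "vessel_speed")
  expect_error(approach_scenario(shot_interval = -1), "shot_interval")
  expect_error(approach_scenario(sample_rate = 8000), "twice the upper band")
})

test_that("airgun recording plants shots at the scenario interval with
           spreading-law amplitudes", {
  sc <- approach_scenario(duration = 60, seed = 11)
  sim <- gen_airgun_recording(sc)
  expect_equal(diff(sim$shots$time_s), rep(10.7, nrow(sim$shots) - 1))
  # halving distance with 20 log10 spreading doubles pulse amplitude
  a <- pulse_amp_at <- function(d) {
    sel <- sc$source_sel_at_1m - sc$spreading_exponent * log10(d)
    sqrt(4 * 10^(sel / 10) / sc$pulse_decay)
  }
  expect_equal(pulse_amp_at(500) / pulse_amp_at(1000), 2, tolerance = 1e-12)
  # the generated shot log follows the same law
  sim_amp <- sim$shots$amplitude_pa
  pred <- pulse_amp_at(sim$shots$distance_m) * 1e-6
  expect_equal(sim_amp, pred, tolerance = 1e-12)
  expect_error(gen_airgun_recording(approach_scenario(duration = 5)),
               "shorter than one")
})

test_that("airgun recording is reproducible from its seed", {
  sc <- approach_scenario(duration = 30, seed = 42)
  a <- gen_airgun_recording(sc)
  b <- gen_airgun_recording(sc)
  expect_identical(a$rec$samples, b$rec$samples)
  expect_identical(a$shots, b$shots)
})

test_that("echogram ground truth equals the Gaussian layer parameters", {
  sc <- approach_scenario(duration = 400)
  track <- gen_approach_track(sc)
  ls <- layer_scenario(layer_mean_depth = 25, layer_sd = 5, noise_sd_db = 0)
  ech <- gen_echogram(ls, track, noise = FALSE)
  expect_true(all(ech$truth$cm_true_m == 25))
  expect_true(all(ech$truth$inertia_true_m2 == 25))
  expect_equal(diff(ech$grid$depth_centers[1:2]), 2)
  expect_equal(diff(ech$grid$time_centers[1:2]), 2)
  # transducer sits 5 m off the bottom: no bins in the last 5 m
  expect_lte(max(ech$grid$depth_centers), ls$water_depth - 5)
})

test_that("planted inertia response raises ground-truth inertia with distance", {
  sc <- approach_scenario(duration = 4000)
  track <- gen_approach_track(sc)
  ls <- layer_scenario(inertia_response_slope = 2)
  ech <- gen_echogram(ls, track, noise = FALSE)
  # truth carries the planted law exactly: sd^2 + 2 m^2 per km of distance
  expect_equal(ech$truth$inertia_true_m2, 25 + 2 * ech$truth$distance_m / 1000,
               tolerance = 1e-12)
  # so the planted contrast between 9 km and the source is 18 m^2
  i9 <- 25 + 2 * 9; i0 <- 25
  expect_equal(i9 - i0, 18)
  expect_error(gen_echogram(layer_scenario(layer_mean_depth = 68,
                                           cm_response_slope = 2),
                            track, noise = FALSE),
               "escapes the water column")
})

test_that("bag trials are nondecreasing, bounded, and hit degenerate limits", {
  for (seed in 1:5) {
    sc <- mortality_scenario(seed = seed)
    bt <- gen_bag_trials(sc)
    cum <- as.matrix(bt[grep("^dead_day", names(bt))])
    expect_true(all(apply(cum, 1, function(r) all(diff(r) >= 0))))
    expect_true(all(cum <= bt$n0) && all(cum >= 0))
  }
  null_sc <- mortality_scenario(treatments = list(
    list(name = "a", n_bags = 5, n_individuals = 10,
         day0_death_prob = 0, daily_hazard = 0),
    list(name = "b", n_bags = 5, n_individuals = 10,
         day0_death_prob = 0, daily_hazard = 0)))
  expect_true(all(as.matrix(gen_bag_trials(null_sc)[-(1:4)]) == 0))
  absorb <- mortality_scenario(treatments = list(
    list(name = "a", n_bags = 3, n_individuals = 10,
         day0_death_prob = 1, daily_hazard = 0),
    list(name = "b", n_bags = 3, n_individuals = 10,
         day0_death_prob = 0, daily_hazard = 0)))
  ba <- gen_bag_trials(absorb)
  cum <- as.matrix(ba[ba$treatment == "a", grep("^dead_day", names(ba))])
  expect_true(all(cum == 10))
})

test_that("simulated day-7 mortality matches the geometric-survival closed form", {
  p0 <- 0.054; h <- zooseis:::hazard_for_day7(0.251, p0)
  sc <- mortality_scenario(treatments = list(
    list(name = "x", n_bags = 10000, n_individuals = 10,
         day0_death_prob = p0, daily_hazard = h),
    list(name = "y", n_bags = 1, n_individuals = 10,
         day0_death_prob = 0, daily_hazard = 0)), seed = 3)
  bt <- gen_bag_trials(sc)
  prop7 <- bt$dead_day7[bt$treatment == "x"] / 10
  expected <- 1 - (1 - p0) * (1 - h)^7
  se <- sd(prop7) / sqrt(length(prop7))
  expect_equal(expected, 0.251, tolerance = 1e-12)
  expect_lt(abs(mean(prop7) - expected), 3 * se)
})

test_that("net samples follow the mortality curve and carry phase flags", {
  flat <- mortality_scenario(net_mortality_curve = function(d) rep(0.2, length(d)),
                             net_dispersion = 0, seed = 5)
  nets <- gen_net_samples(flat, distances = rep(1000, 400))
  expect_equal(mean(nets$n_dead), 20, tolerance = 0.05)
  expect_true(all(nets$phase == "during"))
  inc <- mortality_scenario(net_mortality_curve = function(d) 0.05 + d / 2e4,
                            seed = 6)
  d <- seq(500, 9500, length.out = 20)
  expect_equal(cor(rank(inc$net_mortality_curve(d)), rank(d)), 1)
  both <- gen_net_samples(inc, distances = d, after_distances = d[1:5])
  expect_equal(sum(both$phase == "after"), 5)
  expect_error(gen_net_samples(flat, distances = numeric(0)), "non-empty")
})

test_that("stain image generator places labeled non-overlapping organisms", {
  empty <- gen_stain_images(image_scenario(n_organisms = 0, seed = 1))
  expect_equal(nrow(empty[[1]]$labels), 0)
  rep0 <- batch_vital_report(empty)
  expect_equal(rep0$summary$n_live + rep0$summary$n_dead,
               rep(0L, nrow(rep0$summary)))

  sc <- image_scenario(n_organisms = 25, seed = 8)
  a <- gen_stain_images(sc, 2)
  b <- gen_stain_images(sc, 2)
  expect_identical(a[[1]]$image, b[[1]]$image)
  expect_identical(a[[2]]$labels, b[[2]]$labels)
  # pairwise center distances exceed the sum of the semi-major axes
  lab <- a[[1]]$labels
  d2 <- as.matrix(dist(lab[c("x", "y")]))^2
  lim <- outer(lab$a, lab$a, "+")^2
  expect_true(all(d2[upper.tri(d2)] > lim[upper.tri(lim)]))
  expect_error(gen_stain_images(image_scenario(n_organisms = 500, width = 100,
                                               height = 100, seed = 1)),
               "place|canvas")
})
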