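test_that("dB/linear conversion is the defining power law and a true inverse", {
  expect_equal(db_to_linear(-70), 1e-7)
  expect_equal(db_to_linear(0), 1)
  set.seed(41)
  m <- matrix(runif(60, -90, -50), 6)
  expect_equal(linear_to_db(db_to_linear(m)), m, tolerance = 1e-12)
})

test_that("profile moments match point-mass and symmetry cases", {
  z <- seq(1, 69, by = 2)
  point <- rep(0, length(z)); point[z == 21] <- 1e-7
  expect_equal(center_of_mass(point, z, 2), 21)
  expect_equal(inertia(point, z, 2), 0)
  two <- rep(0, length(z)); two[z == 11] <- 1e-7; two[z == 31] <- 1e-7
  expect_equal(center_of_mass(two, z, 2), 21)
  expect_equal(inertia(two, z, 2), 100)
  uniform <- rep(1e-7, length(z))
  expect_equal(center_of_mass(uniform, z, 2), 35)
  expect_true(is.na(center_of_mass(rep(0, length(z)), z, 2)))
})

test_that("area scattering follows the 4 pi 1852^2 closed form and is linear", {
  z <- c(10, 12)
  expect_equal(area_scattering(c(0, 0), 2), 0)
  one <- c(1e-7, 0)
  expect_equal(area_scattering(one, 2), 4 * pi * 1852^2 * 2e-7)
  expect_equal(area_scattering(2 * one, 2), 2 * area_scattering(one, 2))
})

test_that("grid indicators equal a brute-force double-loop oracle", {
  set.seed(42)
  for (rep in 1:100) {
    g <- random_masked_grid()
    # keep at least one unmasked cell per column
    for (j in seq_along(g$time_centers))
      if (all(g$mask[, j])) g$mask[1, j] <- FALSE
    ind <- indicators_by_time(g)
    j <- sample(length(g$time_centers), 1)
    oracle <- oracle_column_moments(g, j)
    expect_equal(ind$cm_m[j], oracle$cm, tolerance = 1e-9)
    expect_equal(ind$inertia_m2[j], oracle$inertia, tolerance = 1e-9)
    expect_equal(ind$sa[j], oracle$sa, tolerance = 1e-9)
  }
})

test_that("moments are gain-invariant and equivariant under depth shifts", {
  set.seed(43)
  z <- seq(1, 39, by = 2)
  sv <- runif(length(z), 0, 1e-6)
  expect_equal(center_of_mass(7 * sv, z, 2), center_of_mass(sv, z, 2))
  expect_equal(inertia(7 * sv, z, 2), inertia(sv, z, 2))
  expect_equal(area_scattering(7 * sv, 2), 7 * area_scattering(sv, 2))
  expect_equal(center_of_mass(sv, z + 3, 2), center_of_mass(sv, z, 2) + 3)
  expect_equal(inertia(sv, z + 3, 2), inertia(sv, z, 2))
})

test_that("merging adjacent time bins averages CM with s_A weights", {
  set.seed(44)
  g <- random_masked_grid(n_depth = 10, n_time = 2, mask_prob = 0)
  ind <- indicators_by_time(g)
  merged_sv <- linear_to_db((db_to_linear(g$sv_db[, 1]) +
                               db_to_linear(g$sv_db[, 2])) / 2)
  gm <- sv_grid(matrix(merged_sv), g$depth_centers, 1)
  cm_merged <- indicators_by_time(gm)$cm_m
  expect_equal(cm_merged,
               sum(ind$cm_m * ind$sa) / sum(ind$sa), tolerance = 1e-12)
})

test_that("exclusion masking removes surface and bottom-clearance bands", {
  g <- random_masked_grid(n_depth = 35, n_time = 4, dz = 2, mask_prob = 0)
  e <- apply_exclusions(g, surface_depth = 5)
  expect_true(all(e$mask[e$depth_centers < 5, ]))
  expect_true(all(e$mask[e$depth_centers > max(e$depth_centers) - 5, ]))
  expect_false(any(e$mask[e$depth_centers >= 5 &
                            e$depth_centers <= max(e$depth_centers) - 5, ]))
  noop <- apply_exclusions(g, 0, 0)
  expect_identical(noop$mask, g$mask)
  expect_error(apply_exclusions(g, 70), "deepest bin")
  expect_error(apply_exclusions(g, 30, bottom_clearance = 70), "every cell")
})

test_that("a discretized Gaussian layer recovers its moments within the
           bin correction", {
  z <- seq(1, 69, by = 2)
  # point-sampled layer: aliasing at 2 m spacing is negligible for sd 5 m
  sv <- exp(-(z - 25)^2 / (2 * 25))
  expect_equal(center_of_mass(sv, z, 2), 25, tolerance = 1e-3)
  expect_equal(inertia(sv, z, 2), 25, tolerance = 1e-3)
  # cell-integrated weights pick up the Delta z^2 / 12 correction
  svi <- pnorm(z + 1, 25, 5) - pnorm(z - 1, 25, 5)
  expect_equal(inertia(svi, z, 2), 25 + 4 / 12, tolerance = 1e-3)
})

test_that("indicator regression recovers exact linear responses", {
  ind <- data.frame(time_s = 1:20, cm_m = 30 + 0.002 * seq(100, 2000, by = 100),
                    inertia_m2 = 25, sa = 1,
                    distance_m = seq(100, 2000, by = 100))
  fit <- suppressWarnings(fit_indicator_glm(ind, "cm"))
  expect_equal(fit$slope, 0.002, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-12)
  const <- ind; const$distance_m <- 500
  expect_error(fit_indicator_glm(const, "cm"), "constant")
  expect_error(fit_indicator_glm(ind[1:2, ], "cm"), ">= 3")
})

test_that("distance binning preserves constants and collinearity", {
  ind <- data.frame(time_s = 1:90, cm_m = 30, inertia_m2 = 25, sa = 1,
                    distance_m = seq(50, 8950, by = 100))
  b <- bin_by_distance(ind)
  expect_lte(nrow(b), 9)
  expect_true(all(b$cm_m == 30))
  lin <- ind; lin$cm_m <- 10 + 0.001 * lin$distance_m
  bl <- bin_by_distance(lin)
  fit <- lm(cm_m ~ distance_bin_m, data = bl)
  expect_equal(unname(coef(fit)[2]), 0.001, tolerance = 1e-9)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)
})

test_that("stationary noise-free layers give constant indicators; masked
           columns drop out of fits", {
  track <- data.frame(time_s = c(0, 400), distance_m = c(9000, 8000))
  ech <- gen_echogram(layer_scenario(noise_sd_db = 0), track, noise = FALSE)
  ind <- indicators_by_time(ech$grid)
  expect_equal(ind$cm_m, rep(25, nrow(ind)), tolerance = 0.01)
  g <- ech$grid
  g$mask[, 3] <- TRUE
  ind2 <- add_distance(indicators_by_time(g), track)
  expect_true(is.na(ind2$cm_m[3]))
  fit <- suppressWarnings(fit_indicator_glm(ind2, "cm"))
  expect_equal(fit$n, nrow(ind2) - 1)
})

test_that("Sv grid CSV round-trips exactly", {
  g <- random_masked_grid(mask_prob = 0)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_svgrid_csv(g, path)
  back <- read_svgrid_csv(path)
  expect_equal(back$depth_centers, g$depth_centers)
  expect_equal(back$time_centers, g$time_centers)
  expect_equal(unname(back$sv_db), unname(g$sv_db), tolerance = 1e-12)
})
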