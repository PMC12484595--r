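# Shared fixture builders for the test suite. All fixtures are built in
# code; nothing is read from disk.

# A sine-burst pressure recording of given amplitude (Pa) and duration.
sine_rec <- function(amp = 1, freq = 100, duration = 1, fs = 44100) {
  n <- round(duration * fs)
  pressure_recording(amp * sin(2 * pi * freq * (0:(n - 1)) / fs), fs)
}

# Random Sv grid with a random mask (depth x time), values in dB.
random_masked_grid <- function(n_depth = 12, n_time = 8, dz = 2, dt = 2,
                               mask_prob = 0.2) {
  sv <- matrix(runif(n_depth * n_time, -90, -60), n_depth)
  mask <- matrix(runif(n_depth * n_time) < mask_prob, n_depth)
  sv_grid(sv, depth_centers = dz * (seq_len(n_depth) - 0.5),
          time_centers = dt * (seq_len(n_time) - 0.5), mask = mask)
}

# Brute-force double-loop moments over unmasked cells of one column.
oracle_column_moments <- function(grid, j) {
  dz <- diff(grid$depth_centers[1:2])
  num_cm <- 0; den <- 0
  for (i in seq_along(grid$depth_centers)) {
    if (grid$mask[i, j]) next
    w <- 10^(grid$sv_db[i, j] / 10) * dz
    num_cm <- num_cm + grid$depth_centers[i] * w
    den <- den + w
  }
  cm <- num_cm / den
  num_i <- 0
  for (i in seq_along(grid$depth_centers)) {
    if (grid$mask[i, j]) next
    w <- 10^(grid$sv_db[i, j] / 10) * dz
    num_i <- num_i + (grid$depth_centers[i] - cm)^2 * w
  }
  list(cm = cm, inertia = num_i / den, sa = 4 * pi * 1852^2 * den)
}

# Net-sample table straight from vectors (bypasses the generator).
nets_from <- function(distance, prop_dead, phase = "during", n = 100) {
  dead <- round(prop_dead * n)
  data.frame(haul_id = seq_along(distance), approach = 1L,
             distance_m = distance, phase = phase,
             n_live = n - dead, n_dead = dead)
}

# Flat RGB image (h x w) of one color.
flat_image <- function(rgb, h = 40, w = 40) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# Paint a filled axis-aligned rectangle of color `rgb` onto `img`.
paint_rect <- function(img, rows, cols, rgb) {
  for (ch in 1:3) img[rows, cols, ch] <- rgb[ch]
  img
}

# Independent per-bag-day binomial mortality data in long format.
independent_bag_days <- function(n_bags, n_ind, p_by_treatment, days = 0:7) {
  rows <- lapply(names(p_by_treatment), function(tr) {
    nd <- length(days) * n_bags[[tr]]
    data.frame(treatment = tr,
               bag_id = rep(seq_len(n_bags[[tr]]), each = length(days)),
               day = rep(days, n_bags[[tr]]),
               dead = rbinom(nd, n_ind, p_by_treatment[[tr]]))
  })
  out <- do.call(rbind, rows)
  out$alive <- n_ind - out$dead
  out
}
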