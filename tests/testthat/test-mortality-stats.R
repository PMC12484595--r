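test_that("proportion_dead is elementary and guards its denominator", {
  expect_equal(proportion_dead(36, 100), 0.36)
  expect_equal(proportion_dead(0, 50), 0)
  expect_equal(proportion_dead(10, 10), 1)
  expect_error(proportion_dead(1, 0), "total")
})

test_that("Spearman correlation handles monotone, degenerate and tied data", {
  up <- nets_from(distance = 1:6 * 1000, prop_dead = seq(0.1, 0.35, by = 0.05))
  expect_equal(spearman_mortality_distance(up)$rho, 1)
  down <- nets_from(distance = 1:6 * 1000, prop_dead = seq(0.35, 0.1, by = -0.05))
  expect_equal(spearman_mortality_distance(down)$rho, -1)
  const <- nets_from(distance = 1:5 * 1000, prop_dead = rep(0.2, 5))
  res <- spearman_mortality_distance(const)
  expect_true(is.na(res$rho))
  expect_equal(res$method, "degenerate")
})

test_that("Spearman exact permutation p agrees with cor.test and with its
           own large-sample approximation", {
  set.seed(51)
  dev <- numeric(10)
  for (i in 1:10) {
    x <- sample(1000, 7); y <- sample(1000, 7)   # tie-free
    mine <- zooseis:::spearman_test(x, y, exact_limit = 9)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(mine$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ct$p.value, tolerance = 1e-12)
    dev[i] <- abs(zooseis:::spearman_test(x, y, exact_limit = 0)$p_value -
                    mine$p_value)
  }
  # t approximation tracks the discrete exact distribution on average
  expect_lt(mean(dev), 0.02)
  expect_lt(max(dev), 0.05)
})

test_that("Mann-Whitney matches exact enumeration landmarks and wilcox.test", {
  sep <- nets_from(distance = 1:8, prop_dead = c(1:4, 11:14) / 20,
                   phase = rep(c("during", "after"), each = 4))
  res <- mann_whitney_during_after(sep)
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)
  swap <- sep; swap$phase <- rev(swap$phase)
  expect_equal(mann_whitney_during_after(swap)$p_value, res$p_value)
  ident <- nets_from(distance = 1:8, prop_dead = rep(0.2, 8),
                     phase = rep(c("during", "after"), each = 4))
  expect_equal(mann_whitney_during_after(ident)$p_value, 1)
  set.seed(52)
  for (i in 1:5) {
    x <- sample(1000, 5); y <- sample(1000, 6)
    mine <- zooseis:::mann_whitney_test(x, y)
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$U, unname(wt$statistic))
    expect_equal(mine$p_value, wt$p.value, tolerance = 1e-12)
  }
  one_sided_empty <- nets_from(distance = 1:3, prop_dead = c(0.1, 0.2, 0.3))
  expect_error(mann_whitney_during_after(one_sided_empty), "non-empty")
})

test_that("cumulative mortality curve does per-day bookkeeping", {
  bag <- data.frame(bag_id = 1, treatment = "x", n0 = 10,
                    dead_day0 = 1, dead_day1 = 1, dead_day2 = 1,
                    dead_day3 = 2, dead_day4 = 2, dead_day5 = 2,
                    dead_day6 = 2, dead_day7 = 2)
  cv <- cumulative_mortality_curve(bag, "x")
  expect_equal(cv$mean, c(0.1, 0.1, 0.1, 0.2, 0.2, 0.2, 0.2, 0.2))
  zero <- bag; zero[grep("dead", names(zero))] <- 0
  expect_true(all(cumulative_mortality_curve(zero, "x")$mean == 0))
  for (seed in 1:5) {
    bt <- gen_bag_trials(mortality_scenario(seed = seed))
    for (tr in unique(bt$treatment))
      expect_true(all(diff(cumulative_mortality_curve(bt, tr)$mean) >= -1e-12))
  }
})

test_that("binomial GLM recovers a planted treatment log-odds contrast", {
  set.seed(53)
  dat <- independent_bag_days(list(control = 50, exposed = 50), 50,
                              list(control = 0.1, exposed = 0.3))
  fit <- fit_mortality_glm(dat)
  est <- fit$coefficients[fit$coefficients$term == "treatmentexposed", ]
  truth <- log((0.3 / 0.7) / (0.1 / 0.9))
  expect_lt(abs(est$estimate - truth), 3 * est$se)
  expect_lt(fit$treatment_p, 1e-6)
})

test_that("GLM supports immediate-only, factor-day, separation flag, and
           is row-order invariant", {
  bt <- gen_bag_trials(mortality_scenario(seed = 7))
  imm <- suppressWarnings(fit_bag_glm(bt, immediate_only = TRUE))
  expect_false(any(grepl("day", imm$coefficients$term)))
  fac <- suppressWarnings(fit_bag_glm(bt, day_as_factor = TRUE))
  expect_true(any(grepl("day_term1", fac$coefficients$term)))
  sep_dat <- independent_bag_days(list(control = 6, exposed = 6), 10,
                                  list(control = 0.3, exposed = 0))
  expect_warning(fit_sep <- fit_mortality_glm(sep_dat), "separation")
  expect_true(fit_sep$separation)
  full <- suppressWarnings(fit_bag_glm(bt))
  shuffled <- bt[sample(nrow(bt)), ]
  full2 <- suppressWarnings(fit_bag_glm(shuffled))
  expect_equal(full$treatment_p, full2$treatment_p, tolerance = 1e-12)
  expect_error(fit_mortality_glm(sep_dat[sep_dat$treatment == "control", ]),
               ">= 2 treatments")
})

test_that("rank tests are invariant to input row order", {
  set.seed(54)
  nets <- gen_net_samples(mortality_scenario(seed = 9),
                          distances = seq(500, 9500, length.out = 15),
                          after_distances = seq(1000, 9000, length.out = 8))
  perm <- nets[sample(nrow(nets)), ]
  expect_equal(spearman_mortality_distance(nets)$p_value,
               spearman_mortality_distance(perm)$p_value)
  expect_equal(mann_whitney_during_after(nets)$p_value,
               mann_whitney_during_after(perm)$p_value)
})

test_that("power analysis saturates for huge effects and validates input", {
  big <- mortality_scenario(treatments = list(
    list(name = "control", n_bags = 12, n_individuals = 10,
         day0_death_prob = 0.05, daily_hazard = 0),
    list(name = "exposed", n_bags = 36, n_individuals = 10,
         day0_death_prob = 0.9, daily_hazard = 0)), seed = 10)
  pw <- power_analysis(big, n_reps = 100, immediate_only = TRUE)
  expect_gte(pw$power, 0.99)
  expect_error(power_analysis(big, n_reps = 50), "100")
  degenerate <- mortality_scenario(treatments = list(
    list(name = "a", n_bags = 2, n_individuals = 10,
         day0_death_prob = 0, daily_hazard = 0),
    list(name = "b", n_bags = 2, n_individuals = 10,
         day0_death_prob = 0, daily_hazard = 0)))
  expect_error(power_analysis(degenerate, n_reps = 100), "degenerate")
})
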