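#' Proportion of dead individuals
#'
#' @param dead Dead count(s).
#' @param total Total count(s); must be positive.
#' @return `dead / total`.
#' @export
proportion_dead <- function(dead, total) {
  if (any(total <= 0)) stop_invalid("total must be > 0")
  dead / total
}

# All permutations of 1..n as an (n! x n) index matrix.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Spearman correlation of net mortality with source distance
#'
#' Rank correlation (mid-ranks for ties) of the proportion of dead
#' individuals against distance, restricted to one sampling phase. For
#' n <= `exact_limit` the two-sided p-value is computed by exhaustive
#' permutation of one margin's ranks; above that, the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom is used.
#'
#' @param samples Net samples (`distance_m`, `phase`, `n_live`, `n_dead`).
#' @param phase Phase to test (`"during"` by default).
#' @param exact_limit Largest n for exhaustive enumeration.
#' @return List: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_mortality_distance <- function(samples, phase = "during",
                                        exact_limit = 9) {
  s <- samples[samples$phase == phase, , drop = FALSE]
  n <- nrow(s)
  if (n < 3) stop_invalid("need >= 3 samples in phase '%s'", phase)
  prop <- proportion_dead(s$n_dead, s$n_live + s$n_dead)
  spearman_test(s$distance_m, prop, exact_limit)
}

spearman_test <- function(x, y, exact_limit = 9) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "degenerate"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    pm <- all_perms(n)
    ry_mat <- matrix(ry[pm], nrow(pm), n)
    rx_c <- rx - mean(rx)
    # cor for each permuted ry; means/sds invariant under permutation
    num <- as.vector(ry_mat %*% rx_c)
    den <- sqrt(sum(rx_c^2) * sum((ry - mean(ry))^2))
    rho_all <- num / den
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    list(rho = rho, p_value = p, n = n, method = "exact permutation")
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    list(rho = rho, p_value = 2 * stats::pt(-abs(tt), n - 2), n = n,
         method = "t approximation")
  }
}

#' Mann-Whitney test of mortality during versus after exposure
#'
#' Two-sided rank-sum test on the proportion of dead individuals between
#' the `during` and `after` sampling phases. Ties get mid-ranks. For
#' total n <= `exact_limit` the permutation distribution of the rank sum
#' is enumerated exhaustively over all group assignments (tie-exact);
#' above that a normal approximation with tie correction is used.
#'
#' @param samples Net samples with a `phase` column.
#' @param exact_limit Largest total n for exhaustive enumeration.
#' @return List: `U`, `p_value`, `n1`, `n2`, `method`.
#' @export
mann_whitney_during_after <- function(samples, exact_limit = 14) {
  g1 <- samples$phase == "during"
  g2 <- samples$phase == "after"
  if (!any(g1) || !any(g2)) stop_invalid("both phases must be non-empty")
  prop <- proportion_dead(samples$n_dead, samples$n_live + samples$n_dead)
  mann_whitney_test(prop[g1], prop[g2], exact_limit)
}

mann_whitney_test <- function(x, y, exact_limit = 14) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_limit) {
    combs <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combs], n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
    list(U = U, p_value = p, n1 = n1, n2 = n2, method = "exact permutation")
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sigma2)
    list(U = U, p_value = 2 * stats::pnorm(-abs(z)), n1 = n1, n2 = n2,
         method = "normal approximation")
  }
}

bag_day_cols <- function(trials) {
  cols <- grep("^dead_day[0-9]+$", names(trials), value = TRUE)
  cols[order(as.integer(sub("dead_day", "", cols)))]
}

#' Reshape bag trials to long bag-day format
#'
#' One row per bag and follow-up day with cumulative `dead` and remaining
#' `alive` counts — the binomial encoding used by the mortality models.
#'
#' @param trials Bag trials from [gen_bag_trials()] or [read_bags_csv()].
#' @return Data frame: `bag_id`, `treatment`, `day`, `dead`, `alive`.
#' @export
bag_trials_long <- function(trials) {
  cols <- bag_day_cols(trials)
  days <- as.integer(sub("dead_day", "", cols))
  out <- do.call(rbind, lapply(seq_along(cols), function(i) {
    data.frame(bag_id = trials$bag_id, treatment = trials$treatment,
               day = days[i], dead = trials[[cols[i]]],
               alive = trials$n0 - trials[[cols[i]]])
  }))
  out[order(out$bag_id, out$day), , drop = FALSE]
}

#' Cumulative mortality curve of one treatment
#'
#' Across-bag mean and standard deviation of the cumulative proportion
#' dead for each follow-up day.
#'
#' @param trials Bag trials.
#' @param treatment Treatment name.
#' @return Data frame: `day`, `mean`, `sd`, `n_bags`.
#' @export
cumulative_mortality_curve <- function(trials, treatment) {
  tr <- trials[trials$treatment == treatment, , drop = FALSE]
  if (nrow(tr) == 0) stop_invalid("no bags with treatment '%s'", treatment)
  cols <- bag_day_cols(tr)
  days <- as.integer(sub("dead_day", "", cols))
  prop <- as.matrix(tr[cols]) / tr$n0
  data.frame(day = days,
             mean = colMeans(prop),
             sd = apply(prop, 2, stats::sd),
             n_bags = nrow(tr))
}

#' Binomial GLM of mortality on treatment and time
#'
#' Logit-link binomial model of per-bag-day (dead, alive) counts with
#' treatment and day as fixed effects and (by default) their interaction:
#' `cbind(dead, alive) ~ treatment * day`. Day enters as a continuous
#' covariate by default (`day_as_factor = TRUE` switches to factor
#' coding). The reported `treatment_p` is the likelihood-ratio p-value of
#' all treatment terms (main effects plus interaction) against the
#' day-only model; per-coefficient Wald tests are in `coefficients`.
#'
#' Repeated measures on the same bag across days are not modelled — the
#' fit treats bag-days as independent binomials, so for data with strong
#' within-bag correlation its test is anti-conservative.
#'
#' Complete separation (a treatment with no deaths, or no survivors, over
#' the whole table) is detected and flagged with a warning; the
#' maximum-likelihood coefficients involved diverge and their Wald tests
#' are meaningless, but the likelihood-ratio `treatment_p` remains usable.
#'
#' @param data Long bag-day data (`treatment`, `day`, `dead`, `alive`),
#'   e.g. from [bag_trials_long()].
#' @param include_interaction Include `treatment:day`?
#' @param day_as_factor Treat day as a factor instead of continuous?
#' @param reference Reference treatment level for contrasts.
#' @return An object of class `mortality_glm`: `coefficients` (data
#'   frame: term, estimate, se, p), `treatment_p`, `formula`, `n`,
#'   `separation`, and the underlying `glm` fit.
#' @export
fit_mortality_glm <- function(data, include_interaction = TRUE,
                              day_as_factor = FALSE,
                              reference = "control") {
  if (length(unique(data$treatment)) < 2)
    stop_invalid("need >= 2 treatments")
  lev <- unique(data$treatment)
  if (reference %in% lev) lev <- c(reference, setdiff(lev, reference))
  data$treatment <- factor(data$treatment, levels = lev)
  data$day_term <- if (day_as_factor) factor(data$day) else data$day
  sep <- vapply(split(data, data$treatment),
                function(d) sum(d$dead) == 0 || sum(d$alive) == 0,
                logical(1))
  if (any(sep))
    warning("complete separation: treatment(s) ",
            paste(names(sep)[sep], collapse = ", "),
            " have all-zero deaths or survivors; Wald tests unreliable")
  has_day <- length(unique(data$day)) > 1
  rhs <- if (!has_day) "treatment"
  else if (include_interaction) "treatment * day_term"
  else "treatment + day_term"
  f1 <- stats::as.formula(paste("cbind(dead, alive) ~", rhs))
  f0 <- stats::as.formula(paste("cbind(dead, alive) ~",
                                if (has_day) "day_term" else "1"))
  fit <- stats::glm(f1, family = stats::binomial(), data = data)
  fit0 <- stats::glm(f0, family = stats::binomial(), data = data)
  lrt <- stats::anova(fit0, fit, test = "Chisq")
  cf <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], p = cf[, 4], row.names = NULL),
    treatment_p = lrt$`Pr(>Chi)`[2],
    formula = paste(deparse(f1), collapse = ""),
    n = nrow(data), separation = any(sep), fit = fit
  ), class = "mortality_glm")
}

#' @export
print.mortality_glm <- function(x, ...) {
  cat(sprintf("binomial GLM: %s (n = %d bag-days)\n", x$formula, x$n))
  print(x$coefficients, digits = 3)
  cat(sprintf("treatment effect (LRT): p = %.4g%s\n", x$treatment_p,
              if (x$separation) "  [complete separation flagged]" else ""))
  invisible(x)
}

#' Binomial GLM on bag trials
#'
#' Convenience wrapper fitting [fit_mortality_glm()] to bag trials, either
#' on the full cumulative follow-up (all days) or restricted to immediate
#' (day 0) mortality with treatment as the only fixed effect.
#'
#' @param trials Bag trials.
#' @param immediate_only Use only day-0 counts?
#' @inheritParams fit_mortality_glm
#' @return A `mortality_glm` object.
#' @export
fit_bag_glm <- function(trials, include_interaction = TRUE,
                        day_as_factor = FALSE, reference = "control",
                        immediate_only = FALSE) {
  long <- bag_trials_long(trials)
  if (immediate_only) long <- long[long$day == 0, , drop = FALSE]
  fit_mortality_glm(long, include_interaction = include_interaction,
                    day_as_factor = day_as_factor, reference = reference)
}

#' Monte Carlo power of the bag-experiment treatment test
#'
#' Simulates the bag experiment `n_reps` times from the scenario, fits
#' the mortality GLM to each replicate, and reports the fraction of
#' replicates whose treatment likelihood-ratio p-value falls below
#' `alpha`, with a binomial standard error. Under a null scenario
#' (identical treatments) this estimates the test's size; under an effect
#' scenario, its power.
#'
#' @param scenario A [mortality_scenario()].
#' @param n_reps Number of simulated experiments (>= 100).
#' @param alpha Significance threshold.
#' @param immediate_only Restrict the fitted model to day-0 mortality?
#' @return List: `power`, `se`, `n_reps`, `alpha`.
#' @export
power_analysis <- function(scenario, n_reps = 200, alpha = 0.05,
                           immediate_only = FALSE) {
  stopifnot(inherits(scenario, "mortality_scenario"))
  if (n_reps < 100) stop_invalid("n_reps must be >= 100")
  p_any <- vapply(scenario$treatments,
                  function(tr) tr$day0_death_prob + tr$daily_hazard, numeric(1))
  if (all(p_any == 0))
    stop_invalid("degenerate scenario: no treatment has any mortality")
  hits <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    sc <- scenario
    sc$seed <- scenario$seed + r
    trials <- gen_bag_trials(sc)
    res <- tryCatch(
      suppressWarnings(fit_bag_glm(trials, immediate_only = immediate_only,
                                   reference = scenario$treatments[[1]]$name)),
      error = function(e) NULL)
    hits[r] <- !is.null(res) && is.finite(res$treatment_p) &&
      res$treatment_p < alpha
  }
  power <- mean(hits)
  list(power = power, se = sqrt(power * (1 - power) / n_reps),
       n_reps = n_reps, alpha = alpha)
}
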