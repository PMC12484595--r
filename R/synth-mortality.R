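#' Simulate bag exposure trials
#'
#' Simulates the bag experiment: per bag, day-0 deaths are binomial with
#' the treatment's immediate death probability, and each survivor dies
#' independently on each follow-up day with the treatment's daily hazard
#' (geometric survival — the daily inspection schedule makes a discrete
#' hazard the natural model). Dead counts are reported cumulatively and
#' are nondecreasing by construction.
#'
#' @param scenario A [mortality_scenario()].
#' @return A data frame of class `bag_trials`: `bag_id`, `treatment`,
#'   `line_id`, `n0`, and cumulative dead counts `dead_day0` ..
#'   `dead_day<follow_up_days>`.
#' @export
gen_bag_trials <- function(scenario) {
  stopifnot(inherits(scenario, "mortality_scenario"))
  days <- 0:scenario$follow_up_days
  with_seed(scenario$seed, {
    rows <- list()
    bag_id <- 0L
    for (tr in scenario$treatments) {
      for (b in seq_len(tr$n_bags)) {
        bag_id <- bag_id + 1L
        n <- tr$n_individuals
        dead <- stats::rbinom(1, n, tr$day0_death_prob)
        cum <- integer(length(days))
        cum[1] <- dead
        for (d in seq_len(scenario$follow_up_days)) {
          new_dead <- stats::rbinom(1, n - cum[d], tr$daily_hazard)
          cum[d + 1] <- cum[d] + new_dead
        }
        row <- data.frame(bag_id = bag_id, treatment = tr$name,
                          line_id = ((b - 1L) %/% 3L) + 1L, n0 = n)
        row[paste0("dead_day", days)] <- as.list(cum)
        rows[[bag_id]] <- row
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("bag_trials", "data.frame")
    out
  })
}

#' Simulate net hauls during and after an approach
#'
#' Draws per-haul dead counts from a beta-binomial around the scenario's
#' expected mortality-versus-distance curve. The beta-binomial dispersion
#' reproduces the overdispersion of field hauls, where mortality varies
#' widely along an approach. Hauls are flagged `during` or `after`
#' exposure.
#'
#' @param scenario A [mortality_scenario()].
#' @param distances Distances of the `during` hauls (m).
#' @param after_distances Distances of `after` hauls (m); may be empty.
#' @param approach Approach label(s) recycled across hauls.
#' @return A data frame of class `net_samples`: `haul_id`, `approach`,
#'   `distance_m`, `phase`, `n_live`, `n_dead`.
#' @export
gen_net_samples <- function(scenario, distances,
                            after_distances = numeric(0), approach = 1L) {
  stopifnot(inherits(scenario, "mortality_scenario"))
  if (length(distances) == 0) stop_invalid("distances must be non-empty")
  d_all <- c(distances, after_distances)
  phase <- rep(c("during", "after"), c(length(distances), length(after_distances)))
  p <- scenario$net_mortality_curve(d_all)
  if (any(p < 0 | p > 1)) stop_invalid("net_mortality_curve must return values in [0,1]")
  n <- scenario$net_n_individuals
  rho <- scenario$net_dispersion
  with_seed(scenario$seed + 1L, {
    p_draw <- if (rho > 0) {
      # beta with mean p and intra-class correlation rho
      a <- p * (1 - rho) / rho
      b <- (1 - p) * (1 - rho) / rho
      ifelse(p %in% c(0, 1), p, stats::rbeta(length(p), a, b))
    } else p
    dead <- stats::rbinom(length(p_draw), n, p_draw)
    out <- data.frame(haul_id = seq_along(d_all),
                      approach = rep_len(approach, length(d_all)),
                      distance_m = d_all, phase = phase,
                      n_live = n - dead, n_dead = dead)
    class(out) <- c("net_samples", "data.frame")
    out
  })
}
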