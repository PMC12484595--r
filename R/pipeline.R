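#' Configuration of a full pipeline run
#'
#' Bundles every scenario and analysis parameter into one object with
#' defaults matching the field protocol: 10 s analysis windows over
#' 10 Hz-20 kHz, a 2 m x 2 s echo-integration grid with 5 m surface
#' exclusion, 1 km distance bins up to 9 km, and a 5% significance
#' threshold. Override any block by passing a named list of replacements;
#' unspecified entries keep their defaults.
#'
#' @param seed Master seed; each stage derives its own scenario seed from
#'   it, so a run is fully determined by its config.
#' @param approach,layer,mortality,image Named lists of overrides for the
#'   corresponding scenario constructor arguments.
#' @param analysis Named list of overrides for the analysis block
#'   (`window_length`, `f_lo`, `f_hi`, `p2p_on_filtered`,
#'   `surface_exclusion`, `bottom_clearance`, `bin_width`,
#'   `max_distance`, `alpha`, `reference`, `sound_duration`, `n_images`,
#'   `n_net_hauls`).
#' @param stain Named list of overrides for [stain_thresholds()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, approach = list(), layer = list(),
                       mortality = list(), image = list(),
                       analysis = list(), stain = list()) {
  default_analysis <- list(
    window_length = 10, f_lo = 10, f_hi = 20000, p2p_on_filtered = TRUE,
    surface_exclusion = 5, bottom_clearance = 5,
    bin_width = 1000, max_distance = 9000,
    alpha = 0.05, reference = "control",
    sound_duration = 120, n_images = 4, n_net_hauls = 27)
  merge_block <- function(defaults, over) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop_invalid("unknown config entries: %s",
                                  paste(bad, collapse = ", "))
    utils::modifyList(defaults, over)
  }
  structure(list(
    seed = as.integer(seed),
    approach = approach, layer = layer, mortality = mortality,
    image = image,
    analysis = merge_block(default_analysis, analysis),
    stain = stain
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The file may contain any subset of the blocks `seed`, `approach`,
#' `layer`, `mortality`, `image`, `analysis`, `stain`; missing entries
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y),
    c("seed", "approach", "layer", "mortality", "image", "analysis", "stain"))])
}

config_scenarios <- function(config) {
  list(
    approach = do.call(approach_scenario,
                       utils::modifyList(list(seed = config$seed),
                                         config$approach)),
    layer = do.call(layer_scenario,
                    utils::modifyList(list(seed = config$seed + 100L),
                                      config$layer)),
    mortality = do.call(mortality_scenario,
                        utils::modifyList(list(seed = config$seed + 200L),
                                          config$mortality)),
    image = do.call(image_scenario,
                    utils::modifyList(list(seed = config$seed + 300L),
                                      config$image))
  )
}

#' Generate a complete synthetic dataset directory
#'
#' Emits every input the analysis stages consume — track CSV, airgun WAV
#' plus shot log, Sv grid CSV, bags CSV, nets CSV, stained-organism PNGs
#' with a labels CSV — from one configuration.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config_scenarios(config)
  an <- config$analysis
  paths <- list()

  track <- gen_approach_track(sc$approach)
  paths$track <- write_track_csv(track, file.path(out_dir, "track.csv"))

  snd_sc <- sc$approach
  snd_sc$duration <- min(an$sound_duration, sc$approach$duration)
  sim <- gen_airgun_recording(snd_sc, track, window_length = an$window_length)
  paths$wav <- write_wav(sim$rec$samples, file.path(out_dir, "recording.wav"),
                         snd_sc$sample_rate, format = "float")
  utils::write.csv(sim$shots, file.path(out_dir, "shots.csv"), row.names = FALSE)
  paths$shots <- file.path(out_dir, "shots.csv")

  ech <- gen_echogram(sc$layer, track)
  paths$grid <- write_svgrid_csv(ech$grid, file.path(out_dir, "svgrid.csv"))

  bags <- gen_bag_trials(sc$mortality)
  paths$bags <- write_bags_csv(bags, file.path(out_dir, "bags.csv"))
  nets <- gen_net_samples(sc$mortality,
                          distances = net_haul_distances(an$n_net_hauls),
                          after_distances = net_haul_distances(10))
  paths$nets <- write_nets_csv(nets, file.path(out_dir, "nets.csv"))

  imgs <- gen_stain_images(sc$image, n_images = an$n_images)
  lab_all <- list()
  for (i in seq_along(imgs)) {
    p <- file.path(out_dir, sprintf("stain_%02d.png", i))
    png::writePNG(imgs[[i]]$image, p)
    lab <- imgs[[i]]$labels
    if (nrow(lab)) lab$image <- basename(p)
    lab_all[[i]] <- lab
  }
  utils::write.csv(do.call(rbind, lab_all),
                   file.path(out_dir, "stain_labels.csv"), row.names = FALSE)
  paths$images <- file.path(out_dir, sprintf("stain_%02d.png", seq_along(imgs)))
  invisible(paths)
}

net_haul_distances <- function(n) seq(500, 9500, length.out = n)

#' Run the full pipeline on synthetic data
#'
#' Simulates each stage's inputs from the configuration, runs the
#' corresponding analysis, and returns a report juxtaposing recovered
#' quantities with the generator's ground truth: windowed sound metrics
#' versus the planted shot log, vertical-indicator regressions versus the
#' planted layer response, image classification accuracy versus the true
#' labels, and the mortality statistics versus the scenario expectations.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the report is written
#'   as `report.json` (with the config embedded) and a `summary.md`.
#' @param stages Which stages to run; the sound stage is the slow one
#'   (megasamples of waveform) and can be dropped when only the
#'   ecological stages are of interest.
#' @return A list of class `pipeline_report`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL,
                    stages = c("sound", "echo", "images", "mortality")) {
  stopifnot(inherits(config, "run_config"))
  sc <- config_scenarios(config)
  an <- config$analysis
  track <- gen_approach_track(sc$approach)
  report <- list(seed = config$seed, stages = stages)

  if ("sound" %in% stages) {
    snd_sc <- sc$approach
    snd_sc$duration <- min(an$sound_duration, sc$approach$duration)
    sim <- gen_airgun_recording(snd_sc, track, window_length = an$window_length)
    metrics <- metrics_vs_distance(sim$rec, track,
                                   window_length = an$window_length,
                                   f_lo = an$f_lo, f_hi = an$f_hi,
                                   filter = an$p2p_on_filtered)
    joined <- merge(metrics, sim$window_truth,
                    by.x = "window_start_s", by.y = "window_start_s")
    shot_win <- joined$n_shots > 0
    report$sound <- list(
      n_windows = nrow(metrics),
      max_sel_db = max(metrics$sel_db),
      max_p2p_pa = max(metrics$p2p_pa),
      mean_abs_sel_error_db = mean(abs(joined$sel_db - joined$expected_sel_db)),
      mean_noise_window_sel_db =
        if (any(!shot_win)) mean(joined$sel_db[!shot_win]) else NA_real_,
      noise_floor_sel_db = sc$approach$noise_floor_sel,
      metrics = metrics)
  }

  if ("echo" %in% stages) {
    ech <- gen_echogram(sc$layer, track)
    grid <- apply_exclusions(ech$grid, an$surface_exclusion, an$bottom_clearance)
    ind <- add_distance(indicators_by_time(grid), track)
    ind <- ind[ind$distance_m <= an$max_distance, , drop = FALSE]
    fit_cm <- fit_indicator_glm(ind, "cm")
    fit_in <- fit_indicator_glm(ind, "inertia")
    report$echo <- list(
      n_time_bins = nrow(ind),
      mean_cm_m = mean(ind$cm_m, na.rm = TRUE),
      mean_inertia_m2 = mean(ind$inertia_m2, na.rm = TRUE),
      cm_slope_per_km = fit_cm$slope * 1000, cm_p = fit_cm$p_value,
      inertia_slope_per_km = fit_in$slope * 1000, inertia_p = fit_in$p_value,
      planted_cm_slope_per_km = sc$layer$cm_response_slope,
      planted_inertia_slope_per_km = sc$layer$inertia_response_slope,
      binned = bin_by_distance(ind, an$bin_width, an$max_distance))
  }

  if ("images" %in% stages) {
    thr <- do.call(stain_thresholds, config$stain)
    imgs <- gen_stain_images(sc$image, n_images = an$n_images)
    rep_v <- batch_vital_report(imgs, thr)
    truth <- do.call(rbind, lapply(imgs, `[[`, "labels"))
    # per-image counts are comparable even without region matching
    true_dead <- sum(truth$status == "dead")
    pooled <- rep_v$summary[rep_v$summary$image == "pooled", ]
    acc <- classification_accuracy(imgs, thr)
    report$images <- list(
      n_organisms_true = nrow(truth),
      n_detected = pooled$n_live + pooled$n_dead,
      proportion_dead = pooled$proportion_dead,
      true_proportion_dead = true_dead / max(nrow(truth), 1),
      accuracy = acc)
  }

  if ("mortality" %in% stages) {
    trials <- gen_bag_trials(sc$mortality)
    curves <- lapply(unique(trials$treatment),
                     function(tr) cumulative_mortality_curve(trials, tr))
    names(curves) <- unique(trials$treatment)
    fit_cum <- suppressWarnings(fit_bag_glm(trials, reference = an$reference))
    fit_imm <- suppressWarnings(fit_bag_glm(trials, reference = an$reference,
                                            immediate_only = TRUE))
    nets <- gen_net_samples(sc$mortality,
                            distances = net_haul_distances(an$n_net_hauls),
                            after_distances = net_haul_distances(10))
    sp <- spearman_mortality_distance(nets)
    mw <- mann_whitney_during_after(nets)
    day7 <- vapply(curves, function(cv) cv$mean[cv$day == max(cv$day)], numeric(1))
    imm_cf <- fit_imm$coefficients
    imm_contrast <- imm_cf$p[grepl("^treatment", imm_cf$term)]
    names(imm_contrast) <- sub("^treatment", "", imm_cf$term[grepl("^treatment", imm_cf$term)])
    report$mortality <- list(
      day7_mean_by_treatment = day7,
      cumulative_treatment_p = fit_cum$treatment_p,
      immediate_treatment_p = fit_imm$treatment_p,
      immediate_contrast_p = imm_contrast,
      spearman_rho = sp$rho, spearman_p = sp$p_value, spearman_n = sp$n,
      mann_whitney_U = mw$U, mann_whitney_p = mw$p_value,
      curves = curves)
  }

  report <- structure(report, class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    json <- report
    json$config <- unclass(config)
    json$config$mortality$net_mortality_curve <- NULL
    for (st in c("sound", "echo", "mortality"))
      json[[st]][c("metrics", "binned", "curves")] <- NULL
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(format_report_md(report), file.path(out_dir, "summary.md"))
  }
  report
}

classification_accuracy <- function(imgs, thr) {
  # score detections against planted labels by nearest organism center
  correct <- 0L; total <- 0L
  for (im in imgs) {
    if (nrow(im$labels) == 0) next
    seg <- segment_organisms(im$image, thr)
    if (nrow(seg$regions) == 0) next
    for (id in seg$regions$object_id) {
      idx <- which(seg$labels == id, arr.ind = TRUE)
      cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
      k <- which.min((im$labels$x - cx)^2 + (im$labels$y - cy)^2)
      call <- classify_stain(stain_fraction(im$image, seg$labels, id, thr), thr)
      total <- total + 1L
      if (call == im$labels$status[k]) correct <- correct + 1L
    }
  }
  if (total == 0) return(NA_real_)
  correct / total
}

format_report_md <- function(x) {
  out <- c("# Pipeline run summary", sprintf("seed: %d", x$seed), "")
  if (!is.null(x$sound)) out <- c(out, "## Sound", sprintf(
    "- %d windows; max SEL %.1f dB re 1 uPa^2 s; max p2p %.3g Pa; mean |SEL error| %.2f dB",
    x$sound$n_windows, x$sound$max_sel_db, x$sound$max_p2p_pa,
    x$sound$mean_abs_sel_error_db))
  if (!is.null(x$echo)) out <- c(out, "## Vertical distribution", sprintf(
    "- CM slope %.3g m/km (p = %.3g); inertia slope %.3g m^2/km (p = %.3g); planted %.3g / %.3g",
    x$echo$cm_slope_per_km, x$echo$cm_p, x$echo$inertia_slope_per_km,
    x$echo$inertia_p, x$echo$planted_cm_slope_per_km,
    x$echo$planted_inertia_slope_per_km))
  if (!is.null(x$images)) out <- c(out, "## Staining", sprintf(
    "- %d/%d organisms detected; proportion dead %.3f (true %.3f); accuracy %.3f",
    x$images$n_detected, x$images$n_organisms_true, x$images$proportion_dead,
    x$images$true_proportion_dead, x$images$accuracy))
  if (!is.null(x$mortality)) out <- c(out, "## Mortality", sprintf(
    "- cumulative treatment p = %.3g; immediate p = %.3g; Spearman rho = %.3f (p = %.3g); Mann-Whitney p = %.3g",
    x$mortality$cumulative_treatment_p, x$mortality$immediate_treatment_p,
    x$mortality$spearman_rho, x$mortality$spearman_p, x$mortality$mann_whitney_p))
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}
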