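#' Simulate photographs of Neutral Red stained zooplankton
#'
#' Draws dark elliptical organisms on a light background (dishes lit from
#' below), with the red-channel saturation of each body sampled from a
#' class-conditional range: strong uptake for live animals, diffusive
#' residual uptake for dead ones. Organisms are placed without overlap by
#' rejection sampling; true labels are returned for accuracy scoring.
#'
#' Images are H x W x 3 arrays of channel values in [0, 1] (the layout of
#' `png::readPNG`). Body color is HSV with hue 0 (red), saturation equal
#' to the stain intensity, and fixed value, so a saturation threshold
#' separates the classes exactly when the class ranges are disjoint.
#'
#' @param scenario An [image_scenario()].
#' @param n_images Number of images to generate.
#' @return A list of class `stain_image_set`; each element has `image`
#'   (array) and `labels` (data frame: `organism`, `x`, `y`, `a`, `b`,
#'   `angle`, `stain`, `status`).
#' @export
gen_stain_images <- function(scenario, n_images = 1) {
  stopifnot(inherits(scenario, "image_scenario"))
  out <- with_seed(scenario$seed, {
    lapply(seq_len(n_images), function(i) gen_one_stain_image(scenario))
  })
  structure(out, class = "stain_image_set")
}

gen_one_stain_image <- function(sc) {
  w <- sc$width; h <- sc$height
  img <- array(sc$background_level, dim = c(h, w, 3))
  n <- sc$n_organisms
  labels <- data.frame(organism = integer(0), x = numeric(0), y = numeric(0),
                       a = numeric(0), b = numeric(0), angle = numeric(0),
                       stain = numeric(0), status = character(0))
  if (n > 0) {
    n_live <- stats::rbinom(1, n, sc$live_fraction)
    status <- sample(c(rep("live", n_live), rep("dead", n - n_live)))
    placed <- matrix(numeric(0), 0, 3)    # x, y, radius
    max_r <- max(sc$organism_size_px)
    if (2 * max_r + 4 > min(w, h))
      stop_invalid("canvas too small for the organism size range")
    for (k in seq_len(n)) {
      a <- stats::runif(1, sc$organism_size_px[1], sc$organism_size_px[2])
      b <- a * stats::runif(1, 0.4, 0.8)       # copepod-like elongation
      ang <- stats::runif(1, 0, pi)
      ok <- FALSE
      for (try in 1:200) {
        cx <- stats::runif(1, a + 2, w - a - 2)
        cy <- stats::runif(1, a + 2, h - a - 2)
        if (nrow(placed) == 0 ||
            all((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2 >
                (placed[, 3] + a + 2)^2)) { ok <- TRUE; break }
      }
      if (!ok) stop_invalid(
        "failed to place %d non-overlapping organisms on a %dx%d canvas", n, w, h)
      placed <- rbind(placed, c(cx, cy, a))
      rng <- if (status[k] == "live") sc$live_stain_range else sc$dead_stain_range
      stain <- stats::runif(1, rng[1], rng[2])
      img <- draw_ellipse(img, cx, cy, a, b, ang,
                          hsv_red(stain, sc$body_value))
      labels <- rbind(labels, data.frame(
        organism = k, x = cx, y = cy, a = a, b = b, angle = ang,
        stain = stain, status = status[k]))
    }
  }
  if (sc$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), sd = sc$noise_sd), dim = dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  list(image = img, labels = labels)
}

# RGB of an HSV color with hue 0 (red): R = v, G = B = v * (1 - s).
hsv_red <- function(sat, value) c(value, value * (1 - sat), value * (1 - sat))

draw_ellipse <- function(img, cx, cy, a, b, ang, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  xs <- max(1, floor(cx - a)):min(w, ceiling(cx + a))
  ys <- max(1, floor(cy - a)):min(h, ceiling(cy + a))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(ang) + dy * sin(ang)
  v <- -dx * sin(ang) + dy * cos(ang)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  for (ch in 1:3) {
    sub <- img[ys, xs, ch]
    sub[inside] <- rgb[ch]
    img[ys, xs, ch] <- sub
  }
  img
}
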