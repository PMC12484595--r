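#' Color thresholds for Neutral Red live/dead classification
#'
#' The classifier marks a pixel as stained when its HSV coordinates fall
#' in a red hue window (circular, so the default 330-30 degrees wraps
#' through 0), with saturation above `min_sat` and value inside
#' `[min_val, max_val]`. An organism is called live when the fraction of
#' its pixels that are stained reaches `min_stain_frac` (the >= boundary
#' counts as live). The field macro's numeric thresholds are not
#' published, so these are explicit, per-batch configuration with
#' defaults chosen on synthetic fixtures.
#'
#' @param hue_lo,hue_hi Red hue window edges (degrees); `hue_lo > hue_hi`
#'   wraps around 0.
#' @param min_sat Minimum saturation of a stained pixel.
#' @param min_val,max_val Value (brightness) window of a stained pixel.
#' @param min_stain_frac Minimum stained-pixel fraction for a live call.
#' @param min_area,max_area Connected-component area bounds (px).
#' @return An object of class `stain_thresholds`.
#' @export
stain_thresholds <- function(hue_lo = 330, hue_hi = 30,
                             min_sat = 0.45,
                             min_val = 0.1, max_val = 1,
                             min_stain_frac = 0.3,
                             min_area = 20, max_area = Inf) {
  if (min_stain_frac < 0 || min_stain_frac > 1)
    stop_invalid("min_stain_frac must be in [0,1]")
  if (hue_lo == hue_hi) stop_invalid("hue window is empty")
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi, min_sat = min_sat,
                 min_val = min_val, max_val = max_val,
                 min_stain_frac = min_stain_frac,
                 min_area = min_area, max_area = max_area),
            class = "stain_thresholds")
}

# 8-connectivity labeling: EBImage::bwlabel is 4-connected, so labels
# touching only diagonally are merged afterwards with union-find.
label_components8 <- function(bw) {
  lab <- EBImage::bwlabel(bw)
  nl <- max(lab)
  if (nl < 2) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1, 1), c(1, -1))) {
    a <- lab[1:(nr - 1), if (shift[2] == 1) 1:(nc - 1) else 2:nc]
    b <- lab[2:nr, if (shift[2] == 1) 2:nc else 1:(nc - 1)]
    touch <- a > 0 & b > 0 & a != b
    if (any(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment organisms from a stained-plankton photograph
#'
#' Foreground/background separation by automatic (Otsu) thresholding of
#' the gray intensity — organisms are darker than the back-lit
#' background — followed by 8-connected component labeling and an area
#' filter. Touching organisms are not split; components whose area
#' exceeds `max_area` are dropped and should be reviewed manually.
#'
#' @param image H x W x 3 array of channel values in [0, 1].
#' @param thresholds A [stain_thresholds()].
#' @return List: `labels` (integer H x W matrix, 0 = background),
#'   `regions` (data frame: `object_id`, `area_px`).
#' @export
segment_organisms <- function(image, thresholds = stain_thresholds()) {
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  empty <- list(labels = matrix(0L, nrow(gray), ncol(gray)),
                regions = data.frame(object_id = integer(0),
                                     area_px = integer(0)))
  if (stats::sd(gray) < 1e-4) return(empty)
  th <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  fore <- gray < th
  if (!any(fore) || all(fore)) return(empty)
  # Otsu always splits something; demand a real bimodal separation so a
  # blank frame with pixel noise yields no detections
  s_within <- sqrt((stats::var(gray[fore]) + stats::var(gray[!fore])) / 2)
  if (is.na(s_within) ||
      mean(gray[!fore]) - mean(gray[fore]) < 4 * s_within) return(empty)
  bw <- matrix(as.numeric(fore), nrow(gray))
  lab <- label_components8(bw)
  ids <- setdiff(unique(as.vector(lab)), 0)
  if (length(ids) == 0)
    return(list(labels = lab,
                regions = data.frame(object_id = integer(0),
                                     area_px = integer(0))))
  areas <- tabulate(lab[lab > 0], nbins = max(ids))
  keep <- ids[areas[ids] >= thresholds$min_area &
                areas[ids] <= thresholds$max_area]
  lab[!(lab %in% keep)] <- 0L
  new_id <- match(lab, c(0L, keep)) - 1L
  lab <- matrix(as.integer(new_id), nrow(lab))
  list(labels = lab,
       regions = data.frame(object_id = seq_along(keep),
                            area_px = as.integer(areas[keep])))
}

stained_pixel_mask <- function(image, thresholds) {
  r <- as.vector(image[, , 1]); g <- as.vector(image[, , 2])
  b <- as.vector(image[, , 3])
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  in_hue <- if (thresholds$hue_lo <= thresholds$hue_hi)
    hue >= thresholds$hue_lo & hue <= thresholds$hue_hi
  else hue >= thresholds$hue_lo | hue <= thresholds$hue_hi
  pass <- in_hue & hsv[2, ] >= thresholds$min_sat &
    hsv[3, ] >= thresholds$min_val & hsv[3, ] <= thresholds$max_val
  matrix(pass, dim(image)[1], dim(image)[2])
}

#' Stain fraction of a segmented organism
#'
#' Fraction of the organism's pixels whose HSV coordinates fall in the
#' red stain window.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param labels Label matrix from [segment_organisms()].
#' @param object_id Which component.
#' @param thresholds A [stain_thresholds()].
#' @return Stained-pixel fraction in [0, 1].
#' @export
stain_fraction <- function(image, labels, object_id,
                           thresholds = stain_thresholds()) {
  idx <- labels == object_id
  if (!any(idx)) stop_invalid("object %d not present in labels", object_id)
  mean(stained_pixel_mask(image, thresholds)[idx])
}

#' Live/dead call from a stain fraction
#'
#' @param frac Stained-pixel fraction.
#' @param thresholds A [stain_thresholds()].
#' @return `"live"` if `frac >= min_stain_frac`, else `"dead"`.
#' @export
classify_stain <- function(frac, thresholds = stain_thresholds()) {
  ifelse(frac >= thresholds$min_stain_frac, "live", "dead")
}

#' Live/dead report over a batch of images
#'
#' Segments every image, classifies each detection, and tabulates live
#' and dead counts per image plus a pooled total. Images that cannot be
#' read are collected in an `errors` element rather than aborting the
#' batch.
#'
#' @param images A `stain_image_set`, a list of H x W x 3 arrays, or a
#'   character vector of PNG paths.
#' @param thresholds A [stain_thresholds()].
#' @return List of class `vital_report`: `summary` (data frame: `image`,
#'   `n_live`, `n_dead`, `proportion_dead`, with a pooled last row),
#'   `detections` (data frame: `image`, `object_id`, `area_px`,
#'   `stain_fraction`, `status`), `errors` (character).
#' @export
batch_vital_report <- function(images, thresholds = stain_thresholds()) {
  errors <- character(0)
  det_all <- list()
  per_image <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    name <- if (is.character(img)) img else sprintf("image_%d", i)
    arr <- tryCatch({
      if (is.character(img)) load_image(img)
      else if (is.list(img) && !is.null(img$image)) img$image
      else img
    }, error = function(e) e)
    if (inherits(arr, "error")) {
      errors <- c(errors, sprintf("%s: %s", name, conditionMessage(arr)))
      next
    }
    seg <- segment_organisms(arr, thresholds)
    if (nrow(seg$regions) > 0) {
      frac <- vapply(seg$regions$object_id, function(id)
        stain_fraction(arr, seg$labels, id, thresholds), numeric(1))
      status <- classify_stain(frac, thresholds)
      det_all[[name]] <- data.frame(image = name,
                                    object_id = seg$regions$object_id,
                                    area_px = seg$regions$area_px,
                                    stain_fraction = frac, status = status)
      n_live <- sum(status == "live"); n_dead <- sum(status == "dead")
    } else {
      n_live <- 0L; n_dead <- 0L
    }
    per_image[[name]] <- data.frame(
      image = name, n_live = n_live, n_dead = n_dead,
      proportion_dead = if (n_live + n_dead > 0) n_dead / (n_live + n_dead)
                        else NA_real_)
  }
  summary <- do.call(rbind, per_image)
  if (!is.null(summary) && nrow(summary) > 0) {
    tot_l <- sum(summary$n_live); tot_d <- sum(summary$n_dead)
    summary <- rbind(summary, data.frame(
      image = "pooled", n_live = tot_l, n_dead = tot_d,
      proportion_dead = if (tot_l + tot_d > 0) tot_d / (tot_l + tot_d)
                        else NA_real_))
    rownames(summary) <- NULL
  }
  detections <- if (length(det_all)) do.call(rbind, det_all) else NULL
  if (!is.null(detections)) rownames(detections) <- NULL
  structure(list(summary = summary, detections = detections, errors = errors),
            class = "vital_report")
}

#' @export
print.vital_report <- function(x, ...) {
  cat("vital staining report\n")
  print(x$summary, digits = 3)
  if (length(x$errors)) cat("unreadable:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

load_image <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  arr[, , 1:3, drop = FALSE]
}

#' Write an audit overlay with stained pixels marked
#'
#' Reproduces the field macro's audit image: every pixel inside a
#' segmented organism that passes the stain thresholds is painted vivid
#' green, so the basis of each live/dead call can be inspected.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param thresholds A [stain_thresholds()].
#' @param path Optional PNG output path; the overlay array is returned
#'   invisibly either way.
#' @return The overlay array, invisibly.
#' @export
stain_overlay <- function(image, thresholds = stain_thresholds(), path = NULL) {
  seg <- segment_organisms(image, thresholds)
  mark <- stained_pixel_mask(image, thresholds) & seg$labels > 0
  out <- image
  r <- out[, , 1]; g <- out[, , 2]; b <- out[, , 3]
  r[mark] <- 0; g[mark] <- 1; b[mark] <- 0
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  if (!is.null(path)) png::writePNG(out, path)
  invisible(out)
}
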