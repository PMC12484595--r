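#' Read and write pipeline CSV formats
#'
#' Plain-text interchange formats shared by the generators and analysis
#' stages: the approach track (`time_s`, `distance_m`), the Sv grid
#' (first column `depth_m` holding depth-bin centers, remaining columns
#' one per time-bin center, cells Sv in dB re 1 m^-1), bag trials and net
#' samples.
#'
#' @param x Object to write.
#' @param path File path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_track_csv <- function(x, path) {
  utils::write.csv(x[c("time_s", "distance_m")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_track_csv <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("time_s", "distance_m") %in% names(x)))
    stop_invalid("track CSV must have columns time_s, distance_m")
  x
}

#' @rdname pipeline_io
#' @export
write_svgrid_csv <- function(x, path) {
  stopifnot(inherits(x, "sv_grid"))
  df <- data.frame(depth_m = x$depth_centers, x$sv_db, check.names = FALSE)
  names(df)[-1] <- format(x$time_centers, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_svgrid_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "depth_m")
    stop_invalid("Sv grid CSV must have depth_m as its first column")
  sv_grid(as.matrix(df[-1]), df$depth_m, as.numeric(names(df)[-1]))
}

#' @rdname pipeline_io
#' @export
write_bags_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_bags_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("bag_id", "treatment", "n0")
  if (!all(need %in% names(x)) || length(grep("^dead_day", names(x))) == 0)
    stop_invalid("bags CSV must have bag_id, treatment, n0, dead_day* columns")
  class(x) <- c("bag_trials", "data.frame")
  x
}

#' @rdname pipeline_io
#' @export
write_nets_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_nets_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("haul_id", "distance_m", "phase", "n_live", "n_dead")
  if (!all(need %in% names(x)))
    stop_invalid("nets CSV must have columns %s", paste(need, collapse = ", "))
  class(x) <- c("net_samples", "data.frame")
  x
}
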