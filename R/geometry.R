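#' Sorter geometry
#'
#' Dimensions of the multi-column sorter. The defaults reproduce the printed
#' device: ten vertical columns of 18 x 3 x 3 mm joined at their bottoms by a
#' feed conduit and at their tops by a collection conduit, both 1 mm tall and
#' 3 mm deep, an internal width of 41 mm, and a mean conduit velocity of
#' 0.5 mm/s. The column pitch (horizontal period) is derived as
#' `device_length / n_columns`.
#'
#' @param n_columns number of vertical columns.
#' @param column_height column height, m. A value of 0 degenerates the device
#'   into two disconnected straight conduits (useful as an analytic limit).
#' @param column_width column width (x), m.
#' @param column_depth column depth (y), m.
#' @param conduit_height height (z) of feed and collection conduits, m.
#' @param conduit_depth depth (y) of the conduits, m.
#' @param device_length internal length of the device (x), m.
#' @param mean_conduit_velocity mean cross-sectional velocity in each
#'   conduit, m/s.
#' @return object of class `sorter_geometry`.
#' @examples
#' sorter_geometry()          # the printed device
#' sorter_geometry(n_columns = 1, device_length = 4.1e-3)
#' @export
sorter_geometry <- function(n_columns = 10,
                            column_height = 18e-3,
                            column_width = 3e-3,
                            column_depth = 3e-3,
                            conduit_height = 1e-3,
                            conduit_depth = 3e-3,
                            device_length = 41e-3,
                            mean_conduit_velocity = 0.5e-3) {
  n_columns <- as.integer(n_columns)
  if (is.na(n_columns) || n_columns < 1)
    stop("n_columns must be at least 1", call. = FALSE)
  for (nm in c("column_width", "column_depth", "conduit_height",
               "conduit_depth", "device_length", "mean_conduit_velocity"))
    .check_positive(parse_quantity(get(nm)), nm)
  column_height <- parse_quantity(column_height)
  .check_nonneg(column_height, "column_height")
  g <- list(n_columns = n_columns,
            column_height = column_height,
            column_width = parse_quantity(column_width),
            column_depth = parse_quantity(column_depth),
            conduit_height = parse_quantity(conduit_height),
            conduit_depth = parse_quantity(conduit_depth),
            device_length = parse_quantity(device_length),
            mean_conduit_velocity = parse_quantity(mean_conduit_velocity))
  g$column_pitch <- g$device_length / g$n_columns
  if (g$column_pitch < g$column_width)
    stop("column pitch (device_length / n_columns) smaller than the ",
         "column width: columns overlap", call. = FALSE)
  g$total_height <- g$column_height + 2 * g$conduit_height
  structure(g, class = "sorter_geometry")
}

#' Build a sorter geometry from a configuration list
#'
#' Missing entries fall back to the printed device of [sorter_geometry()].
#' Values may be numbers or quantity strings (`"18 mm"`, `"0.5 mm/s"`).
#'
#' @param config named list of geometry fields (possibly empty).
#' @return object of class `sorter_geometry`.
#' @export
build_geometry <- function(config = list()) {
  config <- .parse_quantities(as.list(config))
  known <- names(formals(sorter_geometry))
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown geometry fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  # a configured device must have real columns; the zero-height straight
  # conduit limit is reserved for programmatic use of sorter_geometry()
  if (!is.null(config$column_height) && config$column_height <= 0)
    stop("column_height must be positive for a device configuration",
         call. = FALSE)
  do.call(sorter_geometry, config)
}

#' @export
print.sorter_geometry <- function(x, ...) {
  cat(sprintf(
    "<sorter_geometry> %d columns %.3g x %.3g x %.3g mm, conduits %.3g mm tall,\n  length %.3g mm, pitch %.3g mm, mean conduit velocity %.3g mm/s\n",
    x$n_columns, 1e3 * x$column_height, 1e3 * x$column_width,
    1e3 * x$column_depth, 1e3 * x$conduit_height, 1e3 * x$device_length,
    1e3 * x$column_pitch, 1e3 * x$mean_conduit_velocity))
  invisible(x)
}

#' Conduit transit time
#'
#' Time for a fluid parcel to traverse a length at the mean conduit velocity:
#' 80 s across the 40 mm internal path, 6 s across one 3 mm column mouth.
#'
#' @param length path length, m.
#' @param mean_velocity mean velocity, m/s (> 0).
#' @return time, s.
#' @export
transit_time <- function(length, mean_velocity) {
  length <- parse_quantity(length)
  mean_velocity <- parse_quantity(mean_velocity)
  .check_nonneg(length, "length")
  .check_positive(mean_velocity, "mean_velocity")
  length / mean_velocity
}
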