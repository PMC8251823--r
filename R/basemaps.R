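#' Calibrate a precipitation isoscape to expected feather values
#'
#' Feathers grown at the natal site record the local precipitation
#' deuterium signal with a species-group-specific offset and attenuation.
#' This applies the linear transfer function for ground-foraging migratory
#' songbirds to convert expected precipitation values (δ2Hp, ‰) into
#' expected feather values (δ2Hf, ‰).
#'
#' @param precip_d2h Numeric vector of per-cell expected precipitation
#'   δ2H values (‰ vs VSMOW).
#' @param intercept Calibration intercept in ‰. Default −175.57.
#' @param slope Unitless calibration slope. Default 0.95.
#' @return Numeric vector of expected feather δ2Hf values (‰), same length
#'   as `precip_d2h`.
#' @examples
#' calibrate_isoscape(c(-40, 0, 20))
#' @export
calibrate_isoscape <- function(precip_d2h, intercept = -175.57, slope = 0.95) {
  if (!is.numeric(precip_d2h) || length(precip_d2h) == 0L)
    stop("`precip_d2h` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(precip_d2h)))
    stop("`precip_d2h` contains non-finite values (NA/NaN/Inf); ",
         "mask or impute cells before calibration", call. = FALSE)
  if (!is.finite(intercept) || !is.finite(slope))
    stop("calibration intercept and slope must be finite", call. = FALSE)
  intercept + slope * precip_d2h
}

#' Construct a gridded candidate-origin basemap
#'
#' Bundles the per-cell expected marker surfaces (feather δ2Hf and wing
#' chord) with the relative-abundance prior over a regular grid covering
#' the breeding range. Cells flagged outside the range mask are dropped
#' *before* abundance is normalized, so origin probabilities are
#' conditional on the breeding range.
#'
#' @param cells Data frame with columns `lon`, `lat` (decimal degrees of
#'   cell centers), `expected_isotope` (‰ δ2Hf), `expected_wing` (mm), and
#'   `abundance` (raw nonnegative relative abundance, normalized
#'   internally). An optional logical `in_range` column is the range mask;
#'   an optional `cell_id` column is checked for uniqueness.
#' @param cell_size_km Grid resolution (cell edge) in km.
#' @return Object of class `marker_basemap`: a list with `cells` (data
#'   frame with contiguous `cell_id` 1..J and normalized `rel_abundance`)
#'   and `cell_size_km`.
#' @export
marker_basemap <- function(cells, cell_size_km) {
  stopifnot(is.data.frame(cells))
  needed <- c("lon", "lat", "expected_isotope", "expected_wing", "abundance")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols))
    stop("basemap cells are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1L ||
      !is.finite(cell_size_km) || cell_size_km <= 0)
    stop("`cell_size_km` must be a single positive number", call. = FALSE)
  if ("cell_id" %in% names(cells) && anyDuplicated(cells$cell_id))
    stop("duplicate cell_id values in basemap input", call. = FALSE)
  if ("in_range" %in% names(cells)) {
    cells <- cells[isTRUE_vec(cells$in_range), , drop = FALSE]
  }
  if (nrow(cells) < 2L)
    stop("degenerate basemap: fewer than 2 cells inside the range mask",
         call. = FALSE)
  check_lonlat(cells$lon, cells$lat)
  if (any(!is.finite(cells$expected_isotope)) ||
      any(!is.finite(cells$expected_wing)))
    stop("expected marker surfaces contain non-finite values", call. = FALSE)
  rel <- normalize_abundance(cells$abundance)
  out <- data.frame(
    cell_id          = seq_len(nrow(cells)),
    lon              = cells$lon,
    lat              = cells$lat,
    expected_isotope = cells$expected_isotope,
    expected_wing    = cells$expected_wing,
    rel_abundance    = rel
  )
  structure(list(cells = out, cell_size_km = cell_size_km),
            class = "marker_basemap")
}

#' @export
print.marker_basemap <- function(x, ...) {
  cat(sprintf(
    "<marker_basemap> %d cells, %.0f km resolution\n", nrow(x$cells),
    x$cell_size_km))
  cat(sprintf("  isotope range: [%.1f, %.1f] permil\n",
              min(x$cells$expected_isotope), max(x$cells$expected_isotope)))
  cat(sprintf("  wing range:    [%.1f, %.1f] mm\n",
              min(x$cells$expected_wing), max(x$cells$expected_wing)))
  invisible(x)
}

#' Read a basemap from a flat CSV of grid cells
#'
#' Expected columns (header row, comma separated, '.' decimal):
#' `lon`, `lat`, `expected_isotope`, `expected_wing`, `abundance`, with
#' optional `cell_id` and `in_range`. All layers must live on the same
#' grid, one row per cell; mixing grids across files is not supported and
#' must be resolved upstream.
#'
#' @param path Path to the CSV file.
#' @param cell_size_km Grid resolution in km.
#' @return A [marker_basemap()].
#' @export
read_basemap_csv <- function(path, cell_size_km) {
  if (!file.exists(path)) stop("basemap file not found: ", path, call. = FALSE)
  marker_basemap(utils::read.csv(path), cell_size_km = cell_size_km)
}

#' Construct the study-plot table
#'
#' @param plots Data frame with columns `plot_id`, `lon`, `lat` and
#'   optionally plot covariates (see [indiana_plot_covariates()]).
#' @return The validated data frame, classed `study_plots`.
#' @export
study_plots <- function(plots) {
  stopifnot(is.data.frame(plots))
  needed <- c("plot_id", "lon", "lat")
  if (!all(needed %in% names(plots)))
    stop("plots need columns: ", paste(needed, collapse = ", "), call. = FALSE)
  if (anyDuplicated(plots$plot_id))
    stop("plot_id values must be unique", call. = FALSE)
  check_lonlat(plots$lon, plots$lat)
  class(plots) <- c("study_plots", "data.frame")
  plots
}

#' Great-circle distance matrix between plots and basemap cells
#'
#' Haversine distances on a spherical Earth, in km. Row i, column j holds
#' the distance from plot i to the center of cell j; the kernel prior is
#' evaluated at these cell-center distances.
#'
#' @param plots A [study_plots()] table (or data frame with `lon`, `lat`).
#' @param basemap A [marker_basemap()].
#' @param earth_radius_km Sphere radius; default 6371 km.
#' @return Numeric matrix `[n_plots, n_cells]` with plot_id rownames.
#' @export
distance_matrix <- function(plots, basemap, earth_radius_km = 6371) {
  stopifnot(inherits(basemap, "marker_basemap"))
  check_lonlat(plots$lon, plots$lat)
  cells <- basemap$cells
  pm <- cbind(plots$lon, plots$lat)
  cm <- cbind(cells$lon, cells$lat)
  D <- matrix(NA_real_, nrow(pm), nrow(cm))
  for (i in seq_len(nrow(pm))) {
    D[i, ] <- geosphere::distHaversine(pm[i, ], cm,
                                       r = earth_radius_km * 1000) / 1000
  }
  rownames(D) <- as.character(plots$plot_id)
  D
}

#' Normalize raw abundance to an origin-probability surface
#'
#' Divides each cell's abundance by the range-wide total, yielding the
#' prior probability that a cell is a natal origin.
#'
#' @param x Nonnegative numeric vector with at least one positive entry.
#' @return Probability vector summing to 1.
#' @export
normalize_abundance <- function(x) {
  if (!is.numeric(x) || length(x) == 0L)
    stop("abundance must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(x)))
    stop("abundance contains non-finite values", call. = FALSE)
  if (any(x < 0))
    stop("abundance values must be nonnegative", call. = FALSE)
  tot <- sum(x)
  if (tot <= 0)
    stop("abundance is zero everywhere; cannot form a probability surface",
         call. = FALSE)
  x / tot
}

# shared coordinate validation
check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("coordinates contain non-finite values", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(lon < -360 | lon > 360))
    stop("longitude outside [-360, 360]", call. = FALSE)
  invisible(TRUE)
}

# treat NA in a logical mask as outside the range
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
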