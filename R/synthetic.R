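#' Define a synthetic assignment scenario
#'
#' Describes a complete synthetic study: a regular lon/lat grid of
#' candidate origin cells with latitudinally graded expected markers
#' (feather δ2Hf declining northward, wing length increasing northward),
#' an abundance surface, a true dispersal kernel, the marker noise
#' covariance, study plots, and per-plot sample sizes. Every stage of the
#' pipeline can then be exercised and benchmarked against known truth.
#'
#' Marker gradient defaults give a combined two-marker geographic
#' resolution of roughly 100 km (isotope SD 6.9 ‰ over a −0.06 ‰/km
#' gradient, wing SD 3.0 mm over 0.012 mm/km), matching the resolution
#' feather isotopes typically achieve in the field.
#'
#' @param n_cols,n_rows Grid dimensions (columns = east-west).
#' @param cell_size_km Cell edge in km.
#' @param center_lon,center_lat Grid center (decimal degrees).
#' @param isotope_ref Expected δ2Hf (‰) at the grid center.
#' @param isotope_slope_per_km Change in expected δ2Hf per km northward.
#' @param wing_ref Expected wing chord (mm) at the grid center.
#' @param wing_slope_per_km Change in expected wing per km northward.
#' @param surface_noise_sd Length-2 vector, SD of smooth spatial noise
#'   added to the (isotope, wing) surfaces; 0 disables.
#' @param abundance `"uniform"` or `"smooth"` (log-Gaussian smooth field).
#' @param kernel True dispersal kernel, a [kernel_prior()].
#' @param sigma True marker noise covariance, a [marker_covariance()].
#' @param plots Data frame `plot_id`, `lon`, `lat` (optionally
#'   covariates); defaults to one plot at the grid center.
#' @param n_per_plot Individuals per plot (recycled over plots).
#' @param seed Master seed; all stages draw from named substreams of it.
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_cols = 1, n_rows = 361, cell_size_km = 2.5,
                               center_lon = -86.5, center_lat = 39,
                               isotope_ref = -55,
                               isotope_slope_per_km = -0.06,
                               wing_ref = 103,
                               wing_slope_per_km = 0.012,
                               surface_noise_sd = c(0, 0),
                               abundance = c("uniform", "smooth"),
                               kernel = kernel_prior(1.1, 55, "true"),
                               sigma = marker_covariance(),
                               plots = NULL,
                               n_per_plot = 300,
                               seed = 1L) {
  abundance <- match.arg(abundance)
  if (n_cols * n_rows <= 1L)
    stop("degenerate grid: need more than one cell", call. = FALSE)
  if (any(surface_noise_sd < 0))
    stop("surface noise SDs must be nonnegative", call. = FALSE)
  if (is.null(plots))
    plots <- data.frame(plot_id = "p1", lon = center_lon, lat = center_lat)
  plots <- study_plots(plots)
  if (any(n_per_plot < 1))
    stop("n_per_plot must be >= 1", call. = FALSE)
  structure(list(
    n_cols = n_cols, n_rows = n_rows, cell_size_km = cell_size_km,
    center_lon = center_lon, center_lat = center_lat,
    isotope_ref = isotope_ref, isotope_slope_per_km = isotope_slope_per_km,
    wing_ref = wing_ref, wing_slope_per_km = wing_slope_per_km,
    surface_noise_sd = rep_len(surface_noise_sd, 2),
    abundance = abundance, kernel = kernel, sigma = sigma,
    plots = plots, n_per_plot = rep_len(n_per_plot, nrow(plots)),
    seed = as.integer(seed)), class = "synthetic_scenario")
}

# named substream seed derived from the master seed, kept under 2^31
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
  (as.integer(seed) %% 1000003L) * 1999L + h * 13L + 7L
}

#' Build the gridded basemap for a synthetic scenario
#'
#' Lays out the grid around the scenario center (cell spacing converted
#' from km to degrees at the center latitude), evaluates the latitudinal
#' marker gradients at each cell center's northward offset, optionally
#' adds smooth spatial noise, and attaches the abundance surface.
#' Deterministic given the scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [marker_basemap()].
#' @export
make_basemap <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  km_per_deg <- pi * 6371 / 180
  dlat <- s$cell_size_km / km_per_deg
  dlon <- s$cell_size_km / (km_per_deg * cos(s$center_lat * pi / 180))
  row_off <- (seq_len(s$n_rows) - (s$n_rows + 1) / 2)
  col_off <- (seq_len(s$n_cols) - (s$n_cols + 1) / 2)
  g <- expand.grid(col = col_off, row = row_off)
  lat <- s$center_lat + g$row * dlat
  lon <- s$center_lon + g$col * dlon
  north_km <- g$row * s$cell_size_km
  iso  <- s$isotope_ref + s$isotope_slope_per_km * north_km
  wing <- s$wing_ref + s$wing_slope_per_km * north_km
  if (any(s$surface_noise_sd > 0)) {
    set.seed(substream_seed(s$seed, "basemap"))
    smooth_range <- 4 * s$cell_size_km
    iso  <- iso + smooth_field(lon, lat, smooth_range,
                               s$surface_noise_sd[1])
    wing <- wing + smooth_field(lon, lat, smooth_range,
                                s$surface_noise_sd[2])
  }
  ab <- if (s$abundance == "uniform") rep(1, length(lat)) else {
    set.seed(substream_seed(s$seed, "abundance"))
    exp(smooth_field(lon, lat, 6 * s$cell_size_km, 0.5))
  }
  marker_basemap(
    data.frame(lon = lon, lat = lat, expected_isotope = iso,
               expected_wing = wing, abundance = ab),
    cell_size_km = s$cell_size_km)
}

# cheap Gaussian-weighted smoothing of iid noise: a low-rent random field
smooth_field <- function(lon, lat, range_km, sd) {
  if (sd == 0) return(numeric(length(lon)))
  eps <- stats::rnorm(length(lon))
  pts <- cbind(lon, lat)
  D <- matrix(0, length(lon), length(lon))
  for (i in seq_along(lon))
    D[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = 6371000) / 1000
  W <- exp(-(D / range_km)^2)
  z <- as.numeric(W %*% eps) / sqrt(rowSums(W^2))
  z * sd
}

#' Simulate dispersing individuals for a synthetic scenario
#'
#' Forward model of the assignment framework: for each plot, each
#' individual's true natal cell is drawn from the discrete distribution
#' proportional to kernel(distance to plot) times relative abundance over
#' all cells, then its marker vector is drawn bivariate-normal around the
#' origin cell's expected markers with the scenario covariance. The true
#' origin, distance, and plot are returned alongside the observed records
#' so recovery can be scored.
#'
#' @param scenario A [synthetic_scenario()].
#' @param basemap Basemap to simulate on; defaults to
#'   `make_basemap(scenario)`.
#' @return List with `individuals` (columns `individual_id`, `plot_id`,
#'   `isotope`, `wing`), `truth` (adds `true_cell`, `true_distance_km`),
#'   and the plot-to-cell `distances` matrix.
#' @export
simulate_individuals <- function(scenario, basemap = make_basemap(scenario)) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(basemap, "marker_basemap"))
  s <- scenario
  cells <- basemap$cells
  if (any(s$plots$lon < min(cells$lon) - 1e-9 |
          s$plots$lon > max(cells$lon) + 1e-9 |
          s$plots$lat < min(cells$lat) - 1e-9 |
          s$plots$lat > max(cells$lat) + 1e-9))
    stop("plot located outside the basemap grid", call. = FALSE)
  D <- distance_matrix(s$plots, basemap)
  d_floor <- s$cell_size_km / 2
  set.seed(substream_seed(s$seed, "origins"))
  recs <- vector("list", nrow(s$plots))
  for (p in seq_len(nrow(s$plots))) {
    w <- kernel_weight(D[p, ], s$kernel, d_floor = d_floor) *
      cells$rel_abundance
    prob <- w / sum(w)
    n_p <- s$n_per_plot[p]
    cell <- sample.int(nrow(cells), n_p, replace = TRUE, prob = prob)
    recs[[p]] <- data.frame(
      plot_id = s$plots$plot_id[p], true_cell = cell,
      true_distance_km = D[p, cell])
  }
  truth <- do.call(rbind, recs)
  truth$individual_id <- sprintf("ind%04d", seq_len(nrow(truth)))
  set.seed(substream_seed(s$seed, "markers"))
  U <- chol(s$sigma)
  zmat <- matrix(stats::rnorm(2 * nrow(truth)), nrow = 2)
  noise <- t(U) %*% zmat
  individuals <- data.frame(
    individual_id = truth$individual_id,
    plot_id = truth$plot_id,
    isotope = cells$expected_isotope[truth$true_cell] + noise[1, ],
    wing    = cells$expected_wing[truth$true_cell] + noise[2, ])
  list(individuals = individuals,
       truth = truth[, c("individual_id", "plot_id", "true_cell",
                         "true_distance_km")],
       distances = D)
}

#' Simulate bootstrap replicates of immigrant flags from a logistic model
#'
#' Generates `B` independent replicate flag sets with
#' logit P(z = 1) = beta0 + beta1 x + beta2 x^2, for benchmarking the
#' regression stage against known effect signs (e.g. a hump-shaped
#' density effect, or a null effect with `beta1 = beta2 = 0`).
#'
#' @param x Covariate value per individual.
#' @param beta0,beta1,beta2 True coefficients on the logit scale.
#' @param B Number of replicates.
#' @param seed Seed (replicates use independent L'Ecuyer-CMRG substreams).
#' @return Binary matrix `[B, length(x)]`.
#' @export
simulate_flag_replicates <- function(x, beta0, beta1 = 0, beta2 = 0,
                                     B = 200, seed = 1L) {
  p <- stats::plogis(beta0 + beta1 * x + beta2 * x^2)
  flags <- matrix(0L, B, length(x))
  restore <- save_rng_state()
  on.exit(restore(), add = TRUE)
  stream <- init_rng_streams(seed)
  for (b in seq_len(B)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, envir = globalenv())
    flags[b, ] <- stats::rbinom(length(x), 1, p)
  }
  flags
}
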