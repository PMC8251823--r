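#' Marker covariance matrix
#'
#' The 2x2 covariance Sigma describing local (within-site) variation in
#' the marker vector (isotope, wing). It is a fixed input to the
#' assignment model, estimated once from the sample variances and
#' covariance of the markers at the study plots, not re-estimated during
#' assignment. Defaults are the Indiana Wood Thrush study values.
#'
#' @param var_isotope Variance of feather δ2Hf (‰²). Default 47.88.
#' @param var_wing Variance of wing chord (mm²). Default 9.20.
#' @param cov_iso_wing Covariance (‰·mm). Default −1.21.
#' @return 2x2 symmetric positive-definite matrix, classed
#'   `marker_covariance`, rows/cols named `isotope`, `wing`.
#' @export
marker_covariance <- function(var_isotope = 47.88, var_wing = 9.20,
                              cov_iso_wing = -1.21) {
  S <- matrix(c(var_isotope, cov_iso_wing, cov_iso_wing, var_wing), 2, 2,
              dimnames = list(c("isotope", "wing"), c("isotope", "wing")))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    kappa_s <- if (min(abs(ev)) == 0) Inf else max(abs(ev)) / min(abs(ev))
    stop(sprintf(
      "marker covariance is not positive definite (eigenvalues %.4g, %.4g; condition number %.3g)",
      ev[1], ev[2], kappa_s), call. = FALSE)
  }
  structure(S, class = c("marker_covariance", "matrix"))
}

#' Weibull dispersal-kernel prior
#'
#' Distance prior on natal dispersal: the probability of dispersing
#' distance d declines (for shape < 1, with a heavy tail relative to the
#' exponential) according to a Weibull density with shape υ and scale λ
#' (km).
#'
#' @param shape Weibull shape υ > 0 (unitless).
#' @param scale Weibull scale λ > 0 (km).
#' @param label Optional name for reporting (e.g. `"gamma1"`).
#' @return List of class `kernel_prior`.
#' @seealso [study_kernel_priors()] for the three study parameterisations.
#' @export
kernel_prior <- function(shape, scale, label = NULL) {
  if (!is.finite(shape) || shape <= 0) stop("shape must be > 0", call. = FALSE)
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0", call. = FALSE)
  structure(list(shape = shape, scale = scale,
                 label = label %||% sprintf("weibull(%g,%g)", shape, scale)),
            class = "kernel_prior")
}

#' The three study dispersal-kernel priors
#'
#' Three Weibull kernels sharing a 5.7 km median natal dispersal distance
#' (from the body-mass scaling rule for a c. 50 g songbird) but implying
#' increasing frequency of long-distance dispersal: `gamma1` (shape 0.75,
#' scale 9.26) is the most restrictive prior on long-distance dispersal,
#' `gamma3` (shape 0.60, scale 10.47) the least.
#'
#' @return Named list of three [kernel_prior()] objects.
#' @export
study_kernel_priors <- function() {
  list(gamma1 = kernel_prior(0.75,  9.26,  "gamma1"),
       gamma2 = kernel_prior(0.675, 9.78,  "gamma2"),
       gamma3 = kernel_prior(0.60,  10.47, "gamma3"))
}

#' Bivariate-normal marker likelihood
#'
#' Density of the observed marker vector y* = (isotope, wing) under the
#' hypothesis that cell j (with expected markers mu_j) is the natal
#' origin: a multivariate normal with fixed covariance Sigma. Computed in
#' log space.
#'
#' @param y Observed marker vector, length 2, order (isotope ‰, wing mm).
#' @param mu Expected marker vector for one cell (length 2) or a matrix
#'   with one row per cell and columns (isotope, wing).
#' @param sigma A [marker_covariance()].
#' @param log Return log-density?
#' @return Density (or log-density), one value per row of `mu`.
#' @export
marker_likelihood <- function(y, mu, sigma = marker_covariance(), log = FALSE) {
  sigma <- as_marker_covariance(sigma)
  if (length(y) != 2L || any(!is.finite(y)))
    stop("`y` must be a finite length-2 vector (isotope, wing)", call. = FALSE)
  if (is.null(dim(mu))) mu <- matrix(mu, ncol = 2, byrow = FALSE)
  if (ncol(mu) != 2L) stop("`mu` must have 2 columns (isotope, wing)",
                           call. = FALSE)
  U <- chol(sigma)                       # sigma = U'U
  logdet <- 2 * sum(log(diag(U)))
  # Mahalanobis distance via triangular solve, vectorized over cells
  dev <- t(cbind(y[1] - mu[, 1], y[2] - mu[, 2]))
  z <- backsolve(U, dev, transpose = TRUE)
  maha <- colSums(z^2)
  ll <- -0.5 * (maha + logdet + 2 * log(2 * pi))
  if (log) ll else exp(ll)
}

#' Weibull dispersal-kernel density
#'
#' Evaluates the kernel prior g(d | υ, λ) at distance d km. For shapes
#' below 1 the Weibull density diverges as d → 0, so callers working on a
#' grid evaluate at `max(d, d_floor)` with `d_floor` = half the cell size
#' (a disperser "at distance zero" is really somewhere within its own
#' cell). The default `d_floor = 0` evaluates the density exactly as
#' written.
#'
#' @param distance Nonnegative distance(s) in km.
#' @param prior A [kernel_prior()].
#' @param d_floor Minimum distance (km) at which to evaluate the density.
#' @param log Return log-density?
#' @return Kernel density value(s).
#' @export
kernel_weight <- function(distance, prior, d_floor = 0, log = FALSE) {
  stopifnot(inherits(prior, "kernel_prior"))
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distances must be finite and nonnegative", call. = FALSE)
  stats::dweibull(pmax(distance, d_floor), shape = prior$shape,
                  scale = prior$scale, log = log)
}

#' Median of a Weibull dispersal kernel
#'
#' Closed form λ (ln 2)^(1/υ), in km. Inverting it for λ at a fixed
#' median is how kernels of different shape are matched to a common
#' median dispersal distance.
#'
#' @param shape Weibull shape υ > 0.
#' @param scale Weibull scale λ > 0 (km).
#' @return Median dispersal distance in km.
#' @examples
#' weibull_median(0.75, 9.26)   # ~5.7 km
#' weibull_median(1.24, 32.24)  # ~24 km
#' @export
weibull_median <- function(shape, scale) {
  if (any(shape <= 0) || any(scale <= 0))
    stop("shape and scale must be > 0", call. = FALSE)
  scale * log(2)^(1 / shape)
}

#' Posterior origin surface for one individual
#'
#' Combines, over every candidate cell j, the marker likelihood, the
#' dispersal-kernel prior evaluated at the plot-to-cell distance, and the
#' relative-abundance prior, and normalizes:
#' pi_j ∝ [y* | mu_j, Sigma] g(d_ij | υ, λ) N_j.
#' Accumulation is in log space with log-sum-exp normalization, since
#' range-wide grids underflow in linear space.
#'
#' @param y Observed marker vector (isotope ‰, wing mm), length 2.
#' @param basemap A [marker_basemap()].
#' @param prior A [kernel_prior()].
#' @param distances Distances (km) from the individual's breeding plot to
#'   each basemap cell, aligned with `basemap$cells` (a row of
#'   [distance_matrix()]).
#' @param sigma A [marker_covariance()].
#' @param d_floor Kernel evaluation floor in km; defaults to half the
#'   basemap cell size.
#' @return Probability vector over cells (sums to 1), classed
#'   `origin_posterior`.
#' @export
posterior_surface <- function(y, basemap, prior, distances,
                              sigma = marker_covariance(),
                              d_floor = basemap$cell_size_km / 2) {
  stopifnot(inherits(basemap, "marker_basemap"))
  cells <- basemap$cells
  if (length(distances) != nrow(cells))
    stop("`distances` must align with basemap cells (length ",
         nrow(cells), ")", call. = FALSE)
  ll  <- marker_likelihood(y, as.matrix(cells[, c("expected_isotope",
                                                  "expected_wing")]),
                           sigma, log = TRUE)
  lk  <- kernel_weight(distances, prior, d_floor = d_floor, log = TRUE)
  la  <- ifelse(cells$rel_abundance > 0, log(cells$rel_abundance), -Inf)
  lp  <- ll + lk + la
  if (all(!is.finite(lp)))
    stop("posterior underflow: all cells have zero unnormalized posterior ",
         "(max log-likelihood ", sprintf("%.1f", max(ll)),
         "); check marker units and basemap alignment", call. = FALSE)
  m <- max(lp[is.finite(lp)])
  w <- exp(lp - m)
  p <- w / sum(w)
  structure(p, class = "origin_posterior")
}

#' Posterior origin surfaces for a set of individuals
#'
#' Runs [posterior_surface()] for every individual, looking up each
#' individual's plot-to-cell distance row.
#'
#' @param individuals Data frame with columns `individual_id`, `plot_id`,
#'   `isotope`, `wing` (see [read_individuals_csv()]).
#' @param basemap A [marker_basemap()].
#' @param prior A [kernel_prior()].
#' @param distances Matrix from [distance_matrix()] (plots x cells).
#' @param sigma A [marker_covariance()].
#' @param d_floor Kernel evaluation floor in km.
#' @return Matrix `[n_individuals, n_cells]` of posterior probabilities;
#'   rownames are individual ids.
#' @export
assign_individuals <- function(individuals, basemap, prior, distances,
                               sigma = marker_covariance(),
                               d_floor = basemap$cell_size_km / 2) {
  individuals <- validate_individuals(individuals)
  miss <- setdiff(unique(individuals$plot_id), rownames(distances))
  if (length(miss))
    stop("individuals reference plot_id(s) absent from the distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  J <- nrow(basemap$cells)
  P <- matrix(NA_real_, nrow(individuals), J,
              dimnames = list(individuals$individual_id, NULL))
  for (i in seq_len(nrow(individuals))) {
    P[i, ] <- posterior_surface(
      c(individuals$isotope[i], individuals$wing[i]),
      basemap, prior,
      distances[as.character(individuals$plot_id[i]), ],
      sigma = sigma, d_floor = d_floor)
  }
  P
}

#' Read individual marker records from CSV
#'
#' Columns (case-insensitive): `individual_id`, `plot_id`, `d2hf_permil`,
#' `wing_mm`.
#'
#' @param path CSV path.
#' @return Data frame with columns `individual_id`, `plot_id`, `isotope`,
#'   `wing`.
#' @export
read_individuals_csv <- function(path) {
  if (!file.exists(path))
    stop("individuals file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  names(d) <- tolower(names(d))
  needed <- c("individual_id", "plot_id", "d2hf_permil", "wing_mm")
  if (!all(needed %in% names(d)))
    stop("individuals CSV needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  validate_individuals(data.frame(
    individual_id = d$individual_id,
    plot_id       = d$plot_id,
    isotope       = d$d2hf_permil,
    wing          = d$wing_mm
  ))
}

validate_individuals <- function(d) {
  stopifnot(is.data.frame(d))
  needed <- c("individual_id", "plot_id", "isotope", "wing")
  if (!all(needed %in% names(d)))
    stop("individuals need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(d$isotope)) || any(!is.finite(d$wing)))
    stop("marker values must be finite", call. = FALSE)
  if (anyDuplicated(d$individual_id))
    stop("individual_id values must be unique", call. = FALSE)
  d
}

as_marker_covariance <- function(sigma) {
  if (inherits(sigma, "marker_covariance")) return(sigma)
  if (is.matrix(sigma) && all(dim(sigma) == 2L)) {
    if (!isTRUE(all.equal(sigma[1, 2], sigma[2, 1])))
      stop("marker covariance must be symmetric", call. = FALSE)
    return(marker_covariance(sigma[1, 1], sigma[2, 2], sigma[1, 2]))
  }
  stop("`sigma` must be a marker_covariance or symmetric 2x2 matrix",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
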