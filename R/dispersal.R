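#' Draw a natal origin from a posterior surface
#'
#' Probabilistic single-origin assignment: cell j is drawn with its
#' posterior probability pi_j (a categorical draw).
#'
#' @param posterior Probability vector over cells (an `origin_posterior`
#'   or any nonnegative vector summing to 1).
#' @param n Number of independent draws.
#' @return Integer cell indices, length `n`.
#' @export
draw_origin <- function(posterior, n = 1) {
  p <- as.numeric(posterior)
  if (any(!is.finite(p)) || any(p < 0))
    stop("degenerate posterior: probabilities must be finite and >= 0",
         call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6)
    stop("posterior is not normalized (sums to ", sprintf("%.6f", sum(p)),
         ")", call. = FALSE)
  sample.int(length(p), size = n, replace = TRUE, prob = p)
}

#' Bootstrap origin draws and dispersal distances
#'
#' Propagates assignment uncertainty: every replicate independently
#' redraws a single origin cell for every individual from its posterior
#' surface, and converts the draw to a dispersal distance (origin cell to
#' the individual's breeding plot). One global seed seeds a L'Ecuyer-CMRG
#' stream sequence with one independent substream per replicate, so any
#' replicate can be regenerated in isolation; draws use inverse-CDF
#' sampling against each individual's cumulative posterior. The caller's
#' RNG state is restored on exit.
#'
#' @param posteriors Matrix `[n_individuals, n_cells]` from
#'   [assign_individuals()]; rows must each sum to 1.
#' @param plot_ids Breeding plot of each individual (length =
#'   `nrow(posteriors)`).
#' @param distances Plot-to-cell distance matrix from [distance_matrix()].
#' @param B Number of bootstrap replicates. Default 1000.
#' @param seed Integer seed for the replicate substreams.
#' @return Object of class `bootstrap_draws`: list with `origins` and
#'   `distances` (both `[B, n_individuals]`), `plot_ids`,
#'   `individual_ids`, `B`, `seed`.
#' @export
bootstrap_dispersal <- function(posteriors, plot_ids, distances, B = 1000,
                                seed = 1L) {
  stopifnot(is.matrix(posteriors), B >= 1)
  n <- nrow(posteriors)
  if (length(plot_ids) != n)
    stop("`plot_ids` must have one entry per individual", call. = FALSE)
  if (any(!is.finite(posteriors)) || any(posteriors < 0))
    stop("degenerate posterior matrix (non-finite or negative entries)",
         call. = FALSE)
  rs <- rowSums(posteriors)
  if (any(abs(rs - 1) > 1e-6))
    stop("posterior rows must each sum to 1", call. = FALSE)
  pid <- as.character(plot_ids)
  miss <- setdiff(unique(pid), rownames(distances))
  if (length(miss))
    stop("plot_id(s) missing from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  cumP <- t(apply(posteriors, 1, cumsum))
  cumP[, ncol(cumP)] <- 1  # guard against rounding in the last bin
  origins <- matrix(NA_integer_, B, n)
  restore <- save_rng_state()
  on.exit(restore(), add = TRUE)
  stream <- init_rng_streams(seed)
  for (b in seq_len(B)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, envir = globalenv())
    u <- stats::runif(n)
    origins[b, ] <- vapply(seq_len(n), function(i)
      findInterval(u[i], cumP[i, ]) + 1L, integer(1))
  }
  D <- matrix(NA_real_, B, n)
  for (i in seq_len(n)) D[, i] <- distances[pid[i], origins[, i]]
  structure(list(origins = origins, distances = D, plot_ids = plot_ids,
                 individual_ids = rownames(posteriors), B = B, seed = seed),
            class = "bootstrap_draws")
}

# snapshot the caller's RNG kind and state; returns a restore closure
save_rng_state <- function() {
  orng <- RNGkind()
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    RNGkind(orng[1], orng[2], orng[3])
    if (had) assign(".Random.seed", old, envir = globalenv())
  }
}

# seed the base L'Ecuyer-CMRG stream; replicate b uses the b-th substream
init_rng_streams <- function(seed) {
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  get(".Random.seed", envir = globalenv())
}

#' Classify long-distance immigrants
#'
#' Feather isotopes resolve origins to roughly 100 km, so an individual
#' whose drawn origin lies at least `threshold` km from its breeding plot
#' is classified as a long-distance immigrant (the boundary distance is
#' inclusive). Thresholds of 50 and 150 km are used for sensitivity
#' analyses.
#'
#' @param distance Dispersal distance(s) in km, nonnegative.
#' @param threshold Classification cutoff in km. Default 100.
#' @return Integer flag(s): 1 = long-distance immigrant, 0 = short.
#' @export
classify_immigrant <- function(distance, threshold = 100) {
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distances must be finite and nonnegative", call. = FALSE)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  as.integer(distance >= threshold)
}

#' Plot-level immigration rate
#'
#' Proportion of sampled individuals on a plot flagged as long-distance
#' immigrants: sum(z) / n_p. Interpretable as the probability of
#' long-distance immigration into the plot.
#'
#' @param flags Binary vector of immigrant flags for one plot.
#' @return Proportion in `[0, 1]`.
#' @export
immigration_rate <- function(flags) {
  if (length(flags) == 0L)
    stop("no individuals on plot; immigration rate undefined", call. = FALSE)
  if (any(!flags %in% c(0, 1)))
    stop("flags must be binary 0/1", call. = FALSE)
  mean(flags)
}

#' Weibull maximum-likelihood fit to dispersal distances
#'
#' Fits shape and scale by unconstrained optimization of the
#' log-likelihood on log-parameters (guaranteeing positivity), started
#' from moment-matched values. Zero distances (an individual assigned to
#' its own plot's cell) are lifted to `d_floor` first, since the Weibull
#' support is positive.
#'
#' @param distances Dispersal distances in km; at least 10 values.
#' @param d_floor Minimum distance substituted for zeros, in km.
#' @return List with `shape`, `scale`, `median_km`, `loglik`, `converged`.
#' @export
fit_weibull_mle <- function(distances, d_floor = 0.5) {
  d <- as.numeric(distances)
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and nonnegative", call. = FALSE)
  if (length(d) < 10L)
    stop("need at least 10 distances to fit a kernel", call. = FALSE)
  d <- pmax(d, d_floor)
  if (any(d <= 0))
    stop("non-positive distances remain after flooring; increase d_floor",
         call. = FALSE)
  start <- weibull_moment_start(d)
  nll <- function(theta) {
    -sum(stats::dweibull(d, shape = exp(theta[1]), scale = exp(theta[2]),
                         log = TRUE))
  }
  opt <- stats::optim(log(c(start$shape, start$scale)), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  shape <- exp(opt$par[1]); scale <- exp(opt$par[2])
  converged <- opt$convergence == 0 && is.finite(opt$value) &&
    shape > 1e-6 && shape < 1e3 && scale > 1e-6 && scale < 1e6
  list(shape = shape, scale = scale,
       median_km = weibull_median(shape, scale),
       loglik = -opt$value, converged = converged)
}

# moment-matched Weibull start values (CV-based shape approximation)
weibull_moment_start <- function(d) {
  cv <- stats::sd(d) / mean(d)
  shape0 <- if (!is.finite(cv) || cv <= 0) 1 else min(max(cv^-1.086, 0.05), 50)
  scale0 <- mean(d) / gamma(1 + 1 / shape0)
  list(shape = shape0, scale = scale0)
}

#' Refit the dispersal kernel to every bootstrap replicate
#'
#' One Weibull MLE per replicate's distance vector; non-converged
#' replicates are flagged and excluded from downstream quantile
#' summaries, with a count reported.
#'
#' @param draws A [bootstrap_dispersal()] result.
#' @param d_floor Minimum distance substituted for zeros (km); defaults
#'   to 0.5 km and should normally be half the basemap cell size.
#' @return Data frame of class `kernel_fits`: one row per replicate with
#'   `replicate`, `shape_hat`, `scale_hat`, `median_km`, `converged`.
#' @export
fit_kernels <- function(draws, d_floor = 0.5) {
  stopifnot(inherits(draws, "bootstrap_draws"))
  B <- draws$B
  out <- data.frame(replicate = seq_len(B), shape_hat = NA_real_,
                    scale_hat = NA_real_, median_km = NA_real_,
                    converged = FALSE)
  for (b in seq_len(B)) {
    f <- fit_weibull_mle(draws$distances[b, ], d_floor = d_floor)
    out$shape_hat[b] <- f$shape
    out$scale_hat[b] <- f$scale
    out$median_km[b] <- f$median_km
    out$converged[b] <- f$converged
  }
  class(out) <- c("kernel_fits", "data.frame")
  out
}

#' Summarize bootstrap kernel fits
#'
#' Mean and bootstrap percentile interval (2.5/97.5% by default) of the
#' replicate shape, scale, and median estimates, over converged
#' replicates.
#'
#' @param fits A [fit_kernels()] result.
#' @param probs Interval probabilities. Default `c(0.025, 0.975)`.
#' @return Data frame with one row per parameter (`shape`, `scale`,
#'   `median_km`): mean, lower, upper, plus `n_converged` and `n_failed`.
#' @export
summarize_kernel_fits <- function(fits, probs = c(0.025, 0.975)) {
  stopifnot(inherits(fits, "kernel_fits"))
  ok <- fits[fits$converged, , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("no converged replicate fits to summarize", call. = FALSE)
  n_failed <- sum(!fits$converged)
  if (n_failed > 0)
    message(n_failed, " replicate kernel fit(s) failed to converge and were excluded")
  one <- function(x, par) data.frame(
    parameter = par, mean = mean(x),
    lower = unname(stats::quantile(x, probs[1])),
    upper = unname(stats::quantile(x, probs[2])),
    n_converged = nrow(ok), n_failed = n_failed)
  rbind(one(ok$shape_hat, "shape"),
        one(ok$scale_hat, "scale"),
        one(ok$median_km, "median_km"))
}

#' Per-plot long-distance immigrant summaries
#'
#' For each bootstrap replicate, counts the individuals on each plot
#' whose drawn dispersal distance meets the threshold, then summarizes
#' counts and immigration rates across replicates by the median and a
#' bootstrap percentile interval.
#'
#' @param draws A [bootstrap_dispersal()] result.
#' @param threshold Long-distance threshold in km. Default 100.
#' @param probs Interval probabilities. Default `c(0.025, 0.975)`.
#' @return Data frame: `plot_id`, `n`, `threshold_km`, `median_immigrants`,
#'   `lower`, `upper`, `median_rate`, `rate_lower`, `rate_upper`.
#' @export
immigrant_summary <- function(draws, threshold = 100,
                              probs = c(0.025, 0.975)) {
  stopifnot(inherits(draws, "bootstrap_draws"))
  flags <- matrix(classify_immigrant(draws$distances, threshold),
                  nrow = draws$B)
  plots <- unique(draws$plot_ids)
  res <- lapply(plots, function(p) {
    idx <- which(draws$plot_ids == p)
    counts <- rowSums(flags[, idx, drop = FALSE])
    rates <- counts / length(idx)
    data.frame(plot_id = p, n = length(idx), threshold_km = threshold,
               median_immigrants = stats::median(counts),
               lower = unname(stats::quantile(counts, probs[1])),
               upper = unname(stats::quantile(counts, probs[2])),
               median_rate = stats::median(rates),
               rate_lower = unname(stats::quantile(rates, probs[1])),
               rate_upper = unname(stats::quantile(rates, probs[2])))
  })
  do.call(rbind, res)
}
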