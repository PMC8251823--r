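# Small in-code fixtures shared across test files.

# five cells along a latitudinal gradient with uneven abundance
toy_basemap <- function() {
  marker_basemap(
    data.frame(
      lon = rep(-86.5, 5),
      lat = c(37, 38, 39, 40, 41),
      expected_isotope = c(-40, -48, -55, -63, -70),
      expected_wing = c(100, 101.5, 103, 104.5, 106),
      abundance = c(2, 5, 1, 3, 4)),
    cell_size_km = 30)
}

toy_plot <- function() study_plots(
  data.frame(plot_id = "p1", lon = -86.5, lat = 39))

# independent brute-force evaluation of the posterior: explicit bivariate
# normal density (solve-based), Weibull pdf, abundance, linear-space
# normalization -- no shared code with posterior_surface()
brute_posterior <- function(y, mu, sigma, dists, d_floor, shape, scale,
                            abund, lik_scale = 1, kern_scale = 1,
                            ab_scale = 1) {
  inv <- solve(sigma)
  dens <- apply(mu, 1, function(m) {
    v <- y - m
    exp(-0.5 * (t(v) %*% inv %*% v)) / (2 * pi * sqrt(det(sigma)))
  })
  d <- pmax(dists, d_floor)
  kern <- (shape / scale) * (d / scale)^(shape - 1) * exp(-(d / scale)^shape)
  w <- (dens * lik_scale) * (kern * kern_scale) * (abund * ab_scale)
  w / sum(w)
}
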