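test_that("marker likelihood matches bivariate normal closed forms", {
  I2 <- marker_covariance(1, 1, 0)
  expect_equal(marker_likelihood(c(0, 0), c(0, 0), I2), 1 / (2 * pi),
               tolerance = 1e-12)
  S <- marker_covariance(47.88, 9.20, 0)
  expect_equal(marker_likelihood(c(-50, 100), c(-50, 100), S),
               1 / (2 * pi * sqrt(47.88 * 9.20)), tolerance = 1e-12)
  # off-center value against the explicit solve-based formula
  Sfull <- marker_covariance()
  y <- c(-48, 104); m <- c(-55, 102)
  v <- y - m
  ref <- exp(-0.5 * t(v) %*% solve(Sfull) %*% v) /
    (2 * pi * sqrt(det(Sfull)))
  expect_equal(marker_likelihood(y, m, Sfull), as.numeric(ref),
               tolerance = 1e-12)
  expect_equal(marker_likelihood(y, m, Sfull, log = TRUE),
               log(marker_likelihood(y, m, Sfull)), tolerance = 1e-10)
})

test_that("marker likelihood integrates to one (quadrature oracle)", {
  S <- marker_covariance()  # includes the negative isotope-wing covariance
  mu <- c(-55, 103)
  sds <- sqrt(diag(S))
  gx <- seq(mu[1] - 9 * sds[1], mu[1] + 9 * sds[1], by = sds[1] / 5)
  gy <- seq(mu[2] - 9 * sds[2], mu[2] + 9 * sds[2], by = sds[2] / 5)
  grid <- as.matrix(expand.grid(gx, gy))
  # density at y over the grid equals density at grid points treated as mu
  dens <- marker_likelihood(mu, grid, S)
  total <- unname(sum(dens) * (sds[1] / 5) * (sds[2] / 5))
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("singular covariance is rejected with a diagnostic", {
  expect_error(marker_covariance(1, 1, 1), "positive definite")
  expect_error(marker_covariance(0, 9.2, 0), "positive definite")
})

test_that("kernel weight evaluates the Weibull dispersal density", {
  expect_equal(kernel_weight(0, kernel_prior(1, 10)), 0.1)   # exponential limit
  expect_equal(kernel_weight(10, kernel_prior(2, 10)), 0.2 * exp(-1),
               tolerance = 1e-12)
  expect_error(kernel_weight(-1, kernel_prior(1, 10)), "nonnegative")
  # flooring moves the evaluation point, not the input
  p <- kernel_prior(0.75, 9.26)
  expect_equal(kernel_weight(0, p, d_floor = 15), kernel_weight(15, p))
})

test_that("half the kernel mass lies below the closed-form median", {
  for (pars in list(c(0.75, 9.26), c(0.675, 9.78), c(0.60, 10.47),
                    c(1.24, 32.24), c(2, 5))) {
    pr <- kernel_prior(pars[1], pars[2])
    med <- weibull_median(pars[1], pars[2])
    mass <- integrate(function(d) kernel_weight(d, pr), 0, med,
                      rel.tol = 1e-10)$value
    expect_equal(mass, 0.5, tolerance = 1e-7)
  }
})

test_that("posterior surface matches brute-force evaluation to 1e-12", {
  bm <- toy_basemap()
  pl <- toy_plot()
  D <- distance_matrix(pl, bm)
  S <- marker_covariance()
  prior <- kernel_prior(0.75, 9.26)
  y <- c(-52, 102.4)
  post <- posterior_surface(y, bm, prior, D[1, ], sigma = S)
  ref <- brute_posterior(
    y, as.matrix(bm$cells[, c("expected_isotope", "expected_wing")]),
    S, D[1, ], d_floor = 15, shape = 0.75, scale = 9.26,
    abund = bm$cells$rel_abundance)
  expect_equal(as.numeric(post), ref, tolerance = 1e-12)
  expect_equal(sum(post), 1, tolerance = 1e-12)
})

test_that("posterior is invariant to rescaling likelihood, kernel, prior", {
  bm <- toy_basemap()
  D <- distance_matrix(toy_plot(), bm)
  S <- marker_covariance()
  y <- c(-60, 104)
  post <- posterior_surface(y, bm, kernel_prior(0.675, 9.78), D[1, ],
                            sigma = S)
  mu <- as.matrix(bm$cells[, c("expected_isotope", "expected_wing")])
  ref <- brute_posterior(y, mu, S, D[1, ], 15, 0.675, 9.78,
                         bm$cells$rel_abundance,
                         lik_scale = 1e6, kern_scale = 1e-4, ab_scale = 42)
  expect_equal(as.numeric(post), ref, tolerance = 1e-12)
})

test_that("symmetric cells split the posterior evenly", {
  bm <- marker_basemap(
    data.frame(lon = c(-87, -86), lat = c(39, 39),
               expected_isotope = -55, expected_wing = 103, abundance = 1),
    cell_size_km = 30)
  pl <- study_plots(data.frame(plot_id = "p", lon = -86.5, lat = 39))
  D <- distance_matrix(pl, bm)
  post <- posterior_surface(c(-50, 100), bm, kernel_prior(0.75, 9.26), D[1, ])
  expect_equal(as.numeric(post), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("flat likelihood and flat kernel reduce posterior to abundance", {
  bm <- toy_basemap()
  bm$cells$expected_isotope <- -55   # identical markers: flat likelihood
  bm$cells$expected_wing <- 103
  D <- distance_matrix(toy_plot(), bm)
  # huge scale makes the kernel flat over the map
  post <- posterior_surface(c(-55, 103), bm, kernel_prior(1, 1e9), D[1, ])
  expect_equal(as.numeric(post), bm$cells$rel_abundance, tolerance = 1e-6)
})

test_that("kernel washes out as scale grows (no-kernel limit)", {
  bm <- toy_basemap()
  D <- distance_matrix(toy_plot(), bm)
  S <- marker_covariance()
  y <- c(-58, 103.5)
  post <- posterior_surface(y, bm, kernel_prior(1, 1e6), D[1, ], sigma = S)
  mu <- as.matrix(bm$cells[, c("expected_isotope", "expected_wing")])
  lik <- marker_likelihood(y, mu, S)
  nokernel <- lik * bm$cells$rel_abundance
  nokernel <- nokernel / sum(nokernel)
  expect_equal(as.numeric(post), nokernel, tolerance = 1e-3)
})

test_that("increasing one cell's abundance increases its posterior", {
  base <- data.frame(
    lon = rep(-86.5, 5), lat = c(37, 38, 39, 40, 41),
    expected_isotope = c(-40, -48, -55, -63, -70),
    expected_wing = c(100, 101.5, 103, 104.5, 106),
    abundance = c(2, 5, 1, 3, 4))
  D <- distance_matrix(toy_plot(), marker_basemap(base, 30))
  y <- c(-52, 102)
  p1 <- posterior_surface(y, marker_basemap(base, 30),
                          kernel_prior(0.75, 9.26), D[1, ])
  boosted <- base; boosted$abundance[4] <- boosted$abundance[4] * 3
  p2 <- posterior_surface(y, marker_basemap(boosted, 30),
                          kernel_prior(0.75, 9.26), D[1, ])
  expect_gt(p2[4], p1[4])
})

test_that("log-space and naive linear-space posteriors agree", {
  bm <- toy_basemap()
  D <- distance_matrix(toy_plot(), bm)
  S <- marker_covariance()
  prior <- kernel_prior(0.75, 9.26)
  set.seed(41)
  for (i in 1:10) {
    y <- c(runif(1, -70, -40), runif(1, 100, 106))
    post <- posterior_surface(y, bm, prior, D[1, ], sigma = S)
    mu <- as.matrix(bm$cells[, c("expected_isotope", "expected_wing")])
    lin <- marker_likelihood(y, mu, S) *
      kernel_weight(D[1, ], prior, d_floor = 15) * bm$cells$rel_abundance
    expect_equal(as.numeric(post), lin / sum(lin), tolerance = 1e-10)
  }
})

test_that("degenerate all-zero posterior is rejected with a diagnostic", {
  bm <- toy_basemap()
  bm$cells$rel_abundance <- 0
  D <- distance_matrix(toy_plot(), toy_basemap())
  expect_error(
    posterior_surface(c(-55, 103), bm, kernel_prior(0.75, 9.26), D[1, ]),
    "underflow")
})

test_that("individuals CSV round-trips with case-insensitive headers", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Individual_ID,Plot_ID,D2Hf_permil,Wing_mm",
               "a1,p1,-52.3,103.1", "a2,p1,-61.0,99.8"), tmp)
  d <- read_individuals_csv(tmp)
  expect_equal(d$individual_id, c("a1", "a2"))
  expect_equal(d$isotope, c(-52.3, -61.0))
  expect_equal(d$wing, c(103.1, 99.8))
})

test_that("assignment rejects individuals from unknown plots", {
  bm <- toy_basemap()
  D <- distance_matrix(toy_plot(), bm)
  ind <- data.frame(individual_id = "x", plot_id = "nope",
                    isotope = -55, wing = 103)
  expect_error(assign_individuals(ind, bm, kernel_prior(1, 10), D),
               "absent from the distance matrix")
})
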