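test_that("origin draws follow the posterior (point mass and frequencies)", {
  expect_true(all(draw_origin(c(1, 0, 0), n = 50) == 1L))
  set.seed(51)
  d <- draw_origin(c(0.5, 0.5), n = 1e5)
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(mean(d == 1L) - 0.5), 3 * se)
  # goodness of fit on an arbitrary 5-cell posterior
  p <- c(0.05, 0.3, 0.1, 0.35, 0.2)
  set.seed(52)
  d5 <- draw_origin(p, n = 1e5)
  gof <- chisq.test(tabulate(d5, 5), p = p)
  expect_gt(gof$p.value, 0.001)
  expect_error(draw_origin(c(NaN, 0.5)), "degenerate")
  expect_error(draw_origin(c(0.4, 0.4)), "not normalized")
})

test_that("immigrant classification threshold is inclusive", {
  expect_identical(classify_immigrant(100, 100), 1L)
  expect_identical(classify_immigrant(99.999, 100), 0L)
  expect_identical(classify_immigrant(c(30, 50, 150), 50), c(0L, 1L, 1L))
  expect_identical(classify_immigrant(c(120, 150, 160), 150), c(0L, 1L, 1L))
})

test_that("immigration rate is the mean flag", {
  expect_equal(immigration_rate(c(0, 0, 0, 1)), 0.25)
  expect_equal(immigration_rate(rep(1, 7)), 1)
  expect_error(immigration_rate(integer(0)), "undefined")
  expect_error(immigration_rate(c(0, 2)), "binary")
})

test_that("Weibull MLE recovers parameters at large n", {
  set.seed(61)
  d <- rweibull(1e5, shape = 1.24, scale = 32.24)
  f <- fit_weibull_mle(d, d_floor = 0)
  expect_true(f$converged)
  expect_lt(abs(f$shape - 1.24), 0.02)
  expect_lt(abs(f$scale - 32.24), 0.5)
})

test_that("Weibull MLE handles the exponential special case", {
  set.seed(62)
  d <- rexp(5e4, rate = 1 / 20)
  f <- fit_weibull_mle(d, d_floor = 0)
  expect_lt(abs(f$shape - 1), 0.02)
  expect_lt(abs(f$scale - 20), 0.5)
})

test_that("MLE log-likelihood beats moment-matched parameters", {
  set.seed(63)
  for (i in 1:10) {
    d <- rweibull(200, shape = runif(1, 0.6, 2.5), scale = runif(1, 5, 60))
    f <- fit_weibull_mle(d, d_floor = 0)
    mom <- natalassign:::weibull_moment_start(d)
    ll_mom <- sum(dweibull(d, mom$shape, mom$scale, log = TRUE))
    expect_gte(f$loglik, ll_mom - 1e-6)
  }
})

test_that("in-package Weibull MLE agrees with fitdistrplus", {
  skip_if_not_installed("fitdistrplus")
  set.seed(64)
  d <- rweibull(2000, shape = 0.9, scale = 28)
  f <- fit_weibull_mle(d, d_floor = 0)
  ref <- fitdistrplus::fitdist(d, "weibull")
  expect_equal(f$shape, unname(ref$estimate["shape"]), tolerance = 1e-4)
  expect_equal(f$scale, unname(ref$estimate["scale"]), tolerance = 1e-4)
})

test_that("Weibull median closed form", {
  expect_equal(weibull_median(1, 10), 10 * log(2))
  expect_equal(weibull_median(0.75, 9.26), 9.26 * log(2)^(1 / 0.75))
  expect_error(weibull_median(-1, 10), "> 0")
})

test_that("point-mass posteriors collapse bootstrap to true distances", {
  bm <- toy_basemap()
  D <- distance_matrix(toy_plot(), bm)
  true_cells <- c(2, 4, 5, 1, 3, 3, 2, 5, 4, 1)
  P <- matrix(0, length(true_cells), 5,
              dimnames = list(sprintf("i%02d", seq_along(true_cells)), NULL))
  P[cbind(seq_along(true_cells), true_cells)] <- 1
  draws <- bootstrap_dispersal(P, rep("p1", 10), D, B = 25, seed = 3)
  for (b in 1:25)
    expect_equal(draws$distances[b, ], unname(D[1, true_cells]))
})

test_that("bootstrap draws are reproducible from the seed", {
  bm <- toy_basemap()
  D <- distance_matrix(toy_plot(), bm)
  set.seed(71)
  P <- matrix(rgamma(8 * 5, 1), 8, 5,
              dimnames = list(sprintf("i%d", 1:8), NULL))
  P <- P / rowSums(P)
  d1 <- bootstrap_dispersal(P, rep("p1", 8), D, B = 50, seed = 9)
  d2 <- bootstrap_dispersal(P, rep("p1", 8), D, B = 50, seed = 9)
  d3 <- bootstrap_dispersal(P, rep("p1", 8), D, B = 50, seed = 10)
  expect_identical(d1$origins, d2$origins)
  expect_false(identical(d1$origins, d3$origins))
})

test_that("bootstrap draw frequencies match the posterior row", {
  bm <- toy_basemap()
  D <- distance_matrix(toy_plot(), bm)
  p <- c(0.05, 0.3, 0.1, 0.35, 0.2)
  P <- matrix(p, 1, 5, byrow = TRUE, dimnames = list("i1", NULL))
  draws <- bootstrap_dispersal(P, "p1", D, B = 2e4, seed = 5)
  freq <- tabulate(draws$origins[, 1], 5) / 2e4
  expect_true(all(abs(freq - p) < 3 * sqrt(p * (1 - p) / 2e4) + 1e-9))
})

test_that("immigrant summaries match direct enumeration over replicates", {
  bm <- toy_basemap()
  pl <- study_plots(data.frame(plot_id = c("p1", "p2"),
                               lon = c(-86.5, -86.5), lat = c(39, 37.5)))
  D <- distance_matrix(pl, bm)
  set.seed(81)
  n <- 30
  plot_ids <- rep(c("p1", "p2"), c(18, 12))
  P <- matrix(rgamma(n * 5, 1), n, 5,
              dimnames = list(sprintf("i%02d", 1:n), NULL))
  P <- P / rowSums(P)
  draws <- bootstrap_dispersal(P, plot_ids, D, B = 100, seed = 4)
  s <- immigrant_summary(draws, threshold = 100)
  # oracle: count immigrants replicate by replicate, plot by plot
  for (p in c("p1", "p2")) {
    idx <- which(plot_ids == p)
    counts <- sapply(1:100, function(b)
      sum(draws$distances[b, idx] >= 100))
    row <- s[s$plot_id == p, ]
    expect_equal(row$median_immigrants, median(counts))
    expect_equal(row$lower, unname(quantile(counts, 0.025)))
    expect_equal(row$upper, unname(quantile(counts, 0.975)))
    expect_equal(row$median_rate, median(counts) / length(idx))
  }
})

test_that("immigration counts are monotone non-increasing in threshold", {
  bm <- toy_basemap()
  D <- distance_matrix(toy_plot(), bm)
  set.seed(91)
  P <- matrix(rgamma(20 * 5, 1), 20, 5,
              dimnames = list(sprintf("i%02d", 1:20), NULL))
  P <- P / rowSums(P)
  draws <- bootstrap_dispersal(P, rep("p1", 20), D, B = 40, seed = 6)
  counts <- sapply(c(50, 100, 150), function(th)
    sum(classify_immigrant(draws$distances, th)))
  expect_true(all(diff(counts) <= 0))
})
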