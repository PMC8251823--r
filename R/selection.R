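#' Single-predictor logistic regression of immigrant status
#'
#' Fits immigrant status (0/1) against one plot covariate by maximum
#' likelihood, optionally with a quadratic term (used for conspecific
#' density, where the social-cues hypothesis predicts a hump: positive
#' linear, negative quadratic effect). With only 12 plots, multi-predictor
#' and random-effect structures are not estimable, so each covariate is
#' tested in its own model.
#'
#' The optimizer works on an internally centered/scaled copy of the
#' covariate for conditioning; coefficients are back-transformed and
#' reported in raw covariate units unless `standardize = TRUE`.
#'
#' @param z Binary response (long-distance immigrant flags), one per
#'   individual; must contain both classes.
#' @param x Covariate value per individual (individuals inherit their
#'   plot's value).
#' @param quadratic Include a quadratic term?
#' @param standardize Report coefficients per SD of `x` instead of raw
#'   units?
#' @return List: `coefficients` (named `intercept`, `beta1`, and `beta2`
#'   if quadratic), `converged`, `separation`, `deviance`,
#'   `null_deviance`.
#' @export
fit_logistic_single <- function(z, x, quadratic = FALSE,
                                standardize = FALSE) {
  if (length(z) != length(x))
    stop("`z` and `x` must have equal length", call. = FALSE)
  if (any(!z %in% c(0, 1))) stop("`z` must be binary 0/1", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  if (length(unique(z)) < 2L)
    stop("response has a single class; coefficients are not identified",
         call. = FALSE)
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("covariate has zero variance; effect undefined", call. = FALSE)
  xs <- (x - m) / s
  separation <- FALSE
  fit <- withCallingHandlers(
    if (quadratic) stats::glm(z ~ xs + I(xs^2), family = stats::binomial())
    else           stats::glm(z ~ xs,           family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  if (standardize) {
    out <- c(intercept = unname(co[1]), beta1 = unname(co[2]))
    if (quadratic) out <- c(out, beta2 = unname(co[3]))
  } else if (quadratic) {
    # logit = a + b1*(x-m)/s + b2*((x-m)/s)^2 rewritten in raw x
    a <- co[1]; b1 <- co[2]; b2 <- co[3]
    out <- c(intercept = unname(a - b1 * m / s + b2 * m^2 / s^2),
             beta1     = unname(b1 / s - 2 * b2 * m / s^2),
             beta2     = unname(b2 / s^2))
  } else {
    out <- c(intercept = unname(co[1] - co[2] * m / s),
             beta1     = unname(co[2] / s))
  }
  converged <- isTRUE(fit$converged) && !separation && all(is.finite(out))
  list(coefficients = out, converged = converged, separation = separation,
       deviance = fit$deviance, null_deviance = fit$null.deviance)
}

#' Bootstrap effect summaries for one predictor
#'
#' Fits the single-predictor model to every bootstrap replicate's
#' immigrant flags and summarizes each coefficient across converged
#' replicates: mean, 2.5/97.5% percentile interval, and the proportion of
#' replicate estimates above and below zero (the one-tailed sign
#' probabilities used to test the habitat-selection predictions).
#'
#' @param flags Binary matrix `[B, n_individuals]` of immigrant flags
#'   (e.g. `classify_immigrant(draws$distances, 100)` reshaped), or a
#'   [bootstrap_dispersal()] object together with `threshold`.
#' @param x Covariate value per individual.
#' @param quadratic Include a quadratic term?
#' @param standardize Report standardized coefficients?
#' @param threshold Long-distance threshold (km), used only when `flags`
#'   is a `bootstrap_draws` object.
#' @param predictor Label recorded in the output.
#' @return Data frame with one row per coefficient: `predictor`,
#'   `coefficient`, `mean`, `q2.5`, `q97.5`, `pr_positive`, `pr_negative`,
#'   `n_converged`, `n_failed`, `high_failure` (TRUE when more than half
#'   the replicates failed).
#' @export
bootstrap_effects <- function(flags, x, quadratic = FALSE,
                              standardize = FALSE, threshold = 100,
                              predictor = "x") {
  if (inherits(flags, "bootstrap_draws"))
    flags <- matrix(classify_immigrant(flags$distances, threshold),
                    nrow = flags$B)
  stopifnot(is.matrix(flags))
  if (ncol(flags) != length(x))
    stop("flag columns must align with individuals", call. = FALSE)
  B <- nrow(flags)
  k <- if (quadratic) 3L else 2L
  est <- matrix(NA_real_, B, k)
  ok <- logical(B)
  for (b in seq_len(B)) {
    res <- tryCatch(
      fit_logistic_single(flags[b, ], x, quadratic = quadratic,
                          standardize = standardize),
      error = function(e) NULL)
    if (!is.null(res) && res$converged) {
      est[b, ] <- res$coefficients
      ok[b] <- TRUE
    }
  }
  n_conv <- sum(ok)
  if (n_conv == 0L)
    stop("no replicate converged for predictor '", predictor, "'",
         call. = FALSE)
  high_failure <- (B - n_conv) > B / 2
  if (high_failure)
    warning("more than half of the replicates failed to converge for '",
            predictor, "'", call. = FALSE)
  coef_names <- c("intercept", "beta1", if (quadratic) "beta2")
  e <- est[ok, , drop = FALSE]
  out <- data.frame(
    predictor = predictor,
    coefficient = coef_names,
    mean = colMeans(e),
    q2.5 = apply(e, 2, stats::quantile, 0.025),
    q97.5 = apply(e, 2, stats::quantile, 0.975),
    pr_positive = colMeans(e > 0),
    pr_negative = colMeans(e < 0),
    n_converged = n_conv,
    n_failed = B - n_conv,
    high_failure = high_failure,
    row.names = NULL)
  out
}

#' Habitat-selection hypothesis tests on bootstrap replicates
#'
#' Runs the three single-predictor bootstrap regressions that
#' discriminate the four settlement hypotheses: habitat amount (random
#' immigration predicts a positive slope), patch quality R (ideal
#' free/dominance/social cues predict positive), and conspecific density
#' with linear + quadratic terms (ideal free: positive linear; ideal
#' dominance: negative; social cues: positive linear with negative
#' quadratic).
#'
#' @param draws A [bootstrap_dispersal()] result, or a `[B, n]` flag
#'   matrix.
#' @param covariates Plot covariate table with columns `plot_id`, `R`,
#'   `habitat_ha`, `density` (see [indiana_plot_covariates()]).
#' @param plot_ids Plot membership per individual; defaults to
#'   `draws$plot_ids` when `draws` is a `bootstrap_draws`.
#' @param threshold Long-distance threshold in km. Default 100.
#' @param standardize Report standardized coefficients?
#' @return Data frame combining [bootstrap_effects()] rows for the three
#'   models, with a `model` column (`habitat`, `quality`, `density`) and
#'   the threshold used.
#' @export
selection_tests <- function(draws, covariates, plot_ids = NULL,
                            threshold = 100, standardize = FALSE) {
  if (inherits(draws, "bootstrap_draws")) {
    plot_ids <- plot_ids %||% draws$plot_ids
    flags <- matrix(classify_immigrant(draws$distances, threshold),
                    nrow = draws$B)
  } else {
    flags <- draws
    if (is.null(plot_ids))
      stop("`plot_ids` is required when passing a raw flag matrix",
           call. = FALSE)
  }
  needed <- c("plot_id", "R", "habitat_ha", "density")
  if (!all(needed %in% names(covariates)))
    stop("covariates need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  idx <- match(plot_ids, covariates$plot_id)
  if (anyNA(idx))
    stop("some individuals belong to plots absent from the covariate table",
         call. = FALSE)
  specs <- list(
    list(model = "habitat", x = covariates$habitat_ha[idx], quad = FALSE),
    list(model = "quality", x = covariates$R[idx],          quad = FALSE),
    list(model = "density", x = covariates$density[idx],    quad = TRUE))
  res <- lapply(specs, function(s) {
    eff <- bootstrap_effects(flags, s$x, quadratic = s$quad,
                             standardize = standardize,
                             predictor = s$model)
    eff$model <- s$model
    eff$threshold_km <- threshold
    eff
  })
  do.call(rbind, res)
}

#' Pairwise Pearson correlations among plot covariates
#'
#' @param covariates Data frame of plot covariates; correlations are
#'   computed among `R`, `habitat_ha`, and `density` when present,
#'   otherwise among all numeric non-identifier columns.
#' @return Symmetric correlation matrix. Zero-variance columns yield NA
#'   entries, with a warning naming them.
#' @export
covariate_correlations <- function(covariates) {
  stopifnot(is.data.frame(covariates))
  if (nrow(covariates) < 3L)
    stop("need at least 3 plots for correlations", call. = FALSE)
  std <- c("R", "habitat_ha", "density")
  cols <- if (all(std %in% names(covariates))) std else
    setdiff(names(covariates)[vapply(covariates, is.numeric, TRUE)],
            c("plot_id", "n"))
  X <- as.matrix(covariates[, cols, drop = FALSE])
  degenerate <- cols[apply(X, 2, function(v) stats::sd(v) == 0)]
  if (length(degenerate))
    warning("zero-variance column(s), correlations undefined: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  suppressWarnings(stats::cor(X))
}

#' Covariates of the 12 Indiana Wood Thrush study plots
#'
#' Per-plot self-recruitment rate `R` (expected population growth rate
#' absent immigration, the patch-quality measure), `habitat_ha`
#' (deciduous forest within a 2 km radius, ha), `density` (mean Wood
#' Thrush per ha from distance-sampling point counts), and `n`
#' (second-year individuals sampled).
#'
#' @return Data frame with 12 rows and columns `plot_id`, `R`,
#'   `habitat_ha`, `density`, `n`.
#' @export
indiana_plot_covariates <- function() {
  path <- system.file("extdata", "indiana_plot_covariates.csv",
                      package = "natalassign", mustWork = TRUE)
  utils::read.csv(path)
}
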