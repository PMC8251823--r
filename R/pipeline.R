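#' Assemble a pipeline run configuration
#'
#' Collects inputs and settings for [run_pipeline()]. Inputs may be given
#' as in-memory objects (`basemap`, `individuals`, `plots`, `covariates`)
#' or as CSV paths (`basemap_csv` + `cell_size_km`, `individuals_csv`,
#' `covariates_csv`). Defaults reproduce the study settings: Sigma
#' [[47.88, −1.21], [−1.21, 9.20]], B = 1000, threshold 100 km, and the
#' three matched-median kernel priors.
#'
#' @param basemap A [marker_basemap()], or NULL with `basemap_csv` set.
#' @param individuals Individual records (see [read_individuals_csv()]).
#' @param plots A [study_plots()] table.
#' @param covariates Plot covariate table; NULL skips the regression
#'   stage.
#' @param basemap_csv,individuals_csv,covariates_csv Optional CSV paths.
#' @param cell_size_km Required with `basemap_csv`.
#' @param sigma A [marker_covariance()].
#' @param priors List of [kernel_prior()]s. Default
#'   [study_kernel_priors()].
#' @param thresholds Long-distance thresholds (km). Default 100.
#' @param B Bootstrap replicates. Default 1000.
#' @param seed Master seed.
#' @param write_posteriors Also write the dense posterior matrices?
#' @return List of class `run_config`.
#' @export
run_config <- function(basemap = NULL, individuals = NULL, plots = NULL,
                       covariates = NULL, basemap_csv = NULL,
                       individuals_csv = NULL, covariates_csv = NULL,
                       cell_size_km = NULL, sigma = marker_covariance(),
                       priors = study_kernel_priors(),
                       thresholds = 100, B = 1000, seed = 1L,
                       write_posteriors = FALSE) {
  if (is.null(basemap)) {
    if (is.null(basemap_csv) || is.null(cell_size_km))
      stop("supply `basemap` or both `basemap_csv` and `cell_size_km`",
           call. = FALSE)
    basemap <- read_basemap_csv(basemap_csv, cell_size_km)
  }
  if (is.null(individuals)) {
    if (is.null(individuals_csv))
      stop("supply `individuals` or `individuals_csv`", call. = FALSE)
    individuals <- read_individuals_csv(individuals_csv)
  }
  individuals <- validate_individuals(individuals)
  if (is.null(plots))
    stop("`plots` (plot_id, lon, lat) is required", call. = FALSE)
  plots <- study_plots(plots)
  if (is.null(covariates) && !is.null(covariates_csv))
    covariates <- utils::read.csv(covariates_csv)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (any(thresholds <= 0)) stop("thresholds must be > 0", call. = FALSE)
  if (!all(vapply(priors, inherits, TRUE, "kernel_prior")))
    stop("`priors` must be a list of kernel_prior objects", call. = FALSE)
  if (is.null(names(priors)) || any(names(priors) == ""))
    names(priors) <- vapply(priors, `[[`, "", "label")
  structure(list(basemap = basemap, individuals = individuals,
                 plots = plots, covariates = covariates,
                 sigma = as_marker_covariance(sigma), priors = priors,
                 thresholds = thresholds, B = as.integer(B),
                 seed = as.integer(seed),
                 write_posteriors = isTRUE(write_posteriors)),
            class = "run_config")
}

#' Run the full assignment-to-regression pipeline
#'
#' For each kernel prior: computes per-individual posterior origin
#' surfaces, bootstraps origin draws and dispersal distances, refits the
#' Weibull kernel to every replicate, summarizes per-plot long-distance
#' immigrant counts at each threshold, and (when covariates are supplied)
#' runs the habitat-selection bootstrap regressions. All outputs are
#' written as CSVs under `out_dir` together with a machine-readable run
#' manifest (seed, settings, file checksums); an identical configuration
#' and seed reproduces byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress per-stage progress messages?
#' @return (Invisibly) a list with per-prior results: `posteriors`,
#'   `draws`, `kernel_fits`, `kernel_summary`, `immigrants`, `selection`,
#'   plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  cfg <- config
  n_ind <- nrow(cfg$individuals)
  say("stage basemap: ", nrow(cfg$basemap$cells), " cells in range, ",
      cfg$basemap$cell_size_km, " km resolution")
  say("stage inputs: ", n_ind, " individuals across ",
      length(unique(cfg$individuals$plot_id)), " plots")
  D <- with_stage("distances",
                  distance_matrix(cfg$plots, cfg$basemap))
  d_floor <- cfg$basemap$cell_size_km / 2
  results <- list()
  files <- character()
  for (pname in names(cfg$priors)) {
    prior <- cfg$priors[[pname]]
    say(sprintf("prior %s (shape %.3g, scale %.3g km)", pname,
                prior$shape, prior$scale))
    P <- with_stage("assignment",
      assign_individuals(cfg$individuals, cfg$basemap, prior, D,
                         sigma = cfg$sigma, d_floor = d_floor))
    draws <- with_stage("bootstrap",
      bootstrap_dispersal(P, cfg$individuals$plot_id, D, B = cfg$B,
                          seed = substream_seed(cfg$seed,
                                                paste0("boot_", pname))))
    fits <- with_stage("kernel_fit", fit_kernels(draws, d_floor = d_floor))
    say("  bootstrap: ", cfg$B, " replicates; kernel fits converged: ",
        sum(fits$converged), "/", cfg$B)
    ksum <- summarize_kernel_fits(fits)
    imm <- do.call(rbind, lapply(cfg$thresholds, function(th)
      with_stage("classification", immigrant_summary(draws, threshold = th))))
    sel <- NULL
    if (!is.null(cfg$covariates)) {
      sel <- do.call(rbind, lapply(cfg$thresholds, function(th)
        with_stage("regression",
                   selection_tests(draws, cfg$covariates, threshold = th))))
      sel$prior <- pname
    }
    fits_out <- fits
    fits_out$prior <- pname
    ksum$prior <- pname
    imm$prior <- pname
    files[length(files) + 1L] <-
      write_result_csv(fits_out, out_dir, paste0("kernel_fits_", pname))
    files[length(files) + 1L] <-
      write_result_csv(ksum, out_dir, paste0("kernel_summary_", pname))
    files[length(files) + 1L] <-
      write_result_csv(imm, out_dir, paste0("immigrants_", pname))
    if (!is.null(sel))
      files[length(files) + 1L] <-
        write_result_csv(sel, out_dir, paste0("selection_", pname))
    if (cfg$write_posteriors) {
      pd <- data.frame(individual_id = rep(rownames(P), each = ncol(P)),
                       cell_id = rep(seq_len(ncol(P)), times = nrow(P)),
                       probability = as.vector(t(P)))
      files[length(files) + 1L] <-
        write_result_csv(pd, out_dir, paste0("posteriors_", pname))
    }
    results[[pname]] <- list(posteriors = P, draws = draws,
                             kernel_fits = fits, kernel_summary = ksum,
                             immigrants = imm, selection = sel)
  }
  manifest <- list(
    package = "natalassign",
    version = as.character(utils::packageVersion("natalassign")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed, B = cfg$B, thresholds = cfg$thresholds,
    priors = lapply(cfg$priors, function(p)
      list(label = p$label, shape = p$shape, scale = p$scale)),
    sigma = list(var_isotope = cfg$sigma[1, 1], var_wing = cfg$sigma[2, 2],
                 cov_iso_wing = cfg$sigma[1, 2]),
    n_individuals = n_ind, n_cells = nrow(cfg$basemap$cells),
    n_plots = nrow(cfg$plots),
    outputs = as.list(tools::md5sum(files)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("wrote ", length(files), " result files + manifest to ", out_dir)
  results$manifest <- manifest
  invisible(results)
}

# label errors with the pipeline stage that raised them
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_result_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}
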