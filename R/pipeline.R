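# End-to-end analyses: structure selection, knockout screening, nonlinear
# variants. Each takes a dataset (or a scenario name), runs
# interpolate -> resample -> fit_ensemble over the requested model set, and
# returns tidy tables; with output_dir set, tables are written as CSV files
# stamped with the seed and a configuration hash.

.resolve_dataset <- function(data, seed) {
  if (inherits(data, "ft_dataset")) return(data)
  if (is.character(data) && length(data) == 1) {
    return(generate_dataset(make_scenario(data, seed = seed)))
  }
  if (inherits(data, "ft_truth_config")) return(generate_dataset(data))
  stop("data must be an ft_dataset, a truth_config, or a scenario name")
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(cfg)), f)
  unname(tools::md5sum(f))
}

.write_report <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), unlist(meta)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.run_prepare <- function(data, n_intermediate, n_samples, seed) {
  ds <- .resolve_dataset(data, seed)
  dense <- interpolate(ds, n_intermediate)
  rs <- resample(dense, n_samples, seed)
  list(dataset = ds, dense = dense, resamples = rs)
}

.fit_spec_set <- function(specs, rs, optimizer, optimizer_cfg) {
  stats::setNames(
    lapply(specs, fit_ensemble, resamples = rs, optimizer = optimizer,
           optimizer_cfg = optimizer_cfg),
    vapply(specs, function(s) s$label, "")
  )
}

#' Select the best model structure by AICc
#'
#' Fits the structural alternatives -- cumulative input (M1), major-regulator
#' (M2), gene-specific (M3) -- and, optionally, the coefficient-sharing
#' variants of M1 (c1 shared, split by vernalization, split by time of day),
#' then ranks them by AICc from the ensemble-mean minimized cost.
#'
#' @param data An [ft_dataset()], an [truth_config()], or a scenario name
#'   for [make_scenario()].
#' @param n_intermediate Interior points per observed interval (default 3).
#' @param n_samples Resampled replicates (default 200; the reference
#'   analysis uses 1000).
#' @param seed Seed controlling all randomness of the run.
#' @param c1_variants Also fit the M1 sharing-scheme variants?
#' @param optimizer,optimizer_cfg Passed to [fit_ensemble()].
#' @param output_dir If non-`NULL`, the comparison table is written there as
#'   `structure_selection.csv` with seed and config-hash header lines.
#' @return A list of class `ft_run`: `table` (the [compare_structures()]
#'   report), `fits`, `m`, `seed`, `config_hash`.
#' @export
run_structure_selection <- function(data, n_intermediate = 3,
                                    n_samples = 200, seed = 1,
                                    c1_variants = TRUE,
                                    optimizer = "nelder-mead",
                                    optimizer_cfg = list(),
                                    output_dir = NULL) {
  prep <- .run_prepare(data, n_intermediate, n_samples, seed)
  specs <- list(model_spec("M1"), model_spec("M2"), model_spec("M3"))
  if (c1_variants) {
    specs <- c(specs, list(
      model_spec("M1", c1_varies_by = "none", label = "M1_c1_shared"),
      model_spec("M1", c1_varies_by = "daytime", label = "M1_c1_daytime")
    ))
  }
  fits <- .fit_spec_set(specs, prep$resamples, optimizer, optimizer_cfg)
  table <- compare_structures(fits)
  cfg <- list(analysis = "structure_selection", n_intermediate = n_intermediate,
              n_samples = n_samples, seed = seed, c1_variants = c1_variants,
              optimizer = optimizer, line = prep$dataset$line,
              photoperiod = prep$dataset$photoperiod)
  hash <- .config_hash(cfg)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    .write_report(table, file.path(output_dir, "structure_selection.csv"),
                  list(seed = seed, config_md5 = hash))
  }
  structure(list(table = table, fits = fits, m = fits[[1]]$m, seed = seed,
                 config_hash = hash), class = "ft_run")
}

#' Screen regulator knockouts against the full model
#'
#' Fits the knockout hypotheses H0-H5, then evaluates them the three ways the
#' workflow prescribes: (1) paired tests of the minimized-cost distributions
#' against H0, (2) block-level pattern-defect diagnostics of each hypothesis
#' relative to H0, and (3) the ensemble parameter summaries.
#'
#' @inheritParams run_structure_selection
#' @param hypotheses Character vector of hypotheses to fit (default H0-H5).
#' @param test_method,adjust Passed to [test_hypotheses()].
#' @param flag_factor Passed to [block_diagnostics()].
#' @return A list of class `ft_run`: `comparison` (hypothesis test table),
#'   `diagnostics` (named list of [block_diagnostics()] tables),
#'   `parameters` (the [summarize_parameters()] table), `fits`, `seed`,
#'   `config_hash`.
#' @export
run_knockout_analysis <- function(data, n_intermediate = 3, n_samples = 200,
                                  seed = 1, hypotheses = paste0("H", 0:5),
                                  test_method = "wilcoxon", adjust = "none",
                                  flag_factor = 2,
                                  optimizer = "nelder-mead",
                                  optimizer_cfg = list(),
                                  output_dir = NULL) {
  stopifnot("H0" %in% hypotheses)
  prep <- .run_prepare(data, n_intermediate, n_samples, seed)
  specs <- lapply(hypotheses, hypothesis_spec)
  fits <- .fit_spec_set(specs, prep$resamples, optimizer, optimizer_cfg)
  comparison <- test_hypotheses(fits, baseline = "H0", method = test_method,
                                adjust = adjust)
  mean_params <- lapply(fits, function(f) {
    stats::setNames(f$summary$mean, f$summary$parameter)
  })
  ref_diag <- block_diagnostics(fits$H0$spec, mean_params$H0, prep$dense)
  diagnostics <- lapply(names(fits), function(nm) {
    block_diagnostics(fits[[nm]]$spec, mean_params[[nm]], prep$dense,
                      reference = ref_diag, flag_factor = flag_factor)
  })
  names(diagnostics) <- names(fits)
  parameters <- summarize_parameters(fits)
  cfg <- list(analysis = "knockout", n_intermediate = n_intermediate,
              n_samples = n_samples, seed = seed, hypotheses = hypotheses,
              test_method = test_method, adjust = adjust,
              flag_factor = flag_factor, optimizer = optimizer,
              line = prep$dataset$line,
              photoperiod = prep$dataset$photoperiod)
  hash <- .config_hash(cfg)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- list(seed = seed, config_md5 = hash)
    .write_report(comparison,
                  file.path(output_dir, "knockout_comparison.csv"), meta)
    diag_flat <- do.call(rbind, lapply(names(diagnostics), function(nm) {
      cbind(model = nm, as.data.frame(diagnostics[[nm]]))
    }))
    .write_report(diag_flat,
                  file.path(output_dir, "knockout_diagnostics.csv"), meta)
    .write_report(parameters,
                  file.path(output_dir, "knockout_parameters.csv"), meta)
  }
  structure(list(comparison = comparison, diagnostics = diagnostics,
                 parameters = parameters, fits = fits, seed = seed,
                 config_hash = hash), class = "ft_run")
}

#' Compare nonlinear and time-dependent variants of the cumulative model
#'
#' Fits M1 together with its equal-parameter-count modifications -- squared
#' inputs (M4), exponential response (M5), logarithmic response (M6) and a
#' time-modulated coefficient (M7) -- and tests each variant's minimized-cost
#' distribution against M1, paired across replicates.
#'
#' @inheritParams run_structure_selection
#' @param test_method Passed to [test_hypotheses()].
#' @return A list of class `ft_run`: `table` (paired comparison vs M1),
#'   `fits`, `seed`, `config_hash`.
#' @export
run_nonlinear_variants <- function(data, n_intermediate = 3,
                                   n_samples = 200, seed = 1,
                                   test_method = "wilcoxon",
                                   optimizer = "nelder-mead",
                                   optimizer_cfg = list(),
                                   output_dir = NULL) {
  prep <- .run_prepare(data, n_intermediate, n_samples, seed)
  specs <- lapply(c("M1", "M4", "M5", "M6", "M7"), model_spec)
  ks <- vapply(specs, count_parameters, 1L)
  stopifnot(length(unique(ks)) == 1)  # equal-parameter-count contract
  fits <- .fit_spec_set(specs, prep$resamples, optimizer, optimizer_cfg)
  table <- test_hypotheses(fits, baseline = "M1", method = test_method)
  cfg <- list(analysis = "nonlinear_variants",
              n_intermediate = n_intermediate, n_samples = n_samples,
              seed = seed, optimizer = optimizer, line = prep$dataset$line,
              photoperiod = prep$dataset$photoperiod)
  hash <- .config_hash(cfg)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    .write_report(table, file.path(output_dir, "nonlinear_variants.csv"),
                  list(seed = seed, config_md5 = hash))
  }
  structure(list(table = table, fits = fits, seed = seed,
                 config_hash = hash), class = "ft_run")
}

#' @export
print.ft_run <- function(x, ...) {
  cat("<ft_run> seed ", x$seed, ", config ", substr(x$config_hash, 1, 8),
      "\n", sep = "")
  main <- if (!is.null(x$table)) x$table else x$comparison
  print(main)
  invisible(x)
}
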