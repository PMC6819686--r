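## Pipeline drivers: thin, config-driven wrappers that chain the module
## functions and write the tabular reports. They are the package's
## command surface; each stage logs its wall time and dimensions.

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

#' Read a run configuration from YAML
#'
#' Converts a YAML file with (subsets of) the [sim_config()] fields plus
#' optional `omegas`, `qc` (thresholds), `min_frequency` and
#' `n_mask_periods` entries into the list consumed by the `run_*`
#' drivers.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_sge("the 'yaml' package is needed to read YAML configs",
             class = "sge_config_error")
  yaml::read_yaml(path)
}

#' Simulate a dataset and write it to disk
#'
#' @param config a [sim_config()] (or a list of its arguments).
#' @param out_dir output directory; `NULL` skips writing.
#' @param quiet suppress stage logs.
#' @return the `sge_dataset`, invisibly.
#' @export
run_simulation <- function(config, out_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  t0 <- proc.time()[3]
  ds <- simulate_dataset(config)
  stage_log(quiet, "simulated %d pedigree animals, %d phenotypes, %d genotyped (%.1fs)",
            nrow(ds$pedigree), nrow(ds$phenotypes), length(ds$geno_ids),
            proc.time()[3] - t0)
  if (!is.null(out_dir)) {
    write_dataset(ds, out_dir)
    stage_log(quiet, "dataset written to %s", out_dir)
  }
  invisible(ds)
}

#' Fit the pedigree baselines and the omega grid on a dataset
#'
#' Applies the group-size filter, builds the design and relationship
#' matrices, QCs the genotypes (when present), and runs [omega_grid()].
#' Without genotypes the grid is restricted to the two pedigree models
#' with a logged notice.
#'
#' @param dataset an `sge_dataset` or a list with `pedigree` (a
#'   [pedigree_table]), `phenotypes`, and optionally `genotypes`.
#' @param omegas omega values for the single-step fits.
#' @param thresholds [qc_thresholds()] for the genotypes.
#' @param min_frequency group-size filter threshold.
#' @param dilution apply the dilution covariate to social incidences.
#' @param tau genomic scaling constant.
#' @param tol,max_iter REML controls.
#' @param out_dir when set, writes `model_grid.tsv` and the QC report.
#' @param quiet suppress stage logs.
#' @return the [omega_grid()] table, with the prepared `design`, dense
#'   `A`, `A_inv` and genotype objects attached as attributes for reuse.
#' @export
run_model_grid <- function(dataset, omegas = seq(0.1, 1, by = 0.1),
                           thresholds = qc_thresholds(),
                           min_frequency = 0.10, dilution = TRUE, tau = 1,
                           tol = 1e-8, max_iter = 500,
                           out_dir = NULL, quiet = FALSE) {
  ped <- dataset$pedigree
  if (is.null(ped$F)) ped <- compute_inbreeding(ped)
  t0 <- proc.time()[3]
  phen <- group_size_filter(dataset$phenotypes, min_frequency)
  stage_log(quiet, "group-size filter kept %d of %d records",
            nrow(phen), nrow(dataset$phenotypes))
  spec <- social_model_spec(include_social = TRUE, relationship = "pedigree",
                            dilution = dilution)
  design <- build_design(phen, ped, spec)
  A <- build_A(ped)
  A_inv <- build_A_inverse(ped)
  stage_log(quiet, "design: %d records, %d fixed-effect columns, %d litters, %d pens (%.1fs)",
            length(design$y), ncol(design$X), ncol(design$W), ncol(design$V),
            proc.time()[3] - t0)

  A22 <- G_b <- NULL; geno_ids <- character(0); Mq <- NULL
  if (!is.null(dataset$genotypes)) {
    Mq <- qc_filter(dataset$genotypes, thresholds)
    Mq <- impute_mean(Mq)
    G <- build_G(Mq)
    geno_ids <- rownames(Mq)
    A22 <- build_A22(ped, geno_ids)
    G_b <- blend_G(G, A22)
    stage_log(quiet, "genomics: %d animals x %d markers post-QC, cor(offdiag G, A22) = %.3f",
              nrow(Mq), ncol(Mq), g_a22_offdiag_correlation(G, A22))
  }
  t1 <- proc.time()[3]
  grid <- omega_grid(design, A, A_inv = A_inv, A22 = A22, G_b = G_b,
                     geno_ids = geno_ids, omegas = omegas, tau = tau,
                     tol = tol, max_iter = max_iter)
  best <- grid$model[which.min(grid$AIC)]
  stage_log(quiet, "grid of %d models fitted in %.1fs; dAIC = 0 at %s",
            nrow(grid), proc.time()[3] - t1, best)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_grid(grid, file.path(out_dir, "model_grid.tsv"))
    if (!is.null(Mq))
      write_qc_report(Mq, file.path(out_dir, "qc_report.tsv"))
  }
  attr(grid, "design") <- design
  attr(grid, "A") <- A
  attr(grid, "A_inv") <- A_inv
  attr(grid, "A22") <- A22
  attr(grid, "G_b") <- G_b
  attr(grid, "geno_ids") <- geno_ids
  attr(grid, "pedigree") <- ped
  grid
}

#' Forward-validate the fitted models
#'
#' Runs [forward_validation()] for each converged model of an
#' [run_model_grid()] result, reusing its estimated components, and
#' tabulates the accuracy summary (mean theoretical DBV/SBV accuracy of
#' the validation animals and the CBV-phenotype correlation).
#'
#' @param dataset the `sge_dataset` the grid was fitted on.
#' @param grid an [run_model_grid()] result.
#' @param n_mask number of trailing birth periods masked.
#' @param min_frequency group-size filter threshold.
#' @param out_dir when set, writes `validation.tsv`.
#' @param quiet suppress stage logs.
#' @return data frame with columns `model`, `DBV_acc`, `SBV_acc`, `Cor`;
#'   the full `sge_validation` objects are attached as attribute
#'   `"validations"`.
#' @export
run_validation <- function(dataset, grid, n_mask = 2, min_frequency = 0.10,
                           out_dir = NULL, quiet = FALSE) {
  fits <- attr(grid, "fits")
  vals <- list()
  rows <- list()
  for (lab in names(fits)) {
    f <- fits[[lab]]
    if (!inherits(f, "sge_fit")) next
    spec <- social_model_spec(
      include_social = f$include_social,
      relationship = if (grepl("^omega", lab)) "single-step" else "pedigree",
      omega = if (grepl("^omega", lab)) as.numeric(sub("omega_", "", lab)) else 1)
    t0 <- proc.time()[3]
    v <- forward_validation(dataset, spec, components = f$components,
                            n_mask = n_mask, min_frequency = min_frequency)
    stage_log(quiet, "validated %s: Cor = %.3f over %d animals (%.1fs)",
              lab, v$cv_correlation, v$n_validation, proc.time()[3] - t0)
    vals[[lab]] <- v
    rows[[lab]] <- data.frame(model = lab,
                              DBV_acc = unname(v$R_D["mean"]),
                              SBV_acc = if (!is.null(v$R_S))
                                unname(v$R_S["mean"]) else NA_real_,
                              Cor = v$cv_correlation)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(out, file.path(out_dir, "validation.tsv"), sep = "\t")
  }
  attr(out, "validations") <- vals
  out
}
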