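#' Solve Henderson's mixed-model equations
#'
#' Builds and solves the MME of the (social) animal model at fixed
#' variance components, returning BLUE fixed effects, BLUP breeding
#' values for every pedigree animal, litter and pen solutions, and the
#' prediction error variance (PEV) of the genetic effects read from the
#' diagonal of the inverted coefficient matrix.
#'
#' @param design a [build_design()] object.
#' @param K_inv sparse precision of the genetic relationship: `A^-1` from
#'   [build_A_inverse()] or `H^-1` from [build_H_inverse()].
#' @param components a [variance_components()] vector (the genetic block
#'   uses its 2x2 `C` for social fits, `aD` alone otherwise).
#' @param pev compute PEV (inverts the coefficient matrix, or solves
#'   selected columns when `pev_ids` is a small subset).
#' @param pev_ids animal ids for which PEV is wanted (default: all).
#' @return an `sge_solutions` list: `beta`, `a_D`, `a_S` (or `NULL`),
#'   `litter`, `group`, `PEV_D`, `PEV_S`, plus the components and
#'   `n_bar` used.
#' @export
solve_mme <- function(design, K_inv, components, pev = TRUE, pev_ids = NULL) {
  include_social <- !is.null(design$Z_S) && design$spec$include_social
  vc <- unclass(components)
  n_ped <- nrow(K_inv)
  ped_ids <- rownames(K_inv)
  y <- design$y
  floor_val <- 1e-10 * max(stats::var(y), 1)
  sig_e <- max(vc[["e"]], floor_val)

  Zlist <- list(design$Z_D)
  if (include_social) Zlist <- c(Zlist, list(design$Z_S))
  Wmat <- do.call(cbind, c(list(Matrix::Matrix(design$X, sparse = TRUE)),
                           Zlist, list(design$W, design$V)))
  ## genetic precision block
  if (include_social) {
    C <- matrix(c(vc[["aD"]], vc[["aDaS"]], vc[["aDaS"]], vc[["aS"]]), 2, 2)
    eg <- eigen(C, symmetric = TRUE)
    C <- eg$vectors %*% diag(pmax(eg$values, floor_val)) %*% t(eg$vectors)
    Gprec <- kronecker(solve(C), K_inv)
  } else {
    Gprec <- K_inv / max(vc[["aD"]], floor_val)
  }
  p <- ncol(design$X)
  n_l <- ncol(design$W); n_g <- ncol(design$V)
  prec <- Matrix::bdiag(Matrix::Matrix(0, p, p),
                        Gprec,
                        Matrix::Diagonal(n_l) / max(vc[["l"]], floor_val),
                        Matrix::Diagonal(n_g) / max(vc[["g"]], floor_val))
  M <- Matrix::forceSymmetric(Matrix::crossprod(Wmat) / sig_e + prec)
  rhs <- Matrix::crossprod(Wmat, y) / sig_e
  sol <- tryCatch(as.numeric(Matrix::solve(M, rhs)),
                  error = function(e) stop_sge("singular mixed-model equations: %s",
                                               conditionMessage(e),
                                               class = "sge_numeric_error"))
  off_D <- p
  off_S <- p + n_ped
  off_l <- p + n_ped * (1 + include_social)
  off_g <- off_l + n_l
  a_D <- setNames(sol[off_D + seq_len(n_ped)], ped_ids)
  a_S <- if (include_social) setNames(sol[off_S + seq_len(n_ped)], ped_ids) else NULL
  out <- list(beta = setNames(sol[seq_len(p)], colnames(design$X)),
              a_D = a_D, a_S = a_S,
              litter = setNames(sol[off_l + seq_len(n_l)], colnames(design$W)),
              group = setNames(sol[off_g + seq_len(n_g)], colnames(design$V)),
              PEV_D = NULL, PEV_S = NULL,
              components = components, n_bar = design$n_bar,
              include_social = include_social)
  if (pev) {
    if (is.null(pev_ids)) pev_ids <- ped_ids
    pos <- match(as.character(pev_ids), ped_ids)
    if (anyNA(pos))
      stop_sge("PEV requested for animal(s) not in the relationship matrix",
               class = "sge_lookup_error")
    cols <- off_D + pos
    if (include_social) cols <- c(cols, off_S + pos)
    dim_M <- nrow(M)
    if (length(cols) < dim_M / 3) {
      E <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                                dims = c(dim_M, length(cols)))
      Minv_cols <- Matrix::solve(M, E)
      dvals <- Matrix::diag(Matrix::t(E) %*% Minv_cols)
    } else {
      Minv <- chol2inv(chol(as.matrix(M)))
      dvals <- diag(Minv)[cols]
    }
    out$PEV_D <- setNames(dvals[seq_along(pos)], ped_ids[pos])
    if (include_social)
      out$PEV_S <- setNames(dvals[length(pos) + seq_along(pos)], ped_ids[pos])
  }
  class(out) <- "sge_solutions"
  out
}

#' Total breeding value
#'
#' `TBV_i = DBV_i + (n - 1) SBV_i`: the total heritable impact of animal
#' i on the population, combining its direct effect on its own phenotype
#' and its social effect on each of its `n - 1` pen mates.
#'
#' @param dbv,sbv per-animal direct and social breeding values (`sbv`
#'   may be `NULL` for the classical model).
#' @param n (average) group size, >= 1.
#' @return per-animal TBV.
#' @export
total_breeding_value <- function(dbv, sbv, n) {
  if (n < 1) stop_sge("group size must be >= 1", class = "sge_config_error")
  if (is.null(sbv)) return(dbv)
  dbv + (n - 1) * sbv
}

#' Combined breeding value
#'
#' `CBV_i = DBV_i + sum of SBVs of i's pen mates` -- the heritable
#' prediction of animal i's own record, used against the corrected
#' phenotype in forward validation. Animals without a pen fall back to
#' `CBV = DBV` with a warning; under the classical model `CBV = DBV`
#' for everyone.
#'
#' @param dbv,sbv named per-animal breeding values (`sbv` may be `NULL`).
#' @param pens data frame with columns `animal` and `pen` giving pen
#'   membership of the target animals.
#' @return named CBV vector over `pens$animal`.
#' @export
combined_breeding_value <- function(dbv, sbv, pens) {
  animal <- as.character(pens$animal)
  out <- dbv[animal]
  if (is.null(sbv)) { names(out) <- animal; return(out) }
  no_pen <- is.na(pens$pen)
  if (any(no_pen))
    warning(sprintf("%d animal(s) without a pen: CBV = DBV", sum(no_pen)))
  by_pen <- split(animal[!no_pen], as.character(pens$pen[!no_pen]))
  for (mem in by_pen) {
    tot <- sum(sbv[mem])
    out[mem] <- out[mem] + (tot - sbv[mem])
  }
  names(out) <- animal
  out
}

#' Total heritable variance
#'
#' `sigma2_TBV = sigma2_aD + 2 (n - 1) sigma_aDaS + (n - 1)^2 sigma2_aS`,
#' the variance of total breeding values at group size `n`; the
#' `(n - 1)^2` term makes even small social variances substantial in
#' large groups.
#'
#' @param components a [variance_components()] vector.
#' @param n (average) group size, >= 1.
#' @return scalar variance.
#' @export
total_heritable_variance <- function(components, n) {
  if (n < 1) stop_sge("group size must be >= 1", class = "sge_config_error")
  vc <- unclass(components)
  vc[["aD"]] + 2 * (n - 1) * vc[["aDaS"]] + (n - 1)^2 * vc[["aS"]]
}

#' Phenotypic variance of the social model
#'
#' `sigma2_P = sigma2_aD + (n - 1) sigma2_aS + sigma2_g + sigma2_l +
#' sigma2_e`; with no social component this reduces to the classical
#' sum of variances.
#'
#' @inheritParams total_heritable_variance
#' @return scalar variance.
#' @export
phenotypic_variance <- function(components, n) {
  if (n < 1) stop_sge("group size must be >= 1", class = "sge_config_error")
  vc <- unclass(components)
  vc[["aD"]] + (n - 1) * vc[["aS"]] + vc[["g"]] + vc[["l"]] + vc[["e"]]
}

#' Total heritability
#'
#' `T2 = sigma2_TBV / sigma2_P`. Unlike classical heritability this
#' ratio can exceed 1 for large groups, because the numerator grows with
#' `(n - 1)^2` while the denominator grows with `(n - 1)`.
#'
#' @inheritParams total_heritable_variance
#' @return scalar ratio.
#' @export
total_heritability <- function(components, n) {
  sp <- phenotypic_variance(components, n)
  if (sp <= 0) stop_sge("phenotypic variance is zero", class = "sge_undefined_error")
  total_heritable_variance(components, n) / sp
}

#' Correlation between direct and social genetic effects
#'
#' `r = sigma_aDaS / sqrt(sigma2_aD sigma2_aS)`; positive values mean
#' animals that grow fast also stimulate their pen mates' growth.
#'
#' @param components a [variance_components()] vector with strictly
#'   positive `aD` and `aS`.
#' @return scalar correlation in [-1, 1].
#' @export
genetic_correlation <- function(components) {
  vc <- unclass(components)
  if (vc[["aD"]] <= 0 || vc[["aS"]] <= 0)
    stop_sge("genetic correlation undefined: zero direct or social variance",
             class = "sge_undefined_error")
  vc[["aDaS"]] / sqrt(vc[["aD"]] * vc[["aS"]])
}

#' Theoretical accuracy from prediction error variance
#'
#' `R_i = sqrt(1 - PEV_i / ((1 + F_i) sigma2))` with `F_i` the pedigree
#' inbreeding coefficient and `sigma2` the genetic variance of the
#' effect (direct or social). Numerical excess of PEV over
#' `(1 + F) sigma2` is clipped to `R = 0` with a warning.
#'
#' @param pev per-animal prediction error variance.
#' @param F per-animal inbreeding coefficients.
#' @param sigma2 genetic variance of the evaluated effect.
#' @return per-animal accuracies in [0, 1].
#' @export
theoretical_accuracy <- function(pev, F, sigma2) {
  if (sigma2 <= 0)
    stop_sge("genetic variance must be positive", class = "sge_undefined_error")
  ratio <- pev / ((1 + F) * sigma2)
  if (any(ratio > 1 + 1e-12))
    warning(sprintf("%d PEV value(s) exceed (1+F) sigma2; accuracy clipped to 0",
                    sum(ratio > 1 + 1e-12)))
  out <- sqrt(pmax(0, 1 - pmin(ratio, 1)))
  names(out) <- names(pev)
  out
}

## training-estimable fixed-effect prediction for new records: shared
## non-batch columns use the training estimates; batch (a year-month-week
## composite whose validation levels never occur in training) is handled
## afterwards by centring within validation batch
fixed_prediction_shared <- function(beta, phen, age_center) {
  pred <- rep(if ("(Intercept)" %in% names(beta)) beta[["(Intercept)"]] else 0,
              nrow(phen))
  for (nmb in names(beta)) {
    if (nmb == "(Intercept)" || startsWith(nmb, "batch")) next
    if (nmb == "age") {
      pred <- pred + beta[[nmb]] * (phen$age_days - age_center)
    } else if (startsWith(nmb, "sex")) {
      pred <- pred + beta[[nmb]] * (as.character(phen$sex) == sub("^sex", "", nmb))
    } else if (startsWith(nmb, "size")) {
      pred <- pred + beta[[nmb]] *
        (as.character(phen$group_size) == sub("^size", "", nmb))
    }
  }
  pred
}

#' Forward cross-validation of combined breeding values
#'
#' Masks the phenotypes of the last `n_mask` birth periods, solves the
#' model on the training records (validation animals stay in the
#' pedigree and, for single-step variants, in H), and correlates the
#' validation animals' combined breeding values with their phenotypes
#' corrected for fixed effects. Theoretical accuracies of the validation
#' animals' direct and social breeding values are summarised alongside.
#'
#' @param dataset an `sge_dataset` (or a list with `pedigree`,
#'   `phenotypes`, and optionally `genotypes`/`geno_ids`).
#' @param spec a [social_model_spec()] choosing the model variant.
#' @param components training variance components (a
#'   [variance_components()]); when `NULL` they are estimated on the
#'   training records by [fit_reml()].
#' @param n_mask number of trailing birth periods masked (default 2).
#' @param thresholds QC thresholds applied to the genotypes for
#'   single-step variants.
#' @param min_frequency group-size filter threshold applied to the
#'   records before analysis.
#' @return an `sge_validation` list: `cv_correlation`, `n_validation`,
#'   accuracy summaries `R_D` and `R_S` (mean, sd), the per-animal
#'   validation table, and the components used.
#' @export
forward_validation <- function(dataset, spec = social_model_spec(),
                               components = NULL, n_mask = 2,
                               thresholds = qc_thresholds(),
                               min_frequency = 0.10) {
  ped <- dataset$pedigree
  if (is.null(ped$F)) ped <- compute_inbreeding(ped)
  phen <- group_size_filter(dataset$phenotypes, min_frequency)
  periods <- sort(unique(phen$birth_period))
  if (length(periods) < max(2, n_mask + 1))
    stop_sge("forward validation needs more birth periods than are masked",
             class = "sge_validation_error")
  val_periods <- utils::tail(periods, n_mask)
  train <- phen[!(phen$birth_period %in% val_periods), , drop = FALSE]
  val <- phen[phen$birth_period %in% val_periods, , drop = FALSE]
  if (nrow(val) == 0L)
    stop_sge("empty validation set", class = "sge_validation_error")

  design <- build_design(train, ped, spec)
  A_inv <- build_A_inverse(ped)
  if (spec$relationship == "single-step") {
    if (is.null(dataset$genotypes))
      stop_sge("single-step validation needs genotypes", class = "sge_config_error")
    Mq <- qc_filter(dataset$genotypes, thresholds)
    Mq <- impute_mean(Mq)
    G <- build_G(Mq)
    A22 <- build_A22(ped, rownames(Mq))
    G_b <- blend_G(G, A22)
    K_inv <- build_H_inverse(A_inv, A22, G_b, tau = spec$tau,
                             omega = spec$omega, geno_ids = rownames(Mq),
                             quiet = TRUE)
  } else {
    K_inv <- A_inv
  }
  if (is.null(components)) {
    K <- dense_K_from_inverse(K_inv)
    fit <- fit_reml(design, K)
    components <- fit$components
  }
  sol <- solve_mme(design, K_inv, components, pev = TRUE,
                   pev_ids = unique(val$animal))

  cbv <- combined_breeding_value(sol$a_D, sol$a_S,
                                 val[, c("animal", "pen")])
  pred <- fixed_prediction_shared(sol$beta, val,
                                  age_center = mean(train$age_days))
  resid <- val$adg - pred
  y_c <- resid - stats::ave(resid, as.character(val$batch))
  if (stats::sd(y_c) < 1e-10 || stats::sd(cbv) < 1e-10)
    stop_sge("corrected phenotype or CBV has no variance in the validation set",
             class = "sge_validation_error")
  cv_cor <- stats::cor(cbv, y_c)

  Fv <- setNames(ped$F, ped$id)[unique(val$animal)]
  R_D <- theoretical_accuracy(sol$PEV_D, Fv, unclass(components)[["aD"]])
  R_S <- if (sol$include_social && unclass(components)[["aS"]] > 0)
    theoretical_accuracy(sol$PEV_S, Fv, unclass(components)[["aS"]]) else NULL
  tab <- data.frame(animal = val$animal, pen = val$pen,
                    y = val$adg, y_corrected = y_c,
                    DBV = unname(sol$a_D[val$animal]),
                    SBV = if (sol$include_social) unname(sol$a_S[val$animal]) else NA_real_,
                    CBV = unname(cbv),
                    R_D = unname(R_D[val$animal]),
                    R_S = if (!is.null(R_S)) unname(R_S[val$animal]) else NA_real_)
  structure(list(model_label = model_label(spec),
                 cv_correlation = cv_cor, n_validation = nrow(val),
                 R_D = c(mean = mean(R_D), sd = stats::sd(R_D)),
                 R_S = if (!is.null(R_S))
                   c(mean = mean(R_S), sd = stats::sd(R_S)) else NULL,
                 table = tab, components = components,
                 n_train = nrow(train)),
            class = "sge_validation")
}

#' Per-animal evaluation table
#'
#' Combines MME solutions into the standard per-animal report: DBV, SBV,
#' TBV at the model's average group size, CBV from pen membership, PEV
#' and theoretical accuracies.
#'
#' @param sol an [solve_mme()] result with PEV.
#' @param ped an inbreeding-annotated [pedigree_table].
#' @param pens data frame `animal`, `pen` (defaults: no pens, CBV = DBV).
#' @return data frame with one row per animal carrying PEV.
#' @export
evaluation_table <- function(sol, ped, pens = NULL) {
  ids <- names(sol$PEV_D)
  if (is.null(ped$F)) ped <- compute_inbreeding(ped)
  F <- setNames(ped$F, ped$id)[ids]
  vc <- unclass(sol$components)
  dbv <- sol$a_D[ids]
  sbv <- if (sol$include_social) sol$a_S[ids] else NULL
  tbv <- total_breeding_value(dbv, sbv, sol$n_bar)
  if (is.null(pens)) pens <- data.frame(animal = ids, pen = NA_character_)
  cbv <- suppressWarnings(combined_breeding_value(sol$a_D, sol$a_S, pens))
  data.frame(animal = ids,
             DBV = unname(dbv),
             SBV = if (!is.null(sbv)) unname(sbv) else NA_real_,
             TBV = unname(tbv),
             CBV = unname(cbv[ids]),
             PEV_D = unname(sol$PEV_D[ids]),
             PEV_S = if (!is.null(sol$PEV_S)) unname(sol$PEV_S[ids]) else NA_real_,
             R_D = unname(theoretical_accuracy(sol$PEV_D[ids], F, vc[["aD"]])),
             R_S = if (sol$include_social && vc[["aS"]] > 0)
               unname(theoretical_accuracy(sol$PEV_S[ids], F, vc[["aS"]]))
             else NA_real_)
}
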