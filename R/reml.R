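## REML for the social animal model, records-level formulation.
##
## The marginal covariance of the n analysed records is
##   V(theta) = sum_i theta_i S_i
## with fixed structure matrices
##   S_aD   = Z_D K Z_D',  S_aDaS = Z_D K Z_S' + Z_S K Z_D',
##   S_aS   = Z_S K Z_S',  S_g = V V',  S_l = W W',  S_e = I,
## where K is the (dense) relationship matrix among pedigree animals
## (A for pedigree models, H for single-step models). All REML
## quantities -- restricted log-likelihood, gradient, average-information
## matrix and the EM fallback -- are computed from V and the projection
## matrix P, which at desk scale (n up to a few thousand records) is
## faster and simpler than sparse selected inversion of the mixed-model
## equations, and exactly equivalent.

component_names <- function(include_social)
  if (include_social) c("aD", "aDaS", "aS", "g", "l", "e") else c("aD", "g", "l", "e")

## structure matrices S_i and the effect dimensions used by the EM step
reml_structures <- function(design, K) {
  n <- length(design$y)
  apos <- match(design$animal, rownames(K))
  if (anyNA(apos))
    stop_sge("relationship matrix K lacks phenotyped animal(s)",
             class = "sge_lookup_error")
  S <- list()
  S$aD <- K[apos, apos, drop = FALSE]
  include_social <- !is.null(design$Z_S)
  if (include_social) {
    T_SK <- as.matrix(design$Z_S %*% K)        # n x n_ped
    DS <- t(T_SK[, apos, drop = FALSE])        # Z_D K Z_S'
    S$aDaS <- DS + t(DS)
    S$aS <- symm(as.matrix(T_SK %*% Matrix::t(design$Z_S)))
  }
  S$g <- as.matrix(Matrix::tcrossprod(design$V))
  S$l <- as.matrix(Matrix::tcrossprod(design$W))
  S$e <- diag(n)
  m <- c(aD = nrow(K), aDaS = nrow(K), aS = nrow(K),
         g = ncol(design$V), l = ncol(design$W), e = n)
  list(S = S[component_names(include_social)],
       m = m[component_names(include_social)],
       include_social = include_social)
}

## restricted log-likelihood and the P-matrix quantities at theta
reml_eval <- function(theta, S, X, y) {
  V <- Reduce(`+`, Map(`*`, theta, S))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  beta <- drop(chol2inv(chX) %*% (XtVi %*% y))
  P <- Vi - crossprod(XtVi, chol2inv(chX) %*% XtVi)
  P <- symm(P)
  Py <- drop(P %*% y)
  logL <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                    sum(y * Py))
  list(logL = logL, P = P, Py = Py, beta = beta)
}

## project a parameter vector back into the admissible cone:
## variances floored, genetic 2x2 block eigenvalue-clipped to PSD
project_theta <- function(theta, include_social, floor_val) {
  for (nm in c("aD", "aS", "g", "l", "e"))
    if (nm %in% names(theta)) theta[nm] <- max(theta[nm], floor_val)
  if (include_social) {
    C <- matrix(c(theta["aD"], theta["aDaS"], theta["aDaS"], theta["aS"]), 2, 2)
    eg <- eigen(C, symmetric = TRUE)
    clip <- 1e-8 * max(sum(diag(C)), floor_val)
    if (any(eg$values < clip)) {
      C <- eg$vectors %*% diag(pmax(eg$values, clip)) %*% t(eg$vectors)
      theta["aD"] <- max(C[1, 1], floor_val)
      theta["aS"] <- max(C[2, 2], floor_val)
      theta["aDaS"] <- C[1, 2]
    }
  }
  theta
}

#' Fit the social animal model by average-information REML
#'
#' Estimates the (co)variance components of the classical
#' (direct-genetic-only) or social animal model by AI-REML on the
#' records-level likelihood, with step halving and an EM-REML fallback
#' whenever the average-information update leaves the admissible
#' parameter space (variances non-negative, genetic 2x2 block positive
#' semidefinite via eigenvalue clipping). Iteration stops when the
#' largest relative component change drops below `tol`.
#'
#' @param design a [build_design()] object (its `spec` decides whether
#'   the social effect is fitted).
#' @param K dense relationship matrix among pedigree animals, with animal
#'   ids as dimnames: `A` from [build_A()] for pedigree models, or the
#'   inverse of the single-step `H^-1` (see [omega_grid()]).
#' @param start optional named start values (`aD`, `aDaS`, `aS`, `g`,
#'   `l`, `e`); the default splits the phenotypic variance equally over
#'   the variances with zero covariance.
#' @param tol convergence tolerance on the max relative parameter change.
#' @param max_iter iteration cap; exceeding it returns `converged = FALSE`.
#' @param fix character vector of component names held at their start
#'   values (excluded from the update and from the AIC parameter count).
#' @param em_burnin number of initial EM-REML iterations before the AI
#'   updates take over.
#' @param label model label stored in the result (defaults to
#'   `PED_classic`/`PED_social`/`omega_x.x` from the design's spec).
#' @param verbose print the likelihood trajectory.
#' @return an `sge_fit`: `components` ([variance_components()]), `logL`,
#'   `aic`, `k`, `converged`, `n_iter`, `model_label`, `beta`, `n_bar`,
#'   `n_records`, and the iteration `trajectory`.
#' @export
fit_reml <- function(design, K, start = NULL, tol = 1e-8, max_iter = 500,
                     fix = character(0), label = NULL, em_burnin = 3,
                     verbose = FALSE) {
  include_social <- !is.null(design$Z_S) && design$spec$include_social
  nm <- component_names(include_social)
  str <- reml_structures(design, K)
  S <- str$S
  y <- design$y
  X <- design$X
  vy <- stats::var(y)
  floor_val <- 1e-8 * vy

  theta <- setNames(rep(0, length(nm)), nm)
  nvar <- setdiff(nm, "aDaS")
  theta[nvar] <- vy / length(nvar)
  if (!is.null(start)) {
    start <- unlist(start)
    common <- intersect(names(start), nm)
    theta[common] <- start[common]
  }
  theta <- project_theta(theta, include_social, floor_val)
  bad_fix <- setdiff(fix, nm)
  if (length(bad_fix))
    stop_sge("unknown component(s) in 'fix': %s", paste(bad_fix, collapse = ", "),
             class = "sge_config_error")
  free <- setdiff(nm, fix)

  ev <- reml_eval(theta, S, X, y)
  if (is.null(ev))
    stop_sge("singular covariance at the starting values", class = "sge_numeric_error")
  traj <- matrix(NA_real_, 0, length(nm) + 1,
                 dimnames = list(NULL, c(nm, "logL")))
  converged <- FALSE
  iter <- 0L
  stall <- 0L
  lambda <- 0
  while (iter < max_iter) {
    iter <- iter + 1L
    ## gradient and AI matrix
    w <- lapply(S, function(Si) drop(Si %*% ev$Py))
    tr <- vapply(S, function(Si) sum(ev$P * Si), 0)
    q <- vapply(w, function(wi) sum(ev$Py * wi), 0)
    grad <- -0.5 * (tr - q)
    Pw <- lapply(w, function(wi) drop(ev$P %*% wi))
    AI <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
    for (i in seq_along(nm)) for (j in i:length(nm)) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(w[[i]] * Pw[[j]])
    }
    if (length(free) == 0L) { converged <- TRUE; break }

    ## active set: variances pinned at the floor whose gradient points
    ## further down stay put this iteration, so the AI step is not wasted
    ## fighting the boundary
    pinned <- vapply(free, function(nmi) {
      nmi != "aDaS" && theta[nmi] <= floor_val * (1 + 1e-6) && grad[nmi] < 0
    }, TRUE)
    active <- free[!pinned]
    if (length(active) == 0L) { converged <- TRUE; break }

    AIf <- AI[active, active, drop = FALSE]
    accepted <- FALSE
    ## Levenberg-Marquardt damped AI step: lambda persists across
    ## iterations, shrinking while steps are accepted and growing on
    ## rejection, which suppresses the zigzag AI-REML shows on flat
    ## likelihood ridges. The first few iterations use EM only (monotone,
    ## picks a sensible basin).
    if (iter > em_burnin) {
      for (h in 1:8) {
        damp <- AIf + lambda * diag(diag(AIf), nrow(AIf))
        delta <- tryCatch(solve(damp, grad[active]), error = function(e) NULL)
        if (is.null(delta)) { lambda <- max(lambda * 10, 1e-4); next }
        cand <- theta
        cand[active] <- cand[active] + delta
        cand <- project_theta(cand, include_social, floor_val)
        ev_c <- reml_eval(cand, S, X, y)
        if (!is.null(ev_c) && ev_c$logL >= ev$logL - 1e-10) {
          theta_new <- cand; ev_new <- ev_c; accepted <- TRUE
          ## extend along the accepted direction while it keeps paying:
          ## cheap acceleration along flat likelihood ridges
          for (dbl in 1:4) {
            cand2 <- theta
            cand2[active] <- cand2[active] + 2^dbl * delta
            cand2 <- project_theta(cand2, include_social, floor_val)
            ev_2 <- reml_eval(cand2, S, X, y)
            if (is.null(ev_2) || ev_2$logL <= ev_new$logL) break
            theta_new <- cand2; ev_new <- ev_2
          }
          lambda <- lambda / 10
          if (lambda < 1e-8) lambda <- 0
          break
        }
        lambda <- max(lambda * 10, 1e-4)
      }
    }
    if (!accepted) {
      ## EM-REML step: theta_i <- theta_i + theta_i^2 / m_i * 2 grad_i for
      ## iid components; matrix form C <- C + (1/q) C M C for the genetic
      ## block, with M built from the same gradient entries
      cand <- theta
      for (nmi in intersect(free, c("g", "l", "e")))
        cand[nmi] <- theta[nmi] + theta[nmi]^2 / str$m[nmi] * 2 * grad[nmi]
      if (include_social && any(c("aD", "aDaS", "aS") %in% free)) {
        C <- matrix(c(theta["aD"], theta["aDaS"], theta["aDaS"], theta["aS"]), 2, 2)
        M <- matrix(c(2 * grad["aD"], grad["aDaS"],
                      grad["aDaS"], 2 * grad["aS"]), 2, 2)
        Cn <- C + (C %*% M %*% C) / str$m["aD"]
        if ("aD" %in% free) cand["aD"] <- Cn[1, 1]
        if ("aS" %in% free) cand["aS"] <- Cn[2, 2]
        if ("aDaS" %in% free) cand["aDaS"] <- Cn[1, 2]
      } else if ("aD" %in% free) {
        cand["aD"] <- theta["aD"] + theta["aD"]^2 / str$m["aD"] * 2 * grad["aD"]
      }
      cand <- project_theta(cand, include_social, floor_val)
      ev_c <- reml_eval(cand, S, X, y)
      if (is.null(ev_c))
        stop_sge("singular covariance during EM fallback", class = "sge_numeric_error")
      theta_new <- cand; ev_new <- ev_c
    }
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-4 * vy))
    dll <- ev_new$logL - ev$logL
    stall <- if (dll < 1e-8 * (1 + abs(ev$logL))) stall + 1L else 0L
    traj <- rbind(traj, c(theta_new, ev_new$logL))
    if (verbose)
      message(sprintf("iter %3d logL %.6f max rel change %.2e", iter,
                      ev_new$logL, rel))
    theta <- theta_new
    ev <- ev_new
    ## converged when parameters settle, or when the restricted likelihood
    ## has been stationary for several iterations (components pinned at a
    ## boundary can keep cycling below any parameter tolerance)
    if (rel < tol || stall >= 3L) { converged <- TRUE; break }
  }

  k <- length(free)
  comps <- variance_components(aD = theta[["aD"]],
                               aDaS = if (include_social) theta[["aDaS"]] else 0,
                               aS = if (include_social) theta[["aS"]] else 0,
                               g = theta[["g"]], l = theta[["l"]],
                               e = theta[["e"]])
  if (is.null(label)) label <- model_label(design$spec)
  structure(list(components = comps, logL = ev$logL, aic = aic(ev$logL, k),
                 k = k, converged = converged, n_iter = iter,
                 model_label = label, beta = setNames(ev$beta, colnames(X)),
                 n_bar = design$n_bar, n_records = length(y),
                 include_social = include_social, trajectory = traj),
            class = "sge_fit")
}

#' @export
print.sge_fit <- function(x, ...) {
  cat(sprintf("%s fit (%d records, n_bar = %.2f): logL = %.3f, AIC = %.3f, %s in %d iter\n",
              x$model_label, x$n_records, x$n_bar, x$logL, x$aic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(round(unclass(x$components), 2))
  invisible(x)
}

#' Akaike information criterion
#'
#' `-2 logL + 2 k`, with `k` the number of free (co)variance parameters
#' (4 for the classical model, 6 for the social model); fixed-effect
#' counts are identical across the compared models and cancel in delta
#' AIC.
#'
#' @param logL REML log-likelihood.
#' @param k number of free parameters (>= 1).
#' @return scalar AIC.
#' @examples
#' aic(0, 4)     # 8
#' aic(-100, 6)  # 212
#' @export
aic <- function(logL, k) {
  if (k < 1) stop_sge("k must be >= 1", class = "sge_config_error")
  -2 * logL + 2 * k
}

## dense relationship matrix from a sparse precision (pedigree or H inverse)
dense_K_from_inverse <- function(K_inv) {
  Kd <- as.matrix(Matrix::solve(K_inv))
  dimnames(Kd) <- dimnames(K_inv)
  symm(Kd)
}

#' Fit the model grid over omega plus the pedigree baselines
#'
#' Runs `PED_classic`, `PED_social` and one single-step social fit per
#' `omega` (tau fixed), warm-starting each omega fit from the previous
#' one, and tabulates components, derived genetic parameters and delta
#' AIC relative to the grid minimum -- the grid-and-select workflow used
#' to tune the single-step relationship matrix.
#'
#' @param design a social-model [build_design()] object (its `Z_S` is
#'   ignored for the classical fit).
#' @param A dense pedigree relationship matrix from [build_A()].
#' @param A_inv sparse pedigree inverse from [build_A_inverse()]; only
#'   needed when genotypes are supplied.
#' @param A22,G_b pedigree block and blended genomic matrix for the
#'   genotyped animals (`NULL` for a pedigree-only grid).
#' @param geno_ids genotyped animal ids.
#' @param omegas omega values in (0, 1]; default 0.1 to 1.0 by 0.1.
#' @param tau genomic scaling, fixed at 1 by default.
#' @param start optional start values passed to the first fit.
#' @param tol,max_iter REML controls, see [fit_reml()].
#' @return data frame (class `sge_grid`) with one row per model: label,
#'   omega, components, `r`, `sigma2_P`, `T2`, `logL`, `AIC`, `dAIC`,
#'   convergence; the fit objects are attached as attribute `"fits"`.
#' @export
omega_grid <- function(design, A, A_inv = NULL, A22 = NULL, G_b = NULL,
                       geno_ids = NULL, omegas = seq(0.1, 1, by = 0.1),
                       tau = 1, start = NULL, tol = 1e-8, max_iter = 500) {
  if (any(omegas <= 0 | omegas > 1))
    stop_sge("omega values must lie in (0, 1]", class = "sge_config_error")
  have_geno <- !is.null(G_b) && !is.null(A22) && length(geno_ids) > 0
  fits <- list()
  design_classic <- design
  design_classic$spec$include_social <- FALSE
  design_classic$Z_S <- NULL
  design_classic$spec$relationship <- "pedigree"
  fits$PED_classic <- fit_reml(design_classic, A, start = start,
                               tol = tol, max_iter = max_iter,
                               label = "PED_classic")
  design_social <- design
  design_social$spec$include_social <- TRUE
  design_social$spec$relationship <- "pedigree"
  ## warm-start the social fit from the nested classical optimum: ascent
  ## is monotone, so the social likelihood can never fall below it
  start_social <- unclass(fits$PED_classic$components)
  start_social["aS"] <- 0.05 * start_social["aD"]
  start_social["aDaS"] <- 0
  fits$PED_social <- fit_reml(design_social, A, start = start_social,
                              tol = tol, max_iter = max_iter,
                              label = "PED_social", em_burnin = 0)
  if (have_geno) {
    warm <- unclass(fits$PED_social$components)
    for (om in omegas) {
      lab <- sprintf("omega_%.1f", om)
      fit <- tryCatch({
        H_inv <- build_H_inverse(A_inv, A22, G_b, tau = tau, omega = om,
                                 geno_ids = geno_ids, quiet = TRUE)
        K <- dense_K_from_inverse(H_inv)
        spec_om <- design$spec
        spec_om$include_social <- TRUE
        spec_om$relationship <- "single-step"
        spec_om$tau <- tau; spec_om$omega <- om
        d_om <- design; d_om$spec <- spec_om
        fit_reml(d_om, K, start = warm, tol = tol, max_iter = max_iter,
                 label = lab, em_burnin = 0)
      }, error = function(e) e)
      fits[[lab]] <- fit
      if (inherits(fit, "sge_fit")) warm <- unclass(fit$components)
    }
  } else {
    message("no genomic information supplied: grid restricted to pedigree models")
  }

  rows <- lapply(names(fits), function(lab) {
    f <- fits[[lab]]
    if (!inherits(f, "sge_fit"))
      return(data.frame(model = lab, omega = NA_real_, aD = NA_real_,
                        aDaS = NA_real_, aS = NA_real_, g = NA_real_,
                        l = NA_real_, e = NA_real_, r = NA_real_,
                        sigma2_P = NA_real_, T2 = NA_real_, logL = NA_real_,
                        AIC = NA_real_, converged = FALSE, n_iter = NA_integer_,
                        error = conditionMessage(f)))
    vc <- f$components
    r <- if (f$include_social && vc[["aD"]] > 0 && vc[["aS"]] > 0)
      genetic_correlation(vc) else NA_real_
    data.frame(model = lab,
               omega = if (grepl("^omega", lab)) as.numeric(sub("omega_", "", lab)) else NA_real_,
               aD = vc[["aD"]], aDaS = vc[["aDaS"]], aS = vc[["aS"]],
               g = vc[["g"]], l = vc[["l"]], e = vc[["e"]], r = r,
               sigma2_P = phenotypic_variance(vc, f$n_bar),
               T2 = total_heritability(vc, f$n_bar),
               logL = f$logL, AIC = f$aic, converged = f$converged,
               n_iter = f$n_iter, error = NA_character_)
  })
  out <- do.call(rbind, rows)
  out$dAIC <- out$AIC - min(out$AIC, na.rm = TRUE)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("sge_grid", "data.frame")
  out
}

#' Write an omega-grid table as TSV
#'
#' Columns mirror the published layout: components, `r`, `sigma2_P`,
#' `T2` and `dAIC` per model.
#'
#' @param grid an [omega_grid()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  cols <- c("model", "aD", "aDaS", "aS", "g", "l", "e", "r",
            "sigma2_P", "T2", "dAIC")
  data.table::fwrite(as.data.frame(grid)[, cols], path, sep = "\t")
  invisible(path)
}
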