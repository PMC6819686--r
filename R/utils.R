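#' @importFrom stats rnorm rbinom runif var cor sd pchisq model.matrix setNames aggregate
#' @importFrom utils write.table read.table
#' @import Matrix
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sge <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "sge_error")))
}

#' Check that a 2x2 direct-social covariance matrix is positive semidefinite
#'
#' @param C 2x2 symmetric matrix.
#' @param tol relative eigenvalue tolerance.
#' @return `TRUE`/`FALSE`.
#' @keywords internal
is_psd2 <- function(C, tol = 1e-10) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(abs(ev), 1))
}

## symmetrize to iron out floating-point asymmetry from BLAS products
symm <- function(M) (M + t(M)) / 2
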