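#' Quality-control thresholds for SNP dosage panels
#'
#' Conventional defaults for a medium-density pig chip: markers with minor
#' allele frequency below 1%, call rate below 90%, or Hardy-Weinberg
#' chi-square p-value below 1e-6 are removed, as are animals with call
#' rate below 90%. Every threshold is a knob; set a missingness threshold
#' to 1, `min_maf` to 0 and `hwe_alpha` to 0 to disable a rule.
#'
#' @param min_maf minimum minor allele frequency.
#' @param max_marker_missing maximum missing proportion per marker
#'   (1 - call rate).
#' @param max_animal_missing maximum missing proportion per animal.
#' @param hwe_alpha significance level of the 1-df Hardy-Weinberg
#'   chi-square test on genotype counts.
#' @param drop_monomorphic drop markers with no variation.
#' @param drop_nonautosomal drop markers whose chromosome label (when
#'   supplied to [qc_filter()]) is X, Y or MT.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_maf = 0.01, max_marker_missing = 0.10,
                          max_animal_missing = 0.10, hwe_alpha = 1e-6,
                          drop_monomorphic = TRUE, drop_nonautosomal = TRUE) {
  props <- c(min_maf, max_marker_missing, max_animal_missing)
  if (any(props < 0 | props > 1))
    stop_sge("QC proportions must lie in [0, 1]", class = "sge_config_error")
  structure(list(min_maf = min_maf, max_marker_missing = max_marker_missing,
                 max_animal_missing = max_animal_missing, hwe_alpha = hwe_alpha,
                 drop_monomorphic = drop_monomorphic,
                 drop_nonautosomal = drop_nonautosomal),
            class = "qc_thresholds")
}

hwe_pvalues <- function(M) {
  n0 <- colSums(M == 0, na.rm = TRUE)
  n1 <- colSums(M == 1, na.rm = TRUE)
  n2 <- colSums(M == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
  x2 <- numeric(length(n))
  ok <- e0 > 0 & e1 > 0 & e2 > 0
  x2[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] + (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  pv <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  pv[!ok] <- 1  # monomorphic markers are handled by their own rule
  pv
}

#' Filter a SNP dosage matrix
#'
#' Applies the QC chain in a fixed order: animal missingness, then
#' non-autosomal markers (when chromosome labels are given), monomorphic
#' markers, marker missingness, minor allele frequency, and the
#' Hardy-Weinberg chi-square test. A report with counts removed per rule
#' is attached.
#'
#' @param M animals x markers matrix of dosages in \{0, 1, 2, NA\}.
#' @param thresholds a [qc_thresholds()] object.
#' @param chrom optional character vector of chromosome labels per marker.
#' @return the filtered matrix with attribute `"qc_report"` (data frame
#'   with columns rule, markers_removed, animals_removed).
#' @export
qc_filter <- function(M, thresholds = qc_thresholds(), chrom = NULL) {
  stopifnot(is.matrix(M))
  bad <- !(M %in% c(0, 1, 2, NA))
  if (any(bad))
    stop_sge("dosages must be 0/1/2 or missing", class = "sge_config_error")
  report <- data.frame(rule = character(0), markers_removed = integer(0),
                       animals_removed = integer(0))
  note <- function(rule, mk = 0L, an = 0L)
    rbind(report, data.frame(rule = rule, markers_removed = mk, animals_removed = an))

  an_miss <- rowMeans(is.na(M))
  drop_an <- an_miss > thresholds$max_animal_missing
  report <- note("animal_missingness", 0L, sum(drop_an))
  M <- M[!drop_an, , drop = FALSE]

  if (!is.null(chrom) && thresholds$drop_nonautosomal) {
    stopifnot(length(chrom) == ncol(M))
    drop_chr <- toupper(chrom) %in% c("X", "Y", "MT", "M", "XY")
    report <- note("nonautosomal", sum(drop_chr), 0L)
    M <- M[, !drop_chr, drop = FALSE]
    chrom <- chrom[!drop_chr]
  }

  if (thresholds$drop_monomorphic) {
    ## all-missing markers are left to the missingness rule
    mono <- apply(M, 2, function(x) length(unique(x[!is.na(x)])) == 1L)
    report <- note("monomorphic", sum(mono), 0L)
    M <- M[, !mono, drop = FALSE]
  }

  mk_miss <- colMeans(is.na(M))
  drop_miss <- mk_miss > thresholds$max_marker_missing
  report <- note("marker_missingness", sum(drop_miss), 0L)
  M <- M[, !drop_miss, drop = FALSE]

  if (ncol(M)) {
    p <- colMeans(M, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    drop_maf <- maf < thresholds$min_maf
    report <- note("maf", sum(drop_maf), 0L)
    M <- M[, !drop_maf, drop = FALSE]
  }

  if (ncol(M) && thresholds$hwe_alpha > 0) {
    drop_hwe <- hwe_pvalues(M) < thresholds$hwe_alpha
    report <- note("hwe", sum(drop_hwe), 0L)
    M <- M[, !drop_hwe, drop = FALSE]
  }

  if (ncol(M) == 0L)
    stop_sge("all markers removed by QC", class = "sge_empty_panel_error")
  attr(M, "qc_report") <- report
  M
}

#' Write a QC report as TSV
#' @param M matrix returned by [qc_filter()] (or a report data frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(M, path) {
  rep <- if (is.data.frame(M)) M else attr(M, "qc_report")
  data.table::fwrite(rep, path, sep = "\t")
  invisible(path)
}

#' Observed allele frequencies per marker
#'
#' @param M animals x markers dosage matrix (0/1/2, NA allowed).
#' @return numeric vector `p_m` = mean dosage / 2 over non-missing entries.
#' @export
allele_frequencies <- function(M) {
  nobs <- colSums(!is.na(M))
  if (any(nobs == 0))
    stop_sge("marker(s) with all entries missing: %s",
             paste(utils::head(which(nobs == 0), 5), collapse = ", "),
             class = "sge_empty_panel_error")
  colMeans(M, na.rm = TRUE) / 2
}

#' Mean-impute missing dosages
#' @param M dosage matrix.
#' @param p allele frequencies (defaults to observed).
#' @return matrix with `NA` replaced by `2 p_m`.
#' @export
impute_mean <- function(M, p = allele_frequencies(M)) {
  if (!anyNA(M)) return(M)
  idx <- which(is.na(M), arr.ind = TRUE)
  M[idx] <- 2 * p[idx[, 2]]
  M
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = Z Z' / (2 sum p_m (1 - p_m))` with `Z` the dosage matrix centered
#' by twice the allele frequency.
#'
#' @param M complete dosage matrix (impute first; see [impute_mean()]).
#' @param p per-marker allele frequencies used for centering and scaling.
#' @return dense symmetric G with animal ids as dimnames.
#' @export
build_G <- function(M, p = allele_frequencies(M)) {
  if (anyNA(M))
    stop_sge("missing dosages: impute before building G", class = "sge_config_error")
  if (sum(p > 0 & p < 1) < 2L)
    stop_sge("fewer than 2 polymorphic markers", class = "sge_degenerate_panel_error")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop_sge("degenerate panel: sum p(1-p) is zero", class = "sge_degenerate_panel_error")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  symm(G)
}

#' Blend the genomic and pedigree relationship matrices
#'
#' `G_b = alpha G + beta A22`, the standard guard that keeps the genomic
#' matrix invertible and restores a polygenic remainder. Defaults 0.95/0.05.
#'
#' @param G,A22 conformable square matrices over the same animals.
#' @param alpha,beta blending weights summing to 1.
#' @return blended matrix `G_b`.
#' @export
blend_G <- function(G, A22, alpha = 0.95, beta = 0.05) {
  if (!all(dim(G) == dim(A22)))
    stop_sge("G (%d x %d) and A22 (%d x %d) are not conformable",
             nrow(G), ncol(G), nrow(A22), ncol(A22), class = "sge_shape_error")
  if (abs(alpha + beta - 1) > 1e-8)
    stop_sge("blending weights must sum to 1", class = "sge_config_error")
  alpha * G + beta * as.matrix(A22)
}

#' Single-step H-inverse
#'
#' `H^-1 = A^-1` plus the genotyped-animal block
#' `tau G_b^-1 - omega A22^-1`, the tuned single-step relationship
#' inverse. The block is computed densely and embedded by id into the
#' sparse pedigree inverse. Condition numbers of `G_b` and `A22` are
#' reported via `message()`.
#'
#' @param A_inv sparse pedigree relationship inverse from
#'   [build_A_inverse()], with animal ids as dimnames.
#' @param A22 pedigree relationship block of the genotyped animals.
#' @param G_b (blended) genomic relationship matrix, same animal order as
#'   `A22`.
#' @param tau scaling of the genomic inverse (1 fixes the genomic scale).
#' @param omega scaling of the pedigree-block inverse; the proportion of
#'   polygenic variance not explained by markers is its usual reading.
#' @param geno_ids animal ids of the rows of `G_b`/`A22`.
#' @param quiet suppress the condition-number message.
#' @return sparse symmetric H-inverse with attributes `tau` and `omega`.
#' @export
build_H_inverse <- function(A_inv, A22, G_b, tau = 1, omega = 1, geno_ids,
                            quiet = FALSE) {
  geno_ids <- as.character(geno_ids)
  pos <- match(geno_ids, rownames(A_inv))
  if (anyNA(pos))
    stop_sge("genotyped id(s) absent from pedigree inverse: %s",
             paste(geno_ids[is.na(pos)], collapse = ", "), class = "sge_lookup_error")
  if (length(geno_ids) == 0L) return(A_inv)
  G_b <- as.matrix(G_b); A22 <- as.matrix(A22)
  kG <- kappa(G_b, exact = FALSE); kA <- kappa(A22, exact = FALSE)
  if (!quiet)
    message(sprintf("H-inverse: cond(G_b) ~ %.3g, cond(A22) ~ %.3g", kG, kA))
  Gi <- tryCatch(chol2inv(chol(G_b)),
                 error = function(e) stop_sge(
                   "G_b is not positive definite; blend with A22 (beta > 0) or lower omega",
                   class = "sge_linalg_error"))
  Ai22 <- tryCatch(chol2inv(chol(A22)),
                   error = function(e) stop_sge(
                     "A22 is singular; check for duplicated genotyped animals",
                     class = "sge_linalg_error"))
  block <- tau * Gi - omega * Ai22
  n <- nrow(A_inv)
  idx <- expand.grid(i = pos, j = pos)
  B <- Matrix::sparseMatrix(i = idx$i, j = idx$j, x = as.vector(block),
                            dims = c(n, n), dimnames = dimnames(A_inv))
  H_inv <- Matrix::forceSymmetric(Matrix::drop0(A_inv + B, tol = 0))
  attr(H_inv, "tau") <- tau
  attr(H_inv, "omega") <- omega
  H_inv
}

#' Pearson correlation of off-diagonal G and A22 elements
#'
#' The usual concordance diagnostic between genomic and pedigree
#' relationships, computed over strictly-lower-triangle pairs.
#'
#' @param G,A22 square matrices over the same animals in the same order.
#' @return scalar correlation.
#' @export
g_a22_offdiag_correlation <- function(G, A22) {
  if (nrow(G) < 3L)
    stop_sge("off-diagonal correlation needs at least 3 animals (2 pairs)",
             class = "sge_undefined_error")
  lt <- lower.tri(G)
  g <- G[lt]; a <- as.matrix(A22)[lt]
  if (stats::sd(g) == 0 || stats::sd(a) == 0)
    stop_sge("off-diagonal elements have zero variance", class = "sge_undefined_error")
  stats::cor(g, a)
}

#' Bundle relationship matrices for a single-step analysis
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree block for the genotyped animals.
#' @param A_inv sparse pedigree inverse.
#' @param tau,omega single-step scaling constants.
#' @param alpha,beta blending weights for `G_b = alpha G + beta A22`.
#' @param geno_ids genotyped animal ids (defaults to rownames of `G`).
#' @param quiet passed to [build_H_inverse()].
#' @return a `relationship_set` list with elements `G`, `A22`, `G_b`,
#'   `H_inv`, `tau`, `omega`, `alpha_blend`, `beta_blend`, `geno_ids`.
#' @export
relationship_set <- function(G, A22, A_inv, tau = 1, omega = 1,
                             alpha = 0.95, beta = 0.05,
                             geno_ids = rownames(G), quiet = TRUE) {
  G_b <- blend_G(G, A22, alpha, beta)
  H_inv <- build_H_inverse(A_inv, A22, G_b, tau = tau, omega = omega,
                           geno_ids = geno_ids, quiet = quiet)
  structure(list(G = G, A22 = A22, G_b = G_b, H_inv = H_inv,
                 tau = tau, omega = omega, alpha_blend = alpha,
                 beta_blend = beta, geno_ids = as.character(geno_ids)),
            class = "relationship_set")
}

#' Read genotype dosages
#'
#' `read_genotypes_raw()` parses the PLINK `.raw` additive-coding dialect
#' (header `FID IID PAT MAT SEX PHENOTYPE SNP1_A ...`, `NA` for missing);
#' `read_genotypes_tsv()` parses a plain table whose first column is the
#' animal id and remaining columns are 0/1/2 dosages.
#'
#' @param path input file.
#' @return dosage matrix with animal ids as rownames.
#' @export
read_genotypes_raw <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("FID", "IID")
  if (!all(need %in% names(df)))
    stop_sge("not a PLINK .raw header (FID/IID missing)", class = "sge_config_error")
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(df))
  M <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(df$IID)
  M
}

#' @rdname read_genotypes_raw
#' @export
read_genotypes_tsv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(df[[1]])
  M
}

#' Write genotype dosages
#'
#' @param M dosage matrix with animal ids as rownames.
#' @param path output file.
#' @param format `"raw"` (PLINK .raw-compatible) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(M, path, format = c("raw", "tsv")) {
  format <- match.arg(format)
  if (format == "raw") {
    out <- data.frame(FID = rownames(M), IID = rownames(M), PAT = 0L, MAT = 0L,
                      SEX = 0L, PHENOTYPE = -9L)
    out <- cbind(out, as.data.frame(M))
    data.table::fwrite(out, path, sep = " ", na = "NA", quote = FALSE)
  } else {
    out <- cbind(data.frame(id = rownames(M)), as.data.frame(M))
    data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  }
  invisible(path)
}
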