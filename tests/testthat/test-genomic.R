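make_panel <- function(n, m, seed = 1) {
  set.seed(seed)
  M <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(paste0("a", seq_len(n)), paste0("snp", seq_len(m))))
  storage.mode(M) <- "double"
  M
}

test_that("QC chain removes planted failures and nothing else", {
  M <- make_panel(100, 50, seed = 2)
  M[, 3] <- 2                                # monomorphic
  planted_missing <- c(10, 20, 30, 40, 44)
  M[, planted_missing] <- NA                 # all-missing markers
  out <- qc_filter(M, qc_thresholds(min_maf = 0, hwe_alpha = 0,
                                    max_marker_missing = 0.1))
  rep <- attr(out, "qc_report")
  expect_equal(rep$markers_removed[rep$rule == "monomorphic"], 1L)
  expect_equal(rep$markers_removed[rep$rule == "marker_missingness"], 5L)
  expect_false(any(colnames(out) %in% colnames(M)[c(3, planted_missing)]))
  expect_equal(ncol(out), 44L)

  ## thresholds all disabled: identity
  loose <- qc_thresholds(min_maf = 0, max_marker_missing = 1,
                         max_animal_missing = 1, hwe_alpha = 0,
                         drop_monomorphic = FALSE, drop_nonautosomal = FALSE)
  M2 <- make_panel(30, 20, seed = 3)
  expect_equal(unname(qc_filter(M2, loose)), unname(M2), ignore_attr = TRUE)

  ## animal missingness rule
  M3 <- make_panel(20, 30, seed = 4)
  M3[1, 1:29] <- NA
  out3 <- qc_filter(M3, qc_thresholds(min_maf = 0, hwe_alpha = 0))
  expect_equal(nrow(out3), 19L)
  expect_false("a1" %in% rownames(out3))

  ## HWE: a marker with only heterozygotes in a large sample fails
  M4 <- make_panel(200, 10, seed = 5)
  M4[, 7] <- 1
  out4 <- qc_filter(M4, qc_thresholds(min_maf = 0, hwe_alpha = 1e-6))
  expect_false("snp7" %in% colnames(out4))

  ## non-autosomal markers dropped when labels are given
  M5 <- make_panel(30, 4, seed = 6)
  out5 <- qc_filter(M5, qc_thresholds(min_maf = 0, hwe_alpha = 0),
                    chrom = c("1", "X", "2", "Y"))
  expect_equal(colnames(out5), c("snp1", "snp3"))

  expect_error(qc_filter(matrix(c(0, 3), 1, 2), qc_thresholds()),
               class = "sge_config_error")
  M6 <- matrix(2, 5, 2)
  expect_error(qc_filter(M6, qc_thresholds()), class = "sge_empty_panel_error")
})

test_that("allele frequencies are per-marker mean dosage over two", {
  M <- matrix(c(0, 1, 2), 3, 1)
  expect_equal(allele_frequencies(M), 0.5, ignore_attr = TRUE)
  expect_equal(allele_frequencies(matrix(0, 4, 1)), 0, ignore_attr = TRUE)
  Mk <- matrix(c(2, 2, 1, 0, NA, 1), 3, 2)   # counts by hand: 5/6 and 1/4
  expect_equal(unname(allele_frequencies(Mk)), c(5 / 6, 0.25))
  expect_error(allele_frequencies(matrix(NA_real_, 3, 1)),
               class = "sge_empty_panel_error")
})

test_that("VanRaden G: hand example, duplicates, and A22 concordance", {
  M <- matrix(c(2, 0, 0, 2), 2, 2, dimnames = list(c("a", "b"), NULL))
  G <- build_G(M, p = c(0.5, 0.5))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2, 2))

  ## duplicated animal: identical rows and G_ij = G_ii
  M3 <- rbind(M, a2 = M[1, ])
  rownames(M3) <- c("a", "b", "a2")
  G3 <- build_G(M3, p = c(0.5, 0.5))
  expect_equal(unname(G3["a", ]), unname(G3["a2", ]))
  expect_equal(G3["a", "a2"], G3["a", "a"])

  expect_error(build_G(matrix(1, 3, 2), p = c(0, 0)),
               class = "sge_degenerate_panel_error")
  expect_error(build_G(matrix(NA_real_, 2, 2)), class = "sge_config_error")

  ## gene-dropped genotypes with founder frequencies: G tracks A22
  cfg <- sim_config(n_founders = 40, n_generations = 2,
                    litters_per_generation = 15, litter_size_range = c(2, 4),
                    n_markers = 800, seed = 31)
  ped <- compute_inbreeding(simulate_pedigree(cfg))
  geno <- simulate_genotypes(ped, cfg)
  ids <- ped$id[ped$.si > 0L][1:60]
  G <- build_G(geno[ids, ], p = attr(geno, "founder_freq"))
  A22 <- build_A22(ped, ids)
  expect_lt(abs(mean(G[lower.tri(G)]) - mean(A22[lower.tri(A22)])), 0.05)
  expect_gt(g_a22_offdiag_correlation(G, A22), 0.5)
})

test_that("blending is a convex combination with checked weights", {
  G <- matrix(c(2, -2, -2, 2), 2, 2)
  A22 <- diag(2)
  expect_equal(blend_G(G, A22, 1, 0), G)
  expect_equal(blend_G(G, A22, 0, 1), A22)
  expect_equal(blend_G(G, A22, 0.95, 0.05),
               matrix(c(1.95, -1.9, -1.9, 1.95), 2, 2))
  expect_error(blend_G(G, diag(3)), class = "sge_shape_error")
  expect_error(blend_G(G, A22, 0.9, 0.2), class = "sge_config_error")
})

test_that("H-inverse: cancellation, dense-oracle block, omega linearity", {
  ped <- random_pedigree(30, 170, seed = 21)
  A_inv <- build_A_inverse(ped)
  ids <- sample(ped$id, 30)
  A22 <- build_A22(ped, ids)

  ## tau = omega = 1 with G_b = A22 cancels exactly
  H0 <- build_H_inverse(A_inv, A22, A22, tau = 1, omega = 1, geno_ids = ids,
                        quiet = TRUE)
  expect_lt(max(abs(as.matrix(H0) - as.matrix(A_inv))), 1e-10)

  ## no genotyped animals: A-inverse returned untouched
  expect_equal(build_H_inverse(A_inv, A22, A22, geno_ids = character(0)), A_inv)

  ## genotyped block equals the dense computation
  set.seed(77)
  Gn <- A22 + crossprod(matrix(rnorm(30 * 30, 0, 0.05), 30))
  dimnames(Gn) <- dimnames(A22)
  G_b <- blend_G(Gn, A22)
  H <- build_H_inverse(A_inv, A22, G_b, tau = 1, omega = 0.6, geno_ids = ids,
                       quiet = TRUE)
  blk <- as.matrix(H)[ids, ids] - as.matrix(A_inv)[ids, ids]
  expect_lt(max(abs(blk - (chol2inv(chol(G_b)) - 0.6 * chol2inv(chol(A22))))),
            1e-8)

  ## symmetric for every omega in the grid, and linear in omega on the block
  H1 <- build_H_inverse(A_inv, A22, G_b, 1, 0.3, ids, quiet = TRUE)
  H2 <- build_H_inverse(A_inv, A22, G_b, 1, 0.9, ids, quiet = TRUE)
  D <- as.matrix(H1 - H2)
  off <- setdiff(rownames(A_inv), ids)
  expect_equal(max(abs(D[off, ])), 0)
  expect_lt(max(abs(D[ids, ids] - (0.9 - 0.3) * chol2inv(chol(A22)))), 1e-8)
  for (om in seq(0.1, 1, 0.1)) {
    Hom <- build_H_inverse(A_inv, A22, G_b, 1, om, ids, quiet = TRUE)
    expect_true(Matrix::isSymmetric(Hom))
  }
})

test_that("relationship_set bundles blended G and the tuned H-inverse", {
  ped <- random_pedigree(20, 80, seed = 33)
  A_inv <- build_A_inverse(ped)
  ids <- sample(ped$id, 20)
  A22 <- build_A22(ped, ids)
  set.seed(34)
  G <- A22 + crossprod(matrix(rnorm(400, 0, 0.05), 20))
  dimnames(G) <- dimnames(A22)
  rs <- relationship_set(G, A22, A_inv, tau = 1, omega = 0.7)
  expect_s3_class(rs, "relationship_set")
  expect_equal(rs$G_b, blend_G(G, A22, 0.95, 0.05))
  expect_equal(attr(rs$H_inv, "omega"), 0.7)
  expect_equal(as.matrix(rs$H_inv),
               as.matrix(build_H_inverse(A_inv, A22, rs$G_b, 1, 0.7, ids,
                                         quiet = TRUE)),
               ignore_attr = TRUE)
})

test_that("off-diagonal correlation diagnostics", {
  G <- matrix(c(1, 0.2, 0.4, 0.2, 1, 0.1, 0.4, 0.1, 1), 3, 3)
  expect_equal(g_a22_offdiag_correlation(G, G), 1.0)
  expect_error(g_a22_offdiag_correlation(matrix(1, 1, 1), matrix(1, 1, 1)),
               class = "sge_undefined_error")
  A_const <- matrix(0.5, 3, 3); diag(A_const) <- 1
  G3 <- diag(3) + 0.1 * (row(diag(3)) - col(diag(3)))^2
  expect_error(g_a22_offdiag_correlation(G3, A_const),
               class = "sge_undefined_error")
})

test_that("genotype writers and readers round-trip both dialects", {
  M <- make_panel(8, 5, seed = 9)
  M[2, 3] <- NA
  fraw <- withr::local_tempfile(fileext = ".raw")
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(M, fraw, "raw")
  write_genotypes(M, ftsv, "tsv")
  expect_equal(read_genotypes_raw(fraw), M, ignore_attr = TRUE)
  expect_equal(read_genotypes_tsv(ftsv), M, ignore_attr = TRUE)
  ## mean imputation fills with 2p
  p <- allele_frequencies(M)
  Mi <- impute_mean(M)
  expect_equal(Mi[2, 3], unname(2 * p[3]))
  expect_false(anyNA(Mi))
})
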