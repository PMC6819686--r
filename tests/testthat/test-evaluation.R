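# 6-animal, 2-pen fixture with a non-trivial pedigree for MME tests
mme_fixture <- function(seed = 4) {
  ped <- compute_inbreeding(as_pedigree(data.frame(
    id   = c("s1", "d1", "s2", "d2", "o1", "o2", "o3", "o4", "o5", "o6"),
    sire = c("0", "0", "0", "0", "s1", "s1", "s2", "s2", "s1", "s2"),
    dam  = c("0", "0", "0", "0", "d1", "d1", "d2", "d2", "d2", "d1"))))
  pens <- list(pA = c("o1", "o3", "o5"), pB = c("o2", "o4", "o6"))
  phen <- toy_phenotypes(ped, pens, seed = seed, sigma = 20)
  list(ped = ped, phen = phen,
       design = build_design(phen, ped, social_model_spec()))
}

test_that("MME solutions and PEV match the dense BLUP oracle", {
  fx <- mme_fixture()
  vc <- variance_components(aD = 150, aDaS = 30, aS = 40, g = 60, l = 50,
                            e = 300)
  A <- build_A(fx$ped)
  sol <- solve_mme(fx$design, build_A_inverse(fx$ped), vc)
  orc <- oracle_blup(fx$design, A, vc)
  expect_equal(unname(sol$beta), unname(orc$beta), tolerance = 1e-8)
  expect_lt(max(abs(sol$a_D - orc$a_D[names(sol$a_D)])), 1e-8)
  expect_lt(max(abs(sol$a_S - orc$a_S[names(sol$a_S)])), 1e-8)
  expect_lt(max(abs(sol$PEV_D - orc$PEV_D[names(sol$PEV_D)])), 1e-8)
  expect_lt(max(abs(sol$PEV_S - orc$PEV_S[names(sol$PEV_S)])), 1e-8)

  ## record permutation leaves the solutions unchanged
  perm <- c(4, 2, 6, 1, 5, 3)
  design_p <- build_design(fx$phen[perm, ], fx$ped, social_model_spec())
  sol_p <- solve_mme(design_p, build_A_inverse(fx$ped), vc)
  expect_equal(sol_p$a_D, sol$a_D, tolerance = 1e-9)

  ## selected-column PEV path agrees with the full inversion
  sol_sub <- solve_mme(fx$design, build_A_inverse(fx$ped), vc,
                       pev_ids = c("o1", "s2"))
  expect_equal(sol_sub$PEV_D, sol$PEV_D[c("o1", "s2")], tolerance = 1e-9)

  ## shrinkage limit: vanishing genetic variance sends all DBV to zero
  tiny <- variance_components(aD = 1e-8, aDaS = 0, aS = 1e-8, g = 60, l = 50,
                              e = 300)
  sol0 <- solve_mme(fx$design, build_A_inverse(fx$ped), tiny, pev = FALSE)
  expect_lt(max(abs(sol0$a_D)), 1e-6)
})

test_that("TBV and CBV arithmetic", {
  expect_equal(total_breeding_value(10, 2, 6), 20)
  expect_equal(total_breeding_value(c(a = 5), c(a = 3), 1), c(a = 5))
  expect_equal(total_breeding_value(7, NULL, 4), 7)

  dbv <- c(a = 1.0, b = 0.5, c = -0.2, solo = 2)
  sbv <- c(a = 0.1, b = 0.5, c = -0.2, solo = 9)
  pens <- data.frame(animal = c("a", "b", "c", "solo"),
                     pen = c("p", "p", "p", NA))
  expect_warning(cbv <- combined_breeding_value(dbv, sbv, pens), "without a pen")
  expect_equal(cbv[["a"]], 1.0 + 0.5 - 0.2)
  expect_equal(cbv[["b"]], 0.5 + 0.1 - 0.2)
  expect_equal(cbv[["solo"]], 2)            # falls back to DBV
  ## classical model: no SBV, CBV is DBV everywhere
  expect_equal(combined_breeding_value(dbv, NULL, pens), dbv,
               ignore_attr = TRUE)
  ## every pen-of-n CBV uses exactly n - 1 mate contributions
  expect_equal(unname(cbv[c("a", "b", "c")] - dbv[c("a", "b", "c")]),
               unname(sum(sbv[c("a", "b", "c")]) - sbv[c("a", "b", "c")]))
})

test_that("derived genetic parameters reproduce printed worked examples", {
  ys_social <- variance_components(aD = 2320, aDaS = 72, aS = 23, g = 479,
                                   l = 256, e = 3739)
  ## quadratic form at n = 6: 2320 + 10*72 + 25*23 = 3615
  expect_equal(total_heritable_variance(ys_social, 6), 3615)
  expect_equal(total_heritable_variance(ys_social, 1),
               unclass(ys_social)[["aD"]])

  lr_classic <- variance_components(aD = 2078, g = 433, l = 208, e = 3039)
  expect_equal(phenotypic_variance(lr_classic, 5), 5758)
  expect_equal(round(total_heritability(lr_classic, 5), 2), 0.36)
  ys_classic <- variance_components(aD = 2255, g = 675, l = 260, e = 3712)
  expect_equal(round(total_heritability(ys_classic, 7), 2), 0.33)

  ## covariance raises total heritable variance at fixed variances
  with_cov <- total_heritable_variance(ys_social, 6)
  no_cov <- total_heritable_variance(
    variance_components(aD = 2320, aDaS = 0, aS = 23, g = 479, l = 256,
                        e = 3739), 6)
  expect_gt(with_cov, no_cov)

  ## phenotypic variance at n = 3 exceeds n = 2 by exactly sigma2_aS
  expect_equal(phenotypic_variance(ys_social, 3) -
                 phenotypic_variance(ys_social, 2),
               unclass(ys_social)[["aS"]])

  expect_equal(round(genetic_correlation(ys_social), 2), 0.31)
  expect_equal(round(genetic_correlation(
    variance_components(aD = 2878, aDaS = 11, aS = 23, e = 1)), 2), 0.04)
  expect_equal(genetic_correlation(
    variance_components(aD = 100, aDaS = 0, aS = 50, e = 1)), 0)
  expect_error(genetic_correlation(lr_classic), class = "sge_undefined_error")
})

test_that("theoretical accuracy endpoints and oracle agreement", {
  expect_equal(theoretical_accuracy(0, 0, 100), 1)
  expect_equal(theoretical_accuracy(150, 0.5, 100), 0)
  expect_warning(r <- theoretical_accuracy(200, 0, 100), "clipped")
  expect_equal(r, 0)

  fx <- mme_fixture()
  vc <- variance_components(aD = 150, aDaS = 30, aS = 40, g = 60, l = 50,
                            e = 300)
  sol <- solve_mme(fx$design, build_A_inverse(fx$ped), vc)
  orc <- oracle_blup(fx$design, build_A(fx$ped), vc)
  F <- setNames(fx$ped$F, fx$ped$id)
  ids <- names(sol$PEV_D)
  expect_equal(theoretical_accuracy(sol$PEV_D, F[ids], 150),
               sqrt(1 - orc$PEV_D[ids] / ((1 + F[ids]) * 150)),
               tolerance = 1e-8)
  expect_true(all(theoretical_accuracy(sol$PEV_D, F[ids], 150) >= 0 &
                    theoretical_accuracy(sol$PEV_D, F[ids], 150) <= 1))
})

test_that("evaluation table assembles breeding values and accuracies", {
  fx <- mme_fixture()
  vc <- variance_components(aD = 150, aDaS = 30, aS = 40, g = 60, l = 50,
                            e = 300)
  sol <- solve_mme(fx$design, build_A_inverse(fx$ped), vc)
  tab <- evaluation_table(sol, fx$ped, fx$phen[, c("animal", "pen")])
  expect_setequal(names(tab), c("animal", "DBV", "SBV", "TBV", "CBV",
                                "PEV_D", "PEV_S", "R_D", "R_S"))
  expect_equal(tab$TBV, tab$DBV + (sol$n_bar - 1) * tab$SBV)
  i <- match(fx$phen$animal[1], tab$animal)
  mates <- setdiff(fx$phen$animal[fx$phen$pen == fx$phen$pen[1]],
                   fx$phen$animal[1])
  expect_equal(tab$CBV[i], tab$DBV[i] + sum(sol$a_S[mates]))
  expect_true(all(tab$R_D >= 0 & tab$R_D <= 1))
})

test_that("scale equivariance: c^2 on components, invariant T2 and r", {
  cfg <- sim_config(n_founders = 70, n_generations = 2,
                    litters_per_generation = 24, litter_size_range = c(2, 5),
                    group_size_range = c(4, 6), n_markers = 0,
                    genotyped_fraction = 0, seed = 23)
  ds <- simulate_dataset(cfg)
  ped <- compute_inbreeding(ds$pedigree)
  phen <- group_size_filter(ds$phenotypes)
  design <- build_design(phen, ped, social_model_spec())
  A <- build_A(ped)
  f1 <- fit_reml(design, A)

  phen2 <- phen
  phen2$adg <- phen2$adg * 3
  design2 <- build_design(phen2, ped, social_model_spec())
  f2 <- fit_reml(design2, A, start = unclass(f1$components) * 9)
  expect_equal(unclass(f2$components), unclass(f1$components) * 9,
               tolerance = 1e-3)
  n <- design$n_bar
  expect_equal(total_heritability(f2$components, n),
               total_heritability(f1$components, n), tolerance = 1e-3)
  expect_equal(genetic_correlation(f2$components),
               genetic_correlation(f1$components), tolerance = 1e-3)
})

test_that("forward validation masks trailing periods and correlates CBV", {
  cfg <- sim_config(n_founders = 90, n_generations = 3,
                    litters_per_generation = 32, litter_size_range = c(2, 5),
                    group_size_range = c(4, 6), batches_per_generation = 2,
                    n_markers = 0, genotyped_fraction = 0,
                    true_components = variance_components(
                      aD = 2000, aDaS = 120, aS = 120, g = 300, l = 250,
                      e = 3300),
                    seed = 29)
  ds <- simulate_dataset(cfg)
  v <- forward_validation(ds, social_model_spec(), n_mask = 2)
  expect_s3_class(v, "sge_validation")
  expect_true(abs(v$cv_correlation) <= 1)
  expect_equal(v$n_validation, nrow(v$table))
  expect_true(all(v$table$R_D >= 0 & v$table$R_D <= 1))

  ## masking bookkeeping: with six periods of similar size, masking two
  ## holds out roughly a third of the records
  phen <- group_size_filter(ds$phenotypes)
  share <- v$n_validation / nrow(phen)
  expected_share <- sum(phen$birth_period %in%
                          utils::tail(sort(unique(phen$birth_period)), 2)) /
    nrow(phen)
  expect_equal(share, expected_share)

  ## single-period data cannot be split
  ds1 <- ds
  ds1$phenotypes$birth_period <- 1
  expect_error(forward_validation(ds1, social_model_spec()),
               class = "sge_validation_error")

  ## purely fixed-effect phenotypes leave nothing to correlate
  cfg0 <- sim_config(n_founders = 60, n_generations = 2,
                     litters_per_generation = 20, n_markers = 0,
                     genotyped_fraction = 0,
                     true_components = variance_components(
                       aD = 0, aDaS = 0, aS = 0, g = 0, l = 0, e = 0),
                     batch_effect_sd = 10, sex_effect = 20,
                     age_slope = 0, size_effect_sd = 0, seed = 31)
  ds0 <- simulate_dataset(cfg0)
  expect_error(
    forward_validation(ds0, social_model_spec(),
                       components = variance_components(
                         aD = 1e-6, aDaS = 0, aS = 1e-6, g = 1e-6, l = 1e-6,
                         e = 1e-6)),
    class = "sge_validation_error")
})
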