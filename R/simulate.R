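#' Variance components of the social animal model
#'
#' Bundles the six (co)variance parameters: direct genetic `aD`,
#' direct-social covariance `aDaS`, social genetic `aS`, pen (group) `g`,
#' birth-litter `l`, and residual `e`, all on the (g/d)^2 scale of ADG.
#' The 2x2 genetic matrix `C = [[aD, aDaS], [aDaS, aS]]` must be positive
#' semidefinite.
#'
#' @param aD,aDaS,aS,g,l,e component values.
#' @return named numeric vector of class `variance_components`.
#' @examples
#' variance_components(aD = 2320, aDaS = 72, aS = 23, g = 479, l = 256, e = 3739)
#' @export
variance_components <- function(aD, aDaS = 0, aS = 0, g = 0, l = 0, e) {
  vc <- c(aD = aD, aDaS = aDaS, aS = aS, g = g, l = l, e = e)
  if (any(vc[c("aD", "aS", "g", "l", "e")] < 0))
    stop_sge("variances must be non-negative", class = "sge_config_error")
  if (!is_psd2(genetic_C(vc)))
    stop_sge("genetic (co)variance matrix C = [[%g, %g], [%g, %g]] is not positive semidefinite",
             aD, aDaS, aDaS, aS, class = "sge_config_error")
  structure(vc, class = "variance_components")
}

genetic_C <- function(vc) {
  matrix(c(vc[["aD"]], vc[["aDaS"]], vc[["aDaS"]], vc[["aS"]]), 2, 2)
}

#' Configuration of the pen-structured population simulator
#'
#' Defines a closed nucleus-herd-like population: discrete generations of
#' litters from randomly mated parents, year-month-week-like batches,
#' single-sex pens assembled within batch, unlinked biallelic markers gene-
#' dropped through the pedigree, and ADG phenotypes generated under the
#' direct + social genetic model.
#'
#' @param n_founders number of founder animals (generation 0).
#' @param n_generations number of offspring generations (0 = founders only).
#' @param litters_per_generation litters produced each generation (capped
#'   at the number of available dams).
#' @param litter_size_range integer `c(min, max)` litter size.
#' @param group_size_range integer `c(min, max)` pen size.
#' @param batches_per_generation contemporary batches per generation.
#' @param n_markers number of unlinked biallelic markers.
#' @param founder_allele_freq_range founder allele frequencies are drawn
#'   uniformly from this open interval of (0, 1).
#' @param true_components a [variance_components()] truth.
#' @param intercept baseline ADG in g/d.
#' @param batch_effect_sd,sex_effect,size_effect_sd fixed-effect
#'   magnitudes in g/d (batch and size-class effects are drawn normal with
#'   these SDs; `sex_effect` is added to males).
#' @param age_mean,age_sd,age_slope age-at-target-weight covariate:
#'   simulated `N(age_mean, age_sd^2)` days with linear slope
#'   `age_slope` g/d per day on the centred age.
#' @param genotyped_fraction fraction of phenotyped animals genotyped.
#' @param genetic_architecture `"pedigree"` draws breeding values by the
#'   bivariate Mendelian-sampling recursion (covariance exactly `C` x `A`);
#'   `"markers"` builds them from small additive effects at the
#'   gene-dropped markers, so genomic relationships carry real signal.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders = 80,
                       n_generations = 3,
                       litters_per_generation = 30,
                       litter_size_range = c(3, 6),
                       group_size_range = c(3, 8),
                       batches_per_generation = 2,
                       n_markers = 500,
                       founder_allele_freq_range = c(0.1, 0.9),
                       true_components = variance_components(
                         aD = 2320, aDaS = 72, aS = 23,
                         g = 479, l = 256, e = 3739),
                       intercept = 790,
                       batch_effect_sd = 30,
                       sex_effect = 40,
                       size_effect_sd = 10,
                       age_mean = 155, age_sd = 10, age_slope = -2,
                       genotyped_fraction = 0.3,
                       genetic_architecture = c("pedigree", "markers"),
                       seed = 1L) {
  genetic_architecture <- match.arg(genetic_architecture)
  if (n_founders < 2 && n_generations > 0)
    stop_sge("need at least 2 founders to mate", class = "sge_config_error")
  if (n_generations < 0)
    stop_sge("n_generations must be >= 0", class = "sge_config_error")
  rng_ok <- function(r) length(r) == 2 && r[1] >= 1 && r[1] <= r[2]
  if (!rng_ok(litter_size_range) || !rng_ok(group_size_range))
    stop_sge("invalid litter or group size range", class = "sge_config_error")
  fr <- founder_allele_freq_range
  if (fr[1] <= 0 || fr[2] >= 1 || fr[1] > fr[2])
    stop_sge("founder allele frequencies must lie strictly inside (0, 1)",
             class = "sge_config_error")
  if (genotyped_fraction < 0 || genotyped_fraction > 1)
    stop_sge("genotyped_fraction must lie in [0, 1]", class = "sge_config_error")
  if (!inherits(true_components, "variance_components"))
    true_components <- do.call(variance_components, as.list(true_components))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a discrete-generation pedigree with litters and batches
#'
#' Founders form generation 0; each later generation mates sampled dams
#' (one litter each) to sires sampled with replacement, giving full-sib
#' litters and paternal half-sib families. Litters are assigned to
#' contemporary batches within their generation; `birth_period` indexes
#' batches sequentially in time.
#'
#' @param config a [sim_config()].
#' @return a [pedigree_table] with extra columns `sex`, `generation`,
#'   `litter` and `birth_period`.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  n0 <- config$n_founders
  id <- as.character(seq_len(n0))
  sex <- sample(rep(c("M", "F"), length.out = n0))
  gen <- rep(0L, n0)
  litter <- rep(NA_character_, n0)
  sire <- dam <- rep(NA_character_, n0)
  period <- rep(0L, n0)
  next_id <- n0 + 1L
  next_period <- 1L
  for (g in seq_len(config$n_generations)) {
    prev <- which(gen == g - 1L)
    sires <- id[prev][sex[prev] == "M"]
    dams <- id[prev][sex[prev] == "F"]
    if (!length(sires) || !length(dams))
      stop_sge("generation %d has no available sires or dams", g,
               class = "sge_config_error")
    n_lit <- min(config$litters_per_generation, length(dams))
    lit_dam <- sample(dams, n_lit)
    lit_sire <- sample(sires, n_lit, replace = TRUE)
    lit_batch <- sample.int(config$batches_per_generation, n_lit, replace = TRUE)
    for (k in seq_len(n_lit)) {
      ls <- sample(config$litter_size_range[1]:config$litter_size_range[2], 1L)
      ids_k <- as.character(seq.int(next_id, length.out = ls))
      next_id <- next_id + ls
      id <- c(id, ids_k)
      sire <- c(sire, rep(lit_sire[k], ls))
      dam <- c(dam, rep(lit_dam[k], ls))
      sex <- c(sex, sample(c("M", "F"), ls, replace = TRUE))
      gen <- c(gen, rep(g, ls))
      litter <- c(litter, rep(sprintf("L%d_%d", g, k), ls))
      period <- c(period, rep(next_period - 1L + lit_batch[k], ls))
    }
    next_period <- next_period + config$batches_per_generation
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam,
                         birth_period = period, sex = sex,
                         generation = gen, litter = litter,
                         stringsAsFactors = FALSE))
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotypes are drawn as independent Bernoulli(`p_m`) alleles;
#' each offspring inherits one randomly chosen allele per marker from each
#' parent. Dosages are therefore consistent in expectation with the
#' pedigree relationship matrix.
#'
#' @param ped a [pedigree_table].
#' @param config a [sim_config()].
#' @param p optional vector of founder allele frequencies overriding the
#'   uniform draw (length `n_markers`).
#' @return animals x markers dosage matrix in \{0, 1, 2\} with attribute
#'   `"founder_freq"`.
#' @export
simulate_genotypes <- function(ped, config, p = NULL) {
  set.seed(config$seed + 1L)
  m <- config$n_markers
  if (is.null(p)) {
    fr <- config$founder_allele_freq_range
    p <- stats::runif(m, fr[1], fr[2])
  }
  stopifnot(length(p) == m)
  n <- nrow(ped)
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- ped$.si[i]; d <- ped$.di[i]
    h1[i, ] <- if (s > 0L) {
      pick <- stats::runif(m) < 0.5
      ifelse(pick, h1[s, ], h2[s, ])
    } else stats::rbinom(m, 1L, p)
    h2[i, ] <- if (d > 0L) {
      pick <- stats::runif(m) < 0.5
      ifelse(pick, h1[d, ], h2[d, ])
    } else stats::rbinom(m, 1L, p)
  }
  M <- h1 + h2
  storage.mode(M) <- "double"
  dimnames(M) <- list(ped$id, sprintf("snp%d_A", seq_len(m)))
  attr(M, "founder_freq") <- p
  M
}

## bivariate breeding values by Mendelian-sampling recursion:
## a_i = 0.5 (a_s + a_d) + sqrt(w_i) U' z, with C = U'U and
## w_i = 0.5 - 0.25 (F_s + F_d) (unknown-parent variants as in mendelian_d)
draw_bv_pedigree <- function(ped, C) {
  n <- nrow(ped)
  ## symmetric PSD square root: exact zeros stay exact (chol would need
  ## jitter on singular C)
  eg <- eigen(C, symmetric = TRUE)
  U <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2) %*% t(eg$vectors)
  a <- matrix(0, n, 2)
  w <- mendelian_d(ped$.si, ped$.di, ped$F)
  Z <- matrix(stats::rnorm(2 * n), n, 2)
  for (i in seq_len(n)) {
    mu <- c(0, 0)
    if (ped$.si[i] > 0L) mu <- mu + 0.5 * a[ped$.si[i], ]
    if (ped$.di[i] > 0L) mu <- mu + 0.5 * a[ped$.di[i], ]
    a[i, ] <- mu + sqrt(w[i]) * drop(Z[i, ] %*% U)
  }
  rownames(a) <- ped$id
  a
}

## breeding values as sums of small marker effects; effect covariance is
## scaled so founder-level Var(a) targets C under HWE at founder frequencies
draw_bv_markers <- function(ped, C, genotypes) {
  p <- attr(genotypes, "founder_freq")
  denom <- sum(2 * p * (1 - p))
  eg <- eigen(C / denom, symmetric = TRUE)
  U <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2) %*% t(eg$vectors)
  alpha <- matrix(stats::rnorm(2 * length(p)), ncol = 2) %*% U
  Zc <- sweep(genotypes[ped$id, , drop = FALSE], 2, 2 * p)
  a <- Zc %*% alpha
  rownames(a) <- ped$id
  a
}

#' Simulate ADG phenotypes under the social genetic model
#'
#' Draws direct and social breeding values with covariance `C` x `A`
#' (or from marker effects, see [sim_config()]), assembles single-sex pens
#' within batch after sorting litters, and generates phenotypes
#' `y_i = fixed + a_D,i + sum of pen mates' a_S + litter + pen + residual`.
#' Founders are not phenotyped (they have no litter or pen).
#'
#' @param ped a [pedigree_table] from [simulate_pedigree()].
#' @param config a [sim_config()].
#' @param genotypes dosage matrix over all pedigree animals (required for
#'   the `"markers"` architecture and for drawing the genotyped subset).
#' @return an `sge_dataset` list: `pedigree`, `phenotypes`, `genotypes`
#'   (genotyped subset), `geno_ids`, `truth` (matrix of true `a_D`, `a_S`
#'   plus the generating components) and the `config`.
#' @export
simulate_social_phenotypes <- function(ped, config, genotypes = NULL) {
  vc <- config$true_components
  C <- genetic_C(vc)
  if (!is_psd2(C))
    stop_sge("genetic (co)variance matrix C is not positive semidefinite",
             class = "sge_config_error")
  if (is.null(ped$F)) ped <- compute_inbreeding(ped)
  set.seed(config$seed + 2L)
  a <- if (config$genetic_architecture == "markers") {
    if (is.null(genotypes))
      stop_sge("'markers' architecture needs gene-dropped genotypes",
               class = "sge_config_error")
    draw_bv_markers(ped, C, genotypes)
  } else draw_bv_pedigree(ped, C)
  aD <- setNames(a[, 1], ped$id)
  aS <- setNames(a[, 2], ped$id)

  ph <- ped[ped$.si > 0L | ped$.di > 0L, , drop = FALSE]  # non-founders
  if (nrow(ph) == 0L) {
    phen <- data.frame(animal = character(0), adg = numeric(0))
  } else {
    ## pens: within batch x sex, litters kept contiguous so full-sib
    ## counts per pen arise naturally
    cell <- interaction(ph$birth_period, ph$sex, drop = TRUE)
    pen <- rep(NA_character_, nrow(ph))
    rng <- config$group_size_range
    for (cl in levels(cell)) {
      rows <- which(cell == cl)
      rows <- rows[order(ph$litter[rows])]
      k <- 1L
      while (length(rows)) {
        size <- if (length(rows) <= rng[2]) length(rows)
                else sample(rng[1]:rng[2], 1L)
        take <- rows[seq_len(size)]
        pen[take] <- sprintf("P%s_%d", cl, k)
        rows <- rows[-seq_len(size)]
        k <- k + 1L
      }
    }
    pens <- split(seq_len(nrow(ph)), pen)
    gsize <- integer(nrow(ph))
    for (rows in pens) gsize[rows] <- length(rows)

    batches <- sort(unique(ph$birth_period))
    b_eff <- setNames(stats::rnorm(length(batches), 0, config$batch_effect_sd),
                      batches)
    sizes <- sort(unique(gsize))
    s_eff <- setNames(stats::rnorm(length(sizes), 0, config$size_effect_sd),
                      sizes)
    litters <- sort(unique(ph$litter))
    l_eff <- setNames(stats::rnorm(length(litters), 0, sqrt(vc[["l"]])), litters)
    g_eff <- setNames(stats::rnorm(length(pens), 0, sqrt(vc[["g"]])), names(pens))
    age <- stats::rnorm(nrow(ph), config$age_mean, config$age_sd)
    e <- stats::rnorm(nrow(ph), 0, sqrt(vc[["e"]]))

    social <- numeric(nrow(ph))
    for (rows in pens) {
      sA <- aS[ph$id[rows]]
      tot <- sum(sA)
      social[rows] <- tot - sA  # each record: pen total minus own aS
    }
    y <- config$intercept +
      b_eff[as.character(ph$birth_period)] +
      ifelse(ph$sex == "M", config$sex_effect, 0) +
      s_eff[as.character(gsize)] +
      config$age_slope * (age - config$age_mean) +
      aD[ph$id] + social + l_eff[ph$litter] + g_eff[pen[seq_len(nrow(ph))]] + e
    phen <- data.frame(animal = ph$id, adg = as.numeric(y),
                       batch = sprintf("b%d", ph$birth_period),
                       sex = ph$sex, pen = pen, litter = ph$litter,
                       age_days = age, group_size = gsize,
                       birth_period = ph$birth_period,
                       stringsAsFactors = FALSE)
  }

  geno_ids <- character(0); geno_sub <- NULL
  if (!is.null(genotypes) && config$genotyped_fraction > 0 && nrow(phen)) {
    n_g <- round(config$genotyped_fraction * nrow(phen))
    geno_ids <- sort(sample(phen$animal, n_g))
    geno_sub <- genotypes[geno_ids, , drop = FALSE]
    attr(geno_sub, "founder_freq") <- attr(genotypes, "founder_freq")
  }

  structure(list(pedigree = ped, phenotypes = phen, genotypes = geno_sub,
                 geno_ids = geno_ids,
                 truth = list(aD = aD, aS = aS, components = vc,
                              architecture = config$genetic_architecture),
                 config = config),
            class = "sge_dataset")
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_pedigree()],
#' [simulate_genotypes()] and [simulate_social_phenotypes()] from one
#' configuration. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an `sge_dataset` (see [simulate_social_phenotypes()]).
#' @export
simulate_dataset <- function(config) {
  ped <- simulate_pedigree(config)
  geno <- if (config$n_markers > 0) simulate_genotypes(ped, config) else NULL
  simulate_social_phenotypes(ped, config, geno)
}

#' Write a simulated dataset to disk
#'
#' Emits pedigree.csv, phenotypes.csv, genotypes.raw, genotypes.tsv and
#' truth CSVs (true breeding values and generating components) into `dir`.
#'
#' @param dataset an `sge_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(dataset$pedigree, file.path(dir, "pedigree.csv"))
  data.table::fwrite(dataset$phenotypes, file.path(dir, "phenotypes.csv"))
  if (!is.null(dataset$genotypes)) {
    write_genotypes(dataset$genotypes, file.path(dir, "genotypes.raw"), "raw")
    write_genotypes(dataset$genotypes, file.path(dir, "genotypes.tsv"), "tsv")
  }
  tr <- data.frame(animal = names(dataset$truth$aD),
                   true_aD = unname(dataset$truth$aD),
                   true_aS = unname(dataset$truth$aS))
  data.table::fwrite(tr, file.path(dir, "truth_breeding_values.csv"))
  vc <- dataset$truth$components
  data.table::fwrite(data.frame(component = names(unclass(vc)),
                                value = as.numeric(vc)),
                     file.path(dir, "truth_components.csv"))
  invisible(dir)
}
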