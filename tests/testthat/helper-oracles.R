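# Independent oracles, deliberately implemented with different algorithms
# than the package (recursive kinship vs tabular loop; dense joint-MME
# inversion vs sparse solve) so that agreement is a two-route check.

# additive relationship by the Emik-Terrill recursion with memoisation
oracle_A <- function(ped) {
  n <- nrow(ped)
  si <- ped$.si; di <- ped$.di
  memo <- new.env(hash = TRUE, parent = emptyenv())
  a <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      1 + 0.5 * a(si[i], di[i])
    } else {
      0.5 * (a(i, si[j]) + a(i, di[j]))   # j is the younger (larger index)
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- a(i, j)
  A
}

# random valid pedigree: each non-founder picks two earlier animals as
# parents (possibly related), in litters of full sibs
random_pedigree <- function(n_founders, n_offspring, seed, litter_max = 4) {
  set.seed(seed)
  id <- as.character(seq_len(n_founders))
  sire <- dam <- rep(NA_character_, n_founders)
  next_id <- n_founders + 1L
  while (next_id <= n_founders + n_offspring) {
    pool <- seq_len(next_id - 1L)
    par <- sample(pool, 2L)
    ls <- min(sample(litter_max, 1L), n_founders + n_offspring - next_id + 1L)
    for (k in seq_len(ls)) {
      id <- c(id, as.character(next_id))
      sire <- c(sire, as.character(par[1]))
      dam <- c(dam, as.character(par[2]))
      next_id <- next_id + 1L
    }
  }
  compute_inbreeding(as_pedigree(
    data.frame(id = id, sire = ifelse(is.na(sire), "0", sire),
               dam = ifelse(is.na(dam), "0", dam))))
}

# dense GLS/BLUP oracle: joint mixed-model equations assembled with base
# matrices only, solved and inverted densely
oracle_blup <- function(design, K, components) {
  vc <- unclass(components)
  include_social <- !is.null(design$Z_S)
  X <- as.matrix(design$X)
  ZD <- as.matrix(design$Z_D)
  W <- as.matrix(design$W); V <- as.matrix(design$V)
  y <- design$y
  Zu <- if (include_social) cbind(ZD, as.matrix(design$Z_S)) else ZD
  Gu <- if (include_social) {
    C <- matrix(c(vc["aD"], vc["aDaS"], vc["aDaS"], vc["aS"]), 2, 2)
    kronecker(C, K)
  } else vc[["aD"]] * K
  Zall <- cbind(Zu, W, V)
  Gall_inv <- as.matrix(Matrix::bdiag(solve(Gu),
                                      diag(ncol(W)) / vc[["l"]],
                                      diag(ncol(V)) / vc[["g"]]))
  se <- vc[["e"]]
  M <- rbind(cbind(crossprod(X) / se, crossprod(X, Zall) / se),
             cbind(crossprod(Zall, X) / se,
                   crossprod(Zall) / se + Gall_inv))
  rhs <- c(crossprod(X, y), crossprod(Zall, y)) / se
  Minv <- solve(M)
  sol <- drop(Minv %*% rhs)
  p <- ncol(X); nq <- nrow(K)
  list(beta = sol[seq_len(p)],
       a_D = setNames(sol[p + seq_len(nq)], rownames(K)),
       a_S = if (include_social) setNames(sol[p + nq + seq_len(nq)], rownames(K)) else NULL,
       PEV_D = setNames(diag(Minv)[p + seq_len(nq)], rownames(K)),
       PEV_S = if (include_social)
         setNames(diag(Minv)[p + nq + seq_len(nq)], rownames(K)) else NULL)
}

# small pen-structured phenotype table on an explicit pedigree
toy_phenotypes <- function(ped, pens, seed = 1, sigma = 1) {
  set.seed(seed)
  animals <- unlist(pens)
  data.frame(animal = animals,
             adg = rnorm(length(animals), 100, sigma),
             batch = "b1",
             sex = "M",
             pen = rep(names(pens), lengths(pens)),
             litter = paste0("L", match(animals, ped$id) %% 3),
             age_days = rnorm(length(animals), 155, 5),
             birth_period = 1,
             stringsAsFactors = FALSE)
}
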