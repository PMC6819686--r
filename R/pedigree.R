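#' Pedigree tables
#'
#' A pedigree table is a data frame with one row per animal, topologically
#' ordered so that parents always precede offspring. Columns are `id` (the
#' original animal label, as character), `sire` and `dam` (labels, `NA` when
#' unknown), and optionally `birth_period` (integer time index used by the
#' forward-validation split), `sex` and `litter`. Internal integer codes
#' `.i`, `.si`, `.di` (row indices, 0 = unknown parent) are added for matrix
#' construction, and [compute_inbreeding()] adds the column `F`.
#'
#' @name pedigree_table
NULL

#' Validate and order a pedigree
#'
#' Checks a raw animal/sire/dam table, inserts parents that appear only in
#' the sire or dam column as founders (with a warning), reorders rows so
#' that parents precede offspring, and attaches integer index columns used
#' by the relationship-matrix builders.
#'
#' @param df data frame whose first three columns are animal, sire and dam
#'   labels; unknown parents coded `0`, `""` or `NA`. An optional
#'   `birth_period` column (and any further columns such as `sex`, `litter`)
#'   is carried through.
#' @return A `pedigree_table` data frame (see [pedigree_table]).
#' @examples
#' ped <- as_pedigree(data.frame(id = c(3, 1, 2), sire = c(1, 0, 0),
#'                               dam = c(2, 0, 0)))
#' ped$id
#' @export
as_pedigree <- function(df) {
  if (ncol(df) < 3L)
    stop_sge("pedigree needs at least 3 columns (animal, sire, dam)", class = "sge_pedigree_error")
  df <- as.data.frame(df)
  extra <- df[, -(1:3), drop = FALSE]
  id   <- as.character(df[[1]])
  sire <- as.character(df[[2]])
  dam  <- as.character(df[[3]])
  unk <- function(x) is.na(x) | x == "0" | x == ""
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  if (anyDuplicated(id))
    stop_sge("duplicate animal id(s): %s", paste(unique(id[duplicated(id)]), collapse = ", "),
             class = "sge_pedigree_error")
  if (any(id == sire, na.rm = TRUE) || any(id == dam, na.rm = TRUE)) {
    bad <- id[(!is.na(sire) & id == sire) | (!is.na(dam) & id == dam)]
    stop_sge("pedigree cycle: animal(s) %s recorded as own parent",
             paste(bad, collapse = ", "), class = "sge_pedigree_error")
  }
  ## parents not listed as animals become founders
  missing_par <- setdiff(c(sire, dam), c(id, NA_character_))
  if (length(missing_par)) {
    warning(sprintf("%d parent(s) not listed as animals; inserted as founders: %s",
                    length(missing_par), paste(utils::head(missing_par, 5), collapse = ", ")))
    id <- c(missing_par, id)
    sire <- c(rep(NA_character_, length(missing_par)), sire)
    dam <- c(rep(NA_character_, length(missing_par)), dam)
    if (ncol(extra)) {
      pad <- extra[rep(NA_integer_, length(missing_par)), , drop = FALSE]
      extra <- rbind(pad, extra)
    }
  }
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  ## Kahn topological order over parent -> offspring edges
  indeg <- (si > 0L) + (di > 0L)
  children <- split(c(idx[si > 0L], idx[di > 0L]), c(si[si > 0L], di[di > 0L]))
  queue <- idx[indeg == 0L]
  ord <- integer(0)
  indeg_work <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (w in children[[as.character(v)]]) {
      indeg_work[w] <- indeg_work[w] - 1L
      if (indeg_work[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) < n) {
    cyc <- id[setdiff(idx, ord)]
    stop_sge("pedigree cycle involving: %s", paste(utils::head(cyc, 10), collapse = ", "),
             class = "sge_pedigree_error")
  }
  out <- data.frame(id = id[ord],
                    sire = sire[ord],
                    dam = dam[ord],
                    stringsAsFactors = FALSE)
  if (ncol(extra)) out <- cbind(out, extra[ord, , drop = FALSE])
  rownames(out) <- NULL
  new_idx <- seq_len(n); names(new_idx) <- out$id
  out$.i <- new_idx
  out$.si <- ifelse(is.na(out$sire), 0L, new_idx[out$sire])
  out$.di <- ifelse(is.na(out$dam), 0L, new_idx[out$dam])
  class(out) <- c("pedigree_table", "data.frame")
  out
}

#' Read a pedigree CSV
#'
#' @param path CSV file with columns animal, sire, dam and optionally
#'   birth_period; unknown parents coded 0 or empty.
#' @return A validated, ordered [pedigree_table].
#' @export
read_pedigree <- function(path) {
  df <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(character = 1:3))
  names(df)[1:3] <- c("id", "sire", "dam")
  as_pedigree(df)
}

#' Write a pedigree CSV (0 = unknown parent)
#' @param ped a [pedigree_table]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(animal = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam))
  if (!is.null(ped$birth_period)) out$birth_period <- ped$birth_period
  data.table::fwrite(out, path)
  invisible(path)
}

## Mendelian-sampling variance d_i given parental inbreeding; unknown
## parents are treated as unrelated non-inbred founders.
mendelian_d <- function(si, di, Fvec) {
  Fs <- ifelse(si > 0L, Fvec[pmax(si, 1L)], NA_real_)
  Fd <- ifelse(di > 0L, Fvec[pmax(di, 1L)], NA_real_)
  d <- ifelse(si > 0L & di > 0L, 0.5 - 0.25 * (Fs + Fd),
       ifelse(si > 0L, 0.75 - 0.25 * Fs,
       ifelse(di > 0L, 0.75 - 0.25 * Fd, 1)))
  d
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes the pedigree inbreeding coefficient F for every animal, i.e.
#' `F_i = A_ii - 1` with A the numerator relationship matrix, without
#' forming A. Animals with one or both parents unknown get `F = 0`.
#'
#' @param ped a [pedigree_table]
#' @return the pedigree with an added numeric column `F`.
#' @export
compute_inbreeding <- function(ped) {
  n <- nrow(ped)
  si <- ped$.si; di <- ped$.di
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    D[i] <- mendelian_d(si[i], di[i], F)
    if (si[i] == 0L || di[i] == 0L) { F[i] <- 0; next }
    ## a_ii = sum over ancestors j (incl. i) of L_j^2 D_j, walking from i down
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * D[j]
      if (si[j] > 0L) L[si[j]] <- L[si[j]] + 0.5 * L[j]
      if (di[j] > 0L) L[di[j]] <- L[di[j]] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  ped$F <- F
  ped
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Builds A by the recurrence `a_ij = 0.5 (a_{i,s(j)} + a_{i,d(j)})` for
#' `i < j` and `a_ii = 1 + 0.5 a_{s(i),d(i)}`. Intended for desk-scale
#' pedigrees; [build_A22()] restricts the computation to an ancestor
#' closure for larger ones.
#'
#' @param ped a [pedigree_table]
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  n <- nrow(ped)
  si <- ped$.si; di <- ped$.di
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      i <- seq_len(j - 1L)
      row <- numeric(j - 1L)
      if (s > 0L) row <- row + 0.5 * A[i, s]
      if (d > 0L) row <- row + 0.5 * A[i, d]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: each animal contributes
#' `1/d_i` at (i,i), `-0.5/d_i` at (i,parent) and `0.25/d_i` at
#' (parent,parent') for its known parents, with Mendelian-sampling
#' variance `d_i = 0.5 - 0.25 (F_s + F_d)` (0.75 - 0.25 F with one known
#' parent, 1 with none).
#'
#' @param ped a [pedigree_table]; inbreeding is computed if absent.
#' @return sparse symmetric `Matrix::dsCMatrix` with ids as dimnames.
#' @export
build_A_inverse <- function(ped) {
  if (is.null(ped$F)) ped <- compute_inbreeding(ped)
  n <- nrow(ped)
  si <- ped$.si; di <- ped$.di
  d <- mendelian_d(si, di, ped$F)
  if (any(d <= 0))
    stop_sge("non-positive Mendelian-sampling variance for animal(s) %s",
             paste(ped$id[d <= 0], collapse = ", "), class = "sge_pedigree_error")
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  alpha <- 1 / d
  idx <- seq_len(n)
  add(idx, idx, alpha)
  has_s <- si > 0L; has_d <- di > 0L
  add(idx[has_s], si[has_s], -0.5 * alpha[has_s])
  add(si[has_s], idx[has_s], -0.5 * alpha[has_s])
  add(idx[has_d], di[has_d], -0.5 * alpha[has_d])
  add(di[has_d], idx[has_d], -0.5 * alpha[has_d])
  add(si[has_s], si[has_s], 0.25 * alpha[has_s])
  add(di[has_d], di[has_d], 0.25 * alpha[has_d])
  both <- has_s & has_d
  add(si[both], di[both], 0.25 * alpha[both])
  add(di[both], si[both], 0.25 * alpha[both])
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(M)
}

## ancestor closure of a set of row indices
ancestor_closure <- function(ped, idx) {
  keep <- logical(nrow(ped))
  keep[idx] <- TRUE
  ## parents precede offspring, so one backward sweep closes the set
  for (j in nrow(ped):1) {
    if (keep[j]) {
      if (ped$.si[j] > 0L) keep[ped$.si[j]] <- TRUE
      if (ped$.di[j] > 0L) keep[ped$.di[j]] <- TRUE
    }
  }
  which(keep)
}

#' Pedigree relationship submatrix for the genotyped animals
#'
#' Computes `A22`, the block of the numerator relationship matrix for a
#' subset of (genotyped) animals, running the tabular method only on the
#' ancestor closure of that subset.
#'
#' @param ped a [pedigree_table]
#' @param ids character vector of genotyped animal ids.
#' @return dense symmetric matrix in the order of `ids`.
#' @export
build_A22 <- function(ped, ids) {
  pos <- match(as.character(ids), ped$id)
  if (anyNA(pos))
    stop_sge("animal id(s) not in pedigree: %s",
             paste(ids[is.na(pos)], collapse = ", "), class = "sge_lookup_error")
  keep <- ancestor_closure(ped, pos)
  sub <- ped[keep, , drop = FALSE]
  remap <- integer(nrow(ped)); remap[keep] <- seq_along(keep)
  sub$.i <- seq_len(nrow(sub))
  ## index via pmax: a 0 inside a subscript vector would drop elements
  sub$.si <- ifelse(sub$.si > 0L, remap[pmax(sub$.si, 1L)], 0L)
  sub$.di <- ifelse(sub$.di > 0L, remap[pmax(sub$.di, 1L)], 0L)
  A <- build_A(sub)
  A[match(as.character(ids), sub$id), match(as.character(ids), sub$id), drop = FALSE]
}

#' Export a symmetric matrix as coordinate-format text
#'
#' Writes the lower triangle (including diagonal) as `i j value` rows with
#' 1-based indices, the interchange format of pedigree/BLUP tooling.
#'
#' @param M matrix (dense or sparse).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_relationship_triplets <- function(M, path) {
  M <- as(as(as(M, "dMatrix"), "generalMatrix"), "TsparseMatrix")
  keep <- M@i >= M@j
  df <- data.frame(i = M@i[keep] + 1L, j = M@j[keep] + 1L, value = M@x[keep])
  df <- df[order(df$i, df$j), ]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
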