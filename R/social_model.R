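#' Specify a social-genetic-effects model variant
#'
#' Describes which variance structure and relationship source a fit uses:
#' the classical animal model (direct genetic effect only) or the social
#' model with bivariate direct/social genetic effects, either with
#' pedigree relationships or with the tuned single-step H matrix. Litter
#' and pen (group) are always fitted as iid random effects; batch, sex and
#' group-size class are fixed effects and age at target weight a
#' covariate.
#'
#' @param include_social fit the social genetic effect (bivariate genetic
#'   structure) or the classical direct-only model.
#' @param relationship `"pedigree"` or `"single-step"`.
#' @param tau,omega single-step scaling constants (used when
#'   `relationship = "single-step"`).
#' @param dilution apply the group-size dilution covariate
#'   `d_g = sqrt((n_bar - 1)/(n_g - 1))` to social incidences; with
#'   `FALSE` all social incidences are 1.
#' @param keep_singleton_pens keep records of animals housed alone (their
#'   social incidence row is all zero); if `FALSE` such records are
#'   dropped by [build_design()].
#' @return a `social_model_spec` list.
#' @export
social_model_spec <- function(include_social = TRUE,
                              relationship = c("pedigree", "single-step"),
                              tau = 1, omega = 1, dilution = TRUE,
                              keep_singleton_pens = TRUE) {
  relationship <- match.arg(relationship)
  if (omega <= 0 || omega > 1)
    stop_sge("omega must lie in (0, 1]", class = "sge_config_error")
  structure(list(include_social = include_social, relationship = relationship,
                 tau = tau, omega = omega, dilution = dilution,
                 keep_singleton_pens = keep_singleton_pens),
            class = "social_model_spec")
}

model_label <- function(spec) {
  if (spec$relationship == "single-step")
    sprintf("omega_%.1f", spec$omega)
  else if (spec$include_social) "PED_social" else "PED_classic"
}

#' Dilution covariate for social incidences
#'
#' `d_g = sqrt((n_bar - 1)/(n_g - 1))` equalises the heritable social
#' variance contributed by pens of different sizes. For a pen of 1 there
#' are no pen mates and `d = 0`; with dilution disabled `d = 1`.
#'
#' @param n_g pen size(s) of the record.
#' @param n_bar average pen size over the analysed records.
#' @param enabled logical; `FALSE` returns 1 (0 for pens of 1).
#' @return numeric vector of dilution factors.
#' @export
dilution_factor <- function(n_g, n_bar, enabled = TRUE) {
  if (any(n_g < 1))
    stop_sge("group size must be >= 1", class = "sge_config_error")
  if (enabled && n_bar <= 1)
    stop_sge("average group size must exceed 1 when dilution is enabled",
             class = "sge_config_error")
  d <- if (enabled) sqrt((n_bar - 1) / pmax(n_g - 1, 1)) else rep(1, length(n_g))
  d[n_g == 1] <- 0
  d
}

#' Drop records in rare pen-size classes
#'
#' Removes all records belonging to pens whose size class accounts for at
#' most `min_frequency` of the records, the usual pre-filter before
#' fitting group-size as a fixed class.
#'
#' @param phen phenotype data frame with a `pen` column (pen sizes are
#'   recomputed from pen membership).
#' @param min_frequency retention threshold on the record share of a size
#'   class (default 0.10: classes with > 10% of records are kept).
#' @return the filtered data frame, with a refreshed `group_size` column.
#' @export
group_size_filter <- function(phen, min_frequency = 0.10) {
  pen_size <- table(phen$pen)
  gs <- as.integer(pen_size[as.character(phen$pen)])
  share <- table(gs) / length(gs)
  keep_sizes <- as.integer(names(share)[share > min_frequency])
  out <- phen[gs %in% keep_sizes, , drop = FALSE]
  if (nrow(out) == 0L)
    stop_sge("group-size filter removed every record", class = "sge_empty_data_error")
  out$group_size <- gs[gs %in% keep_sizes]
  rownames(out) <- NULL
  out
}

#' Build fixed and random design matrices
#'
#' Constructs the incidence matrices of the social animal model: `X`
#' (intercept, reference-coded batch, sex and group-size classes, centred
#' age covariate), `Z_D` (records x pedigree animals, one 1 per row),
#' `Z_S` (the dilution factor `d_g` at each pen mate of the record's
#' animal, zero on the animal itself), `W` (litters) and `V` (pens).
#' Aliased fixed-effect columns are dropped so `X` has full column rank.
#'
#' @param phen phenotype data frame with columns `animal`, `adg`, `batch`,
#'   `sex`, `pen`, `litter`, `age_days` (and optionally `group_size`).
#' @param ped a [pedigree_table] containing every phenotyped animal.
#' @param spec a [social_model_spec()].
#' @return a `design_matrices` list: `X`, `Z_D`, `Z_S` (or `NULL`), `W`,
#'   `V`, `y`, `n_bar`, `group_size`, level keys, and the analysed
#'   phenotype table.
#' @export
build_design <- function(phen, ped, spec = social_model_spec()) {
  phen <- as.data.frame(phen)
  phen$animal <- as.character(phen$animal)
  apos <- match(phen$animal, ped$id)
  if (anyNA(apos))
    stop_sge("phenotyped animal(s) absent from pedigree: %s",
             paste(utils::head(phen$animal[is.na(apos)], 5), collapse = ", "),
             class = "sge_linkage_error")
  batch_by_pen <- tapply(as.character(phen$batch), phen$pen,
                         function(b) length(unique(b)))
  if (any(batch_by_pen > 1))
    stop_sge("pen(s) spanning more than one batch: %s",
             paste(names(batch_by_pen)[batch_by_pen > 1], collapse = ", "),
             class = "sge_validation_error")
  pen_size <- table(phen$pen)
  phen$group_size <- as.integer(pen_size[as.character(phen$pen)])
  if (!spec$keep_singleton_pens) {
    phen <- phen[phen$group_size > 1, , drop = FALSE]
    apos <- match(phen$animal, ped$id)
  }
  n <- nrow(phen)
  n_ped <- nrow(ped)
  n_bar <- mean(phen$group_size)

  ## fixed effects: reference-level coding with intercept; single-level
  ## factors and aliased columns pruned by QR
  fdat <- data.frame(batch = factor(phen$batch), sex = factor(phen$sex),
                     size = factor(phen$group_size),
                     age = phen$age_days - mean(phen$age_days))
  keep_terms <- c(vapply(fdat[c("batch", "sex", "size")], nlevels, 1L) > 1L, TRUE)
  form <- stats::as.formula(paste("~", paste(c("batch", "sex", "size", "age")[keep_terms],
                                             collapse = " + ")))
  X <- stats::model.matrix(form, fdat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]

  Z_D <- Matrix::sparseMatrix(i = seq_len(n), j = apos, x = 1,
                              dims = c(n, n_ped), dimnames = list(NULL, ped$id))
  litter_lev <- sort(unique(as.character(phen$litter)))
  W <- Matrix::sparseMatrix(i = seq_len(n),
                            j = match(as.character(phen$litter), litter_lev), x = 1,
                            dims = c(n, length(litter_lev)),
                            dimnames = list(NULL, litter_lev))
  pen_lev <- sort(unique(as.character(phen$pen)))
  V <- Matrix::sparseMatrix(i = seq_len(n),
                            j = match(as.character(phen$pen), pen_lev), x = 1,
                            dims = c(n, length(pen_lev)),
                            dimnames = list(NULL, pen_lev))

  Z_S <- NULL
  if (spec$include_social) {
    d <- dilution_factor(phen$group_size, n_bar, enabled = spec$dilution)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    rows_by_pen <- split(seq_len(n), as.character(phen$pen))
    for (rows in rows_by_pen) {
      if (length(rows) < 2L) next
      mates <- apos[rows]
      for (r in seq_along(rows)) {
        ii <- c(ii, rep(rows[r], length(rows) - 1L))
        jj <- c(jj, mates[-r])
        xx <- c(xx, rep(d[rows[r]], length(rows) - 1L))
      }
    }
    Z_S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n_ped),
                                dimnames = list(NULL, ped$id))
  }

  structure(list(X = X, Z_D = Z_D, Z_S = Z_S, W = W, V = V,
                 y = phen$adg, n_bar = n_bar, group_size = phen$group_size,
                 animal = phen$animal, litter_levels = litter_lev,
                 pen_levels = pen_lev, phen = phen, spec = spec),
            class = "design_matrices")
}
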