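#' Basal area of a single stem
#'
#' Circular cross-section at breast height, in square metres, from DBH in
#' centimetres: `pi * (dbh / 200)^2`.
#'
#' @param dbh diameter(s) at breast height, cm; must be positive.
#' @return basal area(s) in m^2.
#' @examples
#' basal_area(20)   # 0.0314 m^2
#' @export
basal_area <- function(dbh) {
  if (!is.numeric(dbh) || any(!is.finite(dbh)) || any(dbh <= 0))
    stop("`dbh` must be positive and finite (cm)", call. = FALSE)
  pi * (dbh / 200)^2
}

#' Importance-value components for one stage
#'
#' Computes, per species: density D (trees/ha), frequency F (proportion of
#' quadrats occupied), dominance d (summed stem basal area, m^2/ha), their
#' relative forms RD, RF, Rd (each species' share of the column total, in
#' percent) and the importance value IV = (RD + RF + Rd) / 3. Each stage
#' table self-normalises, so RD, RF, Rd and IV each sum to 100 within a
#' stage.
#'
#' The relative forms default to the self-normalising ratios
#' `D_i / sum(D)`, `F_i / sum(F)`, `d_i / sum(d)` (the only forms under
#' which the shares sum to 100 percent). `denominators = "printed"`
#' reproduces a variant sometimes printed in the field literature (RD as
#' individuals over total density, RF as frequency over the number of
#' species); it does not normalise and is provided for comparison only.
#'
#' @param stemmap a `stem_map`.
#' @param grid a `quadrat_grid`; default built from the stem map geometry.
#' @param stage_filter optional stage label.
#' @param denominators `"standard"` or `"printed"` (see Details).
#' @return data frame with one row per species: `species`, `n`, `density`,
#'   `relative_density`, `frequency`, `relative_frequency`, `dominance`,
#'   `relative_dominance`, `importance_value`; sorted by density
#'   descending. Zero rows (with a warning) if no tree survives the filter.
#' @export
iv_components <- function(stemmap, grid = NULL, stage_filter = NULL,
                          denominators = c("standard", "printed")) {
  denominators <- match.arg(denominators)
  stopifnot(inherits(stemmap, "stem_map"))
  g <- geometry(stemmap)
  if (is.null(grid)) grid <- build_quadrat_grid(g)
  trees <- stemmap
  if (!is.null(stage_filter)) {
    stage_filter <- match.arg(stage_filter, levels(stemmap$stage))
    trees <- trees[trees$stage == stage_filter, , drop = FALSE]
  }
  cols <- c("species", "n", "density", "relative_density", "frequency",
            "relative_frequency", "dominance", "relative_dominance",
            "importance_value")
  if (!nrow(trees)) {
    warning("no trees", if (!is.null(stage_filter))
      paste0(" in stage ", stage_filter), "; empty IV table", call. = FALSE)
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                         cols))
    out$species <- character(0)
    return(out)
  }
  area_ha <- g$width * g$height / 1e4
  sp <- sort(unique(trees$species))
  n_i <- as.numeric(table(factor(trees$species, levels = sp)))
  cell <- locate_quadrat(trees$x, trees$y, grid)$cell
  occ <- table(factor(trees$species, levels = sp),
               factor(cell, levels = seq_len(grid$N))) > 0
  F_i <- rowSums(occ) / grid$N
  d_i <- as.numeric(tapply(basal_area(trees$dbh),
                           factor(trees$species, levels = sp),
                           sum)) / area_ha
  D_i <- n_i / area_ha
  if (denominators == "standard") {
    RD <- 100 * D_i / sum(D_i)
    RF <- 100 * F_i / sum(F_i)
    Rd <- 100 * d_i / sum(d_i)
  } else {
    RD <- 100 * n_i / sum(D_i)       # individuals over total density
    RF <- 100 * F_i / length(sp)     # frequency over number of species
    Rd <- 100 * d_i / sum(d_i)
  }
  out <- data.frame(species = sp, n = n_i, density = D_i,
                    relative_density = RD, frequency = F_i,
                    relative_frequency = RF, dominance = d_i,
                    relative_dominance = Rd,
                    importance_value = (RD + RF + Rd) / 3,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$density, out$species), ]
  rownames(out) <- NULL
  out
}

#' Importance values by development stage
#'
#' One IV table per development stage plus the pooled table over all trees,
#' with species ordered by pooled density descending.
#'
#' @inheritParams iv_components
#' @return named list of IV tables: one per stage level plus `"all"`.
#' @export
iv_table_by_stage <- function(stemmap, grid = NULL,
                              denominators = c("standard", "printed")) {
  denominators <- match.arg(denominators)
  stopifnot(inherits(stemmap, "stem_map"))
  if (is.null(grid)) grid <- build_quadrat_grid(geometry(stemmap))
  stages <- levels(stemmap$stage)
  out <- lapply(stages, function(st)
    suppressWarnings(iv_components(stemmap, grid, stage_filter = st,
                                   denominators = denominators)))
  names(out) <- stages
  out$all <- iv_components(stemmap, grid, denominators = denominators)
  pooled_order <- out$all$species
  out <- lapply(out, function(tab) {
    tab[order(match(tab$species, pooled_order)), , drop = FALSE]
  })
  lapply(out, function(tab) { rownames(tab) <- NULL; tab })
}

#' Select the dominant species by importance value
#'
#' Top-`k` species from an IV table, ranked by importance value with ties
#' broken by density and then by species label. The cumulative share of
#' stand density covered by the selection is attached, mirroring the usual
#' statement that the chosen dominants account for a given fraction of the
#' overstory.
#'
#' @param iv_table an IV table from [iv_components()].
#' @param k number of species to keep (`>= 2`, `<=` species count).
#' @return character vector of `k` species labels, IV-descending, with
#'   attribute `density_share` (fraction of total density covered).
#' @export
select_dominant <- function(iv_table, k = 11) {
  if (k < 2) stop("pairwise analysis needs at least 2 species (k >= 2)",
                  call. = FALSE)
  if (k > nrow(iv_table))
    stop("k = ", k, " exceeds the ", nrow(iv_table),
         " species in the table", call. = FALSE)
  ord <- order(-iv_table$importance_value, -iv_table$density,
               iv_table$species)
  sel <- iv_table[ord[seq_len(k)], ]
  structure(sel$species,
            density_share = sum(sel$density) / sum(iv_table$density))
}
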