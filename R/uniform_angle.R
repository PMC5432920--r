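#' Reduced window for edge correction
#'
#' Insets the plot rectangle by the buffer width on all four sides. Only
#' trees inside the reduced window serve as reference trees for the
#' uniform angle index; trees in the buffer strip are used only as
#' neighbours, so every reference tree's four nearest neighbours are
#' guaranteed to be genuine (not censored by the plot edge).
#'
#' @param geom a [plot_geometry()].
#' @return named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @examples
#' reduced_window(plot_geometry(140, 70, 14, 5))  # 130 x 60 m window
#' @export
reduced_window <- function(geom) {
  stopifnot(inherits(geom, "plot_geometry"))
  b <- geom$buffer_width
  c(xmin = b, xmax = geom$width - b, ymin = b, ymax = geom$height - b)
}

in_window <- function(x, y, win) {
  x >= win[["xmin"]] & x <= win[["xmax"]] &
  y >= win[["ymin"]] & y <= win[["ymax"]]
}

#' Four nearest neighbours of a reference tree
#'
#' Euclidean nearest neighbours over all trees in the stem map (reduced
#' window and buffer alike), excluding the reference itself. Distance ties
#' are broken by tree id (lexicographically smaller id first) so results
#' are reproducible; coincident coordinates are a data error.
#'
#' @param ref_id tree id of the reference tree.
#' @param stemmap a `stem_map` with at least 5 trees.
#' @param k number of neighbours (4 for the uniform angle index).
#' @return list with `reference` (the id), `neighbor_ids`, `distances`
#'   (non-decreasing) and `azimuths` (degrees clockwise from north,
#'   in `[0, 360)`).
#' @export
four_nearest <- function(ref_id, stemmap, k = 4) {
  stopifnot(inherits(stemmap, "stem_map"))
  i <- match(as.character(ref_id), stemmap$tree_id)
  if (is.na(i)) stop("unknown tree id: ", ref_id, call. = FALSE)
  if (nrow(stemmap) < k + 1)
    stop("need at least ", k + 1, " trees for ", k, " neighbours",
         call. = FALSE)
  dx <- stemmap$x - stemmap$x[i]
  dy <- stemmap$y - stemmap$y[i]
  d <- sqrt(dx^2 + dy^2)
  coincident <- which(d == 0)
  if (length(coincident) > 1)
    stop("coincident coordinates: trees ",
         paste(stemmap$tree_id[coincident], collapse = ", "), call. = FALSE)
  ord <- order(d, stemmap$tree_id)
  nb <- setdiff(ord, i)[seq_len(k)]
  az <- (atan2(dx[nb], dy[nb]) * 180 / pi) %% 360
  list(reference = stemmap$tree_id[i],
       neighbor_ids = stemmap$tree_id[nb],
       distances = d[nb], azimuths = az)
}

#' Circular gaps between neighbour directions
#'
#' Sorts the azimuths and returns the gaps between consecutive directions
#' plus the wrap-around gap; the gaps always sum to 360 degrees.
#'
#' @param azimuths directions in degrees.
#' @return numeric vector of gaps (same length as `azimuths`), summing to
#'   360.
#' @export
adjacent_gaps <- function(azimuths) {
  az <- sort(azimuths %% 360)
  diff(c(az, az[1] + 360))
}

#' Uniform angle index of one neighbourhood
#'
#' For the four azimuthal gaps between a tree's neighbours, the index
#' `W_i` is the fraction of the four angles between adjacent neighbour
#' directions that are strictly smaller than the standard angle `alpha0`
#' (72 degrees, i.e. 360/(k+1) for k = 4). The angle between two adjacent
#' directions is always the smaller of the two arcs (at most 180 degrees),
#' so a tight one-sided fan of neighbours — all four gaps small on one
#' side, one large reflex gap — scores `W_i = 1`. `W_i` takes the five
#' values 0, 0.25, 0.5, 0.75, 1: a regular (even) spread of neighbours
#' gives 0, a clumped one-sided spread gives 1.
#'
#' @param gaps the four circular gaps from [adjacent_gaps()] (must sum to
#'   360).
#' @param alpha0 standard angle, degrees.
#' @return `W_i`, one of 0, 0.25, 0.5, 0.75, 1.
#' @examples
#' w_index(c(90, 90, 90, 90))    # 0: perfectly regular
#' w_index(c(10, 10, 10, 330))   # 1: all neighbours on one side
#' @export
w_index <- function(gaps, alpha0 = 72) {
  if (abs(sum(gaps) - 360) > 1e-6)
    stop("gaps must sum to 360 degrees", call. = FALSE)
  angles <- pmin(gaps, 360 - gaps)  # angle between adjacent directions
  sum(angles < alpha0) / length(gaps)
}

#' Mean uniform angle index of a stand or population
#'
#' Computes `W_i` for every reference tree (trees inside the reduced
#' window, optionally restricted to one species and/or stage) with the
#' four nearest neighbours drawn from all trees in the plot, and averages
#' them. The mean classifies the spatial pattern: below `bounds[1]`
#' (0.475) regular, above `bounds[2]` (0.517) clumped, inside the band
#' random.
#'
#' By default neighbours are of any species (stand structure around each
#' reference population); `conspecific_neighbors = TRUE` restricts
#' neighbours to the reference tree's own species.
#'
#' @param stemmap a `stem_map`.
#' @param species optional species label for the reference trees.
#' @param stage optional stage label for the reference trees.
#' @param k neighbours per reference tree.
#' @param alpha0 standard angle, degrees.
#' @param bounds lower/upper limits of the random band.
#' @param conspecific_neighbors if `TRUE`, neighbours must be conspecific
#'   with the reference tree.
#' @return object of class `uniform_angle`: list with `per_tree` (data
#'   frame `tree_id`, `species`, `stage`, `w`), `mean_w`, `n_reference`
#'   and `classification` (`"regular"`, `"random"` or `"clumped"`).
#' @export
mean_uniform_angle <- function(stemmap, species = NULL, stage = NULL,
                               k = 4, alpha0 = 72,
                               bounds = c(0.475, 0.517),
                               conspecific_neighbors = FALSE) {
  stopifnot(inherits(stemmap, "stem_map"))
  geom <- geometry(stemmap)
  win <- reduced_window(geom)
  ref <- in_window(stemmap$x, stemmap$y, win)
  if (!is.null(species)) ref <- ref & stemmap$species == species
  if (!is.null(stage)) ref <- ref & stemmap$stage == stage
  ref_idx <- which(ref)
  if (!length(ref_idx))
    stop("no reference trees in the reduced window",
         if (!is.null(species)) paste0(" for species ", species),
         if (!is.null(stage)) paste0(" in stage ", stage), call. = FALSE)
  pool <- if (conspecific_neighbors) {
    if (is.null(species))
      stop("conspecific_neighbors requires a `species`", call. = FALSE)
    which(stemmap$species == species)
  } else seq_len(nrow(stemmap))
  if (length(pool) < k + 1)
    stop("fewer than ", k + 1, " candidate trees; cannot find ", k,
         " neighbours", call. = FALSE)
  x <- stemmap$x; y <- stemmap$y; ids <- stemmap$tree_id
  w <- vapply(ref_idx, function(i) {
    cand <- setdiff(pool, i)
    dx <- x[cand] - x[i]; dy <- y[cand] - y[i]
    d <- sqrt(dx^2 + dy^2)
    if (any(d == 0))
      stop("coincident coordinates: trees ", ids[i], ", ",
           ids[cand[d == 0][1]], call. = FALSE)
    nb <- order(d, ids[cand])[seq_len(k)]
    az <- (atan2(dx[nb], dy[nb]) * 180 / pi) %% 360
    w_index(adjacent_gaps(az), alpha0)
  }, numeric(1))
  mean_w <- mean(w)
  classification <- if (mean_w < bounds[1]) "regular"
                    else if (mean_w > bounds[2]) "clumped"
                    else "random"
  structure(list(per_tree = data.frame(tree_id = ids[ref_idx],
                                       species = stemmap$species[ref_idx],
                                       stage = stemmap$stage[ref_idx],
                                       w = w, stringsAsFactors = FALSE),
                 mean_w = mean_w, n_reference = length(ref_idx),
                 classification = classification, alpha0 = alpha0,
                 bounds = bounds),
            class = "uniform_angle")
}

#' @export
print.uniform_angle <- function(x, ...) {
  cat(sprintf(
    "Uniform angle index: mean W = %.3f over %d reference trees -> %s\n",
    x$mean_w, x$n_reference, x$classification))
  invisible(x)
}

#' Uniform angle summary per species and stage
#'
#' Convenience wrapper producing one [mean_uniform_angle()] summary row for
#' the whole stand and for each requested species.
#'
#' @param stemmap a `stem_map`.
#' @param species species labels to summarise individually (default: all).
#' @param ... passed to [mean_uniform_angle()].
#' @return data frame with `subset`, `n_reference`, `mean_w`,
#'   `classification`; species with no reference tree in the reduced
#'   window get an `NA` row.
#' @export
uniform_angle_summary <- function(stemmap, species = NULL, ...) {
  if (is.null(species)) species <- sort(unique(stemmap$species))
  all_res <- mean_uniform_angle(stemmap, ...)
  rows <- list(data.frame(subset = "all",
                          n_reference = all_res$n_reference,
                          mean_w = all_res$mean_w,
                          classification = all_res$classification,
                          stringsAsFactors = FALSE))
  for (sp in species) {
    res <- tryCatch(mean_uniform_angle(stemmap, species = sp, ...),
                    error = function(e) NULL)
    rows[[length(rows) + 1L]] <-
      data.frame(subset = sp,
                 n_reference = if (is.null(res)) 0L else res$n_reference,
                 mean_w = if (is.null(res)) NA_real_ else res$mean_w,
                 classification = if (is.null(res)) NA_character_
                                  else res$classification,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
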