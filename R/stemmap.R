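#' Plot geometry
#'
#' Describes the rectangular study plot: outer dimensions, the quadrat
#' (subplot) size used as the sampling unit for presence/absence, and the
#' width of the buffer strip used for nearest-neighbour edge correction.
#' The default geometry is a 140 x 70 m plot divided into 50 quadrats of
#' 14 x 14 m with a 5 m buffer.
#'
#' @param width plot width in metres (x extent).
#' @param height plot height in metres (y extent).
#' @param quadrat_size side length of the square quadrats, metres.
#' @param buffer_width width of the edge-correction buffer strip, metres.
#'   Must be smaller than half the shorter plot side.
#' @return An object of class `plot_geometry`: a list with elements
#'   `width`, `height`, `quadrat_size`, `buffer_width`.
#' @examples
#' plot_geometry()                    # the 140 x 70 m default
#' plot_geometry(100, 50, 10, 5)
#' @export
plot_geometry <- function(width = 140, height = 70, quadrat_size = 14,
                          buffer_width = 5) {
  for (nm in c("width", "height", "quadrat_size", "buffer_width")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (width <= 0 || height <= 0 || quadrat_size <= 0)
    stop("plot dimensions and quadrat size must be strictly positive",
         call. = FALSE)
  if (buffer_width < 0)
    stop("`buffer_width` must be non-negative", call. = FALSE)
  if (buffer_width >= min(width, height) / 2)
    stop("`buffer_width` (", buffer_width, " m) must be less than half the ",
         "shorter plot side (", min(width, height) / 2, " m): the reduced ",
         "window would be empty", call. = FALSE)
  structure(list(width = width, height = height,
                 quadrat_size = quadrat_size, buffer_width = buffer_width),
            class = "plot_geometry")
}

#' @export
print.plot_geometry <- function(x, ...) {
  cat(sprintf("Plot geometry: %g x %g m, quadrats %g m, buffer %g m\n",
              x$width, x$height, x$quadrat_size, x$buffer_width))
  invisible(x)
}

#' Assign a development stage from DBH
#'
#' Trees are classified into development stages by diameter at breast
#' height using left-closed, right-open intervals. The defaults follow the
#' common field convention: juvenile (5 <= DBH < 10 cm), medium
#' (10 <= DBH < 25 cm), large (DBH >= 25 cm). Trees below the 5 cm survey
#' threshold are not valid census records and are rejected.
#'
#' @param dbh numeric vector of diameters at breast height, cm.
#' @param breaks increasing numeric vector of stage breakpoints; the first
#'   element is the census DBH threshold.
#' @param labels stage labels, one per interval (`length(breaks)` of them;
#'   the last interval is unbounded above).
#' @return factor of stages with levels `labels`.
#' @examples
#' assign_stage(c(5, 9.9, 10, 24.9, 25, 60))
#' @export
assign_stage <- function(dbh, breaks = c(5, 10, 25),
                         labels = c("juvenile", "medium", "large")) {
  if (length(labels) != length(breaks))
    stop("`labels` must have one entry per stage interval", call. = FALSE)
  if (is.unsorted(breaks, strictly = TRUE))
    stop("`breaks` must be strictly increasing", call. = FALSE)
  if (!is.numeric(dbh) || any(!is.finite(dbh)))
    stop("`dbh` must be finite numeric; the census records only trees with ",
         "DBH >= ", breaks[1], " cm", call. = FALSE)
  if (any(dbh < breaks[1]))
    stop("DBH below the census threshold of ", breaks[1],
         " cm (smallest offending value: ", min(dbh), " cm)", call. = FALSE)
  cut(dbh, breaks = c(breaks, Inf), labels = labels, right = FALSE)
}

#' Construct a stem map
#'
#' A stem map is the basic data object: one row per censused tree with its
#' identifier, species code, coordinates (metres from the plot's south-west
#' corner) and DBH (cm), plus the plot geometry. Stages are derived from
#' DBH at construction.
#'
#' @param trees data frame with columns `tree_id`, `species`, `x`, `y`,
#'   `dbh`.
#' @param geometry a [plot_geometry()].
#' @param stage_breaks passed to [assign_stage()].
#' @return A `stem_map`: the tree data frame (with derived `stage` column)
#'   carrying the geometry as an attribute.
#' @export
stem_map <- function(trees, geometry = plot_geometry(),
                     stage_breaks = c(5, 10, 25)) {
  stopifnot(inherits(geometry, "plot_geometry"))
  req <- c("tree_id", "species", "x", "y", "dbh")
  miss <- setdiff(req, names(trees))
  if (length(miss))
    stop("missing stem-map column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  trees <- as.data.frame(trees)[, req]
  trees$tree_id <- as.character(trees$tree_id)
  trees$species <- as.character(trees$species)
  if (anyDuplicated(trees$tree_id)) {
    dup <- trees$tree_id[duplicated(trees$tree_id)][1]
    stop("duplicate tree_id: ", dup, call. = FALSE)
  }
  for (nm in c("x", "y", "dbh"))
    if (!is.numeric(trees[[nm]]) || any(!is.finite(trees[[nm]])))
      stop("column `", nm, "` must be finite numeric", call. = FALSE)
  bad <- trees$x < 0 | trees$x > geometry$width |
         trees$y < 0 | trees$y > geometry$height
  if (any(bad))
    stop("tree(s) outside the plot rectangle: ",
         paste(utils::head(trees$tree_id[bad], 5), collapse = ", "),
         call. = FALSE)
  trees$stage <- assign_stage(trees$dbh, breaks = stage_breaks)
  rownames(trees) <- NULL
  structure(trees, geometry = geometry, stage_breaks = stage_breaks,
            class = c("stem_map", "data.frame"))
}

#' @export
print.stem_map <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("Stem map: %d trees, %d species, %g x %g m plot\n",
              nrow(x), length(unique(x$species)), g$width, g$height))
  print(table(stage = x$stage))
  invisible(x)
}

#' Plot geometry of a stem map
#' @param x a `stem_map`.
#' @return the [plot_geometry()] attached to the stem map.
#' @export
geometry <- function(x) attr(x, "geometry")

#' Read a stem map from CSV
#'
#' Reads a delimited text census with header columns
#' `tree_id,species,x,y,dbh`. In strict mode (the default) any row outside
#' the plot rectangle or below the DBH threshold aborts the read; in
#' lenient mode such rows are dropped with a message reporting the count.
#'
#' @param path path to a CSV file.
#' @param geometry a [plot_geometry()].
#' @param mode `"strict"` (reject bad rows with an error) or `"lenient"`
#'   (drop them, reporting how many).
#' @param stage_breaks passed to [assign_stage()].
#' @return a [stem_map()].
#' @export
read_stemmap <- function(path, geometry = plot_geometry(),
                         mode = c("strict", "lenient"),
                         stage_breaks = c(5, 10, 25)) {
  mode <- match.arg(mode)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("tree_id", "species", "x", "y", "dbh")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("stem-map file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (nm in c("x", "y", "dbh")) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    if (any(is.na(v)))
      stop("non-numeric `", nm, "` in row(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "),
           " of ", path, call. = FALSE)
    raw[[nm]] <- v
  }
  bad <- raw$x < 0 | raw$x > geometry$width |
         raw$y < 0 | raw$y > geometry$height | raw$dbh < stage_breaks[1]
  if (any(bad)) {
    if (mode == "strict")
      stop(sum(bad), " row(s) outside the plot or below the ",
           stage_breaks[1], " cm DBH threshold (first offending row: ",
           which(bad)[1], "); use mode = \"lenient\" to drop them",
           call. = FALSE)
    message("read_stemmap: dropped ", sum(bad),
            " row(s) outside the plot or below the DBH threshold")
    raw <- raw[!bad, , drop = FALSE]
  }
  stem_map(raw, geometry = geometry, stage_breaks = stage_breaks)
}

#' Write a stem map to CSV
#'
#' Writes the canonical five-column census format (`tree_id,species,x,y,dbh`);
#' the derived stage column is not written since it is a pure function of
#' DBH.
#'
#' @param x a `stem_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stemmap <- function(x, path) {
  stopifnot(inherits(x, "stem_map"))
  utils::write.csv(x[, c("tree_id", "species", "x", "y", "dbh")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the quadrat grid
#'
#' Tiles the plot rectangle with square quadrats from the origin (SW
#' corner). In strict mode the plot sides must be exact multiples of the
#' quadrat size (as in a plot laid out around its subplots); lenient mode
#' drops the leftover margin.
#'
#' @param geometry a [plot_geometry()].
#' @param mode `"strict"` or `"lenient"`.
#' @return A `quadrat_grid`: list with `n_cols`, `n_rows`, `quadrat_size`,
#'   `N` (total quadrat count).
#' @examples
#' build_quadrat_grid(plot_geometry(140, 70, 14))  # N = 50
#' @export
build_quadrat_grid <- function(geometry, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "plot_geometry"))
  s <- geometry$quadrat_size
  if (s > min(geometry$width, geometry$height))
    stop("quadrat size exceeds a plot dimension", call. = FALSE)
  rw <- geometry$width %% s
  rh <- geometry$height %% s
  if (mode == "strict" && (rw > 1e-9 || rh > 1e-9))
    stop("plot does not divide evenly into ", s, " m quadrats (remainders ",
         rw, " m x ", rh, " m); use mode = \"lenient\" to drop the margin",
         call. = FALSE)
  n_cols <- as.integer(floor(geometry$width / s + 1e-9))
  n_rows <- as.integer(floor(geometry$height / s + 1e-9))
  structure(list(n_cols = n_cols, n_rows = n_rows, quadrat_size = s,
                 N = n_cols * n_rows),
            class = "quadrat_grid")
}

#' @export
print.quadrat_grid <- function(x, ...) {
  cat(sprintf("Quadrat grid: %d x %d cells of %g m (N = %d)\n",
              x$n_cols, x$n_rows, x$quadrat_size, x$N))
  invisible(x)
}

#' Locate points in the quadrat grid
#'
#' Quadrat membership is half-open, `[k*s, (k+1)*s)`, so a tree exactly on
#' an interior quadrat line belongs to the cell to its north-east; points
#' exactly on the far east/north edge of the gridded region are clamped
#' into the last cell so that the census partition is exhaustive.
#'
#' @param x,y coordinates in metres (vectors of equal length).
#' @param grid a `quadrat_grid`.
#' @return data frame with zero-based `col`, `row` and one-based `cell`
#'   index (column-major: `cell = col + row * n_cols + 1`).
#' @export
locate_quadrat <- function(x, y, grid) {
  stopifnot(inherits(grid, "quadrat_grid"), length(x) == length(y))
  s <- grid$quadrat_size
  xmax <- grid$n_cols * s
  ymax <- grid$n_rows * s
  out <- x < 0 | x > xmax | y < 0 | y > ymax
  if (any(out))
    stop("point(s) outside the gridded region: index ",
         paste(utils::head(which(out), 5), collapse = ", "), call. = FALSE)
  col <- pmin(floor(x / s), grid$n_cols - 1L)
  row <- pmin(floor(y / s), grid$n_rows - 1L)
  data.frame(col = as.integer(col), row = as.integer(row),
             cell = as.integer(col + row * grid$n_cols + 1L))
}

#' Species-by-quadrat matrix
#'
#' Cross-tabulates the stem map into a species x quadrat matrix, either as
#' 0/1 presence indicators (the sampling unit for the association tests) or
#' as abundance counts. Species listed in `species` but absent after stage
#' filtering are retained as all-zero rows (with a warning), so that pair
#' enumeration is identical across stages.
#'
#' @param stemmap a `stem_map`.
#' @param grid a `quadrat_grid` (default: built from the stem map's
#'   geometry).
#' @param species ordered species labels to tabulate; default all species
#'   present, in order of decreasing abundance.
#' @param stage_filter optional stage label; only trees of that stage are
#'   counted.
#' @param mode `"presence"` (0/1) or `"abundance"` (counts).
#' @return matrix with `length(species)` rows and `grid$N` columns, with a
#'   `mode` attribute.
#' @export
presence_matrix <- function(stemmap, grid = NULL, species = NULL,
                            stage_filter = NULL,
                            mode = c("presence", "abundance")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stemmap, "stem_map"))
  if (is.null(grid)) grid <- build_quadrat_grid(geometry(stemmap))
  if (is.null(species)) {
    tab <- sort(table(stemmap$species), decreasing = TRUE)
    species <- names(tab)
  }
  if (!length(species)) stop("`species` must be non-empty", call. = FALSE)
  unknown <- setdiff(species, unique(stemmap$species))
  if (length(unknown))
    stop("unknown species label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  trees <- stemmap[stemmap$species %in% species, , drop = FALSE]
  if (!is.null(stage_filter)) {
    stage_filter <- match.arg(stage_filter, levels(stemmap$stage))
    trees <- trees[trees$stage == stage_filter, , drop = FALSE]
  }
  m <- matrix(0L, nrow = length(species), ncol = grid$N,
              dimnames = list(species, NULL))
  if (nrow(trees)) {
    cell <- locate_quadrat(trees$x, trees$y, grid)$cell
    tab <- table(factor(trees$species, levels = species),
                 factor(cell, levels = seq_len(grid$N)))
    m[] <- as.integer(tab)
  }
  if (mode == "presence") m[] <- as.integer(m > 0L)
  empty <- rowSums(m) == 0L
  if (any(empty))
    warning("species with no occurrence",
            if (!is.null(stage_filter)) paste0(" in stage ", stage_filter),
            ": ", paste(species[empty], collapse = ", "),
            " (kept as all-zero rows)", call. = FALSE)
  structure(m, mode_label = mode)
}
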