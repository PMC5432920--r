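# Seeded generators of synthetic stem maps. Every generator takes an
# explicit seed and restores the caller's RNG state, so simulations are
# reproducible and composable: simulate_community() fans a single seed out
# into per-species substreams, so adding a species never perturbs the
# points of existing ones.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  expr
}

# deterministic substream seed for species index i under base seed
substream_seed <- function(seed, i) (seed + 7919L * i) %% .Machine$integer.max

#' Homogeneous Poisson point pattern
#'
#' Complete spatial randomness: the point count is Poisson with mean
#' `intensity * area` and positions are independent uniforms. This is the
#' null ("random") pattern of the uniform angle index.
#'
#' @param intensity expected points per square metre.
#' @param geometry a [plot_geometry()].
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return data frame with columns `x`, `y` (metres).
#' @examples
#' nrow(simulate_poisson(900 / 9800, plot_geometry(), seed = 1))  # ~900
#' @export
simulate_poisson <- function(intensity, geometry = plot_geometry(),
                             seed = NULL) {
  stopifnot(intensity > 0)
  with_seed(seed, {
    n <- stats::rpois(1, intensity * geometry$width * geometry$height)
    data.frame(x = stats::runif(n, 0, geometry$width),
               y = stats::runif(n, 0, geometry$height))
  })
}

#' Thomas cluster point pattern
#'
#' Poisson parents with Poisson(`mean_offspring`) children displaced by an
#' isotropic Gaussian of standard deviation `sigma`; children falling
#' outside the plot are discarded. Parents are generated on a window
#' dilated by `4 * sigma` so cluster fragments near the edge are not
#' under-represented. Small `sigma` relative to parent spacing gives a
#' strongly clumped pattern.
#'
#' @param parent_intensity parents per square metre.
#' @param mean_offspring expected children per parent.
#' @param sigma Gaussian displacement sd, metres.
#' @param geometry a [plot_geometry()].
#' @param seed integer seed.
#' @param parent_window optional 2-column matrix of parent positions to use
#'   instead of simulating them (used to impose habitat association).
#' @return data frame with columns `x`, `y`.
#' @export
simulate_cluster <- function(parent_intensity, mean_offspring, sigma,
                             geometry = plot_geometry(), seed = NULL,
                             parent_window = NULL) {
  stopifnot(mean_offspring > 0, sigma > 0)
  with_seed(seed, {
    if (is.null(parent_window)) {
      stopifnot(parent_intensity > 0)
      pad <- 4 * sigma
      w <- geometry$width + 2 * pad
      h <- geometry$height + 2 * pad
      np <- stats::rpois(1, parent_intensity * w * h)
      px <- stats::runif(np, -pad, geometry$width + pad)
      py <- stats::runif(np, -pad, geometry$height + pad)
    } else {
      px <- parent_window[, 1]
      py <- parent_window[, 2]
      np <- length(px)
    }
    if (np == 0) return(data.frame(x = numeric(0), y = numeric(0)))
    kids <- stats::rpois(np, mean_offspring)
    parent <- rep.int(seq_len(np), kids)
    n <- length(parent)
    x <- px[parent] + stats::rnorm(n, 0, sigma)
    y <- py[parent] + stats::rnorm(n, 0, sigma)
    keep <- x >= 0 & x <= geometry$width & y >= 0 & y <= geometry$height
    data.frame(x = x[keep], y = y[keep])
  })
}

#' Hard-core (inhibition) point pattern
#'
#' Sequential random placement rejecting any candidate within
#' `min_distance` of an accepted point, giving a regular pattern with all
#' pairwise distances at least `min_distance`.
#'
#' @param n number of points to place.
#' @param min_distance hard-core distance, metres.
#' @param geometry a [plot_geometry()].
#' @param seed integer seed.
#' @param max_tries candidate proposals before giving up.
#' @return data frame with columns `x`, `y`.
#' @export
simulate_inhibition <- function(n, min_distance, geometry = plot_geometry(),
                                seed = NULL,
                                max_tries = max(10000, 200 * n)) {
  stopifnot(n >= 0, min_distance >= 0)
  with_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    placed <- 0L; tries <- 0L
    while (placed < n && tries < max_tries) {
      tries <- tries + 1L
      cx <- stats::runif(1, 0, geometry$width)
      cy <- stats::runif(1, 0, geometry$height)
      if (placed == 0L ||
          min((x[seq_len(placed)] - cx)^2 +
              (y[seq_len(placed)] - cy)^2) >= min_distance^2) {
        placed <- placed + 1L
        x[placed] <- cx; y[placed] <- cy
      }
    }
    if (placed < n)
      stop("could not place ", n, " points at min_distance = ",
           min_distance, " m after ", max_tries,
           " tries; reduce n or the distance", call. = FALSE)
    data.frame(x = x, y = y)
  })
}

#' Draw DBH values with a reverse-J stage structure
#'
#' Mixes the three development stages in the given proportions and draws
#' DBH within each stage from a truncated exponential (rate 1/5 per cm),
#' so abundance declines with diameter — the reverse-J structure of
#' self-regenerating stands. The default mix puts 41.3 percent of stems in
#' the juvenile class.
#'
#' @param n number of trees.
#' @param stage_mix proportions over (juvenile, medium, large); must sum
#'   to 1.
#' @param breaks stage DBH breakpoints, cm (last class capped at 80 cm for
#'   simulation).
#' @param seed integer seed.
#' @return numeric vector of DBH values, all `>= breaks[1]`.
#' @export
assign_dbh <- function(n, stage_mix = c(0.413, 0.420, 0.167),
                       breaks = c(5, 10, 25), seed = NULL) {
  if (abs(sum(stage_mix) - 1) > 1e-8)
    stop("`stage_mix` must sum to 1", call. = FALSE)
  stopifnot(length(stage_mix) == 3, length(breaks) == 3)
  with_seed(seed, {
    stage <- sample.int(3, n, replace = TRUE, prob = stage_mix)
    lo <- breaks[stage]
    hi <- c(breaks[-1], 80)[stage]
    # inverse-CDF draw from exp(rate) truncated to [lo, hi)
    rate <- 1 / 5
    u <- stats::runif(n)
    p_lo <- stats::pexp(lo, rate); p_hi <- stats::pexp(hi, rate)
    stats::qexp(p_lo + u * (p_hi - p_lo), rate)
  })
}

#' Community specification for the synthetic generator
#'
#' Bundles the plot geometry, the per-species point-pattern settings and
#' the intended pairwise associations into a reproducible recipe for
#' [simulate_community()]. The default emulates the kind of stand the
#' analysis targets: a 140 x 70 m old-growth plot of roughly 870 stems in
#' 11 dominant species with reverse-J diameter structure, most species
#' clumped, some random, one regular.
#'
#' @param geometry a [plot_geometry()].
#' @param species_specs data frame with columns `label`, `count` (expected
#'   trees), `pattern` (`"poisson"`, `"cluster"` or `"inhibition"`),
#'   `sigma` (cluster displacement sd, m; `NA` otherwise), `min_distance`
#'   (hard-core distance, m; `NA` otherwise) and the juvenile/medium/large
#'   `mix_*` proportions.
#' @param association_design data frame with columns `species_a`,
#'   `species_b`, `sign` (`"+"` or `"-"`) and `strength` in `[0, 1]`
#'   (0 = independence); may be empty.
#' @param seed integer seed.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(geometry = plot_geometry(),
                           species_specs = default_species_specs(),
                           association_design = default_association_design(),
                           seed = 1L) {
  stopifnot(inherits(geometry, "plot_geometry"))
  req <- c("label", "count", "pattern", "sigma", "min_distance",
           "mix_juvenile", "mix_medium", "mix_large")
  miss <- setdiff(req, names(species_specs))
  if (length(miss))
    stop("species_specs lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(species_specs$count < 0))
    stop("expected counts must be non-negative", call. = FALSE)
  if (!all(species_specs$pattern %in% c("poisson", "cluster", "inhibition")))
    stop("pattern must be poisson, cluster or inhibition", call. = FALSE)
  if (any(species_specs$pattern == "cluster" &
          !(species_specs$sigma > 0)))
    stop("cluster species need sigma > 0", call. = FALSE)
  if (any(species_specs$pattern == "inhibition" &
          !(species_specs$min_distance >= 0)))
    stop("inhibition species need min_distance >= 0", call. = FALSE)
  if (nrow(association_design)) {
    stopifnot(all(c("species_a", "species_b", "sign", "strength") %in%
                    names(association_design)))
    if (!all(association_design$sign %in% c("+", "-")))
      stop("association sign must be '+' or '-'", call. = FALSE)
    if (any(association_design$strength < 0 |
            association_design$strength > 1))
      stop("association strength must lie in [0, 1]", call. = FALSE)
    bad <- !c(association_design$species_a, association_design$species_b) %in%
      species_specs$label
    if (any(bad)) stop("association_design names unknown species",
                       call. = FALSE)
  }
  structure(list(geometry = geometry, species_specs = species_specs,
                 association_design = association_design,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' @rdname community_spec
#' @export
default_species_specs <- function() {
  data.frame(
    label = sprintf("sp%02d", 1:11),
    count = c(185, 135, 80, 75, 70, 65, 60, 55, 55, 50, 40),
    pattern = c("cluster", "cluster", "cluster", "cluster", "poisson",
                "cluster", "cluster", "poisson", "cluster", "cluster",
                "inhibition"),
    sigma = c(6, 5, 4, 5, NA, 4, 6, NA, 5, 4, NA),
    min_distance = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, 8),
    mix_juvenile = c(0.20, 0.55, 0.45, 0.50, 0.55, 0.45, 0.50, 0.50,
                     0.35, 0.30, 0.25),
    mix_medium = c(0.45, 0.35, 0.40, 0.40, 0.35, 0.45, 0.40, 0.40,
                   0.45, 0.45, 0.45),
    mix_large = c(0.35, 0.10, 0.15, 0.10, 0.10, 0.10, 0.10, 0.10,
                  0.20, 0.25, 0.30),
    stringsAsFactors = FALSE)
}

#' @rdname community_spec
#' @export
default_association_design <- function() {
  data.frame(species_a = c("sp01", "sp02", "sp01"),
             species_b = c("sp09", "sp04", "sp02"),
             sign = c("+", "+", "-"),
             strength = c(0.8, 0.8, 0.8),
             stringsAsFactors = FALSE)
}

# Habitat patch for association: the fraction f = 1 - 0.5 * strength of
# quadrat-sized cells ranked by distance from an anchor point. Both members
# of a positive pair take the f*N cells nearest the shared anchor; the
# second member of a negative pair takes the f*N cells farthest from it,
# so the two patches overlap in exactly the middle 2f - 1 fraction
# whatever the anchor position.
habitat_cells <- function(anchor, geometry, fraction, farthest = FALSE) {
  s <- geometry$quadrat_size
  grid <- build_quadrat_grid(geometry, mode = "lenient")
  cx <- (rep(seq_len(grid$n_cols), grid$n_rows) - 0.5) * s
  cy <- (rep(seq_len(grid$n_rows), each = grid$n_cols) - 0.5) * s
  d2 <- (cx - anchor[1])^2 + (cy - anchor[2])^2
  keep <- order(d2, decreasing = farthest)[
    seq_len(max(1L, round(fraction * grid$N)))]
  cbind(x0 = cx[keep] - s / 2, y0 = cy[keep] - s / 2)
}

sample_in_cells <- function(n, cells, s) {
  pick <- sample.int(nrow(cells), n, replace = TRUE)
  cbind(cells[pick, "x0"] + stats::runif(n, 0, s),
        cells[pick, "y0"] + stats::runif(n, 0, s))
}

#' Simulate a multi-species stand with known truth
#'
#' Generates each species' point pattern according to its spec, imposes
#' the intended pairwise associations through shared (positive) or opposed
#' (negative) habitat patches, draws DBH values per species, and returns
#' the stem map together with a truth record of the generating patterns
#' and association signs for recovery testing.
#'
#' Association is induced by habitat: a pair with strength `s` confines
#' each member (its points, or its cluster parents) to a patch of
#' quadrat cells covering the fraction `f = 1 - s/2` of the plot: the
#' cells nearest a shared random anchor for both members of a positive
#' pair, and for a negative pair the nearest-`f` cells versus the
#' farthest-`f` cells, which overlap in exactly the fraction `2f - 1`.
#' Strength 0 leaves species unconstrained (independent); strength 1
#' confines a negative pair to disjoint half-plots.
#'
#' @param spec a [community_spec()].
#' @return list with `stemmap` (a [stem_map()]) and `truth` (list with
#'   `patterns`: per-species pattern labels, and `associations`: the
#'   intended pair signs and strengths).
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  geom <- spec$geometry
  ss <- spec$species_specs
  ad <- spec$association_design
  area <- geom$width * geom$height
  # habitat patch per constrained species
  patch <- stats::setNames(vector("list", nrow(ss)), ss$label)
  if (nrow(ad)) {
    anchors <- with_seed(spec$seed, {
      matrix(c(stats::runif(nrow(ad), 0, geom$width),
               stats::runif(nrow(ad), 0, geom$height)), ncol = 2)
    })
    for (p in seq_len(nrow(ad))) {
      if (ad$strength[p] == 0) next
      f <- 1 - 0.5 * ad$strength[p]
      a1 <- anchors[p, ]
      patch[[ad$species_a[p]]] <- habitat_cells(a1, geom, f)
      patch[[ad$species_b[p]]] <- habitat_cells(a1, geom, f,
                                                farthest = ad$sign[p] == "-")
    }
  }
  trees <- vector("list", nrow(ss))
  for (i in seq_len(nrow(ss))) {
    sd_i <- substream_seed(spec$seed, i)
    lab <- ss$label[i]
    cells <- patch[[lab]]
    pts <- with_seed(sd_i, {
      if (ss$pattern[i] == "poisson") {
        n <- stats::rpois(1, ss$count[i])
        if (is.null(cells))
          data.frame(x = stats::runif(n, 0, geom$width),
                     y = stats::runif(n, 0, geom$height))
        else {
          xy <- sample_in_cells(n, cells, geom$quadrat_size)
          data.frame(x = xy[, 1], y = xy[, 2])
        }
      } else if (ss$pattern[i] == "cluster") {
        mean_off <- 10
        n_par <- max(1L, round(ss$count[i] / mean_off))
        par_xy <- if (is.null(cells))
          cbind(stats::runif(n_par, 0, geom$width),
                stats::runif(n_par, 0, geom$height))
        else sample_in_cells(n_par, cells, geom$quadrat_size)
        simulate_cluster(parent_intensity = n_par / area,
                         mean_offspring = mean_off, sigma = ss$sigma[i],
                         geometry = geom, parent_window = par_xy)
      } else {  # inhibition; habitat constraint not supported for hard core
        simulate_inhibition(stats::rpois(1, ss$count[i]),
                            ss$min_distance[i], geom)
      }
    })
    n <- nrow(pts)
    dbh <- assign_dbh(n,
                      stage_mix = c(ss$mix_juvenile[i], ss$mix_medium[i],
                                    ss$mix_large[i]),
                      seed = substream_seed(spec$seed, 1000L + i))
    trees[[i]] <- data.frame(tree_id = sprintf("%s_%04d", lab, seq_len(n)),
                             species = lab, x = pts$x, y = pts$y,
                             dbh = dbh, stringsAsFactors = FALSE)
  }
  all_trees <- do.call(rbind, trees)
  sm <- stem_map(all_trees, geometry = geom)
  truth <- list(patterns = stats::setNames(ss$pattern, ss$label),
                associations = ad, seed = spec$seed)
  list(stemmap = sm, truth = truth)
}
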