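#' Quadrat totals
#'
#' Column sums of a species x quadrat matrix: in presence mode `T_j` is the
#' species richness of quadrat `j`, in abundance mode the total number of
#' individuals. The mean `t` over quadrats is attached.
#'
#' @param pm species x quadrat matrix.
#' @return numeric vector of quadrat totals with attribute `mean`.
#' @export
quadrat_totals <- function(pm) {
  if (!length(pm) || !nrow(pm) || !ncol(pm))
    stop("empty species x quadrat matrix", call. = FALSE)
  Tj <- colSums(pm)
  structure(Tj, mean = mean(Tj))
}

#' Schluter variance-ratio test of overall association
#'
#' Compares the variance of quadrat totals to the sum of per-species
#' variances:
#' `V = S_T^2 / sum(delta_i^2)`, with `S_T^2 = (1/N) sum_j (T_j - t)^2`
#' and `delta_i^2 = (1/N) sum_j (X_ij - t_i)^2` (population-style `1/N`
#' normalisation; `t_i` is the mean occupancy of species `i`). Under
#' independence `V = 1`; `V > 1` indicates overall positive covariation
#' among species, `V < 1` overall negative covariation. Significance is
#' judged by the statistic `W = N * V`, which under independence falls
#' inside a two-sided chi-square band with `df = N` (90 percent by
#' default).
#'
#' @param pm species x quadrat matrix (0/1 presence by default; abundance
#'   counts are accepted and give Schluter's abundance version).
#' @param level total two-sided tail probability of the chi-square band.
#' @return object of class `variance_ratio`: list with `V`, `S_T2`,
#'   `delta_sum` (`sum(delta_i^2)`), `delta_i` (per-species variances),
#'   `W`, `N`, `bounds` (lower/upper chi-square quantiles) and `verdict`
#'   (see [overall_verdict()]).
#' @examples
#' pm <- rbind(sp1 = c(1, 1, 0, 0), sp2 = c(1, 1, 0, 0))
#' variance_ratio(pm)$V  # 2: the two species covary perfectly
#' @export
variance_ratio <- function(pm, level = 0.10) {
  Tj <- quadrat_totals(pm)
  N <- ncol(pm)
  if (N < 2) stop("need at least 2 quadrats", call. = FALSE)
  t_bar <- attr(Tj, "mean")
  S_T2 <- sum((Tj - t_bar)^2) / N
  t_i <- rowMeans(pm)
  delta_i <- rowSums((pm - t_i)^2) / N
  delta_sum <- sum(delta_i)
  if (delta_sum == 0)
    stop("every species is constant across quadrats; ",
         "the variance ratio is undefined", call. = FALSE)
  V <- S_T2 / delta_sum
  W <- w_statistic(V, N)
  bounds <- chisq_bounds(N, level)
  structure(list(V = V, S_T2 = S_T2, delta_sum = delta_sum,
                 delta_i = delta_i, W = W, N = N, bounds = bounds,
                 level = level,
                 verdict = overall_verdict(V, W, bounds)),
            class = "variance_ratio")
}

#' W statistic of the variance-ratio test
#'
#' `W = N * V`, the quadrat count times the variance ratio; under species
#' independence W is approximately chi-square distributed with `df = N`.
#'
#' @param V variance ratio.
#' @param N number of quadrats.
#' @return the W statistic.
#' @export
w_statistic <- function(V, N) {
  stopifnot(is.numeric(V), is.numeric(N), N >= 1)
  N * V
}

#' Chi-square band for the W statistic
#'
#' Two-sided chi-square quantiles with `df = N`: the lower bound at
#' cumulative probability `level/2` and the upper at `1 - level/2`. With
#' the default `level = 0.10` and `N = 50` the band is (34.764, 67.505) —
#' in upper-tail notation, the 0.95 and 0.05 chi-square points.
#'
#' @param N degrees of freedom (the quadrat count).
#' @param level total two-sided tail probability in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @export
chisq_bounds <- function(N, level = 0.10) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("`level` must be a probability strictly between 0 and 1",
         call. = FALSE)
  stopifnot(N >= 1)
  stats::setNames(stats::qchisq(c(level / 2, 1 - level / 2), df = N),
                  c("lower", "upper"))
}

#' Verdict of the overall association test
#'
#' Direction comes from the variance ratio (`V > 1` positive, `V < 1`
#' negative, `V = 1` independent); significance from whether `W` falls
#' outside the chi-square band.
#'
#' @param V variance ratio.
#' @param W the statistic `N * V`.
#' @param bounds lower/upper band, as from [chisq_bounds()].
#' @return one of `"significant_positive"`, `"nonsignificant_positive"`,
#'   `"independent"`, `"nonsignificant_negative"`,
#'   `"significant_negative"`.
#' @export
overall_verdict <- function(V, W, bounds) {
  significant <- W < bounds[["lower"]] || W > bounds[["upper"]]
  if (V == 1) return("independent")
  direction <- if (V > 1) "positive" else "negative"
  paste0(if (significant) "significant_" else "nonsignificant_", direction)
}

#' @export
print.variance_ratio <- function(x, ...) {
  cat(sprintf(
    "Variance-ratio test: V = %.3f, W = %.3f (N = %d; %.0f%% band %.3f-%.3f)\n",
    x$V, x$W, x$N, 100 * (1 - x$level), x$bounds[["lower"]],
    x$bounds[["upper"]]))
  cat("Verdict:", x$verdict, "\n")
  invisible(x)
}

#' Stage-stratified overall association table
#'
#' Runs the variance-ratio test on the presence matrix of each development
#' stage and of the pooled stand, for a fixed species set.
#'
#' @param stemmap a `stem_map`.
#' @param species species labels to include (e.g. the dominant set).
#' @param grid a `quadrat_grid`; default from the stem-map geometry.
#' @param level band tail probability, see [variance_ratio()].
#' @return data frame with one row per stage plus `"all"`: `stage`,
#'   `delta_sum`, `S_T2`, `V`, `W`, `lower`, `upper`, `verdict`.
#' @export
overall_association_by_stage <- function(stemmap, species, grid = NULL,
                                         level = 0.10) {
  stopifnot(inherits(stemmap, "stem_map"))
  if (is.null(grid)) grid <- build_quadrat_grid(geometry(stemmap))
  stages <- c(as.list(levels(stemmap$stage)), list(NULL))
  labels <- c(levels(stemmap$stage), "all")
  rows <- lapply(seq_along(stages), function(i) {
    pm <- suppressWarnings(
      presence_matrix(stemmap, grid, species = species,
                      stage_filter = stages[[i]]))
    vr <- tryCatch(variance_ratio(pm, level), error = function(e) NULL)
    if (is.null(vr))
      return(data.frame(stage = labels[i], delta_sum = NA_real_,
                        S_T2 = NA_real_, V = NA_real_, W = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        verdict = NA_character_, stringsAsFactors = FALSE))
    data.frame(stage = labels[i], delta_sum = vr$delta_sum, S_T2 = vr$S_T2,
               V = vr$V, W = vr$W, lower = vr$bounds[["lower"]],
               upper = vr$bounds[["upper"]], verdict = vr$verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
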