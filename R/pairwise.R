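#' 2 x 2 contingency table for a species pair
#'
#' Cross-tabulates two equal-length presence indicator vectors over the
#' quadrats: `a` quadrats with both species, `b` with A only, `c` with B
#' only, `d` with neither; `N = a + b + c + d` is the quadrat count.
#'
#' @param rowA,rowB 0/1 integer vectors of equal length (>= 2), one entry
#'   per quadrat.
#' @return object of class `contingency`: list with `a`, `b`, `c`, `d`,
#'   `N` and the margins `m = a + b`, `n = c + d`, `r = a + c`,
#'   `s = b + d`.
#' @examples
#' contingency(c(1, 1, 0, 0), c(1, 0, 1, 0))  # a = b = c = d = 1
#' @export
contingency <- function(rowA, rowB) {
  if (length(rowA) != length(rowB))
    stop("presence vectors differ in length", call. = FALSE)
  if (length(rowA) < 2)
    stop("need at least 2 quadrats", call. = FALSE)
  if (!all(rowA %in% c(0, 1)) || !all(rowB %in% c(0, 1)))
    stop("presence vectors must be 0/1 indicators", call. = FALSE)
  a <- sum(rowA == 1 & rowB == 1)
  b <- sum(rowA == 1 & rowB == 0)
  cc <- sum(rowA == 0 & rowB == 1)
  d <- sum(rowA == 0 & rowB == 0)
  as_contingency(a, b, cc, d)
}

#' @rdname contingency
#' @param a,b,c,d non-negative cell counts (both species / A only / B only
#'   / neither).
#' @export
as_contingency <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, N = a + b + c + d,
                 m = a + b, n = c + d, r = a + c, s = b + d),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(A = c("present", "absent"),
                              B = c("present", "absent")))
  print(m)
  cat("N =", x$N, "\n")
  invisible(x)
}

#' Signed Yates-corrected chi-square for a 2 x 2 table
#'
#' The continuity-corrected chi-square statistic
#' `N * (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, carrying the sign of
#' `ad - bc`: positive when the pair co-occurs more than expected, negative
#' when it segregates. Tables with a zero margin (a species present in
#' every quadrat or in none) have a vanishing denominator and are returned
#' as `NA` — the association is undefined, not zero.
#'
#' @param ct a `contingency` table.
#' @return signed chi-square value; `NA` if any margin is zero; exactly 0
#'   when `ad = bc`.
#' @examples
#' yates_chi2(as_contingency(10, 5, 5, 30))   # +11.338
#' @export
yates_chi2 <- function(ct) {
  stopifnot(inherits(ct, "contingency"))
  if (ct$m == 0 || ct$n == 0 || ct$r == 0 || ct$s == 0) return(NA_real_)
  det <- ct$a * ct$d - ct$b * ct$c
  if (det == 0) return(0)
  mag <- ct$N * (abs(det) - ct$N / 2)^2 /
    (ct$m * ct$n * ct$r * ct$s)
  sign(det) * mag
}

#' Chi-square classification thresholds
#'
#' The two band edges of the five-level classification are the chi-square
#' quantiles with one degree of freedom at cumulative probabilities 0.95
#' and 0.99 (3.841 and 6.635 at 3 dp), computed at run time so they carry
#' full precision.
#'
#' @param p cumulative probabilities of the two edges.
#' @return named numeric vector `c(certain = ..., significant = ...)`.
#' @export
chi2_thresholds <- function(p = c(0.95, 0.99)) {
  stats::setNames(stats::qchisq(p, df = 1), c("certain", "significant"))
}

#' Classify a signed chi-square into five association levels
#'
#' `|chi2| < 3.841` gives `none`; `3.841 <= |chi2| < 6.635` gives
#' `positive` or `negative` by sign (an association significant at
#' P < 0.05); `|chi2| >= 6.635` gives `extra_positive` or `extra_negative`
#' (P < 0.01). `NA` input (undefined table) gives `undefined`.
#'
#' @param chi2_signed signed chi-square value(s).
#' @param thresholds the two band edges, as from [chi2_thresholds()].
#' @return factor with levels `extra_negative`, `negative`, `none`,
#'   `positive`, `extra_positive`, `undefined`.
#' @export
classify_chi2 <- function(chi2_signed, thresholds = chi2_thresholds()) {
  lev <- c("extra_negative", "negative", "none", "positive",
           "extra_positive", "undefined")
  out <- ifelse(is.na(chi2_signed), "undefined",
         ifelse(abs(chi2_signed) < thresholds[1], "none",
         ifelse(abs(chi2_signed) < thresholds[2],
                ifelse(chi2_signed > 0, "positive", "negative"),
                ifelse(chi2_signed > 0, "extra_positive",
                       "extra_negative"))))
  factor(out, levels = lev)
}

#' AC association coefficient
#'
#' A bounded measure of association strength on `[-1, 1]` with three
#' denominator branches:
#' \itemize{
#'   \item `ad >= bc`: `(ad - bc) / ((a+b)(b+d))`
#'   \item `ad < bc` and `d >= a`: `(ad - bc) / ((a+b)(a+c))`
#'   \item `ad < bc` and `d < a`: `(ad - bc) / ((b+d)(c+d))`
#' }
#' Complete positive association (`b = c = 0`) gives exactly 1; complete
#' negative association (`a = d = 0`) gives exactly -1; independence
#' (`ad = bc`) gives 0. A zero denominator in the selected branch makes the
#' coefficient undefined (`NA`).
#'
#' @param ct a `contingency` table.
#' @return AC value in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' association_coefficient(as_contingency(10, 5, 5, 30))  # 0.5238
#' @export
association_coefficient <- function(ct) {
  stopifnot(inherits(ct, "contingency"))
  det <- ct$a * ct$d - ct$b * ct$c
  den <- if (det >= 0) ct$m * ct$s
         else if (ct$d >= ct$a) ct$m * ct$r
         else ct$s * ct$n
  if (den == 0) {
    if (det == 0) return(0)   # e.g. a alone or d alone: no association
    return(NA_real_)
  }
  det / den
}

#' All-pairs association analysis
#'
#' Evaluates every unordered species pair of a presence matrix: the 2 x 2
#' quadrat contingency table, the signed Yates chi-square, the AC
#' coefficient and the five-level classification, plus a summary of how
#' many pairs fall in each direction. Percentages are taken over the
#' defined pairs (pairs involving a species present in no quadrat, or in
#' every quadrat, are flagged undefined and excluded).
#'
#' @param pm a species x quadrat presence matrix (rows named by species),
#'   as from [presence_matrix()].
#' @param species optional ordered subset of row names to analyse.
#' @param thresholds classification band edges, see [chi2_thresholds()].
#' @return list of class `pairwise_association`:
#'   \describe{
#'     \item{pairs}{data frame, one row per unordered pair: `species_a`,
#'       `species_b`, `a`, `b`, `c`, `d`, `chi2_signed`, `ac`, `category`,
#'       `defined`.}
#'     \item{summary}{data frame of counts and percentages of positive,
#'       negative, none and undefined pairs.}
#'   }
#' @export
pairwise_analysis <- function(pm, species = rownames(pm),
                              thresholds = chi2_thresholds()) {
  if (is.null(species) || length(species) < 2)
    stop("need at least 2 species", call. = FALSE)
  missing_sp <- setdiff(species, rownames(pm))
  if (length(missing_sp))
    stop("species not in matrix: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  pm <- pm[species, , drop = FALSE]
  if (any(!pm %in% c(0, 1)))
    stop("pairwise analysis needs a presence (0/1) matrix", call. = FALSE)
  idx <- utils::combn(length(species), 2)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    ct <- contingency(pm[i, ], pm[j, ])
    chi2 <- yates_chi2(ct)
    data.frame(species_a = species[i], species_b = species[j],
               a = ct$a, b = ct$b, c = ct$c, d = ct$d,
               chi2_signed = chi2,
               ac = association_coefficient(ct),
               category = as.character(classify_chi2(chi2, thresholds)),
               defined = !is.na(chi2),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs, summary = pair_summary(pairs)),
            class = "pairwise_association")
}

#' Summarise pair directions
#'
#' Counts of positive (signed chi-square > 0, i.e. ad > bc), negative
#' (ad < bc) and no-association (ad = bc) pairs, plus undefined pairs, with
#' percentages over the defined pairs.
#'
#' @param pairs the `pairs` data frame of a [pairwise_analysis()].
#' @return data frame with columns `direction`, `n_pairs`, `percent`.
#' @export
pair_summary <- function(pairs) {
  defined <- pairs[pairs$defined, , drop = FALSE]
  n_def <- nrow(defined)
  n_pos <- sum(defined$chi2_signed > 0)
  n_neg <- sum(defined$chi2_signed < 0)
  n_none <- sum(defined$chi2_signed == 0)
  n_undef <- sum(!pairs$defined)
  pct <- function(n) if (n_def > 0) 100 * n / n_def else NA_real_
  data.frame(direction = c("positive", "negative", "none", "undefined"),
             n_pairs = c(n_pos, n_neg, n_none, n_undef),
             percent = c(pct(n_pos), pct(n_neg), pct(n_none), NA_real_),
             stringsAsFactors = FALSE)
}

#' @export
print.pairwise_association <- function(x, ...) {
  cat(sprintf("Pairwise association: %d pairs\n", nrow(x$pairs)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Semi-matrix of pairwise values
#'
#' Arranges one pairwise column (signed chi-square, AC or category) as a
#' lower-triangular species x species matrix, the tabular analogue of the
#' semi-matrix figures used to display all-pairs association results.
#'
#' @param pw a `pairwise_association`.
#' @param value which column to spread: `"chi2_signed"`, `"ac"` or
#'   `"category"`.
#' @return species x species matrix with the value in the lower triangle.
#' @export
semi_matrix <- function(pw, value = c("chi2_signed", "ac", "category")) {
  value <- match.arg(value)
  stopifnot(inherits(pw, "pairwise_association"))
  sp <- unique(c(pw$pairs$species_a, pw$pairs$species_b))
  m <- matrix(if (value == "category") NA_character_ else NA_real_,
              length(sp), length(sp), dimnames = list(sp, sp))
  for (k in seq_len(nrow(pw$pairs))) {
    i <- match(pw$pairs$species_b[k], sp)  # row below the diagonal
    j <- match(pw$pairs$species_a[k], sp)
    m[max(i, j), min(i, j)] <- pw$pairs[[value]][k]
  }
  m
}
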