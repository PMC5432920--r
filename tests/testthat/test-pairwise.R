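test_that("contingency cross-tabulates presence vectors", {
  ct <- contingency(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(ct[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  ident <- contingency(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(ident[c("a", "b", "c", "d")]),
               c(a = 2, b = 0, c = 0, d = 2))
  set.seed(42)
  A <- rbinom(50, 1, 0.4); B <- rbinom(50, 1, 0.6)
  ct50 <- contingency(A, B)
  expect_equal(ct50$N, 50)
  expect_equal(ct50$m + ct50$n, 50)
  expect_error(contingency(c(1, 0), c(1, 0, 1)), "length")
  expect_error(contingency(c(1, 2), c(1, 0)), "0/1")
})

test_that("Yates chi-square matches hand arithmetic and is signed by ad - bc", {
  # N(|ad-bc| - N/2)^2 / (mnrs) = 50 * 250^2 / (15*35*15*35)
  expect_equal(yates_chi2(as_contingency(10, 5, 5, 30)),
               50 * 250^2 / (15 * 35 * 15 * 35))
  expect_gt(yates_chi2(as_contingency(10, 5, 5, 30)), 0)
  expect_lt(yates_chi2(as_contingency(5, 10, 30, 5)), 0)
  expect_equal(yates_chi2(as_contingency(2, 2, 2, 2)), 0)
  # off-diagonal swap leaves the magnitude unchanged
  expect_equal(abs(yates_chi2(as_contingency(10, 5, 7, 30))),
               abs(yates_chi2(as_contingency(10, 7, 5, 30))))
  # zero margin: species in no quadrat (or all) is undefined
  expect_true(is.na(yates_chi2(as_contingency(0, 0, 5, 45))))
  expect_true(is.na(yates_chi2(as_contingency(10, 40, 0, 0))))
})

test_that("five-level classification uses the 3.841 / 6.635 band edges", {
  expect_equal(as.character(classify_chi2(6.88)), "extra_positive")
  expect_equal(as.character(classify_chi2(-4.02)), "negative")
  expect_equal(as.character(classify_chi2(3.840999)), "none")
  expect_equal(as.character(classify_chi2(-3.842)), "negative")
  expect_equal(as.character(classify_chi2(-6.7)), "extra_negative")
  expect_equal(as.character(classify_chi2(NA_real_)), "undefined")
  thr <- chi2_thresholds()
  expect_equal(unname(round(thr, 3)), c(3.841, 6.635))
})

test_that("AC branches reproduce worked examples and the closed-form limits", {
  # first branch: ad >= bc
  expect_equal(association_coefficient(as_contingency(10, 5, 5, 30)),
               275 / 525)
  # third branch: ad < bc and d < a
  expect_equal(association_coefficient(as_contingency(5, 4, 3, 2)),
               -2 / 30)
  # second branch: ad < bc and d >= a
  expect_equal(association_coefficient(as_contingency(1, 5, 2, 4)),
               (4 - 10) / (6 * 3))
  # complete positive (b = c = 0) and complete negative (a = d = 0)
  expect_equal(association_coefficient(as_contingency(7, 0, 0, 13)), 1)
  expect_equal(association_coefficient(as_contingency(0, 3, 4, 0)), -1)
  expect_equal(association_coefficient(as_contingency(2, 2, 2, 2)), 0)
})

test_that("chi-square and AC match independent oracles on all tables with N <= 12", {
  tabs <- all_tables(12)
  for (k in seq_len(nrow(tabs))) {
    a <- tabs$a[k]; b <- tabs$b[k]; cc <- tabs$c[k]; d <- tabs$d[k]
    ct <- as_contingency(a, b, cc, d)
    expect_equal(yates_chi2(ct), oracle_yates(a, b, cc, d),
                 info = sprintf("chi2 (%d,%d,%d,%d)", a, b, cc, d))
    ac <- association_coefficient(ct)
    expect_equal(ac, oracle_ac(a, b, cc, d),
                 info = sprintf("AC (%d,%d,%d,%d)", a, b, cc, d))
    if (!is.na(ac))
      expect_true(ac >= -1 - 1e-12 && ac <= 1 + 1e-12,
                  info = sprintf("AC bound (%d,%d,%d,%d)", a, b, cc, d))
  }
})

test_that("pair results are label-symmetric in chi-square and sign-coherent", {
  set.seed(7)
  pm <- matrix(rbinom(6 * 50, 1, runif(6, 0.2, 0.8)), nrow = 6,
               dimnames = list(paste0("s", 1:6), NULL))
  pw <- pairwise_analysis(pm)
  for (k in seq_len(nrow(pw$pairs))) {
    r <- pw$pairs[k, ]
    ct <- contingency(pm[r$species_a, ], pm[r$species_b, ])
    swapped <- contingency(pm[r$species_b, ], pm[r$species_a, ])
    expect_equal(yates_chi2(swapped), yates_chi2(ct))
    # the AC branch denominators single out b and d, so only the sign
    # (and the zero) of AC is label-symmetric, not its magnitude
    expect_equal(sign(association_coefficient(swapped)),
                 sign(association_coefficient(ct)))
    if (r$defined) {
      det <- ct$a * ct$d - ct$b * ct$c
      expect_equal(sign(r$chi2_signed), sign(det))
      if (!is.na(r$ac) && det != 0)
        expect_equal(sign(r$ac), sign(det))
    }
  }
})

test_that("pairwise analysis enumerates C(k,2) pairs and excludes undefined ones", {
  set.seed(11)
  pm <- matrix(rbinom(11 * 50, 1, 0.5), nrow = 11,
               dimnames = list(paste0("s", 1:11), NULL))
  pw <- pairwise_analysis(pm)
  expect_equal(nrow(pw$pairs), choose(11, 2))
  expect_equal(sum(pw$summary$n_pairs), choose(11, 2))
  # an all-zero species makes its 10 pairs undefined
  pm0 <- pm
  pm0["s1", ] <- 0L
  pw0 <- pairwise_analysis(pm0)
  expect_equal(sum(!pw0$pairs$defined), 10)
  expect_equal(pw0$summary$n_pairs[pw0$summary$direction == "undefined"],
               10)
  defined_counts <- pw0$summary$n_pairs[pw0$summary$direction !=
                                          "undefined"]
  expect_equal(sum(defined_counts), choose(11, 2) - 10)
  pct <- pw0$summary$percent[pw0$summary$direction == "positive"]
  expect_equal(pct, 100 *
    pw0$summary$n_pairs[pw0$summary$direction == "positive"] / 45)
})

test_that("semi-matrix places every pair once in the lower triangle", {
  set.seed(3)
  pm <- matrix(rbinom(5 * 50, 1, 0.5), nrow = 5,
               dimnames = list(paste0("s", 1:5), NULL))
  pw <- pairwise_analysis(pm)
  m <- semi_matrix(pw, "chi2_signed")
  expect_equal(sum(!is.na(m[lower.tri(m)])), choose(5, 2))
  expect_true(all(is.na(m[upper.tri(m, diag = TRUE)])))
})
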