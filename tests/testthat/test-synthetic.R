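test_that("Poisson generator hits its mean count and is seed-deterministic", {
  geom <- plot_geometry()
  counts <- vapply(1:200, function(s)
    nrow(simulate_poisson(900 / 9800, geom, seed = s)), 0)
  expect_lt(abs(mean(counts) - 900), 3 * sqrt(900 / 200) + 2)
  expect_identical(simulate_poisson(0.01, geom, seed = 4),
                   simulate_poisson(0.01, geom, seed = 4))
  p <- simulate_poisson(0.05, geom, seed = 1)
  expect_true(all(p$x >= 0 & p$x <= 140 & p$y >= 0 & p$y <= 70))
})

test_that("Thomas cluster generator keeps points in the plot with the expected count", {
  geom <- plot_geometry()
  counts <- vapply(1:100, function(s)
    nrow(simulate_cluster(30 / 9800, 30, 1, geom, seed = s)), 0)
  # 30 parents x 30 offspring, nearly all retained at sigma = 1
  expect_gt(mean(counts), 0.9 * 900)
  expect_lt(mean(counts), 1.1 * 900)
  p <- simulate_cluster(30 / 9800, 30, 1, geom, seed = 1)
  expect_true(all(p$x >= 0 & p$x <= 140 & p$y >= 0 & p$y <= 70))
  expect_identical(p, simulate_cluster(30 / 9800, 30, 1, geom, seed = 1))
})

test_that("inhibition generator respects the hard-core distance or fails loudly", {
  geom <- plot_geometry()
  p <- simulate_inhibition(4, 60, geom, seed = 2)
  expect_equal(nrow(p), 4)
  expect_gte(min(dist(p)), 60)
  p2 <- simulate_inhibition(50, 8, geom, seed = 3)
  expect_gte(min(dist(p2)), 8)
  expect_error(simulate_inhibition(40, 60, geom, seed = 1, max_tries = 2000),
               "could not place")
})

test_that("DBH generator matches the stage mix and the census threshold", {
  d <- assign_dbh(10000, seed = 1)
  expect_true(all(d >= 5))
  st <- assign_stage(d)
  expect_lt(abs(mean(st == "juvenile") - 0.413), 0.02)
  expect_lt(abs(mean(st == "medium") - 0.420), 0.02)
  d_juv <- assign_dbh(500, stage_mix = c(1, 0, 0), seed = 2)
  expect_true(all(d_juv >= 5 & d_juv < 10))
  expect_error(assign_dbh(10, stage_mix = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("community simulation is reproducible and respects plot bounds", {
  spec <- community_spec(seed = 101)
  sim1 <- simulate_community(spec)
  sim2 <- simulate_community(spec)
  expect_identical(sim1$stemmap, sim2$stemmap)
  sm <- sim1$stemmap
  expect_true(all(sm$x >= 0 & sm$x <= 140 & sm$y >= 0 & sm$y <= 70))
  expect_true(all(sm$dbh >= 5))
  expect_equal(length(unique(sm$species)), 11)
  # roughly the target stand: ~870 stems expected
  expect_gt(nrow(sm), 650)
  expect_lt(nrow(sm), 1100)
  expect_equal(sim1$truth$patterns[["sp01"]], "cluster")
})

test_that("adding a species leaves existing species' points unchanged", {
  base <- default_species_specs()
  spec1 <- community_spec(species_specs = base,
                          association_design = data.frame(
                            species_a = character(0),
                            species_b = character(0),
                            sign = character(0), strength = numeric(0)),
                          seed = 55)
  extra <- rbind(base, data.frame(label = "sp12", count = 30,
                                  pattern = "poisson", sigma = NA,
                                  min_distance = NA, mix_juvenile = 0.4,
                                  mix_medium = 0.4, mix_large = 0.2))
  spec2 <- community_spec(species_specs = extra,
                          association_design = spec1$association_design,
                          seed = 55)
  sm1 <- simulate_community(spec1)$stemmap
  sm2 <- simulate_community(spec2)$stemmap
  for (sp in base$label) {
    expect_identical(sm1[sm1$species == sp, c("x", "y", "dbh")],
                     sm2[sm2$species == sp, c("x", "y", "dbh")])
  }
})

test_that("habitat association imposes the intended quadrat-level sign", {
  geom <- plot_geometry()
  ss2 <- data.frame(label = c("A", "B"), count = 80, pattern = "poisson",
                    sigma = NA_real_, min_distance = NA_real_,
                    mix_juvenile = 0.413, mix_medium = 0.420,
                    mix_large = 0.167)
  sign_of <- function(sgn, strength, seed) {
    ad <- data.frame(species_a = "A", species_b = "B", sign = sgn,
                     strength = strength)
    sim <- simulate_community(community_spec(geom, ss2, ad, seed = seed))
    pm <- suppressWarnings(presence_matrix(sim$stemmap,
                                           species = c("A", "B")))
    ct <- contingency(pm[1, ], pm[2, ])
    sign(ct$a * ct$d - ct$b * ct$c)
  }
  pos <- vapply(1:40, function(s) sign_of("+", 0.9, s), 0)
  neg <- vapply(1:40, function(s) sign_of("-", 0.9, s), 0)
  expect_gte(mean(pos > 0), 0.9)
  expect_gte(mean(neg < 0), 0.9)
  # strength 0 leaves the pair independent: V centred on 1
  v <- vapply(1:60, function(s) {
    ad0 <- data.frame(species_a = "A", species_b = "B", sign = "+",
                      strength = 0)
    sim <- simulate_community(community_spec(geom, ss2, ad0, seed = s))
    pm <- suppressWarnings(presence_matrix(sim$stemmap,
                                           species = c("A", "B")))
    variance_ratio(pm)$V
  }, 0)
  expect_lt(abs(mean(v) - 1), 0.1)
})

test_that("community spec validates its fields", {
  expect_error(community_spec(species_specs = data.frame(label = "A")),
               "lacks column")
  ss <- default_species_specs()
  ss$pattern[1] <- "fractal"
  expect_error(community_spec(species_specs = ss), "pattern")
  ad <- default_association_design()
  ad$strength[1] <- 2
  expect_error(community_spec(association_design = ad), "strength")
  ad2 <- default_association_design()
  ad2$species_a[1] <- "ghost"
  expect_error(community_spec(association_design = ad2), "unknown")
})
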