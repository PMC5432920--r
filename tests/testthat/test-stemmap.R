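test_that("stage assignment uses left-closed, right-open DBH intervals", {
  st <- assign_stage(c(5, 9.999, 10, 24.999, 25, 80))
  expect_equal(as.character(st),
               c("juvenile", "juvenile", "medium", "medium", "large",
                 "large"))
  expect_error(assign_stage(4.9), "threshold")
  expect_error(assign_stage(NaN), "finite")
  # configurable breaks
  st2 <- assign_stage(12, breaks = c(1, 12, 30))
  expect_equal(as.character(st2), "medium")
})

test_that("stages partition the census: counts over stages sum to total", {
  sm <- simulate_community(community_spec(seed = 3))$stemmap
  expect_false(anyNA(sm$stage))
  expect_equal(sum(table(sm$stage)), nrow(sm))
})

test_that("stem-map CSV round trip preserves coordinates, DBH and labels", {
  sm <- simulate_community(community_spec(seed = 5))$stemmap
  path <- withr::local_tempfile(fileext = ".csv")
  write_stemmap(sm, path)
  back <- read_stemmap(path)
  expect_equal(back$tree_id, sm$tree_id)
  expect_equal(back$species, sm$species)
  expect_equal(back$x, sm$x, tolerance = 1e-12)
  expect_equal(back$y, sm$y, tolerance = 1e-12)
  expect_equal(back$dbh, sm$dbh, tolerance = 1e-12)
  expect_equal(as.character(back$stage), as.character(sm$stage))
})

test_that("strict ingestion rejects out-of-plot and sub-threshold rows; lenient drops them", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tree_id,species,x,y,dbh",
               "t1,A,10,10,12",
               "t2,A,-1,10,12",
               "t3,B,20,20,4.9"), path)
  expect_error(read_stemmap(path), "2 row")
  expect_message(sm <- read_stemmap(path, mode = "lenient"), "dropped 2")
  expect_equal(nrow(sm), 1L)
  # malformed inputs name the problem
  writeLines(c("tree_id,species,x,dbh", "t1,A,1,12"), path)
  expect_error(read_stemmap(path), "lacks column")
  writeLines(c("tree_id,species,x,y,dbh", "t1,A,oops,1,12"), path)
  expect_error(read_stemmap(path), "non-numeric")
  writeLines(c("tree_id,species,x,y,dbh", "t1,A,1,1,12", "t1,A,2,2,12"),
             path)
  expect_error(read_stemmap(path), "duplicate")
})

test_that("quadrat grid divides the default plot into 50 cells and enforces divisibility", {
  grid <- build_quadrat_grid(plot_geometry(140, 70, 14))
  expect_equal(grid$N, 50L)
  expect_equal(c(grid$n_cols, grid$n_rows), c(10L, 5L))
  expect_error(build_quadrat_grid(plot_geometry(140, 75, 14)),
               "divide evenly")
  lenient <- build_quadrat_grid(plot_geometry(140, 75, 14),
                                mode = "lenient")
  expect_equal(lenient$N, 50L)
  expect_equal(build_quadrat_grid(plot_geometry(14, 14, 14))$N, 1L)
})

test_that("quadrat membership is half-open with far-boundary clamping", {
  grid <- build_quadrat_grid(plot_geometry(140, 70, 14))
  expect_equal(locate_quadrat(0, 0, grid)[, c("col", "row")],
               data.frame(col = 0L, row = 0L))
  expect_equal(locate_quadrat(14, 0, grid)$col, 1L)
  expect_equal(locate_quadrat(140, 70, grid)[, c("col", "row")],
               data.frame(col = 9L, row = 4L))
  expect_error(locate_quadrat(141, 0, grid), "outside")
})

test_that("every tree lands in exactly one quadrat; occupancies sum to tree count", {
  sm <- simulate_community(community_spec(seed = 11))$stemmap
  grid <- build_quadrat_grid(geometry(sm))
  loc <- locate_quadrat(sm$x, sm$y, grid)
  expect_true(all(loc$cell >= 1 & loc$cell <= grid$N))
  expect_equal(sum(table(loc$cell)), nrow(sm))
})

test_that("presence matrix: indicators collapse counts, abundance conserves them", {
  geom <- plot_geometry(28, 28, 14, 2)
  sm <- stem_map(data.frame(tree_id = c("1", "2", "3"),
                            species = c("A", "A", "B"),
                            x = c(1, 2, 20), y = c(1, 2, 20), dbh = 10),
                 geom)
  grid <- build_quadrat_grid(geom)
  pm <- presence_matrix(sm, grid, species = c("A", "B"))
  expect_equal(unname(pm["A", 1]), 1L)  # two A stems, one indicator
  ab <- presence_matrix(sm, grid, species = c("A", "B"),
                        mode = "abundance")
  expect_equal(unname(ab["A", 1]), 2L)
  expect_equal(unname(rowSums(ab)), c(2L, 1L))
  # stage filter that empties the matrix warns but keeps zero rows
  expect_warning(z <- presence_matrix(sm, grid, species = c("A", "B"),
                                      stage_filter = "large"),
                 "no occurrence")
  expect_true(all(z == 0L))
  expect_equal(rownames(z), c("A", "B"))
  expect_error(presence_matrix(sm, grid, species = "C"), "unknown species")
})

test_that("abundance row sums equal per-species tree counts after stage filtering", {
  sm <- simulate_community(community_spec(seed = 13))$stemmap
  grid <- build_quadrat_grid(geometry(sm))
  sp <- sort(unique(sm$species))
  for (st in levels(sm$stage)) {
    ab <- suppressWarnings(
      presence_matrix(sm, grid, species = sp, stage_filter = st,
                      mode = "abundance"))
    counts <- table(factor(sm$species[sm$stage == st], levels = sp))
    expect_equal(unname(rowSums(ab)), as.vector(counts))
  }
})

test_that("geometry validation rejects impossible plots", {
  expect_error(plot_geometry(0, 70), "positive")
  expect_error(plot_geometry(140, 70, 14, 35), "half the")
  expect_error(stem_map(data.frame(tree_id = "1", species = "A",
                                   x = 150, y = 1, dbh = 10),
                        plot_geometry()), "outside the plot")
})
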