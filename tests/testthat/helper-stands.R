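# Small in-code fixtures shared across the suite.

# wrap bare coordinates into a single-species stem map
make_stand <- function(x, y, geom = plot_geometry(), species = "sp",
                       dbh = 10) {
  stem_map(data.frame(tree_id = sprintf("t%04d", seq_along(x)),
                      species = species, x = x, y = y, dbh = dbh),
           geometry = geom)
}

# jittered rectangular lattice of ~n points filling the plot
lattice_stand <- function(n = 900, geom = plot_geometry(), jitter = 0.6,
                          seed = 1) {
  set.seed(seed)
  nc <- round(sqrt(n * geom$width / geom$height))
  nr <- round(n / nc)
  gx <- (rep(seq_len(nc), nr) - 0.5) * geom$width / nc
  gy <- (rep(seq_len(nr), each = nc) - 0.5) * geom$height / nr
  m <- length(gx)
  make_stand(pmin(pmax(gx + runif(m, -jitter, jitter), 0), geom$width),
             pmin(pmax(gy + runif(m, -jitter, jitter), 0), geom$height),
             geom)
}

poisson_stand <- function(seed, n = 900, geom = plot_geometry()) {
  p <- simulate_poisson(n / (geom$width * geom$height), geom, seed = seed)
  make_stand(p$x, p$y, geom)
}

cluster_stand <- function(seed, geom = plot_geometry()) {
  p <- simulate_cluster(parent_intensity = 30 / 9800, mean_offspring = 30,
                        sigma = 1, geometry = geom, seed = seed)
  make_stand(p$x, p$y, geom)
}

# enumerate all 2x2 tables with total N <= nmax (includes degenerate ones)
all_tables <- function(nmax = 12) {
  g <- expand.grid(a = 0:nmax, b = 0:nmax, c = 0:nmax, d = 0:nmax)
  g[g$a + g$b + g$c + g$d <= nmax & g$a + g$b + g$c + g$d >= 1, ]
}

# independent Yates chi-square oracle: expected-frequency form,
# sum over the four cells of (|O - E| - 1/2)^2 / E (no clamping),
# algebraically equal to N(|ad-bc| - N/2)^2 / (mnrs)
oracle_yates <- function(a, b, c, d) {
  N <- a + b + c + d
  O <- c(a, b, c, d)
  E <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / N
  if (any(E == 0)) return(NA_real_)
  sgn <- sign(a * d - b * c)
  if (sgn == 0) return(0)
  sgn * sum((abs(O - E) - 0.5)^2 / E)
}

# independent AC oracle, written branch by branch from the definition
oracle_ac <- function(a, b, c, d) {
  det <- a * d - b * c
  if (det >= 0) den <- (a + b) * (b + d)
  else if (d >= a) den <- (a + b) * (a + c)
  else den <- (b + d) * (c + d)
  if (den == 0) { if (det == 0) return(0) else return(NA_real_) }
  det / den
}

# two-species toy stand: 3 + 1 trees, equal DBH, disjoint quadrats,
# on a 20 x 20 plot with four 10 m quadrats
toy_two_species <- function() {
  geom <- plot_geometry(20, 20, 10, 2)
  stem_map(data.frame(
    tree_id = c("a1", "a2", "a3", "b1"),
    species = c("A", "A", "A", "B"),
    x = c(2, 12, 2, 12), y = c(2, 2, 12, 12),
    dbh = 20), geometry = geom)
}
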