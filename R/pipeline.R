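#' Analysis configuration
#'
#' Collects every tunable of the stage-stratified analysis with its
#' standard default: plot geometry (140 x 70 m, 14 m quadrats, 5 m
#' buffer), stage DBH breaks (5, 10, 25 cm), the number of dominant
#' species analysed pairwise (k = 11), the chi-square classification
#' probabilities (0.95, 0.99), the variance-ratio band level (0.10
#' two-sided), and the uniform-angle settings (alpha0 = 72 degrees, random
#' band 0.475-0.517).
#'
#' @param geometry a [plot_geometry()].
#' @param stage_breaks DBH stage breakpoints, cm.
#' @param k number of dominant species for the pairwise and overall tests.
#' @param chi2_probs cumulative probabilities of the classification bands.
#' @param vr_level two-sided tail probability of the variance-ratio band.
#' @param alpha0 standard angle of the uniform angle index, degrees.
#' @param ua_bounds random band of the mean uniform angle index.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(geometry = plot_geometry(),
                            stage_breaks = c(5, 10, 25), k = 11,
                            chi2_probs = c(0.95, 0.99), vr_level = 0.10,
                            alpha0 = 72, ua_bounds = c(0.475, 0.517)) {
  stopifnot(inherits(geometry, "plot_geometry"), k >= 2)
  structure(list(geometry = geometry, stage_breaks = stage_breaks, k = k,
                 chi2_probs = chi2_probs, vr_level = vr_level,
                 alpha0 = alpha0, ua_bounds = ua_bounds),
            class = "analysis_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

#' Run the full stand analysis
#'
#' Executes every analysis stage on a stem map and writes a plain-TSV
#' report bundle: the stage-stratified importance-value table
#' (`iv_table.tsv`), pairwise association tables per stage and pooled
#' (`pairwise_<stage>.tsv`, `pairwise_all.tsv`), the overall
#' variance-ratio table (`overall_association.tsv`), per-population
#' uniform-angle summaries (`uniform_angle.tsv`) and a run manifest
#' (`manifest.yaml`) echoing the configuration, the package version and
#' the input checksum. Reruns on identical input and configuration produce
#' byte-identical reports.
#'
#' @param input a `stem_map`, or a path to a stem-map CSV.
#' @param out_dir output directory (created if needed).
#' @param config an [analysis_config()].
#' @return invisibly, a list with the in-memory results (`iv`, `dominant`,
#'   `pairwise`, `overall`, `uniform_angle`) and `files`, the paths
#'   written.
#' @export
run_analysis <- function(input, out_dir, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  geom <- config$geometry
  sm <- if (inherits(input, "stem_map")) input
        else read_stemmap(input, geometry = geom,
                          stage_breaks = config$stage_breaks)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- build_quadrat_grid(geom)
  files <- character(0)

  # importance values, stage-stratified
  iv <- iv_table_by_stage(sm, grid)
  iv_long <- do.call(rbind, lapply(names(iv), function(st) {
    if (!nrow(iv[[st]])) return(NULL)
    cbind(stage = st, iv[[st]])
  }))
  files["iv"] <- write_tsv(iv_long, file.path(out_dir, "iv_table.tsv"))

  # dominant species by pooled IV
  k <- min(config$k, nrow(iv$all))
  dominant <- select_dominant(iv$all, k)

  # pairwise association per stage and pooled
  thr <- chi2_thresholds(config$chi2_probs)
  stages <- c(stats::setNames(as.list(levels(sm$stage)), levels(sm$stage)),
              list(all = NULL))
  pairwise <- lapply(stages, function(st) {
    pm <- suppressWarnings(presence_matrix(sm, grid, species = dominant,
                                           stage_filter = st))
    pairwise_analysis(pm, thresholds = thr)
  })
  for (st in names(pairwise)) {
    files[paste0("pairwise_", st)] <-
      write_tsv(pairwise[[st]]$pairs,
                file.path(out_dir, paste0("pairwise_", st, ".tsv")))
  }

  # overall association (variance ratio) per stage and pooled
  overall <- overall_association_by_stage(sm, dominant, grid,
                                          level = config$vr_level)
  files["overall"] <- write_tsv(overall,
                                file.path(out_dir,
                                          "overall_association.tsv"))

  # uniform angle index, whole stand and per dominant population
  ua <- uniform_angle_summary(sm, species = dominant,
                              alpha0 = config$alpha0,
                              bounds = config$ua_bounds)
  files["uniform_angle"] <- write_tsv(ua,
                                      file.path(out_dir,
                                                "uniform_angle.tsv"))

  manifest <- list(
    package = "standassoc",
    version = as.character(utils::packageVersion("standassoc")),
    input = if (is.character(input)) normalizePath(input) else "<in-memory>",
    input_md5 = if (is.character(input)) unname(tools::md5sum(input))
                else NA,
    n_trees = nrow(sm),
    n_species = length(unique(sm$species)),
    dominant_species = as.character(dominant),
    config = list(width = geom$width, height = geom$height,
                  quadrat_size = geom$quadrat_size,
                  buffer_width = geom$buffer_width,
                  stage_breaks = config$stage_breaks, k = config$k,
                  chi2_probs = config$chi2_probs,
                  vr_level = config$vr_level, alpha0 = config$alpha0,
                  ua_bounds = config$ua_bounds))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  files["manifest"] <- file.path(out_dir, "manifest.yaml")

  invisible(list(stemmap = sm, iv = iv, dominant = dominant,
                 pairwise = pairwise, overall = overall,
                 uniform_angle = ua, files = files))
}

#' Simulate a stand and write it to disk
#'
#' Runs [simulate_community()] and writes the stem map as the canonical
#' CSV plus the generating truth (per-species pattern, intended pair
#' associations, seed) as YAML, reporting per-species counts.
#'
#' @param spec a [community_spec()], or a path to a YAML file with fields
#'   `geometry`, `species_specs`, `association_design`, `seed`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `stemmap`, `truth` and `files`.
#' @export
run_simulate <- function(spec = community_spec(), out_dir) {
  if (is.character(spec)) spec <- read_community_spec(spec)
  stopifnot(inherits(spec, "community_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_community(spec)
  stems_path <- file.path(out_dir, "stems.csv")
  write_stemmap(sim$stemmap, stems_path)
  truth_path <- file.path(out_dir, "truth.yaml")
  yaml::write_yaml(list(
    seed = sim$truth$seed,
    patterns = as.list(sim$truth$patterns),
    associations = if (nrow(sim$truth$associations))
      lapply(seq_len(nrow(sim$truth$associations)), function(i)
        as.list(sim$truth$associations[i, ])) else list()),
    truth_path)
  counts <- table(sim$stemmap$species)
  message("simulated ", nrow(sim$stemmap), " trees in ", length(counts),
          " species (", paste(names(counts), counts, sep = "=",
                              collapse = ", "), ")")
  invisible(list(stemmap = sim$stemmap, truth = sim$truth,
                 files = c(stems = stems_path, truth = truth_path)))
}

#' Read a community spec from YAML
#'
#' @param path YAML file with optional fields `geometry` (width, height,
#'   quadrat_size, buffer_width), `species_specs` (list of per-species
#'   records), `association_design` (list of pair records) and `seed`;
#'   missing fields fall back to the defaults of [community_spec()].
#' @return a [community_spec()].
#' @export
read_community_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  geom <- if (is.null(y$geometry)) plot_geometry()
          else do.call(plot_geometry, y$geometry)
  ss <- if (is.null(y$species_specs)) default_species_specs()
        else do.call(rbind, lapply(y$species_specs, function(r) {
          r <- utils::modifyList(list(sigma = NA_real_,
                                      min_distance = NA_real_), r)
          as.data.frame(r, stringsAsFactors = FALSE)
        }))
  ad <- if (is.null(y$association_design)) default_association_design()
        else if (!length(y$association_design))
          data.frame(species_a = character(0), species_b = character(0),
                     sign = character(0), strength = numeric(0))
        else do.call(rbind, lapply(y$association_design, function(r)
          as.data.frame(r, stringsAsFactors = FALSE)))
  community_spec(geometry = geom, species_specs = ss,
                 association_design = ad,
                 seed = if (is.null(y$seed)) 1L else y$seed)
}
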