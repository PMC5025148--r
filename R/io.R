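# Readers/writers for the standard formats (CSV, GeoJSON) and the
# end-to-end pipeline driver with a run manifest. Conventions, enforced
# here once: coordinates are WGS84 decimal degrees, areas km^2, grid cell
# membership half-open [min, max).

KD_TRAIT_COLUMNS <- c("species_id", "subfamily", "tribe", "genus",
                      "subgenus", "species", "status", "frac_SA",
                      "frac_sA", "n_provinces", "endemic_to_SA",
                      "marginal_in_SA", "mobility_class", "trophic_class")

#' Read an occurrence CSV
#'
#' Expects columns `species_id`, `lon`, `lat` and optionally `date` and
#' `collector`. Malformed rows (missing species, non-finite or
#' out-of-range coordinates) are excluded and collected into an error
#' report attached as attribute `"errors"`, not silently dropped.
#'
#' @param path CSV file path.
#' @return Data frame of valid records.
#' @export
read_occurrences <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("species_id", "lon", "lat")
  miss <- setdiff(req, names(d))
  if (length(miss)) kd_stop("occurrence file lacks column(s): %s",
                            paste(miss, collapse = ", "))
  if (!"date" %in% names(d)) d$date <- NA_character_
  if (!"collector" %in% names(d)) d$collector <- NA_character_
  d$lon <- suppressWarnings(as.numeric(d$lon))
  d$lat <- suppressWarnings(as.numeric(d$lat))
  bad <- is.na(d$species_id) | d$species_id == "" |
    !is.finite(d$lon) | !is.finite(d$lat) |
    d$lon < -180 | d$lon > 180 | d$lat < -90 | d$lat > 90
  errors <- NULL
  if (any(bad)) {
    errors <- cbind(row = which(bad), d[bad, req, drop = FALSE])
    kd_warn("%d malformed record(s) excluded (see attr(x, 'errors'))",
            sum(bad))
  }
  out <- d[!bad, c(req, "date", "collector"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Write an occurrence table to CSV
#' @param occurrences Occurrence data frame.
#' @param path Output path.
#' @export
write_occurrences <- function(occurrences, path) {
  write.csv(occurrences[, c("species_id", "lon", "lat", "date",
                            "collector")],
            path, row.names = FALSE)
  invisible(path)
}

#' Read a species trait CSV
#'
#' Requires the standard header (species_id, taxonomy, status,
#' distribution-rule inputs, mobility and trophic classes); `tribe` and
#' `subgenus` may be empty.
#'
#' @param path CSV file path.
#' @return Validated trait data frame.
#' @export
read_traits <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(KD_TRAIT_COLUMNS, names(d))
  if (length(miss)) kd_stop("trait file lacks column(s): %s",
                            paste(miss, collapse = ", "))
  d$tribe <- ifelse(is.na(d$tribe), "", as.character(d$tribe))
  d$subgenus <- ifelse(is.na(d$subgenus), "", as.character(d$subgenus))
  if (anyDuplicated(d$species_id)) kd_stop("duplicate species_id")
  d$endemic_to_SA <- as.logical(d$endemic_to_SA)
  d$marginal_in_SA <- as.logical(d$marginal_in_SA)
  d[, KD_TRAIT_COLUMNS]
}

#' Write a species trait table to CSV
#' @param traits Trait data frame.
#' @param path Output path.
#' @export
write_traits <- function(traits, path) {
  write.csv(traits[, KD_TRAIT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes scoring, range metrics, gridding, hotspot delineation and
#' classification, association tests, and (optionally) the spatial
#' pairwise models, comparative phylogenetic ranking and accumulation
#' curves, in that order. When `out_dir` is given every artifact is
#' written (CSV/GeoJSON/Newick) together with a JSON run manifest
#' (configuration, seed, package version, per-stage record counts and an
#' MD5 content hash); reruns with identical inputs and seed reproduce the
#' manifest hash.
#'
#' @param traits Trait data frame (or path to CSV).
#' @param occurrences Occurrence data frame (or path to CSV).
#' @param region Region ring matrix, list of rings, or GeoJSON path.
#' @param hotspot_polygons List of rings or GeoJSON path (optional; if
#'   `NULL` the hotspot classification stages are skipped).
#' @param out_dir Output directory (optional).
#' @param cell_deg Grid cell size in degrees (default 1).
#' @param origin Graticule origin (default `c(0, 0)`).
#' @param top_fraction Hotspot percentile fraction (default 0.10).
#' @param inclusion_rule Polygon inclusion rule (default 0.5).
#' @param correct Continuity correction for association tests (default
#'   `TRUE`).
#' @param seed Seed for permutation tests (default 1).
#' @param run_spatial,run_phylo,run_sac Toggle the optional stages.
#' @return List bundle: `scores`, `ranges`, `grid`, `metrics`, `flags`,
#'   `hotspots` (cell-id sets), `associations`, `venn`, `comparison`,
#'   `tree`, `pgls`, `spatial`, `sac`, `manifest`.
#' @export
run_pipeline <- function(traits, occurrences, region,
                         hotspot_polygons = NULL, out_dir = NULL,
                         cell_deg = 1, origin = c(0, 0),
                         top_fraction = 0.10, inclusion_rule = 0.5,
                         correct = TRUE, seed = 1,
                         run_spatial = FALSE, run_phylo = TRUE,
                         run_sac = TRUE) {
  if (is.character(traits)) traits <- read_traits(traits)
  if (is.character(occurrences)) occurrences <- read_occurrences(occurrences)
  if (is.character(region)) region <- read_geojson_polygons(region)
  if (is.character(hotspot_polygons)) {
    hotspot_polygons <- read_geojson_polygons(hotspot_polygons)
  }
  counts <- list(n_species_input = nrow(traits),
                 n_records_input = nrow(occurrences))

  # stage 1: scoring (DD/NE excluded here and from all later stages)
  scores <- score_species(traits)
  excluded <- attr(scores, "excluded")
  counts$n_species_excluded_dd_ne <- length(excluded)
  counts$n_species_scored <- nrow(scores)
  drop_rec <- occurrences$species_id %in% excluded
  if (any(drop_rec)) {
    message(sprintf("dropping %d record(s) of DD/NE species", sum(drop_rec)))
    occurrences <- occurrences[!drop_rec, , drop = FALSE]
  }
  unknown <- setdiff(unique(occurrences$species_id), traits$species_id)
  if (length(unknown)) {
    kd_stop("records for species missing from the trait table: %s",
            paste(unknown, collapse = ", "))
  }
  counts$n_records_used <- nrow(occurrences)

  # stage 2: range metrics
  ranges <- summarize_ranges(occurrences)
  counts$n_species_endemic <- sum(ranges$endemic)

  # stage 3: gridding
  grid <- build_fishnet(region, cell_deg = cell_deg, origin = origin)
  assigned <- assign_records(occurrences, grid)
  counts$n_cells <- nrow(grid)
  counts$n_records_unassigned <- attr(assigned, "n_unassigned")
  metrics <- cell_metrics(assigned, grid, scores, ranges)
  counts$n_cells_with_data <- sum(!is.na(metrics$richness_total))

  # stage 4: hotspot delineation
  hot_count <- count_based_hotspots(metrics, top_fraction)
  hot_score <- score_based_hotspots(metrics, top_fraction)
  has <- !is.na(metrics$richness_total)
  flags <- data.frame(
    cell_id = metrics$cell_id,
    has_data = has,
    count_based = ifelse(has, metrics$cell_id %in% hot_count, NA),
    score_based = ifelse(has, metrics$cell_id %in% hot_score, NA),
    stringsAsFactors = FALSE)

  associations <- NULL; venn <- NULL; comparison <- NULL; sac <- NULL
  if (!is.null(hotspot_polygons)) {
    incl <- polygon_inclusion(grid, hotspot_polygons, rule = inclusion_rule)
    flags$inclusion_fraction <- incl$inclusion_fraction
    flags$biodiversity <- ifelse(has, incl$biodiversity, NA)
    dsub <- flags[has, , drop = FALSE]
    associations <- data.frame(
      pair = c("count_vs_biodiversity", "score_vs_biodiversity",
               "count_vs_score"),
      chisq = NA_real_, df = 1L, p.value = NA_real_,
      stringsAsFactors = FALSE)
    tests <- list(
      chi2_association(dsub$count_based, dsub$biodiversity, correct),
      chi2_association(dsub$score_based, dsub$biodiversity, correct),
      chi2_association(dsub$count_based, dsub$score_based, correct))
    associations$chisq <- vapply(tests, `[[`, numeric(1), "statistic")
    associations$p.value <- vapply(tests, `[[`, numeric(1), "p.value")
    venn <- venn_counts(dsub$count_based, dsub$score_based,
                        dsub$biodiversity)
    comparison <- compare_hotspot_vs_non(metrics[has, , drop = FALSE],
                                         dsub$biodiversity)
    if (run_sac) {
      comm <- community_matrix(assigned)
      hotcells <- dsub$cell_id[dsub$biodiversity]
      a <- comm[rownames(comm) %in% hotcells, , drop = FALSE]
      b <- comm[!(rownames(comm) %in% hotcells), , drop = FALSE]
      if (nrow(a) >= 2 && nrow(b) >= 2) {
        sac <- list(sample = compare_sacs(a, b, type = "sample"),
                    individual = compare_sacs(a, b, type = "individual"))
      }
    }
  }

  tree <- NULL; pgls <- NULL
  if (run_phylo) {
    tree <- taxonomy_to_tree(traits[!(traits$species_id %in% excluded), ])
    pgls <- score_model_set(scores, tree)
  }
  spatial <- NULL
  if (run_spatial) {
    spatial <- pairwise_measure_models(metrics, grid, seed = seed)
  }

  manifest <- list(package = "katydiv",
                   version = as.character(packageVersion("katydiv")),
                   r_version = as.character(getRversion()),
                   seed = seed,
                   parameters = list(cell_deg = cell_deg, origin = origin,
                                     top_fraction = top_fraction,
                                     inclusion_rule = inclusion_rule,
                                     continuity_correction = correct),
                   counts = counts)
  bundle <- list(scores = scores, ranges = ranges, grid = grid,
                 metrics = metrics, flags = flags,
                 hotspots = list(count_based = hot_count,
                                 score_based = hot_score),
                 associations = associations, venn = venn,
                 comparison = comparison, tree = tree, pgls = pgls,
                 spatial = spatial, sac = sac, manifest = manifest)
  if (!is.null(out_dir)) {
    bundle$manifest <- write_bundle(bundle, out_dir)
  }
  bundle
}

#' Write pipeline outputs and the run manifest
#' @noRd
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write.csv(bundle$scores, fp("scores.csv"), row.names = FALSE)
  write.csv(bundle$ranges, fp("ranges.csv"), row.names = FALSE)
  write.csv(as.data.frame(bundle$metrics), fp("cell_metrics.csv"),
            row.names = FALSE, na = "NA")
  write.csv(bundle$flags, fp("hotspot_flags.csv"), row.names = FALSE)
  write_grid_geojson(bundle$grid, fp("grid.geojson"))
  if (!is.null(bundle$associations)) {
    write.csv(bundle$associations, fp("associations.csv"),
              row.names = FALSE)
    write.csv(data.frame(region = names(bundle$venn),
                         n_cells = as.integer(bundle$venn)),
              fp("venn.csv"), row.names = FALSE)
    write.csv(bundle$comparison, fp("hotspot_comparison.csv"),
              row.names = FALSE)
  }
  if (!is.null(bundle$tree)) {
    ape::write.tree(bundle$tree, fp("tree.nwk"))
    write.csv(bundle$pgls$ranking, fp("model_ranking.csv"),
              row.names = FALSE)
  }
  if (!is.null(bundle$spatial)) {
    write.csv(bundle$spatial, fp("spatial_models.csv"), row.names = FALSE)
  }
  manifest <- bundle$manifest
  hashed <- sort(setdiff(list.files(out_dir, full.names = TRUE),
                         fp("manifest.json")))
  manifest$files <- basename(hashed)
  manifest$content_md5 <- unname(tools::md5sum(hashed))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}
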