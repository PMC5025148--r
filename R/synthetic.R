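# Synthetic study systems with planted ground truth: a notched rectangular
# study region, hotspot polygons, a species pool with phylogenetically
# correlated traits on a taxonomy-derived tree, and spatially clustered
# occurrence records whose range sizes track the distribution score.

#' Default synthetic study region
#'
#' A 10 x 8 degree rectangle (lon 20--30, lat -35 to -27) with a
#' triangular "coastline" notch bitten out of the southern edge, so that
#' fishnet cells along the notch are clipped and land-area weighting is
#' exercised.
#'
#' @return A (lon, lat) ring matrix.
#' @export
synthetic_region <- function() {
  cbind(lon = c(20, 23.5, 24.5, 25.5, 30, 30, 20),
        lat = c(-35, -35, -33.6, -35, -35, -27, -27))
}

#' Default synthetic hotspot polygons
#'
#' Two full-height coastal strips (western and eastern) jointly covering
#' about `hotspot_fraction` of the study region; they avoid the coastline
#' notch so the polygons lie entirely on land.
#'
#' @param hotspot_fraction Target area fraction in (0, 1).
#' @return Named list of (lon, lat) ring matrices.
#' @export
synthetic_hotspots <- function(hotspot_fraction = 0.3) {
  if (hotspot_fraction <= 0 || hotspot_fraction >= 1) {
    kd_stop("hotspot_fraction must be in (0, 1)")
  }
  # region is ~78.6 deg^2; strips are 8 deg tall
  w_total <- hotspot_fraction * 78.6 / 8
  w_west <- min(w_total * 0.55, 3.4)
  w_east <- min(w_total - w_west, 4.4)
  list(
    west = cbind(lon = c(20, 20 + w_west, 20 + w_west, 20),
                 lat = c(-35, -35, -27, -27)),
    east = cbind(lon = c(30 - w_east, 30, 30, 30 - w_east),
                 lat = c(-35, -35, -27, -27)))
}

#' Rejection-sample points inside (or outside) polygon rings
#' @noRd
sample_point <- function(region, inside = NULL, outside = NULL,
                         max_tries = 2000) {
  bb <- apply(region, 2, range)
  for (k in seq_len(max_tries)) {
    p <- c(runif(1, bb[1, 1], bb[2, 1]), runif(1, bb[1, 2], bb[2, 2]))
    if (!point_in_ring(p[1], p[2], region)) next
    in_target <- if (is.null(inside)) TRUE else
      any(vapply(inside, function(r) point_in_ring(p[1], p[2], r),
                 logical(1)))
    out_ok <- if (is.null(outside)) TRUE else
      !any(vapply(outside, function(r) point_in_ring(p[1], p[2], r),
                  logical(1)))
    if (in_target && out_ok) return(p)
  }
  kd_stop("rejection sampling failed; target area too small?")
}

#' Random nested taxonomy (subfamily -> genus -> subgenus)
#' @noRd
random_taxonomy <- function(n) {
  n_sf <- 8L
  sf_w <- runif(n_sf, 0.3, 1.3)
  subfam <- paste0("subfam", sample.int(n_sf, n, replace = TRUE,
                                        prob = sf_w))
  genus <- character(n); subgenus <- rep("", n)
  gi <- 0L
  for (sfn in unique(subfam)) {
    i <- which(subfam == sfn)
    n_gen <- max(1L, min(length(i), 1L + stats::rpois(1, 1.6)))
    gids <- sample.int(n_gen, length(i), replace = TRUE)
    for (g in unique(gids)) {
      gi <- gi + 1L
      j <- i[gids == g]
      genus[j] <- sprintf("gen%02d", gi)
      if (length(j) >= 4 && runif(1) < 0.5) {
        sg <- sample(1:2, length(j), replace = TRUE)
        subgenus[j] <- sprintf("%s_sg%d", genus[j], sg)
      }
    }
  }
  data.frame(subfamily = subfam, genus = genus, subgenus = subgenus,
             stringsAsFactors = FALSE)
}

#' Draw a standardized trait with phylogenetic signal
#' @noRd
phylo_latent <- function(chol_C, sd_diag) {
  drop(crossprod(chol_C, rnorm(ncol(chol_C)))) / sd_diag
}

#' Simulate a complete synthetic dataset with planted ground truth
#'
#' Generates every input the pipeline consumes: a species trait table on a
#' random nested taxonomy, spatially clustered occurrence records, the
#' study-region polygon and hotspot polygons — plus the ground truth
#' needed to test recovery. The generative model:
#' \itemize{
#'   \item Traits carry phylogenetic signal: latent Gaussian fields with
#'     Pagel's lambda = `lambda` on the taxonomy tree drive range size,
#'     mobility and trophic specialization (mobility and trophic latents
#'     correlate with the narrowness latent, so threatened species tend
#'     to be flightless specialists).
#'   \item Red List statuses are assigned by narrowness rank at the
#'     configured marginal proportions; each species then receives a true
#'     range area (log-uniform within its status band) consistent with
#'     range-threshold screening, and the recorded status is perturbed to
#'     a neighbouring category with probability `status_noise`.
#'   \item Each species occupies a Gaussian range kernel whose width
#'     decreases with its distribution score; narrow-range specialist
#'     species (D = 3, LH >= 2) place their kernels inside hotspot
#'     polygons with odds multiplied by `enrichment`.
#'   \item Records are allocated with a mild bias toward widespread
#'     species (museum collections overrepresent common taxa), with a
#'     floor of 3 records per species, and sampled from the kernels,
#'     truncated to the region.
#' }
#' All randomness flows from `seed` through per-stage derived seeds
#' (taxonomy/traits, geography, records), so the same seed gives
#' identical outputs and stage-level reuse is reproducible.
#'
#' @param n_species Number of species (default 130).
#' @param n_records Total occurrence records (default 1100; must be at
#'   least `3 * n_species`).
#' @param seed Integer seed.
#' @param hotspot_fraction Area fraction of the region covered by hotspot
#'   polygons (default 0.3).
#' @param enrichment Odds multiplier (>= 1) for specialist kernels to sit
#'   inside hotspot polygons (default 4; 1 = no planted association).
#' @param lambda True phylogenetic signal of the latent traits (default
#'   0.8).
#' @param dd_fraction Fraction of species recorded as Data Deficient
#'   (default 0.12).
#' @param status_probs Marginal status proportions among assessed species
#'   (default approximately LC 0.65, VU 0.146, EN 0.085, CR 0.119).
#' @param status_noise Probability of perturbing a recorded status to a
#'   neighbouring category (default 0.05).
#' @param cell_deg Grid resolution used for the planted hotspot truth
#'   (default 1, matching the pipeline default).
#' @param presence_threshold Minimum expected detection probability for a
#'   species to count as truly present in a cell of the planted truth
#'   (default 0.5).
#' @return List with elements `traits` (trait table in the standard
#'   column order), `occurrences` (`species_id`, `lon`, `lat`, `date`,
#'   `collector`), `region` (ring matrix), `hotspot_polygons` (list of
#'   rings) and `ground_truth` (list: `status_screened`, `eoo_true_km2`,
#'   `centers`, `sd_km`, `specialists`, `lambda`, `latent_narrowness`,
#'   `true_scores` per cell, `true_hotspot_cells`, `hotspot_area_fraction`).
#' @export
simulate_dataset <- function(n_species = 130, n_records = 1100, seed = 1,
                             hotspot_fraction = 0.3, enrichment = 4,
                             lambda = 0.8, dd_fraction = 0.12,
                             status_probs = c(LC = 0.650, VU = 0.146,
                                              EN = 0.085, CR = 0.119),
                             status_noise = 0.05, cell_deg = 1,
                             presence_threshold = 0.5) {
  if (n_species < 10 || n_records < 3 * n_species) {
    kd_stop("need n_species >= 10 and n_records >= 3 * n_species")
  }
  if (hotspot_fraction <= 0 || hotspot_fraction >= 1) {
    kd_stop("hotspot_fraction must be in (0, 1)")
  }
  if (enrichment < 1) kd_stop("enrichment must be >= 1")
  if (lambda < 0 || lambda > 1) kd_stop("lambda must be in [0, 1]")
  status_probs <- status_probs / sum(status_probs)

  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1, 3)

  # ---- stage 1: taxonomy, tree, traits ---------------------------------
  set.seed(stage_seeds[1])
  ids <- sprintf("sp%03d", seq_len(n_species))
  tax <- random_taxonomy(n_species)
  traits0 <- cbind(data.frame(species_id = ids, stringsAsFactors = FALSE),
                   tax)
  tree <- taxonomy_to_tree(traits0)
  C <- lambda_covariance(tree, lambda)[ids, ids]
  L <- chol(C)
  sdC <- sqrt(diag(C))
  g_narrow <- phylo_latent(L, sdC)
  # mobility/trophic latents track narrowness: narrow-range species tend
  # to be flightless diet specialists (the D ~ LH coupling)
  g_mob <- 0.85 * g_narrow + sqrt(1 - 0.85^2) * phylo_latent(L, sdC)
  g_tro <- 0.80 * g_narrow + sqrt(1 - 0.80^2) * phylo_latent(L, sdC)

  # statuses by narrowness rank at the configured proportions
  n_cat <- round(status_probs * n_species)
  n_cat["LC"] <- n_species - sum(n_cat[c("VU", "EN", "CR")])
  rank_narrow <- order(g_narrow + rnorm(n_species, 0, 0.9),
                       decreasing = TRUE)
  status_true <- character(n_species)
  cuts <- cumsum(n_cat[c("CR", "EN", "VU", "LC")])
  status_true[rank_narrow[seq_len(cuts[1])]] <- "CR"
  status_true[rank_narrow[(cuts[1] + 1):cuts[2]]] <- "EN"
  status_true[rank_narrow[(cuts[2] + 1):cuts[3]]] <- "VU"
  status_true[rank_narrow[(cuts[3] + 1):cuts[4]]] <- "LC"

  bands <- list(CR = c(20, 100), EN = c(150, 4500),
                VU = c(5500, 19000), LC = c(21000, 150000))
  eoo_true <- setNames(vapply(status_true, function(s) {
    b <- bands[[s]]
    exp(runif(1, log(b[1]), log(b[2])))
  }, numeric(1)), ids)
  stopifnot(identical(unname(screen_criterion_b(eoo_true)), status_true))

  # recorded status: neighbour perturbation, then DD masking
  levs <- c("LC", "VU", "EN", "CR")
  status_rec <- status_true
  flip <- runif(n_species) < status_noise
  for (i in which(flip)) {
    k <- match(status_true[i], levs)
    k2 <- if (k == 1) 2L else if (k == 4) 3L else k + sample(c(-1L, 1L), 1)
    status_rec[i] <- levs[k2]
  }
  dd <- runif(n_species) < dd_fraction
  status_rec[dd] <- "DD"

  D <- as.integer(cut(eoo_true, c(-Inf, 5000, 20000, 120000, Inf),
                      labels = FALSE))
  D <- 4L - D  # narrowest band -> 3
  # distribution-rule inputs consistent with D
  frac_SA <- frac_sA <- numeric(n_species)
  n_prov <- integer(n_species)
  endemic <- marginal <- logical(n_species)
  for (i in seq_len(n_species)) {
    if (D[i] == 3) {
      endemic[i] <- TRUE; marginal[i] <- FALSE
      frac_SA[i] <- runif(1, 0.01, 0.15); frac_sA[i] <- frac_SA[i]
      n_prov[i] <- sample(1:2, 1)
    } else if (D[i] == 2) {
      if (runif(1) < 0.85) {
        endemic[i] <- TRUE; marginal[i] <- FALSE
        frac_SA[i] <- runif(1, 0.35, 0.6); frac_sA[i] <- frac_SA[i] * 0.9
        n_prov[i] <- sample(3:6, 1)
      } else {
        endemic[i] <- FALSE; marginal[i] <- TRUE
        frac_SA[i] <- runif(1, 0.02, 0.2); frac_sA[i] <- runif(1, 0.7, 0.95)
        n_prov[i] <- sample(1:2, 1)
      }
    } else if (D[i] == 1) {
      endemic[i] <- FALSE; marginal[i] <- FALSE
      if (runif(1) < 0.7) {
        frac_SA[i] <- runif(1, 0.68, 0.74); frac_sA[i] <- runif(1, 0.68, 0.95)
        n_prov[i] <- sample(4:8, 1)
      } else {
        frac_SA[i] <- runif(1, 0.1, 0.32); frac_sA[i] <- runif(1, 0.7, 0.95)
        n_prov[i] <- sample(1:3, 1)
      }
    } else {
      endemic[i] <- FALSE; marginal[i] <- FALSE
      frac_SA[i] <- runif(1, 0.76, 0.98); frac_sA[i] <- runif(1, 0.76, 0.98)
      n_prov[i] <- sample(7:9, 1)
    }
  }
  stopifnot(identical(
    score_distribution(frac_SA, frac_sA, n_prov, endemic, marginal), D))

  mob_cut <- qnorm(cumsum(c(0.40, 0.25)))   # flighted / partial / flightless
  tro_cut <- qnorm(cumsum(c(0.25, 0.20, 0.35)))
  M <- findInterval(g_mob, mob_cut)
  Tr <- findInterval(g_tro, tro_cut)
  mob_lev <- c("fully_flighted", "partial_or_one_sex", "flightless")
  tro_lev <- c("omnivorous", "predatory", "herbivorous_polyphagous",
               "herbivorous_monophagous")
  LH <- score_life_history(M, Tr)

  traits <- data.frame(
    species_id = ids, subfamily = tax$subfamily, tribe = "",
    genus = tax$genus, subgenus = tax$subgenus, species = ids,
    status = status_rec, frac_SA = frac_SA, frac_sA = frac_sA,
    n_provinces = n_prov, endemic_to_SA = endemic,
    marginal_in_SA = marginal,
    mobility_class = mob_lev[M + 1], trophic_class = tro_lev[Tr + 1],
    stringsAsFactors = FALSE)

  # ---- stage 2: geography ----------------------------------------------
  set.seed(stage_seeds[2])
  region <- synthetic_region()
  hps <- synthetic_hotspots(hotspot_fraction)
  area_region <- ring_area_km2(region)
  f_h <- sum(vapply(hps, ring_area_km2, numeric(1))) / area_region
  specialists <- D == 3 & LH >= 2
  # narrow-range specialists cluster in radiation cores; each core sits
  # inside the hotspot polygons with odds multiplied by `enrichment`
  p_core_hot <- enrichment * f_h / (enrichment * f_h + (1 - f_h))
  n_core <- max(3L, round(sum(specialists) / 2))
  cores <- matrix(NA_real_, n_core, 2)
  used_cells <- character(0)
  for (k in seq_len(n_core)) {
    for (tries in 1:50) {
      p <- if (runif(1) < p_core_hot) sample_point(region, inside = hps)
      else sample_point(region, outside = hps)
      # snap radiation cores to the center of their grid cell so the
      # planted unit matches the analysis resolution; cores occupy
      # distinct cells
      ps <- floor(p / cell_deg) * cell_deg + cell_deg / 2
      if (!point_in_ring(ps[1], ps[2], region)) ps <- p
      key <- paste(floor(ps / cell_deg), collapse = "_")
      if (!(key %in% used_cells)) break
    }
    used_cells <- c(used_cells, key)
    cores[k, ] <- ps
  }
  # ordinary species centers are inset from the region boundary so edge
  # cells are covered by kernel tails rather than orphan range centers
  bb <- apply(region, 2, range)
  inset <- cbind(lon = c(bb[1, 1] + 0.8, bb[2, 1] - 0.8,
                         bb[2, 1] - 0.8, bb[1, 1] + 0.8),
                 lat = c(bb[1, 2] + 0.8, bb[1, 2] + 0.8,
                         bb[2, 2] - 0.8, bb[2, 2] - 0.8))
  centers <- matrix(NA_real_, n_species, 2,
                    dimnames = list(ids, c("lon", "lat")))
  spec_core <- integer(n_species)
  spec_core[which(specialists)] <-
    (seq_len(sum(specialists)) - 1L) %% n_core + 1L
  for (i in seq_len(n_species)) {
    if (specialists[i]) {
      co <- cores[spec_core[i], ]
      for (tries in 1:50) {
        p <- co + rnorm(2, 0, 0.12)
        if (point_in_ring(p[1], p[2], region)) break
        p <- co
      }
      centers[i, ] <- p
    } else {
      centers[i, ] <- sample_point(region, inside = list(inset))
    }
  }
  sd_km <- sqrt(eoo_true / pi) / 2

  # ---- stage 3: records -------------------------------------------------
  set.seed(stage_seeds[3])
  w <- eoo_true^0.45
  extra <- as.vector(stats::rmultinom(1, n_records - 3L * n_species,
                                      w / sum(w)))
  n_i <- 3L + extra
  occ <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    sx <- sd_km[i] / (111.32 * cos(centers[i, 2] * pi / 180))
    sy <- sd_km[i] / 110.57
    pts <- matrix(NA_real_, n_i[i], 2)
    for (k in seq_len(n_i[i])) {
      for (tries in 1:50) {
        p <- centers[i, ] + rnorm(2) * c(sx, sy)
        if (point_in_ring(p[1], p[2], region)) break
        p <- centers[i, ]
      }
      pts[k, ] <- p
    }
    occ[[i]] <- data.frame(species_id = ids[i], lon = pts[, 1],
                           lat = pts[, 2], stringsAsFactors = FALSE)
  }
  occurrences <- do.call(rbind, occ)
  occurrences$date <- as.character(
    as.Date("1960-01-01") + sample.int(20000, nrow(occurrences),
                                       replace = TRUE))
  occurrences$collector <- "synthetic"
  rownames(occurrences) <- NULL

  # ---- planted hotspot truth -------------------------------------------
  grid <- build_fishnet(region, cell_deg = cell_deg)
  scores <- suppressMessages(score_species(traits))
  smap <- setNames(scores[["T+D+LH"]], scores$species_id)
  assessed <- ids[!dd]
  # truth: a species is truly present where a faithful sampler would be
  # expected to find it — detection probability 1 - (1 - mass)^E[records]
  # above `presence_threshold`, with mass the kernel probability in the
  # cell rectangle and E[records] the deterministic allocation expectation
  w_rec <- eoo_true^0.45
  e_rec <- setNames(3 + (n_records - 3 * n_species) * w_rec / sum(w_rec),
                    ids)
  sx_all <- sd_km / (111.32 * cos(centers[, 2] * pi / 180))
  sy_all <- sd_km / 110.57
  true_scores <- rep(NA_real_, nrow(grid))
  names(true_scores) <- grid$cell_id
  rect_km2 <- vapply(seq_len(nrow(grid)), function(ci) ring_area_km2(cbind(
    lon = c(grid$lon0[ci], grid$lon1[ci], grid$lon1[ci], grid$lon0[ci]),
    lat = c(grid$lat0[ci], grid$lat0[ci], grid$lat1[ci], grid$lat1[ci]))),
    numeric(1))
  for (ci in seq_len(nrow(grid))) {
    mass <- (pnorm(grid$lon1[ci], centers[assessed, 1], sx_all[assessed]) -
               pnorm(grid$lon0[ci], centers[assessed, 1], sx_all[assessed])) *
      (pnorm(grid$lat1[ci], centers[assessed, 2], sy_all[assessed]) -
         pnorm(grid$lat0[ci], centers[assessed, 2], sy_all[assessed]))
    # coastline clipping removes sampling area; scale kernel mass by the
    # land fraction of the cell rectangle
    mass <- mass * min(1, grid$land_area_km2[ci] / rect_km2[ci])
    pdet <- 1 - (1 - mass)^e_rec[assessed]
    if (sum(pdet) > presence_threshold) {
      true_scores[ci] <- sum(pdet * smap[assessed]) / sum(pdet)
    }
  }
  true_hot <- suppressWarnings(top_percentile_cells(true_scores, 0.10))

  list(traits = traits, occurrences = occurrences, region = region,
       hotspot_polygons = hps,
       ground_truth = list(
         status_screened = setNames(status_true, ids),
         eoo_true_km2 = setNames(eoo_true, ids),
         centers = centers, sd_km = setNames(sd_km, ids),
         specialists = ids[specialists], lambda = lambda,
         latent_narrowness = setNames(g_narrow, ids),
         true_scores = true_scores,
         true_hotspot_cells = as.character(true_hot),
         hotspot_area_fraction = f_h),
       config = list(n_species = n_species, n_records = n_records,
                     seed = seed, hotspot_fraction = hotspot_fraction,
                     enrichment = enrichment, lambda = lambda,
                     dd_fraction = dd_fraction, status_noise = status_noise,
                     cell_deg = cell_deg,
                     presence_threshold = presence_threshold))
}

#' Hand-built worked example dataset
#'
#' A tiny six-species, 3 x 3 cell dataset over the unit square grid
#' lon/lat 0--3 with every downstream metric computable by hand: one
#' maximal-score narrow endemic (composite 9), one zero-score widespread
#' species, intermediate species, and one Data Deficient species whose
#' records must be excluded. The matching hand-computed expected outputs
#' ship under `inst/extdata/worked/`.
#'
#' @return List with `traits`, `occurrences`, `region` (ring matrix) and
#'   `hotspot_polygons` (one ring covering the western 1.6 degrees).
#' @export
worked_fixture <- function() {
  traits <- data.frame(
    species_id = c("spA", "spB", "spC", "spD", "spE", "spF"),
    subfamily = c("SFa", "SFa", "SFa", "SFb", "SFb", "SFb"),
    tribe = "",
    genus = c("genA", "genA", "genB", "genC", "genC", "genD"),
    subgenus = c("genA_sg1", "genA_sg1", "", "", "", ""),
    species = c("spA", "spB", "spC", "spD", "spE", "spF"),
    status = c("CR", "LC", "VU", "LC", "EN", "DD"),
    frac_SA = c(0.05, 0.90, 0.50, 0.40, 0.10, 0.90),
    frac_sA = c(0.05, 0.90, 0.50, 0.45, 0.10, 0.90),
    n_provinces = c(1L, 9L, 4L, 5L, 2L, 9L),
    endemic_to_SA = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    marginal_in_SA = FALSE,
    mobility_class = c("flightless", "fully_flighted",
                       "partial_or_one_sex", "fully_flighted",
                       "flightless", "fully_flighted"),
    trophic_class = c("herbivorous_monophagous", "omnivorous",
                      "herbivorous_polyphagous", "predatory",
                      "omnivorous", "omnivorous"),
    stringsAsFactors = FALSE)
  occurrences <- data.frame(
    species_id = c("spA", "spA", "spA", "spA",
                   "spB", "spB", "spB", "spB", "spB",
                   "spC", "spC", "spC",
                   "spD", "spD",
                   "spE", "spE", "spE",
                   "spF", "spF"),
    lon = c(0.40, 0.40, 0.45, 1.50,
            0.50, 1.00, 2.50, 1.50, 2.50,
            0.50, 0.60, 1.50,
            1.50, 1.60,
            0.50, 0.55, 0.60,
            2.50, 2.40),
    lat = c(0.50, 0.50, 0.55, 1.50,
            0.50, 0.50, 0.50, 2.50, 2.50,
            1.50, 1.40, 0.60,
            1.50, 1.60,
            2.50, 2.45, 2.56,
            2.50, 2.60),
    date = "2000-01-01", collector = "worked example",
    stringsAsFactors = FALSE)
  region <- cbind(lon = c(0, 3, 3, 0), lat = c(0, 0, 3, 3))
  hotspot <- list(west = cbind(lon = c(0, 1.6, 1.6, 0),
                               lat = c(0, 0, 3, 3)))
  list(traits = traits, occurrences = occurrences, region = region,
       hotspot_polygons = hotspot)
}
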