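# Hotspot delineation (top-decile cells, count-based and score-based),
# classification against biodiversity hotspot polygons under area-inclusion
# rules, and association tests.

#' Cells in the top percentile of a metric
#'
#' Selects the cells whose value is at or above the empirical
#' `(1 - top_fraction)` quantile, computed over cells with data only; all
#' ties at the threshold are included. If every value is equal the whole
#' set is returned with a degeneracy warning.
#'
#' @param values Named numeric vector (names = cell ids); `NA` entries
#'   (no-data cells) are dropped before the quantile is taken.
#' @param top_fraction Fraction of cells to target, in (0, 1); default 0.10.
#' @return Character vector of selected cell ids; the threshold is
#'   attached as attribute `"threshold"`.
#' @export
top_percentile_cells <- function(values, top_fraction = 0.10) {
  if (top_fraction <= 0 || top_fraction >= 1) {
    kd_stop("top_fraction must be in (0, 1)")
  }
  values <- values[!is.na(values)]
  if (!length(values)) kd_stop("no cells with data")
  if (is.null(names(values))) names(values) <- as.character(seq_along(values))
  thr <- as.numeric(quantile(values, 1 - top_fraction, names = FALSE))
  if (max(values) == min(values)) {
    kd_warn("all cell values equal (%.4g): every cell is tied at the threshold",
            values[1])
  }
  structure(names(values)[values >= thr], threshold = thr)
}

#' Count-based hotspot cells
#'
#' The union ("and/or" rule) of the top-decile cells of the four richness
#' measures: total, threatened, endemic and sensitive species richness.
#'
#' @param metrics Cell metrics table from [cell_metrics()].
#' @param top_fraction Top fraction per measure (default 0.10).
#' @return Character vector of hotspot cell ids.
#' @export
count_based_hotspots <- function(metrics, top_fraction = 0.10) {
  measures <- c("richness_total", "richness_threatened",
                "richness_endemic", "richness_sensitive")
  avail <- measures[vapply(measures, function(m)
    any(!is.na(metrics[[m]])), logical(1))]
  if (length(avail) < length(measures)) {
    kd_warn("measure(s) with no data skipped: %s",
            paste(setdiff(measures, avail), collapse = ", "))
  }
  sets <- lapply(avail, function(m) {
    v <- setNames(metrics[[m]], metrics$cell_id)
    top_percentile_cells(v, top_fraction)
  })
  sort(unique(unlist(sets)))
}

#' Score-based hotspot cells
#'
#' Top-decile cells of the mean composite T+D+LH score.
#'
#' @inheritParams count_based_hotspots
#' @return Character vector of hotspot cell ids.
#' @export
score_based_hotspots <- function(metrics, top_fraction = 0.10) {
  v <- setNames(metrics[["mean_T+D+LH"]], metrics$cell_id)
  sort(unique(as.character(top_percentile_cells(v, top_fraction))))
}

#' Classify grid cells against hotspot polygons
#'
#' Computes, for every grid cell, the fraction of its land area that falls
#' within the supplied biodiversity hotspot polygons and flags the cell
#' under an area-inclusion rule: strictly greater than the rule fraction
#' for rules 0.25/0.50/0.75, or complete inclusion (within relative area
#' tolerance 1e-6) for rule 1. Hotspot polygons are assumed to lie on land
#' (inside the study region) and to be mutually disjoint.
#'
#' @param grid A `fishnet_grid`.
#' @param hotspot_polygons List of (lon, lat) ring matrices.
#' @param rule One of 0.25, 0.5, 0.75, 1 (default 0.5).
#' @return Data frame `cell_id`, `inclusion_fraction`, `biodiversity`.
#' @export
polygon_inclusion <- function(grid, hotspot_polygons, rule = 0.5) {
  stopifnot(inherits(grid, "fishnet_grid"))
  if (is.matrix(hotspot_polygons)) hotspot_polygons <- list(hotspot_polygons)
  if (!all(vapply(hotspot_polygons, function(r)
    is.matrix(r) && nrow(r) >= 3, logical(1)))) {
    kd_stop("invalid hotspot polygon geometry")
  }
  if (!rule %in% c(0.25, 0.5, 0.75, 1)) {
    kd_stop("rule must be one of 0.25, 0.5, 0.75, 1")
  }
  frac <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    inter <- 0
    for (hp in hotspot_polygons) {
      cl <- clip_ring_rect(hp, grid$lon0[i], grid$lat0[i],
                           grid$lon1[i], grid$lat1[i])
      if (!is.null(cl)) inter <- inter + ring_area_km2(cl)
    }
    frac[i] <- min(inter / grid$land_area_km2[i], 1)
  }
  flag <- if (rule == 1) frac >= 1 - 1e-6 else frac > rule
  data.frame(cell_id = grid$cell_id, inclusion_fraction = frac,
             biodiversity = flag, stringsAsFactors = FALSE)
}

#' Chi-squared association between two hotspot classifications
#'
#' Pearson chi-squared test on the 2x2 cross-tabulation of two cell flag
#' vectors over the same cells, with Yates continuity correction by
#' default (the stock 2x2 behaviour of a chi-squared test in R).
#'
#' @param flags_a,flags_b Logical vectors over the same cells.
#' @param correct Apply continuity correction (default `TRUE`).
#' @return List with `statistic`, `df` (= 1), `p.value` and the 2x2
#'   `table`.
#' @export
chi2_association <- function(flags_a, flags_b, correct = TRUE) {
  if (length(flags_a) != length(flags_b)) kd_stop("flag length mismatch")
  keep <- !is.na(flags_a) & !is.na(flags_b)
  tab <- table(factor(flags_a[keep], levels = c(FALSE, TRUE)),
               factor(flags_b[keep], levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    kd_stop("degenerate table: a marginal total is zero")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, table = tab)
}

#' Venn region counts for three hotspot classifications
#'
#' Counts the seven intersection regions of the count-based, score-based
#' and biodiversity hotspot cell sets.
#'
#' @param count_flags,score_flags,biodiversity_flags Logical vectors over
#'   the same cells.
#' @return Named integer vector: `count_only`, `score_only`, `bio_only`,
#'   `count_score`, `count_bio`, `score_bio`, `all_three`,
#'   `total_flagged`.
#' @export
venn_counts <- function(count_flags, score_flags, biodiversity_flags) {
  stopifnot(length(count_flags) == length(score_flags),
            length(score_flags) == length(biodiversity_flags))
  cf <- count_flags & !is.na(count_flags)
  sf <- score_flags & !is.na(score_flags)
  bf <- biodiversity_flags & !is.na(biodiversity_flags)
  c(count_only = sum(cf & !sf & !bf),
    score_only = sum(!cf & sf & !bf),
    bio_only = sum(!cf & !sf & bf),
    count_score = sum(cf & sf & !bf),
    count_bio = sum(cf & !sf & bf),
    score_bio = sum(!cf & sf & bf),
    all_three = sum(cf & sf & bf),
    total_flagged = sum(cf | sf | bf))
}

#' Sensitivity of results to the polygon inclusion rule
#'
#' Classifies cells under each of the four inclusion rules and reports,
#' per rule and diversity measure, the number of hotspot cells and the
#' hotspot-minus-non-hotspot median difference, followed by a
#' Kruskal--Wallis test across rules on those differences.
#'
#' @param metrics Cell metrics table.
#' @param grid A `fishnet_grid`.
#' @param hotspot_polygons List of ring matrices.
#' @param measures Metric columns to compare (default: the four richness
#'   counts and the six mean scores).
#' @return List with `table` (rule x measure median differences and cell
#'   counts) and `kruskal` (H statistic, df, p across rules).
#' @export
inclusion_rule_sensitivity <- function(metrics, grid, hotspot_polygons,
                                       measures = NULL) {
  if (is.null(measures)) {
    measures <- c("richness_total", "richness_threatened",
                  "richness_endemic", "richness_sensitive",
                  paste0("mean_", composite_names()))
  }
  measures <- measures[vapply(measures, function(m)
    any(!is.na(metrics[[m]])), logical(1))]
  rules <- c(0.25, 0.5, 0.75, 1)
  rows <- list()
  for (r in rules) {
    fl <- polygon_inclusion(grid, hotspot_polygons, rule = r)
    hot <- fl$biodiversity[match(metrics$cell_id, fl$cell_id)]
    has <- !is.na(metrics$richness_total)
    for (m in measures) {
      v <- metrics[[m]]
      dmed <- median(v[has & hot], na.rm = TRUE) -
        median(v[has & !hot], na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        rule = r, measure = m, n_hotspot_cells = sum(hot & has),
        median_difference = dmed, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  kw <- kruskal.test(tab$median_difference, factor(tab$rule))
  list(table = tab,
       kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p.value = kw$p.value))
}

#' Compare diversity measures between hotspot and non-hotspot cells
#'
#' Mann--Whitney (Wilcoxon rank-sum) test per diversity measure between
#' cells inside and outside biodiversity hotspots, with group medians.
#'
#' @param metrics Cell metrics table.
#' @param biodiversity_flags Logical vector over `metrics$cell_id`.
#' @param measures Metric columns (default as in
#'   [inclusion_rule_sensitivity()]).
#' @return Data frame: `measure`, `U`, `p.value`, `median_hotspot`,
#'   `median_other`, `n_hotspot`, `n_other`.
#' @export
compare_hotspot_vs_non <- function(metrics, biodiversity_flags,
                                   measures = NULL) {
  if (is.null(measures)) {
    measures <- c("richness_total", "richness_threatened",
                  "richness_endemic", "richness_sensitive",
                  paste0("mean_", composite_names()))
  }
  rows <- lapply(measures, function(m) {
    v <- metrics[[m]]
    keep <- !is.na(v) & !is.na(biodiversity_flags)
    x <- v[keep & biodiversity_flags]
    y <- v[keep & !biodiversity_flags]
    if (!length(x) || !length(y)) kd_stop("a group is empty for %s", m)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    data.frame(measure = m, U = unname(wt$statistic), p.value = wt$p.value,
               median_hotspot = median(x), median_other = median(y),
               n_hotspot = length(x), n_other = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
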