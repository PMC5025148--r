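test_that("top-percentile selection respects the quantile threshold and ties", {
  v <- setNames(1:10, paste0("c", 1:10))
  expect_identical(as.character(top_percentile_cells(v, 0.10)), "c10")
  vt <- setNames(c(5, 5, 5, 1, 1, 1, 1, 1, 1, 1), paste0("c", 1:10))
  expect_setequal(top_percentile_cells(vt, 0.10), c("c1", "c2", "c3"))
  # >= ceiling(f * n) cells selected; equality without ties
  set.seed(2)
  v2 <- setNames(sample(1000, 122), paste0("c", 1:122))
  sel <- top_percentile_cells(v2, 0.10)
  expect_identical(length(sel), as.integer(ceiling(0.10 * 122)))
  expect_true(all(v2[sel] >= attr(sel, "threshold")))
  # NA (no-data) cells are excluded from the denominator
  v3 <- c(v2, setNames(rep(NA_real_, 28), paste0("n", 1:28)))
  expect_setequal(top_percentile_cells(v3, 0.10), sel)
  # degenerate: all equal
  expect_warning(all_eq <- top_percentile_cells(setNames(rep(2, 5), 1:5)),
                 "tied")
  expect_identical(length(all_eq), 5L)
  # invariance under strictly monotone transforms
  expect_setequal(top_percentile_cells(exp(v2 / 300), 0.10), sel)
  expect_error(top_percentile_cells(v2, 0), "top_fraction")
})

test_that("count-based hotspots are the union over the four richness measures", {
  perm_top <- function(top2) {
    v <- integer(20); v[top2] <- c(20L, 19L); v[-top2] <- 1:18; v
  }
  m <- data.frame(cell_id = paste0("c", 1:20),
                  richness_total = perm_top(c(1, 2)),
                  richness_threatened = perm_top(c(3, 4)),
                  richness_endemic = perm_top(c(5, 6)),
                  richness_sensitive = perm_top(c(7, 8)))
  hs <- count_based_hotspots(m)
  expect_setequal(hs, paste0("c", 1:8))
  # a cell top in a single measure only is included (the and/or rule)
  expect_true("c5" %in% hs)
  # endemic measure unavailable: skipped with a warning
  m$richness_endemic <- NA_integer_
  expect_warning(hs2 <- count_based_hotspots(m), "skipped")
  expect_setequal(hs2, paste0("c", c(1:4, 7, 8)))
})

test_that("polygon inclusion fractions are strict and rule 1.0 means complete", {
  g <- build_fishnet(cbind(lon = c(0, 2, 2, 0), lat = c(0, 0, 1, 1)))
  half <- cbind(lon = c(0, 1.5, 1.5, 0), lat = c(0, 0, 1, 1))
  pi50 <- polygon_inclusion(g, half, rule = 0.5)
  expect_equal(pi50$inclusion_fraction, c(1, 0.5), tolerance = 1e-4)
  expect_identical(pi50$biodiversity, c(TRUE, FALSE))  # strict > 0.5
  expect_identical(polygon_inclusion(g, half, rule = 1)$biodiversity,
                   c(TRUE, FALSE))
  expect_identical(polygon_inclusion(g, half, rule = 0.25)$biodiversity,
                   c(TRUE, TRUE))
  expect_error(polygon_inclusion(g, half, rule = 0.4), "rule")
  # nested rules: hotspot cells shrink as the rule tightens
  sim <- simulate_dataset(n_species = 20, n_records = 80, seed = 2)
  g2 <- build_fishnet(sim$region)
  sets <- lapply(c(0.25, 0.5, 0.75, 1), function(r) {
    f <- polygon_inclusion(g2, sim$hotspot_polygons, rule = r)
    f$cell_id[f$biodiversity]
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  expect_true(all(sets[[4]] %in% sets[[3]]))
})

test_that("chi-squared association matches the closed form and is symmetric", {
  # [[10,20],[30,40]] uncorrected equals n(ad-bc)^2/(r1 r2 c1 c2)
  fa <- rep(c(TRUE, FALSE), c(30, 70))
  fb <- c(rep(c(TRUE, FALSE), c(10, 20)), rep(c(TRUE, FALSE), c(30, 40)))
  un <- chi2_association(fa, fb, correct = FALSE)
  expect_equal(un$statistic, oracle_chi2(10, 20, 30, 40), tolerance = 1e-12)
  expect_equal(un$statistic, 0.7936508, tolerance = 1e-6)
  # symmetry
  expect_equal(chi2_association(fb, fa, correct = FALSE)$statistic,
               un$statistic)
  # correction shrinks the statistic
  expect_lt(chi2_association(fa, fb, correct = TRUE)$statistic,
            un$statistic)
  # exact independence: 0 with p = 1 under correction
  ia <- rep(c(TRUE, FALSE), each = 20)
  ib <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 10)
  z <- chi2_association(ia, ib)
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)
  expect_error(chi2_association(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               "degenerate")
})

test_that("venn counts equal brute-force set algebra", {
  expect_true(all(venn_counts(logical(5), logical(5), logical(5)) == 0))
  v1 <- venn_counts(TRUE, TRUE, TRUE)
  expect_identical(unname(v1["all_three"]), 1L)
  expect_identical(sum(v1[1:7]), 1L)
  set.seed(8)
  a <- sample(c(TRUE, FALSE), 200, TRUE)
  b <- sample(c(TRUE, FALSE), 200, TRUE)
  c_ <- sample(c(TRUE, FALSE), 200, TRUE)
  v <- venn_counts(a, b, c_)
  expect_identical(unname(v["count_only"]), sum(a & !b & !c_))
  expect_identical(unname(v["score_bio"]), sum(!a & b & c_))
  expect_identical(unname(v["all_three"]), sum(a & b & c_))
  expect_identical(sum(v[1:7]), sum(a | b | c_))
  expect_identical(unname(v["total_flagged"]), sum(a | b | c_))
})

test_that("inclusion-rule sensitivity reports differences per rule with a global test", {
  sim <- simulate_dataset(n_species = 30, n_records = 120, seed = 6)
  b <- suppressMessages(run_pipeline(sim$traits, sim$occurrences, sim$region,
                                     sim$hotspot_polygons,
                                     run_phylo = FALSE, run_sac = FALSE))
  irs <- inclusion_rule_sensitivity(b$metrics, b$grid, sim$hotspot_polygons)
  expect_setequal(unique(irs$table$rule), c(0.25, 0.5, 0.75, 1))
  expect_identical(irs$kruskal$df, 3L)
  # median differences equal an independent recomputation for one rule
  fl <- polygon_inclusion(b$grid, sim$hotspot_polygons, rule = 0.5)
  hot <- fl$biodiversity[match(b$metrics$cell_id, fl$cell_id)]
  has <- !is.na(b$metrics$richness_total)
  d_oracle <- median(b$metrics$richness_total[has & hot]) -
    median(b$metrics$richness_total[has & !hot])
  expect_equal(irs$table$median_difference[
    irs$table$rule == 0.5 & irs$table$measure == "richness_total"],
    d_oracle)
})

test_that("hotspot vs non-hotspot comparison has the documented degenerate forms", {
  m <- data.frame(cell_id = paste0("c", 1:6),
                  richness_total = c(1, 2, 3, 4, 5, 6))
  fl <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  cmp <- compare_hotspot_vs_non(m, fl, measures = "richness_total")
  # complete separation: hotspot group all larger, U = n1*n2
  expect_equal(unname(cmp$U), 9)
  expect_identical(cmp$median_hotspot, 5)
  # identical groups: U = n1 n2 / 2, p ~ 1
  m2 <- m; m2$richness_total <- rep(c(1, 2, 3), 2)
  cmp2 <- compare_hotspot_vs_non(m2, fl, measures = "richness_total")
  expect_equal(unname(cmp2$U), 4.5)
  expect_gt(cmp2$p.value, 0.9)
  expect_error(compare_hotspot_vs_non(m, rep(TRUE, 6),
                                      measures = "richness_total"),
               "empty")
})

test_that("rank-sum test detects a one-SD shift with high power at n = 50", {
  set.seed(123)
  rej <- mean(replicate(500, {
    x <- rnorm(50); y <- rnorm(50, 1)
    suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value) < 0.05
  }))
  expect_gte(rej, 0.8)
})
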