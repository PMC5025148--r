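test_that("threat scoring maps categories in ascending order and rejects unassessed", {
  expect_identical(score_threat(c("LC", "VU", "EN", "CR")), c(0L, 1L, 2L, 3L))
  expect_error(score_threat("DD"), "excluded from scoring")
  expect_error(score_threat("NE"), "excluded from scoring")
  expect_error(score_threat("XX"), "unknown status")
})

test_that("distribution decision list reproduces the chart and its boundaries", {
  # one case per rule
  expect_identical(score_distribution(0.2, 0.2, 2, TRUE, FALSE), 3L)
  expect_identical(score_distribution(0.5, 0.5, 5, TRUE, FALSE), 2L)
  expect_identical(score_distribution(0.1, 0.8, 1, FALSE, TRUE), 2L)
  expect_identical(score_distribution(0.7, 0.8, 6, FALSE, FALSE), 1L)
  expect_identical(score_distribution(0.2, 0.8, 3, FALSE, FALSE), 1L)
  expect_identical(score_distribution(0.9, 0.9, 9, FALSE, FALSE), 0L)
  # strict thresholds: boundary values fall through
  expect_error(score_distribution(2 / 3, 2 / 3, 6, FALSE, FALSE), "no distribution rule")
  # endemic + few provinces wins over everything
  expect_identical(score_distribution(0.9, 0.9, 1, TRUE, FALSE), 3L)
  # deterministic and order-independent
  set.seed(1)
  fs <- runif(20, 0.76, 1); fa <- runif(20, 0.76, 1)
  o <- sample(20)
  expect_identical(score_distribution(fs, fa, 9, FALSE, FALSE)[o],
                   score_distribution(fs[o], fa[o], 9, FALSE, FALSE))
  expect_error(score_distribution(1.2, 0.5, 1, FALSE, FALSE), "fractions")
})

test_that("life-history mapping is total, surjective, and matches the chart", {
  expect_identical(score_life_history(2, 3), 3L)
  expect_identical(score_life_history(0, 0), 0L)
  expect_identical(score_life_history(1, 1), 1L)
  grid <- expand.grid(M = 0:2, Tr = 0:3)
  lh <- score_life_history(grid$M, grid$Tr)
  expect_setequal(unique(lh), 0:3)
  expect_identical(lh, c(0L, 1L, 1L, 1L, 1L, 2L, 1L, 2L, 3L, 2L, 3L, 3L))
  # image depends only on the sum
  expect_identical(score_life_history(2, 1), score_life_history(0, 3))
  expect_error(score_life_history(3, 0), "M must be")
  expect_error(score_life_history(0, 4), "Tr must be")
})

test_that("composites are the named sums and the full composite is bounded by 9", {
  cs <- composite_scores(1, 2, 2, 2)  # LH = 3
  expect_identical(names(cs), composite_names())
  expect_equal(unlist(cs), c(`T+D` = 3, `T+LH` = 4, `D+LH` = 5,
                             `T+D+M` = 5, `T+D+Tr` = 5, `T+D+LH` = 6))
  expect_true(all(composite_scores(0, 0, 0, 0) == 0))
  grid <- expand.grid(T = 0:3, D = 0:3, M = 0:2, Tr = 0:3)
  full <- composite_scores(grid$T, grid$D, grid$M, grid$Tr)[["T+D+LH"]]
  expect_identical(range(full), c(0L, 9L))
})

test_that("score_species excludes DD/NE, validates columns and flags duplicates", {
  tr <- make_traits(4)
  tr$status <- c("LC", "CR", "DD", "NE")
  expect_message(sc <- score_species(tr), "excluding 2")
  expect_identical(nrow(sc), 2L)
  expect_identical(attr(sc, "excluded"), c("t03", "t04"))
  tr2 <- make_traits(2); tr2$species_id <- c("a", "a")
  expect_error(score_species(tr2), "duplicate")
  expect_error(score_species(make_traits(2)[
    , setdiff(names(make_traits(2)), "status")]), "lacks column")
})

test_that("Kruskal-Wallis H equals the rank-formula oracle and survives monotone transforms", {
  x <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal.test(x, factor(g))
  expect_equal(unname(kw$statistic), oracle_kruskal_h(x, g))
  kw2 <- kruskal.test(exp(x / 5), factor(g))
  expect_equal(unname(kw$statistic), unname(kw2$statistic))
  # with ties
  xt <- c(1, 1, 2, 2, 2, 3, 4, 4, 5)
  expect_equal(unname(kruskal.test(xt, factor(g))$statistic),
               oracle_kruskal_h(xt, g))
})

test_that("trait comparison flags a planted LC-deficit in distribution scores", {
  set.seed(42)
  n <- 60
  status <- rep(c("LC", "VU", "EN"), times = c(40, 10, 10))
  D <- ifelse(status == "LC", sample(0:1, n, TRUE), sample(2:3, n, TRUE))
  sc <- data.frame(species_id = sprintf("s%02d", 1:n), status = status,
                   D = D, M = sample(0:2, n, TRUE),
                   Tr = sample(0:3, n, TRUE), LH = sample(0:3, n, TRUE))
  cmp <- compare_traits_across_status(sc)
  expect_lt(cmp$D$kruskal$p.value, 0.001)
  # LC letter group disjoint from both threatened groups
  expect_false(grepl(substr(cmp$D$letters["LC"], 1, 1),
                     cmp$D$letters["VU"], fixed = TRUE))
  # identical values across groups: H ~ 0, pairwise p ~ 1
  sc$M <- 1L
  cmp0 <- compare_traits_across_status(sc, traits = "M")
  expect_equal(cmp0$M$kruskal$statistic, 0, tolerance = 1e-12)
  expect_true(all(cmp0$M$nemenyi >= 0.999))
  expect_identical(length(unique(cmp0$M$letters)), 1L)
  # a category with < 2 members is excluded with a warning
  sc2 <- sc; sc2$status[1] <- "CR"
  expect_warning(compare_traits_across_status(sc2), "< 2 members")
})
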