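test_that("Moran's I equals the double-sum oracle with the expected null mean", {
  # rook-weight checkerboard on a 4x4 lattice: strong negative autocorrelation
  g <- expand.grid(x = 1:4, y = 1:4)
  v <- (-1)^(g$x + g$y)
  W <- (as.matrix(dist(g)) == 1) * 1
  mi <- morans_i(v, weights = W, n_permutations = 99, seed = 1)
  expect_equal(mi$I, oracle_morans_i(v, W), tolerance = 1e-12)
  expect_equal(mi$expected, -1 / 15)
  expect_lt(mi$I, mi$expected)
  # inverse-distance default weights against the oracle
  set.seed(5)
  xy <- cbind(runif(12, 0, 5), runif(12, 0, 5))
  vals <- rnorm(12)
  Wd <- 1 / as.matrix(dist(xy)); diag(Wd) <- 0
  mi2 <- morans_i(vals, xy, lonlat = FALSE, n_permutations = 99, seed = 1)
  expect_equal(mi2$I, oracle_morans_i(vals, Wd), tolerance = 1e-12)
  # affine invariance
  mi3 <- morans_i(3 * vals + 7, xy, lonlat = FALSE,
                  n_permutations = 99, seed = 1)
  expect_equal(mi2$I, mi3$I, tolerance = 1e-12)
  expect_error(morans_i(rep(1, 12), xy, lonlat = FALSE), "zero variance")
})

test_that("a smooth gradient is detected as positive autocorrelation", {
  g <- expand.grid(x = 1:6, y = 1:6)
  set.seed(21)
  v <- g$x + g$y + rnorm(36, 0, 0.3)
  mi <- morans_i(v, as.matrix(g), lonlat = FALSE,
                 n_permutations = 499, seed = 9)
  expect_gt(mi$I, 0)
  expect_lt(mi$p.value, 0.05)
})

test_that("permutation p-values are approximately uniform under the null", {
  g <- expand.grid(x = 1:5, y = 1:5)
  set.seed(31)
  ps <- replicate(200, morans_i(rnorm(25), as.matrix(g), lonlat = FALSE,
                                n_permutations = 99)$p.value)
  # permutation p-values are discrete; break ties for the KS statistic
  ps <- ps + runif(200, -0.004, 0.004)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("PQL matches ordinary Poisson regression in the independence limit", {
  set.seed(77)
  n <- 200
  x <- rnorm(n)
  xy <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  y <- rpois(n, exp(0.8 + 0.4 * x))
  f <- spatial_poisson_pql(y, cbind(x = x), xy, lonlat = FALSE)
  g <- glm(y ~ x, family = poisson())
  se <- sqrt(diag(summary(g)$cov.scaled))
  expect_true(f$converged)
  expect_lt(abs(f$coefficients["x"] - coef(g)[2]), 2 * se[2])
  expect_lt(abs(f$coefficients["(Intercept)"] - coef(g)[1]), 2 * se[1])
  # slope t-value sign equals slope sign
  expect_identical(sign(f$t_values["x"]), sign(f$coefficients["x"]))
  expect_error(spatial_poisson_pql(y[1:5], cbind(x = x[1:5]),
                                   xy[1:5, ], lonlat = FALSE), "n >= 10")
  expect_error(spatial_poisson_pql(y, cbind(x = x, x2 = x), xy,
                                   lonlat = FALSE), "singular")
})

test_that("marginal r-squared is 0 for intercept-only, bounded, and monotone in effect", {
  set.seed(13)
  n <- 120
  xy <- cbind(runif(n, 0, 30), runif(n, 0, 30))
  y0 <- rpois(n, exp(1))
  f0 <- spatial_poisson_pql(y0, NULL, xy, lonlat = FALSE)
  # intercept-only: no fixed-effect variance
  expect_lt(f0$marginal_r2, 1e-10)
  slopes <- c(0.1, 0.4, 0.8)
  r2 <- sapply(slopes, function(b) {
    mean(replicate(20, {
      x <- rnorm(n)
      y <- rpois(n, exp(1 + b * x))
      spatial_poisson_pql(y, cbind(x = x), xy, lonlat = FALSE)$marginal_r2
    }))
  })
  expect_true(all(diff(r2) > 0))
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("PQL at a negligible fixed range reproduces the plain Poisson fit", {
  set.seed(99)
  n <- 100
  x <- rnorm(n)
  xy <- cbind(runif(n, 0, 40), runif(n, 0, 40))
  y <- rpois(n, exp(0.6 + 0.5 * x))
  # rho fixed at 1e-8: the correlation matrix is the identity and the
  # PQL loop is exactly iteratively reweighted least squares
  f <- spatial_poisson_pql(y, cbind(x = x), xy, lonlat = FALSE, rho = 1e-8)
  g <- glm(y ~ x, family = poisson())
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
})

test_that("the pairwise measure matrix agrees with individually run models", {
  sim <- simulate_dataset(n_species = 40, n_records = 200, seed = 17)
  b <- suppressMessages(run_pipeline(sim$traits, sim$occurrences, sim$region,
                                     sim$hotspot_polygons,
                                     run_phylo = FALSE, run_sac = FALSE))
  pm <- pairwise_measure_models(
    b$metrics, b$grid,
    measures = c(total = "richness_total",
                 threatened = "richness_threatened",
                 `T+D+LH` = "mean_T+D+LH"),
    n_permutations = 49, seed = 3)
  expect_identical(nrow(pm), 3L)
  # rerun one pair by hand
  has <- !is.na(b$metrics$richness_total)
  dat <- b$metrics[has, ]
  cen <- b$grid[match(dat$cell_id, b$grid$cell_id),
                c("centroid_lon", "centroid_lat")]
  f <- spatial_poisson_pql(
    dat$richness_threatened,
    cbind(predictor = dat$richness_total, land = dat$land_area_km2),
    coords = cen, family = "poisson")
  row <- pm[pm$response == "threatened" & pm$predictor == "total", ]
  expect_equal(row$slope, unname(f$coefficients["predictor"]))
  expect_equal(row$marginal_r2, f$marginal_r2)
  # score response uses the Gaussian working model: still finite and sane
  expect_true(all(is.finite(pm$slope)))
})
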