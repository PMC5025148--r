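test_that("taxonomy trees nest subfamily/genus/subgenus with unit branches", {
  # two species in one subgenus form a cherry with tip-to-tip distance 2
  t2 <- taxonomy_to_tree(data.frame(
    species_id = c("a", "b"), subfamily = "S", genus = "g",
    subgenus = "s", stringsAsFactors = FALSE))
  expect_identical(sort(t2$tip.label), c("a", "b"))
  expect_equal(ape::cophenetic.phylo(t2)["a", "b"], 2)
  # congeners are closer than a species from another genus
  t3 <- taxonomy_to_tree(data.frame(
    species_id = c("a", "b", "c"), subfamily = "S",
    genus = c("g", "g", "h"), subgenus = "", stringsAsFactors = FALSE))
  d <- ape::cophenetic.phylo(t3)
  expect_lt(d["a", "b"], d["a", "c"])
  # internal branches are unit; terminal padding makes the tree ultrametric
  internal <- t3$edge[, 2] > length(t3$tip.label)
  expect_true(all(t3$edge.length[internal] == 1))
  expect_true(ape::is.ultrametric(t3))
  # subgenus membership makes species closer than congeners outside it
  t4 <- taxonomy_to_tree(data.frame(
    species_id = c("a", "b", "c"), subfamily = "S", genus = "g",
    subgenus = c("s1", "s1", ""), stringsAsFactors = FALSE))
  d4 <- ape::cophenetic.phylo(t4)
  expect_lt(d4["a", "b"], d4["a", "c"])
  expect_error(taxonomy_to_tree(data.frame(
    species_id = c("a", "a"), subfamily = "S", genus = "g",
    stringsAsFactors = FALSE)), "duplicate")
})

test_that("a large synthetic taxonomy yields a fully resolved multifurcating tree", {
  sim <- simulate_dataset(n_species = 114, n_records = 400, seed = 13)
  tr <- taxonomy_to_tree(sim$traits)
  expect_identical(length(tr$tip.label), 114L)
  expect_identical(anyDuplicated(tr$tip.label), 0L)
  # every internal node has at least two children
  kids <- table(tr$edge[, 1])
  expect_true(all(kids >= 2))
  internal <- tr$edge[, 2] > 114
  expect_true(all(tr$edge.length[internal] == 1))
  expect_true(ape::is.ultrametric(tr))
})

test_that("lambda covariance scales off-diagonals only and stays PSD", {
  t3 <- taxonomy_to_tree(data.frame(
    species_id = c("a", "b", "c"), subfamily = "S",
    genus = c("g", "g", "h"), subgenus = "", stringsAsFactors = FALSE))
  C1 <- lambda_covariance(t3, 1)
  expect_equal(C1, ape::vcv(t3))
  C0 <- lambda_covariance(t3, 0)
  expect_true(all(C0[upper.tri(C0)] == 0))
  expect_equal(diag(C0), diag(C1))
  # cherry with unit branches at lambda = 0.5: off-diagonal = 0.5 * shared depth
  Ch <- lambda_covariance(t3, 0.5)
  expect_equal(Ch["a", "b"], 0.5 * C1["a", "b"])
  expect_error(lambda_covariance(t3, 1.2), "lambda")
  # PSD on a bigger taxonomy tree for several lambdas
  sim <- simulate_dataset(n_species = 40, n_records = 150, seed = 23)
  tr <- taxonomy_to_tree(sim$traits)
  for (lam in c(0, 0.3, 0.7, 1)) {
    ev <- eigen(lambda_covariance(tr, lam), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("PGLS at lambda = 0 reproduces OLS and the ML profile is optimal at lambda-hat", {
  sim <- simulate_dataset(n_species = 50, n_records = 200, seed = 31)
  tr <- taxonomy_to_tree(sim$traits)
  sc <- suppressMessages(score_species(sim$traits))
  ols <- fit_comparative(T ~ D, sc, tr, mode = "OLS")
  p0 <- fit_comparative(T ~ D, sc, tr, mode = "PGLS", lambda = 0)
  expect_equal(p0$coefficients, ols$coefficients, tolerance = 1e-8)
  expect_equal(p0$logLik, ols$logLik, tolerance = 1e-8)
  pg <- fit_comparative(T ~ D, sc, tr, mode = "PGLS")
  p1 <- fit_comparative(T ~ D, sc, tr, mode = "PGLS", lambda = 1)
  expect_gte(pg$logLik + 1e-8, p0$logLik)
  expect_gte(pg$logLik + 1e-8, p1$logLik)
  # AIC bookkeeping: 2k - 2 logLik with the lambda parameter counted
  expect_equal(pg$AIC, 2 * pg$k - 2 * pg$logLik)
  expect_identical(pg$k, ols$k + 1L)
  expect_error(fit_comparative(T ~ D + M + Tr + LH, sc[1:5, ], tr,
                               mode = "OLS"), "n > number")
})

test_that("PGLS agrees with an independent GLS implementation on a small case", {
  skip_if_not_installed("nlme")
  sim <- simulate_dataset(n_species = 30, n_records = 120, seed = 41)
  tr <- taxonomy_to_tree(sim$traits)
  C <- ape::vcv(tr)
  set.seed(1)
  dat <- data.frame(
    y = drop(crossprod(chol(C), rnorm(nrow(C)))),
    x = rnorm(nrow(C)), species_id = rownames(C))
  # compare at a common fixed lambda (nlme's corPagel optimizes lambda on
  # an unconstrained scale and can leave [0, 1], so free fits need not
  # coincide at the boundary)
  for (lam in c(0.3, 0.7)) {
    mine <- fit_comparative(y ~ x, dat, tr, mode = "PGLS", lambda = lam)
    ref <- nlme::gls(y ~ x, data = dat, method = "ML",
                     correlation = ape::corPagel(lam, tr,
                                                 form = ~species_id,
                                                 fixed = TRUE))
    expect_equal(unname(mine$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(mine$logLik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-6)
  }
})

test_that("Brownian traits recover high lambda and white noise recovers low lambda", {
  sim <- simulate_dataset(n_species = 60, n_records = 220, seed = 51)
  tr <- taxonomy_to_tree(sim$traits)
  C <- ape::vcv(tr)
  L <- chol(C)
  ids <- rownames(C)
  set.seed(2)
  lam_bm <- replicate(40, {
    dat <- data.frame(y = drop(crossprod(L, rnorm(60))), species_id = ids)
    fit_comparative(y ~ 1, dat, tr, mode = "PGLS")$lambda
  })
  lam_wn <- replicate(40, {
    dat <- data.frame(y = rnorm(60), species_id = ids)
    fit_comparative(y ~ 1, dat, tr, mode = "PGLS")$lambda
  })
  expect_gte(mean(lam_bm), 0.8)
  expect_lte(mean(lam_wn), 0.2)
})

test_that("model ranking orders by AIC, breaks ties by parsimony, and checks data identity", {
  sim <- simulate_dataset(n_species = 40, n_records = 160, seed = 61)
  tr <- taxonomy_to_tree(sim$traits)
  sc <- suppressMessages(score_species(sim$traits))
  ms <- score_model_set(sc, tr)
  expect_identical(nrow(ms$ranking), 16L)
  expect_true(all(diff(ms$ranking$AIC) >= 0))
  expect_true(all(is.na(ms$ranking$lambda[ms$ranking$mode == "OLS"])))
  expect_true(all(ms$ranking$lambda[ms$ranking$mode == "PGLS"] >= 0))
  # nested interaction models never lose log-likelihood
  f_main <- fit_comparative(T ~ D, sc, tr, mode = "OLS")
  f_int <- fit_comparative(T ~ D * LH, sc, tr, mode = "OLS")
  expect_gte(f_int$logLik + 1e-8, f_main$logLik)
  # differing observations are rejected
  f_other <- fit_comparative(T ~ D, sc[-1, ], tr, mode = "OLS")
  expect_error(rank_models(list(f_main, f_other)), "differing data")
})
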