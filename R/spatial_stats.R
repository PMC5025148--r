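# Spatial statistics for grid-cell analyses: global Moran's I with a
# permutation test, and spatially correlated regression via a penalized
# quasi-likelihood (PQL) loop with an exponential correlation structure,
# profiled range parameter, and marginal r^2.

#' Pairwise distance matrix for cell centroids
#' @noRd
kd_distmat <- function(coords, lonlat = TRUE) {
  coords <- as.matrix(coords)
  if (lonlat) {
    d <- geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
  } else {
    d <- as.matrix(dist(coords))
  }
  d
}

#' Global Moran's I with permutation test
#'
#' Computes the global Moran autocorrelation statistic
#' I = (n / sum(w)) * (sum_ij w_ij z_i z_j) / sum(z_i^2) with centered
#' values z, zero diagonal weights, and a two-sided permutation p-value.
#' The default weight scheme is inverse distance between cell centroids
#' (great-circle km for lon/lat coordinates), with no row
#' standardization. Under no autocorrelation E\[I\] = -1/(n-1).
#'
#' @param values Numeric vector (one value per cell), non-constant.
#' @param coords Two-column matrix of cell centroids (ignored when
#'   `weights` is supplied).
#' @param weights Optional precomputed weight matrix (zero diagonal).
#' @param lonlat Treat `coords` as lon/lat degrees (default `TRUE`);
#'   otherwise Euclidean.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return List with `I`, `expected` (= -1/(n-1)), `z` (permutation
#'   z-score), `p.value` (two-sided permutation p), and `n`.
#' @export
morans_i <- function(values, coords = NULL, weights = NULL, lonlat = TRUE,
                     n_permutations = 999, seed = NULL) {
  n <- length(values)
  if (n < 4) kd_stop("need >= 4 cells")
  if (any(is.na(values))) kd_stop("values must not contain NA")
  if (var(values) == 0) kd_stop("zero variance: values are constant")
  if (is.null(weights)) {
    if (is.null(coords)) kd_stop("supply coords or weights")
    d <- kd_distmat(coords, lonlat)
    if (any(d[upper.tri(d)] == 0)) kd_stop("centroids must be distinct")
    weights <- 1 / d
    diag(weights) <- 0
  } else {
    weights <- as.matrix(weights)
    diag(weights) <- 0
  }
  S0 <- sum(weights)
  stat <- function(v) {
    z <- v - mean(v)
    (n / S0) * sum(weights * tcrossprod(z)) / sum(z^2)
  }
  I <- stat(values)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(i) stat(sample(values)), numeric(1))
  E <- -1 / (n - 1)
  p <- (1 + sum(abs(perm - E) >= abs(I - E))) / (n_permutations + 1)
  list(I = I, expected = E,
       z = (I - mean(perm)) / sd(perm), p.value = p, n = n)
}

#' Spatially correlated regression by penalized quasi-likelihood
#'
#' Fits a regression with an exponential spatial correlation structure
#' C_ij = exp(-d_ij / rho) on the errors by an iterated working-response
#' (PQL) loop. For `family = "poisson"` (count responses, log link) the
#' loop starts from an ordinary Poisson regression and iterates the
#' working response z = eta + (y - mu)/mu with weights mu, solving a
#' generalized least squares problem under
#' Sigma(rho) = W^(-1/2) C(rho) W^(-1/2) at each step; for
#' `family = "gaussian"` (bounded mean-score responses) the identity
#' working response gives a single GLS solve. The range parameter rho is
#' profiled on a log-spaced grid spanning
#' \[0.1 * median(d), 2 * max(d)\] at every iteration and refined once by
#' golden-section search after convergence.
#'
#' @param y Response vector (non-negative counts for Poisson).
#' @param X Predictor matrix or data frame (no intercept column; one is
#'   added internally).
#' @param coords Two-column matrix of cell centroids.
#' @param family `"poisson"` or `"gaussian"`.
#' @param lonlat Interpret `coords` as lon/lat (default `TRUE`).
#' @param n_rho Number of grid points for the rho profile (default 20).
#' @param rho Optional fixed range parameter; skips profiling (e.g.
#'   `rho = 1e-8` reduces the model to independent errors).
#' @param tol Convergence tolerance on max |delta beta| (default 1e-6).
#' @param max_iter Maximum PQL iterations (default 50).
#' @return Object of class `spatial_fit`: list with `coefficients`, `se`,
#'   `t_values`, `rho` (range, units of `coords` distances), `sigma2`,
#'   `marginal_r2`, `converged`, `n_iterations`, `family`, `n`, plus the
#'   working residuals and design for downstream use.
#' @export
spatial_poisson_pql <- function(y, X, coords,
                                family = c("poisson", "gaussian"),
                                lonlat = TRUE, n_rho = 20, rho = NULL,
                                tol = 1e-6, max_iter = 50) {
  family <- match.arg(family)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (n < 10) kd_stop("need n >= 10 cells")
  if (family == "poisson" && any(y < 0)) kd_stop("counts must be >= 0")
  Xd <- cbind(`(Intercept)` = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) kd_stop("singular design matrix")
  D <- kd_distmat(coords, lonlat)
  if (any(D[upper.tri(D)] == 0)) kd_stop("centroids must be distinct")
  du <- D[upper.tri(D)]
  rho_grid <- exp(seq(log(0.1 * median(du)), log(2 * max(du)),
                      length.out = n_rho))
  chol_cache <- new.env(parent = emptyenv())
  get_chol <- function(rho) {
    key <- sprintf("%.12g", rho)
    if (!is.null(chol_cache[[key]])) return(chol_cache[[key]])
    L <- chol(exp(-D / rho))
    chol_cache[[key]] <- L
    L
  }
  # GLS of z on Xd with weights w under Sigma = W^{-1/2} C(rho) W^{-1/2}:
  # premultiplying by W^{1/2} reduces to GLS under C(rho), so one Cholesky
  # of C per rho serves every iteration.
  gls_at <- function(rho, z, w) {
    L <- get_chol(rho)
    sw <- sqrt(w)
    Xw <- Xd * sw
    zw <- z * sw
    A <- backsolve(L, Xw, transpose = TRUE)
    b <- backsolve(L, zw, transpose = TRUE)
    qrA <- qr(A)
    beta <- qr.coef(qrA, b)
    r <- b - A %*% beta
    rss <- sum(r^2)
    # Gaussian profile log-likelihood of the working response
    logdet <- 2 * sum(log(diag(L))) - sum(log(w))
    pll <- -0.5 * (n * log(rss / n) + logdet)
    list(beta = beta, rss = rss, pll = pll, A = A)
  }
  profile_rho <- function(z, w, grid) {
    fits <- lapply(grid, gls_at, z = z, w = w)
    i <- which.max(vapply(fits, `[[`, numeric(1), "pll"))
    list(rho = grid[i], fit = fits[[i]], i = i)
  }
  golden_refine <- function(z, w, lo, hi) {
    g <- (sqrt(5) - 1) / 2
    a <- log(lo); b <- log(hi)
    c1 <- b - g * (b - a); d1 <- a + g * (b - a)
    fc <- gls_at(exp(c1), z, w)$pll
    fd <- gls_at(exp(d1), z, w)$pll
    while (b - a > 1e-3) {
      if (fc > fd) {
        b <- d1; d1 <- c1; fd <- fc
        c1 <- b - g * (b - a); fc <- gls_at(exp(c1), z, w)$pll
      } else {
        a <- c1; c1 <- d1; fc <- fd
        d1 <- a + g * (b - a); fd <- gls_at(exp(d1), z, w)$pll
      }
    }
    exp((a + b) / 2)
  }

  if (family == "poisson") {
    init <- glm.fit(Xd, y, family = poisson())
    beta <- init$coefficients
  } else {
    beta <- qr.coef(qr(Xd), y)
  }
  converged <- FALSE
  iter <- 0L
  rho_fixed <- !is.null(rho)
  if (!rho_fixed) rho <- rho_grid[ceiling(n_rho / 2)]
  z <- NULL; w <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Xd %*% beta)
    if (family == "poisson") {
      mu <- exp(eta)
      mu <- pmax(mu, 1e-8)
      z <- eta + (y - mu) / mu
      w <- mu
    } else {
      z <- y
      w <- rep(1, n)
    }
    if (rho_fixed) {
      ft_it <- gls_at(rho, z, w)
      beta_new <- drop(ft_it$beta)
    } else {
      pr <- profile_rho(z, w, rho_grid)
      rho <- pr$rho
      beta_new <- drop(pr$fit$beta)
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!rho_fixed) {
    # one golden-section refinement, then re-converge beta at fixed rho
    i <- which(abs(rho_grid - rho) < 1e-12)[1]
    lo <- rho_grid[max(1, i - 1)]; hi <- rho_grid[min(n_rho, i + 1)]
    rho <- golden_refine(z, w, lo, hi)
  }
  for (k in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    if (family == "poisson") {
      mu <- pmax(exp(eta), 1e-8)
      z <- eta + (y - mu) / mu
      w <- mu
    } else { z <- y; w <- rep(1, n) }
    ft <- gls_at(rho, z, w)
    beta_new <- drop(ft$beta)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  ft <- gls_at(rho, z, w)
  p <- ncol(Xd)
  sigma2 <- ft$rss / (n - p)
  XtX <- crossprod(ft$A)
  covb <- sigma2 * solve(XtX)
  se <- sqrt(diag(covb))
  beta <- drop(ft$beta)
  names(beta) <- names(se) <- colnames(Xd)
  fit <- structure(list(
    coefficients = beta, se = se, t_values = beta / se,
    rho = rho, sigma2 = sigma2, converged = converged,
    n_iterations = iter, family = family, n = n,
    eta = drop(Xd %*% beta), X = Xd, y = y), class = "spatial_fit")
  fit$marginal_r2 <- marginal_r2(fit)
  fit
}

#' Marginal r-squared of a spatial fit
#'
#' Variance of the fixed-effect linear predictor over the sum of that
#' variance and the distribution-specific variance: the lognormal
#' approximation ln(1 + 1/exp(beta0)) for the Poisson family, or the
#' residual variance for the Gaussian working model. Appropriate for
#' models with no random effects; always in \[0, 1\].
#'
#' @param fit A `spatial_fit` object.
#' @return Numeric scalar in \[0, 1\].
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "spatial_fit"))
  vf <- var(fit$eta)
  vd <- if (fit$family == "poisson") {
    log(1 + 1 / exp(fit$coefficients[["(Intercept)"]]))
  } else {
    fit$sigma2
  }
  unname(vf / (vf + vd))
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat(sprintf("Spatial %s fit (PQL, exponential correlation), n = %d\n",
              x$family, x$n))
  cat(sprintf("  rho = %.4g, marginal r^2 = %.3f, converged: %s (%d iter)\n",
              x$rho, x$marginal_r2, x$converged, x$n_iterations))
  print(data.frame(estimate = x$coefficients, se = x$se, t = x$t_values))
  invisible(x)
}

#' Pairwise spatial models between diversity measures
#'
#' For every ordered pair of diversity measures (lower triangle: each
#' measure regressed on every measure listed before it), fits the plain
#' GLM, computes Moran's I of its Pearson residuals (permutation p), then
#' the spatial PQL model with the predictor measure and cell land area as
#' fixed effects, reporting slope, t-value and marginal r^2. Count
#' responses use the Poisson family; mean-score responses use the
#' Gaussian working model.
#'
#' @param metrics Cell metrics table ([cell_metrics()]).
#' @param grid A `fishnet_grid` (for centroids).
#' @param measures Named character vector of metric columns; names are
#'   display labels. Defaults to total/threatened/endemic/sensitive
#'   richness and the mean T+D+LH score.
#' @param n_permutations Permutations for the Moran's I test.
#' @param seed Seed for the permutation test.
#' @return Data frame with one row per pair: `response`, `predictor`,
#'   `slope`, `t_value`, `marginal_r2`, `morans_i`, `morans_p`,
#'   `converged`.
#' @export
pairwise_measure_models <- function(metrics, grid, measures = NULL,
                                    n_permutations = 199, seed = 1) {
  if (is.null(measures)) {
    measures <- c(total = "richness_total", threatened = "richness_threatened",
                  endemic = "richness_endemic", sensitive = "richness_sensitive",
                  `T+D+LH` = "mean_T+D+LH")
  }
  has <- !is.na(metrics$richness_total)
  dat <- metrics[has, , drop = FALSE]
  cen <- grid[match(dat$cell_id, grid$cell_id),
              c("centroid_lon", "centroid_lat")]
  land <- dat$land_area_km2
  rows <- list()
  for (ri in seq_along(measures)[-1]) {
    for (ci in seq_len(ri - 1)) {
      yv <- dat[[measures[ri]]]
      xv <- dat[[measures[ci]]]
      keep <- !is.na(yv) & !is.na(xv)
      fam <- if (grepl("^mean_", measures[ri])) "gaussian" else "poisson"
      g <- if (fam == "poisson") {
        glm(yv[keep] ~ xv[keep] + land[keep], family = poisson())
      } else {
        glm(yv[keep] ~ xv[keep] + land[keep], family = gaussian())
      }
      mi <- morans_i(residuals(g, type = "pearson"), coords = cen[keep, ],
                     n_permutations = n_permutations, seed = seed)
      sf <- spatial_poisson_pql(yv[keep],
                                cbind(predictor = xv[keep], land = land[keep]),
                                coords = cen[keep, ], family = fam)
      rows[[length(rows) + 1L]] <- data.frame(
        response = names(measures)[ri], predictor = names(measures)[ci],
        slope = unname(sf$coefficients["predictor"]),
        t_value = unname(sf$t_values["predictor"]),
        marginal_r2 = sf$marginal_r2,
        morans_i = mi$I, morans_p = mi$p.value,
        converged = sf$converged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$stars <- cut(out$morans_p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out
}
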