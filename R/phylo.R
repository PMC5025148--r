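# Taxonomy-derived trees and phylogenetic generalized least squares with
# Pagel's lambda, with OLS/PGLS model ranking by AIC.

#' Build a taxonomy-derived tree
#'
#' Constructs the conservative comparative tree used when no molecular
#' phylogeny is available: subfamilies, genera and subgenera are treated
#' as monophyletic and nested as polytomies, every internal branch length
#' is 1, and species lacking a subgenus attach at the genus level.
#' Taxonomic levels with a single member are collapsed (no unary nodes),
#' so every internal node has at least two children. Terminal branches
#' are then extended so every tip sits at the same depth (the tree is
#' ultrametric): this leaves all shared path lengths — hence relative
#' relatedness — untouched while making the Pagel lambda = 0 model
#' coincide exactly with ordinary least squares. For covariance purposes
#' the tree is rooted at the basal subfamily polytomy.
#'
#' @param traits Data frame with columns `species_id`, `subfamily`,
#'   `genus` and optionally `subgenus` (empty string or `NA` = none).
#' @return An [ape::phylo] tree with `species_id` tip labels and unit
#'   branch lengths.
#' @export
taxonomy_to_tree <- function(traits) {
  req <- c("species_id", "subfamily", "genus")
  if (!all(req %in% names(traits))) {
    kd_stop("traits must have columns %s", paste(req, collapse = ", "))
  }
  if (anyDuplicated(traits$species_id)) kd_stop("duplicate species_id")
  if (any(is.na(traits$subfamily)) || any(is.na(traits$genus))) {
    kd_stop("every species needs subfamily and genus")
  }
  sg <- if ("subgenus" %in% names(traits)) as.character(traits$subgenus) else
    rep(NA_character_, nrow(traits))
  sg[!is.na(sg) & sg == ""] <- NA_character_
  esc <- function(x) gsub("[ ,:;()\\[\\]']", "_", x)
  tip <- esc(traits$species_id)

  clade <- function(children) {
    # children: character vector of newick fragments; collapse singletons
    if (length(children) == 1) children else
      paste0("(", paste(children, collapse = ","), "):1")
  }
  nwk_sf <- lapply(split(seq_len(nrow(traits)), traits$subfamily),
    function(i_sf) {
      gsplit <- split(i_sf, traits$genus[i_sf])
      gfrags <- vapply(gsplit, function(i_g) {
        has_sg <- !is.na(sg[i_g])
        frags <- character(0)
        if (any(has_sg)) {
          sgs <- split(i_g[has_sg], sg[i_g[has_sg]])
          frags <- c(frags, vapply(sgs, function(i_s) {
            clade(paste0(tip[i_s], ":1"))
          }, character(1)))
        }
        no_sg <- i_g[!has_sg]
        if (length(no_sg)) frags <- c(frags, paste0(tip[no_sg], ":1"))
        clade(frags)
      }, character(1))
      clade(gfrags)
    })
  txt <- if (length(nwk_sf) == 1) {
    paste0(sub(":1$", "", nwk_sf[[1]]), ";")
  } else {
    paste0("(", paste(unlist(nwk_sf), collapse = ","), ");")
  }
  tr <- ape::read.tree(text = txt)
  # a lone tip fragment at the top level has no length; normalize to 1
  tr$edge.length[is.na(tr$edge.length)] <- 1
  # pad terminal branches to a common tip depth (ultrametric)
  depth <- ape::node.depth.edgelength(tr)
  ntip <- length(tr$tip.label)
  tip_edge <- match(seq_len(ntip), tr$edge[, 2])
  tr$edge.length[tip_edge] <-
    tr$edge.length[tip_edge] + max(depth[seq_len(ntip)]) -
    depth[seq_len(ntip)]
  tr
}

#' Pagel's lambda covariance matrix
#'
#' Brownian-motion covariance from shared root-to-tip path lengths, with
#' off-diagonal entries multiplied by lambda (0 = star phylogeny, 1 =
#' unscaled Brownian covariance). Diagonal entries are unchanged.
#'
#' @param tree An [ape::phylo] tree.
#' @param lambda Signal multiplier in \[0, 1\].
#' @return Covariance matrix over tips (tip labels as dimnames).
#' @export
lambda_covariance <- function(tree, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 ||
      is.na(lambda) || lambda < 0 || lambda > 1) {
    kd_stop("lambda must be a single value in [0, 1]")
  }
  C <- ape::vcv(tree)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Gaussian GLS log-likelihood under a covariance matrix (ML)
#' @noRd
gls_loglik <- function(y, Xd, V) {
  n <- length(y)
  L <- chol(V)
  A <- backsolve(L, Xd, transpose = TRUE)
  b <- backsolve(L, y, transpose = TRUE)
  qrA <- qr(A)
  beta <- qr.coef(qrA, b)
  r <- b - A %*% beta
  rss <- sum(r^2)
  sigma2 <- rss / n                      # ML variance
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) - sum(log(diag(L)))
  covb <- sigma2 * n / (n - ncol(Xd)) * chol2inv(qr.R(qrA))
  list(beta = drop(beta), logLik = ll, sigma2 = sigma2,
       se = sqrt(diag(covb)))
}

#' Fit an OLS or PGLS comparative model
#'
#' Ordinary least squares or phylogenetic generalized least squares under
#' Pagel's lambda covariance, by maximum likelihood (so AIC is comparable
#' across fixed-effect structures). For PGLS, lambda is estimated by
#' bounded ML on \[0, 1\] (golden-section/Brent with endpoint checks,
#' tolerance 1e-6). The AIC parameter count is the number of regression
#' coefficients plus one for the residual variance plus one when lambda is
#' estimated.
#'
#' @param formula Model formula (e.g. `T ~ D * LH`).
#' @param data Data frame with row names (or a `species_id` column)
#'   matching the tree's tip labels.
#' @param tree An [ape::phylo] tree covering all observations.
#' @param mode `"OLS"` or `"PGLS"`.
#' @param lambda Optional fixed lambda for PGLS (skips estimation; the
#'   AIC parameter count then excludes the lambda parameter).
#' @return Object of class `comparative_fit`: list with `model_label`,
#'   `mode`, `coefficients`, `se`, `t_values`, `lambda` (`NA` for OLS),
#'   `logLik`, `AIC`, `k`, `n`, `formula`, and the response vector `y`.
#' @export
fit_comparative <- function(formula, data, tree, mode = c("OLS", "PGLS"),
                            lambda = NULL) {
  mode <- match.arg(mode)
  if (!is.null(data$species_id)) rownames(data) <- data$species_id
  ids <- rownames(data)
  if (is.null(ids) || !all(ids %in% tree$tip.label)) {
    kd_stop("observation ids must match tree tip labels")
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  Xd <- model.matrix(formula, mf)
  n <- length(y)
  if (n <= ncol(Xd)) kd_stop("need n > number of parameters")
  if (qr(Xd)$rank < ncol(Xd)) kd_stop("singular design matrix")

  if (mode == "OLS") {
    V <- diag(n)
    f <- gls_loglik(y, Xd, V)
    lambda <- NA_real_
    k <- ncol(Xd) + 1L
    ll <- f$logLik
  } else {
    C <- ape::vcv(tree)[ids, ids]
    dC <- diag(C)
    if (is.null(lambda)) {
      ll_at <- function(lam) {
        V <- C * lam
        diag(V) <- dC
        gls_loglik(y, Xd, V)$logLik
      }
      opt <- optimize(ll_at, c(0, 1), maximum = TRUE, tol = 1e-6)
      cand <- c(0, opt$maximum, 1)
      lls <- c(ll_at(0), opt$objective, ll_at(1))
      lambda <- cand[which.max(lls)]
      k <- ncol(Xd) + 2L
    } else {
      if (lambda < 0 || lambda > 1) kd_stop("lambda must be in [0, 1]")
      k <- ncol(Xd) + 1L
    }
    V <- C * lambda
    diag(V) <- dC
    f <- gls_loglik(y, Xd, V)
    ll <- f$logLik
  }
  lab <- paste(deparse(formula), mode)
  structure(list(model_label = lab, mode = mode,
                 coefficients = f$beta, se = f$se,
                 t_values = f$beta / f$se,
                 lambda = lambda, logLik = ll, AIC = 2 * k - 2 * ll,
                 sigma2 = f$sigma2, k = k, n = n,
                 formula = formula, y = as.numeric(y)),
            class = "comparative_fit")
}

#' @export
print.comparative_fit <- function(x, ...) {
  cat(sprintf("%s: logLik = %.3f, AIC = %.2f", x$model_label, x$logLik, x$AIC))
  if (x$mode == "PGLS") cat(sprintf(", lambda = %.2f", x$lambda))
  cat("\n")
  print(data.frame(estimate = x$coefficients, se = x$se, t = x$t_values))
  invisible(x)
}

#' Rank comparative fits by AIC
#'
#' Orders a set of OLS/PGLS fits on identical observations by ascending
#' AIC, breaking ties by fewer parameters, and reports lambda for PGLS
#' rows.
#'
#' @param fits List of `comparative_fit` objects.
#' @return Data frame: `rank`, `model`, `mode`, `AIC`, `delta_AIC`,
#'   `logLik`, `k`, `lambda`.
#' @export
rank_models <- function(fits) {
  if (length(fits) < 2) kd_stop("need >= 2 fits")
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1) kd_stop("fits are on differing data")
  # fits with identical response must share the same observations
  resp <- lapply(fits, `[[`, "y")
  dep <- vapply(fits, function(f) deparse(f$formula[[2]]), character(1))
  for (d in unique(dep)) {
    ys <- resp[dep == d]
    if (!all(vapply(ys, function(v) isTRUE(all.equal(v, ys[[1]])),
                    logical(1)))) {
      kd_stop("fits with response %s use differing observations", d)
    }
  }
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  kk <- vapply(fits, `[[`, numeric(1), "k")
  o <- order(aic, kk)
  data.frame(
    rank = seq_along(fits),
    model = vapply(fits[o], function(f) deparse(f$formula), character(1)),
    mode = vapply(fits[o], `[[`, character(1), "mode"),
    AIC = aic[o], delta_AIC = aic[o] - min(aic),
    logLik = vapply(fits[o], `[[`, numeric(1), "logLik"),
    k = kk[o],
    lambda = vapply(fits[o], `[[`, numeric(1), "lambda"),
    stringsAsFactors = FALSE)
}

#' Fit the standard score-covariation model set
#'
#' Builds the sixteen comparative models relating the score elements: the
#' threat element T regressed on D, LH, M, Tr singly and on the D x LH,
#' D x M and D x Tr interactions, plus D regressed on LH — each as OLS and
#' as PGLS — and ranks them by AIC.
#'
#' @param scores Score table from [score_species()].
#' @param tree Taxonomy tree from [taxonomy_to_tree()] (tips =
#'   `species_id`).
#' @return List with `fits` (named list of `comparative_fit`) and
#'   `ranking` (from [rank_models()]).
#' @export
score_model_set <- function(scores, tree) {
  dat <- scores
  rownames(dat) <- dat$species_id
  keep <- intersect(tree$tip.label, rownames(dat))
  if (length(keep) < nrow(dat)) kd_stop("tree does not cover all species")
  forms <- list(`D ~ LH` = D ~ LH, `T ~ D * LH` = T ~ D * LH,
                `T ~ D * M` = T ~ D * M, `T ~ D * Tr` = T ~ D * Tr,
                `T ~ D` = T ~ D, `T ~ LH` = T ~ LH, `T ~ M` = T ~ M,
                `T ~ Tr` = T ~ Tr)
  fits <- list()
  for (nm in names(forms)) {
    for (mode in c("OLS", "PGLS")) {
      fits[[paste(nm, mode)]] <-
        fit_comparative(forms[[nm]], dat, tree, mode = mode)
    }
  }
  list(fits = fits, ranking = rank_models(fits))
}
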