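# Composite biotic-index scoring: threat (T), distribution (D), mobility (M),
# trophic level (Tr) and life history (LH = chart image of M + Tr).

#' Score Red List threat status
#'
#' Maps an assessed IUCN Red List category to the threat element T of the
#' composite species score, in ascending order of threat: LC = 0, VU = 1,
#' EN = 2, CR = 3. Data Deficient (DD) and Not Evaluated (NE) species never
#' reach scoring and are rejected.
#'
#' @param status Character vector of categories in `LC`, `VU`, `EN`, `CR`.
#' @return Integer vector of threat scores (0--3).
#' @examples
#' score_threat(c("LC", "CR"))
#' @export
score_threat <- function(status) {
  status <- as.character(status)
  bad <- status %in% c("DD", "NE")
  if (any(bad)) {
    kd_stop("status %s: DD/NE species are excluded from scoring",
            paste(unique(status[bad]), collapse = ", "))
  }
  map <- c(LC = 0L, VU = 1L, EN = 2L, CR = 3L)
  unknown <- !(status %in% names(map))
  if (any(unknown)) {
    kd_stop("unknown status value(s): %s",
            paste(unique(status[unknown]), collapse = ", "))
  }
  unname(map[status])
}

#' Score distribution range size
#'
#' Evaluates the distribution element D (0--3) of the species score from
#' range-rule inputs: national range coverage (`frac_SA`, fraction of South
#' Africa + Lesotho + Swaziland), regional coverage (`frac_sA`, fraction of
#' southern Africa), number of provinces occupied, and the endemism and
#' range-margin flags. The narrower the range, the higher the score.
#'
#' The chart is encoded as an explicit decision list evaluated by rule
#' specificity (3, 2, then the very-common 0 rule, then 1); the first
#' matching rule wins:
#' \itemize{
#'   \item 3: national endemic or near-endemic confined to at most 2
#'     provinces.
#'   \item 2: national endemic on more than a third of the country, or
#'     widespread regionally (> 2/3 of southern Africa) but marginal and
#'     very rare nationally (< 1/3).
#'   \item 0: very common, > 3/4 coverage both nationally and regionally.
#'   \item 1: localized over a wide area (> 2/3 of both, short of the
#'     very-common rule), or very common in 1--3 provinces (<= 1/3
#'     nationally) while common regionally (> 2/3), for species whose
#'     national range is not marginal.
#' }
#' The printed percentage thresholds are strict inequalities; boundary
#' values fall through to the next rule. Inputs matching no rule are
#' rejected with a per-rule diagnostic.
#'
#' @param frac_SA Fraction in \[0, 1\] of national range coverage.
#' @param frac_sA Fraction in \[0, 1\] of southern-African coverage.
#' @param n_provinces Integer count of provinces occupied (>= 0).
#' @param endemic_to_SA Logical, national endemic or near-endemic.
#' @param marginal_in_SA Logical, range only marginally enters the country.
#' @return Integer vector of distribution scores (0--3).
#' @examples
#' score_distribution(0.2, 0.2, 2, TRUE, FALSE)  # 3
#' score_distribution(0.9, 0.9, 9, FALSE, FALSE) # 0
#' @export
score_distribution <- function(frac_SA, frac_sA, n_provinces,
                               endemic_to_SA, marginal_in_SA) {
  n <- max(length(frac_SA), length(frac_sA), length(n_provinces),
           length(endemic_to_SA), length(marginal_in_SA))
  frac_SA <- rep_len(as.numeric(frac_SA), n)
  frac_sA <- rep_len(as.numeric(frac_sA), n)
  n_provinces <- rep_len(as.integer(n_provinces), n)
  endemic_to_SA <- rep_len(as.logical(endemic_to_SA), n)
  marginal_in_SA <- rep_len(as.logical(marginal_in_SA), n)
  if (any(!is.finite(frac_SA)) || any(frac_SA < 0 | frac_SA > 1) ||
      any(!is.finite(frac_sA)) || any(frac_sA < 0 | frac_sA > 1)) {
    kd_stop("coverage fractions must be finite and in [0, 1]")
  }
  if (any(is.na(n_provinces)) || any(n_provinces < 0)) {
    kd_stop("n_provinces must be a non-negative integer")
  }

  r3 <- endemic_to_SA & n_provinces <= 2
  r2 <- (endemic_to_SA & frac_SA > 1 / 3) |
    (marginal_in_SA & frac_SA < 1 / 3 & frac_sA > 2 / 3)
  r0 <- frac_SA > 3 / 4 & frac_sA > 3 / 4
  r1 <- (frac_SA > 2 / 3 & frac_sA > 2 / 3) |
    (!marginal_in_SA & frac_SA <= 1 / 3 & frac_sA > 2 / 3 &
       n_provinces <= 3)

  out <- rep(NA_integer_, n)
  out[r1] <- 1L
  out[r0] <- 0L
  out[r2] <- 2L
  out[r3] <- 3L
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    kd_stop(paste0(
      "no distribution rule matches record %d ",
      "(frac_SA=%.3f, frac_sA=%.3f, n_provinces=%d, endemic=%s, ",
      "marginal=%s); rule evaluations: 3=%s, 2=%s, 0=%s, 1=%s"),
      i, frac_SA[i], frac_sA[i], n_provinces[i], endemic_to_SA[i],
      marginal_in_SA[i], r3[i], r2[i], r0[i], r1[i])
  }
  out
}

#' Score mobility
#'
#' Mobility element M, in descending order of mobility: fully flighted = 0,
#' one sex or partially flighted = 1, flightless = 2.
#'
#' @param mobility_class Character vector in `fully_flighted`,
#'   `partial_or_one_sex`, `flightless`.
#' @return Integer vector (0--2).
#' @export
score_mobility <- function(mobility_class) {
  map <- c(fully_flighted = 0L, partial_or_one_sex = 1L, flightless = 2L)
  mobility_class <- as.character(mobility_class)
  if (any(!(mobility_class %in% names(map)))) {
    kd_stop("unknown mobility_class: %s",
            paste(setdiff(mobility_class, names(map)), collapse = ", "))
  }
  unname(map[mobility_class])
}

#' Score trophic level
#'
#' Trophic element Tr, in ascending order of food specialization:
#' omnivorous = 0, predatory = 1, polyphagous herbivore = 2, monophagous
#' herbivore = 3.
#'
#' @param trophic_class Character vector in `omnivorous`, `predatory`,
#'   `herbivorous_polyphagous`, `herbivorous_monophagous`.
#' @return Integer vector (0--3).
#' @export
score_trophic <- function(trophic_class) {
  map <- c(omnivorous = 0L, predatory = 1L,
           herbivorous_polyphagous = 2L, herbivorous_monophagous = 3L)
  trophic_class <- as.character(trophic_class)
  if (any(!(trophic_class %in% names(map)))) {
    kd_stop("unknown trophic_class: %s",
            paste(setdiff(trophic_class, names(map)), collapse = ", "))
  }
  unname(map[trophic_class])
}

#' Score life history from mobility and trophic level
#'
#' The life-history element LH is the chart image of the sum M + Tr:
#' 0 maps to 0, 1--2 to 1, 3 to 2 and 4--5 to 3.
#'
#' @param M Integer mobility scores (0--2).
#' @param Tr Integer trophic scores (0--3).
#' @return Integer vector of LH scores (0--3).
#' @examples
#' score_life_history(2, 3) # 3
#' @export
score_life_history <- function(M, Tr) {
  M <- as.integer(M); Tr <- as.integer(Tr)
  if (any(is.na(M)) || any(M < 0 | M > 2)) kd_stop("M must be in 0..2")
  if (any(is.na(Tr)) || any(Tr < 0 | Tr > 3)) kd_stop("Tr must be in 0..3")
  s <- M + Tr
  lh <- integer(length(s))
  lh[s == 0] <- 0L
  lh[s >= 1 & s <= 2] <- 1L
  lh[s == 3] <- 2L
  lh[s >= 4] <- 3L
  lh
}

#' Composite score combinations
#'
#' Sums the score elements into the six named combinations used as
#' diversity measures: T+D, T+LH, D+LH, T+D+M, T+D+Tr and the full
#' composite T+D+LH (maximum 9).
#'
#' @param T,D,M,Tr Integer score elements; LH is derived from M and Tr.
#' @return Data frame with one column per combination (names as in
#'   [composite_names()]).
#' @export
composite_scores <- function(T, D, M, Tr) {
  LH <- score_life_history(M, Tr)
  out <- data.frame(
    `T+D` = T + D, `T+LH` = T + LH, `D+LH` = D + LH,
    `T+D+M` = T + D + M, `T+D+Tr` = T + D + Tr, `T+D+LH` = T + D + LH,
    check.names = FALSE)
  stopifnot(all(out[["T+D+LH"]] >= 0 & out[["T+D+LH"]] <= 9))
  out
}

#' Score a species trait table
#'
#' Applies the full scoring chart to a validated trait table (see
#' [read_traits()] for the expected columns) and returns one row per
#' assessed species with the five elements and the six composite sums.
#' DD and NE species are excluded before scoring (with a message); their
#' ids are kept in the `"excluded"` attribute of the result.
#'
#' @param traits Data frame of species traits.
#' @return Data frame with columns `species_id`, `status`, `T`, `D`, `M`,
#'   `Tr`, `LH` and the six composite columns.
#' @export
score_species <- function(traits) {
  req <- c("species_id", "status", "frac_SA", "frac_sA", "n_provinces",
           "endemic_to_SA", "marginal_in_SA", "mobility_class",
           "trophic_class")
  miss <- setdiff(req, names(traits))
  if (length(miss)) kd_stop("traits table lacks column(s): %s",
                            paste(miss, collapse = ", "))
  if (anyDuplicated(traits$species_id)) {
    kd_stop("duplicate species_id in trait table")
  }
  drop <- traits$status %in% c("DD", "NE")
  excluded <- traits$species_id[drop]
  if (any(drop)) {
    message(sprintf("excluding %d DD/NE species from scoring", sum(drop)))
    traits <- traits[!drop, , drop = FALSE]
  }
  if (!nrow(traits)) kd_stop("no assessed species left to score")
  T <- score_threat(traits$status)
  D <- score_distribution(traits$frac_SA, traits$frac_sA,
                          traits$n_provinces, traits$endemic_to_SA,
                          traits$marginal_in_SA)
  M <- score_mobility(traits$mobility_class)
  Tr <- score_trophic(traits$trophic_class)
  LH <- score_life_history(M, Tr)
  out <- cbind(
    data.frame(species_id = traits$species_id, status = traits$status,
               T = T, D = D, M = M, Tr = Tr, LH = LH,
               stringsAsFactors = FALSE),
    composite_scores(T, D, M, Tr))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

# ---- trait comparison across threat categories --------------------------

#' Nemenyi all-pairs post-hoc test (chi-square approximation)
#'
#' Tie-corrected Nemenyi test on joint ranks, the all-pairs companion of the
#' Kruskal--Wallis test for unequal group sizes. The pairwise statistic is
#' the squared mean-rank difference over its null variance, divided by the
#' tie-correction factor, and referred to a chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param x Numeric response vector.
#' @param g Grouping factor.
#' @return Symmetric matrix of pairwise p-values (diagonal 1).
#' @export
nemenyi_test <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  if (k < 2) kd_stop("need at least 2 groups")
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  ties <- table(x)
  Cf <- 1 - sum(ties^3 - ties) / (N^3 - N)   # tie correction
  if (Cf <= 0) Cf <- .Machine$double.eps     # all values identical
  p <- matrix(1, k, k, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      stat <- (rbar[i] - rbar[j])^2 /
        (N * (N + 1) / 12 * (1 / ni[i] + 1 / ni[j])) / Cf
      p[i, j] <- p[j, i] <- pchisq(stat, df = k - 1, lower.tail = FALSE)
    }
  }
  p
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Groups sharing a letter are not significantly different at `alpha`.
#' Letters are the maximal cliques of the non-significance graph, ordered
#' by group mean.
#'
#' @param pmat Symmetric matrix of pairwise p-values.
#' @param means Named numeric vector of group means (for letter ordering).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter codes.
#' @export
letter_display <- function(pmat, means, alpha = 0.05) {
  k <- nrow(pmat)
  lev <- rownames(pmat)
  nsd <- pmat > alpha
  diag(nsd) <- TRUE
  # maximal subsets whose members are pairwise non-different (k is tiny)
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  ok <- vapply(subsets, function(s) all(nsd[s, s]), logical(1))
  cand <- subsets[ok]
  maximal <- cand[vapply(cand, function(s) {
    !any(vapply(cand, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, logical(1))]
  ord <- order(vapply(maximal, function(s) min(means[lev[s]]), numeric(1)))
  maximal <- maximal[ord]
  letters_out <- setNames(rep("", k), lev)
  for (i in seq_along(maximal)) {
    m <- maximal[[i]]
    letters_out[m] <- paste0(letters_out[m], letters[i])
  }
  letters_out
}

#' Compare score elements across threat categories
#'
#' For each requested score element, runs a tie-corrected Kruskal--Wallis
#' test across Red List categories followed by Nemenyi all-pairs post-hoc
#' comparisons and a compact letter display at `alpha`. Categories with
#' fewer than two members are excluded with a warning.
#'
#' @param scores Score table from [score_species()].
#' @param traits Which elements to compare (default D, M, Tr, LH).
#' @param alpha Significance level for the letter display.
#' @return Object of class `trait_comparison`: a list with one entry per
#'   element, each holding `kruskal` (statistic, df, p.value), `nemenyi`
#'   (pairwise p matrix) and `letters`.
#' @export
compare_traits_across_status <- function(scores,
                                         traits = c("D", "M", "Tr", "LH"),
                                         alpha = 0.05) {
  g <- factor(scores$status)
  small <- names(which(table(g) < 2))
  if (length(small)) {
    kd_warn("excluding categor%s with < 2 members: %s",
            if (length(small) > 1) "ies" else "y",
            paste(small, collapse = ", "))
    keep <- !(scores$status %in% small)
    scores <- scores[keep, , drop = FALSE]
    g <- droplevels(factor(scores$status))
  }
  if (nlevels(g) < 2) kd_stop("need >= 2 categories with >= 2 members")
  out <- lapply(traits, function(tr) {
    x <- scores[[tr]]
    if (var(x) == 0) {
      # identical values everywhere: no evidence of any difference
      kw <- list(statistic = 0, parameter = nlevels(g) - 1L, p.value = 1)
    } else {
      kw <- kruskal.test(x, g)
    }
    pm <- nemenyi_test(x, g)
    list(kruskal = list(statistic = unname(kw$statistic),
                        df = unname(kw$parameter),
                        p.value = kw$p.value),
         nemenyi = pm,
         letters = letter_display(pm, tapply(x, g, mean), alpha))
  })
  names(out) <- traits
  structure(out, class = "trait_comparison")
}

#' @export
print.trait_comparison <- function(x, ...) {
  for (tr in names(x)) {
    k <- x[[tr]]$kruskal
    cat(sprintf("%-3s Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.4g\n",
                tr, k$statistic, k$df, k$p.value))
    cat("    groups:",
        paste(sprintf("%s=%s", names(x[[tr]]$letters), x[[tr]]$letters),
              collapse = " "), "\n")
  }
  invisible(x)
}
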