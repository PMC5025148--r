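# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# expected richness in t samples: mean over all C(T, t) sample subsets
oracle_sample_sac <- function(comm, t) {
  T_ <- nrow(comm)
  subsets <- utils::combn(T_, t, simplify = FALSE)
  mean(vapply(subsets, function(s) {
    sum(colSums(comm[s, , drop = FALSE]) > 0)
  }, numeric(1)))
}

# expected richness in n individuals: mean over all C(N, n) subsets
oracle_individual_rarefaction <- function(abund, n) {
  pool <- rep(seq_along(abund), abund)
  subsets <- utils::combn(length(pool), n, simplify = FALSE)
  mean(vapply(subsets, function(s) length(unique(pool[s])), numeric(1)))
}

# Moran's I by the literal double sum
oracle_morans_i <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  }
  (n / sum(W)) * num / sum(z^2)
}

# tie-corrected Kruskal-Wallis H from the rank formula
oracle_kruskal_h <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# closed-form 2x2 chi-squared without correction
oracle_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# brute-force point-in-box assignment on an integer graticule
oracle_assign <- function(lon, lat, grid_df) {
  vapply(seq_along(lon), function(k) {
    hit <- which(lon[k] >= grid_df$lon0 & lon[k] < grid_df$lon1 &
                   lat[k] >= grid_df$lat0 & lat[k] < grid_df$lat1)
    if (length(hit)) grid_df$cell_id[hit[1]] else NA_character_
  }, character(1))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small trait table builder for scoring tests
make_traits <- function(n = 8, status = "LC") {
  data.frame(
    species_id = sprintf("t%02d", seq_len(n)),
    subfamily = rep(c("SF1", "SF2"), length.out = n), tribe = "",
    genus = rep(c("g1", "g2", "g3"), length.out = n), subgenus = "",
    species = sprintf("t%02d", seq_len(n)),
    status = rep_len(status, n),
    frac_SA = 0.9, frac_sA = 0.9, n_provinces = 9L,
    endemic_to_SA = FALSE, marginal_in_SA = FALSE,
    mobility_class = "fully_flighted", trophic_class = "omnivorous",
    stringsAsFactors = FALSE)
}
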