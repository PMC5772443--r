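# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the standard synthetic world used across modules
std_world <- function() cached("std_world", gen_world(synth_config(seed = 42)))

# a smaller, faster world for determinism / pipeline tests
small_config <- function(seed = 7) {
  synth_config(seed = seed, grid = grid_spec(-80, -20, 0.5, 40, 40),
               n_species = 6, n_plots = 150, collections_per_species = 250)
}
small_world <- function() cached("small_world", gen_world(small_config()))

# ~10k-record corpus with labelled injected errors
corpus_world <- function() cached(
  "corpus_world",
  gen_world(synth_config(seed = 2025, n_species = 22,
                         collections_per_species = 800)))

# brute-force oracles ------------------------------------------------------

# IDW weighted mean over all plots, straight from the definition
idw_oracle <- function(lon, lat, plon, plat, pra, d_max = 3, power = 0.5) {
  d <- sqrt((plon - lon)^2 + (plat - lat)^2)
  keep <- d <= d_max
  if (!any(keep)) return(0)
  w <- d[keep]^(-power)
  sum(w * pra[keep]) / sum(w)
}

# pairwise win probability with half-ties
auc_oracle <- function(pres, bg) {
  wins <- 0
  for (p in pres) for (b in bg)
    wins <- wins + if (p > b) 1 else if (p == b) 0.5 else 0
  wins / (length(pres) * length(bg))
}

# exhaustive check-loss minimum over all lines through sample-point pairs
rq_pair_oracle <- function(x, y, tau) {
  best <- Inf
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(x[i] - x[j]) < 1e-12) next
    b <- (y[i] - y[j]) / (x[i] - x[j])
    a <- y[i] - b * x[i]
    r <- y - a - b * x
    best <- min(best, sum(r * (tau - (r < 0))))
  }
  best
}

# shoelace polygon area (closed or open vertex matrix)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# the standard kde outlier fixture: a compact cluster (narrow species,
# regions stay <= 3) plus labelled far-away misidentified points
kde_fixture <- function(n_cluster = 20, n_far = 2) {
  set.seed(31)
  g <- grid_spec(-80, -20, 0.5, 60, 60)
  lon <- c(rnorm(n_cluster, -74, 0.5), -62 - seq_len(n_far))
  lat <- c(rnorm(n_cluster, -13, 0.5), rep(-17, n_far))
  data.frame(record_id = seq_len(n_cluster + n_far),
             species = "sp",
             lon = lon, lat = lat, locality = "x",
             error = c(rep("clean", n_cluster),
                       rep("misidentification", n_far)),
             stringsAsFactors = FALSE)
}
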