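# Independent oracles and small fixture builders used across test files.

# Brute-force shortest-path oracle: Bellman-Ford-style relaxation over the
# same 8-connected average-endpoint-cost move model, iterated to a fixed
# point. Deliberately independent of the Dijkstra implementation.
bellman_ford_cost <- function(cost_mat, source_mask, cellsize = 1) {
  nr <- nrow(cost_mat); nc <- ncol(cost_mat)
  d <- matrix(Inf, nr, nc)
  d[source_mask == 1 & !is.na(cost_mat)] <- 0
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(cost_mat[r, c])) next
      for (m in seq_len(nrow(moves))) {
        r2 <- r + moves$dr[m]; c2 <- c + moves$dc[m]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(cost_mat[r2, c2])) next
        len <- cellsize * sqrt(moves$dr[m]^2 + moves$dc[m]^2)
        w <- (cost_mat[r, c] + cost_mat[r2, c2]) / 2 * len
        if (d[r2, c2] + w < d[r, c] - 1e-12) {
          d[r, c] <- d[r2, c2] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d[is.infinite(d)] <- NA_real_
  d[is.na(cost_mat)] <- NA_real_
  d
}

# probability two distinct draws differ (brute-force pair enumeration);
# oracle for haplotype diversity and per-locus gene diversity
pair_diff_prob <- function(labels) {
  n <- length(labels)
  pairs <- utils::combn(n, 2)
  mean(labels[pairs[1, ]] != labels[pairs[2, ]])
}

# random AFLP fixture with >= 2 individuals per population
random_aflp <- function(n_pops, n_per_pop, n_loci, seed,
                        p_band = NULL) {
  set.seed(seed)
  n <- n_pops * n_per_pop
  if (is.null(p_band)) p_band <- runif(n_loci, 0.1, 0.9)
  bands <- t(vapply(seq_len(n), function(i) rbinom(n_loci, 1, p_band),
                    integer(n_loci)))
  ids <- sprintf("ind%03d", seq_len(n))
  rownames(bands) <- ids
  pops <- rep(sprintf("pop%02d", seq_len(n_pops)), each = n_per_pop)
  aflp_matrix(bands, setNames(pops, ids))
}

# minimal valid population table
toy_pop_table <- function(n = 5, seed = 1, lon = NULL, lat = NULL) {
  set.seed(seed)
  df <- data.frame(
    pop_id = sprintf("T%02d", seq_len(n)),
    lon = if (is.null(lon)) runif(n, 10, 13) else lon,
    lat = if (is.null(lat)) runif(n, 45, 48) else lat,
    present_4x = rbinom(n, 1, 0.6),
    present_5x = rbinom(n, 1, 0.4),
    present_7x = rbinom(n, 1, 0.3),
    present_8x = rbinom(n, 1, 0.2),
    elevation = runif(n, 300, 1500),
    inclination = runif(n, 0, 40),
    aspect = runif(n, 0, 180),
    land_use = rbinom(n, 1, 0.5),
    ndvi = runif(n, 0.2, 0.9),
    bio04 = rnorm(n, 650, 50),
    bio12 = runif(n, 600, 1500),
    bio15 = rnorm(n, 30, 5))
  as_population_table(df)
}
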