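test_that("grid construction covers the study extent exactly", {
  g <- build_grid(9.4, 44.7, 13.9, 48.1, 0.1)
  expect_equal(g$n_rows, 34)
  expect_equal(g$n_cols, 45)
  expect_equal(g$n_cells, 1530)
  g2 <- build_grid(0, 0, 1, 1, 0.5)
  expect_equal(g2$n_cells, 4)
  expect_equal(sort(unique(g2$cells$lon)), c(0.25, 0.75))
  expect_equal(sort(unique(g2$cells$lat)), c(0.25, 0.75))
  expect_error(build_grid(0, 0, 1, 1, 0.3), "snap")
  expect_error(build_grid(0, 0, 1, 1, 2), "")
})

test_that("correlation surface is -1 where the index decays monotonically with distance", {
  g <- build_grid(0, 0, 3, 3, 1)
  # collinear populations, index falling with lon; the westmost and
  # eastmost cell centroids lie beyond the population line on each side
  pops <- toy_pop_table(5, lon = c(0.7, 1.2, 1.7, 2.2, 2.7),
                        lat = rep(1.5, 5))
  idx <- setNames(c(10, 8, 6, 4, 2), pops$pop_id)
  s <- correlation_surface(g, pops, idx, distance = "planar")
  west <- which(g$cells$lon == 0.5 & g$cells$lat == 1.5)
  east <- which(g$cells$lon == 2.5 & g$cells$lat == 1.5)
  expect_equal(s$values[west], -1)
  expect_equal(s$values[east], 1)
  # constant index -> warning, all cells undefined
  expect_warning(s0 <- correlation_surface(g, pops,
                                           setNames(rep(1, 5),
                                                    pops$pop_id)),
                 "constant")
  expect_true(all(is.na(s0$values)))
  expect_error(correlation_surface(g, pops, idx[1:2]), ">= 3")
})

test_that("random index values give a near-symmetric, near-zero correlation field", {
  g <- build_grid(10, 45, 12, 47, 0.5)
  pops <- toy_pop_table(30, seed = 8,
                        lon = runif(30, 10, 12), lat = runif(30, 45, 47))
  set.seed(99)
  mean_rho <- replicate(100, {
    idx <- setNames(sample(30), pops$pop_id)
    mean(correlation_surface(g, pops, idx)$values)
  })
  expect_lt(abs(mean(mean_rho)), 0.05)
})

test_that("cell ranking is ascending from the most negative coefficient with average ties", {
  g <- build_grid(0, 0, 3, 1, 1)
  s <- refugeo:::.grid_surface(g, c(-0.9, 0.0, 0.9), "x", "correlation")
  expect_equal(rank_cells(s)$values, c(1, 2, 3))
  s2 <- refugeo:::.grid_surface(g, c(-0.5, -0.5, 0.2), "x", "correlation")
  expect_equal(rank_cells(s2)$values, c(1.5, 1.5, 3))
  expect_error(rank_cells(refugeo:::.grid_surface(g, rep(NA_real_, 3),
                                                  "x", "correlation")),
               "undefined")
  # ranks are a monotone transform of the coefficients
  s3 <- refugeo:::.grid_surface(g, c(0.4, -0.2, 0.1), "x", "correlation")
  expect_equal(cor(s3$values, rank_cells(s3)$values, method = "spearman"),
               1)
})

test_that("rank combination averages per cell and is order-invariant", {
  g <- build_grid(0, 0, 3, 1, 1)
  r1 <- refugeo:::.grid_surface(g, c(1, 2, 3), "a", "rank")
  r2 <- refugeo:::.grid_surface(g, c(3, 2, 1), "b", "rank")
  expect_equal(combine_ranks(list(r1, r2))$values, c(2, 2, 2))
  expect_equal(combine_ranks(list(r1, r1, r1, r1))$values, r1$values)
  expect_equal(combine_ranks(list(r2, r1))$values,
               combine_ranks(list(r1, r2))$values)
  gg <- build_grid(0, 0, 3, 2, 1)
  r3 <- refugeo:::.grid_surface(gg, rep(1, 6), "c", "rank")
  expect_error(combine_ranks(list(r1, r3)), "different grids")
})

test_that("direction test maps the rank/latitude correlation sign to the source margin", {
  g <- build_grid(0, 0, 2, 5, 1)
  combined <- refugeo:::.grid_surface(g, rank(g$cells$lat), "combined",
                                      "combined_rank")
  d <- direction_test(combined)
  expect_equal(d$rho, 1)
  expect_equal(d$inferred_source, "south")
  combined2 <- refugeo:::.grid_surface(g, rank(-g$cells$lat), "combined",
                                       "combined_rank")
  d2 <- direction_test(combined2)
  expect_equal(d2$rho, -1)
  expect_equal(d2$inferred_source, "north")
  # permutation p agrees in direction with asymptotic p
  d3 <- direction_test(combined, method = "permutation", n_perm = 199,
                       seed = 4)
  expect_lt(d3$p, 0.05)
})

test_that("the whole inference is invariant under increasing transforms of the index", {
  set.seed(55)
  g <- build_grid(10, 45, 12, 47, 0.5)
  pops <- toy_pop_table(25, seed = 9, lon = runif(25, 10, 12),
                        lat = runif(25, 45, 47))
  idx <- setNames(runif(25), pops$pop_id)
  run <- function(v) {
    s <- correlation_surface(g, pops, v)
    direction_test(combine_ranks(list(rank_cells(s), rank_cells(s))))
  }
  base <- run(idx)
  for (f in list(function(x) 3.7 * x, function(x) exp(x),
                 function(x) x^3 + 10)) {
    tr <- run(setNames(f(idx), names(idx)))
    expect_equal(tr$rho, base$rho)
    expect_equal(tr$inferred_source, base$inferred_source)
  }
  # relabeling populations changes nothing
  perm <- sample(25)
  pops2 <- pops[perm, ]
  pops2$pop_id <- sprintf("Q%02d", seq_len(25))
  idx2 <- setNames(idx[perm], pops2$pop_id)
  s2 <- correlation_surface(g, pops2, idx2)
  s1 <- correlation_surface(g, pops, idx)
  expect_equal(s2$values, s1$values)
})

test_that("cell and population direction-test variants agree on strong gradients", {
  sim <- simulate_serial_founder(seed = 31, n_loci = 120, deme_rows = 6,
                                 deme_cols = 8, n_pops = 30,
                                 seq_length = 120)
  idx <- compute_genetic_indices(sim$aflp, sim$hap)
  g <- build_grid(9.4, 44.7, 13.8, 48.1, 0.2)
  s <- lapply(c("gene_div", "rarity"), function(ic)
    rank_cells(correlation_surface(g, sim$pops,
                                   setNames(idx[[ic]], idx$pop_id), ic)))
  comb <- combine_ranks(s)
  d_cell <- direction_test(comb, variant = "cell")
  d_pop <- direction_test(comb, pops = sim$pops, variant = "population")
  expect_equal(d_cell$inferred_source, d_pop$inferred_source)
})
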