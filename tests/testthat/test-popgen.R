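test_that("haplotype diversity matches closed forms and the pair-enumeration oracle", {
  expect_equal(haplotype_diversity(c(4)), 0)
  expect_equal(haplotype_diversity(c(1, 1)), 1)
  expect_equal(haplotype_diversity(c(2, 2)), 2 / 3)  # 4 of 6 pairs differ
  expect_true(is.na(haplotype_diversity(c(1))))
  # h equals the probability two distinct draws differ, exhaustively
  set.seed(11)
  for (rep in 1:20) {
    labels <- sample(letters[1:4], sample(2:6, 1), replace = TRUE)
    expect_equal(haplotype_diversity(table(labels)), pair_diff_prob(labels),
                 tolerance = 1e-12)
  }
})

test_that("nucleotide diversity averages pairwise per-site differences", {
  expect_equal(nucleotide_diversity(c("ACGT", "ACGT")), 0)
  expect_equal(nucleotide_diversity(c("ACGTACGTAC", "ACGTACGTAT")), 0.1)
  expect_equal(nucleotide_diversity(c("AAAA", "AAAT", "AATT")),
               (1 + 2 + 1) / (3 * 4))
  expect_true(is.na(nucleotide_diversity("ACGT")))
  # coded indels count as appended binary sites
  aln <- c(a = "AC-T", b = "ACGT")
  ind <- code_indels(aln)
  expect_equal(nucleotide_diversity(aln, ind), 1 / 5)
})

test_that("dominant-marker gene diversity matches direct evaluation and the pair oracle", {
  expect_equal(aflp_gene_diversity(matrix(1, 4, 3)), 0)
  expect_equal(aflp_gene_diversity(matrix(c(1, 0), 2, 1)), 1)
  # n = 4, loci with p = 0.5 and 1.0
  m <- cbind(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(aflp_gene_diversity(m), mean(c(4 / 3 * 0.5, 0)))
  expect_true(is.na(aflp_gene_diversity(matrix(1, 1, 3))))
  # per-locus value equals the probability two distinct individuals differ
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(2:6, 1); L <- sample(1:4, 1)
    m <- matrix(rbinom(n * L, 1, runif(1, 0.2, 0.8)), n, L)
    expected <- mean(vapply(seq_len(L),
                            function(l) pair_diff_prob(m[, l]), numeric(1)))
    expect_equal(aflp_gene_diversity(m), expected, tolerance = 1e-12)
  }
})

test_that("rarity down-weights by dataset-wide band occurrence and conserves totals", {
  # two singleton pops sharing the single band: each owns half of it
  b <- matrix(c(1, 1), 2, 1, dimnames = list(c("i1", "i2"), NULL))
  x <- aflp_matrix(b, c(i1 = "A", i2 = "B"))
  expect_equal(unname(aflp_rarity(x)), c(0.5, 0.5))
  # a private band contributes 1/n_A to its pop only
  b2 <- rbind(i1 = c(1, 1), i2 = c(1, 0), i3 = c(1, 0))
  x2 <- aflp_matrix(b2, c(i1 = "A", i2 = "A", i3 = "B"))
  dw <- aflp_rarity(x2)
  expect_equal(unname(dw["A"]), (2 / 3 + 1 / 1) / 2)
  expect_equal(unname(dw["B"]), (1 / 3 + 0) / 1)
  # conservation: sum_j n_j DW_j = number of retained loci
  for (seed in 1:5) {
    x3 <- random_aflp(4, 3, 25, seed)
    dw3 <- aflp_rarity(x3)
    n_j <- table(factor(unname(x3$pop_of), levels = names(dw3)))
    kept <- sum(colSums(x3$bands) > 0)
    expect_equal(sum(as.numeric(n_j) * dw3), kept, tolerance = 1e-10)
  }
})

test_that("Jost's D_est hits its endpoints and vanishes under panmixia", {
  # identical populations -> 0
  b <- rbind(i1 = c(1, 0, 1), i2 = c(0, 1, 1),
             i3 = c(1, 0, 1), i4 = c(0, 1, 1))
  x <- aflp_matrix(b, c(i1 = "A", i2 = "A", i3 = "B", i4 = "B"))
  expect_equal(jost_dest(x), 0)
  # fixed presence/absence difference -> 1
  b2 <- rbind(i1 = 1, i2 = 1, i3 = 0, i4 = 0)
  rownames(b2) <- paste0("i", 1:4)
  x2 <- aflp_matrix(b2, setNames(c("A", "A", "B", "B"), paste0("i", 1:4)))
  expect_equal(jost_dest(x2), 1)
  expect_error(jost_dest(aflp_matrix(b2[1:2, , drop = FALSE],
                                     c(i1 = "A", i2 = "A"))), ">= 2")
  # k pops drawn from one panmictic pool -> D_est ~ 0 on average
  # (the band-frequency estimator carries O(1/n) positive bias, so the
  # null is checked at a within-population sample size where that bias
  # is inside the tolerance)
  set.seed(21)
  d <- replicate(200, {
    p <- runif(12, 0.2, 0.8)
    n <- 400
    bands <- t(vapply(seq_len(n), function(i) rbinom(12, 1, p),
                      integer(12)))
    rownames(bands) <- sprintf("i%03d", seq_len(n))
    jost_dest(aflp_matrix(bands,
                          setNames(rep(c("A", "B", "C", "D"), each = 100),
                                   rownames(bands))))
  })
  expect_lt(abs(mean(d)), 0.02)
})

test_that("pairwise D_est is symmetric, zero for duplicates, and matches the global k = 2 path", {
  x <- random_aflp(3, 4, 30, seed = 5)
  d <- pairwise_dest(x)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  # agreement with jost_dest on the pair subset
  sub <- x$pop_of %in% c("pop01", "pop03")
  x2 <- aflp_matrix(x$bands[sub, ], x$pop_of[sub])
  expect_equal(d["pop01", "pop03"], jost_dest(x2))
  # duplicate population -> off-diagonal 0
  b <- x$bands[x$pop_of == "pop01", ]
  rownames(b) <- paste0("d", seq_len(nrow(b)))
  both <- rbind(x$bands[x$pop_of == "pop01", ], b)
  pops <- setNames(rep(c("A", "B"), each = 4), rownames(both))
  expect_equal(pairwise_dest(aflp_matrix(both, pops))["A", "B"], 0)
})

test_that("indices are invariant to individual and locus ordering", {
  x <- random_aflp(4, 4, 20, seed = 33)
  set.seed(34)
  ip <- sample(nrow(x$bands)); lp <- sample(ncol(x$bands))
  xp <- aflp_matrix(x$bands[ip, lp], x$pop_of[ip])
  expect_equal(sort(aflp_rarity(x)), sort(aflp_rarity(xp)))
  expect_equal(jost_dest(x), jost_dest(xp))
  for (p in unique(unname(x$pop_of)))
    expect_equal(aflp_gene_diversity(x$bands[x$pop_of == p, ]),
                 aflp_gene_diversity(xp$bands[xp$pop_of == p, ]))
})

test_that("haversine distances hit the closed form and metric properties", {
  tab <- toy_pop_table(2, lon = c(0, 1), lat = c(0, 0))
  d <- pairwise_geo_distance(tab)
  expect_equal(d[1, 2], 111.195, tolerance = 1e-4)
  expect_equal(d[1, 1], 0)
  tab2 <- toy_pop_table(8, seed = 2)
  d2 <- pairwise_geo_distance(tab2)
  expect_equal(d2, t(d2))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(d2[i, j], d2[i, k] + d2[k, j] + 1e-9)
})

test_that("Mantel test matches the lower-triangle Pearson statistic and its trivial cases", {
  set.seed(40)
  pts <- toy_pop_table(12, seed = 40)
  geo <- pairwise_geo_distance(pts)
  # genetic = geographic -> r = 1, minimal p
  m <- mantel_test(geo, geo, n_perm = 99, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 100)
  # affine reversal -> r = -1
  gen <- max(geo) - geo; diag(gen) <- 0
  m2 <- mantel_test(gen, geo, n_perm = 99, seed = 1)
  expect_equal(m2$r, -1)
  # statistic equals hand Pearson on lower triangles; r2 = r^2
  noise <- matrix(0, 12, 12)
  noise[lower.tri(noise)] <- runif(66, 0, 200)
  gen3 <- geo + noise + t(noise)
  rownames(gen3) <- colnames(gen3) <- rownames(geo)
  m3 <- mantel_test(gen3, geo, n_perm = 99, seed = 2)
  expect_equal(m3$r, cor(gen3[lower.tri(gen3)], geo[lower.tri(geo)]),
               tolerance = 1e-12)
  expect_equal(m3$r2, m3$r^2)
  bad <- geo; rownames(bad) <- colnames(bad) <- paste0("X", 1:12)
  expect_error(mantel_test(bad, geo, n_perm = 9, seed = 1), "labels")
})

test_that("genetic index table flags single-individual populations as undefined", {
  sim <- simulate_serial_founder(seed = 5, n_loci = 40, deme_rows = 4,
                                 deme_cols = 5, n_pops = 8,
                                 individuals_per_pop = 1, seq_length = 80)
  idx <- compute_genetic_indices(sim$aflp, sim$hap)
  expect_true(all(is.na(idx$hap_div)))
  expect_true(all(is.na(idx$gene_div)))
  expect_true(all(idx$rarity > 0))
})
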