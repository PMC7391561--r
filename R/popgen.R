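# Per-population genetic indices for chloroplast sequences and dominant
# AFLP markers, plus Jost's D_est differentiation and the Mantel
# isolation-by-distance test.

#' Unbiased haplotype diversity
#'
#' h = n/(n-1) * (1 - sum(x_i^2)) with x_i the haplotype relative
#' frequencies and n the sample size: the probability that two sequences
#' drawn without replacement differ.
#'
#' @param counts positive integer vector of haplotype counts in one
#'   population.
#' @return h in [0, 1]; `NA` when n < 2 (index undefined).
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Nucleotide diversity (per site)
#'
#' Mean pairwise per-site difference: pi = sum_{i<j} d_ij / C(n,2), where
#' d_ij = (number of differing sites) / (alignment length). Coded indel
#' characters, when supplied, are appended to the alignment as extra
#' binary sites; alignment columns where either sequence of a pair carries
#' a gap or `N` do not count as differences (indel variation enters only
#' through the coded characters), while the denominator is the full
#' alignment length plus the number of indel characters.
#'
#' @param seqs character vector of equal-length aligned sequences for one
#'   population.
#' @param indel_characters optional binary matrix (as from
#'   [code_indels()]), rows matching `seqs`.
#' @return pi in [0, 1]; `NA` when fewer than 2 sequences.
#' @export
nucleotide_diversity <- function(seqs, indel_characters = NULL) {
  n <- length(seqs)
  if (n < 2) return(NA_real_)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("nucleotide_diversity: unequal sequence lengths")
  L <- unname(lens[1])
  n_ind <- 0L
  if (!is.null(indel_characters)) {
    indel_characters <- as.matrix(indel_characters)
    if (nrow(indel_characters) != n)
      stop("nucleotide_diversity: indel_characters rows must match seqs")
    n_ind <- ncol(indel_characters)
  }
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- chars[i, ]; b <- chars[j, ]
      ok <- a != "-" & b != "-" & a != "N" & b != "N"
      d <- sum(a[ok] != b[ok])
      if (n_ind > 0)
        d <- d + sum(indel_characters[i, ] != indel_characters[j, ])
      total <- total + d / (L + n_ind)
    }
  }
  total / choose(n, 2)
}

# dominant-marker allele (band) frequency per locus, with optional
# Hardy-Weinberg square-root correction
.band_freq <- function(bands, estimator = c("band", "sqrt")) {
  estimator <- match.arg(estimator)
  p <- colMeans(bands)
  if (estimator == "sqrt") p <- 1 - sqrt(pmax(0, 1 - p))
  p
}

#' Nei gene diversity for dominant markers (one population)
#'
#' Per locus H_l = n/(n-1) * 2 p_l (1 - p_l), with p_l the band
#' (phenotype) frequency; the population value is the mean over loci. This
#' is the band-frequency convention of the AFLPdat script; set
#' `estimator = "sqrt"` for the Hardy-Weinberg square-root allele-frequency
#' estimator as a sensitivity analysis.
#'
#' @param bands n x L binary band matrix of one population.
#' @param estimator `"band"` (default) or `"sqrt"`.
#' @return gene diversity in [0, 1]; `NA` when n < 2.
#' @export
aflp_gene_diversity <- function(bands, estimator = c("band", "sqrt")) {
  bands <- as.matrix(bands)
  n <- nrow(bands)
  if (n < 2) return(NA_real_)
  p <- .band_freq(bands, estimator)
  mean(n / (n - 1) * 2 * p * (1 - p))
}

#' Frequency-down-weighted marker values (rarity, DW)
#'
#' DW_j = (1/n_j) * sum_l occ_jl / occ_l, where occ_jl is the number of
#' individuals in population j carrying band l and occ_l its dataset-wide
#' occurrence. High values flag populations accumulating rare markers,
#' typical of long-isolated (refugial) populations. Loci absent from the
#' whole dataset are dropped with a warning. The values satisfy
#' sum_j n_j * DW_j = number of retained loci.
#'
#' @param x an [aflp_matrix()] object.
#' @return named numeric vector of DW per population.
#' @export
aflp_rarity <- function(x) {
  stopifnot(inherits(x, "aflp_matrix"))
  bands <- x$bands
  if (nrow(bands) == 0L || ncol(bands) == 0L)
    stop("aflp_rarity: empty AFLP matrix")
  occ_total <- colSums(bands)
  if (any(occ_total == 0)) {
    warning("aflp_rarity: dropping ", sum(occ_total == 0),
            " locus/loci absent from the whole dataset")
    bands <- bands[, occ_total > 0, drop = FALSE]
    occ_total <- occ_total[occ_total > 0]
  }
  pops <- unique(unname(x$pop_of))
  vapply(pops, function(p) {
    rows <- which(x$pop_of == p)
    sum(colSums(bands[rows, , drop = FALSE]) / occ_total) / length(rows)
  }, numeric(1), USE.NAMES = TRUE)
}

# per-population band frequencies (pops x loci) and sample sizes
.pop_band_freq <- function(x, estimator = "band") {
  pops <- unique(unname(x$pop_of))
  p <- vapply(pops, function(pp) {
    .band_freq(x$bands[x$pop_of == pp, , drop = FALSE], estimator)
  }, numeric(ncol(x$bands)))
  p <- matrix(p, nrow = ncol(x$bands))   # loci x pops, even for 1 locus
  t(structure(p, dimnames = list(NULL, pops)))
}

#' Jost's D_est from dominant markers
#'
#' Per locus, H_S = unweighted mean across populations of the within-
#' population expected heterozygosity 2p(1-p) and H_T = 2 pbar (1 - pbar)
#' with pbar the unweighted mean band frequency. Locus means are combined
#' as D = ((Hbar_T - Hbar_S) / (1 - Hbar_S)) * k/(k-1) over the k
#' populations. D is ~0 for undifferentiated populations (small negative
#' sampling values are reported unclamped) and 1 for fixed differences.
#'
#' @param x an [aflp_matrix()] object with >= 2 populations, each with
#'   >= 2 individuals.
#' @param estimator band-frequency convention passed to the allele
#'   frequency estimator (see [aflp_gene_diversity()]).
#' @return D_est (scalar).
#' @export
jost_dest <- function(x, estimator = c("band", "sqrt")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(x, "aflp_matrix"))
  pops <- unique(unname(x$pop_of))
  k <- length(pops)
  if (k < 2) stop("jost_dest: need >= 2 populations")
  n_per <- table(factor(unname(x$pop_of), levels = pops))
  if (any(n_per < 2))
    stop("jost_dest: population(s) with < 2 individuals: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  p <- .pop_band_freq(x, estimator)
  hs_l <- colMeans(2 * p * (1 - p))
  pbar <- colMeans(p)
  ht_l <- 2 * pbar * (1 - pbar)
  hs <- mean(hs_l); ht <- mean(ht_l)
  if (1 - hs <= 0) return(NA_real_)
  (ht - hs) / (1 - hs) * k / (k - 1)
}

#' Pairwise Jost's D_est between populations
#'
#' Applies [jost_dest()] to every population pair (k = 2). Populations
#' with fewer than 2 individuals are excluded with a warning.
#'
#' @inheritParams jost_dest
#' @return symmetric distance matrix with zero diagonal, labelled by
#'   pop_id.
#' @export
pairwise_dest <- function(x, estimator = c("band", "sqrt")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(x, "aflp_matrix"))
  pops <- unique(unname(x$pop_of))
  n_per <- table(factor(unname(x$pop_of), levels = pops))
  if (any(n_per < 2)) {
    warning("pairwise_dest: excluding population(s) with < 2 individuals: ",
            paste(names(n_per)[n_per < 2], collapse = ", "))
    pops <- pops[n_per[pops] >= 2]
  }
  k <- length(pops)
  if (k < 2) stop("pairwise_dest: fewer than 2 usable populations")
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      rows <- x$pop_of %in% pops[c(i, j)]
      sub <- aflp_matrix(x$bands[rows, , drop = FALSE], x$pop_of[rows])
      d[i, j] <- d[j, i] <- jost_dest(sub, estimator)
    }
  }
  d
}

#' Great-circle distance matrix between populations
#'
#' Haversine distances (sphere radius 6371 km) between population
#' coordinates.
#'
#' @param table a `population_table` (or data.frame with `pop_id`, `lon`,
#'   `lat`).
#' @return symmetric distance matrix in km, labelled by pop_id.
#' @export
pairwise_geo_distance <- function(table) {
  stopifnot(all(c("pop_id", "lon", "lat") %in% names(table)))
  xy <- cbind(table$lon, table$lat)
  d <- geosphere::distm(xy, xy,
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(d) <- list(table$pop_id, table$pop_id)
  d
}

#' Mantel test for isolation by distance
#'
#' Pearson correlation between the lower triangles of a genetic and a
#' geographic distance matrix, with a one-sided (greater) permutation test
#' obtained by simultaneous row/column shuffling:
#' p = (#\{r_perm >= r_obs\} + 1) / (n_perm + 1). The permutation engine is
#' `vegan::mantel`.
#'
#' @param genetic,geographic symmetric distance matrices with matching
#'   labels (dimnames); `geographic` is reordered to match `genetic`.
#' @param n_perm number of permutations (the analysis default is 10000).
#' @param seed integer seed for the permutations.
#' @return list with `r`, `r2`, `p`, `n_perm`.
#' @export
mantel_test <- function(genetic, geographic, n_perm = 10000, seed) {
  if (missing(seed)) stop("mantel_test: an explicit seed is required")
  ga <- rownames(genetic); gb <- rownames(geographic)
  if (is.null(ga) || is.null(gb) || !setequal(ga, gb) ||
      length(ga) != length(gb))
    stop("mantel_test: distance-matrix labels do not match")
  geographic <- geographic[ga, ga]
  set.seed(as.integer(seed))
  fit <- vegan::mantel(stats::as.dist(genetic), stats::as.dist(geographic),
                       method = "pearson", permutations = n_perm)
  list(r = unname(fit$statistic), r2 = unname(fit$statistic)^2,
       p = unname(fit$signif), n_perm = n_perm)
}

#' Per-population genetic index table
#'
#' Computes the four per-population indices of the colonization-history
#' analysis: haplotype diversity and nucleotide diversity from the cpDNA
#' alignment (with coded indel characters as extra binary sites), and gene
#' diversity and rarity (DW) from the AFLP bands. Indices requiring n >= 2
#' are `NA` for single-individual populations.
#'
#' @param aflp an [aflp_matrix()] object.
#' @param hap a [haplotype_data()] object (may cover a subset of the AFLP
#'   individuals).
#' @return data.frame with `pop_id`, `n_individuals`, `hap_div`,
#'   `nuc_div`, `gene_div`, `rarity`.
#' @export
compute_genetic_indices <- function(aflp, hap) {
  stopifnot(inherits(aflp, "aflp_matrix"), inherits(hap, "haplotype_data"))
  pops <- unique(unname(aflp$pop_of))
  dw <- aflp_rarity(aflp)
  out <- lapply(pops, function(p) {
    a_rows <- which(aflp$pop_of == p)
    h_rows <- which(hap$pop_of == p)
    hd <- nd <- NA_real_
    if (length(h_rows) >= 2) {
      hd <- haplotype_diversity(table(hap$haplotype_id[h_rows]))
      nd <- nucleotide_diversity(
        hap$alignment[h_rows],
        hap$indel_characters[h_rows, , drop = FALSE])
    }
    data.frame(pop_id = p, n_individuals = length(a_rows),
               hap_div = hd, nuc_div = nd,
               gene_div = aflp_gene_diversity(
                 aflp$bands[a_rows, , drop = FALSE]),
               rarity = unname(dw[p]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
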