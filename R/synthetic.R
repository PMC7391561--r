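# Synthetic-data generators: a serial founder-effect (stepping-stone)
# colonization simulator for the genetic pipeline, a logistic occurrence
# simulator for the GLM pipeline, and stylized elevation rasters.

# named substreams derived from one master seed, so modules can be tested
# independently while all randomness flows from a single integer
.sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Stylized synthetic elevation raster
#'
#' Deterministic (given `seed`) elevation surfaces for exercising the
#' cost-distance machinery: `"flat"` is uniform; `"valley"` is a high
#' plateau cut by one low-elevation north-south corridor (colonization
#' along valley bottoms is cheap); `"ridge"` is lowland crossed by a
#' partial east-west ridge that is cheaper to go around than across.
#'
#' @param lon_min,lat_min,lon_max,lat_max extent in decimal degrees.
#' @param cell_size cell edge in degrees.
#' @param relief `"flat"`, `"valley"` or `"ridge"`.
#' @param seed integer seed for the (small) surface roughness.
#' @param base_elev,high_elev low/high elevations in m.
#' @return a [raster_grid()] of elevations (m).
#' @export
make_synthetic_dem <- function(lon_min, lat_min, lon_max, lat_max,
                               cell_size,
                               relief = c("flat", "valley", "ridge"),
                               seed = 1,
                               base_elev = 500, high_elev = 2500) {
  relief <- match.arg(relief)
  nc <- as.integer(round((lon_max - lon_min) / cell_size))
  nr <- as.integer(round((lat_max - lat_min) / cell_size))
  stopifnot(nc >= 1L, nr >= 1L)
  m <- matrix(base_elev, nr, nc)
  if (relief == "valley") {
    m[] <- high_elev
    corridor <- max(1L, round(nc / 2))
    m[, corridor] <- base_elev / 2
  } else if (relief == "ridge") {
    mid <- max(2L, round(nr / 2))
    ridge_rows <- intersect((mid - 1L):(mid + 1L), seq_len(nr))
    ridge_cols <- seq_len(max(1L, round(nc * 0.7)))  # a way around remains
    m[ridge_rows, ridge_cols] <- high_elev * 4
  }
  if (relief != "flat") {
    set.seed(.sub_seed(seed, "dem"))
    m <- m + matrix(stats::runif(nr * nc, 0, base_elev / 100), nr, nc)
  }
  raster_grid(m, origin = c(lon_min, lat_min), cellsize = cell_size)
}

#' Serial founder-effect colonization simulator
#'
#' Stepping-stone simulation of a postglacial range expansion across a
#' lattice of demes. The source edge (one row of demes at the northern or
#' southern margin) starts with an ancestral gene pool; the remaining
#' demes are colonized wavefront-style in order of increasing cost
#' distance from the source edge (computed with [accumulate_cost()] on a
#' synthetic elevation raster, tying the simulator to the cost-distance
#' module). Each new deme is founded from its already-colonized neighbour
#' with the smallest cost distance: `founder_size` diploid founders are
#' binomially sampled from the parent's allele frequencies (and
#' `founder_size` chloroplast lineages multinomially from its haplotype
#' frequencies), after which the deme drifts for `generations_per_step`
#' Wright-Fisher generations at size `deme_size`. Serial founding erodes
#' diversity and rarity away from the source, the gradient the downstream
#' grid-correlation inference detects.
#'
#' When `founder_size == deme_size` and `generations_per_step == 0` the
#' founding is a deterministic transplantation of the parent pool (no
#' drift at all), so every deme is identical and all diversity gradients
#' are flat.
#'
#' AFLP loci are dominant biallelic markers: the underlying allele
#' frequency q drifts and a sampled individual shows the band with
#' probability 1 - (1 - q)^2 (two genome copies visible as one band);
#' `band_mode = "haploid"` uses probability q for simpler unit tests.
#'
#' @param lon_min,lat_min,lon_max,lat_max study extent (decimal degrees);
#'   defaults cover an Eastern-Alps-sized transect.
#' @param deme_rows,deme_cols lattice dimensions.
#' @param source_edge `"south"` or `"north"`.
#' @param n_pops number of demes sampled as populations (default 68).
#' @param individuals_per_pop sampled individuals per population
#'   (default 4, emulating ~3.5 genotyped individuals per population).
#' @param n_loci AFLP loci (default 370).
#' @param n_haplotypes_source distinct chloroplast haplotypes in the
#'   ancestral pool.
#' @param founder_size founders per colonization event (K).
#' @param deme_size deme size after expansion (N, >= K).
#' @param generations_per_step Wright-Fisher generations between
#'   colonization steps.
#' @param seq_length length of the simulated cpDNA alignment (bp, before
#'   the coded indel).
#' @param band_mode `"dominant"` (default) or `"haploid"`.
#' @param dem optional [raster_grid()] elevation raster at deme-lattice
#'   resolution; default is a flat surface.
#' @param seed integer master seed (required; all substreams derive from
#'   it).
#' @return list with `pops` (a `population_table`), `aflp`
#'   ([aflp_matrix()]), `hap` ([haplotype_data()]), `true_source`, and
#'   `demes` (per-deme lattice info incl. cost distance).
#' @export
simulate_serial_founder <- function(lon_min = 9.4, lat_min = 44.7,
                                    lon_max = 13.9, lat_max = 48.1,
                                    deme_rows = 10, deme_cols = 13,
                                    source_edge = c("south", "north"),
                                    n_pops = 68, individuals_per_pop = 4,
                                    n_loci = 370,
                                    n_haplotypes_source = 8,
                                    founder_size = 10, deme_size = 50,
                                    generations_per_step = 5,
                                    seq_length = 500,
                                    band_mode = c("dominant", "haploid"),
                                    dem = NULL, seed) {
  source_edge <- match.arg(source_edge)
  band_mode <- match.arg(band_mode)
  if (missing(seed)) stop("simulate_serial_founder: seed is required")
  stopifnot(founder_size <= deme_size, founder_size >= 1,
            n_pops <= deme_rows * deme_cols, individuals_per_pop >= 1)
  no_drift <- founder_size == deme_size && generations_per_step == 0

  dlat <- (lat_max - lat_min) / deme_rows
  dlon <- (lon_max - lon_min) / deme_cols
  if (is.null(dem)) {
    dem <- raster_grid(matrix(500, deme_rows, deme_cols),
                       origin = c(lon_min, lat_min), cellsize = dlat)
  }
  stopifnot(dem$n_rows == deme_rows, dem$n_cols == deme_cols)
  src <- matrix(0, deme_rows, deme_cols)
  if (source_edge == "south") src[deme_rows, ] <- 1 else src[1, ] <- 1
  surf <- accumulate_cost(dem, raster_grid(src, origin = dem$origin,
                                           cellsize = dem$cellsize),
                          mode = "flat")
  cd <- surf$raster$values
  if (anyNA(cd))
    stop("simulate_serial_founder: unreachable deme(s) on the lattice")

  n_demes <- deme_rows * deme_cols
  # deme index = (row - 1) * deme_cols + col (row 1 = north)
  ord <- order(as.vector(t(cd)), as.vector(t(row(cd))),
               as.vector(t(col(cd))))
  colonized <- rep(FALSE, n_demes)
  q <- matrix(NA_real_, n_demes, n_loci)      # band allele frequencies
  hapf <- matrix(NA_real_, n_demes, n_haplotypes_source)

  set.seed(.sub_seed(seed, "ancestral"))
  q0 <- stats::runif(n_loci, 0.1, 0.9)
  h0 <- rep(1 / n_haplotypes_source, n_haplotypes_source)

  drift_locus <- function(qv, size) stats::rbinom(n_loci, size, qv) / size
  set.seed(.sub_seed(seed, "colonization"))
  cdv <- as.vector(t(cd))
  for (idx in ord) {
    r <- (idx - 1L) %/% deme_cols + 1L
    c0 <- (idx - 1L) %% deme_cols + 1L
    if (src[r, c0] == 1) {                    # ancestral pool at the edge
      q[idx, ] <- q0; hapf[idx, ] <- h0
      colonized[idx] <- TRUE
      next
    }
    nb <- expand.grid(dr = -1:1, dc = -1:1)
    nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
    nr2 <- r + nb$dr; nc2 <- c0 + nb$dc
    ok <- nr2 >= 1 & nr2 <= deme_rows & nc2 >= 1 & nc2 <= deme_cols
    nid <- (nr2[ok] - 1L) * deme_cols + nc2[ok]
    nid <- nid[colonized[nid]]
    if (!length(nid))
      stop("simulate_serial_founder: wavefront reached an isolated deme")
    parent <- nid[which.min(cdv[nid])]
    if (no_drift) {
      q[idx, ] <- q[parent, ]
      hapf[idx, ] <- hapf[parent, ]
    } else {
      qf <- stats::rbinom(n_loci, 2L * founder_size, q[parent, ]) /
        (2L * founder_size)
      hf <- as.vector(stats::rmultinom(1, founder_size, hapf[parent, ])) /
        founder_size
      if (generations_per_step > 0) {
        for (g in seq_len(generations_per_step)) {
          qf <- drift_locus(qf, 2L * deme_size)
          hf <- as.vector(stats::rmultinom(1, deme_size, hf)) / deme_size
        }
      }
      q[idx, ] <- qf; hapf[idx, ] <- hf
    }
    colonized[idx] <- TRUE
  }

  set.seed(.sub_seed(seed, "sampling"))
  pop_demes <- sort(sample.int(n_demes, n_pops))
  pop_ids <- sprintf("P%03d", seq_len(n_pops))
  deme_r <- (pop_demes - 1L) %/% deme_cols + 1L
  deme_c <- (pop_demes - 1L) %% deme_cols + 1L
  lat <- lat_max - (deme_r - 0.5) * dlat
  lon <- lon_min + (deme_c - 0.5) * dlon

  ind_ids <- as.vector(vapply(seq_len(n_pops), function(i)
    paste0(pop_ids[i], "_i", seq_len(individuals_per_pop)),
    character(individuals_per_pop)))
  pop_of <- stats::setNames(rep(pop_ids, each = individuals_per_pop),
                            ind_ids)
  bands <- matrix(0L, length(ind_ids), n_loci,
                  dimnames = list(ind_ids,
                                  sprintf("L%03d", seq_len(n_loci))))
  hap_of_ind <- integer(length(ind_ids))
  for (i in seq_len(n_pops)) {
    rows <- seq((i - 1L) * individuals_per_pop + 1L,
                i * individuals_per_pop)
    qv <- q[pop_demes[i], ]
    p_band <- if (band_mode == "dominant") 1 - (1 - qv)^2 else qv
    bands[rows, ] <- t(vapply(seq_along(rows), function(k)
      stats::rbinom(n_loci, 1L, p_band), integer(n_loci)))
    hap_of_ind[rows] <- sample.int(n_haplotypes_source,
                                   length(rows), replace = TRUE,
                                   prob = hapf[pop_demes[i], ])
  }

  # haplotype sequences: ancestral random sequence, ~3 private
  # substitutions per haplotype; haplotype 2 also carries a 4-bp deletion
  # so the indel-coding path is exercised
  set.seed(.sub_seed(seed, "sequences"))
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, seq_length, replace = TRUE)
  hap_seqs <- character(n_haplotypes_source)
  mut_pos <- sample.int(seq_length - 10L, 3L * n_haplotypes_source)
  for (h in seq_len(n_haplotypes_source)) {
    s <- anc
    for (pos in mut_pos[(3 * (h - 1) + 1):(3 * h)])
      s[pos] <- bases[(match(s[pos], bases)) %% 4 + 1]
    if (h == 2L) s[5:8] <- "-"
    hap_seqs[h] <- paste(s, collapse = "")
  }
  alignment <- stats::setNames(hap_seqs[hap_of_ind], ind_ids)

  set.seed(.sub_seed(seed, "covariates"))
  n <- n_pops
  elev_at <- dem$values[cbind(deme_r, deme_c)]
  pops <- data.frame(
    pop_id = pop_ids, lon = lon, lat = lat,
    present_4x = 1L, present_5x = 0L, present_7x = 0L, present_8x = 0L,
    elevation = elev_at + stats::runif(n, -50, 50),
    inclination = stats::runif(n, 0, 40),
    aspect = stats::runif(n, 0, 180),
    land_use = stats::rbinom(n, 1, 0.5),
    ndvi = stats::runif(n, 0.2, 0.9),
    bio04 = stats::rnorm(n, 650, 60),
    bio12 = stats::runif(n, 600, 1600),
    bio15 = stats::rnorm(n, 30, 6))
  pops <- as_population_table(pops)

  list(pops = pops,
       aflp = aflp_matrix(bands, pop_of),
       hap = haplotype_data(alignment, pop_of),
       true_source = source_edge,
       demes = data.frame(deme = seq_len(n_demes),
                          row = (seq_len(n_demes) - 1L) %/% deme_cols + 1L,
                          col = (seq_len(n_demes) - 1L) %% deme_cols + 1L,
                          cost_distance = cdv))
}

#' Logistic occurrence simulator for the cytotype-distribution model
#'
#' Draws a population table whose sexual-cytotype occurrence follows the
#' binomial GLM the analysis fits:
#' logit Pr(sexual present) = b0 + beta_eco . x + beta_hist * cd +
#' beta_apo . z, where x are the z-scored ecological covariates (the
#' generator draws the latent standardized values from an exchangeable
#' correlated Gaussian and maps them to raw covariate scales by strictly
#' increasing transforms, so the analysis-side standardization recovers
#' them), cd is the standardized cost distance and z are Bernoulli
#' apomict presences.
#'
#' Defaults are the study conditions: n = 235 populations; the Table-style
#' coefficient vector (ecology and apomict effects, no history effect) as
#' generator truth; apomict prevalences (0.35, 0.25, 0.12) so that about
#' 57% of populations contain an apomict; and an intercept moment-matched
#' to a sexual prevalence of ~0.583 (137/235).
#'
#' @param n_pops number of populations (default 235).
#' @param beta0 intercept on the logit scale.
#' @param beta_eco named length-8 coefficient vector over (elevation,
#'   inclination, aspect, land_use, ndvi, bio04, bio12, bio15).
#' @param beta_hist coefficient of standardized cost distance.
#' @param beta_apo length-3 coefficient vector over (present_5x,
#'   present_7x, present_8x).
#' @param apo_prev length-3 apomict cytotype prevalences in (0,1).
#' @param landuse_prev prevalence of mesohemerobic (1) land use.
#' @param cov_rho exchangeable correlation among the 7 continuous
#'   covariates and cost distance (must keep the correlation matrix
#'   positive definite).
#' @param lon_min,lat_min,lon_max,lat_max extent for the random
#'   population coordinates.
#' @param seed integer master seed (required).
#' @return a `population_table` with `cost_distance` filled and an
#'   attribute `truth` holding the generator coefficients.
#' @export
simulate_occurrence <- function(n_pops = 235,
                                beta0 = 3.64,
                                beta_eco = c(elevation = -0.33,
                                             inclination = 0.58,
                                             aspect = 0.12,
                                             land_use = -2.24,
                                             ndvi = 0.06, bio04 = 0.00,
                                             bio12 = -0.71, bio15 = 0.22),
                                beta_hist = 0,
                                beta_apo = c(present_5x = -3.65,
                                             present_7x = -1.56,
                                             present_8x = -2.49),
                                apo_prev = c(0.35, 0.25, 0.12),
                                landuse_prev = 0.5,
                                cov_rho = 0.2,
                                lon_min = 9.4, lat_min = 44.7,
                                lon_max = 13.9, lat_max = 48.1,
                                seed) {
  if (missing(seed)) stop("simulate_occurrence: seed is required")
  stopifnot(length(beta_eco) == 8, length(beta_apo) == 3,
            length(apo_prev) == 3, all(apo_prev > 0 & apo_prev < 1),
            all(is.finite(c(beta0, beta_eco, beta_hist, beta_apo))))
  p_cont <- 8L  # 7 continuous eco covariates + cost distance
  S <- matrix(cov_rho, p_cont, p_cont); diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("simulate_occurrence: covariate correlation not positive ",
         "definite (cov_rho = ", cov_rho, ")")
  set.seed(.sub_seed(seed, "occurrence"))
  Z <- matrix(stats::rnorm(n_pops * p_cont), n_pops) %*% chol(S)
  colnames(Z) <- c("elevation", "inclination", "aspect", "ndvi",
                   "bio04", "bio12", "bio15", "cost_distance")
  lu <- stats::rbinom(n_pops, 1, landuse_prev)
  apo <- cbind(present_5x = stats::rbinom(n_pops, 1, apo_prev[1]),
               present_7x = stats::rbinom(n_pops, 1, apo_prev[2]),
               present_8x = stats::rbinom(n_pops, 1, apo_prev[3]))
  eta <- beta0 +
    Z[, 1:7] %*% beta_eco[c("elevation", "inclination", "aspect", "ndvi",
                            "bio04", "bio12", "bio15")] +
    beta_eco[["land_use"]] * lu +
    beta_hist * Z[, "cost_distance"] +
    apo %*% beta_apo
  y <- stats::rbinom(n_pops, 1, stats::plogis(as.numeric(eta)))

  pops <- data.frame(
    pop_id = sprintf("S%03d", seq_len(n_pops)),
    lon = stats::runif(n_pops, lon_min, lon_max),
    lat = stats::runif(n_pops, lat_min, lat_max),
    present_4x = y,
    present_5x = apo[, 1], present_7x = apo[, 2], present_8x = apo[, 3],
    # strictly increasing affine maps latent z -> raw covariate scales
    elevation = 800 + 300 * Z[, "elevation"],
    inclination = 20 + 8 * Z[, "inclination"],
    aspect = pmin(180, pmax(0, 90 + 25 * Z[, "aspect"])),
    land_use = lu,
    ndvi = 0.5 + 0.15 * Z[, "ndvi"],
    bio04 = 650 + 80 * Z[, "bio04"],
    bio12 = (9.5 + 0.8 * Z[, "bio12"])^3,   # cube root is ~N(9.5, 0.8)
    bio15 = 30 + 8 * Z[, "bio15"],
    cost_distance = 300 + 100 * Z[, "cost_distance"])
  pops <- as_population_table(pops)
  # the exact design matrix the generator used, for parameter-recovery
  # studies (the raw covariates are increasing transforms of these)
  attr(pops, "latent") <- data.frame(Z[, 1:7, drop = FALSE],
                                     land_use = lu,
                                     cost_distance = Z[, "cost_distance"],
                                     apo)
  attr(pops, "truth") <- list(beta0 = beta0, beta_eco = beta_eco,
                              beta_hist = beta_hist, beta_apo = beta_apo,
                              apo_prev = apo_prev,
                              landuse_prev = landuse_prev,
                              cov_rho = cov_rho)
  pops
}

#' Wald-interval recovery study for the occurrence model
#'
#' Repeatedly simulates cytotype occurrence data from the logistic model
#' logit Pr(sexual) = b0 + beta_eco * x + beta_apo . z (one standardized
#' ecological covariate plus the three apomict presence flags), refits the
#' generating model, and reports the pooled empirical coverage of the 95%
#' Wald intervals for the three apomict coefficients. With a correctly
#' calibrated fitter the pooled coverage is ~0.95; substantially lower
#' values would flag miscalibrated standard errors.
#'
#' @param n_reps number of simulation replicates.
#' @param n_pops populations per replicate.
#' @param beta0 intercept (default moment-matched to a sexual prevalence
#'   of ~0.583 under the default effects).
#' @param beta_eco coefficient of the single standardized ecological
#'   covariate.
#' @param beta_apo length-3 coefficients of the apomict presence flags.
#' @param apo_prev length-3 apomict prevalences.
#' @param seed integer master seed.
#' @return list with `coverage` (pooled over the apomict coefficients),
#'   `per_coefficient` coverage, `mean_estimates`, `n_checks`, `n_reps`.
#' @export
wald_recovery_study <- function(n_reps = 500, n_pops = 235,
                                beta0 = 2.44, beta_eco = -0.71,
                                beta_apo = c(-3.65, -1.56, -2.49),
                                apo_prev = c(0.35, 0.25, 0.12), seed) {
  if (missing(seed)) stop("wald_recovery_study: seed is required")
  set.seed(.sub_seed(seed, "recovery"))
  hit <- est <- matrix(NA_real_, n_reps, 3)
  for (r in seq_len(n_reps)) {
    x <- stats::rnorm(n_pops)
    z <- cbind(z1 = stats::rbinom(n_pops, 1, apo_prev[1]),
               z2 = stats::rbinom(n_pops, 1, apo_prev[2]),
               z3 = stats::rbinom(n_pops, 1, apo_prev[3]))
    eta <- beta0 + beta_eco * x + as.numeric(z %*% beta_apo)
    y <- stats::rbinom(n_pops, 1, stats::plogis(eta))
    f <- suppressWarnings(fit_binomial_glm(y, data.frame(x = x, z)))
    co <- f$coefficients
    for (k in 1:3) {
      row <- co[co$term == colnames(z)[k], ]
      est[r, k] <- row$estimate
      hit[r, k] <- as.numeric(beta_apo[k] >= row$estimate - 1.96 * row$se &&
                                beta_apo[k] <= row$estimate + 1.96 * row$se)
    }
  }
  list(coverage = mean(hit), per_coefficient = colMeans(hit),
       mean_estimates = colMeans(est), n_checks = length(hit),
       n_reps = n_reps)
}
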