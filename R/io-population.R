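# Population table and AFLP matrix containers plus predictor preparation.

.pop_required_cols <- c("pop_id", "lon", "lat",
                        "present_4x", "present_5x", "present_7x",
                        "present_8x",
                        "elevation", "inclination", "aspect", "land_use",
                        "ndvi", "bio04", "bio12", "bio15")

.pop_continuous <- c("elevation", "inclination", "aspect", "ndvi",
                     "bio04", "bio12", "bio15")

#' Read a population table
#'
#' Reads the per-population CSV holding coordinates (WGS84 decimal
#' degrees), binary cytotype occurrence flags (tetra/penta/hepta/octoploid)
#' and the ecological covariates used as GLM predictors. An optional
#' `cost_distance` column (filled by [extract_cost()]) is carried through.
#'
#' @param path path to a CSV file with a header row.
#' @return a `data.frame` of class `population_table`, one row per
#'   population.
#' @export
read_population_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.pop_required_cols, names(df))
  if (length(missing_cols))
    stop("population table '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  as_population_table(df)
}

#' Validate a data.frame as a population table
#'
#' @param df data.frame with the population-table columns.
#' @return `df` with class `population_table` prepended.
#' @export
as_population_table <- function(df) {
  missing_cols <- setdiff(.pop_required_cols, names(df))
  if (length(missing_cols))
    stop("population table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_coord <- which(!is.finite(df$lon) | !is.finite(df$lat))
  if (length(bad_coord))
    stop("population table: missing/non-finite coordinates in row(s) ",
         paste(bad_coord, collapse = ", "))
  if (anyDuplicated(df$pop_id))
    stop("population table: duplicated pop_id: ",
         paste(unique(df$pop_id[duplicated(df$pop_id)]), collapse = ", "))
  for (fl in c("present_4x", "present_5x", "present_7x", "present_8x")) {
    bad <- which(!(df[[fl]] %in% c(0, 1)))
    if (length(bad))
      stop("population table: non-binary ", fl, " in row(s) ",
           paste(bad, collapse = ", "))
  }
  bad_aspect <- which(!is.na(df$aspect) & (df$aspect < 0 | df$aspect > 180))
  if (length(bad_aspect))
    stop("population table: aspect outside [0, 180] in row(s) ",
         paste(bad_aspect, collapse = ", "),
         " (aspect is divergence from north)")
  bad_bio12 <- which(!is.na(df$bio12) & df$bio12 < 0)
  if (length(bad_bio12))
    stop("population table: negative bio12 (annual precipitation) in ",
         "row(s) ", paste(bad_bio12, collapse = ", "))
  if (!inherits(df, "population_table"))
    class(df) <- c("population_table", class(df))
  df
}

#' Prepare GLM predictor matrices from a population table
#'
#' Builds the three predictor blocks of the variation-partitioning model:
#' \describe{
#'   \item{eco}{elevation, inclination, aspect, land_use, ndvi, bio04,
#'     bio12, bio15. Annual precipitation (bio12) is cube-root transformed
#'     before scaling; all continuous variables are z-scored (sample SD,
#'     n-1 denominator); the binary land-use indicator
#'     (0 = oligohemerobic/(semi)natural, 1 = mesohemerobic) is left
#'     unscaled.}
#'   \item{hist}{z-scored cost distance from the colonization source
#'     (requires `cost_distance`, see [extract_cost()]).}
#'   \item{apo}{binary presence of the penta-, hepta- and octoploid
#'     apomictic cytotypes.}
#' }
#' Populations with a missing value in any used column are dropped
#' (listwise deletion) with a warning naming them.
#'
#' @param table a `population_table`.
#' @param scale_cost_distance set `FALSE` to keep cost distance on its
#'   native accumulated-cost scale.
#' @return list with matrices `eco` (n x 8), `hist` (n x 1), `apo` (n x 3),
#'   the binary response `y` (presence of the sexual tetraploid cytotype)
#'   and `pop_id` of the retained rows.
#' @export
prepare_predictors <- function(table, scale_cost_distance = TRUE) {
  table <- as_population_table(table)
  if (!"cost_distance" %in% names(table))
    stop("prepare_predictors: 'cost_distance' column missing; ",
         "run extract_cost() first")
  used <- c(.pop_continuous, "land_use", "cost_distance",
            "present_4x", "present_5x", "present_7x", "present_8x")
  keep <- stats::complete.cases(table[used])
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " population(s) with missing values: ",
            paste(table$pop_id[!keep], collapse = ", "))
    table <- table[keep, , drop = FALSE]
  }
  zscore <- function(x, name) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("prepare_predictors: zero variance in column '", name, "'")
    (x - mean(x)) / s
  }
  eco <- cbind(
    elevation   = zscore(table$elevation, "elevation"),
    inclination = zscore(table$inclination, "inclination"),
    aspect      = zscore(table$aspect, "aspect"),
    land_use    = as.numeric(table$land_use),
    ndvi        = zscore(table$ndvi, "ndvi"),
    bio04       = zscore(table$bio04, "bio04"),
    bio12       = zscore(table$bio12^(1 / 3), "bio12"),
    bio15       = zscore(table$bio15, "bio15"))
  hist <- cbind(cost_distance = if (scale_cost_distance)
    zscore(table$cost_distance, "cost_distance") else
      as.numeric(table$cost_distance))
  apo <- cbind(present_5x = as.numeric(table$present_5x),
               present_7x = as.numeric(table$present_7x),
               present_8x = as.numeric(table$present_8x))
  rownames(eco) <- rownames(hist) <- rownames(apo) <- table$pop_id
  list(eco = eco, hist = hist, apo = apo,
       y = as.numeric(table$present_4x), pop_id = table$pop_id)
}

#' Construct an AFLP band matrix
#'
#' @param bands individuals x loci binary (0/1) matrix with individual ids
#'   as row names.
#' @param pop_of named character vector mapping individual id -> pop_id.
#' @return list of class `aflp_matrix` with `bands`, `individuals`,
#'   `pop_of`, `n_loci`.
#' @export
aflp_matrix <- function(bands, pop_of) {
  bands <- as.matrix(bands)
  if (is.null(rownames(bands)))
    stop("aflp_matrix: bands must have individual ids as row names")
  if (!all(bands %in% c(0, 1)))
    stop("aflp_matrix: band entries must be 0/1")
  miss <- setdiff(rownames(bands), names(pop_of))
  if (length(miss))
    stop("aflp_matrix: individuals without population mapping: ",
         paste(miss, collapse = ", "))
  structure(list(bands = bands,
                 individuals = rownames(bands),
                 pop_of = pop_of[rownames(bands)],
                 n_loci = ncol(bands)),
            class = "aflp_matrix")
}

#' Read an AFLP matrix from CSV
#'
#' Expected layout: columns `individual`, `pop_id`, then one 0/1 column per
#' locus.
#'
#' @param path path to the CSV file.
#' @return an [aflp_matrix()] object.
#' @export
read_aflp_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("individual", "pop_id") %in% names(df)))
    stop("AFLP CSV '", path, "' needs 'individual' and 'pop_id' columns")
  loci <- setdiff(names(df), c("individual", "pop_id"))
  if (!length(loci)) stop("AFLP CSV '", path, "' has no locus columns")
  bands <- as.matrix(df[loci])
  rownames(bands) <- df$individual
  aflp_matrix(bands, stats::setNames(df$pop_id, df$individual))
}

#' Write an AFLP matrix to CSV
#'
#' @param x an [aflp_matrix()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aflp_matrix <- function(x, path) {
  stopifnot(inherits(x, "aflp_matrix"))
  df <- data.frame(individual = x$individuals,
                   pop_id = unname(x$pop_of),
                   x$bands, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
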