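# Grid-based colonization-source inference: genetic diversity and rarity
# decay away from the source through serial founder effects, so cells near
# the source show strongly negative correlations between
# centroid-to-population distance and the populations' index values.

#' Build a regular lon/lat analysis grid
#'
#' @param lon_min,lat_min,lon_max,lat_max extent in decimal degrees.
#' @param cell_size cell edge in degrees (the analysis default is 0.1).
#' @return list of class `analysis_grid` with the bounds, `cell_size`,
#'   `n_rows`, `n_cols` and a `cells` data.frame (`row`, `col`, centroid
#'   `lon`, `lat`; row 1 = southernmost).
#' @export
build_grid <- function(lon_min, lat_min, lon_max, lat_max, cell_size) {
  stopifnot(lon_max > lon_min, lat_max > lat_min, cell_size > 0)
  nx <- (lon_max - lon_min) / cell_size
  ny <- (lat_max - lat_min) / cell_size
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop(sprintf(paste0("build_grid: extent is not an integer number of ",
                        "cells; snap bounds, e.g. lon_max = %g, ",
                        "lat_max = %g"),
                 lon_min + ceiling(nx) * cell_size,
                 lat_min + ceiling(ny) * cell_size))
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  if (nx < 1L || ny < 1L)
    stop("build_grid: cell_size larger than the extent")
  cells <- expand.grid(row = seq_len(ny), col = seq_len(nx))
  cells$lon <- lon_min + (cells$col - 0.5) * cell_size
  cells$lat <- lat_min + (cells$row - 0.5) * cell_size
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 cell_size = cell_size, n_rows = ny, n_cols = nx,
                 n_cells = nx * ny, cells = cells),
            class = "analysis_grid")
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat(sprintf("<analysis_grid> %d x %d = %d cells of %g deg, lon [%g, %g], lat [%g, %g]\n",
              x$n_rows, x$n_cols, x$n_cells, x$cell_size,
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

.same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("lon_min", "lon_max", "lat_min", "lat_max",
                       "cell_size")],
                   b[c("lon_min", "lon_max", "lat_min", "lat_max",
                       "cell_size")]))
}

.grid_surface <- function(grid, values, index_name, kind) {
  structure(list(grid = grid, values = values, index_name = index_name,
                 kind = kind),
            class = "grid_surface")
}

#' @export
print.grid_surface <- function(x, ...) {
  cat(sprintf("<grid_surface> %s '%s': %d cells (%d defined), range [%g, %g]\n",
              x$kind, x$index_name, length(x$values),
              sum(!is.na(x$values)),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Per-cell distance/index correlation surface
#'
#' For every grid cell, Spearman's rank correlation between the distance
#' from the cell centroid to each population and the populations' values
#' of one genetic index. Cells at or near the colonization source show
#' strongly negative coefficients (diversity decays with distance from the
#' source); cells far from it show none or positive ones.
#'
#' @param grid an [build_grid()] grid.
#' @param pops a `population_table` (only `pop_id`, `lon`, `lat` used).
#' @param index_values named numeric vector of one index per population
#'   (names = pop_id); populations with `NA` are excluded pairwise.
#' @param index_name label stored on the surface.
#' @param distance `"haversine"` (km, default) or `"planar"` (degrees).
#' @return a `grid_surface` of correlation coefficients (NA where
#'   undefined).
#' @export
correlation_surface <- function(grid, pops, index_values,
                                index_name = "index",
                                distance = c("haversine", "planar")) {
  distance <- match.arg(distance)
  stopifnot(inherits(grid, "analysis_grid"))
  if (is.null(names(index_values)))
    stop("correlation_surface: index_values must be named by pop_id")
  keep <- !is.na(index_values)
  ids <- names(index_values)[keep]
  miss <- setdiff(ids, pops$pop_id)
  if (length(miss))
    stop("correlation_surface: index values for unknown pop_id: ",
         paste(miss, collapse = ", "))
  if (sum(keep) < 3)
    stop("correlation_surface: need >= 3 populations with defined index")
  v <- index_values[keep]
  pt <- pops[match(ids, pops$pop_id), ]
  if (stats::sd(v) == 0) {
    warning("correlation_surface: constant index values; ",
            "all cells undefined")
    return(.grid_surface(grid, rep(NA_real_, grid$n_cells), index_name,
                         "correlation"))
  }
  cl <- grid$cells
  if (distance == "haversine") {
    dmat <- geosphere::distm(cbind(cl$lon, cl$lat), cbind(pt$lon, pt$lat),
                             fun = function(a, b)
                               geosphere::distHaversine(a, b, r = 6371000))
  } else {
    dmat <- sqrt(outer(cl$lon, pt$lon, "-")^2 +
                   outer(cl$lat, pt$lat, "-")^2)
  }
  rv <- rank(v)
  vals <- apply(dmat, 1L, function(d) {
    suppressWarnings(stats::cor(rank(d), rv, method = "pearson"))
  })
  .grid_surface(grid, as.numeric(vals), index_name, "correlation")
}

#' Rank cells of a correlation surface
#'
#' Ascending ranks: rank 1 = most negative correlation = most source-like
#' (refugium-like) cell. Ties get average ranks; undefined cells stay `NA`
#' and are excluded from the ranking.
#'
#' @param surface a correlation `grid_surface`.
#' @return a `grid_surface` of ranks.
#' @export
rank_cells <- function(surface) {
  stopifnot(inherits(surface, "grid_surface"))
  if (all(is.na(surface$values)))
    stop("rank_cells: all cells undefined")
  r <- rank(surface$values, ties.method = "average", na.last = "keep")
  .grid_surface(surface$grid, as.numeric(r), surface$index_name, "rank")
}

#' Combine per-index rank surfaces
#'
#' Per-cell arithmetic mean of the per-index ranks (the combined ranking of
#' the analysis). All surfaces must share one grid.
#'
#' @param surfaces list of >= 2 rank `grid_surface`s on identical grids.
#' @return a `grid_surface` of combined ranks.
#' @export
combine_ranks <- function(surfaces) {
  stopifnot(is.list(surfaces), length(surfaces) >= 2L)
  g <- surfaces[[1]]$grid
  for (s in surfaces) {
    stopifnot(inherits(s, "grid_surface"))
    if (!.same_grid(s$grid, g))
      stop("combine_ranks: surfaces are on different grids")
  }
  m <- do.call(cbind, lapply(surfaces, `[[`, "values"))
  .grid_surface(g, rowMeans(m), "combined", "combined_rank")
}

#' Latitude direction test for the colonization source
#'
#' Correlates the combined cell ranks with latitude (Spearman). Because
#' rank 1 marks the most source-like cell, a positive rho (low ranks in
#' the south) locates the source at the southern ice margin, a negative
#' rho at the northern one.
#'
#' Two variants: `"cell"` correlates each cell's combined rank with the
#' cell centroid latitude; `"population"` assigns each population the
#' combined rank of its containing cell and correlates those with the
#' population latitudes.
#'
#' @param combined a combined-rank `grid_surface`.
#' @param pops `population_table`; required for `variant = "population"`.
#' @param variant `"cell"` (default) or `"population"`.
#' @param method `"asymptotic"` (t approximation, default) or
#'   `"permutation"`.
#' @param n_perm,seed permutation settings when `method = "permutation"`.
#' @return list of class `direction_result` with `rho`, `p`,
#'   `inferred_source` (`"south"` or `"north"`), `variant`, `n`.
#' @export
direction_test <- function(combined, pops = NULL,
                           variant = c("cell", "population"),
                           method = c("asymptotic", "permutation"),
                           n_perm = 9999, seed = NULL) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  stopifnot(inherits(combined, "grid_surface"))
  if (variant == "cell") {
    keep <- !is.na(combined$values)
    xs <- combined$values[keep]
    lats <- combined$grid$cells$lat[keep]
  } else {
    if (is.null(pops)) stop("direction_test: pops required for the ",
                            "population variant")
    xs <- surface_value_at(combined, pops$lon, pops$lat)
    lats <- pops$lat
    keep <- !is.na(xs)
    xs <- xs[keep]; lats <- lats[keep]
  }
  if (length(xs) < 3) stop("direction_test: fewer than 3 defined cells")
  rho <- stats::cor(xs, lats, method = "spearman")
  if (method == "asymptotic") {
    p <- stats::cor.test(xs, lats, method = "spearman",
                         exact = FALSE)$p.value
  } else {
    if (is.null(seed)) stop("direction_test: seed required for ",
                            "permutation method")
    set.seed(as.integer(seed))
    perm <- replicate(n_perm,
                      abs(stats::cor(xs, sample(lats), method = "spearman")))
    p <- (sum(perm >= abs(rho)) + 1) / (n_perm + 1)
  }
  structure(list(rho = rho, p = p,
                 inferred_source = if (rho > 0) "south" else "north",
                 variant = variant, n = length(xs)),
            class = "direction_result")
}

#' @export
print.direction_result <- function(x, ...) {
  cat(sprintf(
    "Colonization direction test (%s variant, n = %d):\n  Spearman rho = %.3f, p = %.3g -> inferred source: %s margin\n",
    x$variant, x$n, x$rho, x$p, x$inferred_source))
  invisible(x)
}

#' Look up surface values at point coordinates
#'
#' @param surface a `grid_surface`.
#' @param lon,lat coordinate vectors.
#' @return surface values of the containing cells (`NA` outside the grid).
#' @export
surface_value_at <- function(surface, lon, lat) {
  g <- surface$grid
  col <- floor((lon - g$lon_min) / g$cell_size) + 1L
  row <- floor((lat - g$lat_min) / g$cell_size) + 1L
  # points on the max edge belong to the last cell
  col[lon == g$lon_max] <- g$n_cols
  row[lat == g$lat_max] <- g$n_rows
  ok <- col >= 1L & col <= g$n_cols & row >= 1L & row <= g$n_rows
  idx <- ifelse(ok, (col - 1L) * g$n_rows + row, NA_integer_)
  # cells are ordered row-fastest by expand.grid(row, col)
  out <- rep(NA_real_, length(lon))
  out[ok] <- surface$values[idx[ok]]
  out
}

#' Convert a grid surface to a raster
#'
#' @param surface a `grid_surface`.
#' @return a [raster_grid()] (row 1 = north) suitable for
#'   [write_raster()].
#' @export
surface_as_raster <- function(surface) {
  g <- surface$grid
  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  m[cbind(g$n_rows - surface$grid$cells$row + 1L, surface$grid$cells$col)] <-
    surface$values
  raster_grid(m, origin = c(g$lon_min, g$lat_min), cellsize = g$cell_size)
}
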