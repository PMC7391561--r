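# Least accumulative cost distance over a raster, following the ESRI
# cost-distance model: 8-connected cells, move cost between adjacent cells
# a and b = (cost_a + cost_b)/2 * planimetric distance, with the sqrt(2)
# factor on diagonal moves. The accumulation is an exact Dijkstra shortest
# path (igraph) from all source cells simultaneously.

.cell_id <- function(r, c, nc) (r - 1L) * nc + c

#' Rasterize a source line onto a raster template
#'
#' Marks as source every cell whose center lies within half a cell size of
#' the line, plus every cell the line passes through (supercover via dense
#' sampling), so the rasterized line is a connected chain.
#'
#' @param line two-column matrix of (lon, lat) vertices (>= 2), e.g. from
#'   [read_geojson_line()].
#' @param template a [raster_grid()] providing extent and resolution.
#' @return a binary [raster_grid()] (1 = source cell).
#' @export
rasterize_source <- function(line, template) {
  stopifnot(inherits(template, "refugeo_raster"))
  line <- as.matrix(line)
  stopifnot(ncol(line) == 2L, nrow(line) >= 2L)
  nr <- template$n_rows; nc <- template$n_cols
  cs <- template$cellsize
  xll <- template$origin[1]; yll <- template$origin[2]
  mask <- matrix(0, nr, nc)
  # centers
  cx <- xll + (seq_len(nc) - 0.5) * cs
  cy <- yll + (nr - seq_len(nr) + 0.5) * cs
  seg_dist <- function(px, py, x1, y1, x2, y2) {
    vx <- x2 - x1; vy <- y2 - y1
    l2 <- vx^2 + vy^2
    t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * vx +
                                                (py - y1) * vy) / l2))
    sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
  }
  for (s in seq_len(nrow(line) - 1L)) {
    x1 <- line[s, 1]; y1 <- line[s, 2]
    x2 <- line[s + 1, 1]; y2 <- line[s + 1, 2]
    # proximity criterion on cell centers
    for (r in seq_len(nr)) {
      d <- seg_dist(cx, cy[r], x1, y1, x2, y2)
      mask[r, d < cs / 2] <- 1
    }
    # supercover: dense sampling along the segment
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    n_step <- max(2L, ceiling(len / (cs / 4)))
    tt <- seq(0, 1, length.out = n_step)
    sx <- x1 + tt * (x2 - x1); sy <- y1 + tt * (y2 - y1)
    col <- floor((sx - xll) / cs) + 1L
    row <- nr - floor((sy - yll) / cs)
    ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
    mask[cbind(row[ok], col[ok])] <- 1
  }
  if (sum(mask) == 0)
    stop("rasterize_source: line does not intersect the raster extent")
  raster_grid(mask, origin = template$origin, cellsize = cs,
              nodata = template$nodata, units = template$units)
}

#' Accumulate least cost distance from source cells
#'
#' Computes, for every cell, the least accumulative cost of reaching it
#' from any source cell, moving between 8-connected cells with move cost
#' (cost_a + cost_b)/2 times the planimetric cell distance (diagonals
#' scaled by sqrt(2)). `NA` (nodata) cells are impassable. Cost values at
#' or below zero are floored at `cost_floor` to keep edge weights positive.
#'
#' In `"flat"` mode the cell distance is `cellsize` in raster units; in
#' `"geographic"` mode (degree rasters) the N-S cell dimension is
#' 111.195 km/degree and the E-W dimension is scaled by the cosine of the
#' cell-row latitude, so accumulated costs are in cost-units x km.
#'
#' @param cost a [raster_grid()] of per-cell impedance (e.g. elevation in
#'   m).
#' @param sources a binary [raster_grid()] with the same dimensions
#'   (1 = source).
#' @param mode `"flat"` or `"geographic"`.
#' @param cost_floor minimum per-cell cost (default 1).
#' @return list of class `cost_surface` with `raster` (accumulated costs;
#'   0 on sources, `NA` on nodata/unreachable cells) and `source_mask`.
#' @export
accumulate_cost <- function(cost, sources, mode = c("flat", "geographic"),
                            cost_floor = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(cost, "refugeo_raster"),
            inherits(sources, "refugeo_raster"))
  if (cost$n_rows != sources$n_rows || cost$n_cols != sources$n_cols)
    stop("accumulate_cost: cost and source rasters differ in shape")
  nr <- cost$n_rows; nc <- cost$n_cols
  cm <- cost$values
  if (all(is.na(cm))) stop("accumulate_cost: all-nodata cost raster")
  cm[!is.na(cm) & cm < cost_floor] <- cost_floor
  src <- which(sources$values == 1 & !is.na(cm))
  if (!length(src)) stop("accumulate_cost: no (traversable) source cell")

  km_deg <- 111.195
  lat_row <- cost$origin[2] + (nr - seq_len(nr) + 0.5) * cost$cellsize
  dx_row <- if (mode == "geographic")
    km_deg * cost$cellsize * cos(lat_row * pi / 180) else
      rep(cost$cellsize, nr)
  dy <- if (mode == "geographic") km_deg * cost$cellsize else cost$cellsize

  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  edge_set <- function(dr, dc) {
    ra <- if (dr == 0L) seq_len(nr) else seq_len(nr - dr)
    ca <- if (dc >= 0L) seq_len(nc - dc) else seq(1L - dc, nc)
    a <- as.vector(outer(ra, ca, function(r, c) .cell_id(r, c, nc)))
    b <- as.vector(outer(ra, ca, function(r, c) .cell_id(r + dr, c + dc, nc)))
    ar <- as.vector(outer(ra, ca, function(r, c) r))
    step <- if (dr == 0L) dx_row[ar]
    else if (dc == 0L) rep(dy, length(a))
    else sqrt(((dx_row[ar] + dx_row[ar + dr]) / 2)^2 + dy^2)
    list(a = a, b = b, step = step)
  }
  es <- lapply(list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)),
               function(o) edge_set(o[1], o[2]))
  a <- unlist(lapply(es, `[[`, "a"))
  b <- unlist(lapply(es, `[[`, "b"))
  step <- unlist(lapply(es, `[[`, "step"))
  cv <- as.vector(t(cm))            # by cell id = (r-1)*nc + c
  w <- (cv[a] + cv[b]) / 2 * step
  ok <- !is.na(w)
  a <- a[ok]; b <- b[ok]; w <- w[ok]

  n_cells <- nr * nc
  virt <- n_cells + 1L
  src_id <- .cell_id(rows[src], cols[src], nc)
  g <- igraph::make_empty_graph(n = virt, directed = FALSE)
  g <- igraph::add_edges(g, c(as.vector(rbind(a, b)),
                              as.vector(rbind(rep(virt, length(src_id)),
                                              src_id))))
  wts <- c(w, rep(0, length(src_id)))
  d <- igraph::distances(g, v = virt, weights = wts, algorithm = "dijkstra")
  d <- as.numeric(d)[seq_len(n_cells)]
  d[!is.finite(d)] <- NA_real_
  ids <- seq_len(n_cells) - 1L
  out <- matrix(NA_real_, nr, nc)
  out[cbind(ids %/% nc + 1L, ids %% nc + 1L)] <- d
  out[is.na(cm)] <- NA_real_
  structure(list(raster = raster_grid(out, origin = cost$origin,
                                      cellsize = cost$cellsize,
                                      nodata = cost$nodata,
                                      units = cost$units),
                 source_mask = sources, mode = mode),
            class = "cost_surface")
}

#' @export
print.cost_surface <- function(x, ...) {
  cat(sprintf("<cost_surface> (%s mode), %d source cells\n", x$mode,
              sum(x$source_mask$values == 1, na.rm = TRUE)))
  print(x$raster)
  invisible(x)
}

#' Extract cost distance at population locations
#'
#' Fills `cost_distance` in the population table with the accumulated cost
#' of the containing cell. Populations falling on nodata cells get `NA`
#' with a warning (they are later dropped from the history predictor by
#' listwise deletion); populations outside the raster extent are an error.
#'
#' @param surface a `cost_surface` from [accumulate_cost()].
#' @param pops a `population_table`.
#' @return `pops` with the `cost_distance` column filled.
#' @export
extract_cost <- function(surface, pops) {
  stopifnot(inherits(surface, "cost_surface"))
  ras <- surface$raster
  cs <- ras$cellsize
  col <- floor((pops$lon - ras$origin[1]) / cs) + 1L
  rowb <- floor((pops$lat - ras$origin[2]) / cs) + 1L   # from bottom
  xmax <- ras$origin[1] + ras$n_cols * cs
  ymax <- ras$origin[2] + ras$n_rows * cs
  col[pops$lon == xmax] <- ras$n_cols
  rowb[pops$lat == ymax] <- ras$n_rows
  outside <- col < 1L | col > ras$n_cols | rowb < 1L | rowb > ras$n_rows
  if (any(outside))
    stop("extract_cost: population(s) outside raster extent: ",
         paste(pops$pop_id[outside], collapse = ", "))
  r <- ras$n_rows - rowb + 1L
  vals <- ras$values[cbind(r, col)]
  if (anyNA(vals))
    warning("extract_cost: population(s) on nodata cells, cost_distance ",
            "set NA: ", paste(pops$pop_id[is.na(vals)], collapse = ", "))
  pops$cost_distance <- vals
  pops
}
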