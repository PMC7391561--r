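# Readers/writers for the plain-text geodata formats the pipeline consumes:
# FASTA alignments, ESRI ASCII grids and GeoJSON LineStrings.

#' Create a raster grid
#'
#' Lightweight in-memory raster used for elevation/cost surfaces. Values are
#' stored as a matrix whose first row is the northernmost row (the ESRI
#' ASCII grid convention); `origin` is the lower-left corner of the extent.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param origin length-2 numeric, (lon, lat) of the lower-left corner.
#' @param cellsize cell edge length (degrees by default; any unit may be
#'   declared via `units`).
#' @param nodata sentinel value written to file for missing cells; in
#'   memory missing cells are `NA`.
#' @param units `"degrees"` or `"metres"`; geographic computations are only
#'   defined for degree rasters.
#' @return an object of class `refugeo_raster`.
#' @export
raster_grid <- function(values, origin, cellsize, nodata = -9999,
                        units = c("degrees", "metres")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L, cellsize > 0,
            length(origin) == 2L, all(is.finite(origin)))
  structure(
    list(values = values, n_rows = nrow(values), n_cols = ncol(values),
         origin = as.numeric(origin), cellsize = as.numeric(cellsize),
         nodata = nodata, units = units),
    class = "refugeo_raster")
}

#' @export
print.refugeo_raster <- function(x, ...) {
  cat(sprintf("<refugeo_raster> %d x %d cells, cellsize %g %s\n",
              x$n_rows, x$n_cols, x$cellsize, x$units))
  cat(sprintf("  lower-left corner: (%g, %g); %d NA cells\n",
              x$origin[1], x$origin[2], sum(is.na(x$values))))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard `ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by rows of values, northernmost row first.
#' `xllcenter`/`yllcenter` headers are accepted and converted to corners.
#'
#' @param path path to a `.asc` file.
#' @param units unit declaration for the cellsize (not stored in the
#'   format itself).
#' @return a [raster_grid()] object; nodata cells become `NA`.
#' @export
read_raster <- function(path, units = c("degrees", "metres")) {
  units <- match.arg(units)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L)
    stop("malformed ESRI ASCII grid '", path, "': fewer than 6 lines")
  hdr <- list(); i <- 1L
  while (i <= length(lines) && grepl("^\\s*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed header at line ", i, " of '", path, "': ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("ESRI ASCII grid '", path, "' header lacks: ",
         paste(setdiff(req, names(hdr)), collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2 else
      stop("ESRI ASCII grid '", path, "' lacks xllcorner/xllcenter")
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2 else
      stop("ESRI ASCII grid '", path, "' lacks yllcorner/yllcenter")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ESRI ASCII grid '", path, "': expected ",
         hdr$ncols * hdr$nrows, " values after header, found ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, origin = c(xll, yll), cellsize = cs, nodata = nodata,
              units = units)
}

#' Write an ESRI ASCII grid
#'
#' @param x a [raster_grid()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  stopifnot(inherits(x, "refugeo_raster"))
  m <- x$values
  m[is.na(m)] <- x$nodata
  hdr <- c(
    sprintf("ncols %d", x$n_cols),
    sprintf("nrows %d", x$n_rows),
    sprintf("xllcorner %.10g", x$origin[1]),
    sprintf("yllcorner %.10g", x$origin[2]),
    sprintf("cellsize %.10g", x$cellsize),
    sprintf("NODATA_value %.10g", x$nodata))
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE,
                                                scientific = FALSE,
                                                digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Cell centroid coordinates of a raster
#'
#' @param x a [raster_grid()] object.
#' @return data.frame with `row`, `col`, `lon`, `lat` (row 1 = north).
#' @export
raster_centroids <- function(x) {
  stopifnot(inherits(x, "refugeo_raster"))
  g <- expand.grid(row = seq_len(x$n_rows), col = seq_len(x$n_cols))
  g$lon <- x$origin[1] + (g$col - 0.5) * x$cellsize
  g$lat <- x$origin[2] + (x$n_rows - g$row + 0.5) * x$cellsize
  g
}

#' Read an aligned FASTA file
#'
#' @param path path to a FASTA file.
#' @param aligned if `TRUE` (default) all sequences must have equal length.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path, aligned = TRUE) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- names(seqs)
  ids <- sub("\\s.*$", "", ids)  # id = first token of the header
  if (anyDuplicated(ids))
    stop("duplicate sequence id in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- ids
  if (aligned && length(unique(nchar(out))) > 1L)
    stop("sequences in '", path, "' are not aligned (unequal lengths)")
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a GeoJSON LineString as a source line
#'
#' Accepts a bare LineString geometry, a Feature wrapping one, or a
#' FeatureCollection whose first feature is a LineString.
#'
#' @param path path to a GeoJSON file.
#' @return matrix with columns `lon`, `lat` (>= 2 vertices).
#' @export
read_geojson_line <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  geom <- g
  if (identical(g$type, "FeatureCollection")) {
    if (length(g$features) == 0L) stop("GeoJSON '", path, "' has no features")
    geom <- list(type = g$features$geometry$type[[1]],
                 coordinates = g$features$geometry$coordinates[[1]])
  } else if (identical(g$type, "Feature")) {
    geom <- g$geometry
  }
  if (!identical(geom$type, "LineString"))
    stop("GeoJSON '", path, "': expected a LineString geometry, got ",
         if (is.null(geom$type)) "<missing type>" else geom$type)
  m <- geom$coordinates
  if (is.list(m)) m <- do.call(rbind, m)
  m <- matrix(as.numeric(m), ncol = 2L,
              dimnames = list(NULL, c("lon", "lat")))
  if (nrow(m) < 2L)
    stop("GeoJSON LineString in '", path, "' has fewer than 2 vertices")
  m
}

#' Write a source line to GeoJSON
#'
#' @param vertices two-column matrix of (lon, lat) vertices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geojson_line <- function(vertices, path) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 2L)
  obj <- list(type = "LineString",
              coordinates = lapply(seq_len(nrow(vertices)),
                                   function(i) as.numeric(vertices[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
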