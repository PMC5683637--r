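#' @include AllClasses.R
NULL

#' Cell-centre coordinates
#'
#' @param spec a [GridSpec-class]
#' @param rows,cols cell indices (vectorised, recycled)
#' @return two-column matrix of x/y cell-centre coordinates
#' @export
cellCenters <- function(spec, rows, cols) {
  cbind(
    x = spec@originX + (cols - 0.5) * spec@cellSize,
    y = spec@originY + (spec@nrows - rows + 0.5) * spec@cellSize
  )
}

#' Cell indices containing points
#'
#' Points on a cell boundary belong to the cell to the right/below
#' (half-open cells), except on the top/right extent edge which is closed.
#'
#' @param spec a [GridSpec-class]
#' @param x,y point coordinates (vectorised)
#' @return two-column integer matrix `(row, col)`; `NA` rows for points
#'   outside the extent
#' @export
cellFromXY <- function(spec, x, y) {
  cs <- spec@cellSize
  col <- floor((x - spec@originX) / cs) + 1
  row <- spec@nrows - floor((y - spec@originY) / cs)
  # points exactly on the top or right edge belong to the edge cell
  col[x == spec@originX + spec@ncols * cs] <- spec@ncols
  row[y == spec@originY + spec@nrows * cs] <- 1
  bad <- col < 1 | col > spec@ncols | row < 1 | row > spec@nrows |
    is.na(col) | is.na(row)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

insideExtent <- function(spec, x, y) {
  cs <- spec@cellSize
  x >= spec@originX & x <= spec@originX + spec@ncols * cs &
    y >= spec@originY & y <= spec@originY + spec@nrows * cs
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text `.asc` raster exchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' row-major cell values, top row first.  `readAsc()` maps the nodata
#' sentinel to `NA`; `writeAsc()` writes `NA` cells as the spec's sentinel.
#'
#' @param path file path
#' @param raster a [GridRaster-class]
#' @return `readAsc()`: a [GridRaster-class]; `writeAsc()`: `path`,
#'   invisibly.
#' @examples
#' r <- GridRaster(matrix(rnorm(20), 4, 5), GridSpec(4, 5))
#' f <- tempfile(fileext = ".asc")
#' writeAsc(r, f)
#' r2 <- readAsc(f)
#' all.equal(gridValues(r), gridValues(r2))
#' @export
readAsc <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- lapply(strsplit(trimws(lines), "\\s+"), function(p) {
    list(key = tolower(p[1]), value = as.numeric(p[2]))
  })
  hdr <- stats::setNames(
    vapply(kv, `[[`, numeric(1), "value"),
    vapply(kv, `[[`, character(1), "key")
  )
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed .asc header in ", path)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr[["nodata_value"]] else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr[["nrows"]])
  nc <- as.integer(hdr[["ncols"]])
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cell values, got ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  GridRaster(m, GridSpec(nr, nc,
    cellSize = hdr[["cellsize"]],
    originX = hdr[["xllcorner"]], originY = hdr[["yllcorner"]],
    nodata = nodata
  ))
}

#' @rdname readAsc
#' @export
writeAsc <- function(raster, path) {
  spec <- raster@spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec@ncols),
    sprintf("nrows %d", spec@nrows),
    sprintf("xllcorner %.10g", spec@originX),
    sprintf("yllcorner %.10g", spec@originY),
    sprintf("cellsize %.10g", spec@cellSize),
    sprintf("NODATA_value %.10g", spec@nodata)
  ), con)
  m <- raster@values
  m[is.na(m)] <- spec@nodata
  utils::write.table(
    format(m, trim = TRUE, digits = 15, scientific = FALSE),
    con,
    row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write an environmental stack as one `.asc` file per layer
#'
#' @param stack an [EnvStack-class]
#' @param dir output directory (created if absent)
#' @return character vector of written paths, invisibly
#' @export
writeStackAsc <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(layerNames(stack), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    writeAsc(stack[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a directory of `.asc` layers as a stack
#'
#' @param dir directory containing `.asc` files (layer name = file stem)
#' @return an [EnvStack-class]
#' @export
readStackAsc <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc files found in ", dir)
  rasters <- lapply(files, readAsc)
  layers <- lapply(rasters, gridValues)
  names(layers) <- sub("\\.asc$", "", basename(files))
  EnvStack(layers, gridSpec(rasters[[1]]))
}
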