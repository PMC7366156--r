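#' Lightweight planar raster
#'
#' A minimal single-band raster in projected metre coordinates: a numeric
#' matrix plus a georeference. Rows run north to south, columns west to east
#' (the layout of the plain-text ESRI ASCII grid format used for I/O), and
#' values refer to cell centers.
#'
#' @param values numeric matrix, `nrow = ny` (row 1 = northernmost row),
#'   `ncol = nx`.
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cellsize cell edge length in m.
#' @param nodata value standing for missing cells on file (internally `NA`).
#' @return an object of class `nfi_raster`.
#' @export
nfi_raster <- function(values, xmin, ymin, cellsize, nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), cellsize > 0, is.finite(xmin), is.finite(ymin))
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize,
         nodata = nodata),
    class = "nfi_raster"
  )
}

#' @export
print.nfi_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<nfi_raster> %d rows x %d cols, cell %.6g m\n  extent x:[%.6g, %.6g] y:[%.6g, %.6g]\n  values: [%.4g, %.4g]%s\n",
    d[1], d[2], x$cellsize,
    x$xmin, x$xmin + d[2] * x$cellsize,
    x$ymin, x$ymin + d[1] * x$cellsize,
    suppressWarnings(min(x$values, na.rm = TRUE)),
    suppressWarnings(max(x$values, na.rm = TRUE)),
    if (anyNA(x$values)) sprintf(" (%d NA)", sum(is.na(x$values))) else ""
  ))
  invisible(x)
}

#' @rdname nfi_raster
#' @param r an `nfi_raster`.
#' @export
raster_extent <- function(r) {
  d <- dim(r$values)
  c(xmin = r$xmin, xmax = r$xmin + d[2] * r$cellsize,
    ymin = r$ymin, ymax = r$ymin + d[1] * r$cellsize)
}

#' Cell-center coordinates of all cells
#'
#' @param r an `nfi_raster`.
#' @return data.frame with columns `x`, `y`, `value`, in row-major (north to
#'   south, west to east) order.
#' @export
raster_xy <- function(r) {
  d <- dim(r$values)
  ymax <- r$ymin + d[1] * r$cellsize
  xs <- r$xmin + (seq_len(d[2]) - 0.5) * r$cellsize
  ys <- ymax - (seq_len(d[1]) - 0.5) * r$cellsize
  data.frame(
    x = rep(xs, times = d[1]),
    y = rep(ys, each = d[2]),
    value = as.vector(t(r$values))
  )
}

#' Nearest-cell raster lookup
#'
#' @param r an `nfi_raster`.
#' @param x,y point coordinates (m); vectors of equal length.
#' @return values at the cells containing the points; `NA` outside the grid.
#' @export
raster_extract <- function(r, x, y) {
  d <- dim(r$values)
  ymax <- r$ymin + d[1] * r$cellsize
  col <- floor((x - r$xmin) / r$cellsize) + 1L
  row <- floor((ymax - y) / r$cellsize) + 1L
  # points exactly on the top/right edge belong to the edge cell
  col[x == r$xmin + d[2] * r$cellsize] <- d[2]
  row[y == r$ymin + d[1] * r$cellsize] <- 1L
  ok <- col >= 1L & col <= d[2] & row >= 1L & row <= d[1] &
    !is.na(col) & !is.na(row)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Bilinear raster interpolation
#'
#' Interpolates between the four surrounding cell centers; outside the ring
#' of outermost centers the nearest-cell value is used.
#'
#' @inheritParams raster_extract
#' @export
raster_interpolate <- function(r, x, y) {
  d <- dim(r$values)
  cs <- r$cellsize
  ymax <- r$ymin + d[1] * cs
  # fractional column/row in cell-center coordinates
  fc <- (x - (r$xmin + 0.5 * cs)) / cs + 1
  fr <- ((ymax - 0.5 * cs) - y) / cs + 1
  c0 <- pmin(pmax(floor(fc), 1), d[2] - 1L)
  r0 <- pmin(pmax(floor(fr), 1), d[1] - 1L)
  if (d[2] == 1L) c0 <- rep(1L, length(x))
  if (d[1] == 1L) r0 <- rep(1L, length(x))
  tx <- pmin(pmax(fc - c0, 0), 1)
  ty <- pmin(pmax(fr - r0, 0), 1)
  c1 <- pmin(c0 + 1L, d[2]); r1 <- pmin(r0 + 1L, d[1])
  v00 <- r$values[cbind(r0, c0)]; v01 <- r$values[cbind(r0, c1)]
  v10 <- r$values[cbind(r1, c0)]; v11 <- r$values[cbind(r1, c1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text raster exchange format (`.asc`): a 6-line header followed by
#' the value matrix from the northernmost row down.
#'
#' @param r an `nfi_raster`.
#' @param path file path.
#' @export
write_asc <- function(r, path) {
  d <- dim(r$values)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", r$nodata)
  ), con)
  v <- r$values
  v[is.na(v)] <- r$nodata
  writeLines(apply(v, 1, function(row) paste(sprintf("%.10g", row), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- val("ncols"); nrows <- val("nrows")
  m <- matrix(
    as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+"))),
    nrow = nrows, ncol = ncols, byrow = TRUE
  )
  nodata <- val("NODATA_value")
  m[m == nodata] <- NA_real_
  nfi_raster(m, val("xllcorner"), val("yllcorner"), val("cellsize"), nodata)
}
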