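#' Raster grid objects
#'
#' A `nr_grid` is the package's raster container: a numeric matrix with square
#' cells of known size (metres) and a top-left origin, row 1 = north. Nodata is
#' stored as `NA`. All layers taking part in one analysis must be *compatible*:
#' same dimensions, cell size and origin.
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, (x, y) map coordinates of the top-left
#'   corner of the top-left cell.
#' @return An object of class `nr_grid`.
#' @export
nr_grid <- function(values, cell_size = 30, origin = c(0, 0)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            length(origin) == 2L)
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "nr_grid")
}

#' Categorical land-use grid
#'
#' A `nr_lucc` grid carries integer class codes plus a legend mapping code to
#' class name. The canonical legend covers the seven classes cropland, forest,
#' shrub, grassland, water, barren and developed, coded 1..7.
#'
#' @param codes integer matrix of class codes (`NA` = nodata).
#' @param cell_size,origin see [nr_grid()].
#' @param legend named integer vector, names are class names.
#' @return Object of classes `nr_lucc`, `nr_grid`.
#' @export
nr_lucc <- function(codes, cell_size = 30, origin = c(0, 0),
                    legend = lucc_legend()) {
  g <- nr_grid(codes, cell_size, origin)
  present <- unique(g$values[!is.na(g$values)])
  if (!all(present %in% legend))
    stop("land-use codes not in legend: ", paste(setdiff(present, legend), collapse = ", "))
  g$legend <- legend
  class(g) <- c("nr_lucc", "nr_grid")
  g
}

#' Canonical seven-class land-use legend
#'
#' @return Named integer vector code per class, in the fixed order
#'   cropland, forest, shrub, grassland, water, barren, developed.
#' @export
lucc_legend <- function() {
  c(cropland = 1L, forest = 2L, shrub = 3L, grassland = 4L,
    water = 5L, barren = 6L, developed = 7L)
}

#' @export
print.nr_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<%s> %d x %d cells of %g m, origin (%g, %g)\n",
              class(x)[1], nrow(v), ncol(v), x$cell_size,
              x$origin[1], x$origin[2]))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  valid: %d/%d, range [%g, %g]\n", sum(ok), length(v),
                min(v[ok]), max(v[ok])))
  invisible(x)
}

#' Test two grids for compatibility
#'
#' Compatible means identical shape, cell size and origin; all layers in one
#' analysis must pass.
#' @param a,b `nr_grid` objects.
#' @return logical.
#' @export
grids_compatible <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

check_compatible <- function(..., .what = "grids") {
  gs <- list(...)
  for (i in seq_along(gs)[-1])
    if (!grids_compatible(gs[[1]], gs[[i]]))
      stop("incompatible ", .what,
           ": shape/cell_size/origin must match across all layers")
  invisible(TRUE)
}

#' Cell area in hectares
#' @param grid an `nr_grid`.
#' @return scalar, cell_size^2 / 1e4.
#' @export
cell_area_ha <- function(grid) grid$cell_size^2 / 1e4

## shifted copy of a matrix: result[i,j] = m[i+dr, j+dc], NA outside
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr); ci <- seq_len(nc)
  rs <- ri + dr; cs <- ci + dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[ri[rok], ci[cok]] <- m[rs[rok], cs[cok]]
  out
}

## D8 neighbour table in tie-break priority order E, S, W, N, SE, SW, NW, NE
d8_offsets <- function(cell_size = 1) {
  data.frame(
    code = 1:8,
    name = c("E", "S", "W", "N", "SE", "SW", "NW", "NE"),
    dr = c(0L, 1L, 0L, -1L, 1L, 1L, -1L, -1L),
    dc = c(1L, 0L, -1L, 0L, 1L, -1L, -1L, 1L),
    step = cell_size * c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))
  )
}

#' Read an ESRI ASCII grid
#'
#' Plain-text `.asc` raster exchange format (ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value header followed by row-major values, first row =
#' north).
#'
#' @param path file path.
#' @return an `nr_grid`.
#' @export
read_asc <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ESRI ASCII header in ", path)
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("value count does not match header in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  yll <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  nr_grid(m, cell_size = hdr$cellsize,
          origin = c(xll, yll + nr * hdr$cellsize))
}

#' Write an ESRI ASCII grid
#'
#' @param grid an `nr_grid`.
#' @param path output path.
#' @param nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - nr * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
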