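#' Aggregate pixel export to a coarse analysis lattice
#'
#' Tiles the raster extent with square analysis cells (default 1500 m), sums
#' pixel export within each cell footprint by the pixel-centre rule, and drops
#' cells whose valid-pixel fraction falls below `min_valid`.
#'
#' @param export export `nr_grid` (kg per pixel).
#' @param cell_size_out analysis cell edge (m), default 1500.
#' @param min_valid minimum fraction of valid pixels for a cell to be kept.
#' @return data.frame of class `cell_frame`: `cell_id`, `row`, `col`,
#'   `x`, `y` (centroid), `value` (kg), `valid_fraction`; attribute
#'   `dropped_value` holds the export sum over dropped cells.
#' @export
aggregate_grid <- function(export, cell_size_out = 1500, min_valid = 0.5) {
  stopifnot(cell_size_out > 0, min_valid >= 0, min_valid <= 1)
  v <- export$values
  nr <- nrow(v); nc <- ncol(v)
  cs <- export$cell_size
  ## pixel-centre offsets from the top-left corner
  px_x <- (col(v) - 0.5) * cs
  px_y <- (row(v) - 0.5) * cs   # measured downward from the north edge
  ccol <- floor(px_x / cell_size_out) + 1L
  crow <- floor(px_y / cell_size_out) + 1L
  id <- (crow - 1L) * max(ccol) + ccol
  valid <- !is.na(v)
  n_tot <- tapply(rep(1, length(id)), id, sum)
  n_val <- tapply(as.numeric(valid), id, sum)
  val <- tapply(ifelse(valid, v, 0), id, sum)
  ids <- as.integer(names(n_tot))
  crow_u <- (ids - 1L) %/% max(ccol) + 1L
  ccol_u <- (ids - 1L) %% max(ccol) + 1L
  frame <- data.frame(
    cell_id = ids, row = crow_u, col = ccol_u,
    x = export$origin[1] + (ccol_u - 0.5) * cell_size_out,
    y = export$origin[2] - (crow_u - 0.5) * cell_size_out,
    value = as.numeric(val),
    valid_fraction = as.numeric(n_val / n_tot)
  )
  keep <- frame$valid_fraction >= min_valid & frame$valid_fraction > 0
  dropped_value <- sum(frame$value[!keep])
  frame <- frame[keep, , drop = FALSE]
  if (!nrow(frame)) stop("no analysis cells survive the min_valid filter")
  rownames(frame) <- NULL
  attr(frame, "dropped_value") <- dropped_value
  attr(frame, "cell_size_out") <- cell_size_out
  class(frame) <- c("cell_frame", "data.frame")
  frame
}

#' Getis-Ord Gi* statistic per analysis cell
#'
#' Self-inclusive local clustering z-score:
#' Gi* = (sum_j w_ij x_j - xbar W_i) / (S sqrt((n sum_j w_ij^2 - W_i^2)/(n-1)))
#' with xbar and S the global mean and population standard deviation and
#' W_i = sum_j w_ij. Default weights: binary queen contiguity on the lattice,
#' self included; alternatively a fixed distance band.
#'
#' @param cells `cell_frame` from [aggregate_grid()].
#' @param scheme `"queen"` (default) or `"distance"`.
#' @param radius band radius in metres for `scheme = "distance"`.
#' @return `cells` with a `z` column added.
#' @export
gi_star <- function(cells, scheme = c("queen", "distance"), radius = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(cells)
  if (n < 3) stop("need at least 3 cells")
  x <- cells$value
  xbar <- mean(x)
  s <- sqrt(mean((x - xbar)^2))
  if (s == 0) stop("constant field: Gi* undefined")
  z <- numeric(n)
  for (i in seq_len(n)) {
    if (scheme == "queen") {
      w <- as.numeric(abs(cells$row - cells$row[i]) <= 1 &
                        abs(cells$col - cells$col[i]) <= 1)
    } else {
      if (is.null(radius)) stop("distance scheme needs a radius")
      d2 <- (cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2
      w <- as.numeric(d2 <= radius^2)
    }
    wi <- sum(w)
    num <- sum(w * x) - xbar * wi
    den <- s * sqrt((n * sum(w^2) - wi^2) / (n - 1))
    z[i] <- num / den
  }
  cells$z <- z
  cells
}

#' Classify Gi* z-scores into confidence categories
#'
#' Fixed two-sided normal thresholds: |z| >= 2.576 -> 99%, >= 1.960 -> 95%,
#' >= 1.645 -> 90%; the sign separates hot from cold; otherwise not
#' significant.
#'
#' @param z numeric vector of Gi* z-scores.
#' @return factor with levels cold99, cold95, cold90, ns, hot90, hot95, hot99.
#' @export
classify_hotspots <- function(z) {
  stopifnot(all(is.finite(z)))
  lev <- c("cold99", "cold95", "cold90", "ns", "hot90", "hot95", "hot99")
  out <- rep("ns", length(z))
  out[z >= 1.645] <- "hot90"; out[z >= 1.960] <- "hot95"; out[z >= 2.576] <- "hot99"
  out[z <= -1.645] <- "cold90"; out[z <= -1.960] <- "cold95"; out[z <= -2.576] <- "cold99"
  factor(out, levels = lev)
}
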