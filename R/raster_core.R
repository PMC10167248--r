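#' Depression filling (Planchon-Darboux)
#'
#' Raises every interior depression to its spill elevation plus a tiny epsilon
#' gradient so that each valid non-border cell ends up with a strictly lower
#' neighbour. Cells not inside a depression are returned bit-identical. Border
#' cells (array edge or adjacent to nodata) act as drains.
#'
#' @param dem an `nr_grid` of elevations (m).
#' @param eps epsilon gradient (m per step) imposed across filled areas;
#'   resolves flats so D8 routing never stalls.
#' @return filled `nr_grid`.
#' @export
fill_sinks <- function(dem, eps = 1e-6) {
  z <- dem$values
  if (all(is.na(z))) stop("empty DEM")
  nr <- nrow(z); nc <- ncol(z)
  valid <- !is.na(z)
  ## border = array edge or any nodata neighbour: these drain freely
  on_edge <- matrix(FALSE, nr, nc)
  on_edge[c(1, nr), ] <- TRUE; on_edge[, c(1, nc)] <- TRUE
  off <- d8_offsets()
  near_na <- matrix(FALSE, nr, nc)
  for (k in seq_len(8)) {
    nb <- shift_mat(z, off$dr[k], off$dc[k])
    ## neighbour position inside array but nodata
    inb <- shift_mat(matrix(1, nr, nc), off$dr[k], off$dc[k])
    near_na <- near_na | (!is.na(inb) & is.na(nb))
  }
  border <- valid & (on_edge | near_na)
  w <- matrix(Inf, nr, nc)
  w[border] <- z[border]
  w[!valid] <- NA
  interior <- valid & !border
  repeat {
    lowest_nb <- matrix(Inf, nr, nc)
    for (k in seq_len(8)) {
      nb <- shift_mat(w, off$dr[k], off$dc[k])
      nb[is.na(nb)] <- Inf
      lowest_nb <- pmin(lowest_nb, nb + eps)
    }
    w_new <- w
    w_new[interior] <- pmax(z[interior], pmin(w[interior], lowest_nb[interior]))
    if (identical(w_new, w)) break
    w <- w_new
  }
  out <- dem
  out$values <- w
  out
}

#' Burn a stream network into a DEM
#'
#' Lowers stream pixels by a fixed drop so that routed flow converges on the
#' mapped network rather than on spurious DEM-derived channels.
#'
#' @param dem elevation `nr_grid`.
#' @param streams boolean `nr_grid` (1/TRUE on stream pixels).
#' @param drop metres to lower stream pixels by (> 0).
#' @return modified `nr_grid`.
#' @export
burn_streams <- function(dem, streams, drop = 10) {
  check_compatible(dem, streams)
  if (!is.numeric(drop) || length(drop) != 1L || drop <= 0)
    stop("drop must be a positive scalar (m)")
  s <- !is.na(streams$values) & streams$values != 0
  out <- dem
  out$values[s] <- out$values[s] - drop
  out
}

#' D8 flow directions
#'
#' Each valid pixel drains to its steepest-descent neighbour, comparing
#' distance-weighted drops (diagonal drop / sqrt(2)). Ties are broken by the
#' fixed priority E, S, W, N, SE, SW, NW, NE. Pixels with no strictly lower
#' neighbour are outlets if they can drain off-grid (array edge or nodata
#' neighbour); an interior pixel with no descent is an error (run
#' [fill_sinks()] first).
#'
#' @param dem sink-free elevation `nr_grid`.
#' @return `nr_flow` object with elements `d8` (codes 1..8, 0 = outlet,
#'   NA = nodata), `receiver` (linear index of downstream cell, NA for
#'   outlets/nodata), `step` (flow-step length in m), plus grid metadata.
#' @export
d8_flow_direction <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  valid <- !is.na(z)
  off <- d8_offsets(dem$cell_size)
  best_slope <- matrix(-Inf, nr, nc)
  best_dir <- matrix(0L, nr, nc)
  can_exit <- matrix(FALSE, nr, nc)
  can_exit[c(1, nr), ] <- TRUE; can_exit[, c(1, nc)] <- TRUE
  for (k in seq_len(8)) {
    nb <- shift_mat(z, off$dr[k], off$dc[k])
    inb <- shift_mat(matrix(1, nr, nc), off$dr[k], off$dc[k])
    can_exit <- can_exit | (!is.na(inb) & is.na(nb))
    s <- (z - nb) / off$step[k]
    upd <- !is.na(s) & s > 0 & s > best_slope
    best_slope[upd] <- s[upd]
    best_dir[upd] <- off$code[k]
  }
  stuck <- valid & best_dir == 0L & !can_exit
  if (any(stuck)) {
    ij <- which(stuck, arr.ind = TRUE)[1, ]
    stop(sprintf("unresolved flat/pit at pixel (row %d, col %d); fill sinks first",
                 ij[1], ij[2]))
  }
  d8 <- best_dir
  d8[!valid] <- NA_integer_
  receiver <- matrix(NA_integer_, nr, nc)
  step <- matrix(NA_real_, nr, nc)
  for (k in seq_len(8)) {
    sel <- which(!is.na(d8) & d8 == k)
    if (!length(sel)) next
    i <- ((sel - 1L) %% nr) + 1L
    j <- ((sel - 1L) %/% nr) + 1L
    receiver[sel] <- (i + off$dr[k]) + (j + off$dc[k] - 1L) * nr
    step[sel] <- off$step[k]
  }
  structure(list(d8 = d8, receiver = receiver, step = step,
                 elevation = z, cell_size = dem$cell_size,
                 origin = dem$origin),
            class = "nr_flow")
}

## ascending-elevation processing order (receivers are strictly lower, so
## descending order puts every donor before its receiver and vice versa)
flow_order <- function(flow, decreasing = TRUE) {
  idx <- which(!is.na(flow$d8))
  idx[order(flow$elevation[idx], decreasing = decreasing)]
}

#' Flow accumulation
#'
#' Number of upslope pixels draining through each pixel, including itself.
#'
#' @param flow `nr_flow` from [d8_flow_direction()].
#' @return `flow` with an `accumulation` matrix added.
#' @export
flow_accumulation <- function(flow) {
  acc <- matrix(NA_real_, nrow(flow$d8), ncol(flow$d8))
  idx <- flow_order(flow, decreasing = TRUE)
  acc[idx] <- 1
  for (i in idx) {
    r <- flow$receiver[i]
    if (!is.na(r)) {
      if (is.na(acc[r])) stop("cyclic or inconsistent flow graph")
      acc[r] <- acc[r] + acc[i]
    }
  }
  flow$accumulation <- acc
  flow
}

#' Slope raster (rise/run fraction)
#'
#' Central differences in both axes (one-sided at borders), floored at a small
#' positive value so downstream connectivity terms never divide by zero.
#'
#' @param dem elevation `nr_grid`.
#' @param floor minimum slope fraction (default 0.005).
#' @return `nr_grid` of slope fractions.
#' @export
slope_raster <- function(dem, floor = 0.005) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  east <- shift_mat(z, 0, 1); west <- shift_mat(z, 0, -1)
  south <- shift_mat(z, 1, 0); north <- shift_mat(z, -1, 0)
  dx <- (east - west) / (2 * dem$cell_size)
  dx1 <- (east - z) / dem$cell_size   # one-sided fallbacks
  dx2 <- (z - west) / dem$cell_size
  dx[is.na(dx)] <- dx1[is.na(dx)]
  dx[is.na(dx)] <- dx2[is.na(dx)]
  dy <- (north - south) / (2 * dem$cell_size)
  dy1 <- (north - z) / dem$cell_size
  dy2 <- (z - south) / dem$cell_size
  dy[is.na(dy)] <- dy1[is.na(dy)]
  dy[is.na(dy)] <- dy2[is.na(dy)]
  dx[is.na(dx)] <- 0; dy[is.na(dy)] <- 0
  s <- sqrt(dx^2 + dy^2)
  s <- pmax(s, floor)
  s[is.na(z)] <- NA
  out <- dem
  out$values <- s
  out
}

#' Downslope flow-path distance to the stream network
#'
#' Walks the D8 path of each pixel, summing step lengths (cell size cardinal,
#' sqrt(2) x cell size diagonal), until the first stream pixel. Stream pixels
#' get 0. Pixels whose path exits at an outlet without meeting a stream get the
#' path length to the outlet and are flagged in `reached_stream`.
#'
#' @param flow `nr_flow` (directions computed).
#' @param streams boolean `nr_grid`.
#' @return `flow` with `dist_to_stream` (m) and `reached_stream` (logical)
#'   matrices added.
#' @export
distance_to_stream <- function(flow, streams) {
  d8 <- flow$d8
  s <- !is.na(streams$values) & streams$values != 0
  dist <- matrix(NA_real_, nrow(d8), ncol(d8))
  reach <- matrix(NA, nrow(d8), ncol(d8))
  idx <- flow_order(flow, decreasing = FALSE)  # receivers first
  for (i in idx) {
    if (s[i]) { dist[i] <- 0; reach[i] <- TRUE; next }
    r <- flow$receiver[i]
    if (is.na(r)) { dist[i] <- 0; reach[i] <- FALSE; next }  # outlet, no stream
    dist[i] <- flow$step[i] + dist[r]
    reach[i] <- reach[r]
  }
  flow$dist_to_stream <- dist
  flow$reached_stream <- reach
  flow$streams <- s
  flow
}

#' Derive a stream raster from flow accumulation
#'
#' Threshold-of-flow-accumulation (TFA) stream definition: pixels whose
#' upslope count reaches the threshold are streams.
#'
#' @param flow `nr_flow` with accumulation.
#' @param tfa threshold in pixels (default 50).
#' @return boolean `nr_grid`.
#' @export
streams_from_accumulation <- function(flow, tfa = 50) {
  if (is.null(flow$accumulation)) stop("run flow_accumulation() first")
  v <- ifelse(is.na(flow$accumulation), NA, as.numeric(flow$accumulation >= tfa))
  nr_grid(v, cell_size = flow$cell_size, origin = flow$origin)
}

#' Mean upslope slope and upslope area
#'
#' Accumulates slope along the flow graph to give, per pixel, the mean slope
#' fraction over all upslope pixels (self included) and the upslope area in
#' square metres -- the D_up ingredients of the connectivity index.
#'
#' @param flow `nr_flow` with accumulation.
#' @param slope slope `nr_grid`.
#' @return list with matrices `mean_slope` and `area_m2`.
#' @keywords internal
upslope_stats <- function(flow, slope) {
  if (is.null(flow$accumulation)) stop("run flow_accumulation() first")
  ssum <- matrix(NA_real_, nrow(flow$d8), ncol(flow$d8))
  idx <- flow_order(flow, decreasing = TRUE)
  ssum[idx] <- slope$values[idx]
  for (i in idx) {
    r <- flow$receiver[i]
    if (!is.na(r)) ssum[r] <- ssum[r] + ssum[i]
  }
  list(mean_slope = ssum / flow$accumulation,
       area_m2 = flow$accumulation * flow$cell_size^2)
}
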