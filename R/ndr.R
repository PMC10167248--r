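#' Biophysical parameter table
#'
#' Per land-use-class parameters of the Nr export model: annual Nr load
#' (kg N ha-1 yr-1), maximum retention efficiency of the class (fraction),
#' critical transport length (m) over which that efficiency is approached,
#' and the proportion of the load taking the subsurface pathway.
#'
#' @param df data.frame with columns `lucode`, `load_n`, `eff_n`,
#'   `crit_len_n`, `prop_subs`.
#' @return validated data.frame of class `biophys_table`.
#' @export
biophys_table <- function(df) {
  need <- c("lucode", "load_n", "eff_n", "crit_len_n", "prop_subs")
  if (!all(need %in% names(df)))
    stop("biophys table must have columns ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  stopifnot(!anyDuplicated(df$lucode),
            all(df$load_n >= 0),
            all(df$eff_n >= 0 & df$eff_n <= 1),
            all(df$crit_len_n > 0),
            all(df$prop_subs >= 0 & df$prop_subs <= 1))
  class(df) <- c("biophys_table", "data.frame")
  df
}

## per-pixel lookup of one biophys column, keyed by land-use code
biophys_lookup <- function(lucc, biophys, col) {
  codes <- lucc$values
  out <- matrix(NA_real_, nrow(codes), ncol(codes))
  present <- unique(codes[!is.na(codes)])
  missing <- setdiff(present, biophys$lucode)
  if (length(missing))
    stop("land-use codes missing from biophys table: ",
         paste(missing, collapse = ", "))
  for (code in present)
    out[!is.na(codes) & codes == code] <- biophys[[col]][biophys$lucode == code]
  out
}

#' NDR model parameters
#'
#' @param k calibration scalar of the logistic connectivity response (> 0).
#' @param ic0 connectivity reference; `NULL` = midpoint of the observed IC
#'   range (the conventional choice).
#' @param eff_subs maximum subsurface retention efficiency (fraction).
#' @param l_subs distance (m) at which subsurface retention saturates.
#' @param ic_orientation `"guide"` uses exp((IC0 - IC)/k) so that delivery
#'   increases with connectivity; `"printed"` flips the sign.
#' @return list of class `ndr_params`.
#' @export
ndr_params <- function(k = 12.5, ic0 = NULL, eff_subs = 0.8, l_subs = 150,
                       ic_orientation = c("guide", "printed")) {
  stopifnot(k > 0, eff_subs >= 0, eff_subs <= 1, l_subs > 0)
  structure(list(k = k, ic0 = ic0, eff_subs = eff_subs, l_subs = l_subs,
                 ic_orientation = match.arg(ic_orientation)),
            class = "ndr_params")
}

#' Partition the per-pixel Nr load into surface and subsurface parts
#'
#' Converts the per-hectare class load to kg per pixel, then splits it by the
#' class's subsurface proportion: surface = (1 - prop_subs) x load,
#' subsurface = prop_subs x load; the two parts always sum to the load
#' exactly.
#'
#' @param lucc `nr_lucc` land-use grid.
#' @param biophys `biophys_table`.
#' @return list of `nr_grid`s: `load_surf`, `load_subs`, `load_total`
#'   (kg per pixel).
#' @export
partition_load <- function(lucc, biophys) {
  area_ha <- cell_area_ha(lucc)
  load_total <- biophys_lookup(lucc, biophys, "load_n") * area_ha
  prop <- biophys_lookup(lucc, biophys, "prop_subs")
  g <- function(v) nr_grid(v, lucc$cell_size, lucc$origin)
  list(load_surf = g((1 - prop) * load_total),
       load_subs = g(prop * load_total),
       load_total = g(load_total))
}

#' Index of connectivity (IC)
#'
#' IC = log10(D_up / D_dn) with D_up = mean upslope slope x sqrt(upslope
#' area m2) and D_dn = sum over the downslope flow path (to the first stream
#' pixel, or the outlet when no stream is met) of step length / local slope.
#' Stream pixels have no downslope resistance term and get `NA` (their
#' delivery is handled separately).
#'
#' @param flow `nr_flow` with accumulation and distance-to-stream computed.
#' @param slope slope `nr_grid` (floored; see [slope_raster()]).
#' @return `nr_grid` of IC values.
#' @export
connectivity_index <- function(flow, slope) {
  if (is.null(flow$dist_to_stream)) stop("run distance_to_stream() first")
  up <- upslope_stats(flow, slope)
  d_up <- up$mean_slope * sqrt(up$area_m2)
  ddn <- matrix(NA_real_, nrow(flow$d8), ncol(flow$d8))
  s <- flow$streams
  idx <- flow_order(flow, decreasing = FALSE)
  for (i in idx) {
    if (s[i]) next
    r <- flow$receiver[i]
    own <- if (is.na(flow$step[i])) flow$cell_size else flow$step[i]
    tail_ <- if (is.na(r) || s[r] || is.na(ddn[r])) 0 else ddn[r]
    ddn[i] <- own / slope$values[i] + tail_
  }
  ic <- log10(d_up / ddn)
  nr_grid(ic, flow$cell_size, flow$origin)
}

#' Downslope retention: the maximum deliverable fraction NDR0
#'
#' Walking each flow path from the stream upslope, the effective downslope
#' retention eff' accumulates with a per-step decay s_i =
#' exp(-5 step / crit_len(i)): a pixel draining directly to a stream has
#' eff' = eff(i) (1 - s_i); otherwise eff' = eff'_down when eff(i) <=
#' eff'_down, else eff'_down s_i + eff(i) (1 - s_i). NDR0 = 1 - eff'.
#' eff' never decreases in the upstream direction along a path, and never
#' exceeds the largest class efficiency on the path. Stream pixels get
#' NDR0 = 1 (their load is delivered in full; see the package vignette).
#'
#' @param lucc `nr_lucc`.
#' @param flow `nr_flow` with `streams` set (run [distance_to_stream()]).
#' @param biophys `biophys_table`.
#' @return `nr_grid` of NDR0 fractions in [0, 1].
#' @export
downslope_retention <- function(lucc, flow, biophys) {
  if (is.null(flow$streams)) stop("run distance_to_stream() first")
  eff_n <- biophys_lookup(lucc, biophys, "eff_n")
  crit <- biophys_lookup(lucc, biophys, "crit_len_n")
  if (any(crit[!is.na(crit)] <= 0)) stop("crit_len_n must be positive")
  s <- flow$streams
  effp <- matrix(NA_real_, nrow(flow$d8), ncol(flow$d8))
  idx <- flow_order(flow, decreasing = FALSE)
  for (i in idx) {
    if (s[i]) { effp[i] <- 0; next }
    step <- if (is.na(flow$step[i])) flow$cell_size else flow$step[i]
    si <- exp(-5 * step / crit[i])
    r <- flow$receiver[i]
    down <- if (is.na(r)) 0 else effp[r]
    if (is.na(r) || s[r]) {
      effp[i] <- eff_n[i] * (1 - si)
    } else if (eff_n[i] <= down) {
      effp[i] <- down
    } else {
      effp[i] <- down * si + eff_n[i] * (1 - si)
    }
  }
  nr_grid(1 - effp, flow$cell_size, flow$origin)
}

#' Surface nutrient delivery ratio
#'
#' NDR_surf = NDR0 / (1 + exp((IC0 - IC)/k)) (guide orientation): a logistic
#' response of the deliverable fraction to hydrologic connectivity, equal to
#' NDR0/2 at IC = IC0 and approaching NDR0 as IC grows.
#'
#' @param ndr0 `nr_grid` from [downslope_retention()].
#' @param ic `nr_grid` from [connectivity_index()].
#' @param params `ndr_params`.
#' @return list: `ndr_surf` grid and the scalar `ic0` used.
#' @export
surface_ndr <- function(ndr0, ic, params = ndr_params()) {
  if (params$k <= 0) stop("k must be positive")
  icv <- ic$values
  ic0 <- params$ic0
  if (is.null(ic0)) {
    fin <- icv[is.finite(icv)]
    if (!length(fin)) stop("no finite IC values to set IC0 from")
    ic0 <- (max(fin) + min(fin)) / 2
  }
  expo <- if (params$ic_orientation == "guide") (ic0 - icv) / params$k
          else (icv - ic0) / params$k
  ndr <- ndr0$values / (1 + exp(expo))
  ## stream pixels (NA IC, valid NDR0): full delivery
  stream_like <- is.na(icv) & !is.na(ndr0$values)
  ndr[stream_like] <- ndr0$values[stream_like]
  list(ndr_surf = nr_grid(ndr, ndr0$cell_size, ndr0$origin), ic0 = ic0)
}

#' Subsurface nutrient delivery ratio
#'
#' NDR_subs = 1 - eff_subs (1 - exp(-5 l / l_subs)) with l the downslope
#' flow-path distance to the stream: 1 at the stream, decaying monotonically
#' to 1 - eff_subs far from it.
#'
#' @param flow `nr_flow` with `dist_to_stream`.
#' @param params `ndr_params`.
#' @return `nr_grid` of NDR_subs fractions.
#' @export
subsurface_ndr <- function(flow, params = ndr_params()) {
  l <- flow$dist_to_stream
  if (is.null(l)) stop("run distance_to_stream() first")
  v <- 1 - params$eff_subs * (1 - exp(-5 * l / params$l_subs))
  nr_grid(v, flow$cell_size, flow$origin)
}

#' Per-pixel Nr export
#'
#' x_exp = load_surf x NDR_surf + load_subs x NDR_subs (kg per pixel).
#'
#' @param loads list from [partition_load()].
#' @param ndr_surf,ndr_subs delivery-ratio grids.
#' @return `nr_grid` of export (kg).
#' @export
pixel_export <- function(loads, ndr_surf, ndr_subs) {
  check_compatible(loads$load_surf, ndr_surf, ndr_subs)
  v <- loads$load_surf$values * ndr_surf$values +
    loads$load_subs$values * ndr_subs$values
  nr_grid(v, ndr_surf$cell_size, ndr_surf$origin)
}

#' Total export over named masks
#'
#' @param export export `nr_grid` (kg per pixel).
#' @param masks named list of boolean `nr_grid`s (e.g. sub-basins); a mask of
#'   `NULL` means the whole valid area. Overlapping masks raise a warning.
#' @return data.frame with columns `mask`, `kg`, `tonnes`.
#' @export
total_export <- function(export, masks = list(basin = NULL)) {
  overlap <- NULL
  cover <- matrix(0, nrow(export$values), ncol(export$values))
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (is.null(m)) {
      sel <- !is.na(export$values)
    } else {
      check_compatible(export, m)
      sel <- !is.na(m$values) & m$values != 0
      cover <<- cover + sel
    }
    data.frame(mask = nm, kg = sum(export$values[sel], na.rm = TRUE))
  })
  if (any(cover > 1)) warning("overlapping masks in total_export()")
  out <- do.call(rbind, rows)
  out$tonnes <- out$kg / 1000
  out
}

#' Calibrate the K parameter against an observed basin total
#'
#' Finds k such that the modelled basin export matches an observed Nr loss,
#' by root-finding on the (assumed monotone) total-export response within the
#' given bounds.
#'
#' @param total_fn function(k) returning modelled basin total (kg).
#' @param observed_total observed Nr loss (kg, > 0).
#' @param k_bounds search interval for k.
#' @param max_load total basin load (kg); exports beyond it are impossible
#'   and rejected up front. `NULL` skips the check.
#' @param tol relative tolerance on the match (default 1e-3).
#' @return list(k, total, rel_error).
#' @export
calibrate_k <- function(total_fn, observed_total, k_bounds = c(0.1, 100),
                        max_load = NULL, tol = 1e-3) {
  stopifnot(observed_total > 0, length(k_bounds) == 2L,
            k_bounds[1] > 0, k_bounds[2] > k_bounds[1])
  if (!is.null(max_load) && observed_total > max_load)
    stop(sprintf("observed total (%.4g kg) exceeds total load (%.4g kg): unattainable",
                 observed_total, max_load))
  lo <- total_fn(k_bounds[1]); hi <- total_fn(k_bounds[2])
  rng <- range(c(lo, hi))
  if (observed_total < rng[1] || observed_total > rng[2])
    stop(sprintf("observed total outside attainable range [%.6g, %.6g] kg on k bounds",
                 rng[1], rng[2]))
  root <- stats::uniroot(function(k) total_fn(k) - observed_total,
                         interval = k_bounds,
                         tol = tol * observed_total / 10)
  tot <- total_fn(root$root)
  list(k = root$root, total = tot,
       rel_error = abs(tot - observed_total) / observed_total)
}

#' Run the full NDR model on prepared inputs
#'
#' Convenience wrapper chaining sink filling, optional stream burning, D8
#' routing, accumulation, slope, distance-to-stream, connectivity, retention,
#' delivery ratios, per-pixel export and basin totals.
#'
#' @param dem elevation `nr_grid`.
#' @param lucc `nr_lucc`.
#' @param biophys `biophys_table`.
#' @param params `ndr_params`.
#' @param streams optional boolean `nr_grid`; derived by TFA when `NULL`.
#' @param tfa threshold-of-flow-accumulation (pixels) when deriving streams.
#' @param burn_drop stream burn depth (m); 0 disables burning.
#' @param slope_floor minimum slope fraction.
#' @param masks named mask list for totals (default whole basin).
#' @return list of class `ndr_bundle`: loads, ic, ic0, ndr0, ndr_surf,
#'   ndr_subs, export, totals, flow, streams.
#' @export
run_ndr <- function(dem, lucc, biophys, params = ndr_params(),
                    streams = NULL, tfa = 50, burn_drop = 10,
                    slope_floor = 0.005, masks = list(basin = NULL)) {
  check_compatible(dem, lucc)
  work <- dem
  if (!is.null(streams) && burn_drop > 0) work <- burn_streams(work, streams, burn_drop)
  filled <- fill_sinks(work)
  flow <- flow_accumulation(d8_flow_direction(filled))
  if (is.null(streams)) streams <- streams_from_accumulation(flow, tfa)
  flow <- distance_to_stream(flow, streams)
  slope <- slope_raster(filled, slope_floor)
  loads <- partition_load(lucc, biophys)
  ic <- connectivity_index(flow, slope)
  ndr0 <- downslope_retention(lucc, flow, biophys)
  surf <- surface_ndr(ndr0, ic, params)
  subs <- subsurface_ndr(flow, params)
  export <- pixel_export(loads, surf$ndr_surf, subs)
  structure(list(loads = loads, ic = ic, ic0 = surf$ic0, ndr0 = ndr0,
                 ndr_surf = surf$ndr_surf, ndr_subs = subs, export = export,
                 totals = total_export(export, masks),
                 flow = flow, streams = streams, params = params),
            class = "ndr_bundle")
}
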