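#' Synthetic watershed configuration
#'
#' Parameters of the seeded generator that emulates a low-relief basin with
#' clustered land-use patches: grid shape and resolution, terrain relief,
#' target class proportions, patch clustering length-scale, and the
#' row-stochastic transition matrix that evolves the mosaic between dates.
#' Defaults mirror a lowland, cropland-dominated basin (cropland 52.45%,
#' forest 11.66%, water 12.18%, developed 23.71%).
#'
#' @param shape c(rows, cols) in pixels.
#' @param cell_size m (default 30).
#' @param seed integer RNG seed; identical seeds give identical outputs.
#' @param relief total terrain relief (m) above the regional tilt.
#' @param class_proportions named vector over the 7-class legend, summing
#'   to 1.
#' @param cluster_len patch clustering length-scale (m).
#' @param true_transition row-stochastic 7 x 7 matrix (per interval).
#' @param interval_years years per transition interval.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(shape = c(64, 64), cell_size = 30, seed = 1,
                         relief = 40,
                         class_proportions = default_proportions(),
                         cluster_len = 300,
                         true_transition = default_transition(),
                         interval_years = 5) {
  stopifnot(length(shape) == 2, all(shape >= 8), cell_size > 0, relief >= 0,
            abs(sum(class_proportions) - 1) < 1e-8,
            all(abs(rowSums(true_transition) - 1) < 1e-8))
  structure(list(shape = as.integer(shape), cell_size = cell_size,
                 seed = as.integer(seed), relief = relief,
                 class_proportions = class_proportions,
                 cluster_len = cluster_len,
                 true_transition = true_transition,
                 interval_years = interval_years),
            class = "synth_config")
}

#' Default land-use class proportions
#'
#' Cropland-dominated lowland mosaic: cropland 0.5245, forest 0.1166,
#' water 0.1218, developed 0.2371, others 0.
#' @return named numeric vector over the canonical legend.
#' @export
default_proportions <- function() {
  c(cropland = 0.5245, forest = 0.1166, shrub = 0, grassland = 0,
    water = 0.1218, barren = 0, developed = 0.2371)
}

#' Default per-interval transition matrix
#'
#' A stylized 5-year row-stochastic matrix for a rapidly urbanising basin:
#' strong persistence, cropland losing mainly to developed land, modest
#' forest-to-cropland reclamation, essentially irreversible urbanisation.
#' @return 7 x 7 row-stochastic matrix with class dimnames.
#' @export
default_transition <- function() {
  cls <- names(lucc_legend())
  p <- diag(7)
  dimnames(p) <- list(cls, cls)
  set_row <- function(p, from, to, probs) {
    p[from, to] <- probs
    p[from, from] <- 1 - sum(probs)
    p
  }
  p <- set_row(p, "cropland", c("forest", "water", "developed"),
               c(0.005, 0.005, 0.06))
  p <- set_row(p, "forest", c("cropland", "developed"), c(0.04, 0.005))
  p <- set_row(p, "shrub", c("forest", "cropland"), c(0.02, 0.02))
  p <- set_row(p, "grassland", c("cropland", "developed"), c(0.03, 0.01))
  p <- set_row(p, "water", c("cropland", "developed"), c(0.01, 0.005))
  p <- set_row(p, "barren", c("cropland", "developed"), c(0.03, 0.02))
  p <- set_row(p, "developed", "cropland", 0.002)
  p
}

## smooth standardized random field: white noise convolved with a truncated
## Gaussian kernel (radius 3 sigma), edge-renormalized; no FFT so results do
## not depend on array size
smooth_field <- function(nr, nc, sigma_px) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma_px <= 0) return(noise)
  rad <- max(1L, ceiling(3 * sigma_px))
  acc <- matrix(0, nr, nc)
  wsum <- matrix(0, nr, nc)
  for (dr in -rad:rad) for (dc in -rad:rad) {
    w <- exp(-(dr^2 + dc^2) / (2 * sigma_px^2))
    acc <- acc + w * shift_fill(noise, dr, dc)
    wsum <- wsum + w * shift_fill(matrix(1, nr, nc), dr, dc)
  }
  f <- acc / wsum
  (f - mean(f)) / stats::sd(f)
}

shift_fill <- function(m, dr, dc) {
  out <- shift_mat(m, dr, dc)
  out[is.na(out)] <- 0
  out
}

#' Generate a synthetic DEM
#'
#' A regional tilt draining towards the east edge plus a smoothed random
#' relief field; the tilt guarantees overall drainage, so depression filling
#' touches only a small fraction of pixels.
#'
#' @param cfg `synth_config`.
#' @return elevation `nr_grid` (m).
#' @export
make_dem <- function(cfg) {
  set.seed(cfg$seed)
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  tilt_drop <- max(cfg$relief, 1) * 3
  tilt <- matrix(rep(seq(tilt_drop, 0, length.out = nc), each = nr), nr, nc)
  z <- tilt + 10
  if (cfg$relief > 0) {
    f <- smooth_field(nr, nc, sigma_px = cfg$cluster_len / cfg$cell_size / 2)
    z <- z + cfg$relief * 0.15 * f
  }
  nr_grid(z, cfg$cell_size, c(0, nr * cfg$cell_size))
}

#' Generate a clustered land-use mosaic
#'
#' Each class gets a smooth Gaussian score field; water is biased to low
#' elevation, forest to steep slopes, developed land to flat lowland. Additive
#' class offsets are calibrated iteratively so the realised argmax proportions
#' land within +/- 2 percentage points of the targets.
#'
#' @param cfg `synth_config`.
#' @param dem elevation `nr_grid` from [make_dem()].
#' @return `nr_lucc`.
#' @export
make_lucc <- function(cfg, dem) {
  set.seed(cfg$seed + 1L)
  leg <- lucc_legend()
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  sigma <- cfg$cluster_len / cfg$cell_size
  zstd <- (dem$values - mean(dem$values)) / stats::sd(dem$values)
  sl <- slope_raster(dem)$values
  slstd <- (sl - mean(sl)) / max(stats::sd(sl), 1e-9)
  fields <- lapply(names(leg), function(nm) {
    f <- smooth_field(nr, nc, sigma)
    if (nm == "water") f <- f - 1.0 * zstd
    if (nm == "forest") f <- f + 0.8 * slstd + 0.5 * zstd
    if (nm == "developed") f <- f - 0.5 * zstd - 0.3 * slstd
    f
  })
  names(fields) <- names(leg)
  target <- cfg$class_proportions[names(leg)]
  offset <- ifelse(target > 0, 0, -Inf)
  names(offset) <- names(leg)
  n <- nr * nc
  codes <- NULL
  for (it in seq_len(300)) {
    stack <- vapply(names(leg), function(nm) as.vector(fields[[nm]] + offset[nm]),
                    numeric(n))
    codes <- max.col(stack, ties.method = "first")
    realised <- tabulate(codes, nbins = 7) / n
    err <- realised - target
    if (max(abs(err[target > 0])) < 0.005) break
    adj <- log((target + 1e-4) / (realised + 1e-4))
    offset[target > 0] <- offset[target > 0] + 0.5 * adj[target > 0]
  }
  nr_lucc(matrix(leg[codes], nr, nc), cfg$cell_size, dem$origin)
}

#' Evolve a land-use map by a known transition matrix
#'
#' Independent per-pixel multinomial draws from the pixel's class row; the
#' empirical transition matrix of the output converges on the generator
#' matrix as the map grows.
#'
#' @param lucc0 starting `nr_lucc`.
#' @param true_transition row-stochastic matrix with class dimnames.
#' @param seed RNG seed.
#' @return evolved `nr_lucc`.
#' @export
evolve_lucc <- function(lucc0, true_transition, seed = 1) {
  set.seed(seed)
  leg <- lucc0$legend
  codes <- lucc0$values
  out <- codes
  for (nm in names(leg)) {
    sel <- which(!is.na(codes) & codes == leg[[nm]])
    if (!length(sel)) next
    row <- true_transition[nm, names(leg)]
    draw <- findInterval(stats::runif(length(sel)), cumsum(row),
                         left.open = TRUE) + 1L
    out[sel] <- leg[draw]
  }
  lucc <- lucc0
  lucc$values <- out
  lucc
}

#' Generate correlated driver rasters
#'
#' Precipitation: smooth field (mm). Population and GDP: lognormal fields
#' boosted where developed land clusters (positively correlated with the
#' developed-class indicator by construction). Soil: 4-class categorical
#' mosaic from a smooth field. FVC: vegetation fraction in [0, 1],
#' anti-correlated with developed land.
#'
#' @param cfg `synth_config`.
#' @param dem elevation `nr_grid`.
#' @param lucc `nr_lucc`.
#' @return named list of `nr_grid`s: precipitation, population, gdp, soil,
#'   fvc.
#' @export
make_drivers <- function(cfg, dem, lucc) {
  set.seed(cfg$seed + 2L)
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  sigma <- cfg$cluster_len / cfg$cell_size
  g <- function(v) nr_grid(v, cfg$cell_size, dem$origin)
  precip <- 1177 + 120 * smooth_field(nr, nc, 2 * sigma)
  dev_density <- box_blur((lucc$values == lucc$legend[["developed"]]) * 1, 3L)
  pop <- exp(1 + 2.5 * dev_density + 0.4 * matrix(stats::rnorm(nr * nc), nr, nc))
  gdp <- exp(0.5 + 3 * dev_density + 0.5 * matrix(stats::rnorm(nr * nc), nr, nc))
  soil_f <- smooth_field(nr, nc, 2 * sigma)
  soil <- matrix(findInterval(soil_f, stats::quantile(soil_f, c(0.25, 0.5, 0.75))) + 1,
                 nr, nc)
  fvc <- pmin(pmax(0.85 - 0.7 * dev_density +
                     0.1 * smooth_field(nr, nc, sigma), 0), 1)
  list(precipitation = g(precip), population = g(pop), gdp = g(gdp),
       soil = g(soil), fvc = g(fvc))
}

box_blur <- function(m, rad) {
  ii <- integral_image(m)
  rr <- row(m); cc <- col(m)
  n <- (pmin(rr + rad, nrow(m)) - pmax(rr - rad, 1) + 1) *
    (pmin(cc + rad, ncol(m)) - pmax(cc - rad, 1) + 1)
  ii(rr - rad, rr + rad, cc - rad, cc + rad) / n
}

#' Default biophysical tables by year
#'
#' Per-class Nr load (kg N ha-1 yr-1) and retention efficiency for the seven
#' classes; the cropland load varies by year (fertiliser application), all
#' other rows are fixed. Critical transport length is 150 m for every class
#' and the subsurface proportion defaults to 0 (all load routed as surface
#' flow unless configured otherwise).
#'
#' @param year one of 1990, 2000, 2005, 2010, 2015, 2020.
#' @return `biophys_table`.
#' @export
default_biophys <- function(year = 2020) {
  crop_load <- c("1990" = 185.31, "2000" = 216.43, "2005" = 209.36,
                 "2010" = 174.20, "2015" = 171.30, "2020" = 158.78)
  y <- as.character(year)
  if (!y %in% names(crop_load))
    stop("unknown year: ", year, " (available: ",
         paste(names(crop_load), collapse = ", "), ")")
  biophys_table(data.frame(
    lucode = unname(lucc_legend()),
    load_n = c(crop_load[[y]], 9.62, 2.12, 10, 8.5, 10, 174.68),
    eff_n = c(0.30, 0.80, 0.70, 0.40, 0.05, 0.05, 0.05),
    crit_len_n = rep(150, 7),
    prop_subs = rep(0, 7)
  ))
}

#' Generate a complete synthetic watershed
#'
#' DEM, land-use maps for the requested years (first map generated, later
#' ones evolved by the configured transition matrix), stream raster, driver
#' rasters and biophysical tables -- everything the analysis pipeline needs.
#'
#' @param cfg `synth_config`.
#' @param years vector of dates; must be spaced by the config's interval for
#'   the Markov accounting to be exact.
#' @param tfa stream threshold (pixels).
#' @return list of class `synth_watershed`: `cfg`, `dem`, `lucc` (named list
#'   by year), `streams`, `drivers`, `biophys` (named list by year).
#' @export
make_watershed <- function(cfg = synth_config(), years = c(2015, 2020),
                           tfa = 50) {
  dem <- make_dem(cfg)
  lucc <- list()
  lucc[[as.character(years[1])]] <- make_lucc(cfg, dem)
  if (length(years) > 1) {
    for (i in seq_along(years)[-1]) {
      prev <- lucc[[as.character(years[i - 1])]]
      lucc[[as.character(years[i])]] <-
        evolve_lucc(prev, cfg$true_transition, seed = cfg$seed + 10L + i)
    }
  }
  filled <- fill_sinks(dem)
  flow <- flow_accumulation(d8_flow_direction(filled))
  streams <- streams_from_accumulation(flow, tfa)
  last <- lucc[[length(lucc)]]
  biophys <- lapply(stats::setNames(nm = as.character(years)), function(y) {
    yy <- if (as.character(y) %in% c("1990", "2000", "2005", "2010", "2015", "2020"))
      as.numeric(y) else 2020
    default_biophys(yy)
  })
  structure(list(cfg = cfg, dem = dem, lucc = lucc, streams = streams,
                 drivers = make_drivers(cfg, dem, last), biophys = biophys),
            class = "synth_watershed")
}

#' Write a synthetic watershed to a self-describing directory
#'
#' ESRI ASCII rasters, CSV biophysical tables and a `manifest.yaml` echoing
#' the seed and configuration.
#'
#' @param ws `synth_watershed`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_watershed <- function(ws, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "drivers"), showWarnings = FALSE)
  write_asc(ws$dem, file.path(dir, "dem.asc"))
  write_asc(ws$streams, file.path(dir, "streams.asc"))
  for (y in names(ws$lucc))
    write_asc(ws$lucc[[y]], file.path(dir, sprintf("lucc_%s.asc", y)))
  for (nm in names(ws$drivers))
    write_asc(ws$drivers[[nm]], file.path(dir, "drivers", paste0(nm, ".asc")))
  for (y in names(ws$biophys))
    utils::write.csv(ws$biophys[[y]],
                     file.path(dir, sprintf("biophys_%s.csv", y)),
                     row.names = FALSE)
  cfg <- ws$cfg
  yaml::write_yaml(list(
    seed = cfg$seed, shape = cfg$shape, cell_size = cfg$cell_size,
    relief = cfg$relief,
    class_proportions = as.list(cfg$class_proportions),
    cluster_len = cfg$cluster_len,
    interval_years = cfg$interval_years,
    years = names(ws$lucc)
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
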