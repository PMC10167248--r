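# strip setup shared by several blocks: 1 x n flow path, stream at east end
strip_inputs <- function(n = 20, classes = NULL, cell = 30) {
  leg <- lucc_legend()
  if (is.null(classes))
    classes <- rep(c("cropland", "forest", "grassland", "developed"),
                   length.out = n)
  codes <- matrix(NA_real_, 3, n)
  codes[2, ] <- leg[classes]
  list(dem = strip_dem(n, cell), streams = strip_streams(n, cell),
       lucc = nr_lucc(codes, cell_size = cell), classes = classes)
}

test_that("load partitioning converts rates to kg/pixel and splits exactly", {
  lu <- uniform_lucc(4, 4, "cropland")
  bp <- default_biophys(2020)
  loads <- partition_load(lu, bp)
  # 158.78 kg/ha on a 0.09 ha pixel, all surface by default
  expect_equal(loads$load_total$values[1, 1], 158.78 * 0.09)
  expect_equal(loads$load_total$values[1, 1], 14.2902)
  expect_equal(loads$load_subs$values, matrix(0, 4, 4))

  bp2 <- bp; bp2$load_n[bp2$lucode == 1] <- 0
  l0 <- partition_load(lu, biophys_table(bp2))
  expect_equal(l0$load_total$values, matrix(0, 4, 4))

  bp3 <- bp; bp3$prop_subs[bp3$lucode == 1] <- 0.3
  l3 <- partition_load(lu, biophys_table(bp3))
  expect_equal(l3$load_surf$values + l3$load_subs$values,
               l3$load_total$values)
  expect_equal(l3$load_subs$values / l3$load_total$values,
               matrix(0.3, 4, 4))

  bad <- nr_lucc(matrix(3, 2, 2))
  bp4 <- bp[bp$lucode != 3, ]
  expect_error(partition_load(bad, biophys_table(bp4)), "missing from biophys")
})

test_that("connectivity index reproduces the hand-computed single-pixel case", {
  # pixel one 30 m step from the stream, slope 0.1, upslope area = itself
  st <- strip_inputs(2, classes = rep("cropland", 2))
  dem <- st$dem; dem$values[2, ] <- c(3, 0)  # slope 0.1 at 30 m cells
  flow <- distance_to_stream(
    flow_accumulation(d8_flow_direction(dem)), st$streams)
  slope <- slope_raster(dem)
  ic <- connectivity_index(flow, slope)
  # D_up = 0.1 * sqrt(900), D_dn = one step of 30/0.1
  expect_equal(ic$values[2, 1], log10((0.1 * 30) / (30 / 0.1)), tolerance = 1e-12)
  expect_equal(ic$values[2, 1], -2)
  expect_true(is.na(ic$values[2, 2]))  # stream pixel carries no IC

  # IC strictly increases toward the stream along a uniform flow line
  st2 <- strip_inputs(12)
  f2 <- distance_to_stream(
    flow_accumulation(d8_flow_direction(st2$dem)), st2$streams)
  ic2 <- connectivity_index(f2, slope_raster(st2$dem))
  line <- ic2$values[2, 1:11]
  expect_true(all(diff(line) > 0))

  # doubling all slopes raises IC everywhere (numerator up, denominator down)
  sl <- slope_raster(st2$dem)
  sl2 <- sl; sl2$values <- sl$values * 2
  ic_hi <- connectivity_index(f2, sl2)
  expect_true(all(ic_hi$values > ic2$values, na.rm = TRUE))
})

test_that("downslope retention follows the recursion and its limits", {
  # single cropland pixel draining 30 m to the stream: eff' = 0.3 (1 - e^-1)
  st <- strip_inputs(2, classes = c("cropland", "water"))
  flow <- distance_to_stream(
    flow_accumulation(d8_flow_direction(st$dem)), st$streams)
  ndr0 <- downslope_retention(st$lucc, flow, default_biophys(2020))
  expect_equal(ndr0$values[2, 1], 1 - 0.30 * (1 - exp(-1)), tolerance = 1e-9)
  expect_equal(ndr0$values[2, 1], 0.8103638, tolerance = 1e-6)
  expect_equal(ndr0$values[2, 2], 1)   # stream pixel delivers in full

  # zero efficiency everywhere -> NDR0 = 1 everywhere
  st2 <- strip_inputs(10)
  f2 <- distance_to_stream(
    flow_accumulation(d8_flow_direction(st2$dem)), st2$streams)
  bp0 <- default_biophys(2020); bp0$eff_n[] <- 0
  n0 <- downslope_retention(st2$lucc, f2, biophys_table(bp0))
  expect_equal(n0$values[2, ], rep(1, 10))

  # long uniform forest slope: eff' approaches 0.80 from below (geometric series)
  st3 <- strip_inputs(60, classes = rep("forest", 60))
  f3 <- distance_to_stream(
    flow_accumulation(d8_flow_direction(st3$dem)), f2 <- strip_streams(60))
  n3 <- downslope_retention(st3$lucc, f3, default_biophys(2020))
  effp <- 1 - n3$values[2, 1:59]
  expect_true(all(effp < 0.80))
  expect_true(all(diff(effp) < 1e-12))     # eff' grows upstream
  # geometric-series closed form for a uniform path: eff' -> eff as n -> inf
  s <- exp(-5 * 30 / 150)
  expect_equal(effp[1], 0.80 * (1 - s^59), tolerance = 1e-9)
})

test_that("surface NDR is the logistic connectivity response", {
  g <- function(v) nr_grid(matrix(v, 1, 1))
  # midpoint: IC = IC0 halves NDR0
  out <- surface_ndr(g(0.6), g(1), ndr_params(k = 12.5, ic0 = 1))
  expect_equal(out$ndr_surf$values[1, 1], 0.30, tolerance = 1e-12)
  # large IC: NDR -> NDR0
  out2 <- surface_ndr(g(0.6), g(1e3), ndr_params(k = 12.5, ic0 = 0))
  expect_equal(out2$ndr_surf$values[1, 1], 0.6, tolerance = 1e-9)
  # hand value: k = 12.5, IC0 = 0, IC = 12.5, NDR0 = 1
  out3 <- surface_ndr(g(1), g(12.5), ndr_params(k = 12.5, ic0 = 0))
  expect_equal(out3$ndr_surf$values[1, 1], 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(out3$ndr_surf$values[1, 1], 0.731059, tolerance = 1e-6)
  # printed orientation flips the sign of the exponent
  out4 <- surface_ndr(g(1), g(12.5),
                      ndr_params(k = 12.5, ic0 = 0, ic_orientation = "printed"))
  expect_equal(out4$ndr_surf$values[1, 1], 1 / (1 + exp(1)), tolerance = 1e-12)
  expect_error(ndr_params(k = -1), "k")
})

test_that("subsurface NDR decays from 1 to 1 - eff_subs with distance", {
  flow <- list(dist_to_stream = matrix(c(0, 150, 1e9), 1, 3),
               cell_size = 30, origin = c(0, 0))
  out <- subsurface_ndr(flow, ndr_params(eff_subs = 0.8, l_subs = 150))
  expect_equal(out$values[1, 1], 1)
  expect_equal(out$values[1, 2], 1 - 0.8 * (1 - exp(-5)), tolerance = 1e-12)
  expect_equal(out$values[1, 2], 0.205390, tolerance = 1e-5)
  expect_equal(out$values[1, 3], 1 - 0.8, tolerance = 1e-9)
  expect_true(all(diff(out$values[1, ]) <= 0))
})

test_that("pixel export obeys mass balance and exact linearity", {
  st <- strip_inputs(10)
  b <- run_ndr(st$dem, st$lucc, default_biophys(2020),
               streams = st$streams, burn_drop = 0)
  lt <- b$loads$load_total$values
  expect_true(all(b$export$values >= 0, na.rm = TRUE))
  expect_true(all(b$export$values <= lt + 1e-12, na.rm = TRUE))

  # scaling all loads by c scales export by exactly c
  bp <- default_biophys(2020); bp$load_n <- bp$load_n * 3
  b3 <- run_ndr(st$dem, st$lucc, biophys_table(bp),
                streams = st$streams, burn_drop = 0)
  expect_equal(b3$export$values, 3 * b$export$values, tolerance = 1e-12)
})

test_that("totals sum masks and flag overlap; disjoint partition is exact", {
  exp_grid <- nr_grid(matrix(1, 25, 40))
  tot <- total_export(exp_grid)
  expect_equal(tot$kg, 1000)
  expect_equal(tot$tonnes, 1)

  empty <- nr_grid(matrix(0, 25, 40))
  expect_equal(total_export(exp_grid, list(none = empty))$kg, 0)

  set.seed(4)
  vals <- nr_grid(matrix(runif(1000), 25, 40))
  part <- sample(1:8, 1000, replace = TRUE)
  masks <- lapply(1:8, function(k)
    nr_grid(matrix(as.numeric(part == k), 25, 40)))
  names(masks) <- paste0("sub", 1:8)
  tt <- total_export(vals, masks)
  expect_equal(sum(tt$kg), total_export(vals)$kg, tolerance = 1e-9)

  expect_warning(total_export(vals, list(a = masks[[1]], b = masks[[1]])),
                 "overlap")
})

test_that("K calibration recovers a known k and rejects unattainable targets", {
  st <- strip_inputs(20)
  total_at <- function(k)
    run_ndr(st$dem, st$lucc, default_biophys(2020),
            params = ndr_params(k = k), streams = st$streams,
            burn_drop = 0)$totals$kg[1]
  observed <- total_at(12.5)
  fit <- calibrate_k(total_at, observed, k_bounds = c(1, 40))
  expect_equal(fit$k, 12.5, tolerance = 0.1)
  expect_lte(fit$rel_error, 1e-3)

  load_tot <- sum(partition_load(st$lucc,
                                 default_biophys(2020))$load_total$values,
                  na.rm = TRUE)
  expect_error(calibrate_k(total_at, load_tot * 2, max_load = load_tot),
               "unattainable")
  expect_error(calibrate_k(total_at, observed * 1e3, k_bounds = c(1, 40)),
               "attainable range")
})

test_that("raising retention efficiency never increases export", {
  st <- strip_inputs(16)
  bp <- default_biophys(2020)
  b1 <- run_ndr(st$dem, st$lucc, bp, streams = st$streams, burn_drop = 0)
  bp2 <- bp; bp2$eff_n <- pmin(bp2$eff_n + 0.15, 1)
  b2 <- run_ndr(st$dem, st$lucc, biophys_table(bp2),
                streams = st$streams, burn_drop = 0)
  expect_true(all(b2$export$values <= b1$export$values + 1e-12, na.rm = TRUE))
  expect_lt(b2$totals$kg[1], b1$totals$kg[1])
})
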