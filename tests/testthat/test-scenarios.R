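lucc_from <- function(codes) nr_lucc(codes, cell_size = 30)

test_that("transition matrices cross-tabulate and row-normalise correctly", {
  a <- uniform_lucc(10, 10, "cropland")
  expect_equal(transition_matrix(a, a)$probs, diag(7),
               ignore_attr = TRUE)

  b <- uniform_lucc(10, 10, "developed")
  tm <- transition_matrix(a, b)
  expect_equal(tm$probs["cropland", "developed"], 1)
  expect_equal(unname(rowSums(tm$probs)), rep(1, 7))

  set.seed(2)
  ra <- lucc_from(matrix(sample(1:7, 400, replace = TRUE), 20, 20))
  rb <- lucc_from(matrix(sample(1:7, 400, replace = TRUE), 20, 20))
  tmr <- transition_matrix(ra, rb)
  expect_equal(sum(tmr$counts), 400)
  expect_equal(unname(rowSums(tmr$probs)), rep(1, 7), tolerance = 1e-12)
})

test_that("transfer proportions report per-class and total shares", {
  a <- uniform_lucc(10, 10, "cropland")
  tp0 <- transfer_proportions(transition_matrix(a, a))
  expect_true(all(tp0$share_of_from == 0))

  # counts [[90, 10], [0, 100]]: cropland -> developed rate 10%
  codes_a <- matrix(c(rep(1, 100), rep(7, 100)), 10, 20)
  codes_b <- codes_a
  codes_b[which(codes_a == 1)[1:10]] <- 7
  tp <- transfer_proportions(transition_matrix(lucc_from(codes_a),
                                               lucc_from(codes_b)))
  row <- tp[tp$from == "cropland" & tp$to == "developed", ]
  expect_equal(row$share_of_from, 0.10)
  expect_equal(row$share_of_transferred, 1)

  # shares per from-class sum to 1 - persistence
  set.seed(5)
  ra <- lucc_from(matrix(sample(c(1, 2, 7), 400, replace = TRUE), 20, 20))
  rb <- lucc_from(matrix(sample(c(1, 2, 7), 400, replace = TRUE), 20, 20))
  tmr <- transition_matrix(ra, rb)
  tpr <- transfer_proportions(tmr)
  for (cl in c("cropland", "forest", "developed")) {
    moved <- sum(tpr$share_of_from[tpr$from == cl])
    persist <- tmr$probs[cl, cl]
    expect_equal(moved, 1 - persist, tolerance = 1e-12)
  }
})

test_that("Markov demand powers the matrix and rounds preserving totals", {
  a <- uniform_lucc(10, 10, "cropland")
  tm <- transition_matrix(a, a, interval_years = 5)
  d <- markov_demand(tm, c(cropland = 100, forest = 0, shrub = 0,
                           grassland = 0, water = 0, barren = 0,
                           developed = 0), 15)
  expect_equal(d$counts[["cropland"]], 100L)

  # [[0.9, 0.1], [0, 1]] over 3 steps from [100, 0] -> [72.9, 27.1]
  tm2 <- tm
  tm2$probs <- diag(7); dimnames(tm2$probs) <- dimnames(tm$probs)
  tm2$probs["cropland", "cropland"] <- 0.9
  tm2$probs["cropland", "developed"] <- 0.1
  areas <- c(cropland = 100, forest = 0, shrub = 0, grassland = 0,
             water = 0, barren = 0, developed = 0)
  d2 <- markov_demand(tm2, areas, 15)
  expect_equal(d2$real[["cropland"]], 72.9, tolerance = 1e-12)
  expect_equal(d2$real[["developed"]], 27.1, tolerance = 1e-12)
  expect_equal(d2$counts[["cropland"]], 73L)
  expect_equal(sum(d2$counts), 100L)
  expect_error(markov_demand(tm2, areas, 7), "integer multiple")
  expect_equal(markov_demand(tm2, areas, 7, force = TRUE)$steps, 1)
})

test_that("scenario modifiers rescale probabilities and honour hard zeroes", {
  a <- uniform_lucc(10, 10, "cropland")
  tm <- transition_matrix(a, a)
  p <- tm$probs
  p["forest", ] <- 0
  p["forest", "cropland"] <- 0.10
  p["forest", "forest"] <- 0.90
  p["water", ] <- 0; p["water", "developed"] <- 0.05; p["water", "water"] <- 0.95
  tm$probs <- p

  ed <- apply_scenario(tm, scenario_preset("ED"))
  expect_equal(ed$probs["forest", "cropland"], 0.16, tolerance = 1e-12)
  expect_equal(ed$probs["forest", "forest"], 0.84, tolerance = 1e-12)
  expect_equal(unname(rowSums(ed$probs)), rep(1, 7), tolerance = 1e-12)

  ec <- apply_scenario(tm, scenario_preset("EC"))
  expect_equal(ec$probs["forest", "developed"], 0)
  expect_equal(ec$probs["water", "developed"], 0)
  expect_equal(unname(rowSums(ec$probs)), rep(1, 7), tolerance = 1e-12)

  rna <- apply_scenario(tm, scenario_preset("RNA"))
  expect_equal(rna$probs, tm$probs)

  expect_error(scenario_spec("bad",
                             prob_modifiers = data.frame(from = "cropland",
                                                         to = "forest",
                                                         mult = -1)),
               "positive")
})

test_that("biophysical overrides implement fertiliser cuts and efficiency gains", {
  bp <- default_biophys(2020)
  rna <- adjust_biophys(bp, scenario_preset("RNA"))
  expect_equal(rna$load_n[rna$lucode == 1], 158.78 * 0.70)
  expect_equal(rna$load_n[rna$lucode == 1], 111.146)
  expect_equal(rna$eff_n, bp$eff_n)

  inue <- adjust_biophys(bp, scenario_preset("INUE"))
  expect_equal(inue$eff_n[inue$lucode == 1], 0.40)
  expect_equal(inue$load_n, bp$load_n)

  both <- adjust_biophys(adjust_biophys(bp, scenario_preset("RNA")),
                         scenario_preset("INUE"))
  expect_equal(both$load_n[both$lucode == 1], 111.146)
  expect_equal(both$eff_n[both$lucode == 1], 0.40)

  combo <- adjust_biophys(bp, scenario_preset("BAU+INUE"))
  expect_equal(combo$eff_n[combo$lucode == 1], 0.40)
})

test_that("suitability model separates classes and yields proper probabilities", {
  set.seed(3)
  # single perfectly separating driver
  codes_b <- matrix(c(rep(1, 200), rep(7, 200)), 20, 20)
  codes_a <- codes_b
  drv <- nr_grid(matrix(c(rnorm(200, -3), rnorm(200, 3)), 20, 20))
  drv2 <- nr_grid(matrix(rnorm(400), 20, 20))
  suit <- suppressWarnings(fit_suitability(list(a = lucc_from(codes_a),
                                                b = lucc_from(codes_b)),
                                           list(x = drv, noise = drv2),
                                           seed = 7))
  pred <- colnames(suit$prob)[max.col(suit$prob)]
  truth <- names(lucc_legend())[match(as.vector(codes_b)[suit$index],
                                      lucc_legend())]
  expect_gt(mean(pred == truth), 0.95)
  expect_equal(unname(rowSums(suit$prob)), rep(1, 400), tolerance = 1e-9)

  # pure-noise drivers: probabilities approach the class priors
  set.seed(8)
  codes_n <- matrix(sample(c(1, 7), 900, TRUE, prob = c(0.7, 0.3)), 30, 30)
  suitn <- suppressWarnings(fit_suitability(
    list(a = lucc_from(codes_n), b = lucc_from(codes_n)),
    list(u = nr_grid(matrix(rnorm(900), 30, 30)),
         v = nr_grid(matrix(rnorm(900), 30, 30))), seed = 9))
  expect_equal(mean(suitn$prob[, "cropland"]), 0.7, tolerance = 0.05)
})

test_that("CA allocation meets demand exactly and respects constraints", {
  set.seed(10)
  codes <- matrix(sample(c(1, 2, 5, 7), 1600, TRUE,
                         prob = c(0.5, 0.2, 0.1, 0.2)), 40, 40)
  lu <- lucc_from(codes)
  drivers <- list(a = nr_grid(matrix(rnorm(1600), 40, 40)),
                  b = nr_grid(matrix(rnorm(1600), 40, 40)))
  suit <- suppressWarnings(fit_suitability(list(a = lu, b = lu), drivers,
                                           seed = 2))
  counts <- sapply(lucc_legend(), function(c) sum(codes == c))
  names(counts) <- names(lucc_legend())

  # demand = current areas: bit-identical return
  out0 <- allocate_demand(lu, suit, counts, seed = 1)
  expect_identical(out0$values, lu$values)

  # shift 60 cropland pixels to developed, 20 to forest
  demand <- counts
  demand["cropland"] <- demand["cropland"] - 80L
  demand["developed"] <- demand["developed"] + 60L
  demand["forest"] <- demand["forest"] + 20L
  ec <- scenario_preset("EC")
  for (seed in c(1, 7, 23)) {
    out <- allocate_demand(lu, suit, demand, ec, seed = seed)
    got <- sapply(lucc_legend(), function(c) sum(out$values == c))
    expect_equal(unname(got), unname(demand[names(lucc_legend())]))
    # EC forbids forest -> developed and water -> developed
    was_forest <- lu$values == 2
    was_water <- lu$values == 5
    expect_equal(sum(out$values[was_forest] == 7), 0)
    expect_equal(sum(out$values[was_water] == 7), 0)
  }
})

test_that("kappa agrees with closed forms and vanishes for shuffled maps", {
  a <- uniform_lucc(10, 10, "cropland")
  k1 <- confusion_kappa(a, a)
  expect_equal(k1$overall_accuracy, 1)
  expect_equal(k1$kappa, 1)

  # confusion [[45, 5], [5, 45]]: OA 0.9, pe 0.5, kappa 0.8
  sim <- c(rep(1, 50), rep(7, 50))
  obs <- sim
  obs[1:5] <- 7
  obs[51:55] <- 1
  k2 <- confusion_kappa(lucc_from(matrix(sim, 10, 10)),
                        lucc_from(matrix(obs, 10, 10)))
  expect_equal(k2$overall_accuracy, 0.9, tolerance = 1e-12)
  expect_equal(k2$kappa, 0.8, tolerance = 1e-12)

  set.seed(19)
  v <- sample(1:7, 1e5, replace = TRUE)
  k3 <- confusion_kappa(lucc_from(matrix(v, 250, 400)),
                        lucc_from(matrix(sample(v), 250, 400)))
  expect_lt(abs(k3$kappa), 0.02)
})
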