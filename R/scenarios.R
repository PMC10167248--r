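#' Inter-period land-use transition model
#'
#' Cross-tabulates two dated maps into an L x L count matrix and row-stochastic
#' transition probabilities (classes with no pixels at the first date get an
#' identity row).
#'
#' @param lucc_a,lucc_b compatible `nr_lucc` maps with the same legend.
#' @param interval_years years between the two dates.
#' @return list of class `transition_model`: `counts`, `probs`,
#'   `interval_years`, `legend`.
#' @export
transition_matrix <- function(lucc_a, lucc_b, interval_years = 5) {
  check_compatible(lucc_a, lucc_b)
  if (!identical(lucc_a$legend, lucc_b$legend)) stop("legend mismatch")
  leg <- lucc_a$legend
  a <- factor(lucc_a$values, levels = leg, labels = names(leg))
  b <- factor(lucc_b$values, levels = leg, labels = names(leg))
  ok <- !is.na(a) & !is.na(b)
  counts <- unclass(table(from = a[ok], to = b[ok]))
  probs <- counts / ifelse(rowSums(counts) > 0, rowSums(counts), 1)
  zero <- rowSums(counts) == 0
  probs[zero, ] <- diag(nrow(counts))[zero, , drop = FALSE]
  structure(list(counts = counts, probs = probs,
                 interval_years = interval_years, legend = leg),
            class = "transition_model")
}

#' Transfer proportions between classes
#'
#' The chord-diagram numbers: per (from, to) pair with from != to, the share
#' of the from-class initial area that moved, and the share of the total
#' transferred area.
#'
#' @param tm `transition_model`.
#' @return data.frame: from, to, count, share_of_from, share_of_transferred.
#' @export
transfer_proportions <- function(tm) {
  cn <- tm$counts
  init <- rowSums(cn)
  off <- which(row(cn) != col(cn), arr.ind = TRUE)
  total_moved <- sum(cn[off])
  out <- data.frame(
    from = rownames(cn)[off[, 1]],
    to = colnames(cn)[off[, 2]],
    count = cn[off],
    share_of_from = ifelse(init[off[, 1]] > 0, cn[off] / init[off[, 1]], 0),
    share_of_transferred = if (total_moved > 0) cn[off] / total_moved else 0
  )
  out[order(out$from, out$to), ]
}

#' Markov projection of land demand
#'
#' demand = areas0 x P^steps with steps = horizon / interval, then rounded to
#' integer pixel counts by the largest-remainder rule so the total is
#' preserved exactly.
#'
#' @param tm `transition_model`.
#' @param areas0 named vector of current pixel counts per class.
#' @param horizon_years projection horizon (must be a multiple of the
#'   transition interval unless `force = TRUE`, which rounds).
#' @param force allow a non-integer step ratio (rounded).
#' @return list: `real` (exact matrix-power projection), `counts` (integer
#'   demand), `steps`.
#' @export
markov_demand <- function(tm, areas0, horizon_years, force = FALSE) {
  ratio <- horizon_years / tm$interval_years
  if (abs(ratio - round(ratio)) > 1e-9 && !force)
    stop("horizon is not an integer multiple of the transition interval")
  steps <- round(ratio)
  p <- tm$probs
  pk <- diag(nrow(p))
  for (s in seq_len(steps)) pk <- pk %*% p
  a0 <- areas0[rownames(p)]
  real <- as.numeric(a0 %*% pk)
  names(real) <- colnames(p)
  counts <- largest_remainder(real)
  list(real = real, counts = counts, steps = steps)
}

## integer rounding preserving the (integer) total
largest_remainder <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  short <- total - sum(fl)
  rem <- x - fl
  bump <- order(rem, decreasing = TRUE)[seq_len(short)]
  fl[bump] <- fl[bump] + 1
  stats::setNames(as.integer(fl), names(x))
}

#' Scenario specification
#'
#' Encodes a scenario as transition-probability modifiers, forbidden
#' transitions, and biophysical overrides (class load multipliers and
#' retention-efficiency replacements).
#'
#' @param name scenario label.
#' @param prob_modifiers data.frame(from, to, mult) of off-diagonal
#'   probability multipliers (> 0).
#' @param forbidden data.frame(from, to) of transitions zeroed and never
#'   executed in allocation.
#' @param load_multipliers named numeric, multiplies `load_n` per class.
#' @param eff_overrides named numeric, replaces `eff_n` per class.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, prob_modifiers = NULL, forbidden = NULL,
                          load_multipliers = NULL, eff_overrides = NULL) {
  if (!is.null(prob_modifiers) && any(prob_modifiers$mult <= 0))
    stop("probability multipliers must be positive (use `forbidden` to zero)")
  structure(list(name = name, prob_modifiers = prob_modifiers,
                 forbidden = forbidden, load_multipliers = load_multipliers,
                 eff_overrides = eff_overrides),
            class = "scenario_spec")
}

#' Packaged scenario presets
#'
#' The seven study scenarios:
#' \describe{
#'   \item{BAU}{business-as-usual Markov projection, no modifiers.}
#'   \item{ED}{economic development: transitions to cropland from water,
#'     barren, grassland and forest +60%; transitions to developed from
#'     water, barren, grassland, forest and cropland +100%.}
#'   \item{EC}{ecological conservation: cropland to forest and to water
#'     doubled; barren to forest and to water +80%; forest and water to
#'     developed forbidden; forest and water to the remaining classes -40%.}
#'   \item{RNA}{reduced Nr application: land use held at the base map,
#'     cropland load x 0.70.}
#'   \item{INUE}{increased Nr use efficiency: land use held at the base map,
#'     cropland retention efficiency set to 0.40.}
#'   \item{BAU+INUE, ED+INUE}{the land-use scenario combined with the INUE
#'     efficiency override.}
#' }
#'
#' @param name one of "BAU", "ED", "EC", "RNA", "INUE", "BAU+INUE",
#'   "ED+INUE".
#' @return `scenario_spec`.
#' @export
scenario_preset <- function(name = c("BAU", "ED", "EC", "RNA", "INUE",
                                     "BAU+INUE", "ED+INUE")) {
  name <- match.arg(name)
  mods <- function(from, to, mult)
    data.frame(from = rep(from, each = length(to)), to = to, mult = mult)
  ed_mods <- rbind(
    mods(c("water", "barren", "grassland", "forest"), "cropland", 1.6),
    mods(c("water", "barren", "grassland", "forest", "cropland"),
         "developed", 2.0))
  ec_other <- setdiff(names(lucc_legend()), c("forest", "water", "developed"))
  ec_mods <- rbind(
    mods("cropland", c("forest", "water"), 2.0),
    mods("barren", c("forest", "water"), 1.8),
    mods(c("forest", "water"), ec_other, 0.6))
  ec_forbidden <- data.frame(from = c("forest", "water"),
                             to = c("developed", "developed"))
  inue_eff <- c(cropland = 0.40)
  switch(name,
    "BAU" = scenario_spec("BAU"),
    "ED" = scenario_spec("ED", prob_modifiers = ed_mods),
    "EC" = scenario_spec("EC", prob_modifiers = ec_mods,
                         forbidden = ec_forbidden),
    "RNA" = scenario_spec("RNA", load_multipliers = c(cropland = 0.70)),
    "INUE" = scenario_spec("INUE", eff_overrides = inue_eff),
    "BAU+INUE" = scenario_spec("BAU+INUE", eff_overrides = inue_eff),
    "ED+INUE" = scenario_spec("ED+INUE", prob_modifiers = ed_mods,
                              eff_overrides = inue_eff))
}

#' Apply a scenario's transition modifiers
#'
#' Multiplies the listed off-diagonal probabilities, zeroes forbidden pairs,
#' and restores each row sum to 1 through the diagonal (persistence). If a
#' diagonal would go negative, the row's off-diagonal entries are rescaled
#' proportionally instead and a warning is issued. Scenarios without
#' transition modifiers (RNA, INUE) return the model unchanged.
#'
#' @param tm `transition_model`.
#' @param spec `scenario_spec`.
#' @return modified `transition_model`.
#' @export
apply_scenario <- function(tm, spec) {
  p <- tm$probs
  cls <- rownames(p)
  mod <- spec$prob_modifiers
  if (!is.null(mod)) {
    bad <- setdiff(c(mod$from, mod$to), cls)
    if (length(bad)) stop("unknown classes in modifiers: ",
                          paste(unique(bad), collapse = ", "))
    for (r in seq_len(nrow(mod))) {
      if (mod$from[r] == mod$to[r]) next
      p[mod$from[r], mod$to[r]] <- p[mod$from[r], mod$to[r]] * mod$mult[r]
    }
  }
  if (!is.null(spec$forbidden))
    for (r in seq_len(nrow(spec$forbidden)))
      p[spec$forbidden$from[r], spec$forbidden$to[r]] <- 0
  for (i in seq_len(nrow(p))) {
    off <- sum(p[i, -i])
    if (off <= 1) {
      p[i, i] <- 1 - off
    } else {
      warning(sprintf("row '%s': off-diagonal mass %.3f > 1; rescaled", cls[i], off))
      p[i, -i] <- p[i, -i] / off
      p[i, i] <- 0
    }
  }
  tm$probs <- p
  tm
}

#' Fit a land-use suitability model
#'
#' Multinomial logistic regression of the later map's class on driver values
#' at sampled pixels: a deterministic, probability-calibrated stand-in for
#' patch-based machine-learning suitability models. Classes absent from the
#' training sample fall back to a uniform prior column (with a warning).
#'
#' @param lucc_pair list(a, b) of `nr_lucc` maps (drivers predict map b).
#' @param drivers named list of `nr_grid` layers.
#' @param seed RNG seed for pixel sampling.
#' @param n_sample training pixels (default 2000).
#' @return list of class `suitability`: `prob` (matrix, valid pixels x
#'   classes), `index` (linear pixel indices), `legend`, `model`.
#' @export
fit_suitability <- function(lucc_pair, drivers, seed = 1, n_sample = 2000) {
  stopifnot(length(drivers) >= 2)
  a <- lucc_pair$a; b <- lucc_pair$b
  check_compatible(a, b)
  for (d in drivers) check_compatible(a, d)
  leg <- b$legend
  dmat <- sapply(drivers, function(d) as.vector(d$values))
  yv <- as.vector(b$values)
  valid <- !is.na(yv) & stats::complete.cases(dmat)
  idx <- which(valid)
  set.seed(seed)
  train <- sample(idx, min(n_sample, length(idx)))
  dftr <- data.frame(y = factor(yv[train], levels = leg), dmat[train, , drop = FALSE])
  fit <- nnet::multinom(y ~ ., data = droplevels(dftr), trace = FALSE,
                        maxit = 200)
  newd <- data.frame(dmat[idx, , drop = FALSE])
  pr <- stats::predict(fit, newdata = newd, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # 2-class case
  trained <- levels(droplevels(dftr$y))
  prob <- matrix(0, length(idx), length(leg),
                 dimnames = list(NULL, names(leg)))
  prob[, match(trained, leg)] <- pr
  absent <- setdiff(names(leg), names(leg)[match(trained, leg)])
  if (length(absent)) {
    warning("classes absent from training sample get a spatially uniform ",
            "vanishing prior: ", paste(absent, collapse = ", "))
    prob[, absent] <- 1e-8
    prob <- prob / rowSums(prob)
  }
  structure(list(prob = prob, index = idx, legend = leg, model = fit),
            class = "suitability")
}

#' Cellular-automata allocation of projected demand
#'
#' Iterative patch-growing: classes short of their demand claim pixels from
#' surplus classes in descending order of a combined score (suitability x
#' neighbourhood share x a small uniform jitter), admitting only scores above
#' a quantile threshold that decreases each round until all demands are met.
#' Forbidden (from, to) transitions are never executed; a donor class is
#' never drawn below its own demand. When demand equals the current counts
#' the input map is returned unchanged.
#'
#' @param lucc0 starting `nr_lucc`.
#' @param suitability `suitability` object on the same grid.
#' @param demand named integer vector of target pixel counts (must sum to the
#'   valid pixel count).
#' @param spec `scenario_spec` (for forbidden transitions); `NULL` = none.
#' @param seed RNG seed (jitter).
#' @param thr_start,thr_decay decreasing acceptance threshold: starting
#'   quantile and per-round decay factor.
#' @param max_rounds safety cap on allocation rounds.
#' @return allocated `nr_lucc`.
#' @export
allocate_demand <- function(lucc0, suitability, demand, spec = NULL, seed = 1,
                            thr_start = 0.9, thr_decay = 0.9,
                            max_rounds = 200) {
  leg <- lucc0$legend
  demand <- demand[names(leg)]
  codes <- lucc0$values
  idx <- suitability$index
  cur <- codes[idx]
  if (sum(demand) != length(cur))
    stop("demand must sum to the number of valid pixels")
  counts <- stats::setNames(vapply(leg, function(c) sum(cur == c), 0L), names(leg))
  if (all(counts == demand)) return(lucc0)
  forb <- matrix(FALSE, length(leg), length(leg),
                 dimnames = list(names(leg), names(leg)))
  if (!is.null(spec$forbidden))
    for (r in seq_len(nrow(spec$forbidden)))
      forb[spec$forbidden$from[r], spec$forbidden$to[r]] <- TRUE
  set.seed(seed)
  nr <- nrow(codes)
  thr <- thr_start
  for (round in seq_len(max_rounds)) {
    deficit <- demand - counts
    if (all(deficit == 0)) break
    neigh <- neighbour_share(codes, leg)
    changed <- FALSE
    for (cl in names(sort(deficit[deficit > 0], decreasing = TRUE))) {
      need <- demand[cl] - counts[cl]
      if (need <= 0) next
      to_code <- leg[[cl]]
      from_ok <- names(leg)[counts > demand & !forb[, cl]]
      if (!length(from_ok)) next
      elig <- which(cur %in% leg[from_ok])
      if (!length(elig)) next
      score <- suitability$prob[elig, cl] *
        (neigh[[cl]][idx[elig]] + 0.01) *
        stats::runif(length(elig), 0.9, 1.1)
      cand <- elig[score >= stats::quantile(score, thr)]
      cand <- cand[order(score[score >= stats::quantile(score, thr)],
                         decreasing = TRUE)]
      for (pxi in cand) {
        if (need <= 0) break
        donor <- names(leg)[match(cur[pxi], leg)]
        if (counts[donor] <= demand[donor]) next
        cur[pxi] <- to_code
        codes[idx[pxi]] <- to_code
        counts[donor] <- counts[donor] - 1L
        counts[cl] <- counts[cl] + 1L
        need <- need - 1L
        changed <- TRUE
      }
    }
    thr <- max(thr * thr_decay, 0)
    if (!changed && thr < 1e-3) {
      blocked <- names(which(demand - counts > 0))
      stop("demand unattainable under constraints for class: ",
           paste(blocked, collapse = ", "))
    }
  }
  if (!all(counts == demand))
    stop("allocation did not converge within max_rounds")
  out <- lucc0
  out$values <- codes
  out
}

## per-class share of the 8 neighbours holding that class
neighbour_share <- function(codes, leg) {
  off <- d8_offsets()
  nvalid <- matrix(0, nrow(codes), ncol(codes))
  acc <- lapply(leg, function(c) matrix(0, nrow(codes), ncol(codes)))
  for (k in seq_len(8)) {
    nb <- shift_mat(codes, off$dr[k], off$dc[k])
    okn <- !is.na(nb)
    nvalid <- nvalid + okn
    for (nm in names(leg))
      acc[[nm]] <- acc[[nm]] + (okn & nb == leg[[nm]])
  }
  lapply(acc, function(a) a / pmax(nvalid, 1))
}

#' Overall accuracy and kappa of a simulated map
#'
#' @param sim,obs compatible `nr_lucc` maps.
#' @return list: `confusion`, `overall_accuracy`, `kappa`.
#' @export
confusion_kappa <- function(sim, obs) {
  check_compatible(sim, obs)
  a <- as.vector(sim$values); b <- as.vector(obs$values)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid overlap between maps")
  leg <- sim$legend
  cm <- unclass(table(factor(a[ok], levels = leg, labels = names(leg)),
                      factor(b[ok], levels = leg, labels = names(leg))))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  # degenerate single-class agreement: chance correction is undefined,
  # perfect agreement scores 1
  kappa <- if (pe == 1) as.numeric(po == 1) else (po - pe) / (1 - pe)
  list(confusion = cm, overall_accuracy = po, kappa = kappa)
}

#' Apply a scenario's biophysical overrides
#'
#' Load multipliers scale `load_n`; efficiency overrides replace `eff_n`.
#' Other rows are untouched; combined scenarios compose both.
#'
#' @param biophys `biophys_table`.
#' @param spec `scenario_spec`.
#' @param legend class legend naming the codes (default canonical).
#' @return modified `biophys_table`.
#' @export
adjust_biophys <- function(biophys, spec, legend = lucc_legend()) {
  bp <- biophys
  apply_named <- function(vals, fn) {
    for (nm in names(vals)) {
      if (!nm %in% names(legend)) stop("unknown class: ", nm)
      row <- bp$lucode == legend[[nm]]
      if (!any(row)) stop("class not in biophys table: ", nm)
      bp[row, ] <<- fn(bp[row, , drop = FALSE], vals[[nm]])
    }
  }
  if (!is.null(spec$load_multipliers))
    apply_named(spec$load_multipliers,
                function(r, v) { r$load_n <- r$load_n * v; r })
  if (!is.null(spec$eff_overrides))
    apply_named(spec$eff_overrides, function(r, v) { r$eff_n <- v; r })
  if (any(bp$eff_n < 0 | bp$eff_n > 1))
    stop("scenario pushes eff_n outside [0, 1]")
  biophys_table(bp)
}
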