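#' Assemble a sample frame of response and driver values
#'
#' Stacks compatible grids into a complete-case data.frame, one row per
#' sampled pixel. Sampling is either exhaustive or simple random with a fixed
#' seed (reruns are identical).
#'
#' @param response `nr_grid` (e.g. Nr export).
#' @param factors named list of `nr_grid` / `nr_lucc` layers.
#' @param sampling list: `type` = "all" or "random"; `n`, `seed` for random.
#' @return data.frame with column `response` plus one column per factor.
#' @export
sample_frame <- function(response, factors,
                         sampling = list(type = "all")) {
  stopifnot(length(factors) >= 1, !is.null(names(factors)))
  for (f in factors) check_compatible(response, f)
  df <- data.frame(response = as.vector(response$values))
  for (nm in names(factors)) df[[nm]] <- as.vector(factors[[nm]]$values)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (identical(sampling$type, "random")) {
    stopifnot(!is.null(sampling$n), !is.null(sampling$seed))
    n <- min(sampling$n, nrow(df))
    set.seed(sampling$seed)
    df <- df[sort(sample.int(nrow(df), n)), , drop = FALSE]
  }
  if (nrow(df) < 30) stop("fewer than 30 complete rows in sample frame")
  rownames(df) <- NULL
  df
}

#' Factor-detector q statistic
#'
#' q = 1 - SSW/SST with SSW = sum_h N_h sigma2_h and SST = N sigma2, all
#' variances population (biased) so that the pixel counts cancel as in the
#' within/total variance decomposition. q is the share of the response's
#' spatial variance explained by the stratification, in [0, 1].
#'
#' @param response numeric vector.
#' @param strata vector of stratum labels (same length).
#' @return list of class `q_result`: `q`, `ssw`, `sst`, `N`, `L`, `sigma2`,
#'   `sigma2_h`, `N_h`, `mean_h`, `strata`.
#' @export
factor_q <- function(response, strata) {
  stopifnot(length(response) == length(strata))
  ok <- !is.na(response) & !is.na(strata)
  y <- response[ok]
  h <- factor(strata[ok])
  h <- droplevels(h)
  N <- length(y); L <- nlevels(h)
  if (N < L || L < 1) stop("need N >= L >= 1")
  sigma2 <- mean((y - mean(y))^2)
  if (sigma2 == 0) stop("zero total variance: q undefined")
  N_h <- as.numeric(table(h))
  mean_h <- as.numeric(tapply(y, h, mean))
  sigma2_h <- as.numeric(tapply(y, h, function(v) mean((v - mean(v))^2)))
  ssw <- sum(N_h * sigma2_h)
  sst <- N * sigma2
  structure(list(q = 1 - ssw / sst, ssw = ssw, sst = sst, N = N, L = L,
                 sigma2 = sigma2, sigma2_h = sigma2_h, N_h = N_h,
                 mean_h = mean_h, response = y, strata = h),
            class = "q_result")
}

#' Significance of the q statistic
#'
#' Default: the noncentral-F test with
#' F = (N - L)/(L - 1) x q/(1 - q), noncentrality
#' lambda = (sum_h N_h ybar_h^2 - (sum_h sqrt(N_h) ybar_h)^2 / N) / sigma2,
#' p = upper tail of F(L-1, N-L; lambda). A seeded permutation test (q
#' recomputed under label permutations) is available as an assumption-free
#' cross-check.
#'
#' @param qr `q_result` from [factor_q()].
#' @param method `"ncf"` (noncentral F) or `"permutation"`.
#' @param n_perm permutations for `method = "permutation"` (default 999).
#' @param seed RNG seed for the permutation test.
#' @return p-value.
#' @export
q_significance <- function(qr, method = c("ncf", "permutation"),
                           n_perm = 999, seed = 1) {
  method <- match.arg(method)
  N <- qr$N; L <- qr$L
  if (L < 2 || N <= L) stop("need N > L >= 2 for a significance test")
  if (method == "ncf") {
    q <- qr$q
    f_val <- (N - L) / (L - 1) * q / (1 - q)
    lambda <- (sum(qr$N_h * qr$mean_h^2) -
                 sum(sqrt(qr$N_h) * qr$mean_h)^2 / N) / qr$sigma2
    stats::pf(f_val, L - 1, N - L, ncp = lambda, lower.tail = FALSE)
  } else {
    set.seed(seed)
    y <- qr$response
    h <- qr$strata
    qs <- q_perm_null(y, h, n_perm)
    (1 + sum(qs >= qr$q)) / (n_perm + 1)
  }
}

## vectorised q under n_perm label permutations (equivalently, permuting y)
q_perm_null <- function(y, h, n_perm) {
  n <- length(y)
  idx <- replicate(n_perm, sample.int(n))
  Y <- matrix(y[idx], nrow = n)
  gs <- rowsum(Y, h)              # group sums, L x n_perm
  gss <- rowsum(Y^2, h)           # group sums of squares
  N_h <- as.numeric(table(h))
  ssw <- colSums(gss - gs^2 / N_h)
  sst <- sum((y - mean(y))^2)
  1 - ssw / sst
}

#' Discretize a continuous driver into strata
#'
#' Break methods: `equal` (equal-width), `quantile`, `natural` (exact
#' Fisher-Jenks minimisation of within-class sum of squares by dynamic
#' programming), `geometric` (geometric-interval), `sd` (mean +/- multiples of
#' the standard deviation). Intervals are left-closed, right-open except the
#' last; empty strata are collapsed with a warning.
#'
#' @param values numeric vector.
#' @param method one of "equal", "quantile", "natural", "geometric", "sd".
#' @param n_strata number of classes (>= 2).
#' @return list of class `strata_vector`: `labels` (integer 1..L), `breaks`,
#'   `method`, `n_strata` (realised L).
#' @export
discretize_factor <- function(values, method = c("equal", "quantile", "natural",
                                                 "geometric", "sd"),
                              n_strata = 4) {
  method <- match.arg(method)
  stopifnot(n_strata >= 2)
  x <- values[!is.na(values)]
  if (length(unique(x)) < n_strata)
    stop("fewer distinct values than strata")
  rng <- range(x)
  inner <- switch(method,
    equal = seq(rng[1], rng[2], length.out = n_strata + 1)[-c(1, n_strata + 1)],
    quantile = unname(stats::quantile(x, probs = seq_len(n_strata - 1) / n_strata)),
    natural = jenks_breaks(x, n_strata),
    geometric = {
      shift <- if (rng[1] > 0) 0 else 1 - rng[1]
      r <- ((rng[2] + shift) / (rng[1] + shift))^(1 / n_strata)
      (rng[1] + shift) * r^seq_len(n_strata - 1) - shift
    },
    sd = {
      m <- mean(x); s <- stats::sd(x)
      m + s * (seq_len(n_strata - 1) - n_strata / 2)
    })
  inner <- sort(unique(inner))
  labels <- findInterval(values, inner) + 1L
  labels[is.na(values)] <- NA_integer_
  ## collapse empty strata (possible with sd/geometric/duplicated quantiles)
  present <- sort(unique(labels[!is.na(labels)]))
  if (length(present) < n_strata)
    warning("empty strata collapsed: ", n_strata, " requested, ",
            length(present), " realised")
  labels <- match(labels, present)
  structure(list(labels = labels, breaks = inner, method = method,
                 n_strata = length(present)),
            class = "strata_vector")
}

## exact Fisher-Jenks optimal 1-D classification: O(k n^2) DP on sorted values
jenks_breaks <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  ss <- function(i, j) {  # within-class SS of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in seq_len(n)) cost[1, j] <- ss(1, j)
  for (m in 2:k) {
    for (j in m:n) {
      for (i in m:j) {   # class m covers xs[i..j]
        c_ <- cost[m - 1, i - 1] + ss(i, j)
        if (c_ < cost[m, j]) { cost[m, j] <- c_; back[m, j] <- i }
      }
    }
  }
  cuts <- integer(k - 1)
  j <- n
  for (m in k:2) {
    i <- back[m, j]
    cuts[m - 1] <- i      # first index of class m
    j <- i - 1
  }
  ## break value between the last member of one class and first of the next
  (xs[cuts - 1] + xs[cuts]) / 2
}

#' Search for the q-maximising discretization of a driver
#'
#' Evaluates [factor_q()] over a method x strata-count grid and returns the
#' scheme with the largest q; ties go to fewer strata, then to method order.
#'
#' @param response numeric vector.
#' @param values continuous driver values (same length).
#' @param methods methods to try (see [discretize_factor()]).
#' @param strata_range candidate strata counts (default 3:8).
#' @return list: `strata` (best `strata_vector`), `q_result`, `search`
#'   (data.frame of all evaluated combinations).
#' @export
optimal_discretization <- function(response, values,
                                   methods = c("equal", "quantile", "natural",
                                               "geometric", "sd"),
                                   strata_range = 3:8) {
  rows <- list(); fits <- list()
  for (mi in seq_along(methods)) for (ns in strata_range) {
    res <- tryCatch({
      sv <- suppressWarnings(discretize_factor(values, methods[mi], ns))
      qr <- factor_q(response, sv$labels)
      list(sv = sv, qr = qr)
    }, error = function(e) NULL)
    if (is.null(res)) next
    key <- sprintf("%s_%d", methods[mi], ns)
    fits[[key]] <- res
    rows[[key]] <- data.frame(method = methods[mi], method_index = mi,
                              n_strata = ns, q = res$qr$q)
  }
  if (!length(rows)) stop("all discretization schemes degenerate")
  search <- do.call(rbind, rows)
  ord <- order(-search$q, search$n_strata, search$method_index)
  best <- search[ord[1], ]
  pick <- fits[[sprintf("%s_%d", best$method, best$n_strata)]]
  list(strata = pick$sv, q_result = pick$qr, search = search)
}

#' Rank candidate drivers by explanatory power
#'
#' For each factor, computes q (continuous factors via
#' [optimal_discretization()], categorical ones stratified directly by their
#' codes) and its p-value, returning a table sorted by descending q.
#'
#' @param frame sample frame from [sample_frame()].
#' @param factor_types named character vector, `"continuous"` or
#'   `"categorical"` per factor column.
#' @param strata_range passed to [optimal_discretization()].
#' @param p_method `"ncf"` or `"permutation"`.
#' @return data.frame: factor, type, method, n_strata, q, p.
#' @export
rank_factors <- function(frame, factor_types, strata_range = 3:8,
                         p_method = "ncf") {
  stopifnot(length(factor_types) >= 1,
            all(names(factor_types) %in% names(frame)))
  rows <- lapply(names(factor_types), function(nm) {
    if (factor_types[[nm]] == "categorical") {
      qr <- factor_q(frame$response, frame[[nm]])
      method <- "categorical"; ns <- qr$L
    } else {
      od <- optimal_discretization(frame$response, frame[[nm]],
                                   strata_range = strata_range)
      qr <- od$q_result
      method <- od$strata$method; ns <- od$strata$n_strata
    }
    data.frame(factor = nm, type = factor_types[[nm]], method = method,
               n_strata = ns, q = qr$q, p = q_significance(qr, p_method))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$q), , drop = FALSE]
  rownames(out) <- NULL
  out
}
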