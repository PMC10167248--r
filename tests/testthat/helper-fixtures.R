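# shared fixture builders: everything generated in code, nothing on disk

# east-sloping plane: drains to the east edge, drop per cell in metres
plane_dem <- function(nr = 8, nc = 8, drop = 1, cell = 30, base = 100) {
  z <- matrix(rep(seq(base + (nc - 1) * drop, base, by = -drop), each = nr), nr, nc)
  nr_grid(z, cell_size = cell)
}

# 1 x n strip descending eastward; stream on the last pixel
strip_dem <- function(n = 20, cell = 30) {
  # 3 rows so interior routing is defined; the middle row is the strip
  z <- matrix(NA_real_, 3, n)
  z[2, ] <- seq(n, 1)
  nr_grid(z, cell_size = cell)
}

strip_streams <- function(n = 20, cell = 30) {
  s <- matrix(NA_real_, 3, n)
  s[2, ] <- 0
  s[2, n] <- 1
  nr_grid(s, cell_size = cell)
}

# random sink-prone DEM with a deterministic seed
random_dem <- function(nr = 16, nc = 16, seed = 1, cell = 30) {
  set.seed(seed)
  base <- plane_dem(nr, nc, drop = 0.5, cell = cell)
  base$values <- base$values + matrix(rnorm(nr * nc, sd = 1.5), nr, nc)
  base
}

# uniform single-class land use over a grid
uniform_lucc <- function(nr, nc, class = "cropland", cell = 30) {
  nr_lucc(matrix(lucc_legend()[[class]], nr, nc), cell_size = cell)
}

# follow the D8 path from a linear index; returns indices visited
follow_path <- function(flow, start, max_steps = 1e5) {
  path <- integer(0)
  cur <- start
  for (s in seq_len(max_steps)) {
    path <- c(path, cur)
    nxt <- flow$receiver[cur]
    if (is.na(nxt)) return(path)
    cur <- nxt
  }
  stop("path did not terminate")
}

# independent scalar recursion of the export model on a west-to-east strip:
# pixel i drains to i+1, stream at pixel n. Returns per-pixel export (kg).
strip_export_oracle <- function(eff, crit_len, load_kg, prop_subs,
                                slope, cell, k, ic0, eff_subs, l_subs) {
  n <- length(eff)
  # downslope retention walking upstream from the stream (pixel n)
  effp <- numeric(n)
  ndr0 <- numeric(n)
  ndr0[n] <- 1                     # stream pixel delivers in full
  for (i in (n - 1):1) {
    s_i <- exp(-5 * cell / crit_len[i])
    if (i == n - 1) {
      effp[i] <- eff[i] * (1 - s_i)
    } else if (eff[i] <= effp[i + 1]) {
      effp[i] <- effp[i + 1]
    } else {
      effp[i] <- effp[i + 1] * s_i + eff[i] * (1 - s_i)
    }
    ndr0[i] <- 1 - effp[i]
  }
  # connectivity: upslope = pixels 1..i (uniform slope), downslope path i..stream
  ic <- numeric(n)
  for (i in 1:(n - 1)) {
    d_up <- mean(slope[1:i]) * sqrt(i * cell^2)
    d_dn <- sum(cell / slope[i:(n - 1)])
    ic[i] <- log10(d_up / d_dn)
  }
  ic[n] <- NA
  ndr_surf <- ndr0 / (1 + exp((ic0 - ic) / k))
  ndr_surf[n] <- 1
  dist <- rev(seq_len(n) - 1) * cell
  ndr_subs <- 1 - eff_subs * (1 - exp(-5 * dist / l_subs))
  load_surf <- (1 - prop_subs) * load_kg
  load_subs <- prop_subs * load_kg
  list(export = load_surf * ndr_surf + load_subs * ndr_subs,
       ndr0 = ndr0, ic = ic, ndr_surf = ndr_surf, ndr_subs = ndr_subs)
}

# naive reference for window landscape metrics on one submatrix of codes
naive_window_metrics <- function(sub, cell_size) {
  ok <- !is.na(sub)
  n <- sum(ok)
  cls <- sort(unique(sub[ok]))
  m <- length(cls)
  p <- sapply(cls, function(c) sum(sub[ok] == c) / n)
  shdi <- -sum(p * log(p))
  # rook adjacencies by explicit double loop, unordered single count
  g <- matrix(0, m, m, dimnames = list(cls, cls))
  nrr <- nrow(sub); ncc <- ncol(sub)
  for (i in seq_len(nrr)) for (j in seq_len(ncc)) {
    if (is.na(sub[i, j])) next
    if (j < ncc && !is.na(sub[i, j + 1])) {
      a <- as.character(sub[i, j]); b <- as.character(sub[i, j + 1])
      g[a, b] <- g[a, b] + 1
      if (a != b) g[b, a] <- g[b, a] + 1
    }
    if (i < nrr && !is.na(sub[i + 1, j])) {
      a <- as.character(sub[i, j]); b <- as.character(sub[i + 1, j])
      g[a, b] <- g[a, b] + 1
      if (a != b) g[b, a] <- g[b, a] + 1
    }
  }
  ai_terms <- sapply(seq_len(m), function(k) {
    a <- sum(sub[ok] == cls[k])
    nsq <- floor(sqrt(a)); rem <- a - nsq^2
    maxg <- 2 * nsq * (nsq - 1) +
      if (rem == 0) 0 else if (rem <= nsq) 2 * rem - 1 else 2 * rem - 2
    if (maxg == 0) p[k] * 100 else p[k] * g[k, k] / maxg * 100
  })
  ai <- sum(ai_terms)
  if (m == 1) {
    contag <- 100
  } else {
    acc <- 0
    for (i in seq_len(m)) for (k in seq_len(m)) {
      rs <- sum(g[i, ])
      if (rs == 0) next
      pik <- p[i] * g[i, k] / rs
      if (pik > 0) acc <- acc + pik * log(pik)
    }
    contag <- (1 + acc / (2 * log(m))) * 100
  }
  # 8-connected patches via igraph components
  mesh <- {
    idx <- which(ok)
    if (length(idx)) {
      edges <- c()
      for (i in seq_len(nrr)) for (j in seq_len(ncc)) {
        if (is.na(sub[i, j])) next
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nrr || jj < 1 || jj > ncc) next
          if (!is.na(sub[ii, jj]) && sub[ii, jj] == sub[i, j]) {
            edges <- c(edges, (j - 1) * nrr + i, (jj - 1) * nrr + ii)
          }
        }
      }
      gph <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2,
                                                byrow = TRUE), directed = FALSE)
      gph <- igraph::add_vertices(gph,
        length(setdiff(as.character(idx), igraph::V(gph)$name)),
        name = setdiff(as.character(idx), igraph::V(gph)$name))
      comp <- igraph::components(gph)
      areas_px <- as.numeric(table(comp$membership))
      area_ha <- cell_size^2 / 1e4
      sum((areas_px * area_ha)^2) / (n * area_ha)
    } else NA_real_
  }
  list(SHDI = shdi, AI = ai, CONTAG = contag, MESH = mesh)
}
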