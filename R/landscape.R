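#' Moving-window specification
#'
#' @param shape `"square"` or `"circle"`.
#' @param size window side (square) or diameter (circle), in metres.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(shape = c("square", "circle"), size = 1500) {
  shape <- match.arg(shape)
  stopifnot(size > 0)
  structure(list(shape = shape, size = size), class = "window_spec")
}

## half-width in pixels; windows shrink at raster borders (valid pixels only)
window_half <- function(window, cell_size) {
  half <- max(1L, floor((window$size / cell_size) / 2))
  if ((2 * half + 1)^2 < 9) stop("window must cover at least 9 pixels")
  half
}

## integral image with NA treated as 0; query(r1,r2,c1,c2) gives box sums
integral_image <- function(m) {
  m[is.na(m)] <- 0
  s <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed after second apply
  s <- t(s)
  function(r1, r2, c1, c2) {
    dims <- dim(r1)
    r1 <- pmax(as.vector(r1), 1L); c1 <- pmax(as.vector(c1), 1L)
    r2 <- pmin(as.vector(r2), nrow(m)); c2 <- pmin(as.vector(c2), ncol(m))
    bad <- r2 < r1 | c2 < c1
    a <- s[cbind(r2, c2)]
    b <- ifelse(r1 > 1, s[cbind(pmax(r1 - 1, 1), c2)], 0)
    d <- ifelse(c1 > 1, s[cbind(r2, pmax(c1 - 1, 1))], 0)
    e <- ifelse(r1 > 1 & c1 > 1, s[cbind(pmax(r1 - 1, 1), pmax(c1 - 1, 1))], 0)
    out <- a - b - d + e
    out[bad] <- 0
    if (!is.null(dims)) dim(out) <- dims
    out
  }
}

#' Proportion of a land-use class in a moving window
#'
#' Fraction of the window's valid pixels belonging to `class`; windows shrink
#' at raster borders.
#'
#' @param lucc `nr_lucc`.
#' @param class class name (in the legend) or integer code.
#' @param window `window_spec`.
#' @return `nr_grid` of fractions in [0, 1].
#' @export
class_proportion <- function(lucc, class, window = window_spec()) {
  code <- resolve_class(lucc, class)
  half <- window_half(window, lucc$cell_size)
  v <- lucc$values
  ind <- integral_image((!is.na(v) & v == code) * 1)
  valid <- integral_image(!is.na(v) * 1)
  rr <- row(v); cc <- col(v)
  r1 <- rr - half; r2 <- rr + half; c1 <- cc - half; c2 <- cc + half
  nv <- valid(r1, r2, c1, c2)
  out <- ind(r1, r2, c1, c2) / ifelse(nv > 0, nv, NA)
  out[is.na(v)] <- NA
  nr_grid(out, lucc$cell_size, lucc$origin)
}

resolve_class <- function(lucc, class) {
  if (is.character(class)) {
    if (!class %in% names(lucc$legend)) stop("unknown class: ", class)
    unname(lucc$legend[class])
  } else {
    if (!class %in% lucc$legend) stop("unknown class code: ", class)
    as.integer(class)
  }
}

#' Moving-window landscape configuration metrics
#'
#' Per-window Fragstats-style metrics on the land-use mosaic:
#' \describe{
#'   \item{SHDI}{Shannon diversity -sum p_k ln p_k of class proportions.}
#'   \item{AI}{aggregation index, 100 x sum p_k g_kk / max_g_kk with g_kk the
#'     rook like-adjacency count (single count) and max_g_kk from the
#'     largest-integer-square construction; a class whose window area admits
#'     no adjacency (single pixel) counts as fully aggregated.}
#'   \item{CONTAG}{contagion, 100 x (1 + sum P_ik ln P_ik / (2 ln m)) with
#'     P_ik = p_i g_ik / sum_k g_ik over the rook adjacency matrix
#'     (single count) and m the number of classes present; 100 when m = 1.}
#'   \item{MESH}{effective mesh size, sum of squared 8-connected patch areas
#'     divided by the window area, in hectares.}
#' }
#' Adjacencies and patches are evaluated within the (border-shrunk) window.
#'
#' @param lucc `nr_lucc`.
#' @param window `window_spec` (square windows only).
#' @param metrics subset of c("SHDI", "CONTAG", "AI", "MESH").
#' @param stride compute every `stride`-th pixel in each axis (others NA);
#'   1 = every pixel.
#' @return named list of `nr_grid`s, one per metric.
#' @export
window_metrics <- function(lucc, window = window_spec(),
                           metrics = c("SHDI", "CONTAG", "AI", "MESH"),
                           stride = 1L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (window$shape != "square")
    stop("window_metrics supports square windows")
  half <- window_half(window, lucc$cell_size)
  v <- lucc$values
  nr <- nrow(v); nc <- ncol(v)
  out <- lapply(metrics, function(m) matrix(NA_real_, nr, nc))
  names(out) <- metrics
  rows <- seq(1L, nr, by = stride); cols <- seq(1L, nc, by = stride)
  for (i in rows) for (j in cols) {
    if (is.na(v[i, j])) next
    sub <- v[max(1, i - half):min(nr, i + half),
             max(1, j - half):min(nc, j + half), drop = FALSE]
    met <- patch_metrics(sub, lucc$cell_size, metrics)
    for (m in metrics) out[[m]][i, j] <- met[[m]]
  }
  lapply(out, nr_grid, cell_size = lucc$cell_size, origin = lucc$origin)
}

## metrics for one window submatrix of class codes (NA = nodata)
patch_metrics <- function(sub, cell_size, metrics) {
  ok <- !is.na(sub)
  n <- sum(ok)
  res <- list()
  if (n == 0) return(stats::setNames(rep(list(NA_real_), length(metrics)), metrics))
  cls <- sort(unique(sub[ok]))
  m <- length(cls)
  p <- vapply(cls, function(c) sum(sub[ok] == c) / n, 0)
  if ("SHDI" %in% metrics) res$SHDI <- -sum(p * log(p))
  if (any(c("AI", "CONTAG") %in% metrics)) {
    g <- adjacency_counts(sub, cls)  # symmetric, single count
    if ("AI" %in% metrics) {
      terms <- vapply(seq_len(m), function(k) {
        a <- sum(sub[ok] == cls[k])
        nsq <- floor(sqrt(a)); rem <- a - nsq^2
        maxg <- 2 * nsq * (nsq - 1) +
          if (rem == 0) 0 else if (rem <= nsq) 2 * rem - 1 else 2 * rem - 2
        if (maxg == 0) p[k] * 100 else p[k] * (g[k, k] / maxg) * 100
      }, 0)
      res$AI <- sum(terms)
    }
    if ("CONTAG" %in% metrics) {
      if (m == 1) {
        res$CONTAG <- 100
      } else {
        rs <- rowSums(g)
        acc <- 0
        for (i in seq_len(m)) for (k in seq_len(m)) {
          if (rs[i] == 0) next
          pik <- p[i] * g[i, k] / rs[i]
          if (pik > 0) acc <- acc + pik * log(pik)
        }
        res$CONTAG <- (1 + acc / (2 * log(m))) * 100
      }
    }
  }
  if ("MESH" %in% metrics) {
    lab <- label_patches(sub)
    a_px <- as.numeric(table(lab[!is.na(lab)]))
    area_ha <- cell_size^2 / 1e4
    res$MESH <- sum((a_px * area_ha)^2) / (n * area_ha)
  }
  res[metrics]
}

## rook adjacency counts between classes, unordered single count
adjacency_counts <- function(sub, cls) {
  m <- length(cls)
  g <- matrix(0, m, m)
  idx <- function(code) match(code, cls)
  nr <- nrow(sub); nc <- ncol(sub)
  if (nc > 1) {
    a <- sub[, -nc]; b <- sub[, -1]
    ok <- !is.na(a) & !is.na(b)
    for (pair in which(ok)) {
      i <- idx(a[pair]); k <- idx(b[pair])
      g[i, k] <- g[i, k] + 1
      if (i != k) g[k, i] <- g[k, i] + 1
    }
  }
  if (nr > 1) {
    a <- sub[-nr, ]; b <- sub[-1, ]
    ok <- !is.na(a) & !is.na(b)
    for (pair in which(ok)) {
      i <- idx(a[pair]); k <- idx(b[pair])
      g[i, k] <- g[i, k] + 1
      if (i != k) g[k, i] <- g[k, i] + 1
    }
  }
  g
}

## 8-connected same-class patch labelling by flood fill
label_patches <- function(sub) {
  nr <- nrow(sub); nc <- ncol(sub)
  lab <- matrix(NA_integer_, nr, nc)
  nxt <- 0L
  dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  for (start in which(!is.na(sub))) {
    if (!is.na(lab[start])) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    code <- sub[start]
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- ((cur - 1L) %% nr) + 1L
      cj <- ((cur - 1L) %/% nr) + 1L
      for (k in 1:8) {
        ni <- ci + dr[k]; nj <- cj + dc[k]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        nidx <- ni + (nj - 1L) * nr
        if (is.na(lab[nidx]) && !is.na(sub[nidx]) && sub[nidx] == code) {
          lab[nidx] <- nxt
          queue <- c(queue, nidx)
        }
      }
    }
  }
  lab
}

#' River-network density in a moving window
#'
#' Approximates stream length per pixel from the stream raster's 8-neighbour
#' connectivity (half of each connecting step: cell size cardinal,
#' sqrt(2) x cell size diagonal; an isolated stream pixel counts one cell
#' length), then divides the window's summed length by the window area.
#'
#' @param streams boolean `nr_grid`.
#' @param window `window_spec` (square).
#' @return `nr_grid` of densities in km per km2.
#' @export
line_density <- function(streams, window = window_spec()) {
  s <- !is.na(streams$values) & streams$values != 0
  cs <- streams$cell_size
  off <- d8_offsets(cs)
  len <- matrix(0, nrow(s), ncol(s))
  conn <- matrix(0, nrow(s), ncol(s))
  for (k in seq_len(8)) {
    nb <- shift_mat(s * 1, off$dr[k], off$dc[k])
    hit <- s & !is.na(nb) & nb == 1
    len[hit] <- len[hit] + off$step[k] / 2
    conn <- conn + hit
  }
  len[s & conn == 0] <- cs          # isolated stream pixel
  half <- window_half(window, cs)
  ii <- integral_image(len)
  rr <- row(len); cc <- col(len)
  r1 <- rr - half; r2 <- rr + half; c1 <- cc - half; c2 <- cc + half
  win_len <- ii(r1, r2, c1, c2)
  n_px <- (pmin(r2, nrow(len)) - pmax(r1, 1) + 1) *
    (pmin(c2, ncol(len)) - pmax(c1, 1) + 1)
  area_km2 <- n_px * cs^2 / 1e6
  dens <- (win_len / 1000) / area_km2
  dens[is.na(streams$values)] <- NA
  nr_grid(dens, cs, streams$origin)
}
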