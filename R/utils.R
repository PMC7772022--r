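#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-seed
#'
#' Counter-based seed derivation: every stochastic stage derives its
#' seed from one base seed and a few stage/subject/run indices, so any
#' part of the pipeline can be re-run in isolation with the same random
#' stream. Results stay below 2^31 - 1.
#'
#' @param base base seed (integer)
#' @param ... integer indices identifying the stage, subject, run, ...
#' @return an integer seed
#' @export
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 69069 + as.double(idx[k]) * 104729 + 12345) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Truncated normal by rejection; truncation in units of SD around the mean,
## with an optional absolute floor. SD = 0 collapses to the mean.
rtruncnorm1 <- function(n, mean, sd, trunc_sd = 4, floor = -Inf) {
  stopifnot(sd >= 0)
  if (sd == 0) return(rep(mean, n))
  lo <- max(mean - trunc_sd * sd, floor)
  hi <- mean + trunc_sd * sd
  if (lo >= hi) stop("empty truncation interval")
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

## ---- raster helpers -------------------------------------------------------
## Rasters are matrices indexed [row, col]; row-major with the top-left
## pixel centre at (0, 0), x increasing with column (medial -> lateral),
## y increasing with row downwards in storage but interpreted with
## y = distal -> proximal handled by the callers through `raster_xy`.

## Physical coordinates of pixel centres. y grows upward (proximal) with
## decreasing row index so that geometry code can use ordinary Cartesian
## conventions.
raster_xy <- function(nr, nc, dx, dy) {
  list(
    x = (seq_len(nc) - 1) * dx,
    y = (nr - seq_len(nr)) * dy
  )
}

## Nearest-pixel lookup of matrix `m` at physical points (x, y); 0 outside.
sample_nearest <- function(m, x, y, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  cc <- round(x / dx) + 1L
  rr <- nr - round(y / dy)
  ok <- cc >= 1L & cc <= nc & rr >= 1L & rr <= nr
  out <- numeric(length(x))
  out[ok] <- m[cbind(rr[ok], cc[ok])]
  out
}

## Bilinear lookup (for BMD resampling under rotation).
sample_bilinear <- function(m, x, y, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  cf <- x / dx + 1
  rf <- nr - y / dy
  c0 <- floor(cf); r0 <- floor(rf)
  tc <- cf - c0; tr <- rf - r0
  get0 <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r)); v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  v00 <- get0(r0, c0); v01 <- get0(r0, c0 + 1)
  v10 <- get0(r0 + 1, c0); v11 <- get0(r0 + 1, c0 + 1)
  (1 - tr) * ((1 - tc) * v00 + tc * v01) + tr * ((1 - tc) * v10 + tc * v11)
}

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- (1 + max(dr, 0)):(nr + min(dr, 0))
  cs <- (1 + max(dc, 0)):(nc + min(dc, 0))
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## One-pixel binary erosion along a single axis (both directions).
erode1 <- function(m, axis) {
  if (axis == "x") m & shift_mat(m, 0, 1) & shift_mat(m, 0, -1)
  else m & shift_mat(m, 1, 0) & shift_mat(m, -1, 0)
}

## Anisotropic erosion to physical depth `d` (mm): interleaves x/y
## single-pixel erosions so the eroded band approximates the rectangle
## metric at spacings (dx, dy).
erode_depth <- function(mask, d, dx, dy) {
  m <- mask
  px <- d / dx; py <- d / dy
  nx <- floor(px); ny <- floor(py)
  i <- j <- 0
  while (i < nx || j < ny) {
    if (i < nx && (i / px <= j / py || j >= ny)) { m <- erode1(m, "x"); i <- i + 1 }
    else { m <- erode1(m, "y"); j <- j + 1 }
  }
  m
}

## 4-connected component labelling (vectorised frontier BFS per seed).
connected_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  remaining <- which(mask)
  while (length(remaining)) {
    cur <- cur + 1L
    frontier <- remaining[1]
    lab[frontier] <- cur
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
              frontier[c > 1L] - nr, frontier[c < nc] + nr)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  list(labels = lab, n = cur)
}

## Rotate a scan's content by `angle` degrees (counter-clockwise in the
## Cartesian frame) about a physical centre point, resampling BMD
## bilinearly and the mask by nearest neighbour.
rotate_raster <- function(bmd, mask, angle_deg, dx, dy, centre) {
  nr <- nrow(mask); nc <- ncol(mask)
  xy <- raster_xy(nr, nc, dx, dy)
  X <- matrix(xy$x, nr, nc, byrow = TRUE)
  Y <- matrix(xy$y, nr, nc)
  a <- angle_deg * pi / 180
  ## target pixel (X, Y) pulls from source rotated by -angle about centre
  xs <- cos(a) * (X - centre[1]) + sin(a) * (Y - centre[2]) + centre[1]
  ys <- -sin(a) * (X - centre[1]) + cos(a) * (Y - centre[2]) + centre[2]
  m2 <- matrix(sample_nearest(mask * 1, as.vector(xs), as.vector(ys), dx, dy) > 0.5, nr, nc)
  b2 <- matrix(sample_bilinear(bmd, as.vector(xs), as.vector(ys), dx, dy), nr, nc)
  b2[!m2] <- 0
  list(bmd = b2, mask = m2)
}

## Exact Euclidean distance-to-background transform (mm), correct up to
## `max_d`. Separable: exact column-direction distances first, then a
## vectorised sweep over horizontal offsets within the radius.
dist_transform <- function(mask, dx, dy, max_d = 30) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- max_d + dy
  ## column-direction distance to nearest background (mm)
  up <- matrix(big, nr, nc)
  prev <- rep(big, nc)
  for (r in seq_len(nr)) {
    prev <- ifelse(mask[r, ], pmin(prev + dy, big), 0)
    up[r, ] <- prev
  }
  dn <- matrix(big, nr, nc)
  prev <- rep(big, nc)
  for (r in rev(seq_len(nr))) {
    prev <- ifelse(mask[r, ], pmin(prev + dy, big), 0)
    dn[r, ] <- pmin(dn[r, ], prev)
  }
  d0 <- pmin(up, dn)
  ## combine with horizontal offsets
  kmax <- ceiling(max_d / dx)
  best <- d0^2
  for (k in seq_len(kmax)) {
    off <- (k * dx)^2
    if (off >= max_d^2) break
    best <- pmin(best, shift_mat(d0, 0, k, fill = 0)^2 + off,
                 shift_mat(d0, 0, -k, fill = 0)^2 + off)
  }
  out <- sqrt(best)
  out[!mask] <- 0
  pmin(out, max_d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
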