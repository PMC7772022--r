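#' Scan raster container
#'
#' A 2D areal-BMD pixel map with a binary femur mask and physical pixel
#' spacing. Row-major storage with the top-left pixel centre at (0, 0);
#' x (mm) grows with column index, y (mm) grows upward (toward the top
#' row), so geometry code uses ordinary Cartesian conventions with y
#' pointing proximally for a correctly oriented scan.
#'
#' @param bmd numeric matrix, g/cm^2 per pixel, non-negative, zero
#'   outside the mask
#' @param mask logical matrix, the femur segmentation (single
#'   4-connected component)
#' @param dx,dy pixel spacing, mm (DXA defaults 0.6 x 1.05)
#' @param check validate invariants (connectivity check is O(pixels))
#' @return object of class `scan_raster`
#' @export
scan_raster <- function(bmd, mask, dx = 0.6, dy = 1.05, check = TRUE) {
  mask <- mask > 0
  stopifnot(is.matrix(bmd), all(dim(bmd) == dim(mask)), dx > 0, dy > 0)
  if (check) {
    if (any(bmd < 0)) stop("negative BMD")
    if (any(bmd[!mask] != 0)) stop("non-zero BMD outside the mask")
    if (!any(mask)) stop("empty mask")
    if (connected_components(mask)$n != 1)
      stop("mask is not a single 4-connected component")
  }
  structure(list(bmd = bmd, mask = mask, dx = dx, dy = dy),
            class = "scan_raster")
}

#' @export
print.scan_raster <- function(x, ...) {
  cat(sprintf("scan_raster %dx%d px (%.2f x %.2f mm), femur area %.0f mm^2\n",
              nrow(x$mask), ncol(x$mask), x$dx, x$dy,
              sum(x$mask) * x$dx * x$dy))
  invisible(x)
}

mirror_scan <- function(scan) {
  nc <- ncol(scan$mask)
  scan_raster(scan$bmd[, nc:1], scan$mask[, nc:1], scan$dx, scan$dy,
              check = FALSE)
}

## pixel centre coordinates of all mask pixels
mask_points <- function(scan) {
  nr <- nrow(scan$mask); nc <- ncol(scan$mask)
  idx <- which(scan$mask)
  r <- ((idx - 1) %% nr) + 1
  c <- ((idx - 1) %/% nr) + 1
  list(x = (c - 1) * scan$dx, y = (nr - r) * scan$dy, idx = idx)
}

## Detect the distal constant-width shaft run and fit its centreline.
## Returns the fitted line (point p0 + direction u, unit, pointing
## proximally), the measured tilt from vertical (degrees, positive
## toward +x) and the perpendicular shaft breadth.
shaft_centreline <- function(scan) {
  pts <- mask_points(scan)
  if (length(pts$idx) < 200) stop("mask too small for shaft detection")
  ## initial axis: distal extreme point toward the mask centroid, refined
  ## below from the constant-width run centreline
  pd <- c(pts$x[which.min(pts$y)], min(pts$y))
  u <- c(mean(pts$x) - pd[1], mean(pts$y) - pd[2])
  u <- u / sqrt(sum(u^2))
  run <- NULL
  for (iter in 1:3) {
    proj <- pts$x * u[1] + pts$y * u[2]
    perp <- pts$x * u[2] - pts$y * u[1]
    s0 <- min(proj)
    stations <- seq(s0 + 2, s0 + 0.55 * (max(proj) - s0), by = 1)
    ## per-1mm-bin extrema; a station slab |proj - s| < 1 is two bins
    bin <- floor(proj - s0)
    bmax <- tapply(perp, bin, max); bmin <- tapply(perp, bin, min)
    bcnt <- tapply(perp, bin, length)
    bkey <- as.integer(names(bmax))
    nlut <- max(bkey) + 2L
    lut_max <- lut_min <- rep(NA_real_, nlut)
    lut_cnt <- rep(0L, nlut)
    okb <- bkey >= 0L
    lut_max[bkey[okb] + 1L] <- bmax[okb]
    lut_min[bkey[okb] + 1L] <- bmin[okb]
    lut_cnt[bkey[okb] + 1L] <- bcnt[okb]
    breadth <- mids <- rep(NA_real_, length(stations))
    for (i in seq_along(stations)) {
      b1 <- round(stations[i] - s0 - 1) + 1L
      ids <- c(b1, b1 + 1L)
      ids <- ids[ids >= 1L & ids <= nlut]
      ids <- ids[lut_cnt[ids] > 0]
      if (!length(ids) || sum(lut_cnt[ids]) < 3) next
      mx <- max(lut_max[ids], na.rm = TRUE); mn <- min(lut_min[ids], na.rm = TRUE)
      breadth[i] <- mx - mn + scan$dx
      mids[i] <- (mx + mn) / 2
    }
    ok <- which(is.finite(breadth))
    if (length(ok) < 5) stop("no identifiable shaft: too few cross-sections")
    ## plateau search: over candidate reference breadths, find the
    ## longest contiguous run of near-constant cross-sections (robust to
    ## arbitrarily long distal corner ramps and to the proximal flare)
    ## among all near-constant runs of >= 4 stations, the shaft is the
    ## most distal one (the trochanteric collar can also be constant)
    ## the shaft breadth cannot greatly exceed the distal-most sections
    ## (which ramp up to it); this excludes the trochanteric collar
    cap_ref <- 1.4 * max(breadth[ok[seq_len(min(10, length(ok)))]]) + 2
    pick_run <- function(min_len) {
      run <- integer(0)
      for (ref in unique(round(breadth[ok], 1))) {
        if (ref > cap_ref) next
        tol <- max(2, 0.08 * ref)
        match <- is.finite(breadth) & abs(breadth - ref) <= tol
        rl <- rle(match)
        ends <- cumsum(rl$lengths)
        good <- which(rl$values & rl$lengths >= min_len)
        if (!length(good)) next
        gi <- good[1]
        cand <- (ends[gi] - rl$lengths[gi] + 1):ends[gi]
        if (!length(run) || cand[1] < run[1] ||
            (cand[1] == run[1] && length(cand) > length(run))) run <- cand
      }
      run
    }
    run <- pick_run(5)
    if (length(run) < 5) run <- pick_run(4)   # short-shaft fallback
    if (length(run) < 4)
      stop("no identifiable shaft: constant-width run too short")
    ## refine direction from the centreline of the run
    fit <- stats::lm.fit(cbind(1, stations[run]), mids[run])
    dpds <- fit$coefficients[2]           # d(perp)/d(s)
    u_new <- u + dpds * c(u[2], -u[1])
    u <- u_new / sqrt(sum(u_new^2))
    if (u[2] < 0) u <- -u
  }
  proj <- pts$x * u[1] + pts$y * u[2]
  perp <- pts$x * u[2] - pts$y * u[1]
  s_mid <- mean(stations[run])
  p_off <- fit$coefficients[1] + fit$coefficients[2] * s_mid
  p0 <- s_mid * u + p_off * c(u[2], -u[1])
  tilt <- atan2(u[1], u[2]) * 180 / pi
  top_station <- stations[max(run)]
  run_top_y <- (top_station * u + (fit$coefficients[1] +
    fit$coefficients[2] * top_station) * c(u[2], -u[1]))[2]
  list(p0 = p0, u = u, tilt = tilt,
       breadth = stats::median(breadth[run], na.rm = TRUE),
       run_top_y = run_top_y)
}

#' Standardise the pose of a femur scan
#'
#' Rotates the scan so the shaft axis sits `target_tilt` degrees from the
#' image vertical (physiological configuration), resampling the BMD map
#' bilinearly and the mask by nearest neighbour. With
#' `canonical_orientation = TRUE` the scan is also mirrored, when
#' necessary, so the femoral head lies on the low-x (left) side.
#'
#' @param scan a [scan_raster()]
#' @param target_tilt degrees from vertical (default 10)
#' @param canonical_orientation mirror so the head is medial-left
#' @return a pose-standardised `scan_raster`
#' @export
standardise_pose <- function(scan, target_tilt = 10,
                             canonical_orientation = FALSE) {
  out <- scan
  for (pass in 1:3) {
    sc <- shaft_centreline(out)
    ang <- sc$tilt - target_tilt
    if (abs(ang) <= if (pass == 1) 1e-6 else 2) break
    pts <- mask_points(out)
    centre <- c(mean(pts$x), mean(pts$y))
    rot <- rotate_raster(out$bmd, out$mask, ang, out$dx, out$dy, centre)
    cc <- connected_components(rot$mask)
    if (cc$n > 1) {  # keep the largest component (resampling specks)
      sizes <- tabulate(cc$labels[cc$labels > 0], cc$n)
      rot$mask <- cc$labels == which.max(sizes)
      rot$bmd[!rot$mask] <- 0
    }
    out <- scan_raster(rot$bmd, rot$mask, out$dx, out$dy, check = FALSE)
  }
  if (canonical_orientation && head_side(out) > 0) out <- mirror_scan(out)
  out
}

## Side of the femoral head: +1 for the +x side, -1 for the -x side.
## The head's extreme excursion from the shaft axis is a point of
## tangency on a sphere (narrow axial spread), whereas the greater
## trochanter presents a flat lateral face (wide axial spread); when the
## spreads are comparable the larger excursion decides.
head_side <- function(scan) {
  sc <- shaft_centreline(scan)
  pts <- mask_points(scan)
  prox <- pts$y > stats::median(pts$y)
  dxs <- (pts$x[prox] - sc$p0[1]) * sc$u[2] - (pts$y[prox] - sc$p0[2]) * sc$u[1]
  along <- (pts$x[prox] - sc$p0[1]) * sc$u[1] + (pts$y[prox] - sc$p0[2]) * sc$u[2]
  spread <- function(sel) {
    if (sum(sel) < 3) return(Inf)
    diff(range(along[sel]))
  }
  sp_neg <- spread(dxs <= min(dxs) + 2)
  sp_pos <- spread(dxs >= max(dxs) - 2)
  if (abs(sp_neg - sp_pos) > 6) {
    if (sp_neg < sp_pos) -1 else 1
  } else if (abs(min(dxs)) >= abs(max(dxs))) -1 else 1
}

## breadth of the contiguous mask run through point p along direction n
## (unit), sampled at `step` mm; returns c(breadth, mid_s) where mid_s is
## the signed offset of the run midpoint from p.
line_breadth <- function(scan, p, n, half = 30, step = 0.4) {
  s <- seq(-half, half, by = step)
  inside <- sample_nearest(scan$mask * 1, p[1] + s * n[1], p[2] + s * n[2],
                           scan$dx, scan$dy) > 0.5
  i0 <- which.min(abs(s))
  if (!inside[i0]) return(c(0, NA))
  lo <- i0; while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(s) && inside[hi + 1]) hi <- hi + 1
  c((hi - lo + 1) * step, (s[lo] + s[hi]) / 2)
}

#' Measure femoral morphometry from a segmentation mask
#'
#' Mask-only measurement of the seven geometric attributes. The shaft
#' axis is the fitted centreline of the distal constant-width shaft run;
#' the head centre is a least-squares circle fit to the medial articular
#' boundary arc; the neck axis joins the head centre to the midpoint of
#' the narrowest neck cross-section found by an angular sweep; NSA is the
#' angle between the neck axis and the distal shaft direction; NW is the
#' narrowest neck breadth; HAL is the mask chord along the neck axis
#' (lateral trochanteric cortex to medial head surface); ITW is the
#' breadth perpendicular to the shaft axis at the level where the hip
#' axis exits the lateral cortex; STW is the median perpendicular breadth
#' of the distal shaft run; SAL is the mask extent along the shaft axis;
#' FA is the mask area.
#'
#' @param scan a pose-standardised [scan_raster()]
#' @return object of class `morphometric_set`: the seven measurements
#'   plus a `landmarks` list (shaft line, head circle, neck axis,
#'   junction, levels) and a `mirrored` flag
#' @export
measure_morphometry <- function(scan) {
  mirrored <- head_side(scan) > 0
  sc0 <- if (mirrored) mirror_scan(scan) else scan
  sc <- shaft_centreline(sc0)
  pts <- mask_points(sc0)

  FA <- length(pts$idx) * sc0$dx * sc0$dy
  proj <- (pts$x - sc$p0[1]) * sc$u[1] + (pts$y - sc$p0[2]) * sc$u[2]
  ## shaft extent on the lateral half-mask: the medial femoral head
  ## (which may overshoot the trochanter tip) does not contribute
  perp_lat <- (pts$x - sc$p0[1]) * sc$u[2] - (pts$y - sc$p0[2]) * sc$u[1]
  lat <- perp_lat >= 0
  SAL <- max(proj[lat]) - min(proj[lat]) + (sc0$dy + sc0$dx) / 2
  STW <- sc$breadth

  ## --- head circle fit on the medial boundary arc ---
  m <- sc0$mask; nr <- nrow(m); nc <- ncol(m)
  interior <- erode1(erode1(m, "x"), "y")
  bidx <- which(m & !interior)
  br <- ((bidx - 1) %% nr) + 1; bc <- ((bidx - 1) %/% nr) + 1
  bx <- (bc - 1) * sc0$dx; by <- (nr - br) * sc0$dy
  ## medial articular arc: near the medial extreme both in x and in y
  ## (the calcar continues the medial profile further down and must not
  ## contaminate the fit)
  y0 <- by[which.min(bx)]
  band <- bx <= min(bx) + 11 & abs(by - y0) <= 16
  if (sum(band) < 12) stop("degenerate mask: no medial head arc")
  fit_circle <- function(xx, yy) {
    sol <- stats::lm.fit(cbind(xx, yy, 1), -(xx^2 + yy^2))$coefficients
    C <- c(-sol[1] / 2, -sol[2] / 2)
    list(C = C, r = sqrt(sum(C^2) - sol[3]))
  }
  cf <- fit_circle(bx[band], by[band])
  ## iterated inlier refit over the whole exposed articular arc
  for (tol_in in c(1.5, 1.0)) {
    resid <- abs(sqrt((bx - cf$C[1])^2 + (by - cf$C[2])^2) - cf$r)
    inl <- resid < tol_in
    if (sum(inl) >= 12) cf <- fit_circle(bx[inl], by[inl])
  }
  C <- cf$C; r_h <- cf$r
  if (!is.finite(r_h) || r_h < 5 || r_h > 60)
    stop("degenerate mask: head circle fit failed")

  ## --- neck search ---
  ## The neck is the widest clearance corridor joining the head to the
  ## shaft: over candidate rays from the head centre spanning the
  ## physiological neck-shaft angle range, maximise the minimum
  ## distance-to-background along the ray (rays that leave the bone
  ## before approaching the shaft are not neck paths). Twice the maximin
  ## clearance is the neck width; the bottleneck locates the narrowest
  ## cross-section.
  dt <- dist_transform(sc0$mask, sc0$dx, sc0$dy, max_d = 40)
  dt_at <- function(x, y) sample_bilinear(dt, x, y, sc0$dx, sc0$dy)
  tJ <- (C[1] - sc$p0[1]) * sc$u[1] + (C[2] - sc$p0[2]) * sc$u[2]
  foot <- sc$p0 + tJ * sc$u                 # shaft point nearest the head
  n_lat <- c(sc$u[2], -sc$u[1])             # unit, lateral (+x side)
  reach <- sqrt(sum((foot - C)^2))
  best <- list(score = -Inf)
  for (nsa_c in seq(92, 158, by = 2) * pi / 180) {
    d <- sin(nsa_c) * n_lat + cos(nsa_c) * sc$u   # from head toward junction
    ## march until just short of the shaft axis line
    t_cross <- reach / sum(d * n_lat) * sign(sum((foot - C) * n_lat))
    if (!is.finite(t_cross) || t_cross < 0.6 * r_h + 3) next
    ts <- seq(0.6 * r_h, t_cross - 1, by = 0.75)
    px <- C[1] + ts * d[1]; py <- C[2] + ts * d[2]
    inside <- sample_nearest(sc0$mask * 1, px, py, sc0$dx, sc0$dy) > 0.5
    stop_at <- which(!inside)[1]
    if (!is.na(stop_at)) {
      if (ts[stop_at] < 0.85 * (t_cross - 1)) next  # leaves the bone early
      keep <- seq_len(stop_at - 1)
      ts <- ts[keep]; px <- px[keep]; py <- py[keep]
    }
    clr <- dt_at(px, py)
    sel <- ts >= 0.7 * r_h                  # ignore the deep-head segment
    if (!any(sel)) next
    score <- min(clr[sel])
    if (score > best$score)
      best <- list(score = score, d = d, ts = ts, clr = clr)
  }
  if (!is.finite(best$score) || best$score <= 0)
    stop("degenerate mask: no neck narrowing detectable")
  NW <- 2 * best$score
  sel <- which(best$clr <= best$score + 0.3 & best$ts >= 0.7 * r_h)
  t_star <- mean(best$ts[sel])              # centre of the bottleneck plateau

  ## refine the neck axis: cross-section midpoints of a near-cylindrical
  ## neck lie on its axis, which passes through the head centre; the
  ## median of their direction angles from C is robust to stations whose
  ## run leaks into the trochanteric contact zone
  ## refine the neck axis on the clearance ridge: across each neck
  ## cross-section the distance-to-background is maximal on the capsule
  ## axis, so the per-cut argmax points anchor the axis robustly even
  ## where the contiguous run leaks into the trochanteric contact zone.
  ## Cuts whose peak clearance clearly exceeds the waist clearance lie
  ## in the head or junction blend and are skipped.
  d_n <- best$d
  for (pass in 1:3) {
    n0 <- c(-d_n[2], d_n[1])
    angs <- c()
    t_hi <- min(t_star + 8, max(best$ts))
    t_lo <- min(1.02 * r_h, t_star - 2)
    if (t_hi < t_lo + 1) break
    ss <- seq(-0.6 * NW, 0.6 * NW, by = 0.4)
    for (t in seq(t_lo, t_hi, by = 0.5)) {
      p <- C + t * d_n
      clr_cut <- dt_at(p[1] + ss * n0[1], p[2] + ss * n0[2])
      pk <- max(clr_cut)
      if (pk < 0.33 * NW || pk > 0.65 * NW) next
      s_pk <- mean(ss[clr_cut >= pk - 0.25])
      mpt <- p + s_pk * n0
      angs <- c(angs, atan2(mpt[2] - C[2], mpt[1] - C[1]))
    }
    if (!length(angs)) break
    ang <- stats::median(angs)
    d_n <- c(cos(ang), sin(ang))            # from C toward the junction
  }
  ts2 <- seq(0.9 * r_h, max(0.9 * r_h + 2, min(t_star + 10, max(best$ts))),
             by = 0.5)
  clr2 <- dt_at(C[1] + ts2 * d_n[1], C[2] + ts2 * d_n[2])
  if (any(clr2 > 0)) {
    m2 <- min(clr2[clr2 > 0])
    if (2 * m2 < NW) NW <- 2 * m2
    t_star <- mean(ts2[clr2 > 0 & clr2 <= m2 + 0.3])
  }
  Mn <- C + t_star * d_n
  ## final anchor: snap the narrowest-section point onto the clearance
  ## ridge and take the axis through the head centre and that point
  n0 <- c(-d_n[2], d_n[1])
  ss <- seq(-0.4 * NW, 0.4 * NW, by = 0.3)
  clr_cut <- dt_at(Mn[1] + ss * n0[1], Mn[2] + ss * n0[2])
  if (max(clr_cut) > 0) {
    s_pk <- mean(ss[clr_cut >= max(clr_cut) - 0.2])
    Mn <- Mn + s_pk * n0
    d_n <- (Mn - C) / sqrt(sum((Mn - C)^2))
  }
  u_n <- -d_n                               # points medially toward the head

  ## NSA: angle between the neck axis and the distal shaft direction
  NSA <- acos(pmin(1, pmax(-1, sum(u_n * (-sc$u))))) * 180 / pi

  ## HAL: contiguous chord through the head centre along the neck axis
  s <- seq(-(r_h + 5), 130, by = 0.25)      # from beyond the head, laterally
  line <- cbind(C[1] - s * u_n[1], C[2] - s * u_n[2])
  inside <- sample_nearest(sc0$mask * 1, line[, 1], line[, 2],
                           sc0$dx, sc0$dy) > 0.5
  i0 <- which.min(abs(s))
  if (!inside[i0]) stop("degenerate mask: head centre outside mask")
  lo <- i0; while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(s) && inside[hi + 1]) hi <- hi + 1
  HAL <- (s[hi] - s[lo]) + 0.25
  exit_pt <- c(C[1] - s[hi] * u_n[1], C[2] - s[hi] * u_n[2])

  ## ITW: breadth perpendicular to the shaft axis at the
  ## intertrochanteric level (the band just distal of the hip-axis exit,
  ## where the full width is held); the median over three probe offsets
  ## absorbs small errors in the estimated exit level
  n_s <- c(sc$u[2], -sc$u[1])               # lateral perpendicular
  itw_probes <- vapply(c(-3, -1.5, 0), function(dz) {
    probe <- exit_pt - 1.2 * n_s + dz * sc$u
    line_breadth(sc0, probe, n_s, half = 80)[1]
  }, numeric(1))
  ITW <- stats::median(itw_probes)
  if (ITW == 0) ITW <- max(itw_probes)
  if (ITW == 0) stop("degenerate mask: no intertrochanteric section")

  ## junction of neck and shaft axes
  den <- u_n[1] * sc$u[2] - u_n[2] * sc$u[1]
  tt <- ((sc$p0[1] - C[1]) * sc$u[2] - (sc$p0[2] - C[2]) * sc$u[1]) / den
  J <- C + tt * u_n

  structure(list(
    NW = NW, HAL = HAL, NSA = NSA, SAL = SAL, ITW = ITW, STW = STW, FA = FA,
    landmarks = list(
      shaft_p0 = sc$p0, shaft_u = sc$u, tilt = sc$tilt,
      run_top_y = sc$run_top_y,
      head_centre = C, head_r = r_h,
      neck_mid = Mn, neck_u = u_n, junction = J,
      exit_pt = exit_pt),
    mirrored = mirrored
  ), class = "morphometric_set")
}

#' @export
print.morphometric_set <- function(x, ...) {
  cat(sprintf(paste0("morphometrics: NW %.1f  HAL %.1f  NSA %.1f deg  ",
                     "SAL %.1f  ITW %.1f  STW %.1f mm  FA %.0f mm^2%s\n"),
              x$NW, x$HAL, x$NSA, x$SAL, x$ITW, x$STW, x$FA,
              if (x$mirrored) "  (mirrored)" else ""))
  invisible(x)
}

## evaluate the two ROI predicates at points (x, y) given landmarks
roi_predicates <- function(morph, neck_band = 15) {
  lm <- morph$landmarks
  list(
    neck = function(x, y) {
      dxp <- x - lm$neck_mid[1]; dyp <- y - lm$neck_mid[2]
      along <- dxp * lm$neck_u[1] + dyp * lm$neck_u[2]
      perp <- -dxp * lm$neck_u[2] + dyp * lm$neck_u[1]
      abs(along) <= neck_band / 2 & abs(perp) <= 0.9 * morph$NW
    },
    troch = function(x, y) {
      dxp <- x - lm$shaft_p0[1]; dyp <- y - lm$shaft_p0[2]
      along <- dxp * lm$shaft_u[1] + dyp * lm$shaft_u[2]
      lat <- dxp * lm$shaft_u[2] - dyp * lm$shaft_u[1]
      sJ <- (lm$junction[1] - lm$shaft_p0[1]) * lm$shaft_u[1] +
        (lm$junction[2] - lm$shaft_p0[2]) * lm$shaft_u[2]
      s0 <- (lm$run_top_y - lm$shaft_p0[2]) / lm$shaft_u[2]
      along >= s0 & along <= sJ & lat > 0
    }
  )
}

#' Partition the femur into neck and trochanteric regions of interest
#'
#' The neck region is a band of configurable width centred on the
#' narrowest neck cross-section, perpendicular to the neck axis. The
#' trochanteric region lies between the subtrochanteric level (top of
#' the distal shaft run) and the intertrochanteric level (neck/shaft
#' junction), lateral of the shaft axis. The regions are disjoint (the
#' neck band wins any overlap) and non-empty; both constructions are
#' fully deterministic.
#'
#' @param scan the pose-standardised [scan_raster()] the morphometry was
#'   measured on
#' @param morph a [measure_morphometry()] result
#' @param neck_band band width along the neck axis, mm
#' @return object of class `roi_partition`: `neck_region` and
#'   `trochanteric_region` (pixel indices into the scan), plus the
#'   predicates used (for element-level reuse)
#' @export
partition_rois <- function(scan, morph, neck_band = 15) {
  stopifnot(inherits(morph, "morphometric_set"))
  sc0 <- if (morph$mirrored) mirror_scan(scan) else scan
  pred <- roi_predicates(morph, neck_band)
  pts <- mask_points(sc0)
  neck <- pred$neck(pts$x, pts$y)
  troch <- pred$troch(pts$x, pts$y) & !neck
  if (!any(neck) || !any(troch)) stop("empty region of interest")
  idx_neck <- pts$idx[neck]; idx_troch <- pts$idx[troch]
  if (morph$mirrored) {             # map pixel indices back to input frame
    nr <- nrow(scan$mask); nc <- ncol(scan$mask)
    remap <- function(i) {
      r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
      (nc - c) * nr + r
    }
    idx_neck <- remap(idx_neck); idx_troch <- remap(idx_troch)
  }
  structure(list(neck_region = sort(idx_neck),
                 trochanteric_region = sort(idx_troch),
                 predicates = pred, neck_band = neck_band,
                 mirrored = morph$mirrored),
            class = "roi_partition")
}

#' Place the PMMA pads
#'
#' A rectangular pad of length `b = b_frac * ITW` is placed flush
#' against the flat lateral cortex of the greater trochanter, centred on
#' the hip-axis exit level (clipped to the flat face); a conforming
#' annular cap covers the medial femoral-head contour. The
#' pressure-conversion thickness is `t = t_frac * NW` (subject-specific,
#' calibrated so cohort-mean hip pressures match the reference fall
#' chain).
#'
#' @param scan pose-standardised [scan_raster()]
#' @param morph a [measure_morphometry()] result
#' @param b_frac pad length as a fraction of ITW
#' @param t_frac conversion thickness as a fraction of NW
#' @param depth pad depth normal to the bone surface, mm
#' @param cap_halfangle head-cap angular half-width, degrees
#' @return object of class `pad_geometry` with `b`, `t`, polygon corner
#'   lists and analytic inside-tests (canonical, head-left frame)
#' @export
place_pads <- function(scan, morph, b_frac = 0.8, t_frac = 0.40,
                       depth = 10, cap_halfangle = 60) {
  lm <- morph$landmarks
  b <- b_frac * morph$ITW
  t <- t_frac * morph$NW
  u <- lm$shaft_u; n_lat <- c(u[2], -u[1])
  ## trochanteric face: through the exit point, parallel to the shaft axis
  sE <- (lm$exit_pt[1] - lm$shaft_p0[1]) * u[1] +
    (lm$exit_pt[2] - lm$shaft_p0[2]) * u[2]
  s0 <- sE - b / 2
  A <- lm$exit_pt + (s0 - sE) * u
  B <- A + b * u
  troch_polygon <- rbind(A, B, B + depth * n_lat, A + depth * n_lat)
  lat0 <- (lm$exit_pt[1] - lm$shaft_p0[1]) * u[2] -
    (lm$exit_pt[2] - lm$shaft_p0[2]) * u[1]
  theta0 <- atan2(lm$neck_u[2], lm$neck_u[1])
  ha <- cap_halfangle * pi / 180
  ang <- seq(theta0 - ha, theta0 + ha, length.out = 24)
  head_polygon <- rbind(
    cbind(lm$head_centre[1] + lm$head_r * cos(ang),
          lm$head_centre[2] + lm$head_r * sin(ang)),
    cbind(lm$head_centre[1] + (lm$head_r + depth) * cos(rev(ang)),
          lm$head_centre[2] + (lm$head_r + depth) * sin(rev(ang))))
  if (b <= 0 || t <= 0) stop("invalid pad dimensions")
  structure(list(
    b = b, t = t, depth = depth,
    troch_polygon = troch_polygon, head_polygon = head_polygon,
    shaft_u = u, n_lat = n_lat, face_lat = lat0, face_s = c(s0, s0 + b),
    shaft_p0 = lm$shaft_p0,
    head_centre = lm$head_centre, head_r = lm$head_r,
    cap_theta0 = theta0, cap_halfangle = ha,
    mirrored = morph$mirrored
  ), class = "pad_geometry")
}

## analytic pad membership at canonical-frame points
pad_inside <- function(pads, which, x, y, slack = 1.6) {
  if (which == "troch") {
    dxp <- x - pads$shaft_p0[1]; dyp <- y - pads$shaft_p0[2]
    s <- dxp * pads$shaft_u[1] + dyp * pads$shaft_u[2]
    lat <- dxp * pads$shaft_u[2] - dyp * pads$shaft_u[1]
    s >= pads$face_s[1] & s <= pads$face_s[2] &
      lat >= pads$face_lat - slack & lat <= pads$face_lat + pads$depth
  } else {
    dxp <- x - pads$head_centre[1]; dyp <- y - pads$head_centre[2]
    r <- sqrt(dxp^2 + dyp^2)
    th <- atan2(dyp, dxp)
    dth <- atan2(sin(th - pads$cap_theta0), cos(th - pads$cap_theta0))
    r >= pads$head_r - slack & r <= pads$head_r + pads$depth &
      abs(dth) <= pads$cap_halfangle
  }
}
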