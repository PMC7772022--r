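#' Cohort specification for the synthetic generator
#'
#' Defaults reproduce the two-group structure of the reference clinical
#' cohort the pipeline emulates: 89 fractured and 48 control
#' postmenopausal women, with group means and SDs for the clinical
#' attributes (age years, height cm, weight kg, total BMD g/cm^2) and the
#' seven femoral morphometrics (NW, HAL, NSA, SAL, ITW, STW mm; NSA
#' degrees; FA mm^2). BMI is always derived from height and weight, never
#' sampled. The cortical rim depth (mm at the reference BMD of
#' 0.75 g/cm^2, scaled linearly by the subject's total BMD) and the
#' rim/interior areal-density ratio control the emergent bone-tissue
#' composition.
#'
#' @param n_fractured,n_control group sizes
#' @param clinical named list per group: each a list of `c(mean, sd)` for
#'   `age`, `height`, `weight`, `bmd`
#' @param shape named list per group: each a list of `c(mean, sd)` for
#'   `NW`, `HAL`, `NSA`, `SAL`, `ITW`, `STW`, `FA`
#' @param bmd_separation optional between-group BMD gap in units of the
#'   pooled SD; when given, the group BMD means are shifted symmetrically
#'   about their midpoint to realise that gap (SDs unchanged)
#' @param canvas raster size `c(rows, cols)`
#' @param pixel pixel spacing `c(dx, dy)` in mm
#' @param noise multiplicative pixel noise SD on the BMD map
#' @param rim_depth cortical rim depth in mm at reference BMD
#' @param rim_ratio rim/interior areal-density ratio
#' @param seed base seed; every subject derives its own sub-seeds
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_fractured = 89, n_control = 48,
                        clinical = NULL, shape = NULL,
                        bmd_separation = NULL,
                        canvas = c(192, 256), pixel = c(0.6, 1.05),
                        noise = 0.05, rim_depth = 2.2, rim_ratio = 2.1,
                        seed = 1) {
  stopifnot(n_fractured >= 2, n_control >= 2)
  if (is.null(clinical)) clinical <- list(
    fractured = list(age = c(81.39, 6.98), height = c(152.67, 7.09),
                     weight = c(63.61, 14.03), bmd = c(0.70, 0.13)),
    control = list(age = c(82.56, 3.88), height = c(151.75, 5.09),
                   weight = c(65.21, 10.01), bmd = c(0.80, 0.10))
  )
  if (is.null(shape)) shape <- list(
    fractured = list(NW = c(29.29, 2.02), HAL = c(89.74, 6.31),
                     NSA = c(126.48, 6.11), SAL = c(83.16, 5.34),
                     ITW = c(50.29, 3.12), STW = c(27.65, 2.17),
                     FA = c(4580.09, 490.35)),
    control = list(NW = c(29.68, 2.32), HAL = c(88.98, 5.48),
                   NSA = c(124.21, 6.24), SAL = c(85.79, 5.19),
                   ITW = c(50.15, 3.32), STW = c(26.44, 1.52),
                   FA = c(4574.10, 372.61))
  )
  for (g in c("fractured", "control")) {
    if (any(vapply(clinical[[g]], function(v) v[2] < 0, logical(1))) ||
        any(vapply(shape[[g]], function(v) v[2] < 0, logical(1))))
      stop("negative SD in cohort spec")
  }
  if (!is.null(bmd_separation)) {
    mf <- clinical$fractured$bmd; mc <- clinical$control$bmd
    nf <- n_fractured; nc <- n_control
    pooled <- sqrt(((nf - 1) * mf[2]^2 + (nc - 1) * mc[2]^2) / (nf + nc - 2))
    mid <- (mf[1] + mc[1]) / 2
    gap <- bmd_separation * pooled
    clinical$fractured$bmd[1] <- mid - gap / 2
    clinical$control$bmd[1] <- mid + gap / 2
  }
  structure(list(n_fractured = n_fractured, n_control = n_control,
                 clinical = clinical, shape = shape,
                 canvas = canvas, pixel = pixel, noise = noise,
                 rim_depth = rim_depth, rim_ratio = rim_ratio, seed = seed),
            class = "cohort_spec")
}

#' Sample clinical records
#'
#' Age, height, weight and total BMD are drawn from truncated Gaussians
#' (+/- 4 SD, floored at physical minima) at the group parameters of the
#' spec; BMI is derived as `weight / (height/100)^2` so the exact
#' BMI-weight-height identity holds for every record.
#'
#' @param spec a [cohort_spec()]
#' @param group `"fractured"` or `"control"`
#' @param n number of records
#' @param seed sampling seed
#' @return data frame of `subject_record` rows: subject_id, group, age,
#'   height, weight, bmi, bmd_total, gender
#' @export
sample_clinical <- function(spec, group, n, seed = spec$seed) {
  if (!group %in% c("fractured", "control")) stop("unknown group label: ", group)
  stopifnot(n >= 1)
  p <- spec$clinical[[group]]
  with_seed(seed, {
    age <- rtruncnorm1(n, p$age[1], p$age[2], floor = 50)
    height <- rtruncnorm1(n, p$height[1], p$height[2], floor = 120)
    weight <- rtruncnorm1(n, p$weight[1], p$weight[2], floor = 30)
    bmd <- rtruncnorm1(n, p$bmd[1], p$bmd[2], floor = 0.2)
    data.frame(
      subject_id = sprintf("%s%04d", substr(group, 1, 4), seq_len(n)),
      group = group,
      age = age, height = height, weight = weight,
      bmi = weight / (height / 100)^2,
      bmd_total = bmd, gender = "female",
      stringsAsFactors = FALSE
    )
  })
}

#' Sample femoral shape parameters
#'
#' Draws the seven morphometric targets from truncated Gaussians at the
#' group parameters and redraws (up to `max_tries`) on the rare draws
#' that violate basic mutual consistency (ordered widths, NSA in the
#' physiological range, shaft length within the hip-axis allowance).
#' Because these constraints exclude a negligible fraction of the
#' truncated Gaussians, the sampled distributions keep the target means
#' essentially exactly; geometric realisability is handled downstream
#' by the renderer.
#'
#' @param spec a [cohort_spec()]
#' @param group group label
#' @param seed sampling seed
#' @param max_tries bounded number of redraws before rejection
#' @return object of class `femur_shape` (NW, HAL, NSA, SAL, ITW, STW,
#'   FA in their natural units, plus rim settings copied from the spec)
#' @export
sample_shape <- function(spec, group, seed = spec$seed, max_tries = 50) {
  if (!group %in% c("fractured", "control")) stop("unknown group label: ", group)
  p <- spec$shape[[group]]
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      v <- lapply(p, function(ms) rtruncnorm1(1, ms[1], ms[2], floor = 1))
      sh <- structure(c(v, list(rim_depth = spec$rim_depth,
                                rim_ratio = spec$rim_ratio)),
                      class = "femur_shape")
      if (shape_valid(sh)) return(sh)
    }
  })
  stop("no consistent shape draw for group '", group, "' after ",
       max_tries, " tries")
}

shape_valid <- function(sh) {
  ok <- with(sh, {
    if (any(c(NW, HAL, NSA, SAL, ITW, STW, FA) <= 0)) return(FALSE)
    if (NSA <= 95 || NSA >= 155) return(FALSE)
    if (STW >= ITW || NW >= ITW) return(FALSE)
    if (SAL < NW + 25) return(FALSE)
    if (SAL > HAL + 25) return(FALSE)   # shaft length vs hip axis allowance
    TRUE
  })
  ok
}

## TRUE when the shape admits a femur template whose area window covers
## the FA target to within 3% (checked on a coarse 2 mm grid); the
## renderer refuses shapes that fail this.
shape_renderable <- function(sh) {
  if (is.null(solve_template(sh, 0.5, 0))) return(FALSE)
  area_at <- function(q) {
    tpl <- solve_template(sh, q, 0)
    gx <- seq(tpl$C[1] - tpl$r_h - 2, tpl$x_lat_t + 2, by = 2)
    gy <- seq(-1, max(tpl$SAL, tpl$C[2] + tpl$r_h) + 2, by = 2)
    pts <- expand.grid(x = gx, y = gy)
    sum(template_inside(tpl, pts$x, pts$y)) * 4
  }
  0.97 * area_at(0) < sh$FA && sh$FA < 1.03 * area_at(1)
}

## Pixels that no area adjustment may touch: every region a morphometric
## measurement depends on (neck clearance corridor, intertrochanteric
## level, medial head arc, distal shaft run, lateral cortex face,
## trochanter tip). Coordinates are shaft-frame.
template_protected <- function(tpl, xs, ys) {
  ## neck corridor: within 0.75 NW of the hip/neck axis between the
  ## head interior and just beyond the junction
  ax <- tpl$C - tpl$J
  L2 <- sum(ax^2)
  tt <- ((xs - tpl$J[1]) * ax[1] + (ys - tpl$J[2]) * ax[2]) / L2
  tt <- pmin(1 + (3 + 0.5 * tpl$r_h) / sqrt(L2), pmax(-(3 / sqrt(L2)), tt))
  px <- tpl$J[1] + tt * ax[1]; py <- tpl$J[2] + tt * ax[2]
  corridor <- (xs - px)^2 + (ys - py)^2 <= (0.75 * tpl$NW)^2
  itw_line <- ys >= tpl$y_exit - 5.5 & ys <= tpl$y_exit + 1.5
  dC2 <- (xs - tpl$C[1])^2 + (ys - tpl$C[2])^2
  head_arc <- dC2 >= (tpl$r_h - 2.5)^2 & dC2 <= (tpl$r_h + 3)^2
  shaft_run <- ys <= tpl$y_tb + 2
  lat_face <- xs >= tpl$x_lat_t - 1.5
  tip <- ys >= tpl$SAL - 1.5
  corridor | itw_line | head_arc | shaft_run | lat_face | tip
}

## Add or remove unprotected boundary pixels until the mask area matches
## the target pixel count (deterministic index order within the final
## partial round). Returns the mask unchanged when the adjustment would
## disconnect it.
adjust_area <- function(mask, target_px, allowed, max_rounds = 30) {
  m <- mask
  for (round in seq_len(max_rounds)) {
    deficit <- target_px - sum(m)
    if (abs(deficit) < 2) break
    if (deficit > 0) {
      cand <- which((shift_mat(m, 1, 0) | shift_mat(m, -1, 0) |
                       shift_mat(m, 0, 1) | shift_mat(m, 0, -1)) &
                      !m & allowed)
      if (!length(cand)) break
      m[cand[seq_len(min(deficit, length(cand)))]] <- TRUE
    } else {
      interior <- erode1(erode1(m, "x"), "y")
      cand <- which(m & !interior & allowed)
      if (!length(cand)) break
      m[cand[seq_len(min(-deficit, length(cand)))]] <- FALSE
    }
  }
  ## heal one-pixel slits and pinholes the partial rounds may leave
  for (k in 1:2) {
    fill <- !m & ((shift_mat(m, 0, 1) & shift_mat(m, 0, -1)) |
                    (shift_mat(m, 1, 0) & shift_mat(m, -1, 0)))
    m <- m | fill
  }
  if (connected_components(m)$n != 1) return(mask)
  m
}

## Solve the parametric femur template in the shaft frame (shaft axis =
## +y from the distal end at y = 0; medial = -x). The silhouette is:
## a constant-width distal shaft, a short flare taper up to the
## intertrochanteric level (where the medial calcar and lateral cortex
## reach their extreme offsets, breadth = ITW), a greater-trochanter
## column whose medial boundary retreats laterally up to the tip, a neck
## capsule of width NW joining the shaft axis to the head centre, and a
## circular head closing the hip axis. Returns landmark geometry, or
## NULL when the parameter set is not realisable.
solve_template <- function(sh, q = 0.5, relax = 0) {
  NW <- sh$NW; HAL <- sh$HAL; NSA <- sh$NSA * pi / 180
  SAL <- sh$SAL; ITW <- sh$ITW; STW <- sh$STW
  lev <- relax + 1L
  m_run <- c(12, 10, 9)[lev]            # minimum distal shaft run, mm
  m_exit <- c(12, 10.5, 9)[lev]         # minimum exit height term
  r_floor <- c(0.40, 0.34, 0.28)[lev] * NW
  overshoot <- c(1.04, 1.07, 1.12)[lev] # allowed head-top / SAL ratio
  neck_div <- c(2.35, 2.2, 2.0)[lev]    # K / neck_div caps the head
  sn <- sin(NSA); cn <- cos(NSA)
  cot <- -cn / sn                       # positive for NSA > 90 degrees
  x_med_t <- -STW / 2 - 0.25 * (ITW - STW)
  x_lat_t <- x_med_t + ITW
  if (cot * x_lat_t < 3) return(NULL)   # chord must exit below the junction
  K <- HAL - x_lat_t / sn               # L_n + r_h
  ## head radius: anatomical proportion of the neck width, shrunk when
  ## necessary so (a) the neck keeps free length, (b) the junction sits
  ## high enough for a measurable distal shaft and (c) the head stays
  ## close to the trochanter-tip level
  y_J_min <- max(0.35 * SAL, m_run + 0.65 * NW, m_exit + cot * x_lat_t)
  if (0.66 * SAL < y_J_min) return(NULL)
  r_cap_yJ <- (overshoot * SAL - K * (-cn) - 1 - y_J_min) / (1 + cn)
  r_h <- min(0.72 * NW, K / neck_div, r_cap_yJ)
  if (!is.finite(r_h) || r_h < r_floor) return(NULL)
  C_x <- x_lat_t - (HAL - r_h) * sn
  if (C_x > -4) return(NULL)            # head must sit medial of the shaft
  L_n <- -C_x / sn
  y_J <- min(0.66 * SAL, overshoot * SAL - r_h - L_n * (-cn) - 1)
  C_y <- y_J + L_n * (-cn)
  y_exit <- C_y + (HAL - r_h) * cn
  y_tb <- min(y_exit - 7, y_J - 0.65 * NW)
  if (y_tb < m_run) return(NULL)
  list(r_h = r_h, x_med_t = x_med_t, x_lat_t = x_lat_t,
       C = c(C_x, C_y), J = c(0, y_J), L_n = L_n,
       u_n = c(-sn, -cn), y_exit = y_exit, y_tb = y_tb,
       gt_width = 0.25 + 0.70 * q, collar_h = 7,
       NW = NW, SAL = SAL, STW = STW, ITW = ITW)
}

## Inside-test of the femur silhouette at shaft-frame points (vectorised).
template_inside <- function(tpl, x, y) {
  corner <- 5  # greater-trochanter tip rounding radius, mm
  ## distal constant-width shaft
  shaft <- x >= -tpl$STW / 2 & x <= tpl$STW / 2 & y >= 0 & y <= tpl$y_tb
  ## flare taper: shaft widths grow linearly to the intertrochanteric
  ## extremes, which are then held over the 4 mm band ending at the
  ## hip-axis exit level (where ITW is defined and measured)
  f <- pmin(1, (y - tpl$y_tb) / (tpl$y_exit - 4 - tpl$y_tb))
  xm <- -tpl$STW / 2 + f * (tpl$x_med_t + tpl$STW / 2)
  xl <- tpl$STW / 2 + f * (tpl$x_lat_t - tpl$STW / 2)
  taper <- y >= tpl$y_tb & y <= tpl$y_exit & x >= xm & x <= xl
  ## greater-trochanter column: lateral face fixed, medial boundary
  ## retreats laterally toward the tip (concave profile so the
  ## intertrochanteric fossa opens just above the exit level) and never
  ## encroaches on the superior neck notch
  x_tip_med <- tpl$x_lat_t - tpl$gt_width * tpl$ITW
  ## full intertrochanteric width is held over a collar above the exit
  ## level so the breadth there is well defined, then retreats
  ch <- tpl$collar_h
  g <- pmax(0, (y - tpl$y_exit - ch) / pmax(1, tpl$SAL - tpl$y_exit - ch))
  xg <- tpl$x_med_t + g^0.35 * (x_tip_med - tpl$x_med_t)
  ## superior capsule edge: line parallel to the neck axis at offset NW/2
  n_sup <- c(tpl$u_n[2], -tpl$u_n[1])        # up-lateral perpendicular
  if (n_sup[2] < 0) n_sup <- -n_sup
  S0 <- tpl$J + (tpl$NW / 2) * n_sup
  t_ax <- (y - S0[2]) / tpl$u_n[2]
  x_sup <- S0[1] + t_ax * tpl$u_n[1]
  ## the guard starts 2.5 mm inside the capsule's junction disc so no
  ## rasterisation gap can open on the hip-axis chord
  active <- t_ax > -tpl$NW / 2 + 2.5 & t_ax < tpl$L_n + tpl$r_h + 8
  xg <- ifelse(active, pmax(xg, x_sup + 3), xg)
  gt <- y >= tpl$y_exit & y <= tpl$SAL & x >= xg & x <= tpl$x_lat_t
  ## rounded tip corners
  in_cm <- gt & x < x_tip_med + corner & y > tpl$SAL - corner &
    ((x - (x_tip_med + corner))^2 + (y - (tpl$SAL - corner))^2 > corner^2)
  in_cl <- gt & x > tpl$x_lat_t - corner & y > tpl$SAL - corner &
    ((x - (tpl$x_lat_t - corner))^2 + (y - (tpl$SAL - corner))^2 > corner^2)
  gt <- gt & !in_cm & !in_cl
  ## neck capsule from J to C
  dx <- tpl$C[1] - tpl$J[1]; dy <- tpl$C[2] - tpl$J[2]
  L2 <- dx^2 + dy^2
  t <- pmin(1, pmax(0, ((x - tpl$J[1]) * dx + (y - tpl$J[2]) * dy) / L2))
  px <- tpl$J[1] + t * dx; py <- tpl$J[2] + t * dy
  neck <- (x - px)^2 + (y - py)^2 <= (tpl$NW / 2)^2
  ## femoral head disc
  head <- (x - tpl$C[1])^2 + (y - tpl$C[2])^2 <= tpl$r_h^2
  shaft | taper | gt | neck | head
}

#' Render a synthetic DXA-like scan from shape parameters
#'
#' Rasterises the parametric proximal-femur silhouette (distal shaft of
#' width STW, trochanteric body of width ITW, neck capsule of width NW at
#' angle NSA, hemispherical head closing the hip axis of length HAL) at
#' the configured pixel spacing, with the shaft axis tilted `tilt`
#' degrees from the image vertical. The head radius is solved so the
#' rasterised area matches the FA target. The BMD map carries a
#' high-density cortical rim over a lower-density trabecular interior
#' plus multiplicative pixel noise, and is rescaled so the mask-mean
#' areal BMD equals `record$bmd_total` exactly.
#'
#' @param shape a `femur_shape` (see [sample_shape()])
#' @param record one-row clinical record (see [sample_clinical()])
#' @param seed noise seed
#' @param spec a [cohort_spec()] supplying canvas, spacing and noise
#' @param tilt shaft tilt from image vertical, degrees
#' @return a [scan_raster()] object
#' @export
render_scan <- function(shape, record, seed = 1, spec = cohort_spec(),
                        tilt = 10) {
  stopifnot(inherits(shape, "femur_shape"), nrow(as.data.frame(record)) == 1)
  nr <- spec$canvas[1]; nc <- spec$canvas[2]
  dx <- spec$pixel[1]; dy <- spec$pixel[2]
  xy <- raster_xy(nr, nc, dx, dy)
  X <- matrix(xy$x, nr, nc, byrow = TRUE)
  Y <- matrix(xy$y, nr, nc)

  rasterise <- function(shape, q, relax) {
    tpl <- solve_template(shape, q, relax)
    if (is.null(tpl)) return(NULL)
    ## shaft-frame bounding box -> image placement with margin
    a <- tilt * pi / 180
    ## shaft frame -> image: proximal shaft leans `tilt` degrees laterally
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    ytop <- max(tpl$SAL, tpl$C[2] + tpl$r_h)
    corners <- rbind(
      c(tpl$C[1] - tpl$r_h, 0), c(tpl$x_lat_t, 0),
      c(tpl$C[1] - tpl$r_h, ytop), c(tpl$x_lat_t, ytop))
    ic <- corners %*% t(R)
    margin <- 14
    off <- c(margin - min(ic[, 1]), margin - min(ic[, 2]))
    if (max(ic[, 1]) + off[1] > (nc - 1) * dx - margin ||
        max(ic[, 2]) + off[2] > (nr - 1) * dy - margin) return(NULL)
    ## image -> shaft frame (inverse rotation)
    xs <- cos(a) * (X - off[1]) - sin(a) * (Y - off[2])
    ys <- sin(a) * (X - off[1]) + cos(a) * (Y - off[2])
    m <- matrix(template_inside(tpl, as.vector(xs), as.vector(ys)), nr, nc)
    list(mask = m, tpl = tpl, off = off, xs = xs, ys = ys)
  }

  ## The renderer only accepts shapes that admit a valid femur template
  ## whose attainable area window covers the FA target; callers (see
  ## [generate_cohort()]) redraw on rejection.
  if (!shape_renderable(shape))
    stop("shape cannot be realised as a femur template")
  target_px <- shape$FA / (dx * dy)
  sh_try <- shape
  relax_used <- 0L
  ## bisection on a coarse 1.5 mm evaluation grid (cheap); the final
  ## exact match to FA is made pixel-wise by adjust_area below
  coarse_area <- function(q) {
    tpl <- solve_template(sh_try, q, relax_used)
    if (is.null(tpl)) return(NA_real_)
    gx <- seq(tpl$C[1] - tpl$r_h - 2, tpl$x_lat_t + 2, by = 1.5)
    gy <- seq(-1, max(tpl$SAL, tpl$C[2] + tpl$r_h) + 2, by = 1.5)
    pts <- expand.grid(x = gx, y = gy)
    sum(template_inside(tpl, pts$x, pts$y)) * 2.25
  }
  f <- function(q) coarse_area(q) - shape$FA
  lo <- 0; hi <- 1
  flo <- f(lo); fhi <- f(hi)
  q_best <- 0.5
  if (!is.na(flo) && !is.na(fhi) && flo * fhi < 0) {
    for (i in 1:9) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (is.na(fm)) { hi <- mid; next }
      if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
    }
    q_best <- (lo + hi) / 2
  } else {
    cand <- c(0, 1, 0.5)
    vals <- abs(c(flo, fhi, f(0.5)))
    q_best <- cand[which.min(ifelse(is.na(vals), Inf, vals))]
  }
  ras <- rasterise(sh_try, q_best, relax_used)
  if (is.null(ras)) stop("shape cannot be rasterised inside the canvas")
  mask <- ras$mask
  ## close any residual gap to the FA target by growing or trimming the
  ## mask outside the measurement-protected zones
  if (abs(sum(mask) - target_px) >= 2) {
    tplr <- ras$tpl
    protected <- template_protected(tplr, as.vector(ras$xs), as.vector(ras$ys))
    ## adjustments stay within the trochanteric / calcar neighbourhood
    region <- as.vector(ras$xs) >= min(tplr$x_med_t - 5, tplr$C[1] + 2) &
      as.vector(ras$xs) <= tplr$x_lat_t &
      as.vector(ras$ys) >= tplr$y_tb - 4 &
      as.vector(ras$ys) <= tplr$SAL - 1.5
    allowed <- matrix(!protected & region, nr, nc)
    mask <- adjust_area(mask, round(target_px), allowed)
  }

  ## BMD texture: cortical rim + trabecular interior + pixel noise,
  ## rescaled so the mask mean equals the subject's total BMD exactly.
  rim <- spec$rim_depth * record$bmd_total / 0.75
  interior <- erode_depth(mask, rim, dx, dy)
  rel <- matrix(0, nr, nc)
  rel[mask] <- spec$rim_ratio
  rel[interior] <- 1
  if (spec$noise > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(nr * nc, 1, spec$noise), nr, nc))
    rel <- rel * pmax(noise, 0.05)
  }
  s <- record$bmd_total / mean(rel[mask])
  bmd <- rel * s
  bmd[!mask] <- 0
  out <- scan_raster(bmd, mask, dx, dy)
  attr(out, "truth") <- list(tpl = ras$tpl, off = ras$off, tilt = tilt)
  out
}

#' Generate a full synthetic cohort
#'
#' Produces `n_fractured + n_control` subjects, each a clinical record
#' plus a rendered scan, fully reproducible from the spec's seed.
#'
#' @param spec a [cohort_spec()]
#' @return object of class `cohort`: list with `clinical` (data frame)
#'   and `scans` (named list of [scan_raster()]s keyed by subject_id)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  groups <- list(fractured = spec$n_fractured, control = spec$n_control)
  clin <- list(); scans <- list()
  for (g in names(groups)) {
    recs <- sample_clinical(spec, g, groups[[g]],
                            seed = derive_seed(spec$seed, 11, match(g, names(groups))))
    for (i in seq_len(nrow(recs))) {
      rec <- recs[i, ]
      ## joint-consistency loop: redraw shapes until one renders AND
      ## survives pose standardisation and morphometry, so every
      ## delivered subject is fully processable downstream
      scan <- NULL
      for (try in 1:60) {
        sh <- sample_shape(spec, g,
                           seed = derive_seed(spec$seed, 22,
                                              match(g, names(groups)), i, try))
        if (!shape_renderable(sh)) next
        cand <- render_scan(
          sh, rec,
          seed = derive_seed(spec$seed, 33, match(g, names(groups)), i),
          spec = spec)
        ## quality gate: the rendered subject must measure without error
        ## AND within loose physiological bounds, so no degenerate
        ## landmark detection can poison downstream attributes
        ok <- tryCatch({
          mo <- measure_morphometry(standardise_pose(cand,
                                                     canonical_orientation = TRUE))
          mo$NW > 15 && mo$NW < 45 && mo$ITW > 30 && mo$ITW < 70 &&
            mo$STW > 15 && mo$STW < 42 && mo$NSA > 95 && mo$NSA < 160 &&
            mo$HAL > 60 && mo$HAL < 120 && mo$SAL > 55 && mo$SAL < 115
        }, error = function(e) FALSE)
        if (isTRUE(ok)) { scan <- cand; break }
      }
      if (is.null(scan))
        stop("no renderable shape for subject ", rec$subject_id)
      scans[[rec$subject_id]] <- scan
    }
    clin[[g]] <- recs
  }
  structure(list(clinical = do.call(rbind, c(clin, list(make.row.names = FALSE))),
                 scans = scans, spec = spec),
            class = "cohort")
}
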