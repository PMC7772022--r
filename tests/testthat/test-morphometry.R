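## rectangular scan helper (axis-aligned bar of width w, height h, mm)
rect_scan <- function(w = 30, h = 120, dx = 0.6, dy = 1.05) {
  nr <- ceiling(h / dy) + 30; nc <- ceiling(w / dx) + 60
  mask <- matrix(FALSE, nr, nc)
  xy <- sidefall:::raster_xy(nr, nc, dx, dy)
  X <- matrix(xy$x, nr, nc, byrow = TRUE)
  Y <- matrix(xy$y, nr, nc)
  mask[X >= 10 & X <= 10 + w & Y >= 5 & Y <= 5 + h] <- TRUE
  bmd <- matrix(0, nr, nc); bmd[mask] <- 1
  scan_raster(bmd, mask, dx, dy)
}

test_that("an axis-aligned bar measures its exact width and area", {
  sc <- rect_scan(w = 30, h = 120)
  cl <- sidefall:::shaft_centreline(sc)
  expect_equal(cl$breadth, 30, tolerance = 0.05)
  expect_equal(abs(cl$tilt), 0, tolerance = 0.5)
  pts <- sidefall:::mask_points(sc)
  expect_equal(length(pts$idx) * sc$dx * sc$dy, 30 * 120,
               tolerance = 0.03 * 3600)
})

test_that("pose standardisation recovers a known rendering tilt", {
  s <- fx_subject(9, "control")
  tilted <- render_scan(s$shape, s$record, seed = 9, spec = s$spec,
                        tilt = 25)
  cl0 <- sidefall:::shaft_centreline(tilted)
  expect_equal(cl0$tilt, 25, tolerance = 2)
  posed <- standardise_pose(tilted)
  cl1 <- sidefall:::shaft_centreline(posed)
  expect_equal(cl1$tilt, 10, tolerance = 0.5)
  ## idempotence: standardising again changes nothing measurable
  posed2 <- standardise_pose(posed)
  cl2 <- sidefall:::shaft_centreline(posed2)
  expect_equal(cl2$tilt, 10, tolerance = 0.5)
})

test_that("length measures scale with pixel spacing, area quadratically", {
  ## dimensional analysis within the adult-femur operating envelope the
  ## landmark detectors are tuned for
  k <- 1.25
  fx <- fx_measured()
  sc <- fx$posed
  big <- scan_raster(sc$bmd, sc$mask, k * sc$dx, k * sc$dy, check = FALSE)
  m1 <- fx$morph
  m2 <- measure_morphometry(big)
  for (att in c("NW", "HAL", "SAL", "ITW", "STW"))
    expect_equal(m2[[att]], k * m1[[att]], tolerance = 0.06,
                 label = att)
  expect_equal(m2$FA, k^2 * m1$FA, tolerance = 1e-9)
  expect_equal(m2$NSA, m1$NSA, tolerance = 2)
})

test_that("rendered shapes round-trip through morphometry", {
  ## >= 90% of renderable seeds recover every generating parameter
  ## within 5% (2 degrees for the neck-shaft angle)
  spec <- cohort_spec()
  n <- 0; okcount <- 0; seed <- 0
  while (n < 22 && seed < 120) {
    seed <- seed + 1
    g <- if (seed %% 2) "fractured" else "control"
    sh <- sample_shape(spec, g, seed = seed)
    if (!sidefall:::shape_renderable(sh)) next
    rec <- sample_clinical(spec, g, 1, seed = seed)
    scan <- render_scan(sh, rec, seed = seed, spec = spec)
    mo <- try(measure_morphometry(
      standardise_pose(scan, canonical_orientation = TRUE)), silent = TRUE)
    n <- n + 1
    if (inherits(mo, "try-error")) next
    rel <- function(a, b) abs(a - b) / b
    ok <- rel(mo$NW, sh$NW) < 0.05 && rel(mo$HAL, sh$HAL) < 0.05 &&
      rel(mo$SAL, sh$SAL) < 0.05 && rel(mo$ITW, sh$ITW) < 0.05 &&
      rel(mo$STW, sh$STW) < 0.05 && rel(mo$FA, sh$FA) < 0.05 &&
      abs(mo$NSA - sh$NSA) < 2
    okcount <- okcount + ok
  }
  expect_gte(n, 20)
  expect_gte(okcount / n, 0.9)
})

test_that("regions of interest are disjoint, non-empty and band-monotone", {
  fx <- fx_measured()
  rois <- partition_rois(fx$posed, fx$morph)
  expect_gt(length(rois$neck_region), 0)
  expect_gt(length(rois$trochanteric_region), 0)
  expect_length(intersect(rois$neck_region, rois$trochanteric_region), 0)
  pts <- sidefall:::mask_points(fx$posed)
  expect_true(all(rois$neck_region %in% pts$idx))
  expect_true(all(rois$trochanteric_region %in% pts$idx))
  ## shrinking the neck band shrinks the neck region (set inclusion)
  narrow <- partition_rois(fx$posed, fx$morph, neck_band = 8)
  expect_true(all(narrow$neck_region %in% rois$neck_region))
  expect_lt(length(narrow$neck_region), length(rois$neck_region))
})

test_that("left-right reflection reflects the regions of interest", {
  fx <- fx_measured()
  sc <- fx$posed
  mir <- sidefall:::mirror_scan(sc)
  rois1 <- partition_rois(sc, fx$morph)
  morph_m <- measure_morphometry(mir)
  rois2 <- partition_rois(mir, morph_m)
  nr <- nrow(sc$mask); nc <- ncol(sc$mask)
  remap <- function(i) {
    r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
    (nc - c) * nr + r
  }
  ## mirrored neck region overlaps the reflected original almost wholly
  ## (sub-pixel re-measurement moves only boundary pixels)
  ov <- length(intersect(sort(remap(rois2$neck_region)),
                         rois1$neck_region)) /
    max(length(rois1$neck_region), length(rois2$neck_region))
  expect_gt(ov, 0.85)
})

test_that("pads sit on their contours with the configured dimensions", {
  fx <- fx_measured()
  pads <- place_pads(fx$posed, fx$morph)
  expect_equal(pads$b, 0.8 * fx$morph$ITW, tolerance = 1e-9)
  expect_equal(pads$t, 0.40 * fx$morph$NW, tolerance = 1e-9)
  ## the two pads never intersect: no sample point is inside both
  xs <- runif(4000, 0, (ncol(fx$posed$mask) - 1) * fx$posed$dx)
  ys <- runif(4000, 0, (nrow(fx$posed$mask) - 1) * fx$posed$dy)
  both <- sidefall:::pad_inside(pads, "troch", xs, ys) &
    sidefall:::pad_inside(pads, "head", xs, ys)
  expect_false(any(both))
  ## reference arithmetic for the pressure denominator
  expect_equal(40 * 11.3, 452)
})
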