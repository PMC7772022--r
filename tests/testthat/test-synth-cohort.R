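test_that("clinical sampling is reproducible and keeps the BMI identity", {
  spec <- cohort_spec()
  r1 <- sample_clinical(spec, "fractured", 25, seed = 7)
  r2 <- sample_clinical(spec, "fractured", 25, seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$bmi, r1$weight / (r1$height / 100)^2, tolerance = 1e-12)
  expect_true(all(r1$height > 0 & r1$weight > 0 & r1$bmd_total > 0))
  expect_true(all(r1$gender == "female"))
  expect_error(sample_clinical(spec, "male", 5), "unknown group")
})

test_that("degenerate zero-SD sampling collapses to the group means", {
  spec <- cohort_spec(clinical = list(
    fractured = list(age = c(80, 0), height = c(150, 0),
                     weight = c(60, 0), bmd = c(0.7, 0)),
    control = list(age = c(82, 0), height = c(151, 0),
                   weight = c(65, 0), bmd = c(0.8, 0))
  ))
  r <- sample_clinical(spec, "fractured", 6, seed = 1)
  expect_true(all(r$age == 80 & r$height == 150 & r$weight == 60))
  expect_equal(unique(r$bmi), 60 / 1.5^2, tolerance = 1e-12)
})

test_that("sampled attribute means calibrate to the group targets", {
  ## at n = 5000 per group, every sampled mean must sit within 3
  ## standard errors of its target
  spec <- cohort_spec()
  n <- 5000
  for (g in c("fractured", "control")) {
    cl <- sample_clinical(spec, g, n, seed = derive_seed(99, match(g, c("fractured", "control"))))
    for (att in c("age", "height", "weight")) {
      tgt <- spec$clinical[[g]][[att]]
      expect_lt(abs(mean(cl[[att]]) - tgt[1]), 3 * tgt[2] / sqrt(n),
                label = paste(g, att))
    }
    tgt <- spec$clinical[[g]]$bmd
    expect_lt(abs(mean(cl$bmd_total) - tgt[1]), 3 * tgt[2] / sqrt(n))
    draws <- vapply(seq_len(n), function(i)
      unlist(sample_shape(spec, g, seed = derive_seed(77, match(g, c("fractured", "control")), i))[1:7]),
      numeric(7))
    for (att in names(spec$shape[[g]])) {
      tgt <- spec$shape[[g]][[att]]
      expect_lt(abs(mean(draws[att, ]) - tgt[1]), 3 * tgt[2] / sqrt(n),
                label = paste(g, att))
    }
  }
})

test_that("rendered scans satisfy the raster invariants exactly", {
  for (seed in c(3, 8, 21)) {
    s <- fx_subject(seed)
    scan <- s$scan
    expect_true(all(scan$bmd >= 0))
    expect_true(all(scan$bmd[!scan$mask] == 0))
    expect_equal(sidefall:::connected_components(scan$mask)$n, 1)
    ## mask-mean BMD equals the subject's total BMD by construction
    expect_equal(mean(scan$bmd[scan$mask]), s$record$bmd_total,
                 tolerance = 1e-6)
  }
})

test_that("noise-free flat-density rendering gives a uniform interior", {
  spec <- cohort_spec(noise = 0, rim_ratio = 1, rim_depth = 2.2)
  rec <- sample_clinical(spec, "control", 1, seed = 5)
  sh <- NULL
  for (s in 5:40) {
    cand <- sample_shape(spec, "control", seed = s)
    if (sidefall:::shape_renderable(cand)) { sh <- cand; break }
  }
  sh$rim_ratio <- 1
  scan <- render_scan(sh, rec, seed = 5, spec = spec)
  vals <- unique(round(scan$bmd[scan$mask], 12))
  expect_length(vals, 1)
  expect_equal(vals, rec$bmd_total, tolerance = 1e-9)
})

test_that("cohort generation is deterministic and respects group sizes", {
  spec <- cohort_spec(n_fractured = 3, n_control = 2, seed = 11)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(lapply(c1$scans, `[[`, "bmd"),
                   lapply(c2$scans, `[[`, "bmd"))
  expect_equal(nrow(c1$clinical), 5)
  expect_equal(sum(c1$clinical$group == "fractured"), 3)
  expect_length(c1$scans, 5)
  ## minimal cohort
  tiny <- generate_cohort(cohort_spec(n_fractured = 2, n_control = 2,
                                      seed = 4))
  expect_equal(nrow(tiny$clinical), 4)
})

test_that("widening the BMD separation moves the group means apart", {
  base <- cohort_spec()
  wide <- cohort_spec(bmd_separation = 2)
  gap0 <- base$clinical$control$bmd[1] - base$clinical$fractured$bmd[1]
  gap2 <- wide$clinical$control$bmd[1] - wide$clinical$fractured$bmd[1]
  expect_gt(gap2, gap0)
  nf <- 89; nc <- 48
  pooled <- sqrt(((nf - 1) * 0.13^2 + (nc - 1) * 0.10^2) / (nf + nc - 2))
  expect_equal(gap2, 2 * pooled, tolerance = 1e-12)
  ## SDs unchanged
  expect_equal(wide$clinical$fractured$bmd[2], 0.13)
})
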