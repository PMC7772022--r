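test_that("tissue partition respects the strict cortical threshold", {
  mk <- function(rho) {
    n <- length(rho)
    structure(list(rho = rho, E = 6850 * pmax(rho, 0.01)^1.49,
                   nu = rep(0.3, n), law = material_law(),
                   area = rep(1, n),
                   tag = factor(rep("femur", n),
                                levels = c("femur", "trochanteric_pad",
                                           "head_pad"))),
              class = "material_field")
  }
  t1 <- tissue_attributes(mk(rep(1.2, 5)))
  expect_equal(t1$CT, 100)
  expect_equal(t1$TB, 0)
  ## the boundary value is trabecular ("greater than" is strict)
  t2 <- tissue_attributes(mk(rep(1.0, 5)))
  expect_equal(t2$TB, 100)
  t3 <- tissue_attributes(mk(c(0.5, 1.5)))
  expect_equal(t3$TB, 50)
  expect_equal(t3$CT, 50)
  expect_identical(t3$TB + t3$CT, 100)
  expect_lt(t3$TBE, t3$CTE)
})

test_that("regional averages are area-weighted means", {
  m <- rect_mesh(2, 1, 2, 1)
  sol <- fx_fake_solution(m)
  sol$elem$area <- c(1, 3, 1, 1)
  sol$elem$VM <- c(4, 8, 0, 0)
  expect_equal(regional_average(sol, 1:2, "VM"), 7)
  sol$elem$VM <- rep(2.5, 4)
  expect_equal(regional_average(sol, 1:4, "VM"), 2.5)
  ## brute-force oracle on a random instance
  set.seed(2)
  a <- runif(50, 0.5, 2); v <- rnorm(50)
  m2 <- rect_mesh(5, 5, 5, 5)
  sol2 <- fx_fake_solution(m2)
  sol2$elem$area <- a
  sol2$elem$VM <- v
  acc <- 0; wsum <- 0
  for (i in 1:50) { acc <- acc + a[i] * v[i]; wsum <- wsum + a[i] }
  expect_equal(regional_average(sol2, 1:50, "VM"), acc / wsum,
               tolerance = 1e-12)
  expect_error(regional_average(sol2, integer(0), "VM"), "empty")
})

test_that("fracture risk index is the capacity-normalised von Mises mean", {
  m <- rect_mesh(3, 3, 3, 3)
  y <- yield_model(7300)
  mats <- uniform_materials(m, E = 3000)
  sy <- 3000 * 7300e-6
  sol <- fx_fake_solution(m, VM = rep(sy, nrow(m$tri)))
  expect_equal(fracture_risk_index(sol, 1:6, y, mats), 1, tolerance = 1e-12)
  sol2 <- fx_fake_solution(m, VM = 2 * rep(sy, nrow(m$tri)))
  expect_equal(fracture_risk_index(sol2, 1:6, y, mats), 2, tolerance = 1e-12)
})

test_that("LSR equals the uniform ratio and the constructed-cluster value", {
  m <- rect_mesh(6, 3, 6, 3)          # 36 triangles of 0.5 mm^2
  y <- yield_model(7300)
  ## uniform demand: any region returns the same ratio
  sol_u <- fx_fake_solution(m, E3 = rep(-0.4 * 7300, nrow(m$tri)))
  expect_equal(load_to_strength_ratio(sol_u, y, 4)$lsr, 0.4,
               tolerance = 1e-12)
  ## a contiguous high-ratio cluster in a low background: the answer is
  ## the smallest ratio the region must absorb to reach the target area
  ## (triangles 1, 19, 20 share edges in this mesh's cell ordering)
  ratios <- rep(0.1, nrow(m$tri))
  ratios[c(19, 1, 20)] <- c(2.0, 1.8, 1.5)  # adjacent cluster, 1.5 mm^2
  sol_c <- fx_fake_solution(m, E3 = -ratios * 7300)
  got <- load_to_strength_ratio(sol_c, y, 1.5)
  expect_equal(got$lsr, 1.5, tolerance = 1e-12)
  ## linearity: doubling the strain field doubles the ratio
  sol_2 <- fx_fake_solution(m, E3 = -2 * ratios * 7300)
  expect_equal(load_to_strength_ratio(sol_2, y, 1.5)$lsr, 3,
               tolerance = 1e-12)
})

test_that("sweep LSR matches the exhaustive threshold oracle", {
  y <- yield_model(7300)
  set.seed(31)
  for (k in 1:50) {
    nx <- sample(4:10, 1); ny <- sample(3:9, 1)
    m <- rect_mesh(nx, ny, nx, ny)      # <= 200 unit-ish elements
    ne <- nrow(m$tri)
    ratio <- exp(rnorm(ne, 0, 0.6))
    sol <- fx_fake_solution(m, E3 = -ratio * 7300)
    target <- runif(1, 2, 6) * mean(m$area)
    got <- load_to_strength_ratio(sol, y, target)$lsr
    expect_equal(got, lsr_oracle(m, ratio, target), tolerance = 1e-12)
  }
})

test_that("femoral strength inverts the load-to-strength ratio", {
  expect_equal(femoral_strength(3000, 0.75), 4000)
  expect_equal(femoral_strength(1234, 1), 1234)
  ## invariant to load magnitude under linear scaling of both
  expect_equal(femoral_strength(2 * 3000, 2 * 0.75), 4000)
  expect_error(femoral_strength(3000, 0), "non-positive")
})

test_that("attribute assembly yields the canonical named 39-vector", {
  sim <- fx_sim()
  v <- sim$attributes
  expect_length(v, 39)
  expect_identical(names(v), attribute_names())
  expect_true(all(is.finite(v)))
  expect_identical(attr(v, "group"), "fractured")
  ## a missing component is rejected by name
  bad_tissue <- list(TB = 80, CT = 20, TBE = 3.2)   # CTE absent
  fall <- sim$fall
  expect_error(
    assemble_attributes(fx_subject()$record, fx_measured()$morph, fall,
                        bad_tissue,
                        as.list(v[22:39])),
    "CTE")
})
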