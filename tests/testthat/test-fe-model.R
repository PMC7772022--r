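## analytic constraint helper: clamp one edge of a rectangular mesh
clamp_left <- function(mesh) {
  left <- which(mesh$nodes[, 1] == min(mesh$nodes[, 1]))
  anchor <- left[which.min(mesh$nodes[left, 2])]
  structure(list(fixed_xy = anchor, fixed_x = setdiff(left, anchor)),
            class = "fe_constraints")
}

test_that("patch test: uniform traction gives the exact constant field", {
  m <- rect_mesh(10, 4, 10, 4)
  mat <- uniform_materials(m, E = 1000, nu = 0.3)
  ld <- edge_pressure_load(m, 2, "femur", c(1, 0))
  s <- fe_solve(m, mat, clamp_left(m), ld)
  expect_equal(max(abs(s$elem$sxx + 2)), 0, tolerance = 1e-9)
  expect_equal(max(abs(s$elem$syy)), 0, tolerance = 1e-9)
  expect_equal(max(abs(s$elem$sxy)), 0, tolerance = 1e-9)
  expect_lt(s$residual, 1e-9)
  ## plane-strain out-of-plane stress and the 3D von Mises closed form
  expect_equal(s$elem$szz, 0.3 * (s$elem$sxx + s$elem$syy), tolerance = 1e-12)
  expect_equal(mean(s$elem$VM) / 2,
               sqrt(0.5 * ((1 - 0.3)^2 + 0.3^2 + 1)), tolerance = 1e-9)
})

test_that("solution scales exactly with the load (linearity)", {
  m <- rect_mesh(8, 8, 6, 6)
  mat <- uniform_materials(m, E = 500, nu = 0.3)
  s1 <- fe_solve(m, mat, clamp_left(m),
                 edge_pressure_load(m, 1, "femur", c(1, 0)))
  s3 <- fe_solve(m, mat, clamp_left(m),
                 edge_pressure_load(m, 3, "femur", c(1, 0)))
  expect_equal(s3$u, 3 * s1$u, tolerance = 1e-10)
  expect_equal(s3$elem$VM, 3 * s1$elem$VM, tolerance = 1e-9)
  ## zero pressure, zero displacement
  s0 <- fe_solve(m, mat, clamp_left(m),
                 edge_pressure_load(m, 1e-30, "femur", c(1, 0)))
  expect_lt(max(abs(s0$u)), 1e-20)
})

test_that("rigid translation leaves element stresses unchanged", {
  m <- rect_mesh(8, 5, 5, 4)
  mat <- uniform_materials(m, E = 800, nu = 0.3)
  ld <- edge_pressure_load(m, 2, "femur", c(1, 0))
  s1 <- fe_solve(m, mat, clamp_left(m), ld)
  m2 <- m; m2$nodes <- m2$nodes + matrix(c(17, -9), nrow(m$nodes), 2,
                                         byrow = TRUE)
  s2 <- fe_solve(m2, mat, clamp_left(m2),
                 edge_pressure_load(m2, 2, "femur", c(1, 0)))
  expect_equal(s1$elem$sxx, s2$elem$sxx, tolerance = 1e-9)
  expect_equal(s1$elem$VM, s2$elem$VM, tolerance = 1e-9)
})

test_that("tip-loaded cantilever approaches beam theory under refinement", {
  cant <- function(nx, ny) {
    L <- 60; H <- 6; E <- 1000; nu <- 0.3; P <- 1
    m <- rect_mesh(L, H, nx, ny)
    left <- which(m$nodes[, 1] == 0)
    co <- structure(list(fixed_xy = left, fixed_x = integer(0)),
                    class = "fe_constraints")
    f <- matrix(0, nrow(m$nodes), 2)
    tip <- which(m$nodes[, 1] == L)
    f[tip, 2] <- -P / length(tip)
    ld <- structure(list(f = f, total = colSums(f), edge_length = H, hp = NA),
                    class = "fe_load")
    s <- fe_solve(m, uniform_materials(m, E, nu), co, ld)
    wtip <- mean(s$u[tip, 2])
    wth <- -P * L^3 / (3 * (E / (1 - nu^2)) * H^3 / 12)
    c(fe = wtip, theory = wth)
  }
  coarse <- cant(80, 8)
  expect_equal(coarse["fe"], coarse["theory"], tolerance = 0.10,
               ignore_attr = TRUE)
  fine <- cant(120, 12)
  err <- function(v) abs(v["fe"] / v["theory"] - 1)
  expect_lt(err(fine), err(coarse))      # converging under refinement
})

test_that("femur meshing hits the element target without inverted cells", {
  fx <- fx_measured()
  pads <- place_pads(fx$posed, fx$morph)
  for (target in c(1500, 3000)) {
    mesh <- mesh_domain(fx$posed, pads, target)
    expect_gt(nrow(mesh$tri), 0.8 * target)
    expect_lt(nrow(mesh$tri), 1.25 * target)
    x <- matrix(mesh$nodes[mesh$tri, 1], nrow(mesh$tri), 3)
    y <- matrix(mesh$nodes[mesh$tri, 2], nrow(mesh$tri), 3)
    a2 <- x[, 1] * (y[, 2] - y[, 3]) + x[, 2] * (y[, 3] - y[, 1]) +
      x[, 3] * (y[, 1] - y[, 2])
    expect_true(all(a2 > 0))
    expect_true(all(c("femur", "trochanteric_pad", "head_pad") %in%
                      as.character(unique(mesh$tag))))
  }
})

test_that("material assignment maps BMD to moduli with pad constants", {
  fx <- fx_measured()
  pads <- place_pads(fx$posed, fx$morph)
  mesh <- mesh_domain(fx$posed, pads, 1500)
  ## uniform map: uniform femur modulus
  uni <- fx$posed
  uni$bmd[uni$mask] <- 0.8
  mat <- assign_materials(mesh, uni, material_law())
  fem <- mat$tag == "femur"
  expect_equal(length(unique(round(mat$E[fem], 9))), 1)
  expect_equal(unique(mat$nu[fem]), 0.3)
  expect_equal(unique(mat$E[!fem]), 1500)
  expect_equal(unique(mat$nu[!fem]), 0.37)
  ## zero-density pixels fall to the modulus floor, never zero
  zero <- fx$posed
  zero$bmd[zero$mask] <- 0
  mat0 <- assign_materials(mesh, zero, material_law())
  expect_true(all(mat0$E[mat0$tag == "femur"] == material_law()$e_min))
})

test_that("constraints and loading act where the fall configuration says", {
  fx <- fx_measured()
  pads <- place_pads(fx$posed, fx$morph)
  mesh <- mesh_domain(fx$posed, pads, 2000)
  con <- apply_constraints(mesh)
  expect_gt(length(con$fixed_xy), 0)
  expect_gt(length(con$fixed_x), 0)
  ## distal clamp sits at the bottom of the femur
  expect_lt(max(mesh$nodes[con$fixed_xy, 2]),
            min(mesh$nodes[, 2]) + 4 * mesh$h)
  ld <- apply_load(mesh, 6.5, pads)
  ## lumped nodal forces reproduce pressure x loaded length exactly
  expect_equal(sqrt(sum(ld$total^2)), 6.5 * ld$edge_length,
               tolerance = 1e-9)
  ## the resultant pushes medially (inward, -x dominated)
  expect_lt(ld$total[1], 0)
  mat <- assign_materials(mesh, fx$posed, material_law())
  sol <- fe_solve(mesh, mat, con, ld)
  expect_lt(sol$residual, 1e-6)
  ## releasing the head-pad restraint increases medial head motion
  con_free <- con; con_free$fixed_x <- integer(0)
  sol_free <- fe_solve(mesh, mat, con_free, ld)
  head_nodes <- unique(as.vector(mesh$tri[mesh$tag == "head_pad", ]))
  expect_gt(max(abs(sol_free$u[head_nodes, 1])),
            max(abs(sol$u[head_nodes, 1])))
})
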