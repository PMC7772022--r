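#' Solve the plane-strain linear-elastic problem
#'
#' Linear (constant-strain) triangle assembly under plane strain, sparse
#' Cholesky solve, and per-element post-processing: the in-plane strain
#' and stress tensors, the out-of-plane stress
#' `sigma_zz = nu (sigma_xx + sigma_yy)`, in-plane principal stresses
#' `S1 >= S3` (MPa) and strains `E1 >= E3` (microstrain), the
#' largest-magnitude principal stress/strain with sign retained
#' (MPStress, MPStrain), the von Mises stress including `sigma_zz`, and
#' the strain energy density `1/2 sigma : epsilon` in J/m^3. Forces and
#' stresses are per unit out-of-plane thickness.
#'
#' @param mesh an [mesh_domain()] mesh
#' @param materials an [assign_materials()] field
#' @param constraints an [apply_constraints()] set
#' @param load an [apply_load()] case
#' @return object of class `fe_solution`: nodal displacements `u`
#'   (n x 2, mm), per-element tensor table `elem`, equilibrium residual
#'   `residual` (relative), applied force `applied`
#' @export
fe_solve <- function(mesh, materials, constraints, load) {
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$tri)
  x <- matrix(mesh$nodes[mesh$tri, 1], ne, 3)
  y <- matrix(mesh$nodes[mesh$tri, 2], ne, 3)
  ## CST shape-function gradients
  b1 <- y[, 2] - y[, 3]; b2 <- y[, 3] - y[, 1]; b3 <- y[, 1] - y[, 2]
  c1 <- x[, 3] - x[, 2]; c2 <- x[, 1] - x[, 3]; c3 <- x[, 2] - x[, 1]
  A2 <- x[, 1] * b1 + x[, 2] * b2 + x[, 3] * b3   # 2 * signed area
  if (any(A2 <= 0)) stop("inverted element(s) in mesh")
  area <- A2 / 2

  E <- materials$E; nu <- materials$nu
  d0 <- E / ((1 + nu) * (1 - 2 * nu))
  D11 <- d0 * (1 - nu); D12 <- d0 * nu; D33 <- d0 * (1 - 2 * nu) / 2

  ## B (3x6) entries per element: B = [b_i 0; 0 c_i; c_i b_i] / 2A
  B <- list(b = cbind(b1, b2, b3) / A2, c = cbind(c1, c2, c3) / A2)

  ## vectorised element stiffness: K_e[p,q] with p,q in 1..6
  ## dof order (u1, v1, u2, v2, u3, v3)
  triplets_i <- vector("list", 36); triplets_j <- vector("list", 36)
  triplets_v <- vector("list", 36)
  cnt <- 0
  dof <- function(node, comp) 2 * (node - 1) + comp
  for (a in 1:3) for (ca in 1:2) for (b in 1:3) for (cb in 1:2) {
    ba <- B$b[, a]; cca <- B$c[, a]; bb <- B$b[, b]; ccb <- B$c[, b]
    v <- if (ca == 1 && cb == 1) {
      D11 * ba * bb + D33 * cca * ccb
    } else if (ca == 1 && cb == 2) {
      D12 * ba * ccb + D33 * cca * bb
    } else if (ca == 2 && cb == 1) {
      D12 * cca * bb + D33 * ba * ccb
    } else {
      D11 * cca * ccb + D33 * ba * bb
    }
    cnt <- cnt + 1
    triplets_i[[cnt]] <- dof(mesh$tri[, a], ca)
    triplets_j[[cnt]] <- dof(mesh$tri[, b], cb)
    triplets_v[[cnt]] <- v * area
  }
  K <- Matrix::sparseMatrix(
    i = unlist(triplets_i), j = unlist(triplets_j),
    x = unlist(triplets_v), dims = c(2 * nn, 2 * nn))

  f <- as.vector(t(load$f))                 # (u1, v1, u2, v2, ...)
  fixed <- c(2 * (constraints$fixed_xy - 1) + 1,
             2 * (constraints$fixed_xy - 1) + 2,
             2 * (constraints$fixed_x - 1) + 1)
  free <- setdiff(seq_len(2 * nn), fixed)
  if (!length(free)) stop("no free degrees of freedom")
  u <- numeric(2 * nn)
  Kff <- K[free, free, drop = FALSE]
  sol <- tryCatch(Matrix::solve(Kff, f[free]),
                  error = function(e) stop("singular system: ", conditionMessage(e)))
  u[free] <- as.vector(sol)

  ## equilibrium: reactions at constrained dofs balance the applied load
  r <- as.vector(K %*% u) - f
  fnorm <- sqrt(sum(f^2))
  residual <- if (fnorm > 0) sqrt(sum(r[free]^2)) / fnorm else sqrt(sum(r[free]^2))

  ux <- u[seq(1, 2 * nn, by = 2)]; uy <- u[seq(2, 2 * nn, by = 2)]
  U1x <- ux[mesh$tri[, 1]]; U2x <- ux[mesh$tri[, 2]]; U3x <- ux[mesh$tri[, 3]]
  U1y <- uy[mesh$tri[, 1]]; U2y <- uy[mesh$tri[, 2]]; U3y <- uy[mesh$tri[, 3]]
  exx <- B$b[, 1] * U1x + B$b[, 2] * U2x + B$b[, 3] * U3x
  eyy <- B$c[, 1] * U1y + B$c[, 2] * U2y + B$c[, 3] * U3y
  gxy <- B$c[, 1] * U1x + B$c[, 2] * U2x + B$c[, 3] * U3x +
    B$b[, 1] * U1y + B$b[, 2] * U2y + B$b[, 3] * U3y

  sxx <- D11 * exx + D12 * eyy
  syy <- D12 * exx + D11 * eyy
  sxy <- D33 * gxy
  szz <- nu * (sxx + syy)

  pr <- function(axx, ayy, axy) {
    m <- (axx + ayy) / 2
    r <- sqrt(((axx - ayy) / 2)^2 + axy^2)
    list(p1 = m + r, p2 = m - r)
  }
  ps <- pr(sxx, syy, sxy)
  pe <- pr(exx, eyy, gxy / 2)
  S1 <- ps$p1; S3 <- ps$p2
  E1 <- pe$p1 * 1e6; E3 <- pe$p2 * 1e6      # microstrain
  MPStress <- ifelse(abs(S1) >= abs(S3), S1, S3)
  MPStrain <- ifelse(abs(E1) >= abs(E3), E1, E3)
  VM <- sqrt(sxx^2 + syy^2 + szz^2 - sxx * syy - syy * szz - szz * sxx +
               3 * sxy^2)
  SED <- 0.5 * (sxx * exx + syy * eyy + sxy * gxy) * 1e6   # MPa -> J/m^3

  elem <- data.frame(
    exx = exx, eyy = eyy, gxy = gxy,
    sxx = sxx, syy = syy, sxy = sxy, szz = szz,
    S1 = S1, S3 = S3, E1 = E1, E3 = E3,
    MPStress = MPStress, MPStrain = MPStrain,
    VM = VM, SED = SED,
    area = area, tag = mesh$tag
  )
  structure(list(u = cbind(ux, uy), elem = elem, residual = residual,
                 applied = load$total, mesh = mesh),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf(paste0("fe_solution: %d elements, |u|max %.3f mm, ",
                     "equilibrium residual %.2e\n"),
              nrow(x$elem), max(sqrt(rowSums(x$u^2))), x$residual))
  invisible(x)
}

#' Export a solution in legacy VTK format
#'
#' Writes nodes, triangles and the main per-element fields for external
#' visualisation.
#'
#' @param solution an [fe_solve()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vtk <- function(solution, path) {
  mesh <- solution$mesh
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0",
               "plane-strain femur solution", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(mesh$nodes))), con)
  write(t(cbind(mesh$nodes, 0)), con, ncolumns = 3)
  ne <- nrow(mesh$tri)
  writeLines(sprintf("CELLS %d %d", ne, 4 * ne), con)
  write(t(cbind(3, mesh$tri - 1)), con, ncolumns = 4)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  write(rep(5, ne), con, ncolumns = 10)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  for (fld in c("VM", "S1", "S3", "SED")) {
    writeLines(c(sprintf("SCALARS %s float 1", fld),
                 "LOOKUP_TABLE default"), con)
    write(solution$elem[[fld]], con, ncolumns = 6)
  }
  writeLines(sprintf("POINT_DATA %d", nrow(mesh$nodes)), con)
  writeLines(c("VECTORS displacement float"), con)
  write(t(cbind(solution$u, 0)), con, ncolumns = 3)
  invisible(path)
}
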