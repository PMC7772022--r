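#' Mesh the femur and pad domains
#'
#' Structured triangulation: a square grid of cells at a resolution
#' chosen so that the triangle count approximates `target_elements`
#' (two triangles per covered cell), with each cell tagged `femur`,
#' `trochanteric_pad` or `head_pad` from the segmentation mask and the
#' analytic pad geometry. The boundary follows the grid at half-cell
#' fidelity; all triangles are counter-clockwise (positive signed area)
#' by construction, and the mesh is conforming because neighbouring
#' cells share grid nodes. Stray cells not connected to the main body
#' are dropped.
#'
#' @param scan pose-standardised, canonically oriented [scan_raster()]
#' @param pads a [place_pads()] result
#' @param target_elements approximate number of triangles (>= 500)
#' @return object of class `fe_mesh`: `nodes` (n x 2 mm), `tri`
#'   (m x 3 node indices), `tag` (factor per element), `area` (mm^2 per
#'   element), `h` (cell size, mm)
#' @export
mesh_domain <- function(scan, pads, target_elements = 6000) {
  stopifnot(inherits(scan, "scan_raster"), target_elements >= 500)
  pts <- mask_points(scan)
  area_femur <- length(pts$idx) * scan$dx * scan$dy
  cap_area <- pads$cap_halfangle * ((pads$head_r + pads$depth)^2 - pads$head_r^2)
  area_est <- area_femur + pads$b * pads$depth + cap_area
  h <- sqrt(2 * area_est / target_elements)

  xr <- range(pts$x); yr <- range(pts$y)
  pad_margin <- pads$depth + 2 * h + 3
  xs <- seq(xr[1] - pad_margin, xr[2] + pad_margin, by = h)
  ys <- seq(yr[1] - pad_margin, yr[2] + pad_margin, by = h)
  nx <- length(xs) - 1; ny <- length(ys) - 1
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  G <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  gx <- cx[G$ix]; gy <- cy[G$iy]

  in_femur <- sample_nearest(scan$mask * 1, gx, gy, scan$dx, scan$dy) > 0.5
  in_troch <- !in_femur & pad_inside(pads, "troch", gx, gy)
  in_head <- !in_femur & !in_troch & pad_inside(pads, "head", gx, gy)
  tag_cell <- rep(NA_character_, nrow(G))
  tag_cell[in_femur] <- "femur"
  tag_cell[in_troch] <- "trochanteric_pad"
  tag_cell[in_head] <- "head_pad"
  keep <- !is.na(tag_cell)
  if (!any(keep)) stop("empty meshing domain")

  ## drop cells not 4-connected to the largest component
  occ <- matrix(FALSE, ny, nx)
  occ[cbind(G$iy[keep], G$ix[keep])] <- TRUE
  cc <- connected_components(occ)
  sizes <- tabulate(cc$labels[cc$labels > 0], cc$n)
  main <- cc$labels == which.max(sizes)
  keep <- keep & main[cbind(G$iy, G$ix)]

  idx <- which(keep)
  ## node grid (nx+1) x (ny+1), only nodes used by kept cells retained
  node_id <- matrix(0L, length(ys), length(xs))
  corn <- rbind(
    cbind(G$ix[idx], G$iy[idx]), cbind(G$ix[idx] + 1L, G$iy[idx]),
    cbind(G$ix[idx] + 1L, G$iy[idx] + 1L), cbind(G$ix[idx], G$iy[idx] + 1L))
  ucorn <- unique(corn)
  node_id[cbind(ucorn[, 2], ucorn[, 1])] <- seq_len(nrow(ucorn))
  nodes <- cbind(x = xs[ucorn[, 1]], y = ys[ucorn[, 2]])

  n00 <- node_id[cbind(G$iy[idx], G$ix[idx])]
  n10 <- node_id[cbind(G$iy[idx], G$ix[idx] + 1L)]
  n11 <- node_id[cbind(G$iy[idx] + 1L, G$ix[idx] + 1L)]
  n01 <- node_id[cbind(G$iy[idx] + 1L, G$ix[idx])]
  tri <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
  tag <- factor(rep(tag_cell[idx], 2),
                levels = c("femur", "trochanteric_pad", "head_pad"))
  area <- rep(h^2 / 2, nrow(tri))
  for (p in c("trochanteric_pad", "head_pad"))
    if (!any(tag == p)) stop("pad '", p, "' produced no elements")
  structure(list(nodes = nodes, tri = tri, tag = tag, area = area, h = h),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("fe_mesh: %d nodes, %d elements (h = %.2f mm): %s\n",
              nrow(x$nodes), nrow(x$tri), x$h,
              paste(names(table(x$tag)), table(x$tag), collapse = ", ",
                    sep = "=")))
  invisible(x)
}

element_centroids <- function(mesh) {
  cbind((mesh$nodes[mesh$tri[, 1], 1] + mesh$nodes[mesh$tri[, 2], 1] +
           mesh$nodes[mesh$tri[, 3], 1]) / 3,
        (mesh$nodes[mesh$tri[, 1], 2] + mesh$nodes[mesh$tri[, 2], 2] +
           mesh$nodes[mesh$tri[, 3], 2]) / 3)
}

#' Material law for BMD-derived bone properties
#'
#' Areal BMD is converted to apparent density through a reference
#' projection thickness, then to Young's modulus by the power law
#' `E = a * rho^p`. Defaults are calibrated so synthetic cohorts produce
#' trabecular moduli in the 3-4.5 GPa range and cortical moduli in the
#' 9-13 GPa range at the 1.0 g/cm^3 cortical threshold.
#'
#' @param a modulus coefficient, MPa per (g/cm^3)^p
#' @param p density exponent
#' @param t_ref areal-to-apparent conversion thickness, cm
#' @param e_min modulus floor, MPa (keeps the stiffness matrix
#'   well-posed on near-void pixels)
#' @param nu_bone,nu_pad Poisson ratios
#' @param e_pad pad (PMMA) modulus, MPa
#' @return object of class `material_law`
#' @export
material_law <- function(a = 6850, p = 1.49, t_ref = 1.0, e_min = 10,
                         nu_bone = 0.3, nu_pad = 0.37, e_pad = 1500) {
  stopifnot(a > 0, p > 0, t_ref > 0, e_min > 0)
  structure(list(a = a, p = p, t_ref = t_ref, e_min = e_min,
                 nu_bone = nu_bone, nu_pad = nu_pad, e_pad = e_pad),
            class = "material_law")
}

#' Assign per-element material properties
#'
#' Femur elements sample the areal BMD at their centroid (nearest pixel;
#' zero-BMD fallthrough uses the modulus floor), convert to apparent
#' density `rho = BMD / t_ref` and modulus `E = a * rho^p`, with Poisson
#' ratio 0.3. Pad elements get the PMMA constants (E = 1500 MPa,
#' nu = 0.37).
#'
#' @param mesh an [mesh_domain()] mesh
#' @param scan the scan the mesh was built on
#' @param law a [material_law()]
#' @return object of class `material_field`: data frame with `rho`
#'   (g/cm^3), `E` (MPa), `nu` per element, plus the law and element
#'   areas
#' @export
assign_materials <- function(mesh, scan, law = material_law()) {
  cen <- element_centroids(mesh)
  n <- nrow(mesh$tri)
  rho <- rep(NA_real_, n); E <- rep(NA_real_, n); nu <- rep(NA_real_, n)
  fem <- mesh$tag == "femur"
  bmd <- sample_nearest(scan$bmd, cen[fem, 1], cen[fem, 2], scan$dx, scan$dy)
  ## boundary elements whose centroid pixel falls just outside the mask
  ## take the densest of their vertex pixels instead
  miss <- which(bmd <= 0)
  if (length(miss)) {
    fem_idx <- which(fem)
    for (k in miss) {
      vtx <- mesh$nodes[mesh$tri[fem_idx[k], ], , drop = FALSE]
      probes <- rbind(vtx, (vtx[c(1, 2, 3), ] + vtx[c(2, 3, 1), ]) / 2)
      bmd[k] <- max(sample_nearest(scan$bmd, probes[, 1], probes[, 2],
                                   scan$dx, scan$dy))
    }
  }
  rho[fem] <- bmd / law$t_ref
  E[fem] <- pmax(law$a * rho[fem]^law$p, law$e_min)
  nu[fem] <- law$nu_bone
  E[!fem] <- law$e_pad
  nu[!fem] <- law$nu_pad
  rho[!fem] <- 0
  structure(list(rho = rho, E = E, nu = nu, law = law,
                 area = mesh$area, tag = mesh$tag),
            class = "material_field")
}

#' Boundary conditions of the sideways-fall configuration
#'
#' The distal end of the femoral shaft is fully restrained (both
#' displacement components of the femur nodes within 1.5 cells of the
#' lowest femur node) and the femoral head pad is restrained in the
#' medial direction (x component of every head-pad node), leaving its
#' vertical motion free.
#'
#' @param mesh an [mesh_domain()] mesh
#' @return object of class `fe_constraints` with node index vectors
#'   `fixed_xy` and `fixed_x`
#' @export
apply_constraints <- function(mesh) {
  fem_nodes <- unique(as.vector(mesh$tri[mesh$tag == "femur", ]))
  ylo <- min(mesh$nodes[fem_nodes, 2])
  fixed_xy <- fem_nodes[mesh$nodes[fem_nodes, 2] <= ylo + 1.5 * mesh$h]
  head_nodes <- unique(as.vector(mesh$tri[mesh$tag == "head_pad", ]))
  fixed_x <- setdiff(head_nodes, fixed_xy)
  if (!length(fixed_xy)) stop("empty distal constraint set")
  if (!length(fixed_x)) stop("empty head-pad constraint set")
  structure(list(fixed_xy = sort(fixed_xy), fixed_x = sort(fixed_x)),
            class = "fe_constraints")
}

#' Pressure load on the trochanteric pad
#'
#' Applies a uniform inward pressure on the lateral free boundary of the
#' trochanteric pad: boundary edges belonging to exactly one
#' trochanteric-pad element whose outward normal is within 60 degrees of
#' the pad's lateral direction receive consistent (edge-lumped) nodal
#' forces `-hp * L / 2` per node along the outward normal. Forces are
#' per unit out-of-plane thickness (N/mm).
#'
#' @param mesh an [mesh_domain()] mesh
#' @param hp applied pressure, MPa
#' @param pads the [place_pads()] geometry (for the lateral direction)
#' @return object of class `fe_load`: force matrix (n x 2, N/mm),
#'   `total` (resultant vector), `edge_length` (loaded length, mm)
#' @export
apply_load <- function(mesh, hp, pads) {
  edge_pressure_load(mesh, hp, "trochanteric_pad", pads$n_lat)
}

#' Uniform pressure on a selected free boundary
#'
#' Lower-level load constructor: applies inward pressure `p` on free
#' boundary edges of elements with tag in `tags` whose outward normal
#' satisfies `normal . direction > cos_min`. Used by [apply_load()] and
#' by verification problems on plain rectangular meshes.
#'
#' @param mesh an `fe_mesh`
#' @param p pressure, MPa
#' @param tags element tags whose boundary is loaded
#' @param direction reference direction for the loaded face
#' @param cos_min normal-alignment threshold
#' @return an `fe_load`
#' @export
edge_pressure_load <- function(mesh, p, tags, direction, cos_min = 0.5) {
  stopifnot(p >= 0)
  ed <- rbind(mesh$tri[, c(1, 2)], mesh$tri[, c(2, 3)], mesh$tri[, c(3, 1)])
  eid <- rep(seq_len(nrow(mesh$tri)), 3)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  on_boundary <- cnt[key] == 1
  sel <- on_boundary & (mesh$tag[eid] %in% tags)
  if (!any(sel)) stop("no free boundary to load")
  ed <- ed[sel, , drop = FALSE]
  v <- mesh$nodes[ed[, 2], , drop = FALSE] - mesh$nodes[ed[, 1], , drop = FALSE]
  L <- sqrt(rowSums(v^2))
  nrm <- cbind(v[, 2], -v[, 1]) / L   # outward normal of a CCW element edge
  direction <- direction / sqrt(sum(direction^2))
  out <- as.vector(nrm %*% direction) > cos_min
  ed <- ed[out, , drop = FALSE]; nrm <- nrm[out, , drop = FALSE]
  L <- L[out]
  if (!length(L)) stop("zero-length loaded edge")
  f <- matrix(0, nrow(mesh$nodes), 2)
  for (k in seq_along(L)) {
    contrib <- -p * L[k] / 2 * nrm[k, ]
    f[ed[k, 1], ] <- f[ed[k, 1], ] + contrib
    f[ed[k, 2], ] <- f[ed[k, 2], ] + contrib
  }
  structure(list(f = f, total = colSums(f), edge_length = sum(L), hp = p),
            class = "fe_load")
}

#' Structured rectangular mesh (verification problems)
#'
#' @param w,h rectangle size, mm
#' @param nx,ny cell counts
#' @param tag element tag
#' @return an `fe_mesh`
#' @export
rect_mesh <- function(w, h, nx, ny, tag = "femur") {
  xs <- seq(0, w, length.out = nx + 1)
  ys <- seq(0, h, length.out = ny + 1)
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  G <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  n00 <- nid(G$i, G$j); n10 <- nid(G$i + 1L, G$j)
  n11 <- nid(G$i + 1L, G$j + 1L); n01 <- nid(G$i, G$j + 1L)
  tri <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
  structure(list(
    nodes = nodes, tri = tri,
    tag = factor(rep(tag, nrow(tri)),
                 levels = c("femur", "trochanteric_pad", "head_pad")),
    area = rep((w / nx) * (h / ny) / 2, nrow(tri)),
    h = sqrt((w / nx) * (h / ny))
  ), class = "fe_mesh")
}

#' Uniform material field (verification problems)
#'
#' @param mesh an `fe_mesh`
#' @param E Young's modulus, MPa
#' @param nu Poisson ratio
#' @param rho apparent density, g/cm^3
#' @return a `material_field`
#' @export
uniform_materials <- function(mesh, E, nu = 0.3, rho = 1) {
  n <- nrow(mesh$tri)
  structure(list(rho = rep(rho, n), E = rep(E, n), nu = rep(nu, n),
                 law = material_law(), area = mesh$area, tag = mesh$tag),
            class = "material_field")
}
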