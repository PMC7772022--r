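#' Bone tissue composition attributes
#'
#' Area-weighted partition of femur elements at the cortical apparent
#' density threshold (strictly greater than 1.0 g/cm^3 counts as
#' cortical), plus the area-weighted mean Young's modulus of each
#' tissue class in GPa. `TB + CT = 100` exactly; an empty class reports
#' a zero modulus with a flag.
#'
#' @param materials an [assign_materials()] field
#' @param threshold cortical density threshold, g/cm^3
#' @return list with `TB`, `CT` (percent), `TBE`, `CTE` (GPa),
#'   `flagged` (logical: a tissue class is empty)
#' @export
tissue_attributes <- function(materials, threshold = 1.0) {
  fem <- materials$tag == "femur"
  if (!any(fem)) stop("no femur elements")
  a <- materials$area[fem]
  rho <- materials$rho[fem]
  E <- materials$E[fem]
  cort <- rho > threshold
  A <- sum(a)
  TB <- 100 * sum(a[!cort]) / A
  CT <- 100 - TB
  TBE <- if (any(!cort)) sum(a[!cort] * E[!cort]) / sum(a[!cort]) / 1000 else 0
  CTE <- if (any(cort)) sum(a[cort] * E[cort]) / sum(a[cort]) / 1000 else 0
  list(TB = TB, CT = CT, TBE = TBE, CTE = CTE,
       flagged = !any(cort) || !any(!cort))
}

#' Area-weighted regional average of an element field
#'
#' `sum(area_e * q_e) / sum(area_e)` over a region (the 2D analogue of
#' volume weighting at uniform thickness).
#'
#' @param solution an [fe_solve()] result
#' @param region element index vector
#' @param quantity element-table column name (e.g. `"S1"`, `"SED"`)
#' @return scalar
#' @export
regional_average <- function(solution, region, quantity) {
  if (!length(region)) stop("empty region")
  a <- solution$elem$area[region]
  q <- solution$elem[[quantity]][region]
  sum(a * q) / sum(a)
}

#' Yield model for strength-related indices
#'
#' A uniform compressive yield strain defines the strain capacity used
#' by the load-to-strength ratio, and the per-element yield stress
#' (modulus times yield strain) defines the capacity used by the
#' fracture risk index.
#'
#' @param yield_strain compressive yield strain, microstrain
#' @return object of class `yield_model`
#' @export
yield_model <- function(yield_strain = 7300) {
  stopifnot(yield_strain > 0)
  structure(list(yield_strain = yield_strain), class = "yield_model")
}

#' Fracture risk index of a region
#'
#' Area-weighted mean ratio of the von Mises stress to the element yield
#' stress (`E_e * yield_strain`).
#'
#' @param solution an [fe_solve()] result
#' @param region element index vector
#' @param yield a [yield_model()]
#' @param materials the [assign_materials()] field (for per-element
#'   moduli)
#' @return dimensionless scalar
#' @export
fracture_risk_index <- function(solution, region, yield, materials) {
  if (!length(region)) stop("empty region")
  sy <- materials$E[region] * yield$yield_strain * 1e-6
  if (any(sy <= 0)) stop("non-positive yield stress")
  a <- solution$elem$area[region]
  sum(a * solution$elem$VM[region] / sy) / sum(a)
}

## element edge adjacency (shared edges) for a subset of elements
element_adjacency <- function(mesh, elems) {
  ed <- rbind(mesh$tri[elems, c(1, 2), drop = FALSE],
              mesh$tri[elems, c(2, 3), drop = FALSE],
              mesh$tri[elems, c(3, 1), drop = FALSE])
  eid <- rep(seq_along(elems), 3)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  sp <- split(eid, key)
  sp <- sp[lengths(sp) == 2]
  if (!length(sp)) return(cbind(integer(0), integer(0)))
  do.call(rbind, sp)
}

#' Load-to-strength ratio
#'
#' Per femur element the demand/capacity ratio is the magnitude of the
#' compressive principal strain over the compressive yield strain. The
#' critical region is the contiguous (edge-adjacent) element set
#' comprising the highest ratios whose cumulative area first reaches
#' `area_target`; LSR is the smallest ratio inside it. Computed exactly
#' by a descending-threshold union-find sweep: the reported value is the
#' largest `r` such that some connected component of elements with
#' ratio >= `r` has area >= `area_target`.
#'
#' @param solution an [fe_solve()] result
#' @param yield a [yield_model()]
#' @param area_target critical contiguous area, mm^2 (default 9)
#' @return list with `lsr` and `region` (element indices of the critical
#'   region)
#' @export
load_to_strength_ratio <- function(solution, yield, area_target = 9) {
  mesh <- solution$mesh
  fem <- which(mesh$tag == "femur")
  areas <- solution$elem$area[fem]
  if (sum(areas) < area_target) stop("femur area below the target region area")
  ratio <- pmax(0, -solution$elem$E3[fem]) / yield$yield_strain
  adj <- element_adjacency(mesh, fem)
  nbr <- vector("list", length(fem))
  if (nrow(adj)) for (k in seq_len(nrow(adj))) {
    nbr[[adj[k, 1]]] <- c(nbr[[adj[k, 1]]], adj[k, 2])
    nbr[[adj[k, 2]]] <- c(nbr[[adj[k, 2]]], adj[k, 1])
  }
  ord <- order(ratio, decreasing = TRUE)
  parent <- seq_along(fem)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  carea <- areas
  added <- rep(FALSE, length(fem))
  for (i in ord) {
    added[i] <- TRUE
    for (j in nbr[[i]]) {
      if (!added[j]) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) {
        parent[rj] <- ri
        carea[ri] <- carea[ri] + carea[rj]
      }
    }
    if (carea[find(i)] >= area_target) {
      root <- find(i)
      members <- which(added & vapply(seq_along(fem), find, integer(1)) == root)
      return(list(lsr = ratio[i], region = fem[members]))
    }
  }
  ## all elements added without reaching the target within one component
  stop("no contiguous region reaches the target area")
}

#' Femoral strength
#'
#' The load at which the critical region reaches yield: by linearity of
#' the model, `FS = FP / LSR`.
#'
#' @param fp attenuated impact force, N
#' @param lsr load-to-strength ratio (> 0)
#' @return femoral strength, N
#' @export
femoral_strength <- function(fp, lsr) {
  if (any(lsr <= 0)) stop("non-positive load-to-strength ratio")
  fp / lsr
}

#' Assemble the canonical 39-attribute vector
#'
#' Collects the clinical, geometric, fall-related, tissue and
#' finite-element attribute groups into the canonical named order (see
#' [attribute_names()]); any missing attribute is rejected by name.
#'
#' @param record one-row clinical record
#' @param morph a [measure_morphometry()] result
#' @param fall a [fall_attributes()] list
#' @param tissue a [tissue_attributes()] list
#' @param mech named list with LSR, FS and the 16 regional FE
#'   attributes plus FRI_N, FRI_T
#' @return named numeric vector of length 39 with attribute
#'   `group` = the subject's group label
#' @export
assemble_attributes <- function(record, morph, fall, tissue, mech) {
  vals <- c(
    Age = record$age, Height = record$height, Weight = record$weight,
    BMI = record$bmi, BMD = record$bmd_total,
    NW = morph$NW, HAL = morph$HAL, NSA = morph$NSA, SAL = morph$SAL,
    ITW = morph$ITW, STW = morph$STW, FA = morph$FA,
    STH = fall$STH, FPK = fall$FPK, FAT = fall$FAT, FP = fall$FP,
    HP = fall$HP,
    TB = tissue$TB, TBE = tissue$TBE, CT = tissue$CT, CTE = tissue$CTE,
    unlist(mech)
  )
  nm <- attribute_names()
  missing <- setdiff(nm, names(vals))
  if (length(missing))
    stop("missing attributes: ", paste(missing, collapse = ", "))
  out <- vals[nm]
  if (any(!is.finite(out)))
    stop("non-finite attributes: ", paste(nm[!is.finite(out)], collapse = ", "))
  attr(out, "group") <- record$group
  out
}
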