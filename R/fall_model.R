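#' Impact-model parameters for the sideways fall
#'
#' Single-degree-of-freedom mass-spring description of the impact of the
#' greater trochanter on the ground. The fall height is a fraction of body
#' height (hip height at the start of the fall), a fraction of body mass
#' takes part in the impact, and the body/ground interface acts as a
#' linear spring. The defaults were calibrated once so that cohort
#' group-mean anthropometrics (women, weight ~63.6-65.2 kg, height
#' ~151.8-152.7 cm) give peak impact forces of ~5.2-5.3 kN, the scale
#' reported for elderly female fallers, and then frozen.
#'
#' @param stiffness effective contact stiffness, N/m
#' @param mass_fraction fraction of body mass effective at impact
#' @param hip_height_fraction hip height as a fraction of body height
#' @param gravity gravitational acceleration, m/s^2
#' @return an object of class `impact_params`
#' @export
impact_params <- function(stiffness = 80100, mass_fraction = 0.35,
                          hip_height_fraction = 0.51, gravity = 9.81) {
  stopifnot(stiffness > 0, mass_fraction > 0, mass_fraction <= 1,
            hip_height_fraction > 0, gravity > 0)
  structure(list(stiffness = stiffness, mass_fraction = mass_fraction,
                 hip_height_fraction = hip_height_fraction, gravity = gravity),
            class = "impact_params")
}

#' Trochanteric soft-tissue thickness from body mass index
#'
#' Linear regression of trochanteric soft-tissue thickness on BMI for
#' women: `STH = 2.3451 * BMI - 33.4440` (mm). Non-positive predictions
#' (very low BMI) are clamped at a configurable floor with a warning.
#'
#' @param bmi body mass index, kg/m^2
#' @param gender only `"female"` is supported; the male regression is not
#'   available
#' @param floor minimum returned thickness, mm
#' @return soft-tissue thickness, mm
#' @export
soft_tissue_thickness <- function(bmi, gender = "female", floor = 1) {
  if (!all(gender == "female")) stop("soft-tissue relation is only available for female subjects")
  stopifnot(all(bmi > 0))
  sth <- 2.3451 * bmi - 33.4440
  if (any(sth <= 0)) {
    warning("non-positive soft-tissue thickness clamped at floor")
    sth <- pmax(sth, floor)
  }
  sth
}

#' Attenuation force absorbed by trochanteric soft tissue
#'
#' `FAT = 71 * STH` with STH in mm and FAT in newtons.
#'
#' @param sth soft-tissue thickness, mm (non-negative)
#' @return attenuation force, N
#' @export
attenuation_force <- function(sth) {
  if (any(sth < 0)) stop("negative soft-tissue thickness")
  71 * sth
}

#' Peak impact force of a sideways fall
#'
#' Mass-spring impact: the hip falls from height `h = hip_height_fraction
#' * height`, reaching velocity `v = sqrt(2 g h)`, and the peak force of
#' an undamped linear impact is `FPK = v * sqrt(k * m_eff)` with
#' `m_eff = mass_fraction * weight`. Monotonically increasing in both
#' weight and height.
#'
#' @param weight body weight, kg
#' @param height body height, cm
#' @param gender subject gender (recorded; the default parameters are
#'   calibrated for women)
#' @param params an [impact_params()] object
#' @return peak impact force, N
#' @export
peak_impact_force <- function(weight, height, gender = "female",
                              params = impact_params()) {
  stopifnot(inherits(params, "impact_params"), all(weight > 0), all(height > 0))
  h <- params$hip_height_fraction * height / 100   # m
  v <- sqrt(2 * params$gravity * h)                # m/s
  v * sqrt(params$stiffness * params$mass_fraction * weight)
}

#' Attenuated impact force
#'
#' `FP = FPK - FAT`. A non-positive result (extreme soft-tissue padding)
#' is flagged with a warning but not rejected, so batch runs survive
#' extreme draws.
#'
#' @param fpk peak impact force, N
#' @param fat attenuation force, N
#' @return attenuated force, N
#' @export
attenuated_force <- function(fpk, fat) {
  stopifnot(all(fpk > 0), all(fat >= 0))
  fp <- fpk - fat
  if (any(fp <= 0)) warning("non-positive attenuated force (soft tissue absorbs the whole impact)")
  fp
}

#' Hip pressure applied through the trochanteric pad
#'
#' `HP = FP / (b * t)` with the pad length `b` and out-of-plane thickness
#' `t` in mm, giving MPa.
#'
#' @param fp attenuated impact force, N
#' @param pads a `pad_geometry` object (see [place_pads()]) or a list with
#'   elements `b` and `t` in mm
#' @return hip pressure, MPa
#' @export
hip_pressure <- function(fp, pads) {
  b <- pads$b; t <- pads$t
  if (!is.numeric(b) || !is.numeric(t) || b * t <= 0) stop("non-positive pad area b*t")
  stopifnot(all(fp > 0))
  fp / (b * t)
}

#' Full fall-related attribute chain for one subject
#'
#' Computes STH, FPK, FAT, FP and HP from the clinical record and the pad
#' geometry. `FP = FPK - FAT` and `HP * b * t = FP` hold to machine
#' precision by construction. FP is floored at `fp_floor` (flagged) so a
#' downstream finite-element load is always well defined.
#'
#' @param record a `subject_record` (see [sample_clinical()]) or any list
#'   with `bmi`, `weight`, `height`, `gender`
#' @param pads pad geometry with `b`, `t` in mm
#' @param params an [impact_params()] object
#' @param fp_floor minimum attenuated force, N
#' @return a list with elements `STH`, `FPK`, `FAT`, `FP`, `HP` and a
#'   logical `flagged`
#' @export
fall_attributes <- function(record, pads, params = impact_params(),
                            fp_floor = 50) {
  sth <- soft_tissue_thickness(record$bmi, record$gender)
  fat <- attenuation_force(sth)
  fpk <- peak_impact_force(record$weight, record$height, record$gender, params)
  fp <- suppressWarnings(attenuated_force(fpk, fat))
  flagged <- fp < fp_floor
  if (flagged) fp <- fp_floor
  ## keep the chain identity FP = FPK - FAT exact even when floored:
  ## flooring adjusts FAT, the least-certain link of the chain
  if (flagged) fat <- fpk - fp
  hp <- hip_pressure(fp, pads)
  list(STH = sth, FPK = fpk, FAT = fat, FP = fp, HP = hp, flagged = flagged)
}
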