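#' Convert raw gauge counts to microstrain
#'
#' Strain bridges record digital counts; the strain is the count difference
#' from the zero-load reading divided by the bridge sensitivity
#' (545.4 counts per microstrain for the acquisition system emulated here).
#'
#' @param peak_counts,zero_counts Integer counts at peak load and at zero load.
#' @param sensitivity Counts per microstrain, > 0.
#' @return Microstrain, sign preserved.
#' @export
#' @examples
#' counts_to_microstrain(5454, 0, 545.4)  # 10
counts_to_microstrain <- function(peak_counts, zero_counts, sensitivity = 545.4) {
  if (!is.numeric(sensitivity) || any(sensitivity <= 0))
    stop("sensitivity must be > 0 (counts per microstrain)")
  (peak_counts - zero_counts) / sensitivity
}

#' Reduce a 45-degree rectangular rosette to principal strains
#'
#' For channels A (0 degrees, along the shaft axis), B (+45) and C (+90):
#' `e1,2 = (eA + eC)/2 +- sqrt((eA - eB)^2 + (eB - eC)^2) / sqrt(2)` and
#' `tan(2 theta) = (2 eB - eA - eC) / (eA - eC)` with theta measured from the
#' gauge-A axis, counterclockwise positive.
#'
#' @param eA,eB,eC Channel strains (any consistent unit; microstrain here).
#' @return An object of class `surface_state`: list with `principal_strains`
#'   (`e1 >= e2`), `principal_angle_deg`, and `vm_stress = NA` until
#'   [surface_vm_stress()] is applied.
#' @export
rosette_principal <- function(eA, eB, eC) {
  stopifnot(is.finite(eA), is.finite(eB), is.finite(eC))
  center <- (eA + eC) / 2
  radius <- sqrt((eA - eB)^2 + (eB - eC)^2) / sqrt(2)
  theta <- 0.5 * atan2(2 * eB - eA - eC, eA - eC) * 180 / pi
  structure(
    list(principal_strains = c(e1 = center + radius, e2 = center - radius),
         principal_angle_deg = theta,
         vm_stress = NA_real_),
    class = "surface_state")
}

#' Forward-project a surface strain state onto rosette channels
#'
#' Normal strain at angle `theta` from the x axis:
#' `e(theta) = (ex + ey)/2 + (ex - ey)/2 cos(2 theta) + (gxy / 2) sin(2 theta)`.
#' Used to simulate what a 0/45/90 rosette glued at `angle_deg` would read;
#' also the independent check that rosette reduction inverts it.
#'
#' @param ex,ey Normal strains on the x/y axes.
#' @param gxy Engineering shear strain.
#' @param angle_deg Rosette orientation: gauge A at this angle from x.
#' @return Numeric `c(eA, eB, eC)`.
#' @export
rosette_channels <- function(ex, ey, gxy = 0, angle_deg = 0) {
  at <- function(th) {
    t2 <- 2 * th * pi / 180
    (ex + ey) / 2 + (ex - ey) / 2 * cos(t2) + gxy / 2 * sin(t2)
  }
  c(eA = at(angle_deg), eB = at(angle_deg + 45), eC = at(angle_deg + 90))
}

#' Surface von Mises stress from principal strains (plane stress)
#'
#' `s1 = E (e1 + nu e2) / (1 - nu^2)`, `s2 = E (e2 + nu e1) / (1 - nu^2)`,
#' `vm = sqrt(s1^2 - s1 s2 + s2^2)`. Strains are interpreted as absolute
#' strain if `microstrain = FALSE` (default is microstrain input, output MPa).
#'
#' @param state A `surface_state` from [rosette_principal()], or a length-2
#'   numeric `c(e1, e2)`.
#' @param E Young's modulus in MPa.
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @param microstrain Are the strains in microstrain? Default TRUE.
#' @return If `state` is a `surface_state`, the state with `vm_stress` (MPa)
#'   filled; otherwise the von Mises stress in MPa.
#' @export
surface_vm_stress <- function(state, E, nu, microstrain = TRUE) {
  if (E <= 0) stop("E must be > 0")
  if (nu < 0 || nu >= 0.5) stop("nu must lie in [0, 0.5)")
  eps <- if (inherits(state, "surface_state")) state$principal_strains else state
  stopifnot(length(eps) == 2L)
  scale <- if (microstrain) 1e-6 else 1
  e1 <- eps[[1]] * scale; e2 <- eps[[2]] * scale
  s1 <- E * (e1 + nu * e2) / (1 - nu^2)
  s2 <- E * (e2 + nu * e1) / (1 - nu^2)
  vm <- sqrt(s1^2 - s1 * s2 + s2^2)
  if (inherits(state, "surface_state")) {
    state$vm_stress <- vm
    state
  } else vm
}

#' Point stress ratio implanted / intact
#'
#' The von Mises stress of the implanted femur divided by that of the intact
#' bone at the same point. Ratios above 1 mean the point sees more stress
#' after implantation, i.e. no stress shielding there.
#'
#' @param implanted_vm,intact_vm von Mises stresses in MPa.
#' @return A list: `ratio` and logical `shielded` (`ratio < 1`).
#' @export
stress_ratio <- function(implanted_vm, intact_vm) {
  if (any(intact_vm <= 0))
    stop("undefined stress ratio: intact von Mises stress must be > 0")
  r <- implanted_vm / intact_vm
  list(ratio = r, shielded = r < 1)
}

#' Average repeated rosette records
#'
#' Channel-wise arithmetic mean over repeated measurements of the same site
#' and load step (the acquisition protocol takes five repeats per
#' configuration). Optionally a median for outlier robustness.
#'
#' @param records Data frame with columns `site`, `load_step_n`, `eA_ue`,
#'   `eB_ue`, `eC_ue`, one row per repeat.
#' @param fun `"mean"` (default) or `"median"`.
#' @return One-row data frame with the aggregated channels and a `repeats`
#'   count.
#' @export
average_repeats <- function(records, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  if (nrow(records) < 1) stop("need at least one record")
  if (length(unique(records$site)) != 1L)
    stop("cannot aggregate records from mixed sites")
  if (!is.null(records$load_step_n) &&
      length(unique(records$load_step_n)) != 1L)
    stop("cannot aggregate records from mixed load steps")
  f <- if (fun == "mean") mean else stats::median
  out <- records[1, , drop = FALSE]
  for (ch in c("eA_ue", "eB_ue", "eC_ue")) out[[ch]] <- f(records[[ch]])
  out$repeats <- nrow(records)
  rownames(out) <- NULL
  out
}
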