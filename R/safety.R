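#' Fatigue parameters for the stem safety analysis
#'
#' Stress ratio `R = sigma_min / sigma_max` of the load cycle (0.1 here:
#' 230 N trough, 2300 N peak), yield strength and endurance limit of the stem
#' material (PEEK: 85.5 MPa and 70 MPa at the 5e6-cycle qualification).
#'
#' @param stress_ratio_R Cycle stress ratio, in `[0, 1]`.
#' @param yield_strength Yield strength sigma_y in MPa, > 0.
#' @param endurance_limit Endurance limit sigma_N in MPa, `0 < sigma_N <=
#'   sigma_y`.
#' @return An object of class `fatigue_params`.
#' @export
fatigue_params <- function(stress_ratio_R = 0.1, yield_strength = 85.5,
                           endurance_limit = 70) {
  if (stress_ratio_R < 0 || stress_ratio_R > 1)
    stop("stress_ratio_R must lie in [0, 1]")
  if (yield_strength <= 0) stop("yield_strength must be > 0")
  if (endurance_limit <= 0 || endurance_limit > yield_strength)
    stop("endurance_limit must satisfy 0 < sigma_N <= sigma_y")
  structure(list(stress_ratio_R = stress_ratio_R,
                 yield_strength = yield_strength,
                 endurance_limit = endurance_limit),
            class = "fatigue_params")
}

#' Static yield factor of safety
#'
#' `FoS_yield = sigma_yield / sigma_max`. Elements with non-positive stress
#' are returned as Inf (unstressed, excluded from minima by the caller).
#'
#' @param sigma_max Maximum von Mises stress in MPa.
#' @param sigma_yield Yield strength in MPa.
#' @return Factor of safety (vectorized).
#' @export
#' @examples
#' yield_fos(82.3, 85.5)  # 1.04
yield_fos <- function(sigma_max, sigma_yield) {
  out <- sigma_yield / sigma_max
  out[sigma_max <= 0] <- Inf
  out
}

#' Mean and alternating stress of a proportional load cycle
#'
#' For a linear-elastic model the trough stress scales with the load:
#' `sigma_min = R * sigma_max`; then `sigma_m = (sigma_max + sigma_min) / 2`
#' and `sigma_a = (sigma_max - sigma_min) / 2`.
#'
#' @param sigma_max Peak von Mises stress in MPa, >= 0.
#' @param params A [fatigue_params()].
#' @return Data frame with `sigma_min`, `sigma_m`, `sigma_a` (MPa).
#' @export
cyclic_stresses <- function(sigma_max, params = fatigue_params()) {
  if (any(sigma_max < 0)) stop("sigma_max must be >= 0")
  sigma_min <- params$stress_ratio_R * sigma_max
  data.frame(sigma_min = sigma_min,
             sigma_m = (sigma_max + sigma_min) / 2,
             sigma_a = (sigma_max - sigma_min) / 2)
}

#' Soderberg fatigue factor of safety
#'
#' `FoS = 1 / (sigma_a / sigma_N + sigma_m / sigma_y)`: the conservative
#' fatigue line joining the endurance limit on the alternating axis to the
#' yield strength on the mean axis. A point with FoS < 1 sits above the line
#' and is predicted to fail in fatigue.
#'
#' @param sigma_a Alternating stress in MPa, >= 0.
#' @param sigma_m Mean stress in MPa, >= 0.
#' @param params A [fatigue_params()].
#' @return Factor of safety (Inf where both stresses are zero).
#' @export
#' @examples
#' soderberg_fos(34.2, 41.8, fatigue_params(0.1, 85.5, 70))  # 1.023
soderberg_fos <- function(sigma_a, sigma_m, params = fatigue_params()) {
  if (any(sigma_a < 0) || any(sigma_m < 0))
    stop("sigma_a and sigma_m must be >= 0")
  denom <- sigma_a / params$endurance_limit + sigma_m / params$yield_strength
  out <- 1 / denom
  out[denom == 0] <- Inf
  out
}

#' Per-element safety map of the stem
#'
#' Applies the cyclic-stress decomposition and both factors of safety to
#' every element of a stem stress field taken at peak load, attaching the
#' Soderberg-diagram coordinates (sigma_m, sigma_a).
#'
#' @param field Element field table of the stem at peak load (e.g. the
#'   `stem_field` of [generate_paired_fields()]).
#' @param params A [fatigue_params()].
#' @return Data frame: `element_id`, `vm_stress_max`, `vm_stress_min`,
#'   `sigma_m`, `sigma_a`, `fos_yield`, `fos_soderberg`, `volume`.
#' @export
safety_map <- function(field, params = fatigue_params()) {
  if (is.null(field) || nrow(field) == 0)
    stop("empty stem selection: no elements to map")
  cyc <- cyclic_stresses(field$vm_stress, params)
  data.frame(element_id = field$element_id,
             vm_stress_max = field$vm_stress,
             vm_stress_min = cyc$sigma_min,
             sigma_m = cyc$sigma_m,
             sigma_a = cyc$sigma_a,
             fos_yield = yield_fos(field$vm_stress, params$yield_strength),
             fos_soderberg = soderberg_fos(cyc$sigma_a, cyc$sigma_m, params),
             volume = field$volume)
}

#' Fraction of the stem predicted unsafe in fatigue
#'
#' Fraction of elements (count weighting, default) or of element volume with
#' a Soderberg factor of safety below 1.
#'
#' @param map A [safety_map()] data frame.
#' @param weight `"count"` or `"volume"`.
#' @return Unsafe fraction in `[0, 1]`.
#' @export
unsafe_fraction <- function(map, weight = c("count", "volume")) {
  weight <- match.arg(weight)
  if (nrow(map) == 0) stop("empty safety map")
  unsafe <- map$fos_soderberg < 1
  if (weight == "count") mean(unsafe)
  else sum(map$volume[unsafe]) / sum(map$volume)
}

#' Minimum factors of safety over the stem
#'
#' Element minimum of both factors of safety, ignoring infinite values
#' (unstressed elements); ties broken by element id.
#'
#' @param map A [safety_map()] data frame.
#' @return List with `fos_yield`, `fos_soderberg`, and the element ids
#'   achieving them.
#' @export
min_fos <- function(map) {
  pick <- function(col) {
    ok <- is.finite(map[[col]])
    if (!any(ok)) return(list(value = Inf, element_id = NA_integer_))
    sub <- map[ok, ]
    sub <- sub[order(sub[[col]], sub$element_id), ][1, ]
    list(value = sub[[col]], element_id = sub$element_id)
  }
  y <- pick("fos_yield"); s <- pick("fos_soderberg")
  list(fos_yield = y$value, fos_yield_element = y$element_id,
       fos_soderberg = s$value, fos_soderberg_element = s$element_id)
}
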