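#' Parameters of the dead-zone remodeling rule
#'
#' `dead_zone_s` is the tolerated band of strain-energy change within which
#' no remodeling occurs (0.6 is the clinically derived typical value);
#' resorption requires `S_implanted < (1 - s) * S_intact`. `strain_floor` is
#' the minimum `|eps_intact|` accepted before an element is flagged excluded
#' (guards the strain-energy ratio against unloaded elements).
#'
#' @param dead_zone_s Dead zone half-width s, in (0, 1). Default 0.6.
#' @param strain_floor Minimum valid `|eps_intact|` (absolute strain).
#' @return An object of class `remodeling_params`.
#' @export
remodeling_params <- function(dead_zone_s = 0.6, strain_floor = 1e-9) {
  if (dead_zone_s <= 0 || dead_zone_s >= 1)
    stop("dead_zone_s must lie in (0, 1)")
  if (strain_floor < 0) stop("strain_floor must be >= 0")
  structure(list(dead_zone_s = dead_zone_s, strain_floor = strain_floor),
            class = "remodeling_params")
}

#' Strain-energy ratio after vs before implantation
#'
#' `S_implanted / S_intact = (eps_implanted / eps_intact)^2`, computed from
#' the principal compressive strains. Elements whose intact strain magnitude
#' is at or below the floor are returned as NA (excluded), never divided.
#'
#' @param eps_implanted,eps_intact Signed principal compressive strains.
#' @param strain_floor Minimum valid `|eps_intact|`.
#' @return Numeric vector of energy ratios (NA where excluded).
#' @export
strain_energy_ratio <- function(eps_implanted, eps_intact, strain_floor = 1e-9) {
  ok <- abs(eps_intact) > strain_floor
  out <- rep(NA_real_, length(eps_intact))
  out[ok] <- (eps_implanted[ok] / eps_intact[ok])^2
  out
}

#' Dead-zone resorption indicator
#'
#' The resorptive function f: with `x = energy_ratio / (1 - s)`, f = 1 when
#' x < 1 (the local unloading exceeds the dead zone, bone resorbs) and 0 when
#' x >= 1 (no remodeling). With s = 0.6 resorption requires an energy ratio
#' below 0.4.
#'
#' @param energy_ratio Non-negative strain-energy ratio(s); NA propagates.
#' @param params A [remodeling_params()].
#' @return Integer 0/1 vector (NA where the ratio is NA).
#' @export
resorption_indicator <- function(energy_ratio, params = remodeling_params()) {
  if (any(energy_ratio < 0, na.rm = TRUE))
    stop("energy_ratio must be >= 0")
  x <- energy_ratio / (1 - params$dead_zone_s)
  as.integer(x < 1)
}

#' Resorbed bone mass fraction of a Gruen zone
#'
#' Mass-weighted fraction of the zone's cortical bone flagged as resorbing:
#' `m_r = sum(f_e rho_e V_e) / sum(rho_e V_e)` over valid elements, with
#' excluded elements (intact strain below the floor) removed from both sums
#' and counted.
#'
#' @param paired A [paired_fields()] object.
#' @param zone Gruen zone, 1-7.
#' @param params A [remodeling_params()].
#' @return One-row data frame: `zone`, `resorbed_mass_fraction`,
#'   `resorbing_mass` (g), `total_mass` (g), `excluded_elements`.
#' @export
resorbed_mass_fraction <- function(paired, zone, params = remodeling_params()) {
  stopifnot(inherits(paired, "paired_fields"))
  sel <- paired$intact$zone == zone & paired$intact$side != "interior"
  if (!any(sel)) stop("no cortical elements in zone ", zone)
  e_int <- paired$intact$comp_strain[sel]
  e_imp <- paired$implanted$comp_strain[sel]
  ratio <- strain_energy_ratio(e_imp, e_int, params$strain_floor)
  f <- resorption_indicator(ratio, params)
  valid <- !is.na(f)
  if (!any(valid))
    stop("undefined resorbed fraction: every element in zone ", zone,
         " was excluded by the strain floor")
  # g = (g/mL) * mm^3 / 1000
  mass <- paired$intact$density[sel][valid] *
    paired$intact$volume[sel][valid] / 1000
  data.frame(zone = zone,
             resorbed_mass_fraction = sum(f[valid] * mass) / sum(mass),
             resorbing_mass = sum(f[valid] * mass),
             total_mass = sum(mass),
             excluded_elements = sum(!valid))
}

#' Per-zone resorption report with totals
#'
#' @param paired A [paired_fields()] object.
#' @param zones Gruen zones to include; default 1:7.
#' @param params A [remodeling_params()].
#' @param weighting `"mass"` (default) or `"volume"` for the total across
#'   zones.
#' @return Data frame of per-zone rows; the mass- (or volume-) weighted total
#'   resorbed fraction is attached as attribute `total`.
#' @export
resorption_report <- function(paired, zones = 1:7,
                              params = remodeling_params(),
                              weighting = c("mass", "volume")) {
  weighting <- match.arg(weighting)
  rep <- do.call(rbind,
                 lapply(zones, function(z) resorbed_mass_fraction(paired, z, params)))
  w <- if (weighting == "mass") rep$total_mass else {
    vapply(zones, function(z) {
      sel <- paired$intact$zone == z & paired$intact$side != "interior"
      sum(paired$intact$volume[sel])
    }, numeric(1))
  }
  attr(rep, "total") <- sum(rep$resorbed_mass_fraction * w) / sum(w)
  rep
}

#' Bone loss reduction of a candidate stem vs a reference stem
#'
#' `(m_r_reference - m_r_candidate) / m_r_reference`. Zones whose reference
#' resorption is zero (typically the distal zone 4) have no defined
#' reduction and are reported as NA.
#'
#' @param mr_reference,mr_candidate Resorbed mass fractions.
#' @return Reduction as a fraction (1 = complete elimination), NA where the
#'   reference fraction is zero.
#' @export
bone_loss_reduction <- function(mr_reference, mr_candidate) {
  out <- (mr_reference - mr_candidate) / mr_reference
  out[mr_reference == 0] <- NA_real_
  out
}
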