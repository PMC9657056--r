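#' Volume-weighted mean von Mises stress
#'
#' `sum(sigma_e * V_e) / sum(V_e)` over the selected cortical elements, using
#' the element-centroid stress as the element integral estimate.
#'
#' @param table Element field table.
#' @param zone Optional Gruen zone (1-7) restricting the selection.
#' @param cortical_only Drop `side == "interior"` elements first? Default TRUE
#'   (stress shielding is evaluated on cortical bone).
#' @return Mean stress in MPa.
#' @export
volume_weighted_mean <- function(table, zone = NULL, cortical_only = TRUE) {
  sel <- table
  if (cortical_only) sel <- sel[sel$side != "interior", ]
  if (!is.null(zone)) sel <- sel[!is.na(sel$zone) & sel$zone == zone, ]
  if (nrow(sel) == 0) stop("empty element selection for the volume average")
  sum(sel$vm_stress * sel$volume) / sum(sel$volume)
}

#' Stress Shielding Increase for one Gruen zone
#'
#' `SSI = (<sigma_intact> - <sigma_implanted>) / <sigma_intact>` with
#' volume-weighted zone means. Positive SSI means the zone is shielded
#' (carries less stress than before implantation); negative SSI means a local
#' stress rise.
#'
#' @param paired A [paired_fields()] object.
#' @param zone Gruen zone, 1-7.
#' @return One-row data frame: `zone`, `mean_vm_intact`, `mean_vm_implanted`,
#'   `ssi`, `volume`.
#' @export
zone_ssi <- function(paired, zone) {
  stopifnot(inherits(paired, "paired_fields"))
  m_int <- volume_weighted_mean(paired$intact, zone)
  m_imp <- volume_weighted_mean(paired$implanted, zone)
  if (m_int == 0) stop("undefined SSI: intact zone mean stress is zero")
  sel <- paired$intact[paired$intact$zone == zone & paired$intact$side != "interior", ]
  data.frame(zone = zone,
             mean_vm_intact = m_int,
             mean_vm_implanted = m_imp,
             ssi = (m_int - m_imp) / m_int,
             volume = sum(sel$volume))
}

#' Per-zone SSI report
#'
#' Computes [zone_ssi()] for every requested zone and attaches cortical
#' volume fractions over the included zones (they sum to 1).
#'
#' @param paired A [paired_fields()] object.
#' @param zones Integer vector of Gruen zones; default 1:7.
#' @return Data frame with one row per zone plus a `volume_fraction` column.
#' @export
ssi_report <- function(paired, zones = 1:7) {
  if (anyDuplicated(zones)) stop("duplicate zones in the report request")
  rep <- do.call(rbind, lapply(zones, function(z) zone_ssi(paired, z)))
  rep$volume_fraction <- rep$volume / sum(rep$volume)
  rep
}

#' Total SSI across Gruen zones
#'
#' Volume-fraction-weighted sum of the per-zone SSI values,
#' `sum(ssi_z * V_z) / sum(V_z)`, over the zones present in the report.
#'
#' @param reports A data frame from [ssi_report()] (or rbind of [zone_ssi()]
#'   rows with a `volume` column).
#' @return Total SSI as a signed fraction.
#' @export
total_ssi <- function(reports) {
  if (anyDuplicated(reports$zone)) stop("duplicate zones in SSI reports")
  vf <- reports$volume / sum(reports$volume)
  sum(reports$ssi * vf)
}
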