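# Shared fixtures: tiny element tables, a hand-rolled single-region beam
# model, and a brute-force Mohr-circle oracle for rosette reduction.

make_table <- function(n, vm_stress = 1, comp_strain = -1e-3, zone = 1L,
                       volume = 1, density = 1.64, side = "medial",
                       z = 10) {
  data.frame(element_id = seq_len(n),
             zone = rep_len(zone, n),
             z = rep_len(z, n),
             side = rep_len(side, n),
             volume = rep_len(volume, n),
             density = rep_len(density, n),
             vm_stress = rep_len(vm_stress, n),
             comp_strain = rep_len(comp_strain, n),
             material = rep_len("cortical", n),
             stringsAsFactors = FALSE)
}

# round as printed results do (half away from zero), not half-to-even
round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# one-station, one-region model: a plain elastic bar of area `area`
bar_model <- function(E = 1000, area = 100, inertia = 1000, z = 50, dz = 100) {
  structure(
    list(stations = list(list(
      z = z, dz = dz,
      regions = data.frame(material = "bar", area = area,
                           i_x = inertia, i_y = inertia,
                           r_in = 0.9 * sqrt(area / pi), r_out = sqrt(area / pi),
                           surface = "cortex", stringsAsFactors = FALSE))),
      working_length = z + dz / 2, stem_tip_z = NA_real_,
      configuration = "intact", stem_material = NA_character_),
    class = "cross_section_model")
}

bar_materials <- function(E = 1000, nu = 0.3) {
  list(bar = material_spec("bar", E, nu, 1.0))
}

# brute-force principal strains: scan the normal strain over a fine angle
# grid instead of using the closed-form reduction
mohr_oracle <- function(ex, ey, gxy) {
  th <- seq(0, 180, by = 0.001) * pi / 180
  e <- (ex + ey) / 2 + (ex - ey) / 2 * cos(2 * th) + gxy / 2 * sin(2 * th)
  c(e1 = max(e), e2 = min(e))
}

# planted-fraction paired fields: q of the mass resorbs (energy ratio 0.25),
# the rest is untouched (ratio 1); all elements share mass and zone
planted_pair <- function(q, n = 8, zone = 1L) {
  stopifnot((q * n) %% 1 == 0)
  intact <- make_table(n, zone = zone, comp_strain = -1e-3)
  implanted <- intact
  k <- q * n
  ratio <- c(rep(0.5, k), rep(1, n - k))   # strain ratio; energy is square
  implanted$comp_strain <- intact$comp_strain * ratio
  implanted$vm_stress <- intact$vm_stress * ratio
  paired_fields(intact, implanted)
}
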