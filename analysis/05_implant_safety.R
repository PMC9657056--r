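#!/usr/bin/env Rscript
# Static yield and Soderberg fatigue factors of safety for the PEEK stem:
# worked values at the reported peak stresses, then the per-element safety
# map of the synthetic stem field at 2300 N (R = 0.1 cycle).

suppressPackageStartupMessages(library(femshield))
dir.create("results", showWarnings = FALSE)

fat <- fatigue_params(stress_ratio_R = 0.1, yield_strength = 85.5,
                      endurance_limit = 70)

# worked values at the peak stresses reported for the PEEK stem's neck and
# distal restriction point
for (s in c(82.3, 76)) {
  cyc <- cyclic_stresses(s, fat)
  cat(sprintf("sigma_max %.1f MPa: FoS_yield %.2f; sigma_m %.1f, sigma_a %.1f -> FoS_Soderberg %.3f\n",
              s, yield_fos(s, fat$yield_strength), cyc$sigma_m, cyc$sigma_a,
              soderberg_fos(cyc$sigma_a, cyc$sigma_m, fat)))
}

# safety map over the synthetic stem field
pr <- generate_paired_fields(femur_geometry(), "PEEK", load_case(2300),
                             seed = 1L)
map <- safety_map(pr$stem_field, fat)
utils::write.csv(map, "results/safety_map_peek.csv", row.names = FALSE)

mf <- min_fos(map)
cat(sprintf("\nsynthetic PEEK stem field (%d elements):\n", nrow(map)))
cat(sprintf("  min FoS_yield %.2f (element %d), min FoS_Soderberg %.2f (element %d)\n",
            mf$fos_yield, mf$fos_yield_element,
            mf$fos_soderberg, mf$fos_soderberg_element))
cat(sprintf("  unsafe fraction: %.2f%% by count, %.2f%% by volume\n",
            100 * unsafe_fraction(map, "count"),
            100 * unsafe_fraction(map, "volume")))
cat("the beam model has no neck/taper stress concentration, so its stem\n")
cat("stresses stay far below yield; the worked values above carry the\n")
cat("reported peak stresses through the same FoS chain\n")
cat("Soderberg diagram data written to results/safety_map_peek.csv\n")
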