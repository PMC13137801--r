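#!/usr/bin/env Rscript
# Band alignment on the NHE scale and ROS half-reaction feasibility for the
# two compositions, plus Tauc bandgap extraction from synthetic absorption
# edges at the two optical gaps.

library(pyrofield)

dir.create("results", showWarnings = FALSE)

materials <- list(
  bto = band_alignment(vbm_nhe = 1.86, bandgap = 3.29),
  btz = band_alignment(vbm_nhe = 1.99, bandgap = 3.15))

reports <- lapply(names(materials), function(m) {
  al <- materials[[m]]
  rep <- ros_feasibility(al, redox_ladder())
  message(sprintf("%s: VBM %+0.2f V, CBM %+0.2f V (vs NHE); feasible: %s",
                  toupper(m), al$vbm_nhe, al$cbm_nhe,
                  paste(rep$reaction[rep$feasible], collapse = ", ")))
  list(alignment = al[c("vbm_nhe", "cbm_nhe", "bandgap")],
       reactions = rep)
})
names(reports) <- names(materials)
jsonlite::write_json(reports, "results/band_alignment_report.json",
                     auto_unbox = TRUE, digits = NA)

# Tauc extraction from noisy synthetic edges at the two optical gaps
tauc_rows <- do.call(rbind, lapply(
  list(c(mat = "bto", eg = 3.29), c(mat = "btz", eg = 3.15)),
  function(cs) {
    eg <- as.numeric(cs[["eg"]])
    est <- vapply(1:20, function(seed) {
      as.numeric(tauc_bandgap(make_spectrum(eg, "direct",
                                            noise_sd = 0.01,
                                            seed = seed)))
    }, numeric(1))
    data.frame(material = cs[["mat"]], true_gap = eg,
               mean_estimate = mean(est), sd_estimate = sd(est),
               max_abs_error = max(abs(est - eg)))
  }))
write.csv(tauc_rows, "results/tauc_extraction.csv", row.names = FALSE)
message(sprintf(
  "Tauc recovery at 1%% noise: BTO %.3f eV, BTZ %.3f eV (difference %.3f eV)",
  tauc_rows$mean_estimate[1], tauc_rows$mean_estimate[2],
  tauc_rows$mean_estimate[1] - tauc_rows$mean_estimate[2]))
message("wrote results/band_alignment_report.json and results/tauc_extraction.csv")
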