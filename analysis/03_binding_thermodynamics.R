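#!/usr/bin/env Rscript
# Double-logarithm binding parameters per temperature, van't Hoff
# thermodynamics and force classification; renders the summary table and
# the diagnostic comparing a van't Hoff refit of the published K_A values
# with the published (dH, dS).

suppressPackageStartupMessages(library(quenchbind))

study_dir <- "results/synthetic_study"
dirs <- list.dirs(study_dir, recursive = FALSE)
stopifnot(length(dirs) > 0)

param_rows <- list(); reports <- list()
for (d in dirs) {
  cx <- sub("_", "/", basename(d))
  files <- list.files(d, pattern = "^titration_.*K\\.csv$", full.names = TRUE)
  binding <- lapply(files, function(f) hill_fit(read_titration(f)))
  binding <- binding[order(vapply(binding, `[[`, numeric(1), "temperature_K"))]
  th <- thermo_analysis(binding)
  for (b in binding) {
    tk <- as.character(b$temperature_K)
    param_rows[[length(param_rows) + 1L]] <- data.frame(
      complex = cx, temperature_K = b$temperature_K, K_A = b$K_A, n = b$n,
      delta_G = th$delta_G_by_T[[tk]], delta_G_from_K = th$delta_G_from_K[[tk]],
      delta_H = th$delta_H, delta_S = th$delta_S,
      force_class = th$force_class$label, r_squared = b$r_squared)
  }
  reports[[cx]] <- structure(list(label = cx, binding = binding,
                                  thermodynamics = th),
                             class = "study_report")
}
params <- do.call(rbind, param_rows)
write.csv(params, "results/binding_parameters.csv", row.names = FALSE)
tab <- render_binding_table(reports)
writeLines(tab, "results/binding_table.txt")

# Diagnostic: the published (dH, dS) are not the OLS van't Hoff fit of the
# published K_A triples; report both without reconciling.
ref <- reference_binding_params()
refit <- do.call(rbind, lapply(split(ref, ref$complex), function(cx) {
  vh <- vant_hoff_fit(cx$temperature_K, cx$K_A)
  data.frame(complex = cx$complex[1],
             published_dH = cx$delta_H[1], refit_dH = vh$delta_H,
             published_dS = cx$delta_S[1], refit_dS = vh$delta_S,
             refit_r_squared = vh$r_squared)
}))
write.csv(refit, "results/vant_hoff_refit.csv", row.names = FALSE)

cat("Recovered binding/thermodynamic parameters (synthetic study):\n\n")
writeLines(tab)
cat("\nAll four complexes: dH < 0 and dS < 0 -> hydrogen-bond/van der Waals\n")
cat("binding, spontaneous (dG < 0) at all temperatures.\n\n")
cat("Note: refitting the published K_A triples by van't Hoff gives dH values\n")
cat("differing from the published ones (e.g. EPX/HSA refit ",
    sprintf("%.1f", refit$refit_dH[refit$complex == "EPX/HSA"]),
    " vs published -105.74 kJ/mol);\n", sep = "")
cat("see results/vant_hoff_refit.csv. Tables: results/binding_parameters.csv,\n")
cat("results/binding_table.txt\n")
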