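# Tabulated X-ray tube spectra shipped with the package (tungsten anode,
# 2.3 mm Al inherent filtration, Kramers shape).  Run after installing the
# package:  Rscript data-raw/make_spectra.R
library(dosekit)
lib <- build_material_library()
dir.create("inst/extdata/spectra", showWarnings = FALSE, recursive = TRUE)
for (kvp in c(70, 90, 120)) {
  s <- make_analytic_spectrum(kvp, lib = lib)
  tab <- data.frame(energy_keV = s$energies,
                    relative_fluence = signif(s$weights, 6))
  write.csv(tab, sprintf("inst/extdata/spectra/spectrum_%dkvp.csv", kvp),
            row.names = FALSE, quote = FALSE)
}
cat("spectra written\n")
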