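#!/usr/bin/env Rscript
# Stage 5: chemical-shift-perturbation mapping of the antitoxin peptide
# titration at the 1:1 analysis point.
#
# Combined 1H/15N shift changes use the nitrogen weight 6.51; the
# intensity attenuation is smoothed with a 5-residue sliding window.
# Hotspots (mean + 1 SD) mark the binding site.

suppressPackageStartupMessages(library(ensdyn))
dir.create("results", showWarnings = FALSE)

free <- read_peak_list("results/fixtures/hsqc_free.csv")
bound <- read_peak_list("results/fixtures/hsqc_bound_1to1.csv")

prof <- csp(free, bound)
utils::write.csv(prof, "results/csp_profile.csv", row.names = FALSE)

hot_shift <- hotspot_call(prof, metric = "csp")
hot_int <- hotspot_call(prof, metric = "intensity")

runs <- function(x) {
  if (!length(x)) return("none")
  b <- cumsum(c(1, diff(x) != 1))
  paste(vapply(split(x, b), function(r)
    if (length(r) > 1) paste0(min(r), "-", max(r)) else as.character(r),
    character(1)), collapse = ", ")
}
cat("Largest combined shift changes (mean + 1 SD):", runs(hot_shift),
    "\n")
cat("Strongest windowed intensity losses:", runs(hot_int), "\n")
cat(sprintf("Median intensity ratio at 1:1: %.2f\n",
            stats::median(prof$intensity_ratio, na.rm = TRUE)))

truth <- jsonlite::read_json("results/fixtures/manifest.json",
                             simplifyVector = TRUE)$site_residues
jac <- length(intersect(hot_shift, truth)) /
  length(union(hot_shift, truth))
cat(sprintf("Overlap with the generator's binding site (Jaccard): %.2f\n",
            jac))
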