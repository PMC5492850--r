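#!/usr/bin/env Rscript
# Stage 5: codon-level selection analyses.
#
# Within each dicot/grass subgroup, all pairwise ML dN/dS values are
# computed (pairs with dS > 2 discarded as saturated); the one-ratio
# branch model is compared with a dicot/grass multi-ratio model by LRT.
# Enable fit_switching in analysis/config.yaml to add the M3 vs M3+S1
# comparison with clade-specific positive-site lists (considerably
# slower).

library(cogevol)
cfg <- validate_config("analysis/config.yaml")
cfg$stages <- "selection"
mf <- run_pipeline(cfg)
print(mf)

bm <- read.delim(file.path(cfg$out_dir, "selection", "branch_models.tsv"))
cat("branch-model fits (one-ratio vs dicot/grass ratios):\n")
print(bm)
pw <- read.delim(file.path(cfg$out_dir, "selection", "pairwise_omega.tsv"))
cat("\nper-subgroup mean pairwise omega:\n")
print(pw[, c("cog_id", "partition", "n_members", "n_pairs", "n_excluded",
             "mean_omega")])
sw <- file.path(cfg$out_dir, "selection", "switching_models.tsv")
if (file.exists(sw)) {
  cat("\nM3 vs M3+S1 fits:\n")
  print(read.delim(sw))
}
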