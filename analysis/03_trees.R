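#!/usr/bin/env Rscript
# Stage 3: per-COG phylogenies.
#
# Filters alignment columns by the 0-100 conservation score (threshold
# 12), estimates pairwise JTT ML distances, builds the NJ tree and
# attaches bootstrap supports.

library(cogevol)
cfg <- validate_config("analysis/config.yaml")
cfg$stages <- "trees"
mf <- run_pipeline(cfg)
print(mf)

trees <- ape::read.tree(file.path(cfg$out_dir, "trees", "cog_trees.nwk"))
if (inherits(trees, "phylo")) trees <- list(trees)
ids <- readLines(file.path(cfg$out_dir, "trees", "cog_ids.txt"))
for (k in seq_along(trees)) {
  sup <- suppressWarnings(as.numeric(trees[[k]]$node.label))
  cat(sprintf("%s: %d tips, median bootstrap %.0f%%\n", ids[k],
              ape::Ntip(trees[[k]]), stats::median(sup, na.rm = TRUE)))
}
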