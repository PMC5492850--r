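#!/usr/bin/env Rscript
# Stage 2: sequence filtering and COG construction.
#
# Applies the short-sequence (< 400 nt) and allele (> 95% identity,
# indel-free) filters, scores all protein pairs by Smith-Waterman, builds
# the BeT graph and merges reciprocal-BeT triangles into COGs.

library(cogevol)
cfg <- validate_config("analysis/config.yaml")
cfg$stages <- c("filter", "cogs")
mf <- run_pipeline(cfg)
print(mf)

removed <- read.delim(file.path(cfg$out_dir, "filtered", "removed.tsv"))
cat("filter removals by reason:\n")
print(table(removed$reason))
rep <- read.delim(file.path(cfg$out_dir, "cogs", "cog_report.tsv"))
cat(sprintf("built %d COGs (%d complete for all 11 species)\n",
            nrow(rep), sum(rep$flag == "complete")))
print(rep)
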