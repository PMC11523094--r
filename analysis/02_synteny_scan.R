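#!/usr/bin/env Rscript

# Scan each species' W chromosome against the rest of its own genome
# (all-matches mode, as for a single-chromosome query) in the
# autosomal-pair clade, and write the chained, refined synteny blocks.

library(lepWorigin)

cladedir <- "results/clades/autosomal_shared"
if (!dir.exists(cladedir)) stop("run analysis/01_simulate_clades.R first")
dir.create("results/blocks", showWarnings = FALSE, recursive = TRUE)

cfg <- scan_config() # 1 kb windows, 45% identity floor, 20 kb chain radius

for (sp in c("sp1", "sp2", "sp3")) {
  fa <- read_genome_fasta(file.path(cladedir, paste0(sp, ".fa")))
  targets <- fa$seq[names(fa$seq) != "W"]
  blocks <- find_synteny_blocks(fa$seq["W"], targets, cfg)
  write_blocks(blocks, file.path("results/blocks", paste0(sp, ".W_blocks.tsv")))
  cov <- coverage_fraction(merge_nonoverlapping(blocks, group_by_target = FALSE),
                           nchar(fa$seq[["W"]]))
  cat(sprintf("%s: %4d blocks; %.1f%% of the W covered (unfiltered)\n",
              sp, nrow(blocks), 100 * cov))
}
cat("blocks written under results/blocks\n")
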