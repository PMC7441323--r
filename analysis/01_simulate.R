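#!/usr/bin/env Rscript
# Stage 1: build the synthetic clade that stands in for the genome panel.
#
# The default simulation mirrors the screen's study design: a focal oyster
# proteome plus 7 more ingroup genomes in three phyla (2 molluscs,
# 2 annelids, 4 flatworms) and 10 outgroup proteomes, with 14 planted
# families (5 pan-clade, 5 clade-specific, 2 chimeric, 2 fast-evolving)
# and a decoy reference database with per-sequence taxon labels.

library(trgscreen)

SEED <- 7L
outdir <- "results/sim"

cfg <- simulation_config(seed = SEED)
sim <- simulate_clade(cfg)
files <- write_simulation(sim, outdir)

cat("Simulated clade (seed", SEED, ")\n")
cat("  genomes:", length(sim$proteomes), "proteomes;",
    length(sim$genome_dna), "with scaffold DNA (unannotated genes)\n")
cat("  focal proteome:", nrow(sim$proteomes$cgig), "genes\n")
print(table(sim$truth$class))
cat("  families lost somewhere:",
    sum(tapply(sim$tip_status$status == "lost", sim$tip_status$family, any)),
    "\n")
cat("  unannotated gene copies:",
    sum(sim$tip_status$status == "unannotated"), "\n")
cat("Wrote", length(files), "files under", outdir, "\n")
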