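#!/usr/bin/env Rscript
# Stage 2: run the homology searches behind the screen and save the hit
# tables. Every focal gene is searched against each non-focal proteome
# (per-genome E-value search spaces) and against the decoy reference
# database; the 11-column TSV written here is the same contract an
# external search tool could fulfil via read_hit_table().

library(trgscreen)

SEED <- 7L
sim <- simulate_clade(simulation_config(seed = SEED))
sc <- scoring_scheme()
focal <- sim$proteomes$cgig

targets <- setdiff(names(sim$proteomes), "cgig")
hits <- do.call(rbind, lapply(targets, function(G)
  search_proteome(focal, sim$proteomes[[G]], sc)))
db_hits <- search_proteome(focal, sim$exclusion_db$records, sc)

dir.create("results", showWarnings = FALSE)
write_hit_table(hits, "results/genome_hits.tsv")
write_hit_table(db_hits, "results/decoy_hits.tsv")

cat("Searched", nrow(focal), "focal genes against", length(targets),
    "genomes and 1 decoy database\n")
cat("  genome hits:", nrow(hits), " (median E of sub-1e-7 hits:",
    format(stats::median(hits$evalue[hits$evalue < 1e-7]), digits = 3),
    ")\n")
cat("  decoy-db hits:", nrow(db_hits), "\n")
by_role <- ifelse(hits$subject_genome %in%
                    unlist(sim$sim_config$ingroup_phyla),
                  "ingroup", "outgroup")
print(tapply(hits$evalue < 1e-7, by_role, sum))
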