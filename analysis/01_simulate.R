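#!/usr/bin/env Rscript
# Stage 1: simulate the multi-cohort peptide-array study.
#
# Generates the peptide library, the per-array sample manifest (Discovery:
# 22 Canadian cases + 21 Canadian controls; Validation: 22 Norwegian cases,
# 6 Canadian cases, 7 Canadian controls, 6 US singleton controls; all
# duplicated except the US arrays; separate assay batches) and the raw
# 16-bit abundance matrix with 100 planted signature peptides.

library(immunosig)

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- default_config(seed = 1L)
write_config(cfg, "results/run_config.json")

lib <- generate_peptide_library(cfg$n_analysis, cfg$n_control,
                                cfg$peptide_length,
                                seed = derive_seed(cfg$seed, 1L))
manifest <- generate_design("paper_default")
spec <- do.call(signal_spec, c(cfg$signal,
                               list(seed = derive_seed(cfg$seed, 2L))))
sim <- simulate_abundances(lib, manifest, spec)

cat("library:", nrow(lib), "peptides (",
    sum(!lib$is_control), "analysis /", sum(lib$is_control), "control )\n")
cat("arrays:", nrow(manifest), "covering",
    length(unique(manifest$subject_id)), "subjects\n")
cat("planted signature peptides:", nrow(sim$planted), "\n")
cat("raw abundance range:", min(sim$abundance), "-", max(sim$abundance), "\n")

write_manifest(manifest, "results/manifest.csv")
writeLines(sim$planted$peptide_id, "results/planted_peptides.txt")
saveRDS(list(cfg = cfg, lib = lib, manifest = manifest, sim = sim),
        "scratch/01_simulated.rds")
cat("saved scratch/01_simulated.rds\n")
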