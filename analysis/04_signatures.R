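#!/usr/bin/env Rscript
# Stage 4: assemble method panels and build candidate signatures.
#
# Unsupervised panels keep the best separating lists (AUC within 0.02 of
# the best, up to two lists); supervised lists pass through.  The seven
# candidate signatures CPS001-CPS007 are unions/intersections of the six
# panels; empty ones are flagged excluded.

library(immunosig)

s1 <- readRDS("scratch/01_simulated.rds")
prep <- readRDS("scratch/02_preprocessed.rds")
lists <- readRDS("scratch/03_lists.rds")
cfg <- s1$cfg

disc <- prep$samples$partition == "discovery"
Xd <- prep$processed[, prep$samples$subject_id[disc]]
yd <- prep$samples$group[disc]

panels <- list(
  sPCA_panel = assemble_panel(lists$spca, Xd, yd, cfg$max_lists,
                              cfg$auc_window, name = "sPCA_panel"),
  sIPCA_panel = assemble_panel(lists$sipca, Xd, yd, cfg$max_lists,
                               cfg$auc_window, name = "sIPCA_panel"),
  GS_panel = assemble_panel(lists$gs, Xd, yd, cfg$max_lists,
                            cfg$auc_window, name = "GS_panel"),
  RL_panel = assemble_panel(list(lists$rl$list), name = "RL_panel"),
  RF_panel = assemble_panel(list(lists$rf), name = "RF_panel"),
  EN_panel = assemble_panel(list(lists$en), name = "EN_panel")
)
for (p in panels) {
  cat(sprintf("%-12s %5d peptides  (lists: %s)\n", p$name,
              length(p$peptide_ids),
              paste(p$constituent_lists, collapse = ", ")))
}

sigs <- build_candidate_signatures(panels)
summ <- signature_summary(sigs)
print(summ, row.names = FALSE)
alt <- attr(sigs, "alternative_cps001")
cat("alternative CPS001 (GS n RL n RF n EN):", length(alt$peptide_ids),
    "peptides -- reported, not carried forward\n")

write.csv(summ, "results/signature_summary.csv", row.names = FALSE)
saveRDS(list(panels = panels, sigs = sigs), "scratch/04_signatures.rds")
cat("saved scratch/04_signatures.rds\n")
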