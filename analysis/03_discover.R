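#!/usr/bin/env Rscript
# Stage 3: run the six feature selectors on the Discovery partition.
#
# Unsupervised (blind to group labels): sparse PCA, sparse IPCA, gene
# shaving -- ten lists each.  Supervised: moderated t (BH <= 0.05),
# random-forest Gini importance, elastic-net selection frequency over 100
# leave-2+2-out runs of 39 samples.

library(immunosig)

s1 <- readRDS("scratch/01_simulated.rds")
prep <- readRDS("scratch/02_preprocessed.rds")
cfg <- s1$cfg

disc <- prep$samples$partition == "discovery"
Xd <- prep$processed[, prep$samples$subject_id[disc]]
yd <- prep$samples$group[disc]
cat("discovery matrix:", nrow(Xd), "peptides x", ncol(Xd), "samples\n")

spca <- sparse_pca_lists(Xd, cfg$k_features, cfg$n_lists,
                         seed = derive_seed(cfg$seed, 3L))
sipca <- sparse_ipca_lists(Xd, cfg$k_features, cfg$n_lists,
                           seed = derive_seed(cfg$seed, 4L))
gs <- gene_shaving_lists(Xd, cfg$n_lists, cfg$shave_fraction,
                         cfg$n_permutations,
                         seed = derive_seed(cfg$seed, 5L))
rl <- moderated_t_select(Xd, yd, cfg$adj_p_threshold)
rf <- random_forest_select(Xd, yd, cfg$rf_trees,
                           seed = derive_seed(cfg$seed, 6L))
en <- elastic_net_frequency_select(Xd, yd, n_runs = cfg$en_runs,
                                   seed = derive_seed(cfg$seed, 7L))

cat("gene-shaving cluster sizes:",
    sapply(gs, function(l) length(l$peptide_ids)), "\n")
cat("moderated t: d0 =", format(rl$d0, digits = 4),
    "; peptides at BH<=0.05:", length(rl$list$peptide_ids), "\n")
cat("random forest: Gini threshold",
    format(rf$method_params$gini_threshold, digits = 3),
    "->", length(rf$peptide_ids), "peptides\n")
cat("elastic net: run size", unique(en$method_params$run_sizes),
    "->", length(en$peptide_ids), "peptides at frequency >=",
    en$method_params$freq_threshold, "\n")

planted <- s1$sim$planted$peptide_id
for (nm in c("rl", "rf", "en")) {
  l <- get(nm)
  ids <- if (nm == "rl") l$list$peptide_ids else l$peptide_ids
  cat(sprintf("%s planted overlap: %d/%d\n", toupper(nm),
              length(intersect(ids, planted)), length(planted)))
}

saveRDS(list(spca = spca, sipca = sipca, gs = gs, rl = rl, rf = rf, en = en),
        "scratch/03_lists.rds")
cat("saved scratch/03_lists.rds\n")
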