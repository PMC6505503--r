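#!/usr/bin/env Rscript
# Stage 5: evaluate the candidate signatures on both partitions.
#
# Signature scores (mean sign-adjusted processed abundance, oriented by
# labels), Mann-Whitney AUCs on Discovery and Validation, the PC1-weight
# AUC on the validation partition, and the blinded PCA/clustering view of
# the strongest candidate.

library(immunosig)

s1 <- readRDS("scratch/01_simulated.rds")
prep <- readRDS("scratch/02_preprocessed.rds")
s4 <- readRDS("scratch/04_signatures.rds")

samples <- prep$samples
X <- prep$processed
disc <- samples$partition == "discovery"
val <- samples$partition == "validation"
Xd <- X[, samples$subject_id[disc]]
yd <- samples$group[disc]
Xv <- X[, samples$subject_id[val]]
yv <- samples$group[val]

d <- evaluate_signatures(s4$sigs, Xd, yd)
v <- evaluate_signatures(s4$sigs, Xv, yv)
tab <- data.frame(name = d$name, size = d$size, excluded = d$excluded,
                  auc_discovery = round(d$auc, 3),
                  auc_validation = round(v$auc, 3))
print(tab, row.names = FALSE)

nonempty <- !tab$excluded
tab$pc1_weight_auc <- NA_real_
for (nm in tab$name[nonempty]) {
  tab$pc1_weight_auc[tab$name == nm] <-
    round(pc1_weight_auc(Xv, s4$sigs[[nm]]), 3)
}
cat("PC1-weight AUCs (validation):",
    paste(tab$name[nonempty], tab$pc1_weight_auc[nonempty]), "\n")

best <- tab$name[nonempty][which.max(tab$auc_validation[nonempty])]
cat("strongest validation signature:", best, "\n")
cv <- cluster_view(Xv, s4$sigs[[best]], labels = yv)
cat("blinded two-cluster Rand index vs labels:",
    round(cv$rand_index, 3), "\n")

write.csv(tab, "results/evaluation.csv", row.names = FALSE)
saveRDS(list(evaluation = tab, best = best, cluster = cv),
        "scratch/05_evaluation.rds")
cat("saved scratch/05_evaluation.rds\n")
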