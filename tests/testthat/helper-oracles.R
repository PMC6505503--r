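# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (exhaustive enumeration, per-element
# stats:: calls) so they share no code with the implementation they check.

# Exhaustive pair-counting AUC: every (case, control) pair inspected.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "case"]
  neg <- scores[labels != "case"]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Welch test through stats::t.test, element by element.
oracle_welch_p <- function(a, b) {
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

# Brute-force refinement: Welch-test every peptide in every comparison with
# stats::t.test and intersect the survivors.
oracle_refine <- function(ids, comparisons, alpha = 0.05) {
  kept <- ids
  for (cmp in comparisons) {
    surv <- ids[vapply(ids, function(p) {
      oracle_welch_p(cmp$case[p, ], cmp$control[p, ]) < alpha
    }, logical(1))]
    kept <- intersect(kept, surv)
  }
  kept
}

# Variance ratio of a sign-aligned cluster, written independently of the
# package internals (plain var()/colMeans on the flipped submatrix).
oracle_cluster_r2 <- function(X, members) {
  sub <- X[members, , drop = FALSE]
  sub <- sub - rowMeans(sub)
  v1 <- eigen(crossprod(sub))$vectors[, 1]
  s <- sign(as.numeric(sub %*% v1))
  s[s == 0] <- 1
  flipped <- sub * s
  m <- colMeans(flipped)
  stats::var(m) / mean(apply(sub, 1, stats::var))
}

# Small simulated study: returns everything the preprocessing and discovery
# tests need, at a configurable scale.
tiny_study <- function(n_analysis = 300, n_control = 10, n_signature = 20,
                       effect_size = 1.5, seed = 1, ...) {
  lib <- generate_peptide_library(n_analysis, n_control, length = 12,
                                  seed = seed)
  man <- generate_design()
  spec <- signal_spec(n_signature_peptides = n_signature,
                      effect_size = effect_size, seed = seed + 1, ...)
  sim <- simulate_abundances(lib, man, spec)
  prep <- preprocess_arrays(sim$abundance, lib, man)
  disc <- prep$samples$partition == "discovery"
  list(lib = lib, man = man, sim = sim, prep = prep,
       X = prep$processed,
       Xd = prep$processed[, prep$samples$subject_id[disc], drop = FALSE],
       yd = prep$samples$group[disc],
       planted = sim$planted$peptide_id)
}

# A matrix whose rownames are simple peptide ids.
named_matrix <- function(values, nrow, ncol, prefix = "P") {
  m <- matrix(values, nrow, ncol)
  rownames(m) <- paste0(prefix, seq_len(nrow))
  colnames(m) <- paste0("s", seq_len(ncol))
  m
}
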