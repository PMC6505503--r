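# Synthetic-data generator: library, design, and abundance contracts.

test_that("peptide libraries use the 16-letter alphabet and are reproducible", {
  lib <- generate_peptide_library(n_analysis = 1000, n_control = 20,
                                  length = 12, seed = 7)
  expect_equal(nrow(lib), 1020)
  expect_false(anyDuplicated(lib$sequence) > 0)
  expect_equal(sum(lib$is_control), 20)
  expect_true(all(nchar(lib$sequence) == 12))
  residues <- unique(strsplit(paste(lib$sequence, collapse = ""), "")[[1]])
  expect_true(all(residues %in% PEPTIDE_ALPHABET))
  expect_false(any(c("T", "M", "I", "C") %in% residues))
  # determinism
  lib2 <- generate_peptide_library(1000, 20, 12, seed = 7)
  expect_identical(lib, lib2)
  # single-residue boundary case
  lib1 <- generate_peptide_library(n_analysis = 1, n_control = 0,
                                   length = 1, seed = 1)
  expect_equal(nrow(lib1), 1)
  expect_true(lib1$sequence %in% PEPTIDE_ALPHABET)
})

test_that("an exhausted alphabet is an explicit error", {
  expect_error(generate_peptide_library(17, 0, length = 1, seed = 1),
               "alphabet exhausted")
  # 16^1 sequences exactly is still feasible
  lib <- generate_peptide_library(16, 0, length = 1, seed = 1)
  expect_setequal(lib$sequence, PEPTIDE_ALPHABET)
})

test_that("the default study design realises the multi-cohort layout", {
  man <- generate_design()
  subj <- man[!duplicated(man$subject_id), ]
  disc <- subj[subj$partition == "discovery", ]
  val <- subj[subj$partition == "validation", ]
  expect_equal(nrow(disc), 43)
  expect_equal(sum(disc$group == "case"), 22)
  expect_equal(sum(disc$group == "control"), 21)
  expect_true(all(disc$cohort == "canadian"))
  expect_equal(sum(val$group == "case"), 28)   # 22 Norwegian + 6 Canadian
  expect_equal(sum(val$group == "control"), 13)  # 7 Canadian + 6 US
  expect_equal(sum(val$cohort == "norwegian" & val$group == "case"), 22)
  expect_equal(sum(val$cohort == "us"), 6)
  # US controls are exempt singletons; everyone else is duplicated
  us_arrays <- man[man$cohort == "us", ]
  expect_true(all(us_arrays$singleton_exempt))
  expect_equal(anyDuplicated(us_arrays$subject_id), 0)
  dup_counts <- table(man$subject_id[man$cohort != "us"])
  expect_true(all(dup_counts == 2))
  # the two assay experiments carry distinct batch labels
  expect_equal(length(unique(man$batch)), 2)
  expect_equal(length(unique(man$batch[man$partition == "discovery"])), 1)
})

test_that("custom designs honour the requested counts", {
  params <- data.frame(group = "case", cohort = "canadian",
                       partition = "discovery", n = 1, n_replicates = 1,
                       singleton_exempt = FALSE)
  man <- generate_design("custom", params)
  expect_equal(nrow(man), 1)
  expect_equal(man$group, "case")
  expect_error(generate_design("custom", transform(params, n = -1)),
               "non-negative")
})

test_that("raw abundances respect the 16-bit range and are deterministic", {
  s <- tiny_study(n_analysis = 200, n_control = 10, n_signature = 10)
  raw <- s$sim$abundance
  expect_true(min(raw) >= 0)
  expect_true(max(raw) <= 65535)
  expect_true(is.integer(raw))
  expect_identical(raw, simulate_abundances(s$lib, s$man, s$sim$spec)$abundance)
  # planted truth exposed, analysis peptides only
  expect_length(s$planted, 10)
  ctrl <- s$lib$peptide_id[s$lib$is_control]
  expect_length(intersect(s$planted, ctrl), 0)
})

test_that("empty inputs and oversized planted sets are explicit errors", {
  lib <- generate_peptide_library(10, 0, 12, seed = 1)
  man <- generate_design()
  expect_error(simulate_abundances(lib[0, ], man, signal_spec(5)), "empty")
  expect_error(simulate_abundances(lib, man[0, ], signal_spec(5)), "empty")
  expect_error(simulate_abundances(lib, man, signal_spec(50)),
               "exceeds the number of analysis peptides")
})

test_that("a null effect gives chance-level per-peptide separation", {
  # Monte-Carlo under the null: one large custom cohort, no planted effect
  params <- data.frame(
    group = c("case", "control"), cohort = "canadian",
    partition = "discovery", n = c(200, 200), n_replicates = 1,
    singleton_exempt = TRUE)
  man <- generate_design("custom", params)
  lib <- generate_peptide_library(20, 0, 12, seed = 3)
  sim <- simulate_abundances(lib, man,
                             signal_spec(n_signature_peptides = 0,
                                         effect_size = 0, seed = 4))
  grp <- man$group[match(colnames(sim$abundance), man$array_id)]
  aucs <- apply(sim$abundance[1:5, ], 1, function(v) {
    auc_mann_whitney(as.numeric(v), grp)
  })
  expect_true(all(abs(aucs - 0.5) < 0.05))
})

test_that("a planted effect of 2 SD is detected in nearly every repeat", {
  man <- generate_design()
  disc_arrays <- man$array_id[man$partition == "discovery" &
                                man$replicate_index == 1]
  grp <- man$group[match(disc_arrays, man$array_id)]
  lib <- generate_peptide_library(30, 0, 12, seed = 5)
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    sim <- simulate_abundances(lib, man,
                               signal_spec(n_signature_peptides = 1,
                                           effect_size = 2.0, seed = 1000 + r))
    pep <- sim$planted$peptide_id
    vals <- log2(sim$abundance[pep, disc_arrays] + 0.5)
    p <- stats::t.test(vals[grp == "case"], vals[grp == "control"])$p.value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("null p-values are approximately uniform across many peptides", {
  lib <- generate_peptide_library(10000, 0, 12, seed = 6)
  man <- generate_design()
  sim <- simulate_abundances(lib, man,
                             signal_spec(n_signature_peptides = 0,
                                         effect_size = 0, seed = 7))
  prep <- preprocess_arrays(sim$abundance, lib, man)
  disc <- prep$samples$partition == "discovery"
  Xd <- prep$processed[, prep$samples$subject_id[disc]]
  yd <- prep$samples$group[disc]
  res <- moderated_t_select(Xd, yd, d0 = 0)
  ks <- suppressWarnings(stats::ks.test(res$table$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("saturation is monotone in the baseline mean", {
  lib <- generate_peptide_library(500, 0, 12, seed = 8)
  man <- generate_design()
  sat_frac <- vapply(c(10, 13, 15, 17), function(mu) {
    sim <- simulate_abundances(lib, man,
                               signal_spec(n_signature_peptides = 0,
                                           baseline_mean_sd = c(mu, 1.5),
                                           seed = 9))
    mean(sim$abundance == 65535)
  }, numeric(1))
  expect_true(all(diff(sat_frac) >= 0))
  expect_gt(sat_frac[4], 0)
})

test_that("outlier arrays are permuted copies with unchanged margins", {
  lib <- generate_peptide_library(500, 0, 12, seed = 10)
  man <- generate_design()
  out_id <- man$array_id[1]
  spec0 <- signal_spec(n_signature_peptides = 0, seed = 11)
  spec1 <- signal_spec(n_signature_peptides = 0, seed = 11,
                       outlier_replicate_ids = out_id)
  a0 <- simulate_abundances(lib, man, spec0)$abundance
  a1 <- simulate_abundances(lib, man, spec1)$abundance
  expect_identical(unname(sort(a1[, out_id])),
                   unname(sort(a0[, out_id])))              # shuffled copy
  expect_false(all(a1[, out_id] == a0[, out_id]))
  expect_identical(a1[, -1], a0[, -1])
})
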