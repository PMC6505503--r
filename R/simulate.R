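# Synthetic peptide-array data: libraries, study designs and raw abundances
# with a planted case/control signature.  The generator reproduces the
# statistical structure the downstream analyses assume -- per-peptide log2
# baselines, duplicate technical replicates, occasional outlier replicates,
# exempt singletons, a between-batch shift separating the discovery and
# validation assay runs, and 16-bit saturation -- so the whole pipeline is
# exercisable without any array scan.

#' 16-letter amino-acid alphabet of the peptide array
#'
#' The array chemistry uses 12-mer peptides drawn from 16 amino acids,
#' excluding threonine, methionine, isoleucine and cysteine.
#'
#' @format A character vector of 16 one-letter residue codes.
#' @export
PEPTIDE_ALPHABET <- c("A", "R", "N", "D", "Q", "E", "G", "H",
                      "L", "K", "F", "P", "S", "W", "Y", "V")

#' Generate a random peptide library
#'
#' Draws unique random peptide sequences over the 16-letter array alphabet
#' (no T, M, I or C) and flags a subset as control peptides.  Defaults match
#' the full-scale array: 125,000 peptides of which 122,926 are analysis
#' features.
#'
#' @param n_analysis Number of analysis (non-control) peptides.
#' @param n_control Number of control peptides.
#' @param length Peptide length in residues.
#' @param seed Integer seed; the same seed yields an identical library.
#' @return A data frame of class `peptide_library` with columns
#'   `peptide_id`, `sequence` and `is_control`.
#' @export
#' @examples
#' lib <- generate_peptide_library(n_analysis = 50, n_control = 5, seed = 1)
#' table(lib$is_control)
generate_peptide_library <- function(n_analysis = 122926L, n_control = 2074L,
                                     length = 12L, seed = 1L) {
  n_analysis <- as.integer(n_analysis)
  n_control <- as.integer(n_control)
  length <- as.integer(length)
  n_total <- n_analysis + n_control
  if (n_total < 1) stop("n_analysis + n_control must be at least 1")
  if (length < 1) stop("peptide length must be at least 1")
  n_possible <- 16^length
  if (n_total > n_possible) {
    stop("alphabet exhausted: requested ", n_total, " unique ", length,
         "-mers but only ", format(n_possible, scientific = FALSE),
         " exist over a 16-letter alphabet")
  }
  seqs <- with_seed(seed, {
    out <- character(0)
    while (base::length(out) < n_total) {
      need <- n_total - base::length(out)
      # oversample to absorb duplicate draws; dedupe keeps first occurrences
      m <- max(need + 10L, ceiling(need * 1.05))
      block <- matrix(sample(PEPTIDE_ALPHABET, m * length, replace = TRUE),
                      nrow = m)
      cand <- do.call(paste0, as.data.frame(block, stringsAsFactors = FALSE))
      out <- unique(c(out, cand))
    }
    out[seq_len(n_total)]
  })
  lib <- data.frame(
    peptide_id = sprintf("P%06d", seq_len(n_total)),
    sequence = seqs,
    is_control = rep(c(FALSE, TRUE), c(n_analysis, n_control)),
    stringsAsFactors = FALSE
  )
  class(lib) <- c("peptide_library", "data.frame")
  lib
}

#' Generate a multi-cohort study design
#'
#' Builds the per-array sample manifest.  The `"paper_default"` template
#' realises the study layout: a Discovery partition of 22 Canadian ME/CFS
#' cases and 21 Canadian controls, and a Validation partition of 22 Norwegian
#' cases, 6 Canadian cases, 7 Canadian controls and 6 US controls, all run in
#' duplicate except the US controls, which are singletons exempt from the
#' singleton-removal rule.  The two partitions carry distinct batch labels,
#' reflecting separate immunoassay experiments.
#'
#' @param template `"paper_default"` or `"custom"`.
#' @param params For `"custom"`: a data frame with columns `group`
#'   (`"case"`/`"control"`), `cohort`, `partition`, `n` (subjects),
#'   `n_replicates` (arrays per subject, 1 or 2) and `singleton_exempt`.
#' @param seed Unused placeholder for API symmetry (the design is
#'   deterministic); kept so callers can thread one master seed everywhere.
#' @return A data frame of class `sample_manifest` with one row per physical
#'   array: `array_id`, `subject_id`, `group`, `cohort`, `partition`,
#'   `replicate_index`, `batch`, `singleton_exempt`.
#' @export
#' @examples
#' m <- generate_design()
#' table(m$partition, m$group)
generate_design <- function(template = c("paper_default", "custom"),
                            params = NULL, seed = NULL) {
  template <- match.arg(template)
  if (template == "paper_default") {
    params <- data.frame(
      group = c("case", "control", "case", "case", "control", "control"),
      cohort = c("canadian", "canadian", "norwegian", "canadian", "canadian", "us"),
      partition = c("discovery", "discovery", "validation", "validation",
                    "validation", "validation"),
      n = c(22L, 21L, 22L, 6L, 7L, 6L),
      n_replicates = c(2L, 2L, 2L, 2L, 2L, 1L),
      singleton_exempt = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(params),
            all(c("group", "cohort", "partition", "n", "n_replicates",
                  "singleton_exempt") %in% names(params)))
  if (any(params$n < 0)) stop("subject counts must be non-negative")
  rows <- list()
  subj <- 0L
  for (i in seq_len(nrow(params))) {
    blk <- params[i, ]
    if (blk$n == 0) next
    for (s in seq_len(blk$n)) {
      subj <- subj + 1L
      sid <- sprintf("S%04d", subj)
      for (r in seq_len(blk$n_replicates)) {
        rows[[base::length(rows) + 1L]] <- data.frame(
          array_id = sprintf("%s_r%d", sid, r),
          subject_id = sid,
          group = blk$group,
          cohort = blk$cohort,
          partition = blk$partition,
          replicate_index = r,
          batch = paste0("batch_", blk$partition),
          singleton_exempt = blk$singleton_exempt,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  class(manifest) <- c("sample_manifest", "data.frame")
  manifest
}

#' Specify the planted signal of a simulated experiment
#'
#' Collects the generative parameters of [simulate_abundances()].  The planted
#' case-vs-control shift is `effect_size` multiplied by the between-peptide
#' baseline standard deviation (`baseline_mean_sd[2]`), applied on the log2
#' scale, so `effect_size` is expressed in units of the spread of per-peptide
#' baseline levels.  Within-group variation is technical: per-array replicate
#' noise with coefficient of variation `replicate_cv`, plus integer rounding
#' and 16-bit saturation.
#'
#' @param n_signature_peptides Number of planted signature peptides.
#' @param effect_size Case-vs-control shift in units of the baseline SD.
#' @param effect_sign_mix Fraction of planted peptides shifted downward in
#'   cases (bound up or down relative to controls).
#' @param baseline_mean_sd Mean and SD of per-peptide log2 baseline levels.
#' @param replicate_cv Technical coefficient of variation between replicate
#'   arrays of one sample (raw scale).
#' @param batch_shift_sd SD of the per-peptide, per-batch log2 shift.
#' @param outlier_replicate_ids Array ids whose values are permuted across
#'   peptides, emulating failed replicates.
#' @param saturation_limit Upper detection limit of the digitizer.
#' @param seed Integer seed for the whole simulation.
#' @return A list of class `signal_spec`.
#' @export
signal_spec <- function(n_signature_peptides = 100L,
                        effect_size = 1.5,
                        effect_sign_mix = 0.5,
                        baseline_mean_sd = c(9, 1.5),
                        replicate_cv = 0.1,
                        batch_shift_sd = 0.3,
                        outlier_replicate_ids = character(0),
                        saturation_limit = 65535L,
                        seed = 1L) {
  if (effect_sign_mix < 0 || effect_sign_mix > 1) {
    stop("effect_sign_mix must lie in [0, 1]")
  }
  stopifnot(base::length(baseline_mean_sd) == 2, baseline_mean_sd[2] >= 0,
            replicate_cv >= 0, batch_shift_sd >= 0, saturation_limit >= 1)
  spec <- list(
    n_signature_peptides = as.integer(n_signature_peptides),
    effect_size = effect_size,
    effect_sign_mix = effect_sign_mix,
    baseline_mean_sd = as.numeric(baseline_mean_sd),
    replicate_cv = replicate_cv,
    batch_shift_sd = batch_shift_sd,
    outlier_replicate_ids = as.character(outlier_replicate_ids),
    saturation_limit = as.integer(saturation_limit),
    seed = as.integer(seed)
  )
  class(spec) <- "signal_spec"
  spec
}

#' Simulate raw peptide-array abundances
#'
#' Generates an integer raw abundance matrix (peptides x arrays) under the
#' model: per-peptide log2 baseline drawn from
#' `N(baseline_mean_sd[1], baseline_mean_sd[2])`; a planted shift of
#' `effect_size * baseline_mean_sd[2]` (random sign per peptide, mixing
#' fraction `effect_sign_mix`) added to case subjects on a random subset of
#' analysis peptides; a per-peptide, per-batch shift `N(0, batch_shift_sd)`;
#' per-array replicate noise with SD `log2(1 + replicate_cv)`; then
#' exponentiation, rounding, and clipping to `[0, saturation_limit]`.
#' Arrays named in `spec$outlier_replicate_ids` are finally permuted across
#' peptides, which destroys within-pair replicate concordance while leaving
#' the marginal distribution intact.  Control peptides never receive a group
#' effect.
#'
#' @param library A [generate_peptide_library()] data frame.
#' @param manifest A [generate_design()] data frame.
#' @param spec A [signal_spec()].
#' @return A list of class `immunosig_sim` with elements `abundance`
#'   (integer matrix, rownames peptide ids, colnames array ids), `planted`
#'   (data frame `peptide_id`, `sign` of the case shift), `library`,
#'   `manifest` and `spec`.  `planted$peptide_id` is the exact planted-truth
#'   set for downstream recovery tests.
#' @export
#' @examples
#' lib <- generate_peptide_library(200, 10, seed = 1)
#' man <- generate_design()
#' sim <- simulate_abundances(lib, man, signal_spec(n_signature_peptides = 20))
#' dim(sim$abundance)
simulate_abundances <- function(library, manifest, spec = signal_spec()) {
  if (is.null(library) || nrow(library) == 0) stop("peptide library is empty")
  if (is.null(manifest) || nrow(manifest) == 0) stop("sample manifest is empty")
  analysis_ids <- library$peptide_id[!library$is_control]
  if (spec$n_signature_peptides > base::length(analysis_ids)) {
    stop("n_signature_peptides exceeds the number of analysis peptides")
  }
  p <- nrow(library)
  arrays <- manifest$array_id
  if (anyDuplicated(arrays)) stop("manifest contains duplicated array_id")
  n_arr <- base::length(arrays)

  out <- with_seed(spec$seed, {
    baseline <- stats::rnorm(p, spec$baseline_mean_sd[1], spec$baseline_mean_sd[2])
    names(baseline) <- library$peptide_id

    planted_id <- sample(analysis_ids, spec$n_signature_peptides)
    n_neg <- round(spec$effect_sign_mix * spec$n_signature_peptides)
    signs <- rep(1, spec$n_signature_peptides)
    if (n_neg > 0) signs[sample.int(spec$n_signature_peptides, n_neg)] <- -1
    delta <- numeric(p)
    names(delta) <- library$peptide_id
    delta[planted_id] <- signs * spec$effect_size * spec$baseline_mean_sd[2]

    batches <- unique(manifest$batch)
    batch_shift <- matrix(stats::rnorm(p * base::length(batches), 0,
                                       spec$batch_shift_sd),
                          nrow = p, dimnames = list(library$peptide_id, batches))

    subjects <- unique(manifest$subject_id)
    case_subject <- manifest$group[match(subjects, manifest$subject_id)] == "case"
    # subject-level expected log2 level: baseline plus planted case shift
    subject_log2 <- outer(delta, as.numeric(case_subject)) + baseline
    colnames(subject_log2) <- subjects

    sd_rep <- log2(1 + spec$replicate_cv)
    log2_mat <- subject_log2[, manifest$subject_id, drop = FALSE] +
      batch_shift[, manifest$batch, drop = FALSE] +
      matrix(stats::rnorm(p * n_arr, 0, sd_rep), nrow = p)
    colnames(log2_mat) <- arrays

    raw <- round(2^log2_mat)
    raw[raw < 0] <- 0
    raw[raw > spec$saturation_limit] <- spec$saturation_limit
    storage.mode(raw) <- "integer"
    rownames(raw) <- library$peptide_id

    for (a in spec$outlier_replicate_ids) {
      if (!a %in% arrays) stop("outlier array id not in manifest: ", a)
      raw[, a] <- raw[sample.int(p), a]
    }
    list(raw = raw, planted = data.frame(peptide_id = planted_id, sign = signs,
                                         stringsAsFactors = FALSE))
  })

  res <- list(abundance = out$raw, planted = out$planted,
              library = library, manifest = manifest, spec = spec)
  class(res) <- "immunosig_sim"
  res
}
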