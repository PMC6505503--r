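# Preprocessing: control-peptide averaging, replicate outlier QC, replicate
# merging, and median-centred log2 normalisation.  The output is the
# per-sample processed matrix every downstream analysis consumes.

#' Average and remove control peptides
#'
#' Splits the raw matrix into analysis peptides and control peptides,
#' reporting the per-array arithmetic mean of the control-peptide values.
#' The control summary is reported for QC only; it is not used to rescale
#' samples.
#'
#' @param raw Integer/numeric matrix, peptides x arrays, rownames peptide ids.
#' @param library A [generate_peptide_library()]-shaped data frame.
#' @return A list with `matrix` (analysis rows only) and `control_summary`
#'   (named numeric vector, one mean per array; length 0 if no controls).
#' @export
average_control_peptides <- function(raw, library) {
  unknown <- setdiff(rownames(raw), library$peptide_id)
  if (base::length(unknown) > 0) {
    stop("matrix contains peptide ids absent from the library: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  is_ctrl <- library$is_control[match(rownames(raw), library$peptide_id)]
  ctrl_rows <- rownames(raw)[is_ctrl]
  if (base::length(ctrl_rows) == 0) {
    return(list(matrix = raw, control_summary = numeric(0)))
  }
  summary <- colMeans(raw[ctrl_rows, , drop = FALSE])
  list(matrix = raw[!is_ctrl, , drop = FALSE], control_summary = summary)
}

# Resolve duplicate replicate pairs from a manifest; errors on > 2 arrays per
# subject within a partition (the study design has duplicates only).
replicate_pairs <- function(manifest) {
  key <- paste(manifest$subject_id, manifest$partition, sep = "|")
  split_idx <- split(seq_len(nrow(manifest)), key)
  sizes <- lengths(split_idx)
  if (any(sizes > 2)) {
    bad <- names(split_idx)[sizes > 2][1]
    stop("subject has more than 2 replicate arrays: ", sub("\\|.*", "", bad))
  }
  split_idx
}

#' Test replicate pairs for outlier arrays
#'
#' For every duplicate pair, computes the Spearman rank correlation between
#' the two arrays over log2 abundances and flags the pair when concordance
#' falls below `min_concordance`.  A permuted (failed) replicate drives the
#' rank correlation to about zero, so pair-level flagging is symmetric: the
#' whole pair is removed downstream, matching the study's QC rule.
#'
#' @param raw Analysis-peptide matrix (peptides x arrays).
#' @param manifest Sample manifest covering the arrays.
#' @param min_concordance Minimum within-pair Spearman correlation.
#' @return A list of class `replicate_qc` with `pairs` (data frame:
#'   `subject_id`, `array_1`, `array_2`, `concordance`, `flagged`),
#'   `removed_pairs` (flagged subject ids), and `removed_singletons`
#'   (non-exempt singleton subject ids slated for removal at merge).
#' @export
test_replicate_outliers <- function(raw, manifest, min_concordance = 0.8) {
  if (min_concordance < 0 || min_concordance > 1) {
    stop("min_concordance must lie in [0, 1]")
  }
  manifest <- manifest[manifest$array_id %in% colnames(raw), , drop = FALSE]
  missing <- setdiff(manifest$array_id, colnames(raw))
  if (base::length(missing) > 0) {
    stop("manifest arrays absent from matrix: ", paste(missing, collapse = ", "))
  }
  idx <- replicate_pairs(manifest)
  lg <- log2(pmax(raw, 0) + 0.5)
  pair_rows <- list()
  singleton_subjects <- character(0)
  exempt <- logical(0)
  for (k in names(idx)) {
    rows <- idx[[k]]
    if (base::length(rows) == 1) {
      singleton_subjects <- c(singleton_subjects, manifest$subject_id[rows])
      exempt <- c(exempt, manifest$singleton_exempt[rows])
      next
    }
    a1 <- manifest$array_id[rows[1]]
    a2 <- manifest$array_id[rows[2]]
    rho <- stats::cor(lg[, a1], lg[, a2], method = "spearman")
    pair_rows[[k]] <- data.frame(
      subject_id = manifest$subject_id[rows[1]],
      array_1 = a1, array_2 = a2,
      concordance = rho,
      flagged = is.na(rho) || rho < min_concordance,
      stringsAsFactors = FALSE
    )
  }
  pairs <- if (base::length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(subject_id = character(0), array_1 = character(0),
               array_2 = character(0), concordance = numeric(0),
               flagged = logical(0))
  rownames(pairs) <- NULL
  qc <- list(
    pairs = pairs,
    removed_pairs = pairs$subject_id[pairs$flagged],
    removed_singletons = singleton_subjects[!exempt],
    min_concordance = min_concordance
  )
  class(qc) <- "replicate_qc"
  qc
}

#' Merge replicate arrays into per-sample abundances
#'
#' Drops pairs flagged by [test_replicate_outliers()] entirely, averages the
#' surviving pairs element-wise (arithmetic mean on the raw scale), and
#' removes singleton samples unless they are exempt (the US control group is
#' run as exempt singletons by design).
#'
#' @param raw Analysis-peptide matrix (peptides x arrays).
#' @param manifest Sample manifest covering the arrays.
#' @param qc A `replicate_qc` object computed on the same arrays.
#' @return A numeric matrix, peptides x merged samples, with subject ids as
#'   column names.  Attribute `provenance` records removed pairs and removed
#'   singletons.
#' @export
merge_replicates <- function(raw, manifest, qc) {
  manifest <- manifest[manifest$array_id %in% colnames(raw), , drop = FALSE]
  idx <- replicate_pairs(manifest)
  keep_cols <- list()
  removed_singletons <- character(0)
  for (k in names(idx)) {
    rows <- idx[[k]]
    sid <- manifest$subject_id[rows[1]]
    if (base::length(rows) == 1) {
      if (manifest$singleton_exempt[rows[1]]) {
        keep_cols[[sid]] <- raw[, manifest$array_id[rows], drop = TRUE]
      } else {
        removed_singletons <- c(removed_singletons, sid)
      }
      next
    }
    if (sid %in% qc$removed_pairs) next
    keep_cols[[sid]] <- rowMeans(raw[, manifest$array_id[rows], drop = FALSE])
  }
  if (base::length(keep_cols) == 0) stop("no samples survive replicate merging")
  # preserve manifest subject order
  order_sid <- unique(manifest$subject_id)
  order_sid <- order_sid[order_sid %in% names(keep_cols)]
  merged <- do.call(cbind, keep_cols[order_sid])
  rownames(merged) <- rownames(raw)
  attr(merged, "provenance") <- list(
    removed_pairs = unique(qc$removed_pairs),
    removed_singletons = removed_singletons
  )
  merged
}

#' Median-centred log2 normalisation
#'
#' Transforms merged abundances to the analysis scale: each sample is
#' log2-transformed and centred at its own median over all analysis
#' peptides, so every processed sample has log2 median exactly zero.  (For
#' odd peptide counts this is identical to dividing raw abundances by the
#' per-sample median before the log; for even counts the centring value is
#' the geometric midpoint of the two central peptides, which is what makes
#' the median-zero property exact.)  Zero raw values are replaced by 0.5 --
#' half the minimum detectable count -- before the log.
#'
#' @param merged Numeric matrix, peptides x samples, non-negative.
#' @return A numeric matrix of processed (log2 median-centred) values with
#'   the input dimnames; attribute `provenance` is carried over if present.
#' @export
#' @examples
#' m <- cbind(s1 = c(2, 4, 8))
#' rownames(m) <- paste0("P", 1:3)
#' normalize_abundances(m)[, 1]   # -1 0 1
normalize_abundances <- function(merged) {
  if (any(merged < 0)) stop("negative abundances are not allowed")
  x <- merged
  x[x == 0] <- 0.5
  lg <- log2(x)
  med <- apply(lg, 2, stats::median)
  raw_med <- apply(merged, 2, stats::median)
  bad <- which(raw_med <= 0)
  if (base::length(bad) > 0) {
    stop("sample has non-positive median abundance: ",
         paste(colnames(merged)[bad], collapse = ", "))
  }
  processed <- sweep(lg, 2, med)
  attr(processed, "provenance") <- attr(merged, "provenance")
  processed
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: control-peptide averaging, replicate outlier QC,
#' replicate merging, and median-centred log2 normalisation, returning the
#' processed matrix together with a subject-level manifest.
#'
#' @param raw Raw matrix including control peptides (peptides x arrays).
#' @param library Peptide library identifying control peptides.
#' @param manifest Per-array sample manifest.
#' @param min_concordance Replicate QC threshold, see
#'   [test_replicate_outliers()].
#' @return A list with `processed` (matrix), `qc` (`replicate_qc`),
#'   `control_summary`, and `samples` (subject-level manifest for the
#'   surviving columns: `subject_id`, `group`, `cohort`, `partition`).
#' @export
preprocess_arrays <- function(raw, library, manifest, min_concordance = 0.8) {
  avg <- average_control_peptides(raw, library)
  qc <- test_replicate_outliers(avg$matrix, manifest, min_concordance)
  merged <- merge_replicates(avg$matrix, manifest, qc)
  processed <- normalize_abundances(merged)
  subj <- manifest[!duplicated(manifest$subject_id),
                   c("subject_id", "group", "cohort", "partition"),
                   drop = FALSE]
  subj <- subj[subj$subject_id %in% colnames(processed), , drop = FALSE]
  subj <- subj[match(colnames(processed), subj$subject_id), , drop = FALSE]
  rownames(subj) <- NULL
  list(processed = processed, qc = qc, control_summary = avg$control_summary,
       samples = subj)
}
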