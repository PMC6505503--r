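# Signature refinement: per-peptide Welch t-tests across four case/control
# comparisons spanning both partitions and all three cohorts; peptides must
# separate in all four to survive.

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t with Satterthwaite degrees of freedom and a
#' two-sided p-value.
#'
#' @param a,b Numeric vectors (each of length at least 2).
#' @return A list with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))$p
welch_t <- function(a, b) {
  if (base::length(a) < 2 || base::length(b) < 2) {
    stop("each group needs at least 2 observations")
  }
  n1 <- base::length(a)
  n2 <- base::length(b)
  v1 <- stats::var(a)
  v2 <- stats::var(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Vectorised Welch test over matrix rows: A and B are peptides x samples for
# the two groups, aligned on rows.
row_welch <- function(A, B) {
  n1 <- ncol(A)
  n2 <- ncol(B)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(A)
  m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  data.frame(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Build the four refinement comparisons
#'
#' Resolves, from the processed matrix and the subject-level sample table,
#' the four case/control contrasts used for refinement: (i) discovery
#' Canadian cases vs discovery Canadian controls; (ii) validation Canadian
#' cases vs validation Canadian controls; (iii) Norwegian cases vs
#' validation Canadian controls; (iv) Norwegian cases vs US controls.
#'
#' @param X Processed matrix with subject ids as column names.
#' @param samples Subject-level data frame with `subject_id`, `group`,
#'   `cohort`, `partition` (e.g. `preprocess_arrays()$samples`).
#' @return A named list of four elements, each `list(case = matrix,
#'   control = matrix)`.
#' @export
build_refinement_comparisons <- function(X, samples) {
  pick <- function(group, cohort, partition) {
    sel <- samples$group == group & samples$cohort == cohort &
      samples$partition == partition
    samples$subject_id[sel]
  }
  defs <- list(
    discovery_canadian = list(case = pick("case", "canadian", "discovery"),
                              control = pick("control", "canadian", "discovery")),
    validation_canadian = list(case = pick("case", "canadian", "validation"),
                               control = pick("control", "canadian", "validation")),
    norwegian_vs_canadian = list(case = pick("case", "norwegian", "validation"),
                                 control = pick("control", "canadian", "validation")),
    norwegian_vs_us = list(case = pick("case", "norwegian", "validation"),
                           control = pick("control", "us", "validation"))
  )
  lapply(stats::setNames(names(defs), names(defs)), function(nm) {
    d <- defs[[nm]]
    if (base::length(d$case) < 2 || base::length(d$control) < 2) {
      stop("comparison '", nm, "' has fewer than 2 samples in a group")
    }
    list(case = X[, d$case, drop = FALSE], control = X[, d$control, drop = FALSE])
  })
}

#' Refine a signature by four-comparison Welch testing
#'
#' Welch-tests every signature peptide in each of the supplied comparisons
#' and retains those with p below `alpha` in all of them; with the four
#' study comparisons this turns CPS001 into the refined signature CPS001A.
#' P-values are unadjusted by default -- the conjunction across comparisons
#' is itself the stringency mechanism -- with an optional BH adjustment per
#' comparison.
#'
#' @param sig Signature (object or character ids).
#' @param comparisons Named list of `list(case = matrix, control = matrix)`
#'   pairs, e.g. from [build_refinement_comparisons()].
#' @param alpha Per-comparison significance threshold.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param name Name of the refined signature.
#' @return A list with `signature` (a `candidate_signature`) and `report`
#'   (data frame: `peptide_id`, one p-value column per comparison, `kept`).
#' @export
refine_signature <- function(sig, comparisons, alpha = 0.05,
                             adjust = c("none", "BH"),
                             name = "CPS001A") {
  adjust <- match.arg(adjust)
  ids <- peptide_ids_of(sig)
  if (base::length(ids) == 0) stop("signature is empty; nothing to refine")
  if (base::length(comparisons) == 0) stop("no comparisons supplied")
  pmat <- sapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    missing <- setdiff(ids, intersect(rownames(cmp$case), rownames(cmp$control)))
    if (base::length(missing) > 0) {
      stop("comparison '", nm, "' is missing signature peptides: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    p <- row_welch(cmp$case[ids, , drop = FALSE],
                   cmp$control[ids, , drop = FALSE])$p
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    p
  })
  if (base::length(ids) == 1) pmat <- matrix(pmat, nrow = 1,
                                             dimnames = list(NULL, names(comparisons)))
  kept <- apply(pmat < alpha, 1, all)
  report <- data.frame(peptide_id = ids, pmat, kept = kept,
                       stringsAsFactors = FALSE, row.names = NULL)
  list(
    signature = new_candidate_signature(
      name, ids[kept],
      paste0("peptides of ", if (is.character(sig)) "input set" else sig$name,
             " with p < ", alpha, " in all ", base::length(comparisons),
             " comparisons")),
    report = report
  )
}
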