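# Signature evaluation: per-sample scores, Mann-Whitney AUC, PC1-weight AUC,
# and the blinded PCA / hierarchical-clustering view.

#' Mann-Whitney AUC of scores against two-group labels
#'
#' The area under the ROC curve computed as the Mann-Whitney statistic:
#' the fraction of (case, control) pairs where the case scores higher, with
#' ties counting one half.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param labels Two-group vector aligned with `scores` (positive class
#'   `"case"` if present, otherwise the first factor level).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_mann_whitney(c(2, 3, 4, 0, 1), c("case", "case", "case", "control", "control"))
auc_mann_whitney <- function(scores, labels) {
  f <- as_group_factor(labels)
  pos <- f == levels(f)[1]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score samples against a peptide signature
#'
#' The signature score of a sample is the mean over signature peptides of
#' the sign-adjusted processed (log2 median-centred) abundance.  Per-peptide
#' signs come from the first principal component of the peptide-standardised
#' signature submatrix (zero loadings count as +1); a single global
#' orientation resolves the inherent sign ambiguity of PC1 and is chosen,
#' using the known group labels, so that the reported AUC is at least 0.5
#' (cases score higher); ties fall back to the case-minus-control mean.
#'
#' @param X Processed matrix, peptides x samples.
#' @param sig A `candidate_signature`, `peptide_panel`, `peptide_list`, or
#'   character vector of peptide ids.
#' @param labels Optional group labels (needed to orient and compute AUC).
#' @param orientation Optional fixed orientation (+1/-1) overriding the
#'   label-based choice.
#' @return A list of class `signature_score` with `scores` (named,
#'   oriented), `signs` (per-peptide), `orientation`, `pc1_loadings`, and
#'   `auc` (NA without labels).
#' @export
signature_score <- function(X, sig, labels = NULL, orientation = NULL) {
  ids <- peptide_ids_of(sig)
  if (base::length(ids) == 0) {
    stop("signature is empty; empty signatures are excluded from evaluation")
  }
  missing <- setdiff(ids, rownames(X))
  if (base::length(missing) > 0) {
    stop("signature peptides absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  sub <- X[ids, , drop = FALSE]
  Z <- standardize_rows(sub)
  u <- pc1_row_loadings(Z)
  signs <- ifelse(u >= 0, 1, -1)
  raw_scores <- colMeans(sub * signs)
  auc_val <- NA_real_
  if (is.null(orientation)) {
    if (!is.null(labels)) {
      a <- auc_mann_whitney(raw_scores, labels)
      if (a > 0.5) {
        orientation <- 1
      } else if (a < 0.5) {
        orientation <- -1
      } else {
        f <- as_group_factor(labels)
        dm <- mean(raw_scores[f == levels(f)[1]]) -
          mean(raw_scores[f != levels(f)[1]])
        orientation <- if (dm >= 0) 1 else -1
      }
    } else {
      orientation <- 1
    }
  }
  scores <- orientation * raw_scores
  if (!is.null(labels)) auc_val <- auc_mann_whitney(scores, labels)
  structure(list(scores = scores, signs = stats::setNames(signs, ids),
                 orientation = orientation,
                 pc1_loadings = stats::setNames(u, ids), auc = auc_val),
            class = "signature_score")
}

#' AUC of signature membership against PC1 weights
#'
#' Performs a PCA of the full peptide-standardised matrix, ranks every
#' peptide by the absolute value of its PC1 weight, and computes the
#' Mann-Whitney AUC of signature membership against that ranking.  Values
#' near 1 indicate the signature's peptides dominate the primary axis of
#' sample separation; random signatures give about 0.5.
#'
#' @param X_full Processed matrix over all analysis peptides.
#' @param sig Signature (object or character ids); must be non-empty.
#' @return AUC in `[0, 1]`.
#' @export
pc1_weight_auc <- function(X_full, sig) {
  ids <- peptide_ids_of(sig)
  if (base::length(ids) == 0) stop("signature is empty")
  Z <- standardize_rows(X_full)
  u <- pc1_row_loadings(Z)
  membership <- ifelse(rownames(X_full) %in% ids, "case", "control")
  if (!any(membership == "case")) {
    stop("no signature peptides present in the matrix")
  }
  auc_mann_whitney(abs(u), membership)
}

#' Blinded PCA / hierarchical-clustering view of a signature
#'
#' Row-standardises the signature submatrix (each peptide to mean 0, SD 1),
#' projects samples onto the first two principal components, and clusters
#' samples by agglomerative clustering on correlation distance.  Group
#' labels are never used for the projection or clustering; when provided
#' they are only compared against the two-cluster cut through the Rand
#' index.
#'
#' @param X Processed matrix, peptides x samples (at least 3 samples).
#' @param sig Signature (object or character ids); must be non-empty.
#' @param labels Optional group labels for the reported Rand index.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param k Number of clusters cut from the dendrogram.
#' @return A list of class `cluster_view`: `coords` (samples x 2 PC
#'   coordinates), `dendrogram` (hclust), `clusters` (cut assignments),
#'   `rand_index` (NA without labels), `dropped_peptides`.
#' @export
cluster_view <- function(X, sig, labels = NULL, linkage = "average", k = 2L) {
  ids <- peptide_ids_of(sig)
  if (base::length(ids) == 0) stop("signature is empty")
  if (ncol(X) < 3) stop("at least 3 samples are required")
  sub <- X[intersect(ids, rownames(X)), , drop = FALSE]
  Z <- standardize_rows(sub)
  dropped <- attr(Z, "constant_rows")
  if (base::length(dropped) > 0) {
    warning("dropping ", base::length(dropped),
            " constant peptide row(s) with zero SD")
    Z <- Z[setdiff(rownames(Z), dropped), , drop = FALSE]
  }
  if (nrow(Z) == 0) stop("no non-constant signature peptides left")
  cp <- crossprod(Z)
  e <- eigen(cp, symmetric = TRUE)
  m <- min(2L, ncol(Z))
  coords <- sapply(seq_len(m), function(j) {
    fix_sign(e$vectors[, j]) * sqrt(max(e$values[j], 0))
  })
  rownames(coords) <- colnames(X)
  colnames(coords) <- paste0("PC", seq_len(m))
  d <- stats::as.dist(1 - stats::cor(Z))
  hc <- stats::hclust(d, method = linkage)
  clusters <- stats::cutree(hc, k = k)
  ri <- if (is.null(labels)) NA_real_ else rand_index(clusters, labels)
  structure(list(coords = coords, dendrogram = hc, clusters = clusters,
                 rand_index = ri, dropped_peptides = dropped),
            class = "cluster_view")
}

#' Evaluate signatures on a partition
#'
#' Scores each non-empty signature and tabulates size and AUC; the layout
#' mirrors the discovery/validation AUC summary table of the analysis.
#'
#' @param sigs Named list of `candidate_signature` objects.
#' @param X Processed matrix for the partition.
#' @param labels Group labels for the partition.
#' @return A data frame: `name`, `size`, `excluded`, `auc`.
#' @export
evaluate_signatures <- function(sigs, X, labels) {
  rows <- lapply(sigs, function(s) {
    a <- if (s$excluded) NA_real_ else signature_score(X, s, labels)$auc
    data.frame(name = s$name, size = base::length(s$peptide_ids),
               excluded = s$excluded, auc = a, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
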