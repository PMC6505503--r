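# Unsupervised selectors: sparse PCA, sparse independent PCA, and gene
# shaving.  Each returns up to ten peptide lists from the Discovery matrix,
# blind to group status.

# Rank-1 sparse factor of a row-centred peptides x samples matrix by
# soft-thresholded power iteration (penalized-matrix-decomposition style).
# The threshold is set each iteration to the (k+1)-th largest |score| so the
# support has exactly k peptides (all peptides when k >= p).
sparse_rank1 <- function(Xc, k, max_iter = 200, tol = 1e-8) {
  p <- nrow(Xc)
  k <- min(k, p)
  cp <- crossprod(Xc)                       # samples x samples
  v <- fix_sign(eigen(cp, symmetric = TRUE)$vectors[, 1])
  w_old <- rep(0, p)
  w <- w_old
  for (it in seq_len(max_iter)) {
    a <- as.numeric(Xc %*% v)
    if (k < p) {
      lam <- sort(abs(a), decreasing = TRUE)[k + 1]
      w <- sign(a) * pmax(abs(a) - lam, 0)
    } else {
      w <- a
    }
    nw <- sqrt(sum(w^2))
    if (nw <= .Machine$double.eps) break
    w <- w / nw
    v_new <- as.numeric(crossprod(Xc, w))
    nv <- sqrt(sum(v_new^2))
    if (nv <= .Machine$double.eps) break
    v <- v_new / nv
    if (sum((w - w_old)^2) < tol) break
    w_old <- w
  }
  w <- fix_sign(w)
  list(loading = w, sample_vec = fix_sign(v))
}

#' Sparse principal component peptide lists
#'
#' Extracts `n_lists` sparse principal components of the processed matrix by
#' soft-thresholded power iteration with projection deflation; each
#' component's support is tuned to exactly `k_features` peptides.  List *i*
#' contains the peptides with nonzero loadings on sparse component *i*,
#' ordered by loading magnitude.
#'
#' @param X Processed matrix, peptides x samples.
#' @param k_features Number of nonzero loadings per component.
#' @param n_lists Number of components/lists.
#' @param seed Accepted for API uniformity; the algorithm is deterministic
#'   (spectral initialisation).
#' @return A list of [new_peptide_list()] objects named `sPCA1..sPCAn`.
#' @export
sparse_pca_lists <- function(X, k_features = 100L, n_lists = 10L, seed = NULL) {
  if (k_features < 1) stop("k_features must be at least 1")
  Xc <- X - rowMeans(X)
  out <- list()
  for (i in seq_len(n_lists)) {
    if (sum(Xc^2) <= 1e-12 * base::length(Xc) || ncol(Xc) < 1) {
      warning("matrix effectively rank-deficient after ", i - 1,
              " components; returning ", i - 1, " lists")
      break
    }
    f <- sparse_rank1(Xc, k_features)
    if (sum(abs(f$loading)) <= .Machine$double.eps) {
      warning("no further structure after ", i - 1,
              " components; returning ", i - 1, " lists")
      break
    }
    sel <- which(f$loading != 0)
    ord <- sel[order(abs(f$loading[sel]), decreasing = TRUE)]
    out[[i]] <- new_peptide_list(
      name = paste0("sPCA", i),
      peptide_ids = rownames(X)[ord],
      method_params = list(k_features = k_features, component = i),
      scores = stats::setNames(f$loading[ord], rownames(X)[ord])
    )
    d <- as.numeric(t(f$loading) %*% Xc %*% f$sample_vec)
    Xc <- Xc - d * tcrossprod(f$loading, f$sample_vec)
  }
  out
}

# Symmetric FastICA (cubic nonlinearity) on an m x N matrix of whitened
# signals (rows = components, columns = observations).  Returns the m x m
# unmixing rotation.
fastica_rotation <- function(S, seed = 1L, max_iter = 200, tol = 1e-8) {
  m <- nrow(S)
  N <- ncol(S)
  W <- with_seed(seed, matrix(stats::rnorm(m * m), m, m))
  sym_orth <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                                     m) %*% t(e$vectors)
    solve_sqrt %*% W
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    Y <- W %*% S                       # m x N
    G <- Y^3
    W_new <- (G %*% t(S)) / N - diag(rowMeans(3 * Y^2), m) %*% W
    W_new <- sym_orth(W_new)
    delta <- 1 - abs(diag(W_new %*% t(W)))
    W <- W_new
    if (max(delta) < tol) break
  }
  W
}

#' Sparse independent principal component peptide lists
#'
#' Computes the leading principal subspace of dimension `n_lists`, rotates
#' the (whitened) peptide loadings by FastICA with a kurtosis-style cubic
#' nonlinearity so that each rotated loading vector is maximally
#' non-Gaussian, and hard-selects the `k_features` largest-magnitude
#' peptides per rotated component.  Components are ordered by the excess
#' kurtosis of their loading vectors (most non-Gaussian first).
#'
#' @inheritParams sparse_pca_lists
#' @param seed Seed for the ICA initialisation.
#' @return A list of [new_peptide_list()] objects named `sIPCA1..sIPCAn`.
#' @export
sparse_ipca_lists <- function(X, k_features = 100L, n_lists = 10L, seed = 1L) {
  if (k_features < 1) stop("k_features must be at least 1")
  Xc <- X - rowMeans(X)
  p <- nrow(Xc)
  cp <- crossprod(Xc)
  e <- eigen(cp, symmetric = TRUE)
  pos <- sum(e$values > max(e$values) * 1e-10)
  m <- min(n_lists, pos, ncol(Xc), p)
  if (m < n_lists) {
    warning("rank supports only ", m, " components; returning ", m, " lists")
  }
  if (m == 0) return(list())
  V <- e$vectors[, seq_len(m), drop = FALSE]
  d <- sqrt(e$values[seq_len(m)])
  U <- Xc %*% V %*% diag(1 / d, m)          # p x m orthonormal loadings
  if (m > 1) {
    W <- fastica_rotation(t(U) * sqrt(p), seed = seed)
    L <- U %*% t(W)                         # rotated loading vectors
  } else {
    L <- U
  }
  # order components by excess kurtosis of their loadings (non-Gaussianity)
  kur <- apply(L, 2, function(z) {
    z <- (z - mean(z)) / stats::sd(z)
    abs(mean(z^4) - 3)
  })
  L <- L[, order(kur, decreasing = TRUE), drop = FALSE]
  out <- list()
  for (i in seq_len(m)) {
    w <- fix_sign(L[, i])
    k <- min(k_features, p)
    ord <- order(abs(w), decreasing = TRUE)[seq_len(k)]
    out[[i]] <- new_peptide_list(
      name = paste0("sIPCA", i),
      peptide_ids = rownames(X)[ord],
      method_params = list(k_features = k_features, component = i, seed = seed),
      scores = stats::setNames(w[ord], rownames(X)[ord])
    )
  }
  out
}

# Variance ratio of a candidate cluster: between-sample variance of the
# sign-aligned cluster mean profile ("super-peptide") over the average
# per-peptide variance.  Rows negatively aligned with the cluster's PC1 are
# flipped before averaging, so anti-correlated members reinforce rather
# than cancel.  Rows must be centred (which shaving preserves).
cluster_r2 <- function(sub, signs, sumsq = sum(sub^2)) {
  n <- ncol(sub)
  m <- as.numeric(crossprod(sub, signs)) / nrow(sub)
  vb <- sum((m - mean(m))^2) / (n - 1)
  vt <- sumsq / (nrow(sub) * (n - 1))
  if (vt <= 0) return(0)
  vb / vt
}

# Independently permute every row of a matrix (vectorised: one radix sort
# on jittered row keys instead of a per-row sample() call).
permute_rows <- function(X) {
  p <- nrow(X)
  n <- ncol(X)
  key <- rep(seq_len(p), n) + stats::runif(p * n)
  ord <- order(key, method = "radix")         # grouped by row, random within
  cols <- matrix(((ord - 1L) %/% p) + 1L, p, n, byrow = TRUE)
  out <- matrix(X[(cols - 1L) * p + seq_len(p)], p, n)
  rownames(out) <- rownames(X)
  out
}

# One shaving sweep: the nested sequence of peptide sets obtained by
# repeatedly removing the shave_fraction least PC1-aligned peptides, with the
# variance ratio at each size.
shave_sequence <- function(Xc, shave_fraction) {
  idx <- seq_len(nrow(Xc))
  Xs <- Xc
  rowss <- rowSums(Xc^2)       # per-row sums of squares, updated by subset
  G <- crossprod(Xs)           # n x n Gram matrix, downdated as rows drop
  sizes <- integer(0)
  r2 <- numeric(0)
  sets <- list()
  sgn <- list()
  repeat {
    k <- base::length(idx)
    v <- fix_sign(eigen(G, symmetric = TRUE, only.values = FALSE)$vectors[, 1])
    a <- as.numeric(Xs %*% v)
    s <- sign(a)
    s[s == 0] <- 1
    sizes <- c(sizes, k)
    sets[[base::length(sets) + 1L]] <- idx
    sgn[[base::length(sgn) + 1L]] <- s
    r2 <- c(r2, cluster_r2(Xs, s, sum(rowss)))
    if (k == 1) break
    align <- abs(a)
    n_drop <- ceiling(shave_fraction * k)
    n_drop <- min(n_drop, k - 1L)
    # threshold at the n_drop-th smallest alignment; spill ties as needed
    thr <- sort(align, partial = n_drop)[n_drop]
    keep <- which(align > thr)
    short <- (k - n_drop) - base::length(keep)
    if (short > 0) {
      keep <- c(keep, which(align == thr)[seq_len(short)])
    }
    keep <- sort(keep)
    idx <- idx[keep]
    if (k - base::length(keep) < k / 2 && k > 2000) {
      # downdating with the dropped block is cheaper than a fresh Gram
      drop_rows <- Xs[-keep, , drop = FALSE]
      Xs <- Xs[keep, , drop = FALSE]
      G <- G - crossprod(drop_rows)
    } else {
      Xs <- Xs[keep, , drop = FALSE]
      G <- crossprod(Xs)       # small sets: recompute, avoids drift
    }
    rowss <- rowss[keep]
  }
  list(sizes = sizes, sets = sets, signs = sgn, r2 = r2)
}

#' Gene shaving peptide lists
#'
#' Implements the shaving algorithm with a permutation gap statistic: (1)
#' compute the first principal component of the current peptide set; (2)
#' repeatedly shave off the `shave_fraction` of peptides least aligned with
#' it, producing a nested sequence of candidate clusters; (3) pick the
#' cluster size whose variance ratio most exceeds its average over
#' `n_permutations` row-permuted matrices (the gap statistic); (4)
#' orthogonalise the matrix with respect to the retained cluster's mean
#' profile and repeat.  Cluster sizes are selected automatically, unlike the
#' fixed-support sparse selectors.
#'
#' @param X Processed matrix, peptides x samples.
#' @param n_lists Number of clusters to extract.
#' @param shave_fraction Fraction of peptides removed per shaving step.
#' @param n_permutations Row permutations for the gap reference.
#' @param max_cluster_size Optional cap on the candidate cluster sizes.
#' @param seed Seed for the permutations.
#' @return A list of [new_peptide_list()] objects named `GS1..GSn`.
#' @export
gene_shaving_lists <- function(X, n_lists = 10L, shave_fraction = 0.10,
                               n_permutations = 20L, max_cluster_size = NULL,
                               seed = 1L) {
  if (shave_fraction <= 0 || shave_fraction >= 1) {
    stop("shave_fraction must lie strictly between 0 and 1")
  }
  Xc <- X - rowMeans(X)
  p <- nrow(Xc)
  n <- ncol(Xc)
  if (p < n_lists) {
    warning("fewer peptides (", p, ") than requested clusters (", n_lists,
            "); returning ", p, " lists")
    n_lists <- p
  }
  out <- list()
  with_seed(seed, {
    for (cl in seq_len(n_lists)) {
      obs <- shave_sequence(Xc, shave_fraction)
      perm_r2 <- matrix(0, n_permutations, base::length(obs$sizes))
      for (b in seq_len(n_permutations)) {
        Xp <- permute_rows(Xc)
        ps <- shave_sequence(Xp, shave_fraction)
        perm_r2[b, ] <- ps$r2
      }
      gap <- obs$r2 - colMeans(perm_r2)
      cand <- seq_along(obs$sizes)
      if (!is.null(max_cluster_size)) {
        cand <- cand[obs$sizes <= max_cluster_size]
        if (!base::length(cand)) cand <- base::length(obs$sizes)
      }
      # ties broken toward the smaller (later, more shaved) cluster
      best <- cand[which(gap[cand] >= max(gap[cand]) - 1e-12)]
      best <- best[base::length(best)]
      members <- obs$sets[[best]]
      msigns <- obs$signs[[best]]
      sub <- Xc[members, , drop = FALSE]
      mprof <- colMeans(sub * msigns)   # sign-aligned "super-peptide" profile
      align <- abs(as.numeric(sub %*% (mprof / sqrt(sum(mprof^2) + 1e-300))))
      ord <- members[order(align, decreasing = TRUE)]
      out[[cl]] <- new_peptide_list(
        name = paste0("GS", cl),
        peptide_ids = rownames(X)[ord],
        method_params = list(shave_fraction = shave_fraction,
                             n_permutations = n_permutations,
                             gap = gap[best], size = base::length(members)),
        scores = stats::setNames(align[order(align, decreasing = TRUE)],
                                 rownames(X)[ord])
      )
      # orthogonalise remaining variation w.r.t. the cluster mean profile
      denom <- sum(mprof^2)
      if (denom > 0) {
        coef <- (Xc %*% mprof) / denom
        Xc <- Xc - tcrossprod(as.numeric(coef), mprof)
      }
    }
  })
  out
}
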