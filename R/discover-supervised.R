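# Supervised selectors: empirical-Bayes moderated t ("robust limma" style),
# random-forest Gini importance, and elastic-net frequency selection.

# Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

# Empirical-Bayes hyperparameters (s0^2, d0) from per-feature variances s2
# with common residual df, by log-scale moment matching.  Variances are
# winsorised at the given quantiles first, which keeps a handful of wild
# features from blowing up the prior ("robust" fit).
estimate_variance_prior <- function(s2, df, winsor = c(0.05, 0.95)) {
  s2 <- pmax(s2, 1e-300)
  q <- stats::quantile(s2, winsor, names = FALSE)
  s2w <- pmin(pmax(s2, q[1]), q[2])
  z <- log(s2w)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(s02 = s02, d0 = d0)
}

#' Moderated two-sample t selection
#'
#' Per-peptide two-group comparison with empirical-Bayes variance
#' moderation: the pooled per-peptide variance \eqn{s_g^2} (residual df
#' \eqn{d_g}) is shrunk toward a prior \eqn{s_0^2} with prior df \eqn{d_0},
#' giving the posterior variance
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)} and a t
#' statistic on \eqn{d_g + d_0} degrees of freedom.  The hyperparameters are
#' estimated by log-scale moment matching on variances winsorised at their
#' 5th/95th percentiles, a minimal robustification against outlier
#' variances.  P-values are Benjamini-Hochberg adjusted and the returned
#' list contains all peptides at or below `adj_p_threshold`.
#'
#' @param X Processed matrix, peptides x samples.
#' @param labels Two-group vector aligned with the columns (positive class
#'   `"case"` if present, otherwise the first factor level).
#' @param adj_p_threshold BH-adjusted p-value cutoff for the returned list.
#' @param d0 Optional fixed prior df; `NULL` estimates it.  `d0 = 0`
#'   reproduces the ordinary pooled-variance t exactly.
#' @param s02 Optional fixed prior variance (used only with fixed `d0 > 0`).
#' @param winsor Winsorisation quantiles for the prior fit.
#' @return A list with `table` (data frame: means, `s2`, `df`, `s2_post`,
#'   `t`, `p`, `adj_p`), `s02`, `d0`, and `list` (a [new_peptide_list()]
#'   named `"RL"` ordered by adjusted p).
#' @export
moderated_t_select <- function(X, labels, adj_p_threshold = 0.05,
                               d0 = NULL, s02 = NULL,
                               winsor = c(0.05, 0.95)) {
  f <- as_group_factor(labels)
  g1 <- f == levels(f)[1]
  g2 <- !g1
  n1 <- sum(g1)
  n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) {
    stop("each group needs at least 2 samples (got ", n1, " and ", n2, ")")
  }
  X1 <- X[, g1, drop = FALSE]
  X2 <- X[, g2, drop = FALSE]
  m1 <- rowMeans(X1)
  m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  if (is.null(d0)) {
    prior <- estimate_variance_prior(s2, dg, winsor)
    d0 <- prior$d0
    s02 <- prior$s02
  } else if (d0 > 0 && is.null(s02)) {
    prior <- estimate_variance_prior(s2, dg, winsor)
    s02 <- prior$s02
  }
  s2_post <- if (is.infinite(d0)) rep(s02, base::length(s2)) else
    if (d0 == 0) s2 else (d0 * s02 + dg * s2) / (d0 + dg)
  tstat <- (m1 - m2) / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- dg + (if (is.infinite(d0)) 0 else d0)
  if (is.infinite(d0)) df_total <- Inf
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  adj_p <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(peptide_id = rownames(X), mean_1 = m1, mean_2 = m2,
                    s2 = s2, df = dg, s2_post = s2_post, t = tstat,
                    p = p, adj_p = adj_p, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  keep <- which(adj_p <= adj_p_threshold)
  keep <- keep[order(adj_p[keep], p[keep])]
  lst <- new_peptide_list(
    name = "RL",
    peptide_ids = rownames(X)[keep],
    method_params = list(adj_p_threshold = adj_p_threshold, d0 = d0, s02 = s02),
    scores = stats::setNames(adj_p[keep], rownames(X)[keep])
  )
  list(table = tab, s02 = s02, d0 = d0, list = lst)
}

#' Random-forest importance selection
#'
#' Fits a classification forest on samples x peptides and returns the
#' peptides whose Mean Decrease Gini (impurity) importance reaches
#' `gini_threshold`, ordered by importance.  When no threshold is given, it
#' is set to the 99.7th percentile of the importances from one refit with
#' permuted labels, an estimate of the upper tail of chance importance.
#'
#' @param X Processed matrix, peptides x samples.
#' @param labels Two-group vector aligned with the columns.
#' @param n_trees Trees per forest.
#' @param gini_threshold Minimum Mean Decrease Gini; `NULL` for the
#'   permutation-calibrated default.
#' @param seed Integer seed (forest and label permutation).
#' @param threshold_quantile Quantile of permuted importances used when
#'   `gini_threshold` is `NULL`.
#' @return A [new_peptide_list()] named `"RF"`; `method_params` records the
#'   threshold used.
#' @export
random_forest_select <- function(X, labels, n_trees = 1000L,
                                 gini_threshold = NULL, seed = 1L,
                                 threshold_quantile = 0.997) {
  f <- as_group_factor(labels)
  if (nlevels(droplevels(f)) < 2) stop("labels contain a single class")
  dat <- t(X)
  fit <- ranger::ranger(x = dat, y = f, num.trees = n_trees,
                        importance = "impurity", num.threads = 1,
                        seed = seed)
  imp <- fit$variable.importance
  if (is.null(gini_threshold)) {
    fp <- with_seed(derive_seed(seed, 1L), sample(f))
    perm_fit <- ranger::ranger(x = dat, y = fp, num.trees = n_trees,
                               importance = "impurity", num.threads = 1,
                               seed = derive_seed(seed, 2L))
    gini_threshold <- stats::quantile(perm_fit$variable.importance,
                                      threshold_quantile, names = FALSE)
  }
  keep <- which(imp >= gini_threshold)
  keep <- keep[order(imp[keep], decreasing = TRUE)]
  new_peptide_list(
    name = "RF",
    peptide_ids = rownames(X)[keep],
    method_params = list(n_trees = n_trees, gini_threshold = gini_threshold,
                         seed = seed),
    scores = stats::setNames(imp[keep], rownames(X)[keep])
  )
}

#' Elastic-net frequency selection
#'
#' Stability-style selection: over `n_runs` resampling runs, each dropping
#' `n_case_drop` cases and `n_control_drop` controls at random (39 of 43
#' samples per run under the default study design), an elastic-net-penalised
#' logistic classifier is fitted with internal cross-validation for the
#' penalty strength; a peptide's frequency is the fraction of runs in which
#' its coefficient at the selected penalty is nonzero, and the returned list
#' keeps peptides with frequency at or above `freq_threshold`.
#'
#' @param X Processed matrix, peptides x samples.
#' @param labels Two-group vector aligned with the columns.
#' @param n_runs Number of resampling runs.
#' @param n_case_drop,n_control_drop Samples removed per run.
#' @param freq_threshold Minimum selection frequency.
#' @param alpha Elastic-net mixing parameter.
#' @param nfolds,nlambda,lambda_min_ratio Internal cross-validation and
#'   penalty-path settings passed to [glmnet::cv.glmnet()].
#' @param seed Integer seed; run-level seeds derive from it.
#' @return A [new_peptide_list()] named `"EN"` with selection frequencies as
#'   scores; `method_params$run_sizes` records the per-run sample counts and
#'   `method_params$failed_runs` any runs skipped after a fit failure.
#' @export
elastic_net_frequency_select <- function(X, labels, n_runs = 100L,
                                         n_case_drop = 2L, n_control_drop = 2L,
                                         freq_threshold = 0.10, alpha = 0.5,
                                         nfolds = 5L, nlambda = 30L,
                                         lambda_min_ratio = 0.05, seed = 1L) {
  f <- as_group_factor(labels)
  pos <- levels(f)[1]
  idx_case <- which(f == pos)
  idx_ctrl <- which(f != pos)
  if (base::length(idx_case) <= n_case_drop ||
      base::length(idx_ctrl) <= n_control_drop) {
    stop("group sizes must exceed the number of dropped samples")
  }
  dat <- t(X)
  counts <- integer(nrow(X))
  run_sizes <- integer(0)
  failed <- 0L
  for (r in seq_len(n_runs)) {
    sel <- with_seed(derive_seed(seed, r), {
      drop_case <- sample(idx_case, n_case_drop)
      drop_ctrl <- sample(idx_ctrl, n_control_drop)
      keep <- setdiff(seq_along(f), c(drop_case, drop_ctrl))
      fit <- tryCatch(
        glmnet::cv.glmnet(dat[keep, , drop = FALSE], f[keep],
                          family = "binomial", alpha = alpha,
                          nfolds = nfolds, nlambda = nlambda,
                          lambda.min.ratio = lambda_min_ratio,
                          thresh = 1e-5),
        error = function(e) NULL)
      if (is.null(fit)) {
        list(nz = NULL, n = base::length(keep))
      } else {
        beta <- stats::coef(fit, s = "lambda.min")[-1]
        list(nz = which(beta != 0), n = base::length(keep))
      }
    })
    run_sizes <- c(run_sizes, sel$n)
    if (is.null(sel$nz)) {
      failed <- failed + 1L
      warning("elastic-net run ", r, " failed to fit and was skipped")
      next
    }
    counts[sel$nz] <- counts[sel$nz] + 1L
  }
  freq <- counts / n_runs
  keep <- which(freq >= freq_threshold)
  keep <- keep[order(freq[keep], decreasing = TRUE)]
  new_peptide_list(
    name = "EN",
    peptide_ids = rownames(X)[keep],
    method_params = list(n_runs = n_runs, n_case_drop = n_case_drop,
                         n_control_drop = n_control_drop,
                         freq_threshold = freq_threshold, alpha = alpha,
                         run_sizes = run_sizes, failed_runs = failed,
                         seed = seed),
    scores = stats::setNames(freq[keep], rownames(X)[keep])
  )
}
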