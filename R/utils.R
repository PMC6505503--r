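# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' package functions are deterministic given their `seed` argument without
#' clobbering the session RNG.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' All randomised stages of the pipeline draw their seeds from one master seed
#' through this counter scheme, so an entire run is reproducible from a single
#' integer. Results stay within the 31-bit range R accepts for [set.seed()].
#'
#' @param master Integer master seed.
#' @param offset Non-negative integer stage counter.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1L, 0)
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(offset))
  m <- 2147483647
  as.integer((abs(as.numeric(master)) %% 1000003) * 2039 + 7 * as.numeric(offset) + 1) %% m
}

# Row-wise standardisation: every row to mean 0, SD 1.  Rows with zero SD are
# returned as all-zero and reported through the "dropped" attribute so callers
# can warn or drop them.
standardize_rows <- function(X) {
  mu <- rowMeans(X)
  Z <- X - mu
  s <- sqrt(rowSums(Z^2) / (ncol(X) - 1))
  zero <- s <= 0 | !is.finite(s)
  s[zero] <- 1
  Z <- Z / s
  attr(Z, "constant_rows") <- rownames(X)[zero]
  Z
}

# Leading left singular vector (per-row loadings) of a rows x samples matrix,
# computed in sample space (n x n eigendecomposition), with a deterministic
# sign convention: the largest-|loading| entry is positive.
pc1_row_loadings <- function(Z) {
  cp <- crossprod(Z)                     # n x n
  e <- eigen(cp, symmetric = TRUE)
  v <- e$vectors[, 1]
  d <- sqrt(max(e$values[1], 0))
  if (d <= .Machine$double.eps) {
    u <- rep(0, nrow(Z))
  } else {
    u <- as.numeric(Z %*% v) / d
  }
  fix_sign(u)
}

# Deterministic sign for an eigen/singular vector: flip so that the entry with
# the largest absolute value is positive.
fix_sign <- function(u) {
  i <- which.max(abs(u))
  if (length(i) && u[i] < 0) u <- -u
  u
}

# Rand index between two hard partitions (pair-counting agreement).
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_i - sum_j) / total
}

# Coerce a two-group label vector to a factor with the positive class first.
as_group_factor <- function(labels, positive = "case") {
  f <- as.factor(labels)
  lev <- levels(f)
  if (length(lev) != 2) {
    stop("labels must contain exactly two groups, got: ",
         paste(lev, collapse = ", "))
  }
  if (positive %in% lev) {
    f <- stats::relevel(f, ref = positive)
  }
  f
}

# Extract peptide ids from a signature/panel/list object or character vector.
peptide_ids_of <- function(x) {
  if (is.character(x)) return(x)
  if (is.list(x) && !is.null(x$peptide_ids)) return(x$peptide_ids)
  stop("cannot extract peptide ids from object of class ",
       paste(class(x), collapse = "/"))
}

# MD5 digest of an arbitrary R object (serialised to a temp file).
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
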