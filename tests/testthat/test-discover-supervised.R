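# Supervised selectors: moderated t, random forest, elastic-net frequency.

test_that("with no shrinkage the moderated t equals the ordinary pooled t", {
  set.seed(10)
  X <- named_matrix(rnorm(200 * 12), 200, 12)
  y <- rep(c("case", "control"), each = 6)
  res <- moderated_t_select(X, y, d0 = 0)
  t_ref <- apply(X, 1, function(v) {
    stats::t.test(v[y == "case"], v[y == "control"],
                  var.equal = TRUE)$statistic
  })
  expect_lt(max(abs(res$table$t - t_ref)), 1e-10)
  p_ref <- apply(X, 1, function(v) {
    stats::t.test(v[y == "case"], v[y == "control"], var.equal = TRUE)$p.value
  })
  expect_lt(max(abs(res$table$p - p_ref)), 1e-10)
})

test_that("the posterior variance interpolates prior and sample variance", {
  set.seed(11)
  X <- named_matrix(rnorm(500 * 10, sd = rep(runif(500, 0.5, 2), each = 10)),
                    500, 10)
  y <- rep(c("case", "control"), each = 5)
  res <- moderated_t_select(X, y)
  expect_true(is.finite(res$d0) || is.infinite(res$d0))
  lo <- pmin(res$table$s2, res$s02)
  hi <- pmax(res$table$s2, res$s02)
  expect_true(all(res$table$s2_post >= lo - 1e-12))
  expect_true(all(res$table$s2_post <= hi + 1e-12))
  # BH-adjusted p never below the raw p
  expect_true(all(res$table$adj_p >= res$table$p - 1e-15))
})

test_that("variance-prior estimation agrees with the reference eBayes fit", {
  skip_if_not_installed("limma")
  set.seed(12)
  n <- 2000
  df <- 10
  s2_true <- 0.04 * df / rchisq(n, df = 8)   # scaled inverse chi-square draw
  s2 <- s2_true * rchisq(n, df) / df
  # no winsorisation so both routes see the same data
  fit <- immunosig:::estimate_variance_prior(s2, df, winsor = c(0, 1))
  ref <- limma::fitFDist(s2, df1 = df)
  expect_equal(fit$s02, ref$scale, tolerance = 0.02)
  expect_equal(fit$d0, ref$df2, tolerance = 0.05)
})

test_that("a global null yields almost no BH discoveries", {
  ok <- 0
  for (s in 1:50) {
    set.seed(300 + s)
    X <- named_matrix(rnorm(10000 * 43, sd = 0.1), 10000, 43)
    y <- rep(c("case", "control"), c(22, 21))
    res <- moderated_t_select(X, y)
    ok <- ok + (sum(res$table$adj_p <= 0.05) <= 2)
  }
  expect_gte(ok, 45)
})

test_that("moderated t recovers a planted effect with high precision and recall", {
  recs <- precs <- numeric(20)
  for (s in 1:20) {
    set.seed(400 + s)
    X <- named_matrix(rnorm(10000 * 43, sd = 1), 10000, 43)
    y <- rep(c("case", "control"), c(22, 21))
    planted <- paste0("P", 1:100)
    X[1:100, y == "case"] <- X[1:100, y == "case"] +
      1.5 * sample(c(-1, 1), 100, TRUE)
    res <- moderated_t_select(X, y)
    hits <- res$list$peptide_ids
    recs[s] <- mean(planted %in% hits)
    precs[s] <- if (length(hits)) mean(hits %in% planted) else 0
  }
  expect_gte(mean(recs), 0.8)
  expect_gte(mean(precs), 0.8)
})

test_that("moderated t is monotone in the mean difference at fixed variance", {
  # identical pooled variances, increasing separation => non-increasing p
  n <- 6
  base <- c(-1, 0, 1)
  deltas <- c(0.5, 1, 2, 4)
  ps <- vapply(deltas, function(d) {
    X <- rbind(c(base, base + d))
    rownames(X) <- "P1"
    colnames(X) <- paste0("s", 1:6)
    moderated_t_select(X, rep(c("case", "control"), each = 3), d0 = 0)$table$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("random forest selection is thresholded, ordered and deterministic", {
  set.seed(13)
  X <- named_matrix(rnorm(500 * 20, sd = 0.5), 500, 20)
  y <- rep(c("case", "control"), each = 10)
  X["P1", y == "case"] <- X["P1", y == "case"] + 5
  res <- random_forest_select(X, y, n_trees = 300, seed = 3)
  expect_true("P1" %in% res$peptide_ids)
  expect_equal(res$peptide_ids[1], names(which.max(res$scores)))
  res2 <- random_forest_select(X, y, n_trees = 300, seed = 3)
  expect_identical(res$peptide_ids, res2$peptide_ids)
  # an infinite threshold empties the list
  res3 <- random_forest_select(X, y, n_trees = 100, gini_threshold = Inf,
                               seed = 3)
  expect_length(res3$peptide_ids, 0)
  expect_error(random_forest_select(X, rep("case", 20), seed = 1),
               "two groups|single class")
})

test_that("a perfectly separating peptide tops the forest importance", {
  hits <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    X <- named_matrix(rnorm(501 * 24), 501, 24)
    y <- rep(c("case", "control"), each = 12)
    X["P1", ] <- ifelse(y == "case", 2, -2) + rnorm(24, sd = 0.1)
    res <- random_forest_select(X, y, n_trees = 500, gini_threshold = 0,
                                seed = s)
    hits <- hits + (res$peptide_ids[1] == "P1")
  }
  expect_gte(hits, 19)
})

test_that("random-forest importance ranking agrees with the classic forest", {
  skip_if_not_installed("randomForest")
  set.seed(14)
  X <- named_matrix(rnorm(200 * 30, sd = 0.5), 200, 30)
  y <- rep(c("case", "control"), each = 15)
  X[1:5, y == "case"] <- X[1:5, y == "case"] + 2
  res <- random_forest_select(X, y, n_trees = 1000, gini_threshold = 0,
                              seed = 5)
  rf <- randomForest::randomForest(x = t(X), y = factor(y), ntree = 1000)
  ref_top <- names(sort(rf$importance[, "MeanDecreaseGini"],
                        decreasing = TRUE))[1:5]
  expect_setequal(res$peptide_ids[1:5], ref_top)
})

test_that("elastic-net runs drop the configured samples and report frequencies", {
  s <- tiny_study(n_analysis = 300, n_control = 10, n_signature = 20,
                  effect_size = 1.5)
  res <- elastic_net_frequency_select(s$Xd, s$yd, n_runs = 10, seed = 9)
  expect_true(all(res$method_params$run_sizes == 39))
  expect_length(res$method_params$run_sizes, 10)
  expect_true(all(res$scores >= 0.1 & res$scores <= 1))
  # planted peptides dominate the selected set
  expect_gt(mean(res$peptide_ids %in% s$planted), 0.5)
})

test_that("elastic-net frequency lists are monotone in the threshold", {
  s <- tiny_study(n_analysis = 200, n_control = 0, n_signature = 10,
                  effect_size = 1.5, seed = 5)
  res_lo <- elastic_net_frequency_select(s$Xd, s$yd, n_runs = 10,
                                         freq_threshold = 0.05, seed = 9)
  res_hi <- elastic_net_frequency_select(s$Xd, s$yd, n_runs = 10,
                                         freq_threshold = 0.5, seed = 9)
  expect_true(all(res_hi$peptide_ids %in% res_lo$peptide_ids))
  # frequencies of 1.0 always survive, frequencies of 0 never appear
  expect_true(all(res_lo$scores > 0))
  expect_error(elastic_net_frequency_select(s$Xd, s$yd, n_case_drop = 50),
               "exceed")
})
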