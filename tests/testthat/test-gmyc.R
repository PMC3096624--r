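test_that("null log-likelihood matches the hand-evaluated two-interval
           product", {
  tr <- fixture_3tip()
  iv <- build_intervals(classify_nodes(tr, tr$root_height * 1.01))
  ## b = (2, 6), x = (1, 1) at lambda = 1, p = 1
  expect_equal(null_loglik(iv, lambda = 1, p = 1), log(2) + log(6) - 8)
  expect_error(null_loglik(iv, lambda = -1, p = 1), "positive")
  ## degenerate single-lineage interval is rejected
  iv_bad <- iv
  iv_bad$csq[1, 1] <- 0
  expect_error(null_loglik(iv_bad, 1, 1), "degenerate")
})

test_that("mixed likelihood with a single all-coalescent cluster equals
           the null exactly", {
  for (seed in 1:10) {
    tr <- random_small_tree(seed)
    iv <- build_intervals(classify_nodes(tr, tr$root_height * 2))
    for (p in c(-0.5, 1, 2)) {
      lam <- 0.5 + seed / 10
      expect_identical(mixed_loglik(iv, lambda1 = NA, lambda2 = lam,
                                    p1 = NA, p2 = p),
                       null_loglik(iv, lam, p))
    }
  }
})

test_that("mixed likelihood on the 4-tip toy tree matches the hand
           enumeration", {
  tr <- fixture_4tip()
  iv <- build_intervals(classify_nodes(tr, 0.5))
  l1 <- 0.7; l2 <- 3; p1 <- 1.2; p2 <- 0.8
  b <- c(l1 * 2^p1,                       # two species stems
         l1 * 2^p1 + l2 * 2^p2,           # CD cluster has 2 lineages
         l1 * 2^p1 + l2 * (2^p2 + 2^p2))  # both clusters at 2 lineages
  x <- c(0.8, 0.1, 0.1)
  expect_equal(mixed_loglik(iv, l1, l2, p1, p2), sum(log(b) - b * x),
               tolerance = 1e-12)
  expect_error(mixed_loglik(iv, -1, l2, p1, p2), "positive")
})

test_that("interval sweep agrees with the geometric midpoint oracle on
           random trees and thresholds", {
  set.seed(42)
  for (seed in 1:40) {
    tr <- random_small_tree(seed)
    thr <- runif(1, 0, tr$root_height * 1.1)
    iv <- build_intervals(classify_nodes(tr, thr))
    l1 <- runif(1, 0.1, 5); l2 <- runif(1, 0.1, 5)
    p1 <- runif(1, -1, 2); p2 <- runif(1, -1, 2)
    expect_equal(
      mixed_loglik(iv, l1, l2, p1, p2),
      oracle_threshold_loglik(tr$phy, thr, l1, l2, p1, p2),
      tolerance = 1e-9)
  }
})

test_that("classify_nodes covers the threshold extremes and the toy
           case", {
  tr <- fixture_4tip()

  cls <- classify_nodes(tr, tr$root_height * 1.01)
  asg <- extract_entities(cls)
  expect_equal(asg$n_entities, 1L)
  expect_equal(asg$n_singletons, 0L)
  expect_setequal(asg$entities[[1]], c("A", "B", "C", "D"))

  cls0 <- classify_nodes(tr, 0)
  asg0 <- extract_entities(cls0)
  expect_equal(asg0$n_entities, 4L)
  expect_equal(asg0$n_clusters, 0L)

  cls5 <- classify_nodes(tr, 0.5)
  asg5 <- extract_entities(cls5)
  expect_equal(asg5$n_clusters, 2L)
  expect_setequal(vapply(asg5$entities, paste, "", collapse = ""),
                  c("AB", "CD"))
  expect_true(all(asg5$type == "cluster"))
})

test_that("classification rejects sets that are not tip-ward closed", {
  tr <- fixture_4tip()
  ## root coalescent but a child diversification violates closure
  expect_error(node_classification(tr, c(TRUE, FALSE, TRUE)),
               "tip-ward closed")
})

test_that("likelihood_ratio_test clips at zero and matches a numeric
           chi-square oracle", {
  expect_equal(likelihood_ratio_test(10, 10, df = 3),
               list(LR = 0, df = 3L, p_value = 1))
  expect_error(likelihood_ratio_test(10, 9, df = 3), "nested")
  expect_error(likelihood_ratio_test(10, 12, df = 0), "positive integer")
  for (case in list(c(5, 3), c(0.3, 1), c(40.1, 3))) {
    lrt <- likelihood_ratio_test(0, case[1] / 2, df = case[2])
    expect_equal(lrt$p_value, oracle_chisq_upper(case[1], case[2]),
                 tolerance = 1e-6)
  }
})

test_that("threshold_confidence_set keeps candidates within delta of
           the maximum", {
  prof <- data.frame(candidate = c(0.1, 0.2, 0.3),
                     logL = c(-5, -3, -4.5))
  expect_equal(threshold_confidence_set(prof, delta = 1.92),
               c(0.2, 0.3))
  ## single candidate and flat profile
  expect_equal(threshold_confidence_set(prof[2, ]), 0.2)
  prof$logL <- -1
  expect_equal(threshold_confidence_set(prof), prof$candidate)
  expect_error(threshold_confidence_set(prof[0, ]), "empty")
})

test_that("single-threshold fit recovers the planted partition on the
           toy tree", {
  tr <- fixture_4tip()
  fit <- fit_single_threshold(tr)
  expect_s3_class(fit, "gmyc_fit")
  expect_gte(fit$LR, 0)
  expect_equal(fit$logLik_mixed, max(fit$profile$logL, na.rm = TRUE))
  ## T is the height of the youngest diversification node
  expect_equal(fit$threshold,
               min(tr$heights[5:7][!fit$classification$coal]))
  ## confidence set contains the winning candidate's height region
  expect_true(length(fit$conf_set) >= 1)
})

test_that("profile ties break toward fewer entities", {
  ## two candidates forced to the same likelihood: compare directly
  prof <- data.frame(candidate = c(0.5, 0.2), logL = c(-2, -2),
                     n_entities = c(2L, 5L))
  best <- which(prof$logL >= max(prof$logL) - 1e-9)
  expect_equal(prof$n_entities[best[which.min(prof$n_entities[best])]], 2L)
  ## end to end: a flat-likelihood degenerate case cannot be forced
  ## robustly, so the rule is asserted through fit internals on the toy
  ## tree where the winner must not have more entities than a tied rival
  tr <- fixture_4tip()
  fit <- fit_single_threshold(tr)
  tied <- which(fit$profile$logL >= fit$logLik_mixed - 1e-9)
  expect_equal(fit$n_species, min(fit$profile$n_entities[tied]))
})

test_that("multiple-threshold search nests the single fit and is a
           fixed point at a local maximum", {
  sim <- fixture_mixed(seed = 2, k = 4, n_j = 5)
  single <- fit_single_threshold(sim$tree)
  multi <- fit_multiple_threshold(sim$tree, start = single)
  expect_gte(multi$logLik_mixed, single$logLik_mixed - 1e-9)
  expect_gte(multi$LR, 0)
  ## restarting from the multiple-threshold optimum stays put
  refit <- optimize_rates(build_intervals(multi$classification))
  again <- fit_multiple_threshold(
    sim$tree,
    start = structure(modifyList(single, list(
      classification = multi$classification,
      logLik_mixed = refit$logLik)), class = "gmyc_fit"))
  expect_identical(again$classification$coal, multi$classification$coal)
})

test_that("multiple-threshold improvement over single is usually not
           significant when one true threshold exists", {
  pvals <- vapply(1:5, function(s) {
    sim <- fixture_mixed(seed = s, k = 4, n_j = 5)
    fit_multiple_threshold(sim$tree)$p_value
  }, 0)
  expect_gte(sum(pvals > 0.05), 3L)
})
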