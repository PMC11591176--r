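test_that("fold plans are stratified partitions with a fixed test subset", {
  man <- data.frame(
    case_id = sprintf("c%03d", 1:100),
    ef_class = rep(c("pEF", "mrEF", "rEF"), c(60, 20, 20)))
  plan <- makeFoldPlan(man, seed = 4)
  sizes <- vapply(plan@subsets, length, integer(1L))
  expect_identical(sizes, rep(20L, 5L))
  for (s in plan@subsets) {
    cls <- table(factor(plan@strata[s], c("pEF", "mrEF", "rEF")))
    expect_identical(as.vector(cls), c(12L, 4L, 4L))
  }
  ## partition: every case in exactly one subset
  expect_setequal(unlist(plan@subsets), man$case_id)
  expect_identical(anyDuplicated(unlist(plan@subsets)), 0L)
  ## determinism
  plan2 <- makeFoldPlan(man, seed = 4)
  expect_identical(plan@subsets, plan2@subsets)
  ## folds never leak and share the same test subset
  tests <- lapply(1:4, function(f) {
    sp <- foldSplit(plan, f)
    expect_length(intersect(sp$train, sp$dev), 0L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_length(intersect(sp$dev, sp$test), 0L)
    sp$test
  })
  for (f in 2:4) expect_identical(tests[[f]], tests[[1L]])
  ## under-filled classes are rejected
  expect_error(makeFoldPlan(data.frame(case_id = letters[1:8],
                                       ef_class = rep(c("pEF", "rEF"),
                                                      c(4, 4))),
                            seed = 1), ">= 5")
})

test_that("AUC equals the Mann-Whitney oracle, including ties", {
  expect_equal(computeAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(computeAuc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(computeAuc(scores, labels), aucOracle(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(computeAuc(1:3, c(1, 1, 1)), "both classes")
})

test_that("threshold metrics follow the confusion-table arithmetic", {
  ## TP=8, FN=2, TN=7, FP=3
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.2, 7), rep(0.8, 3))
  labels <- rep(c(1, 0), c(10, 10))
  m <- thresholdMetrics(scores, labels, 0.5)
  expect_equal(m[["sensitivity"]], 0.8)
  expect_equal(m[["specificity"]], 0.7)
  expect_equal(m[["accuracy"]], 0.75)
  ## degenerate thresholds
  expect_equal(thresholdMetrics(scores, labels, 0)[["sensitivity"]], 1)
  expect_equal(thresholdMetrics(c(0.2, 0.4), c(0, 0), 1)[["specificity"]], 1)
  ## absent class reports NA, not 0
  expect_true(is.na(thresholdMetrics(c(0.2, 0.4), c(0, 0),
                                     0.5)[["sensitivity"]]))
})

test_that("case scores aggregate tensor probabilities by the mean rule", {
  set.seed(12)
  clf <- buildClassifier(modelConfig(2L, 20L, filters = c(4L, 4L),
                                     kernels = c(3L, 3L), pools = c(2L, 2L)))
  x <- array(rnorm(2 * 20 * 6), c(2, 20, 6))
  set <- list(x = x, y = c(0L, 0L, 0L, 1L, 1L, 1L),
              case = c("a", "a", "b", "c", "c", "c"))
  pc <- predictCaseLevel(clf, set)
  p <- predictProba(clf, x)[, "reduced"]
  expect_equal(pc$score[pc$case_id == "a"], mean(p[1:2]))
  expect_equal(pc$score[pc$case_id == "b"], p[3])
  expect_equal(pc$score[pc$case_id == "c"], mean(p[4:6]))
  ## permutation invariance
  perm <- c(5, 2, 6, 1, 3, 4)
  pc2 <- predictCaseLevel(clf, list(x = x[, , perm], y = set$y[perm],
                                    case = set$case[perm]))
  expect_equal(pc2[order(pc2$case_id), "score"],
               pc[order(pc$case_id), "score"], tolerance = 1e-12)
})

test_that("training is deterministic given the control seed", {
  ctl <- trainConfig(epochs = 2, batchSize = 16, seed = 9,
                     devLevel = "data")
  mc <- modelConfig(2L, 20L, filters = c(4L, 4L), kernels = c(3L, 3L),
                    pools = c(2L, 2L))
  set.seed(21)
  tr <- list(x = array(rnorm(2 * 20 * 30), c(2, 20, 30)),
             y = rep(0:1, 15), case = sprintf("c%d", 1:30))
  f1 <- trainFold(tr, tr, mc, ctl)
  f2 <- trainFold(tr, tr, mc, ctl)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$classifier@params, f2$classifier@params)
  expect_error(trainFold(tr, tr, mc, trainConfig(epochs = 0)), ">= 1")
})

test_that("configuration comparisons use t-test and ANOVA/Tukey correctly", {
  ## identical per-fold AUCs: zero difference, p = 1
  same <- data.frame(configuration = rep(c("a", "b"), each = 4),
                     fold = rep(1:4, 2), auc = rep(c(0.8, 0.81), 4))
  cmp <- compareConfigurations(same)
  expect_equal(diff(cmp$summary$mean), 0)
  expect_equal(cmp$p_value, 1)
  ## clearly separated groups: closed-form Student t oracle
  a <- c(0.80, 0.81, 0.80, 0.81); b <- c(0.90, 0.91, 0.90, 0.91)
  two <- data.frame(configuration = rep(c("a", "b"), each = 4),
                    fold = rep(1:4, 2), auc = c(a, b))
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  tstat <- (mean(b) - mean(a)) / (sp * sqrt(1 / 2))
  expect_equal(compareConfigurations(two)$p_value,
               2 * pt(-abs(tstat), df = 6), tolerance = 1e-12)
  expect_lt(compareConfigurations(two)$p_value, 0.001)
  ## three groups, one shifted: Tukey flags exactly the shifted contrasts
  three <- data.frame(
    configuration = rep(c("a", "b", "c"), each = 6),
    fold = rep(1:6, 3),
    auc = c(0.850, 0.851, 0.849, 0.852, 0.848, 0.850,
            0.851, 0.850, 0.852, 0.849, 0.851, 0.850,
            0.901, 0.902, 0.900, 0.903, 0.899, 0.901))
  cmp3 <- compareConfigurations(three, requireBalanced = TRUE)
  expect_identical(cmp3$method, "anova_tukey")
  sig <- cmp3$tukey$`p adj` < 0.05
  names(sig) <- cmp3$tukey$contrast
  expect_false(sig[["b-a"]])
  expect_true(sig[["c-a"]])
  expect_true(sig[["c-b"]])
  ## unequal fold counts are rejected when balance is required
  expect_error(compareConfigurations(two[-1L, ]), "unequal")
})
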