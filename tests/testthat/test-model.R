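test_that("classifier outputs lie on the probability simplex", {
  set.seed(1)
  clf <- buildClassifier(modelConfig(12L, 375L))
  p <- predictProba(clf, array(0, c(12, 375, 3)))
  expect_identical(dim(p), c(3L, 2L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
  ## arbitrary finite input, including extreme magnitudes
  p2 <- predictProba(clf, array(rnorm(12 * 375 * 4, sd = 50), c(12, 375, 4)))
  expect_true(all(p2 >= 0 & p2 <= 1))
  expect_equal(rowSums(p2), rep(1, 4), tolerance = 1e-12)
})

test_that("the same block stack serves 1- to 24-channel inputs", {
  for (ch in c(1L, 5L, 12L, 24L)) {
    set.seed(2)
    clf <- buildClassifier(modelConfig(ch, 375L))
    p <- predictProba(clf, array(rnorm(ch * 375 * 2), c(ch, 375, 2)))
    expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-12)
  }
})

test_that("the default configuration has ten weighted layers", {
  expect_identical(nWeightedLayers(modelConfig(12L, 375L)), 10L)
  expect_identical(nWeightedLayers(modelConfig(24L, 375L)), 10L)
  expect_identical(nWeightedLayers(modelConfig(12L, 1500L)), 10L)
  ## a hidden dense layer adds one
  expect_identical(nWeightedLayers(modelConfig(12L, 375L, fcWidth = 32L)),
                   11L)
})

test_that("configurations that collapse the temporal length name the block", {
  expect_error(modelConfig(12L, 8L, filters = c(4L, 4L, 4L),
                           kernels = c(3L, 3L, 3L), pools = c(4L, 4L, 4L)),
               "block 2")
})

test_that("mixup is a shared-lambda convex combination", {
  set.seed(3)
  x <- array(rnorm(2 * 10 * 6), c(2, 10, 6))
  y <- cbind(rep(c(1, 0), 3), rep(c(0, 1), 3))
  ## lambda forced to 1: identity
  m1 <- mixup(x, y, alpha = 0.2, lambda = 1)
  expect_equal(m1$x, x)
  expect_equal(m1$y, y)
  ## any lambda: soft labels remain on the simplex
  m <- mixup(x, y, alpha = 0.2)
  expect_equal(rowSums(m$y), rep(1, 6), tolerance = 1e-12)
  expect_true(m$lambda >= 0 && m$lambda <= 1)
  ## lambda = 0.5 with a self-pairing is idempotent on identical inputs
  xs <- array(1.5, c(2, 10, 2)); ys <- matrix(0.5, 2, 2)
  ms <- mixup(xs, ys, lambda = 0.5)
  expect_equal(ms$x, xs); expect_equal(ms$y, ys)
  ## batch of one returned unchanged
  m0 <- mixup(x[, , 1, drop = FALSE], y[1, , drop = FALSE])
  expect_identical(m0$x, x[, , 1, drop = FALSE])
})

test_that("weighted loss matches hand arithmetic and reduces to plain CE", {
  p <- matrix(0.5, 2, 2)
  expect_equal(weightedLoss(p, c(0, 1), c(1, 2)), 1.5 * log(2),
               tolerance = 1e-12)
  ## neutral weights = unweighted cross-entropy
  set.seed(4)
  q <- matrix(runif(10, 0.05, 0.95), 5, 2); q <- q / rowSums(q)
  lab <- c(0, 1, 1, 0, 1)
  plain <- -mean(log(ifelse(lab == 1, q[, 2], q[, 1])))
  expect_equal(weightedLoss(q, lab, c(1, 1)), plain, tolerance = 1e-12)
  ## the 1:2 pEF:reduced ratio enters per sample
  manual <- -mean(ifelse(lab == 1, 2, 1) *
                  log(ifelse(lab == 1, q[, 2], q[, 1])))
  expect_equal(weightedLoss(q, lab, c(1, 2)), manual, tolerance = 1e-12)
  ## soft labels: weight is the label-blend of class weights
  soft <- cbind(c(0.3, 0.8), c(0.7, 0.2))
  probs <- cbind(c(0.6, 0.4), c(0.4, 0.6))
  byHand <- mean((soft %*% c(1, 2)) * -rowSums(soft * log(probs)))
  expect_equal(weightedLoss(probs, soft, c(1, 2)), byHand,
               tolerance = 1e-12)
  ## perfect predictions drive the loss to ~0
  perfect <- cbind(c(1, 0), c(0, 1)) * (1 - 1e-12) + 1e-12 / 2
  expect_lt(weightedLoss(perfect, c(0, 1), c(1, 2)), 1e-10)
  ## zero probability at the true class is clipped, not -Inf
  expect_true(is.finite(weightedLoss(cbind(c(1, 0), c(0, 1)), c(1, 0))))
})

test_that("analytic gradients agree with finite differences", {
  mc <- modelConfig(3L, 20L, filters = c(4L, 5L), kernels = c(3L, 3L),
                    pools = c(2L, 2L), fcWidth = 6L)
  set.seed(5)
  clf <- buildClassifier(mc)
  x <- array(rnorm(3 * 20 * 4), c(3, 20, 4))
  y <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  cw <- c(1, 2)
  lossOf <- function(cl) {
    f <- beatwise:::.nnForward(cl, x, training = TRUE)
    weightedLoss(t(f$probs), y, cw)
  }
  fwd <- beatwise:::.nnForward(clf, x, training = TRUE)
  grads <- beatwise:::.nnBackward(
    clf, fwd, beatwise:::.weightedLossGrad(fwd$probs, t(y), cw))
  for (nm in names(grads)) {
    g <- grads[[nm]]
    for (ii in sample(length(g), min(4L, length(g)))) {
      eps <- 1e-6
      up <- clf; up@params[[nm]][ii] <- up@params[[nm]][ii] + eps
      dn <- clf; dn@params[[nm]][ii] <- dn@params[[nm]][ii] - eps
      num <- (lossOf(up) - lossOf(dn)) / (2 * eps)
      expect_equal(g[ii], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss on a linearly separable toy problem", {
  set.seed(6)
  n <- 60
  xs <- array(rnorm(2 * 50 * n, sd = 0.3), c(2, 50, n))
  ys <- rep(0:1, each = n / 2)
  xs[1, 20:30, ys == 1] <- xs[1, 20:30, ys == 1] + 1.5
  tr <- list(x = xs, y = ys, case = sprintf("c%d", seq_len(n)))
  mc <- modelConfig(2L, 50L, filters = c(8L, 8L), kernels = c(5L, 3L),
                    pools = c(2L, 2L))
  fit <- trainFold(tr, tr, mc,
                   trainConfig(epochs = 8, batchSize = 16, seed = 5,
                               devLevel = "data"))
  h <- fit$history
  expect_lt(mean(tail(h$loss, 3)), mean(head(h$loss, 3)))
  expect_gt(max(h$dev_auc), 0.95)
  expect_identical(fit$bestEpoch, which.max(h$dev_auc))
})
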