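## User-facing classifier surface: construction, forward prediction, MixUp
## augmentation and the class-weighted (soft-label) cross-entropy.

#' Number of weighted layers of a configuration
#'
#' Convolutions and fully connected layers carry weights; batch-norm,
#' activation and pooling do not. The default configuration counts ten
#' (nine convolutional blocks plus the output layer).
#'
#' @param config A [ModelConfig-class].
#' @return Integer.
#' @export
nWeightedLayers <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  length(config@filters) + (config@fcWidth > 0L) + 1L
}

## Temporal length after each block's pooling.
.blockLengths <- function(config) {
  len <- config@inputLen
  vapply(seq_along(config@pools), function(b) {
    len <<- len %/% config@pools[b]
    len
  }, integer(1L))
}

#' Build a classifier
#'
#' Instantiates the block stack described by the configuration with
#' He-initialised convolution kernels (no conv bias: batch norm follows),
#' unit batch-norm scale, and a zero-bias fully connected output layer.
#' Weight initialisation draws from the current RNG stream.
#'
#' @param config A [ModelConfig-class]; rejected (naming the offending
#'   block) if pooling collapses the temporal length to zero.
#' @return An [EcgClassifier-class].
#' @export
#' @examples
#' set.seed(1)
#' clf <- buildClassifier(modelConfig(inChannels = 12, inputLen = 375))
#' clf
buildClassifier <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  params <- list()
  cin <- config@inChannels
  for (b in seq_along(config@filters)) {
    cout <- config@filters[b]; k <- config@kernels[b]
    params[[paste0("W", b)]] <-
      array(stats::rnorm(cout * cin * k, 0, sqrt(2 / (cin * k))),
            c(cout, cin, k))
    params[[paste0("g", b)]] <- rep(1, cout)
    params[[paste0("b", b)]] <- rep(0, cout)
    cin <- cout
  }
  flat <- cin * .blockLengths(config)[length(config@pools)]
  if (config@fcWidth > 0L) {
    params$Wh <- matrix(stats::rnorm(config@fcWidth * flat, 0,
                                     sqrt(2 / flat)),
                        config@fcWidth, flat)
    params$bh <- rep(0, config@fcWidth)
    flat <- config@fcWidth
  }
  params$Wfc <- matrix(stats::rnorm(config@nClasses * flat, 0,
                                    sqrt(2 / flat)),
                       config@nClasses, flat)
  params$bfc <- rep(0, config@nClasses)
  new("EcgClassifier", config = config, params = params,
      state = list(bn = rep(list(list()), length(config@filters)),
                   trained = FALSE))
}

#' Class probabilities for a batch
#'
#' @param clf An [EcgClassifier-class].
#' @param x Array (channels x length x batch) or a single channels x length
#'   matrix.
#' @return N x 2 matrix of probabilities, columns `pEF` and `reduced`; rows
#'   lie on the simplex.
#' @export
predictProba <- function(clf, x) {
  stopifnot(is(clf, "EcgClassifier"))
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (dim(x)[1L] != clf@config@inChannels)
    stop(sprintf("input has %d channels; model expects %d", dim(x)[1L],
                 clf@config@inChannels))
  n <- dim(x)[3L]
  ## bounded-memory forward: the im2col buffers grow with the batch
  chunk <- 256L
  p <- do.call(rbind, lapply(seq(1L, n, by = chunk), function(s) {
    idx <- s:min(s + chunk - 1L, n)
    t(.nnForward(clf, x[, , idx, drop = FALSE], training = FALSE)$probs)
  }))
  colnames(p) <- c("pEF", "reduced")
  p
}

#' MixUp augmentation
#'
#' Draws a single mixing weight lambda from Beta(alpha, alpha), a random
#' permutation pi of the batch, and returns
#' `lambda * x + (1 - lambda) * x[pi]` with labels mixed the same way.
#' Batches of one are returned unchanged. Uses the current RNG stream.
#'
#' @param x Channels x length x batch array.
#' @param y N x 2 one-hot (or already soft) label matrix.
#' @param alpha Beta concentration (> 0).
#' @param lambda Optional fixed mixing weight (bypasses the Beta draw).
#' @return List with mixed `x`, `y` and the `lambda` used.
#' @export
mixup <- function(x, y, alpha = 0.2, lambda = NULL) {
  stopifnot(alpha > 0)
  n <- dim(x)[3L]
  if (n < 2L) return(list(x = x, y = y, lambda = 1))
  if (is.null(lambda)) lambda <- stats::rbeta(1L, alpha, alpha)
  perm <- sample.int(n)
  xm <- lambda * x + (1 - lambda) * x[, , perm, drop = FALSE]
  ym <- lambda * y + (1 - lambda) * y[perm, , drop = FALSE]
  list(x = xm, y = ym, lambda = lambda)
}

#' Class-weighted cross-entropy
#'
#' Mean over samples of `w_i * CE_i`, where `CE_i` is the (soft-label)
#' cross-entropy of sample i and `w_i = sum_c y_ic * classWeights_c` — for
#' hard labels simply the weight of the true class, and under MixUp the
#' lambda-blend of the two mixed classes' weights. The reduced-LVEF class
#' carries twice the weight of pEF by default. Probabilities are floored at
#' machine epsilon before the log.
#'
#' @param probs N x 2 probability matrix (columns pEF, reduced).
#' @param labels Either an integer/logical vector (1/TRUE = reduced) or an
#'   N x 2 one-hot/soft matrix.
#' @param classWeights Positive weights, `c(pEF, reduced)`.
#' @return Scalar loss.
#' @export
#' @examples
#' p <- matrix(0.5, 2, 2)
#' weightedLoss(p, c(0, 1))             # 1.5 * log(2)
weightedLoss <- function(probs, labels, classWeights = c(pEF = 1,
                                                         reduced = 2)) {
  stopifnot(all(classWeights > 0))
  if (!is.matrix(labels)) {
    lab <- as.integer(labels)
    stopifnot(all(lab %in% c(0L, 1L)))
    labels <- cbind(1 - lab, lab)
  }
  stopifnot(nrow(labels) == nrow(probs), ncol(probs) == 2L)
  p <- pmax(probs, .Machine$double.eps)
  w <- drop(labels %*% classWeights)
  ce <- -rowSums(labels * log(p))
  mean(w * ce)
}

## Gradient of weightedLoss wrt logits, for the training loop:
## d/dz = w_i * (p - y) / N. probs/labels as (nClasses x N).
.weightedLossGrad <- function(probs, y, classWeights) {
  w <- drop(crossprod(y, classWeights))          # length N
  (probs - y) * matrix(w, nrow(probs), ncol(probs), byrow = TRUE) /
    ncol(probs)
}
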