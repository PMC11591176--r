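## Stratified splitting, model training with dev-checkpoint selection, and
## case-level evaluation.

#' Build a stratified fold plan with a fixed test subset
#'
#' Cases are shuffled within each EF class and dealt round-robin into five
#' subsets, so per-class sizes differ by at most one case across subsets.
#' Subset 5 is the fixed test set; folds 1--4 use subset f as development
#' and the remaining three rotating subsets as training. Splitting is at
#' case level: every tensor derived from a case inherits its subset.
#'
#' @param manifest data.frame with columns `case_id` and `ef_class` (e.g.
#'   from [cohortManifest()]); every class needs at least 5 cases.
#' @param seed Integer seed; the plan is a deterministic function of
#'   (manifest, seed).
#' @return A [FoldPlan-class].
#' @export
#' @examples
#' man <- data.frame(case_id = sprintf("c%02d", 1:20),
#'                   ef_class = rep(c("pEF", "rEF"), each = 10))
#' makeFoldPlan(man, seed = 1)
makeFoldPlan <- function(manifest, seed = 1L) {
  stopifnot(all(c("case_id", "ef_class") %in% names(manifest)))
  tab <- table(manifest$ef_class)
  if (any(tab < 5L))
    stop("every EF class needs >= 5 cases; got: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  subsets <- rep(list(character(0L)), 5L)
  .withSeed(seed, {
    for (cl in sort(unique(manifest$ef_class))) {
      ids <- sample(manifest$case_id[manifest$ef_class == cl])
      sub <- rep(1:5, length.out = length(ids))
      for (s in 1:5)
        subsets[[s]] <- c(subsets[[s]], ids[sub == s])
    }
  })
  strata <- stats::setNames(manifest$ef_class, manifest$case_id)
  new("FoldPlan", subsets = subsets, strata = strata)
}

#' Case ids of one fold's train/dev/test split
#'
#' @param plan A [FoldPlan-class].
#' @param fold Fold index 1--4.
#' @return List with character vectors `train`, `dev`, `test`; asserted
#'   pairwise disjoint.
#' @export
foldSplit <- function(plan, fold) {
  stopifnot(is(plan, "FoldPlan"), fold %in% 1:4)
  dev <- plan@subsets[[fold]]
  train <- unlist(plan@subsets[setdiff(1:4, fold)], use.names = FALSE)
  test <- plan@subsets[[5L]]
  stopifnot(length(intersect(train, dev)) == 0L,
            length(intersect(train, test)) == 0L,
            length(intersect(dev, test)) == 0L)
  list(train = train, dev = dev, test = test)
}

#' Training hyperparameters
#'
#' @param epochs Training epochs (>= 1).
#' @param batchSize Mini-batch size.
#' @param lr Adam learning rate.
#' @param mixupAlpha MixUp Beta concentration; 0 disables MixUp (as in the
#'   reduced-lead analyses).
#' @param classWeights Loss weights `c(pEF, reduced)`; reduced LVEF carries
#'   twice the weight by default.
#' @param seed Seed for initialisation, shuffling and MixUp draws.
#' @param devLevel Checkpoint-selection metric level: `"case"` (mean
#'   probability per case) or `"data"` (per tensor).
#' @return List of hyperparameters for [trainFold()].
#' @export
trainConfig <- function(epochs = 10L, batchSize = 32L, lr = 1e-3,
                        mixupAlpha = 0.2,
                        classWeights = c(pEF = 1, reduced = 2),
                        seed = 1L, devLevel = c("case", "data")) {
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       lr = lr, mixupAlpha = mixupAlpha, classWeights = classWeights,
       seed = as.integer(seed), devLevel = match.arg(devLevel))
}

#' Bundle tensors with labels into a training set
#'
#' @param tensors List of [BeatTensor-class]/[StripTensor-class] objects
#'   sharing one shape.
#' @param labelMap Named logical/0-1 vector per case id: TRUE/1 = reduced
#'   LVEF (< 50%).
#' @return List with `x` (C x L x N array), `y` (integer 0/1 per tensor) and
#'   `case` (character per tensor).
#' @export
tensorSet <- function(tensors, labelMap) {
  st <- stackTensors(tensors)
  y <- as.integer(labelMap[st$meta$case_id])
  if (anyNA(y)) stop("labelMap lacks labels for some cases")
  list(x = st$x, y = y, case = st$meta$case_id)
}

## AUC + threshold metrics of a classifier on a tensor set, at case or data
## level.
.evalOn <- function(clf, set, level = "case", threshold = 0.5) {
  if (level == "case") {
    pc <- predictCaseLevel(clf, set)
    scores <- pc$score; labels <- pc$label
  } else {
    scores <- predictProba(clf, set$x)[, "reduced"]
    labels <- set$y
  }
  auc <- if (length(unique(labels)) == 2L) computeAuc(scores, labels)
         else NA_real_
  c(auc = auc, thresholdMetrics(scores, labels, threshold))
}

#' Train one fold with dev-based checkpoint selection
#'
#' Minimises the class-weighted binary cross-entropy with Adam, optionally
#' applying MixUp to every mini-batch, and returns the epoch checkpoint that
#' maximises the development AUC. Standardisation must already have been
#' applied using training statistics only. Training aborts with a diagnostic
#' if the loss diverges to NaN.
#'
#' @param train,dev Tensor sets from [tensorSet()] (already standardised).
#' @param modelConfig A [ModelConfig-class] matching the tensor shape.
#' @param control Hyperparameters from [trainConfig()]; `epochs >= 1`.
#' @return List with `classifier` (best checkpoint), `history` (per-epoch
#'   loss and dev metrics) and `bestEpoch`.
#' @export
trainFold <- function(train, dev, modelConfig, control = trainConfig()) {
  if (control$epochs < 1L) stop("epoch budget must be >= 1")
  n <- dim(train$x)[3L]
  stopifnot(n >= 2L, length(train$y) == n)
  .withSeed(control$seed, {
    clf <- buildClassifier(modelConfig)
    opt <- list(t = 0L, m = list(), v = list())
    best <- list(auc = -Inf, params = clf@params, state = clf@state,
                 epoch = 0L)
    hist <- vector("list", control$epochs)
    for (ep in seq_len(control$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = control$batchSize)) {
        idx <- ord[start:min(start + control$batchSize - 1L, n)]
        if (length(idx) < 2L) next
        xb <- train$x[, , idx, drop = FALSE]
        yb <- cbind(1 - train$y[idx], train$y[idx])
        if (control$mixupAlpha > 0) {
          mx <- mixup(xb, yb, control$mixupAlpha)
          xb <- mx$x; yb <- mx$y
        }
        fwd <- .nnForward(clf, xb, training = TRUE)
        clf@state <- fwd$state
        loss <- weightedLoss(t(fwd$probs), yb, control$classWeights)
        if (!is.finite(loss))
          stop(sprintf("divergent loss (%.3g) at epoch %d", loss, ep))
        losses <- c(losses, loss)
        dlogits <- .weightedLossGrad(fwd$probs, t(yb), control$classWeights)
        grads <- .nnBackward(clf, fwd, dlogits)
        upd <- .nnAdamStep(clf@params, grads, opt, control$lr)
        clf@params <- upd$params
        opt <- upd$opt
      }
      ev <- .evalOn(clf, dev, level = control$devLevel)
      hist[[ep]] <- data.frame(epoch = ep, loss = mean(losses),
                               dev_auc = ev[["auc"]],
                               dev_accuracy = ev[["accuracy"]])
      if (is.finite(ev[["auc"]]) && ev[["auc"]] > best$auc)
        best <- list(auc = ev[["auc"]], params = clf@params,
                     state = clf@state, epoch = ep)
    }
    clf@params <- best$params
    clf@state <- best$state
    clf@state$trained <- TRUE
    list(classifier = clf, history = do.call(rbind, hist),
         bestEpoch = best$epoch)
  })
}

#' Case-level scores
#'
#' The score of a case is the mean predicted reduced-LVEF probability over
#' all the case's tensors (strips or beats); alternative aggregations are
#' available.
#'
#' @param clf A trained [EcgClassifier-class].
#' @param set A tensor set from [tensorSet()].
#' @param aggregate `"mean"` (default), `"median"` or `"majority"`.
#' @return data.frame with one row per case: `case_id`, `score`, `label`.
#' @export
predictCaseLevel <- function(clf, set,
                             aggregate = c("mean", "median", "majority")) {
  aggregate <- match.arg(aggregate)
  p <- predictProba(clf, set$x)[, "reduced"]
  agg <- switch(aggregate, mean = mean, median = stats::median,
                majority = function(v) mean(v > 0.5))
  sp <- split(seq_along(p), set$case)
  data.frame(
    case_id = names(sp),
    score = vapply(sp, function(i) agg(p[i]), numeric(1L)),
    label = vapply(sp, function(i) set$y[i[1L]], integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability via midranks, so
#' tied scores count one half.
#'
#' @param scores Numeric scores (higher = more likely reduced).
#' @param labels 0/1 or logical labels (1/TRUE = reduced); both classes must
#'   be present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' computeAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
computeAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Accuracy, sensitivity and specificity at a threshold
#'
#' Sensitivity is computed on the reduced-LVEF class (score >= threshold
#' calls reduced). When a class is absent its metric is `NA`, not 0.
#'
#' @param scores,labels As in [computeAuc()].
#' @param threshold Operating point in \[0, 1\] on the probability scale.
#' @return Named numeric: `accuracy`, `sensitivity`, `specificity`.
#' @export
thresholdMetrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  labels <- as.integer(labels)
  call <- as.integer(scores >= threshold)
  tp <- sum(call == 1L & labels == 1L); fn <- sum(call == 0L & labels == 1L)
  tn <- sum(call == 0L & labels == 0L); fp <- sum(call == 1L & labels == 0L)
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_)
}

#' Compare configurations across folds
#'
#' Two configurations are compared with Student's t-test on their per-fold
#' AUCs; three or more with one-way ANOVA plus Tukey's HSD. Reports mean and
#' standard deviation per configuration and the relevant p-values
#' (significance at 0.05).
#'
#' @param results data.frame with columns `configuration`, `fold`, `auc`
#'   (e.g. rows of experiment EvalResults).
#' @param requireBalanced Reject unequal per-configuration fold counts
#'   (default); lead-count bin comparisons disable this.
#' @return List with `summary` (mean, sd, n per configuration), `method`,
#'   `p_value` (global test) and, for >= 3 groups, `tukey` (pairwise
#'   contrasts with adjusted p-values).
#' @export
compareConfigurations <- function(results, requireBalanced = TRUE) {
  stopifnot(all(c("configuration", "auc") %in% names(results)))
  cfgs <- unique(results$configuration)
  if (length(cfgs) < 2L) stop("need at least two configurations")
  counts <- table(results$configuration)
  if (requireBalanced && length(unique(counts)) != 1L)
    stop("unequal fold counts across configurations")
  smry <- do.call(rbind, lapply(cfgs, function(cf) {
    a <- results$auc[results$configuration == cf]
    data.frame(configuration = cf, mean = mean(a), sd = stats::sd(a),
               n = length(a))
  }))
  if (length(cfgs) == 2L) {
    a <- results$auc[results$configuration == cfgs[1L]]
    b <- results$auc[results$configuration == cfgs[2L]]
    p <- if (stats::sd(c(a, b)) == 0) 1
         else stats::t.test(a, b, var.equal = TRUE)$p.value
    list(summary = smry, method = "t", p_value = p, tukey = NULL)
  } else {
    df <- data.frame(auc = results$auc,
                     configuration = factor(results$configuration))
    fit <- stats::aov(auc ~ configuration, data = df)
    p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tk <- as.data.frame(stats::TukeyHSD(fit)$configuration)
    tk$contrast <- rownames(tk); rownames(tk) <- NULL
    list(summary = smry, method = "anova_tukey", p_value = p, tukey = tk)
  }
}

#' @rdname compareConfigurations
#' @param x,g For `compareCategorical`, a contingency table or two factors
#'   (chi-square test); for `compareNonparametric`, a numeric response and a
#'   grouping factor (Kruskal-Wallis test).
#' @return `compareCategorical`/`compareNonparametric`: the corresponding
#'   `htest` object.
#' @export
compareCategorical <- function(x, g = NULL) {
  if (is.null(g)) stats::chisq.test(x) else stats::chisq.test(x, g)
}

#' @rdname compareConfigurations
#' @export
compareNonparametric <- function(x, g) stats::kruskal.test(x, g)
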