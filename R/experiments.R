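## Experiment runners: representation comparison (3 s strip vs single-beat
## vs two-beat), intra-beat segment comparison, and the lead-subset
## ensemble with per-lead contributions. All runners are deterministic
## functions of (cohort, arguments, seed).

.REPRESENTATIONS <- c("strip3s", "single_beat", "two_beat")

## Cheap rolling hash of a configuration, for report provenance.
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

## Per-record preprocessing shared across folds: annotations, single beats,
## two-beat stacks and strips per split role.
.precomputeBeats <- function(records, annotations = c("delineate", "truth"),
                             segment = "PQRST", leads = NULL) {
  annotations <- match.arg(annotations)
  out <- list()
  for (rec in records) {
    ann <- if (annotations == "truth") truthBeats(rec) else delineate(rec)
    beats <- extractSingleBeats(rec, ann)
    if (segment != "PQRST" && length(beats))
      beats <- lapply(beats, function(b)
        makePartial(b, ann[b@beatIndex, , drop = FALSE], segment))
    if (!is.null(leads) && length(beats))
      beats <- lapply(beats, subsetLeads, leads = leads)
    out[[caseId(rec)]] <- list(ann = ann, beats = beats)
  }
  out
}

## Build standardised tensor sets for one fold and representation.
.foldTensorSets <- function(cohort, plan, fold, representation, pre = NULL,
                            labelMap = NULL) {
  split <- foldSplit(plan, fold)
  recs <- cohortRecords(cohort)
  names(recs) <- vapply(recs, caseId, character(1L))
  if (is.null(labelMap)) {
    man <- cohortManifest(cohort)
    labelMap <- stats::setNames(as.integer(man$reduced), man$case_id)
  }
  collect <- function(ids, role) {
    tensors <- list()
    for (id in ids) {
      tl <- if (representation == "strip3s") {
        extractStrips(recs[[id]], splitRole = role)
      } else if (representation == "two_beat") {
        composeTwoBeats(pre[[id]]$beats)
      } else {
        pre[[id]]$beats
      }
      tensors <- c(tensors, tl)
    }
    tensors
  }
  tr <- collect(split$train, "train")
  dv <- collect(split$dev, "dev")
  te <- collect(split$test, "test")
  if (length(tr) == 0L) stop("fold ", fold, ": no training tensors")
  std <- fitStandardiser(tr)
  list(train = tensorSet(applyStandardiser(std, tr), labelMap),
       dev = tensorSet(applyStandardiser(std, dv), labelMap),
       test = tensorSet(applyStandardiser(std, te), labelMap),
       standardiser = std)
}

## Train on one fold's sets and evaluate on the fixed test subset.
.runOneModel <- function(sets, modelConfig, control, label, fold,
                         level = "case") {
  fit <- trainFold(sets$train, sets$dev, modelConfig, control)
  ev <- .evalOn(fit$classifier, sets$test, level = level)
  data.frame(configuration = label, fold = fold, level = level,
             auc = ev[["auc"]], accuracy = ev[["accuracy"]],
             sensitivity = ev[["sensitivity"]],
             specificity = ev[["specificity"]],
             best_epoch = fit$bestEpoch, stringsAsFactors = FALSE)
}

.deriveSeed <- function(seed, fold, idx) {
  as.integer((seed * 1009L + fold * 97L + idx * 7L) %% 2147483L)
}

#' Compare 3 s strip, single-beat and two-beat representations
#'
#' Trains one classifier per representation and fold, evaluates each on the
#' fixed test subset at case level, and compares per-fold AUCs across
#' representations (ANOVA + Tukey HSD for the three groups).
#'
#' @param cohort An [EcgCohort-class].
#' @param folds Folds to run (subset of 1:4).
#' @param modelConfigs Optional named list of [ModelConfig-class] overrides
#'   per representation (`strip3s`, `single_beat`, `two_beat`); defaults to
#'   the ten-weighted-layer configuration at the matching input shape.
#' @param control Hyperparameters from [trainConfig()].
#' @param annotations `"delineate"` (run the detector) or `"truth"`
#'   (generator fiducials).
#' @param planSeed Seed for the fold plan.
#' @return Report list: `results` (one EvalResult row per representation and
#'   fold), `comparison`, `ranking` (configurations by mean AUC, best
#'   first), `seeds`, `config_hash`.
#' @export
runRepresentationExperiment <- function(cohort, folds = 1:4,
                                        modelConfigs = NULL,
                                        control = trainConfig(),
                                        annotations = "delineate",
                                        planSeed = control$seed) {
  stopifnot(is(cohort, "EcgCohort"))
  man <- cohortManifest(cohort)
  plan <- makeFoldPlan(data.frame(case_id = man$case_id,
                                  ef_class = man$ef_class), planSeed)
  pre <- .precomputeBeats(cohortRecords(cohort), annotations)
  defaults <- list(strip3s = modelConfig(12L, 1500L),
                   single_beat = modelConfig(12L, 375L),
                   two_beat = modelConfig(24L, 375L))
  res <- list()
  for (i in seq_along(.REPRESENTATIONS)) {
    rep_ <- .REPRESENTATIONS[i]
    mc <- if (!is.null(modelConfigs[[rep_]])) modelConfigs[[rep_]]
          else defaults[[rep_]]
    for (f in folds) {
      sets <- .foldTensorSets(cohort, plan, f, rep_, pre)
      ctl <- control
      ctl$seed <- .deriveSeed(control$seed, f, i)
      res[[length(res) + 1L]] <-
        .runOneModel(sets, mc, ctl, rep_, f)
    }
  }
  results <- do.call(rbind, res)
  cmp <- if (length(unique(results$configuration)) >= 2L &&
             length(folds) >= 2L)
    compareConfigurations(results) else NULL
  agg <- tapply(results$auc, results$configuration, mean)
  list(results = results,
       comparison = cmp,
       ranking = names(sort(agg, decreasing = TRUE)),
       seeds = list(master = control$seed, plan = planSeed),
       config_hash = .configHash(list(control, lapply(defaults, function(m)
         m@filters))))
}

#' Compare intra-beat partial-segment models
#'
#' Trains a single-beat classifier per segment kind (P, PQRS, QRS, QRST,
#' PQRST) and fold, evaluates at case level on the fixed test subset, and
#' ranks the segments.
#'
#' @inheritParams runRepresentationExperiment
#' @param segments Segment kinds to run.
#' @param modelConfig A 12-channel, 375-sample [ModelConfig-class] used for
#'   every segment.
#' @return Report list as in [runRepresentationExperiment()].
#' @export
runSegmentExperiment <- function(cohort,
                                 segments = c("P", "PQRS", "QRS", "QRST",
                                              "PQRST"),
                                 folds = 1:4,
                                 modelConfig = modelConfig(12L, 375L),
                                 control = trainConfig(),
                                 annotations = "delineate",
                                 planSeed = control$seed) {
  stopifnot(is(cohort, "EcgCohort"))
  man <- cohortManifest(cohort)
  plan <- makeFoldPlan(data.frame(case_id = man$case_id,
                                  ef_class = man$ef_class), planSeed)
  res <- list()
  for (i in seq_along(segments)) {
    seg <- segments[i]
    pre <- .precomputeBeats(cohortRecords(cohort), annotations,
                            segment = seg)
    for (f in folds) {
      sets <- .foldTensorSets(cohort, plan, f, "single_beat", pre)
      ctl <- control
      ctl$seed <- .deriveSeed(control$seed, f, i)
      res[[length(res) + 1L]] <- .runOneModel(sets, modelConfig, ctl, seg, f)
    }
  }
  results <- do.call(rbind, res)
  cmp <- if (length(segments) >= 2L && length(folds) >= 2L)
    compareConfigurations(results) else NULL
  agg <- tapply(results$auc, results$configuration, mean)
  list(results = results, comparison = cmp,
       ranking = names(sort(agg, decreasing = TRUE)),
       seeds = list(master = control$seed, plan = planSeed),
       config_hash = .configHash(list(control, segments)))
}

#' Lead-subset ensemble and per-lead contributions
#'
#' Trains one reduced-lead single-beat classifier per lead set, evaluates at
#' the data level (per tensor, not per case), and derives the per-lead
#' contribution table: mean metric of models whose set contains the lead
#' minus mean metric of those lacking it. MixUp is disabled by default for
#' these reduced-lead runs.
#'
#' @inheritParams runRepresentationExperiment
#' @param leadSets List of lead subsets (see [enumerateLeadSets()]); at
#'   least two sets.
#' @param fold Single fold to run (the ensemble is large; run more folds by
#'   calling repeatedly).
#' @param modelConfig Template [ModelConfig-class]; its channel count is
#'   adapted to each lead set.
#' @return Report list: `results` (one data-level EvalResult row per lead
#'   set, with its `leads` label), `contribution` (per-lead delta table),
#'   `byLeadCount` (bin comparison, when the ensemble spans >= 2 bins),
#'   `seeds`, `config_hash`.
#' @export
runLeadExperiment <- function(cohort,
                              leadSets = enumerateLeadSets("singles"),
                              fold = 1L,
                              modelConfig = modelConfig(12L, 375L),
                              control = trainConfig(mixupAlpha = 0,
                                                    devLevel = "data"),
                              annotations = "delineate",
                              planSeed = control$seed) {
  stopifnot(is(cohort, "EcgCohort"))
  if (length(leadSets) < 2L) stop("need an ensemble of >= 2 lead sets")
  man <- cohortManifest(cohort)
  plan <- makeFoldPlan(data.frame(case_id = man$case_id,
                                  ef_class = man$ef_class), planSeed)
  preFull <- .precomputeBeats(cohortRecords(cohort), annotations)
  res <- list()
  for (i in seq_along(leadSets)) {
    leads <- leadSets[[i]]
    pre <- lapply(preFull, function(p)
      list(ann = p$ann,
           beats = lapply(p$beats, subsetLeads, leads = leads)))
    sets <- .foldTensorSets(cohort, plan, fold, "single_beat", pre)
    mc <- initialize(modelConfig, inChannels = length(leads))
    ctl <- control
    ctl$seed <- .deriveSeed(control$seed, fold, i)
    row <- .runOneModel(sets, mc, ctl, leadSetLabel(leads), fold,
                        level = "data")
    row$leads <- leadSetLabel(leads)
    res[[length(res) + 1L]] <- row
  }
  results <- do.call(rbind, res)
  contrib <- tryCatch(leadContribution(results), error = function(e) NULL)
  byCount <- tryCatch(groupByLeadCount(results), error = function(e) NULL)
  list(results = results, contribution = contrib, byLeadCount = byCount,
       seeds = list(master = control$seed, plan = planSeed),
       config_hash = .configHash(list(control,
                                      lapply(leadSets, paste,
                                             collapse = "+"))))
}

#' Serialise an experiment report to JSON
#'
#' @param report A report list from one of the experiment runners.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeExperimentReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
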