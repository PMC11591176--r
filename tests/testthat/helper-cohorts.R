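## Shared fixtures, built once per test run. Cohorts are small (desk scale)
## but use the generator's default noise/wander levels unless a test needs
## the noise-free regime.

## Clean regime: no noise, no wander, no AF, fixed heart rate. Used for
## exact-arithmetic checks (closure, fiducials, padding).
quietConfig <- function(...) {
  args <- utils::modifyList(
    list(noiseSd = 0, baselineWanderAmp = 0,
         afFraction = c(pEF = 0, mrEF = 0, rEF = 0),
         heartRateSd = 0, rrJitterSd = 0),
    list(...))
  do.call(cohortConfig, args)
}

## One clean record at 60 bpm: exactly 10 beats, analytically placed.
quietRecord <- local({
  cfg <- quietConfig(heartRateMean = 60, seed = 5)
  set.seed(5)
  simulateRecord(cfg, lvef = 60, caseId = "quiet_01")
})

## Compact model configurations for recovery runs (three blocks; the
## ten-layer default is exercised separately in the model tests).
mcBeat <- modelConfig(12L, 375L, filters = c(8L, 16L, 16L),
                      kernels = c(7L, 5L, 3L), pools = c(3L, 3L, 3L))
mcTwo <- modelConfig(24L, 375L, filters = c(8L, 16L, 16L),
                     kernels = c(7L, 5L, 3L), pools = c(3L, 3L, 3L))
mcStrip <- modelConfig(12L, 1500L, filters = c(8L, 16L, 16L),
                       kernels = c(7L, 5L, 3L), pools = c(5L, 4L, 3L))
mcLead <- modelConfig(1L, 375L, filters = c(8L, 16L, 16L),
                      kernels = c(7L, 5L, 3L), pools = c(3L, 3L, 3L))

## 60-case cohorts: a strong T-wave effect on all leads (segment recovery),
## a lead-I-restricted T effect (lead recovery), and a null cohort.
effectCohort <- makeCohort(cohortConfig(
  nCases = c(pEF = 30, mrEF = 15, rEF = 15),
  afFraction = c(pEF = 0, mrEF = 0, rEF = 0),
  effects = list(effectSpec("ST-T", ecgLeadNames(),
                            amplitudeMultiplier = 0.45)),
  seed = 101))

leadCohort <- makeCohort(cohortConfig(
  nCases = c(pEF = 30, mrEF = 15, rEF = 15),
  afFraction = c(pEF = 0, mrEF = 0, rEF = 0),
  effects = list(effectSpec("ST-T", "I", amplitudeMultiplier = 0.4)),
  seed = 202))

nullCohort <- makeCohort(cohortConfig(
  nCases = c(pEF = 30, mrEF = 15, rEF = 15),
  afFraction = c(pEF = 0, mrEF = 0, rEF = 0),
  seed = 303))

## Single-beat tensor sets of one fold of the null cohort, for permutation
## controls: standardised on train statistics.
nullBeatSets <- local({
  man <- cohortManifest(nullCohort)
  plan <- makeFoldPlan(man, seed = 17)
  split <- foldSplit(plan, 1L)
  labelMap <- stats::setNames(as.integer(man$reduced), man$case_id)
  recs <- cohortRecords(nullCohort)
  names(recs) <- vapply(recs, caseId, character(1L))
  beatsOf <- function(ids) unlist(lapply(ids, function(id)
    extractSingleBeats(recs[[id]])), recursive = FALSE)
  tr <- beatsOf(split$train); dv <- beatsOf(split$dev)
  std <- fitStandardiser(tr)
  list(train = tensorSet(applyStandardiser(std, tr), labelMap),
       dev = tensorSet(applyStandardiser(std, dv), labelMap))
})

## Brute-force O(n^2) Mann-Whitney oracle for AUC checks.
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

## Build standardised train/dev/test tensor sets for one representation and
## fold, through the exported API only.
buildSets <- function(cohort, representation = c("single_beat", "two_beat",
                                                 "strip3s"),
                      fold = 1L, planSeed = 17L) {
  representation <- match.arg(representation)
  man <- cohortManifest(cohort)
  plan <- makeFoldPlan(man, seed = planSeed)
  split <- foldSplit(plan, fold)
  labelMap <- stats::setNames(as.integer(man$reduced), man$case_id)
  recs <- cohortRecords(cohort)
  names(recs) <- vapply(recs, caseId, character(1L))
  tensorsOf <- function(ids, role) {
    unlist(lapply(ids, function(id) {
      if (representation == "strip3s")
        return(extractStrips(recs[[id]], splitRole = role))
      beats <- extractSingleBeats(recs[[id]])
      if (representation == "two_beat") composeTwoBeats(beats) else beats
    }), recursive = FALSE)
  }
  tr <- tensorsOf(split$train, "train")
  std <- fitStandardiser(tr)
  mk <- function(tensors) tensorSet(applyStandardiser(std, tensors),
                                    labelMap)
  list(train = mk(tr),
       dev = mk(tensorsOf(split$dev, "dev")),
       test = mk(tensorsOf(split$test, "test")),
       std = std, labelMap = labelMap, plan = plan)
}

## Tensor set over a whole (fresh) cohort, standardised with an existing
## train standardiser -- used to evaluate null controls on many cases.
wholeCohortSet <- function(cohort, representation, std) {
  man <- cohortManifest(cohort)
  labelMap <- stats::setNames(as.integer(man$reduced), man$case_id)
  tensors <- unlist(lapply(cohortRecords(cohort), function(rec) {
    if (representation == "strip3s")
      return(extractStrips(rec, splitRole = "test"))
    beats <- extractSingleBeats(rec)
    if (representation == "two_beat") composeTwoBeats(beats) else beats
  }), recursive = FALSE)
  tensorSet(applyStandardiser(std, tensors), labelMap)
}
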