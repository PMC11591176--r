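#' @import methods
NULL

## ---------------------------------------------------------------------------
## WaveParams: parametric P/Q/R/S/T morphology (Gaussian wavelets)
## ---------------------------------------------------------------------------

#' Parametric beat morphology
#'
#' Each of the five canonical ECG waves (P, Q, R, S, T) is modelled as a
#' Gaussian wavelet with an amplitude (mV, on the dominant dipole axis), a
#' width (ms, the Gaussian sigma) and a latency relative to the R peak (ms).
#' A beat is the sum of the five wavelets; fiducial points (QRS onset, ST
#' junction, T end) are derived analytically as latency +/- 2.5 sigma, so the
#' generator knows the ground truth exactly.
#'
#' @slot amplitude Named numeric (P, Q, R, S, T), mV.
#' @slot width Named numeric, Gaussian sigma in ms; all > 0.
#' @slot latency Named numeric, wave centre relative to the R peak in ms;
#'   strictly increasing in the order P < Q < R < S < T.
#' @export
setClass("WaveParams",
  representation(amplitude = "numeric", width = "numeric",
                 latency = "numeric"))

setValidity("WaveParams", function(object) {
  for (sl in c("amplitude", "width", "latency")) {
    v <- slot(object, sl)
    if (!identical(names(v), .WAVES))
      return(sprintf("%s must be named %s", sl, paste(.WAVES, collapse = ", ")))
    if (any(!is.finite(v))) return(sprintf("%s must be finite", sl))
  }
  if (any(object@width <= 0)) return("widths must be > 0")
  if (any(diff(object@latency) <= 0))
    return("latencies must be ordered P < Q < R < S < T")
  if (object@amplitude[["R"]] < 0) return("R amplitude must be >= 0")
  TRUE
})

#' Default beat morphology
#'
#' Typical adult sinus-beat parameters: a small upright P wave about 170 ms
#' before the R peak, a narrow QRS (Q and S deflections flanking a 1 mV R
#' wave), and a broad T wave about 310 ms after the R peak.
#'
#' @param amplitude,width,latency Optional named overrides (names among
#'   P, Q, R, S, T).
#' @return A [WaveParams-class] object.
#' @export
#' @examples
#' waveParams()
#' waveParams(amplitude = c(T = 0.15))
waveParams <- function(amplitude = NULL, width = NULL, latency = NULL) {
  amp <- c(P = 0.12, Q = -0.10, R = 1.00, S = -0.22, T = 0.30)
  wid <- c(P = 22,   Q = 9,     R = 11,   S = 10,    T = 60)
  lat <- c(P = -170, Q = -28,   R = 0,    S = 28,    T = 310)
  if (!is.null(amplitude)) amp[names(amplitude)] <- amplitude
  if (!is.null(width)) wid[names(width)] <- width
  if (!is.null(latency)) lat[names(latency)] <- latency
  new("WaveParams", amplitude = amp, width = wid, latency = lat)
}

## ---------------------------------------------------------------------------
## EffectSpec: the planted class-dependent waveform effect
## ---------------------------------------------------------------------------

#' Planted class-dependent waveform effect
#'
#' Describes a discriminative signal injected into the synthetic cohort: for
#' records in the listed reduced-EF classes, the targeted wave's amplitude
#' and/or width is multiplied on the targeted leads. Because the location of
#' the effect is known, it serves as ground truth for recovery experiments
#' (which segment and which leads a classifier should find informative).
#'
#' @slot targetWave One of `"P"`, `"QRS"` (applies to Q, R and S wavelets) or
#'   `"ST-T"` (applies to the T wavelet).
#' @slot targetLeads Non-empty subset of [ecgLeadNames()].
#' @slot amplitudeMultiplier,widthMultiplier Positive dimensionless factors.
#' @slot classes Subset of `c("mrEF", "rEF")` the effect applies to.
#' @export
setClass("EffectSpec",
  representation(targetWave = "character", targetLeads = "character",
                 amplitudeMultiplier = "numeric", widthMultiplier = "numeric",
                 classes = "character"))

setValidity("EffectSpec", function(object) {
  if (length(object@targetWave) != 1L ||
      !object@targetWave %in% c("P", "QRS", "ST-T"))
    return("targetWave must be one of P, QRS, ST-T")
  if (length(object@targetLeads) == 0L ||
      !all(object@targetLeads %in% .LEADS))
    return("targetLeads must be a non-empty subset of the 12 lead names")
  if (object@amplitudeMultiplier <= 0 || object@widthMultiplier <= 0)
    return("multipliers must be > 0")
  if (length(object@classes) == 0L ||
      !all(object@classes %in% c("mrEF", "rEF")))
    return("classes must be a non-empty subset of mrEF, rEF")
  TRUE
})

#' @rdname EffectSpec-class
#' @param targetWave,targetLeads,amplitudeMultiplier,widthMultiplier,classes
#'   See the corresponding slots.
#' @return An `EffectSpec` object.
#' @export
#' @examples
#' effectSpec("ST-T", ecgLeadNames(), amplitudeMultiplier = 0.5)
effectSpec <- function(targetWave, targetLeads = ecgLeadNames(),
                       amplitudeMultiplier = 1, widthMultiplier = 1,
                       classes = c("mrEF", "rEF")) {
  new("EffectSpec", targetWave = targetWave, targetLeads = targetLeads,
      amplitudeMultiplier = amplitudeMultiplier,
      widthMultiplier = widthMultiplier, classes = classes)
}

## ---------------------------------------------------------------------------
## CohortConfig
## ---------------------------------------------------------------------------

#' Synthetic cohort configuration
#'
#' Bundles everything the generator needs: per-class case counts, heart-rate
#' and RR-variability parameters, the atrial-fibrillation fraction per class,
#' noise and baseline-wander levels, the 12 x k lead-projection matrix mapping
#' k dipole source channels to the 12 leads, the beat morphology, the list of
#' planted [EffectSpec-class] effects, and the master seed.
#'
#' @slot nCases Named non-negative integer counts (pEF, mrEF, rEF).
#' @slot heartRateMean,heartRateSd Per-record heart rate distribution, bpm.
#' @slot rrJitterSd Within-record RR jitter (sinus rhythm), ms.
#' @slot afFraction Named proportions in \[0,1\] per class.
#' @slot noiseSd Additive per-lead measurement noise, mV.
#' @slot baselineWanderAmp,baselineWanderFreq Baseline wander amplitude (mV)
#'   and frequency (Hz); wander is added to the source channels before lead
#'   projection so the limb-lead algebra is preserved.
#' @slot leadProjection 12 x k numeric matrix, rows in canonical lead order.
#' @slot waves A [WaveParams-class] object.
#' @slot effects List of [EffectSpec-class] objects.
#' @slot seed Integer master seed.
#' @export
setClass("CohortConfig",
  representation(nCases = "integer", heartRateMean = "numeric",
                 heartRateSd = "numeric", rrJitterSd = "numeric",
                 afFraction = "numeric", noiseSd = "numeric",
                 baselineWanderAmp = "numeric", baselineWanderFreq = "numeric",
                 leadProjection = "matrix", waves = "WaveParams",
                 effects = "list", seed = "integer"))

setValidity("CohortConfig", function(object) {
  if (!identical(names(object@nCases), .EF_CLASSES))
    return("nCases must be named pEF, mrEF, rEF")
  if (any(object@nCases < 0L)) return("nCases must be >= 0")
  if (object@heartRateMean <= 0) return("heart rate must be > 0")
  if (!identical(names(object@afFraction), .EF_CLASSES))
    return("afFraction must be named pEF, mrEF, rEF")
  if (any(object@afFraction < 0 | object@afFraction > 1))
    return("afFraction must lie in [0, 1]")
  if (nrow(object@leadProjection) != 12L)
    return("leadProjection must have 12 rows (one per lead)")
  if (object@noiseSd < 0 || object@baselineWanderAmp < 0)
    return("noiseSd and baselineWanderAmp must be >= 0")
  if (!all(vapply(object@effects, is, logical(1L), class2 = "EffectSpec")))
    return("effects must be a list of EffectSpec objects")
  TRUE
})

#' @rdname CohortConfig-class
#' @param nCases,heartRateMean,heartRateSd,rrJitterSd,afFraction,noiseSd
#'   See the corresponding slots.
#' @param baselineWanderAmp,baselineWanderFreq,leadProjection,waves,effects,seed
#'   See the corresponding slots.
#' @return A `CohortConfig` object.
#' @export
#' @examples
#' cohortConfig(nCases = c(pEF = 10, mrEF = 5, rEF = 5), seed = 1)
cohortConfig <- function(nCases = c(pEF = 100L, mrEF = 50L, rEF = 50L),
                         heartRateMean = 70, heartRateSd = 8,
                         rrJitterSd = 10,
                         afFraction = c(pEF = 0.05, mrEF = 0.10, rEF = 0.20),
                         noiseSd = 0.02,
                         baselineWanderAmp = 0.05, baselineWanderFreq = 0.25,
                         leadProjection = defaultLeadProjection(),
                         waves = waveParams(), effects = list(),
                         seed = 1L) {
  nc <- as.integer(round(nCases)); names(nc) <- names(nCases)
  nc <- nc[.EF_CLASSES]; names(nc) <- .EF_CLASSES
  nc[is.na(nc)] <- 0L
  af <- afFraction[.EF_CLASSES]; names(af) <- .EF_CLASSES
  af[is.na(af)] <- 0
  new("CohortConfig", nCases = nc, heartRateMean = heartRateMean,
      heartRateSd = heartRateSd, rrJitterSd = rrJitterSd, afFraction = af,
      noiseSd = noiseSd, baselineWanderAmp = baselineWanderAmp,
      baselineWanderFreq = baselineWanderFreq,
      leadProjection = leadProjection, waves = waves, effects = effects,
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## EcgRecord and EcgCohort
## ---------------------------------------------------------------------------

#' One synthetic or imported 12-lead ECG recording
#'
#' A 10 s, 500 Hz, 12-lead recording (12 x 5000 mV matrix, rows in canonical
#' lead order) with case metadata and, for generated records, exact ground
#' truth: per-beat fiducial sample indices (`truth`) and the effective
#' per-lead wavelet parameters after effects were applied (`waveTable`).
#'
#' @slot caseId Character scalar.
#' @slot signal 12 x 5000 numeric matrix, mV.
#' @slot samplingRate Hz (500).
#' @slot lvef Left ventricular ejection fraction, percent.
#' @slot efClass `"pEF"`, `"mrEF"` or `"rEF"`; must agree with `lvef`
#'   (< 40 rEF, 40--<50 mrEF, >= 50 pEF).
#' @slot af Logical: atrial fibrillation (no P wave, irregular RR).
#' @slot truth data.frame with integer columns `r_peak`, `qrs_onset`,
#'   `st_junction`, `t_end` (1-based sample indices), one row per beat;
#'   empty for imported records.
#' @slot waveTable data.frame (wave, lead, amplitude, width_ms, latency_ms)
#'   of effective per-lead wavelet parameters; empty for imported records.
#' @export
setClass("EcgRecord",
  representation(caseId = "character", signal = "matrix",
                 samplingRate = "numeric", lvef = "numeric",
                 efClass = "character", af = "logical",
                 truth = "data.frame", waveTable = "data.frame"))

setValidity("EcgRecord", function(object) {
  if (!identical(dim(object@signal), c(12L, 5000L)))
    return("signal must be a 12 x 5000 matrix")
  if (object@lvef <= 0 || object@lvef > 100)
    return("lvef must lie in (0, 100]")
  if (!identical(object@efClass, .efClassOf(object@lvef)))
    return("efClass inconsistent with lvef thresholds")
  if (nrow(object@truth) > 0L) {
    tr <- object@truth
    need <- c("r_peak", "qrs_onset", "st_junction", "t_end")
    if (!all(need %in% names(tr))) return("truth lacks fiducial columns")
    if (any(tr$qrs_onset >= tr$r_peak | tr$r_peak >= tr$st_junction |
            tr$st_junction >= tr$t_end))
      return("truth fiducials must satisfy qrs_onset < r_peak < st_junction < t_end")
    if (any(tr$r_peak < 1L | tr$r_peak > 5000L))
      return("truth r_peak out of record bounds")
    if (object@af && nrow(object@waveTable) > 0L &&
        any(object@waveTable$amplitude[object@waveTable$wave == "P"] != 0))
      return("AF records must have zero P amplitude in waveTable")
  }
  TRUE
})

#' A list of ECG records plus the configuration that produced them
#'
#' @slot records List of [EcgRecord-class] objects.
#' @slot config The [CohortConfig-class] used by the generator.
#' @export
setClass("EcgCohort",
  representation(records = "list", config = "CohortConfig"))

setValidity("EcgCohort", function(object) {
  if (!all(vapply(object@records, is, logical(1L), class2 = "EcgRecord")))
    return("records must all be EcgRecord objects")
  ids <- vapply(object@records, function(r) r@caseId, character(1L))
  if (anyDuplicated(ids)) return("case ids must be unique")
  TRUE
})

## ---------------------------------------------------------------------------
## Tensors
## ---------------------------------------------------------------------------

#' Fixed-length beat-anchored tensor
#'
#' A C x 375 matrix: a full single beat (C = 12), a partial-segment beat
#' (C = 12), a two-beat channel stack (C = 24) or a reduced-lead beat
#' (C in 1..12), plus provenance (case, record, beat index, segment kind,
#' lead subset).
#'
#' @slot data Numeric matrix with exactly 375 columns.
#' @slot caseId,recordId Character provenance.
#' @slot beatIndex Integer beat number within the record.
#' @slot segment One of `"P"`, `"PQRS"`, `"QRS"`, `"QRST"`, `"PQRST"`.
#' @slot leads Character lead subset in canonical order.
#' @slot kind `"single"`, `"partial"`, `"two_beat"` or `"reduced"`.
#' @export
setClass("BeatTensor",
  representation(data = "matrix", caseId = "character",
                 recordId = "character", beatIndex = "integer",
                 segment = "character", leads = "character",
                 kind = "character"))

setValidity("BeatTensor", function(object) {
  if (ncol(object@data) != 375L) return("BeatTensor must have 375 columns")
  if (!object@segment %in% c("P", "PQRS", "QRS", "QRST", "PQRST"))
    return("unknown segment kind")
  if (!all(object@leads %in% .LEADS)) return("unknown lead name")
  nr <- nrow(object@data)
  if (object@kind == "two_beat") {
    if (nr != 2L * length(object@leads))
      return("two-beat tensor must stack the lead set twice")
  } else if (nr != length(object@leads)) {
    return("row count must match the lead set")
  }
  if (object@kind != "two_beat" && (nr < 1L || nr > 12L))
    return("row count must lie in 1..12")
  TRUE
})

#' Three-second 12-lead strip
#'
#' @slot data 12 x 1500 numeric matrix.
#' @slot startOffset 0-based sample offset of the strip within the 10 s
#'   record; `startOffset + 1500 <= 5000`.
#' @slot caseId,recordId Character provenance.
#' @export
setClass("StripTensor",
  representation(data = "matrix", startOffset = "integer",
                 caseId = "character", recordId = "character"))

setValidity("StripTensor", function(object) {
  if (!identical(dim(object@data), c(12L, 1500L)))
    return("strip must be a 12 x 1500 matrix")
  if (object@startOffset < 0L || object@startOffset + 1500L > 5000L)
    return("startOffset out of bounds")
  TRUE
})

## ---------------------------------------------------------------------------
## Standardiser
## ---------------------------------------------------------------------------

#' Global scalar standardiser
#'
#' Holds the overall mean and standard deviation (mV) of a training dataset;
#' dev/test/external data are transformed with these same two numbers.
#'
#' @slot mean,sd Scalars; `sd > 0`.
#' @export
setClass("Standardiser", representation(mean = "numeric", sd = "numeric"))

setValidity("Standardiser", function(object) {
  if (!is.finite(object@sd) || object@sd <= 0) return("sd must be > 0")
  TRUE
})

## ---------------------------------------------------------------------------
## FoldPlan
## ---------------------------------------------------------------------------

#' Stratified fold plan with a fixed test subset
#'
#' Cases are split into five disjoint subsets, stratified by EF class.
#' Subsets 1--4 rotate as development sets over the four folds (the other
#' three forming the training set); subset 5 is the fixed test set shared by
#' all folds.
#'
#' @slot subsets List of 5 character vectors of case ids.
#' @slot strata Named character: EF class per case id.
#' @export
setClass("FoldPlan", representation(subsets = "list", strata = "character"))

setValidity("FoldPlan", function(object) {
  if (length(object@subsets) != 5L) return("need exactly 5 subsets")
  all_ids <- unlist(object@subsets)
  if (anyDuplicated(all_ids)) return("subsets must be pairwise disjoint")
  if (!setequal(all_ids, names(object@strata)))
    return("subsets must cover exactly the stratified cases")
  for (cl in unique(object@strata)) {
    n <- vapply(object@subsets[1:4], function(s)
      sum(object@strata[s] == cl), integer(1L))
    if (max(n) - min(n) > 1L)
      return(sprintf("class %s unbalanced across rotating subsets", cl))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## ModelConfig and EcgClassifier
## ---------------------------------------------------------------------------

#' Configuration of the 1D convolutional classifier
#'
#' The network is a stack of `nBlocks` blocks, each a 1D convolution
#' ("same" padding, no bias), batch normalisation, ReLU and max pooling,
#' followed by a flattening fully connected layer and a softmax over the two
#' diagnostic classes (pEF vs reduced LVEF). The default configuration has
#' nine convolutional blocks plus the fully connected layer: ten weighted
#' layers in total.
#'
#' @slot inChannels Input channels (1--24).
#' @slot inputLen 375 (beat tensors) or 1500 (3 s strips).
#' @slot filters,kernels,pools Integer vectors, one entry per block.
#' @slot fcWidth Optional hidden fully connected width (0 = none).
#' @slot nClasses Number of output classes (2).
#' @export
setClass("ModelConfig",
  representation(inChannels = "integer", inputLen = "integer",
                 filters = "integer", kernels = "integer",
                 pools = "integer", fcWidth = "integer",
                 nClasses = "integer"))

setValidity("ModelConfig", function(object) {
  nb <- length(object@filters)
  if (nb < 1L) return("need at least one block")
  if (length(object@kernels) != nb || length(object@pools) != nb)
    return("filters, kernels and pools must have one entry per block")
  if (object@inChannels < 1L || object@inChannels > 24L)
    return("inChannels must lie in 1..24")
  if (any(object@kernels < 1L) || any(object@pools < 1L))
    return("kernels and pools must be >= 1")
  len <- object@inputLen
  for (b in seq_len(nb)) {
    len <- len %/% object@pools[b]
    if (len < 1L)
      return(sprintf("temporal length collapses to zero at block %d", b))
  }
  if (object@nClasses != 2L) return("binary classifier: nClasses must be 2")
  TRUE
})

#' @rdname ModelConfig-class
#' @param inChannels,inputLen,filters,kernels,pools,fcWidth,nClasses See the
#'   corresponding slots; `filters`, `kernels`, `pools` default to the
#'   ten-weighted-layer configuration for the given `inputLen`.
#' @return A `ModelConfig` object.
#' @export
#' @examples
#' modelConfig(inChannels = 12, inputLen = 375)
#' nWeightedLayers(modelConfig(inChannels = 12, inputLen = 375))
modelConfig <- function(inChannels = 12L, inputLen = 375L,
                        filters = c(16L, 16L, 32L, 32L, 64L, 64L,
                                    128L, 128L, 128L),
                        kernels = c(7L, 7L, 5L, 5L, 5L, 3L, 3L, 3L, 3L),
                        pools = NULL, fcWidth = 0L, nClasses = 2L) {
  if (is.null(pools)) {
    pools <- if (length(filters) == 9L) {
      if (inputLen >= 1500L) rep(2L, 9L) else c(rep(2L, 7L), 1L, 1L)
    } else rep(2L, length(filters))
  }
  new("ModelConfig", inChannels = as.integer(inChannels),
      inputLen = as.integer(inputLen), filters = as.integer(filters),
      kernels = as.integer(kernels), pools = as.integer(pools),
      fcWidth = as.integer(fcWidth), nClasses = as.integer(nClasses))
}

#' Trained or untrained classifier instance
#'
#' Holds a [ModelConfig-class] plus the parameter tensors (convolution
#' kernels, batch-norm scale/shift, fully connected weights) and the
#' batch-norm running statistics used at evaluation time.
#'
#' @slot config A [ModelConfig-class].
#' @slot params Named list of numeric arrays.
#' @slot state Named list (batch-norm running mean/var, step counter).
#' @export
setClass("EcgClassifier",
  representation(config = "ModelConfig", params = "list", state = "list"))
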