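## Beat-wise preprocessing: strip oversampling, single-beat extraction with
## T-end padding, partial segments, two-beat composition, lead subsetting and
## train-statistics standardisation.

## Class/split-dependent oversampling factors for 3 s strips.
.STRIP_FACTORS <- list(
  train = c(pEF = 4L, mrEF = 7L, rEF = 6L),
  dev   = c(pEF = 4L, mrEF = 16L, rEF = 11L),
  test  = c(pEF = 4L, mrEF = 16L, rEF = 11L))

#' Evenly spaced strip start offsets
#'
#' Start offsets (0-based samples) for `nSegments` windows of `stripLen`
#' samples inside a record of `recordLen` samples: endpoint-inclusive even
#' spacing from 0 to `recordLen - stripLen`, rounded to integer samples.
#'
#' @param nSegments Number of windows (>= 1).
#' @param recordLen,stripLen Record and window lengths in samples.
#' @return Integer vector of `nSegments` in-bounds offsets.
#' @export
#' @examples
#' oversampleOffsets(4)   # 0 1167 2333 3500
oversampleOffsets <- function(nSegments, recordLen = 5000L,
                              stripLen = 1500L) {
  if (nSegments < 1L) stop("nSegments must be >= 1")
  if (stripLen > recordLen) stop("stripLen exceeds recordLen")
  lastStart <- recordLen - stripLen
  if (nSegments == 1L) return(0L)
  as.integer(round(seq(0L, lastStart, length.out = nSegments)))
}

#' Extract 3 s strips with class-dependent oversampling
#'
#' The number of strips per record is the oversampling factor for the
#' record's EF class and split role: x4/x7/x6 (pEF/mrEF/rEF) for training
#' data and x4/x16/x11 for development and test data.
#'
#' @param record An [EcgRecord-class].
#' @param splitRole `"train"`, `"dev"` or `"test"`.
#' @param class Override of the record's EF class (rarely needed).
#' @return List of [StripTensor-class] objects (12 x 1500 each).
#' @export
extractStrips <- function(record, splitRole = c("train", "dev", "test"),
                          class = efClass(record)) {
  splitRole <- match.arg(splitRole)
  if (!class %in% .EF_CLASSES) stop("unknown EF class: ", class)
  k <- .STRIP_FACTORS[[splitRole]][[class]]
  offs <- oversampleOffsets(k)
  sig <- signalMatrix(record)
  lapply(offs, function(o)
    new("StripTensor", data = sig[, (o + 1L):(o + 1500L), drop = FALSE],
        startOffset = as.integer(o), caseId = caseId(record),
        recordId = caseId(record)))
}

#' Extract fixed-length single beats
#'
#' For each annotated beat, extracts the window from 250 ms before to 500 ms
#' after the R peak (375 samples at 500 Hz) on all 12 leads; samples beyond
#' the T-wave end are replaced, per lead, by the value at the T-wave end.
#' Beats whose window exceeds the record bounds are dropped (their count is
#' attached as attribute `"dropped"`).
#'
#' @param record An [EcgRecord-class].
#' @param annotations Per-beat fiducial data.frame as returned by
#'   [delineate()] (defaults to the generator ground truth for synthetic
#'   records).
#' @return List of [BeatTensor-class] objects (12 x 375).
#' @export
extractSingleBeats <- function(record, annotations = truthBeats(record)) {
  sig <- signalMatrix(record)
  n <- ncol(sig)
  out <- list(); dropped <- 0L
  for (i in seq_len(nrow(annotations))) {
    r <- annotations$r_peak[i]
    ws <- r - 125L; we <- r + 249L
    if (ws < 1L || we > n) { dropped <- dropped + 1L; next }
    m <- sig[, ws:we, drop = FALSE]
    tw <- annotations$t_end[i] - ws + 1L     # T end in window coordinates
    if (tw >= 1L && tw < 375L)
      m[, (tw + 1L):375L] <- m[, tw]
    out[[length(out) + 1L]] <- new("BeatTensor", data = m,
      caseId = caseId(record), recordId = caseId(record),
      beatIndex = i, segment = "PQRST", leads = .LEADS, kind = "single")
  }
  attr(out, "dropped") <- dropped
  out
}

## Span of a segment kind in 0-based half-open window coordinates [lo, hi).
## b = 100 ms before QRS onset, j = ST junction, t = T end.
.segmentSpan <- function(kind, b, j, t) {
  switch(kind,
         P     = c(0L, b),
         QRS   = c(b, j),
         QRST  = c(b, t),
         PQRS  = c(0L, j),
         PQRST = c(0L, 375L))
}

#' Mask a single beat down to a partial segment
#'
#' Keeps the samples of the requested intra-beat segment and replaces the
#' samples outside its span by the span's nearest boundary value (constant
#' continuation), so all five segment kinds share the 12 x 375 input shape.
#' The P/QRS boundary is 100 ms before the detected QRS onset; the other
#' boundaries are the ST junction and the T-wave end.
#'
#' @param beat A full single-beat [BeatTensor-class].
#' @param annotation One-row fiducial data.frame for this beat (record
#'   coordinates).
#' @param kind `"P"`, `"PQRS"`, `"QRS"`, `"QRST"` or `"PQRST"`.
#' @return A [BeatTensor-class] with `segment = kind`.
#' @export
makePartial <- function(beat, annotation,
                        kind = c("P", "PQRS", "QRS", "QRST", "PQRST")) {
  kind <- match.arg(kind)
  stopifnot(is(beat, "BeatTensor"), beat@kind %in% c("single", "reduced"))
  with(annotation, {
    if (!(qrs_onset < r_peak && r_peak < st_junction && st_junction < t_end))
      stop("fiducial ordering violated")
  })
  ws <- annotation$r_peak - 125L   # first window sample, record coordinates
  b <- annotation$qrs_onset - 50L - ws       # 0-based window coordinate
  j <- annotation$st_junction - ws
  t <- annotation$t_end - ws
  clamp <- function(v) min(max(v, 1L), 374L)
  b <- clamp(b); j <- clamp(j); t <- clamp(t)
  if (!(b < j && j < t)) stop("fiducial ordering violated within the window")
  span <- .segmentSpan(kind, b, j, t)
  m <- beat@data
  lo <- span[1L]; hi <- span[2L]              # keep columns lo+1 .. hi
  if (lo > 0L) m[, 1:lo] <- m[, lo + 1L]
  if (hi < 375L) m[, (hi + 1L):375L] <- m[, hi]
  initialize(beat, data = m, segment = kind,
             kind = if (beat@kind == "reduced") "reduced" else "partial")
}

#' Compose two-beat tensors
#'
#' Stacks consecutive beats channel-wise: item i has the i-th beat in rows
#' 1--12 and beat i+1 in rows 13--24; the final beat, lacking a successor,
#' wraps around to the first beat. The output count equals the input count.
#'
#' @param beats List of single-beat [BeatTensor-class] objects from one
#'   record, in beat order.
#' @return List of 24 x 375 [BeatTensor-class] objects (empty list for empty
#'   input).
#' @export
composeTwoBeats <- function(beats) {
  n <- length(beats)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) {
    nxt <- if (i == n) 1L else i + 1L
    new("BeatTensor", data = rbind(beats[[i]]@data, beats[[nxt]]@data),
        caseId = beats[[i]]@caseId, recordId = beats[[i]]@recordId,
        beatIndex = beats[[i]]@beatIndex, segment = beats[[i]]@segment,
        leads = beats[[i]]@leads, kind = "two_beat")
  })
}

#' Restrict a beat tensor to a lead subset
#'
#' Rows are returned in canonical order (I, II, III, aVR, aVL, aVF, V1--V6
#' restricted to the subset), regardless of the order leads are requested in.
#'
#' @param tensor A single-beat or partial [BeatTensor-class].
#' @param leads Non-empty subset of [ecgLeadNames()].
#' @return A reduced-lead [BeatTensor-class].
#' @export
subsetLeads <- function(tensor, leads) {
  stopifnot(is(tensor, "BeatTensor"))
  if (length(leads) == 0L) stop("lead subset must be non-empty")
  if (!all(leads %in% .LEADS))
    stop("unknown lead(s): ", paste(setdiff(leads, .LEADS), collapse = ", "))
  sel <- .LEADS[.LEADS %in% leads]
  idx <- match(sel, tensor@leads)
  if (anyNA(idx)) stop("tensor lacks requested lead(s)")
  initialize(tensor, data = tensor@data[idx, , drop = FALSE], leads = sel,
             kind = if (length(sel) == 12L) tensor@kind else "reduced")
}

## Pool all sample values from a list of tensors / arrays into one vector.
.allValues <- function(x) {
  if (is.array(x) || is.matrix(x)) return(as.numeric(x))
  unlist(lapply(x, function(t) {
    if (is(t, "BeatTensor") || is(t, "StripTensor")) as.numeric(t@data)
    else as.numeric(t)
  }), use.names = FALSE)
}

#' Fit the global standardiser on training data
#'
#' Computes a single scalar mean and standard deviation over every sample of
#' every lead of the training tensors. Development, test and external data
#' must be transformed with these same train statistics.
#'
#' @param tensors List of [BeatTensor-class]/[StripTensor-class] objects, or
#'   a numeric array.
#' @return A [Standardiser-class].
#' @export
#' @examples
#' std <- fitStandardiser(array(rnorm(100, 2, 3), c(2, 5, 10)))
#' std
fitStandardiser <- function(tensors) {
  v <- .allValues(tensors)
  if (length(v) == 0L) stop("training set is empty")
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0) stop("constant training data: sd is zero")
  new("Standardiser", mean = mean(v), sd = s)
}

#' @rdname fitStandardiser
#' @param std A fitted [Standardiser-class].
#' @return `applyStandardiser`: the input with every value replaced by
#'   `(x - mean) / sd`, preserving the input's type.
#' @export
applyStandardiser <- function(std, tensors) {
  stopifnot(is(std, "Standardiser"))
  tf <- function(v) (v - std@mean) / std@sd
  if (is.array(tensors) || is.matrix(tensors)) return(tf(tensors))
  lapply(tensors, function(t) {
    if (is(t, "BeatTensor") || is(t, "StripTensor"))
      initialize(t, data = tf(t@data))
    else tf(t)
  })
}

#' Stack tensors into a channels x length x batch array
#'
#' @param tensors Non-empty list of tensors sharing one shape.
#' @return List with `x` (C x L x N array) and `meta` (data.frame of
#'   provenance: `case_id`, `record_id`).
#' @export
stackTensors <- function(tensors) {
  stopifnot(length(tensors) > 0L)
  mats <- lapply(tensors, tensorData)
  d <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1L))))
    stop("tensors do not share a common shape")
  x <- array(unlist(mats, use.names = FALSE), dim = c(d, length(mats)))
  meta <- data.frame(
    case_id = vapply(tensors, function(t) t@caseId, character(1L)),
    record_id = vapply(tensors, function(t) t@recordId, character(1L)),
    stringsAsFactors = FALSE)
  list(x = x, meta = meta)
}
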