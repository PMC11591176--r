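## QRS detection and beat delineation.
##
## Pan-Tompkins-style detector on lead II (band-pass 5-15 Hz, derivative,
## squaring, 150 ms moving-window integration, thresholding with a 200 ms
## refractory period), refined to the argmax of the multi-lead band-passed
## energy. QRS onset / ST junction come from smoothed-energy threshold
## crossings around the R peak; the T-wave end from the tangent method on the
## low-pass-filtered T wave.

.bandpass <- function(x, fs, lo = 5, hi = 15) {
  bf <- signal::butter(3, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

.lowpass <- function(x, fs, hi = 12) {
  bf <- signal::butter(3, hi / (fs / 2), type = "low")
  signal::filtfilt(bf, x)
}

.movavg <- function(x, w) {
  y <- stats::filter(x, rep(1 / w, w), sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

#' Delineate the beats of a record
#'
#' Detects R peaks and estimates per-beat fiducials (QRS onset, ST junction,
#' T-wave end). Returns an empty annotation table (not an error) when no
#' beats are detectable, e.g. on a flatline.
#'
#' @param x An [EcgRecord-class] or a 12 x 5000 signal matrix in canonical
#'   lead order.
#' @param ... Unused.
#' @return data.frame with integer columns `r_peak`, `qrs_onset`,
#'   `st_junction`, `t_end` (1-based sample indices), ordered by `r_peak`,
#'   satisfying `qrs_onset < r_peak < st_junction < t_end` per row.
#' @export
#' @examples
#' set.seed(1)
#' rec <- simulateRecord(cohortConfig(noiseSd = 0), lvef = 60)
#' ann <- delineate(rec)
#' nrow(ann) == nrow(truthBeats(rec))
setGeneric("delineate", function(x, ...) standardGeneric("delineate"))

#' @rdname delineate
#' @export
setMethod("delineate", "EcgRecord", function(x, ...)
  delineate(signalMatrix(x)))

#' @rdname delineate
#' @export
setMethod("delineate", "matrix", function(x, ...) {
  fs <- .FS
  empty <- data.frame(r_peak = integer(0L), qrs_onset = integer(0L),
                      st_junction = integer(0L), t_end = integer(0L))
  stopifnot(nrow(x) == 12L)
  n <- ncol(x)
  xii <- x[2L, ]
  if (stats::sd(xii) < 1e-7) return(empty)

  ## Pan-Tompkins stages on lead II
  xf <- .bandpass(xii, fs)
  integ <- .movavg(c(0, diff(xf))^2, round(0.15 * fs))
  if (max(integ) < 1e-12) return(empty)
  thr <- 0.08 * max(integ)

  above <- integ > thr
  edges <- diff(c(FALSE, above, FALSE))
  starts <- which(edges == 1L); ends <- which(edges == -1L) - 1L
  cand <- mapply(function(s, e) s - 1L + which.max(integ[s:e]), starts, ends)
  ## refractory merge: keep the stronger of candidates closer than 200 ms
  cand <- sort(cand)
  keep <- logical(length(cand))
  last <- -Inf
  for (i in seq_along(cand)) {
    if (cand[i] - last >= 0.2 * fs) {
      keep[i] <- TRUE; last <- cand[i]
    } else if (integ[cand[i]] > integ[cand[i - 1L]]) {
      keep[i - 1L] <- FALSE; keep[i] <- TRUE; last <- cand[i]
    }
  }
  cand <- cand[keep]
  if (length(cand) == 0L) return(empty)

  ## multi-lead refinement: argmax of mean squared band-passed signal
  bp <- t(apply(x, 1L, .bandpass, fs = fs))
  energy <- colMeans(bp^2)
  es <- .movavg(energy, 11L)
  rpk <- vapply(cand, function(ci) {
    w <- max(1L, ci - 50L):min(n, ci + 50L)
    w[which.max(energy[w])]
  }, numeric(1L))
  rpk <- sort(unique(round(rpk)))
  if (length(rpk) > 1L) rpk <- rpk[c(TRUE, diff(rpk) >= 0.2 * fs)]

  lf <- .lowpass(xii, fs)
  out <- lapply(seq_along(rpk), function(i) {
    r <- rpk[i]
    er <- es[r]
    ## QRS onset: nearest point before R where smoothed energy has decayed
    onset <- r - 25L
    idx <- seq(max(1L, r - 75L), r - 5L)
    low <- idx[es[idx] < 0.0025 * er]
    if (length(low)) onset <- low[length(low)]
    ## ST junction: first decayed point after R
    jpt <- r + 30L
    idx <- seq(r + 5L, min(n, r + 75L))
    low <- idx[es[idx] < 0.004 * er]
    if (length(low)) jpt <- low[1L]
    ## T end: tangent method on the low-passed T wave
    nxt <- if (i < length(rpk)) rpk[i + 1L] - 60L else n
    whi <- min(r + 240L, nxt, n)
    wlo <- jpt + 15L
    te <- r + 190L
    if (whi - wlo > 30L) {
      b <- stats::median(lf[max(wlo, whi - 15L):whi])
      seg <- lf[wlo:whi] - b
      tp <- wlo - 1L + which.max(abs(seg))
      if (tp < whi - 5L) {
        d <- diff(lf[tp:whi])
        ms <- tp - 1L + which.max(abs(d))
        dd <- lf[ms + 1L] - lf[ms]
        off <- (lf[ms] - b) / -dd
        if (is.finite(off) && off > 0 && off < 150)
          te <- ms + round(off)
      }
    }
    te <- min(max(te, jpt + 10L), n)
    c(r_peak = r, qrs_onset = onset, st_junction = jpt, t_end = te)
  })
  ann <- as.data.frame(do.call(rbind, out))
  ann[] <- lapply(ann, as.integer)
  ok <- with(ann, qrs_onset < r_peak & r_peak < st_junction &
                  st_junction < t_end & qrs_onset >= 1L & t_end <= n)
  ann[ok, , drop = FALSE]
})

#' Fraction of reference beats recovered by a detector
#'
#' A reference R peak counts as matched when a detected R peak lies within
#' `tolSamples` of it (default 10 samples = 20 ms at 500 Hz); each detected
#' peak can match at most one reference beat.
#'
#' @param reference,detected Integer vectors of R-peak sample indices.
#' @param tolSamples Matching tolerance in samples.
#' @return Proportion of `reference` beats matched, in \[0, 1\].
#' @export
beatMatchRate <- function(reference, detected, tolSamples = 10L) {
  if (length(reference) == 0L) return(NA_real_)
  used <- logical(length(detected))
  hit <- 0L
  for (r in reference) {
    d <- abs(detected - r)
    d[used] <- Inf
    if (length(d) && min(d) <= tolSamples) {
      used[which.min(d)] <- TRUE
      hit <- hit + 1L
    }
  }
  hit / length(reference)
}
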