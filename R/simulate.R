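## Synthetic 12-lead ECG generator.
##
## Beats are sums of five Gaussian wavelets (P, Q, R, S, T) placed at
## RR-jittered beat times on three dipole source channels, projected to the
## 12 leads through a fixed 12 x 3 matrix whose limb-lead rows satisfy the
## Einthoven/Goldberger relations exactly (III = II - I, aVR = -(I+II)/2,
## aVL = (I - III)/2, aVF = (II + III)/2). Class-dependent effects multiply
## wave amplitude/width on selected leads after projection, so a
## lead-restricted effect deliberately breaks the limb-lead algebra: that IS
## the planted signal a classifier is asked to find.

#' Default 12 x 3 lead projection
#'
#' Maps three dipole source channels (frontal-plane x and y plus a precordial
#' component z) to the 12 standard leads. Limb-lead rows are constructed from
#' the I and II rows so the derived-lead identities hold exactly; precordial
#' rows sweep from right-anterior (V1) to left-lateral (V6).
#'
#' @return Numeric 12 x 3 matrix with lead row names.
#' @export
#' @examples
#' P <- defaultLeadProjection()
#' all.equal(P["III", ], P["II", ] - P["I", ])
defaultLeadProjection <- function() {
  I  <- c(1.00, 0.00, 0.00)
  II <- c(0.50, 0.87, 0.00)
  III <- II - I
  m <- rbind(I = I, II = II, III = III,
             aVR = -(I + II) / 2, aVL = (I - III) / 2, aVF = (II + III) / 2,
             V1 = c(-0.40, 0.10, 0.80), V2 = c(-0.15, 0.15, 0.95),
             V3 = c(0.10, 0.25, 0.90),  V4 = c(0.35, 0.35, 0.75),
             V5 = c(0.55, 0.40, 0.50),  V6 = c(0.65, 0.40, 0.25))
  m
}

## Unit dipole direction of each wave in (x, y, z) source space. Chosen so
## that the R wave is large and positive on lead II (the delineator's anchor)
## and the precordial leads see a realistic R/T progression.
.waveDirections <- function() {
  d <- rbind(P = c(0.40, 0.90, 0.15),
             Q = c(0.80, -0.30, -0.40),
             R = c(0.35, 0.80, 0.40),
             S = c(-0.60, 0.30, -0.70),
             T = c(0.40, 0.70, 0.50))
  d / sqrt(rowSums(d^2))
}

## Effective per-lead wavelet table for one record: base projection of each
## wave's dipole amplitude, then EffectSpec multipliers for matching classes,
## then AF zeroes the P wave.
.effectiveWaveTable <- function(config, efClass, af) {
  proj <- config@leadProjection
  dirs <- .waveDirections()
  wp <- config@waves
  tab <- expand.grid(wave = .WAVES, lead = .LEADS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$amplitude <- NA_real_; tab$width_ms <- NA_real_; tab$latency_ms <- NA_real_
  for (w in .WAVES) {
    perLead <- drop(proj %*% (wp@amplitude[[w]] * dirs[w, ]))
    sel <- tab$wave == w
    tab$amplitude[sel] <- perLead[match(tab$lead[sel], .LEADS)]
    tab$width_ms[sel] <- wp@width[[w]]
    tab$latency_ms[sel] <- wp@latency[[w]]
  }
  for (ef in config@effects) {
    if (!efClass %in% ef@classes) next
    waves <- switch(ef@targetWave, P = "P", QRS = c("Q", "R", "S"),
                    `ST-T` = "T")
    sel <- tab$wave %in% waves & tab$lead %in% ef@targetLeads
    tab$amplitude[sel] <- tab$amplitude[sel] * ef@amplitudeMultiplier
    tab$width_ms[sel] <- tab$width_ms[sel] * ef@widthMultiplier
  }
  if (af) tab$amplitude[tab$wave == "P"] <- 0
  tab
}

## Half-width (ms) of the wavelet support used when deciding whether a beat
## fits completely inside the record, and the analytic fiducial offsets.
.beatGeometry <- function(tab) {
  agg <- do.call(rbind, lapply(.WAVES, function(w) {
    rows <- tab[tab$wave == w, ]
    data.frame(wave = w, width = max(rows$width_ms),
               latency = rows$latency_ms[1L])
  }))
  list(
    first = min(agg$latency - 2.5 * agg$width),   # P support start, ms
    last = max(agg$latency + 2.5 * agg$width),    # T support end, ms
    qrs_onset = agg$latency[agg$wave == "Q"] - 2.5 * agg$width[agg$wave == "Q"],
    st_junction = agg$latency[agg$wave == "S"] + 2.5 * agg$width[agg$wave == "S"],
    t_end = agg$latency[agg$wave == "T"] + 2.5 * agg$width[agg$wave == "T"])
}

#' Simulate one 12-lead ECG record
#'
#' Draws a per-record heart rate, places complete beats at RR-jittered times
#' (i.i.d. RR with no P wave under AF), synthesises each beat as a sum of
#' Gaussian wavelets per lead using the effective wave table for the record's
#' EF class, adds baseline wander on the source channels and white
#' measurement noise per lead, and returns the record together with exact
#' fiducial ground truth.
#'
#' Uses the current RNG state; seed the stream (or use [makeCohort()], which
#' seeds it from the configuration) for reproducibility.
#'
#' @param config A [CohortConfig-class].
#' @param lvef LVEF percent in (0, 100]; determines the EF class.
#' @param af Logical, atrial fibrillation.
#' @param caseId Case identifier.
#' @return An [EcgRecord-class].
#' @export
#' @examples
#' set.seed(7)
#' rec <- simulateRecord(cohortConfig(), lvef = 62)
#' rec
simulateRecord <- function(config, lvef, af = FALSE, caseId = "case") {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  .assertScalarNum(lvef, "lvef")
  if (lvef <= 0 || lvef > 100) stop("lvef must lie in (0, 100]")
  if (config@heartRateMean <= 0) stop("heart rate must be > 0")
  if (nrow(config@leadProjection) != 12L)
    stop("lead projection must have 12 rows")
  cls <- .efClassOf(lvef)

  tab <- .effectiveWaveTable(config, cls, af)
  geom <- .beatGeometry(tab)

  hr <- max(30, stats::rnorm(1L, config@heartRateMean, config@heartRateSd))
  rr <- 60 / hr * .FS                       # mean RR in samples
  lead_in <- ceiling(.ms2smp(-geom$first))  # samples needed before an R peak
  lead_out <- ceiling(.ms2smp(geom$last))   # samples needed after an R peak

  ## Admissible R-peak positions are [lead_in + 1, NSAMP - lead_out]; the
  ## starting phase is drawn uniformly over the slack left after fitting as
  ## many nominal RR intervals as possible, so the beat count is a
  ## deterministic function of the heart rate (60 bpm, no jitter -> 10 beats).
  span <- .NSAMP - lead_out - (lead_in + 1L)
  slack <- span - rr * floor(span / rr)
  r0 <- lead_in + 1L + stats::runif(1L, 0, slack)
  rpeaks <- integer(0L)
  r <- r0
  while (r + lead_out <= .NSAMP) {
    rpeaks <- c(rpeaks, as.integer(round(r)))
    dr <- if (af) {
      stats::rnorm(1L, rr, 0.15 * rr)
    } else {
      rr + stats::rnorm(1L, 0, .ms2smp(config@rrJitterSd))
    }
    r <- r + max(.ms2smp(350), dr)          # refractory floor: 350 ms
  }

  sig <- matrix(0, nrow = 12L, ncol = .NSAMP,
                dimnames = list(.LEADS, NULL))
  tgrid <- seq_len(.NSAMP)
  for (rp in rpeaks) {
    for (w in .WAVES) {
      rows <- tab[tab$wave == w, ]
      amps <- rows$amplitude[match(.LEADS, rows$lead)]
      if (all(amps == 0)) next
      lat <- .ms2smp(rows$latency_ms[1L])
      for (sw in unique(rows$width_ms)) {
        leads <- rows$lead[rows$width_ms == sw]
        a <- amps[match(leads, .LEADS)]
        sigma <- .ms2smp(sw)
        lo <- max(1L, floor(rp + lat - 4 * sigma))
        hi <- min(.NSAMP, ceiling(rp + lat + 4 * sigma))
        if (lo > hi) next
        g <- exp(-((tgrid[lo:hi] - rp - lat)^2) / (2 * sigma^2))
        sig[leads, lo:hi] <- sig[leads, lo:hi] + tcrossprod(a, g)
      }
    }
  }

  if (config@baselineWanderAmp > 0) {
    k <- ncol(config@leadProjection)
    phase <- stats::runif(k, 0, 2 * pi)
    src <- vapply(seq_len(k), function(j)
      config@baselineWanderAmp *
        sin(2 * pi * config@baselineWanderFreq * tgrid / .FS + phase[j]),
      numeric(.NSAMP))
    sig <- sig + config@leadProjection %*% t(src)
  }
  if (config@noiseSd > 0)
    sig <- sig + matrix(stats::rnorm(12L * .NSAMP, 0, config@noiseSd),
                        nrow = 12L)

  truth <- data.frame(
    r_peak = rpeaks,
    qrs_onset = as.integer(rpeaks + round(.ms2smp(geom$qrs_onset))),
    st_junction = as.integer(rpeaks + round(.ms2smp(geom$st_junction))),
    t_end = as.integer(rpeaks + round(.ms2smp(geom$t_end))))

  new("EcgRecord", caseId = caseId, signal = sig, samplingRate = 500,
      lvef = lvef, efClass = cls, af = af, truth = truth, waveTable = tab)
}

#' Generate a synthetic cohort
#'
#' Produces the configured number of records per EF class. LVEF values are
#' drawn uniformly within each class interval (pEF 50--70, mrEF 40--50,
#' rEF 20--40); AF status is Bernoulli with the per-class fraction. The whole
#' cohort is a deterministic function of the configuration (including its
#' seed): the caller's RNG state is left untouched.
#'
#' @param config A [CohortConfig-class]; `config@nCases` must not all be 0.
#' @return An [EcgCohort-class].
#' @export
#' @examples
#' coh <- makeCohort(cohortConfig(nCases = c(pEF = 4, mrEF = 2, rEF = 2),
#'                                seed = 11))
#' coh
makeCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  if (sum(config@nCases) == 0L) stop("all class counts are zero")
  bounds <- list(pEF = c(50, 70), mrEF = c(40, 50), rEF = c(20, 40))
  records <- .withSeed(config@seed, {
    out <- vector("list", sum(config@nCases))
    i <- 0L
    for (cl in .EF_CLASSES) {
      for (j in seq_len(config@nCases[[cl]])) {
        b <- bounds[[cl]]
        ef <- stats::runif(1L, b[1L], b[2L] - 1e-9)
        af <- stats::runif(1L) < config@afFraction[[cl]]
        i <- i + 1L
        out[[i]] <- simulateRecord(config, lvef = ef, af = af,
                                   caseId = sprintf("%s_%03d", cl, j))
      }
    }
    out
  })
  new("EcgCohort", records = records, config = config)
}
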