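## Shared constants and small internal helpers.

.LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
            "V1", "V2", "V3", "V4", "V5", "V6")
.FS <- 500L          # sampling rate, Hz
.NSAMP <- 5000L      # 10 s record length, samples
.STRIP_LEN <- 1500L  # 3 s strip length, samples
.BEAT_LEN <- 375L    # single-beat window length, samples
.WAVES <- c("P", "Q", "R", "S", "T")
.EF_CLASSES <- c("pEF", "mrEF", "rEF")

#' Canonical 12-lead names
#'
#' Returns the standard lead names in the canonical row order used by every
#' signal matrix in the package: I, II, III, aVR, aVL, aVF, V1--V6.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' ecgLeadNames()
ecgLeadNames <- function() .LEADS

## Map an LVEF percentage to its class label (<40 rEF, [40,50) mrEF, >=50 pEF).
.efClassOf <- function(lvef) {
  stopifnot(is.numeric(lvef), lvef > 0, lvef <= 100)
  if (lvef < 40) "rEF" else if (lvef < 50) "mrEF" else "pEF"
}

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## ms -> samples at 500 Hz (0.5 samples per ms)
.ms2smp <- function(ms) ms * .FS / 1000

.assertScalarNum <- function(x, nm, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(nm, " must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0) stop(nm, " must be > 0", call. = FALSE)
  invisible(x)
}
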