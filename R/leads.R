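## Lead-subset enumeration, per-lead contribution statistic, and lead-count
## grouping.

#' Enumerate lead subsets
#'
#' Modes: `"all"` — every non-empty subset of the 12 leads (2^12 - 1 = 4095
#' sets); `"leave_one_out"` — the 12 eleven-lead sets plus the full set;
#' `"singles"` — the 12 singletons; `"sampled"` — `nSample` distinct subsets
#' drawn with subset size uniform over 1..12.
#'
#' @param mode Enumeration mode.
#' @param nSample Number of subsets for `mode = "sampled"`; must not exceed
#'   4095.
#' @param seed Seed for `mode = "sampled"`.
#' @return List of character vectors in canonical lead order.
#' @export
#' @examples
#' length(enumerateLeadSets("singles"))       # 12
#' length(enumerateLeadSets("leave_one_out")) # 13
enumerateLeadSets <- function(mode = c("singles", "leave_one_out", "all",
                                       "sampled"),
                              nSample = 25L, seed = 1L) {
  mode <- match.arg(mode)
  switch(mode,
    singles = lapply(.LEADS, identity),
    leave_one_out = c(lapply(.LEADS, function(l) setdiff(.LEADS, l)),
                      list(.LEADS)),
    all = {
      out <- list()
      for (k in 1:12)
        out <- c(out, utils::combn(.LEADS, k, simplify = FALSE))
      out
    },
    sampled = {
      if (nSample > 4095L) stop("nSample exceeds the 4095 available subsets")
      .withSeed(seed, {
        seen <- character(0L)
        out <- list()
        while (length(out) < nSample) {
          k <- sample.int(12L, 1L)
          s <- .LEADS[sort(sample.int(12L, k))]
          key <- paste(s, collapse = "+")
          if (!key %in% seen) {
            seen <- c(seen, key)
            out[[length(out) + 1L]] <- s
          }
        }
        out
      })
    })
}

#' Label for a lead set
#'
#' @param leads Character vector of lead names.
#' @return `"I+aVR"`-style string in canonical order.
#' @export
leadSetLabel <- function(leads) paste(.LEADS[.LEADS %in% leads],
                                      collapse = "+")

#' Per-lead contribution statistic
#'
#' For each lead, the contribution to a metric is the mean of that metric
#' over the evaluated lead sets that contain the lead minus the mean over
#' the sets that lack it. Requires, per lead, at least one set on each side;
#' leads present in every set (or absent from every set) are rejected as
#' undefined.
#'
#' @param results data.frame with a `leads` column (`"I+aVR"`-style labels,
#'   see [leadSetLabel()]) and metric columns `auc`, and optionally
#'   `accuracy`, `sensitivity`, `specificity`.
#' @param leads Leads to tabulate (default: every lead appearing in
#'   `results`).
#' @return data.frame with one row per lead: `lead`, `delta_auc` and deltas
#'   of the other available metrics, sorted by `delta_auc` (largest first).
#' @export
#' @examples
#' res <- data.frame(leads = c("I", "II", "I+II"),
#'                   auc = c(0.9, 0.8, 0.9))
#' leadContribution(res)
leadContribution <- function(results, leads = NULL) {
  stopifnot("leads" %in% names(results), "auc" %in% names(results))
  sets <- strsplit(results$leads, "+", fixed = TRUE)
  if (is.null(leads)) leads <- .LEADS[.LEADS %in% unlist(sets)]
  metrics <- intersect(c("auc", "accuracy", "sensitivity", "specificity"),
                       names(results))
  rows <- lapply(leads, function(l) {
    has <- vapply(sets, function(s) l %in% s, logical(1L))
    if (all(has) || !any(has))
      stop(sprintf("contribution of %s undefined: lead %s", l,
                   if (all(has)) "present in every set"
                   else "absent from every set"))
    deltas <- vapply(metrics, function(m)
      mean(results[[m]][has]) - mean(results[[m]][!has]), numeric(1L))
    names(deltas) <- paste0("delta_", metrics)
    cbind(data.frame(lead = l, stringsAsFactors = FALSE),
          as.data.frame(as.list(deltas)))
  })
  out <- do.call(rbind, rows)
  out[order(-out$delta_auc), , drop = FALSE]
}

#' Compare model performance across lead-count bins
#'
#' Groups evaluated lead sets by the number of leads used (default bins
#' 1--5, 6--9 and 10--12 leads), reports mean and sd AUC per bin, and runs
#' the one-way ANOVA + Tukey HSD comparison. Empty bins are dropped with a
#' message; at least two non-empty bins are required.
#'
#' @param results As in [leadContribution()].
#' @param bins List of `c(lo, hi)` lead-count ranges.
#' @return The [compareConfigurations()] report, with bins as the
#'   configurations.
#' @export
groupByLeadCount <- function(results,
                             bins = list(c(1L, 5L), c(6L, 9L),
                                         c(10L, 12L))) {
  stopifnot("leads" %in% names(results))
  counts <- lengths(strsplit(results$leads, "+", fixed = TRUE))
  lab <- rep(NA_character_, length(counts))
  for (b in bins) {
    sel <- counts >= b[1L] & counts <= b[2L]
    lab[sel] <- sprintf("%d-%d leads", b[1L], b[2L])
  }
  keep <- !is.na(lab)
  present <- unique(lab[keep])
  if (length(present) < length(bins))
    message("dropping empty lead-count bin(s)")
  if (length(present) < 2L)
    stop("need results spanning at least two lead-count bins")
  df <- data.frame(configuration = lab[keep], fold = NA_integer_,
                   auc = results$auc[keep])
  compareConfigurations(df, requireBalanced = FALSE)
}
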