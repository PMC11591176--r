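test_that("degenerate generator settings produce exactly zero signal", {
  cfg <- quietConfig(waves = waveParams(
    amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0)))
  set.seed(1)
  rec <- simulateRecord(cfg, lvef = 60)
  expect_identical(dim(signalMatrix(rec)), c(12L, 5000L))
  expect_equal(max(abs(signalMatrix(rec))), 0)
})

test_that("beat count is forced by heart rate at zero jitter", {
  cfg <- quietConfig(heartRateMean = 60, seed = 1)
  for (s in 1:3) {
    set.seed(s)
    rec <- simulateRecord(cfg, lvef = 55)
    expect_identical(nrow(truthBeats(rec)), 10L)
  }
})

test_that("limb leads obey the derived-lead algebra in the noise-free regime", {
  ## baseline wander stays on: it is added in source space and must project
  ## consistently with the limb-lead identities
  cfg <- quietConfig(baselineWanderAmp = 0.05, heartRateMean = 72, seed = 2)
  set.seed(2)
  sig <- signalMatrix(simulateRecord(cfg, lvef = 45))
  expect_lt(max(abs(sig["III", ] - (sig["II", ] - sig["I", ]))), 1e-9)
  expect_lt(max(abs(sig["aVR", ] + (sig["I", ] + sig["II", ]) / 2)), 1e-9)
})

test_that("truth R peaks are the noise-free argmax of lead II per beat", {
  sig <- signalMatrix(quietRecord)
  tr <- truthBeats(quietRecord)
  for (i in seq_len(nrow(tr))) {
    w <- max(1, tr$r_peak[i] - 150):min(5000, tr$r_peak[i] + 150)
    expect_identical(w[which.max(sig[2, w])], tr$r_peak[i])
  }
})

test_that("a planted T-wave amplitude effect scales the T wave exactly", {
  cfg <- quietConfig(effects = list(
    effectSpec("ST-T", ecgLeadNames(), amplitudeMultiplier = 0.5,
               classes = c("mrEF", "rEF"))))
  set.seed(9); unaffected <- simulateRecord(cfg, lvef = 60)
  set.seed(9); affected <- simulateRecord(cfg, lvef = 30)
  tr <- truthBeats(unaffected)
  expect_identical(tr$r_peak, truthBeats(affected)$r_peak)
  ## compare within the T-wave support of an interior beat
  w <- (tr$st_junction[2] + 20):tr$t_end[2]
  ratio <- max(abs(signalMatrix(affected)[, w])) /
    max(abs(signalMatrix(unaffected)[, w]))
  expect_equal(ratio, 0.5, tolerance = 1e-6)
})

test_that("effect realisation holds for every wave/lead/multiplier combination", {
  cases <- expand.grid(wave = c("P", "QRS", "ST-T"), mult = c(0.5, 1.6),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cfg <- quietConfig(effects = list(
      effectSpec(cases$wave[i], c("II", "V3"),
                 amplitudeMultiplier = cases$mult[i], classes = "rEF")))
    wtP <- beatwise:::.effectiveWaveTable(cfg, "pEF", FALSE)
    wtR <- beatwise:::.effectiveWaveTable(cfg, "rEF", FALSE)
    waves <- switch(cases$wave[i], P = "P", QRS = c("Q", "R", "S"),
                    `ST-T` = "T")
    sel <- wtP$wave %in% waves & wtP$lead %in% c("II", "V3")
    expect_equal(wtR$amplitude[sel], wtP$amplitude[sel] * cases$mult[i])
    expect_equal(wtR$amplitude[!sel], wtP$amplitude[!sel])
  }
})

test_that("cohorts have configured class counts, in-range LVEF, and AF truth", {
  cfg <- cohortConfig(nCases = c(pEF = 10, mrEF = 5, rEF = 5),
                      afFraction = c(pEF = 0, mrEF = 0, rEF = 1),
                      seed = 77)
  coh <- makeCohort(cfg)
  man <- cohortManifest(coh)
  expect_identical(nrow(man), 20L)
  expect_identical(as.vector(table(factor(man$ef_class,
                                          c("pEF", "mrEF", "rEF")))),
                   c(10L, 5L, 5L))
  expect_true(all(man$lvef[man$ef_class == "pEF"] >= 50))
  expect_true(all(man$lvef[man$ef_class == "mrEF"] >= 40 &
                  man$lvef[man$ef_class == "mrEF"] < 50))
  expect_true(all(man$lvef[man$ef_class == "rEF"] < 40))
  ## af_fraction = 1 for rEF: every rEF record is AF with zero P amplitude
  for (r in cohortRecords(coh)) {
    if (efClass(r) == "rEF") {
      expect_true(isAF(r))
      wt <- waveTable(r)
      expect_true(all(wt$amplitude[wt$wave == "P"] == 0))
    } else {
      expect_false(isAF(r))
    }
  }
})

test_that("cohort generation is bitwise reproducible and leaves the RNG alone", {
  cfg <- cohortConfig(nCases = c(pEF = 3, mrEF = 0, rEF = 2), seed = 12)
  set.seed(999); before <- rnorm(1)
  a <- makeCohort(cfg)
  b <- makeCohort(cfg)
  for (i in seq_along(cohortRecords(a))) {
    expect_identical(signalMatrix(a[[i]]), signalMatrix(b[[i]]))
    expect_identical(truthBeats(a[[i]]), truthBeats(b[[i]]))
  }
  set.seed(999)
  expect_identical(rnorm(1), before)
})

test_that("invalid generator inputs are rejected", {
  expect_error(makeCohort(cohortConfig(nCases = c(pEF = 0, mrEF = 0,
                                                  rEF = 0))),
               "counts")
  expect_error(simulateRecord(cohortConfig(), lvef = 0), "lvef")
  expect_error(simulateRecord(cohortConfig(heartRateMean = -5), lvef = 60))
  expect_error(cohortConfig(leadProjection = matrix(0, 11, 3)), "12 rows")
  expect_error(effectSpec("ST-T", character(0)), "non-empty")
  expect_error(waveParams(width = c(Q = -1)), "widths")
})
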