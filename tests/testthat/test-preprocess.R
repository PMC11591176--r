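test_that("strip start offsets are evenly spaced and endpoint-inclusive", {
  expect_identical(oversampleOffsets(4), c(0L, 1167L, 2333L, 3500L))
  expect_identical(oversampleOffsets(1), 0L)
  o16 <- oversampleOffsets(16)
  expect_length(o16, 16L)
  expect_identical(o16[1L], 0L)
  expect_identical(o16[16L], 3500L)
  expect_true(all(o16 + 1500L <= 5000L))
  expect_true(all(diff(o16) %in% c(233L, 234L)))
  expect_error(oversampleOffsets(0), ">= 1")
})

test_that("strip counts follow the class- and split-dependent factors", {
  expected <- list(train = c(pEF = 4L, mrEF = 7L, rEF = 6L),
                   dev = c(pEF = 4L, mrEF = 16L, rEF = 11L),
                   test = c(pEF = 4L, mrEF = 16L, rEF = 11L))
  for (role in names(expected)) {
    for (cl in names(expected[[role]])) {
      strips <- extractStrips(quietRecord, splitRole = role, class = cl)
      expect_length(strips, expected[[role]][[cl]])
      for (s in strips)
        expect_identical(dim(tensorData(s)), c(12L, 1500L))
    }
  }
  expect_error(extractStrips(quietRecord, "train", class = "low"),
               "unknown EF class")
})

test_that("single beats are 12 x 375 windows padded after the T-wave end", {
  beats <- extractSingleBeats(quietRecord)
  tr <- truthBeats(quietRecord)
  expect_length(beats, nrow(tr))
  for (b in beats) {
    m <- tensorData(b)
    expect_identical(dim(m), c(12L, 375L))
    tw <- tr$t_end[b@beatIndex] - (tr$r_peak[b@beatIndex] - 125L) + 1L
    if (tw < 375L) {
      for (ld in c(1L, 7L))
        expect_true(all(m[ld, tw:375L] == m[ld, tw]))
    }
  }
  ## beats whose window leaves the record are dropped
  ann <- data.frame(r_peak = c(100L, 500L), qrs_onset = c(50L, 450L),
                    st_junction = c(127L, 527L), t_end = c(330L, 730L))
  kept <- extractSingleBeats(quietRecord, ann)
  expect_length(kept, 1L)
  expect_identical(attr(kept, "dropped"), 1L)
})

test_that("partial segments mask by constant continuation and nest correctly", {
  beats <- extractSingleBeats(quietRecord)
  tr <- truthBeats(quietRecord)
  b <- beats[[3L]]
  ann <- tr[b@beatIndex, , drop = FALSE]
  ws <- ann$r_peak - 125L
  bb <- ann$qrs_onset - 50L - ws          # P/QRS boundary, 0-based window
  jj <- ann$st_junction - ws
  tt <- ann$t_end - ws
  full <- tensorData(b)

  pP <- tensorData(makePartial(b, ann, "P"))
  expect_identical(dim(pP), c(12L, 375L))
  expect_equal(pP[, 1:bb], full[, 1:bb])
  for (ld in 1:12)
    expect_true(all(pP[ld, (bb + 1L):375L] == full[ld, bb]))

  pQRS <- tensorData(makePartial(b, ann, "QRS"))
  pQRST <- tensorData(makePartial(b, ann, "QRST"))
  ## QRS and QRST agree on the shared [b, j) span
  expect_equal(pQRS[, (bb + 1L):jj], pQRST[, (bb + 1L):jj])
  ## PQRST is the identity segmentation
  expect_identical(tensorData(makePartial(b, ann, "PQRST")), full)

  ## unmasked-sample monotonicity: P < PQRS < PQRST and QRS < QRST < PQRST
  unmasked <- function(kind) {
    switch(kind, P = seq_len(bb), QRS = (bb + 1L):jj, QRST = (bb + 1L):tt,
           PQRS = seq_len(jj), PQRST = 1:375)
  }
  expect_true(all(unmasked("P") %in% unmasked("PQRS")))
  expect_true(all(unmasked("PQRS") %in% unmasked("PQRST")))
  expect_true(all(unmasked("QRS") %in% unmasked("QRST")))
  expect_true(all(unmasked("QRST") %in% unmasked("PQRST")))

  bad <- ann; bad$st_junction <- bad$qrs_onset - 60L
  expect_error(makePartial(b, bad, "QRS"), "ordering")
})

test_that("two-beat composition stacks consecutive beats and wraps the last", {
  beats <- extractSingleBeats(quietRecord)
  n <- length(beats)
  tb <- composeTwoBeats(beats)
  expect_length(tb, n)
  for (i in seq_len(n)) {
    m <- tensorData(tb[[i]])
    expect_identical(dim(m), c(24L, 375L))
    expect_identical(m[1:12, ], tensorData(beats[[i]]))
    expect_identical(m[13:24, ], tensorData(beats[[if (i == n) 1L else i + 1L]]))
  }
  ## minimal two-beat input: (b0|b1), (b1|b0)
  tb2 <- composeTwoBeats(beats[1:2])
  expect_identical(tensorData(tb2[[2L]])[1:12, ], tensorData(beats[[2L]]))
  expect_identical(tensorData(tb2[[2L]])[13:24, ], tensorData(beats[[1L]]))
  expect_identical(composeTwoBeats(list()), list())
})

test_that("lead subsetting returns canonical order and rejects bad leads", {
  b <- extractSingleBeats(quietRecord)[[1L]]
  r <- subsetLeads(b, c("aVR", "I"))
  expect_identical(tensorLeads(r), c("I", "aVR"))
  expect_identical(tensorData(r)[1L, ], tensorData(b)[1L, ])
  expect_identical(tensorData(r)[2L, ], tensorData(b)[4L, ])
  one <- subsetLeads(b, "I")
  expect_identical(dim(tensorData(one)), c(1L, 375L))
  expect_identical(tensorData(subsetLeads(b, ecgLeadNames())),
                   tensorData(b))
  expect_error(subsetLeads(b, character(0)), "non-empty")
  expect_error(subsetLeads(b, c("I", "W9")), "unknown lead")
})

test_that("standardisation uses global scalar train statistics", {
  set.seed(6)
  train <- array(rnorm(2 * 5 * 40, mean = 3, sd = 2), c(2, 5, 40))
  std <- fitStandardiser(train)
  z <- applyStandardiser(std, train)
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sd(as.numeric(z)), 1, tolerance = 1e-6)
  ## a test set shifted by +5 mV lands at +5/sd_train, not at zero
  zt <- applyStandardiser(std, train + 5)
  expect_equal(mean(zt), 5 / std@sd, tolerance = 1e-6)
  expect_error(fitStandardiser(array(1, c(2, 3, 4))), "constant")
})
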