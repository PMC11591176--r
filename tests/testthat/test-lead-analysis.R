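test_that("lead-set enumeration matches closed-form combinatorics", {
  singles <- enumerateLeadSets("singles")
  expect_length(singles, 12L)
  expect_true(all(lengths(singles) == 1L))
  loo <- enumerateLeadSets("leave_one_out")
  expect_length(loo, 13L)
  expect_identical(sort(unique(lengths(loo))), c(11L, 12L))
  all_sets <- enumerateLeadSets("all")
  expect_length(all_sets, 4095L)       # 2^12 - 1
  expect_equal(as.vector(table(lengths(all_sets))),
               as.vector(choose(12, 1:12)))
  sampled <- enumerateLeadSets("sampled", nSample = 30L, seed = 2)
  expect_length(sampled, 30L)
  expect_identical(anyDuplicated(vapply(sampled, paste, "",
                                        collapse = "+")), 0L)
  expect_identical(enumerateLeadSets("sampled", nSample = 30L, seed = 2),
                   sampled)
  expect_error(enumerateLeadSets("sampled", nSample = 5000L), "exceeds")
})

test_that("contributions are with-minus-without means per metric", {
  ## AUC 0.9 iff the set contains lead I, else 0.8
  sets <- c("I", "II", "I+II", "I+V3", "II+V3", "V3")
  hasI <- vapply(strsplit(sets, "+", fixed = TRUE),
                 function(s) "I" %in% s, logical(1L))
  res <- data.frame(leads = sets, auc = ifelse(hasI, 0.9, 0.8),
                    accuracy = 0.7)
  tab <- leadContribution(res)
  expect_equal(tab$delta_auc[tab$lead == "I"], 0.1)
  expect_equal(tab$delta_accuracy, rep(0, nrow(tab)))
  ## constant metric: every contribution is exactly zero
  resc <- data.frame(leads = sets, auc = 0.85)
  tabc <- leadContribution(resc)
  expect_equal(tabc$delta_auc, rep(0, nrow(tabc)))
  ## a lead present in every set (or absent from all) is undefined
  expect_error(leadContribution(data.frame(leads = c("I", "I+II"),
                                           auc = c(0.8, 0.9)),
                                leads = "I"), "every set")
  expect_error(leadContribution(data.frame(leads = c("II", "III"),
                                           auc = c(0.8, 0.9)),
                                leads = "I"), "absent")
})

test_that("lead-count grouping bins results and runs the ANOVA comparison", {
  set.seed(13)
  mkLeads <- function(k) vapply(k, function(kk)
    paste(sample(ecgLeadNames(), kk), collapse = "+"), "")
  res <- data.frame(
    leads = c(mkLeads(rep(3, 8)), mkLeads(rep(7, 8)), mkLeads(rep(11, 8))),
    auc = c(rnorm(8, 0.78, 0.01), rnorm(8, 0.85, 0.01),
            rnorm(8, 0.85, 0.01)))
  grp <- groupByLeadCount(res)
  expect_identical(grp$method, "anova_tukey")
  expect_identical(sort(grp$summary$configuration),
                   sort(c("1-5 leads", "6-9 leads", "10-12 leads")))
  ## the depressed small-lead bin is separated from both larger bins
  involvesSmall <- grepl("1-5 leads", grp$tukey$contrast, fixed = TRUE)
  expect_true(all(grp$tukey$`p adj`[involvesSmall] < 0.05))
  expect_true(all(grp$tukey$`p adj`[!involvesSmall] > 0.05))
  ## all-equal results show no separation anywhere
  resEq <- res; resEq$auc <- 0.8 + rep(c(0, 1e-4, -1e-4), 8)
  grpEq <- groupByLeadCount(resEq)
  expect_true(all(grpEq$tukey$`p adj` > 0.05))
  ## a single populated bin is rejected
  expect_error(groupByLeadCount(res[1:8, ]), "two lead-count bins")
})
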