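counts <- qualitativeCounts()
assess <- expandQualCounts(counts)

test_that("accuracy rates recompute the printed cells from their counts", {
  r <- accuracyRates(assess, "c5_root")
  expect_equal(r$accuracy, 13 / 15)        # prints as 86.7 (13/15)
  expect_equal(r$fp_rate, 1 / 15)
  expect_equal(r$fn_rate, 1 / 15)
  expect_equal(r$denominator, 15L)

  # two unrecorded radial nerve assessments shrink the denominator
  r <- accuracyRates(assess, "radial_nerve")
  expect_equal(r$denominator, 13L)
  expect_equal(r$accuracy, 11 / 13)        # prints as 84.6 (11/13)

  # every bundled accuracy cell matches its numerator/denominator
  acc <- counts[counts$measure == "accuracy", ]
  for (i in seq_len(nrow(acc))) {
    r <- accuracyRates(assess, acc$structure_id[i])
    expect_equal(r$accuracy, acc$numerator[i] / acc$denominator[i],
                 label = acc$structure_id[i])
  }
})

test_that("accuracy rates are proportions that partition the assessments", {
  all15 <- data.frame(expert_id = "e", region = "SNB",
                      structure_id = "x", outcome = rep("TP", 8))
  r <- accuracyRates(all15, "x")
  expect_equal(r$accuracy, 1); expect_equal(r$fp_rate, 0)
  expect_equal(r$fn_rate, 0)
  for (sid in unique(assess$structure_id)) {
    r <- accuracyRates(assess, sid)
    expect_equal(r$accuracy + r$fp_rate + r$fn_rate, 1, label = sid)
  }
  none <- accuracyRates(assess[0, ], "x")
  expect_true(is.na(none$accuracy))
  expect_equal(none$denominator, 0L)
})

test_that("risk tallies reproduce printed judgment splits and sum to one", {
  t <- riskTally(assess, "c5_root", "nerve_trauma")
  expect_equal(unname(t$proportions),
               c(2, 0, 13) / 15)            # 13.3 / 0 / 86.7
  expect_equal(t$denominator, 15L)

  uni <- data.frame(expert_id = "e", region = "SNB", structure_id = "x",
                    outcome = "TP", risk_nerve_trauma = rep("no_change", 7))
  expect_equal(unname(riskTally(uni, "x", "nerve_trauma")$proportions),
               c(0, 1, 0))

  five <- data.frame(expert_id = "e", region = "SNB", structure_id = "x",
                     outcome = "TP",
                     risk_nerve_trauma = c("increase", "increase",
                                           "no_change", "no_change",
                                           "decrease"))
  expect_equal(unname(riskTally(five, "x", "nerve_trauma")$proportions),
               c(0.4, 0.4, 0.2))

  for (i in which(counts$measure == "risk" & counts$judgment == "increase")) {
    t <- riskTally(assess, counts$structure_id[i], counts$event[i])
    expect_equal(sum(t$proportions), 1)
    expect_equal(sum(t$counts), t$denominator)
  }

  # events outside the region's applicable set are refused
  expect_error(riskTally(assess, "c5_root", "peritoneal_violation"),
               "not applicable.*ISB")
  expect_error(riskTally(assess, "c5_root", "volcanic_eruption"),
               "unknown event")
})

test_that("subjective score summaries use the sample sd and flag empties", {
  s <- subjectiveSummary(c(7, 7, 7))
  expect_equal(s$mean, 7); expect_equal(s$min, 7); expect_equal(s$max, 7)
  expect_equal(s$sd, 0)
  s <- subjectiveSummary(c(0, 10))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, sqrt(50), tolerance = 1e-12)   # ~7.07
  # 15-score panel against a frozen hand computation
  panel <- c(8, 6, 7, 9, 5, 7, 8, 10, 4, 7, 6, 8, 7, 9, 8)
  s <- subjectiveSummary(panel)
  expect_equal(s$mean, 7.266667, tolerance = 1e-6)
  expect_equal(s$min, 4); expect_equal(s$max, 10)
  expect_equal(s$sd, 1.579632, tolerance = 1e-6)
  expect_equal(s$n, 15L)
  expect_true(is.na(subjectiveSummary(numeric(0))$mean))
  expect_error(subjectiveSummary(c(5, 11)), "0-10")
})

test_that("assessment CSVs are validated on load", {
  p <- tempfile(fileext = ".csv")
  write.csv(assess, p, row.names = FALSE)
  re <- loadQualAssessments(p)
  expect_equal(nrow(re), nrow(assess))
  bad <- assess; bad$outcome[1] <- "XX"
  write.csv(bad, p, row.names = FALSE)
  expect_error(loadQualAssessments(p), "invalid outcome")
})
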