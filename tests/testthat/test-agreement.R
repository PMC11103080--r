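# grouped 1-scan set with given per-annotator statuses for one nerve blob
blobSet <- function(statuses, nHumans = length(statuses) - 1L) {
  m <- tinyManifest(nHumans = nHumans)
  ids <- c(sprintf("h%d", seq_len(nHumans)), "ai")
  anns <- mapply(function(id, s) {
    annotation(id, "s1", "blob", "region",
               components = if (s == "present") list(squarePoly(10, 10, 30))
                            else list(),
               status = s)
  }, ids, statuses, SIMPLIFY = FALSE)
  annotationSet(unname(anns), m, grouped = TRUE)
}

test_that("pair counting follows the comparison scheme", {
  st <- simulateStudy(studyConfig(
    nHumans = 19, scansPerRegion = 1, width = 128, height = 96,
    humanProfile = annotatorProfile("t", pOmit = 0, pWrongKind = 0,
                                    pSkipImage = 0)), seed = 5)
  kept <- curate(st)$kept
  sc <- pairwiseScores(kept)
  one <- sc[sc$scan_id == "SNB_01" & sc$group_id == "sciatic_nerve", ]
  expect_equal(sum(one$mode == "HH"), choose(19, 2))   # 171
  expect_equal(sum(one$mode == "HAI"), 19L)
  # global: h*(h-1)/2 HH and h HAI per scan-group
  tab <- table(sc$mode)
  expect_equal(unname(tab["HH"]), 18L * choose(19, 2))
  expect_equal(unname(tab["HAI"]), 18L * 19L)
})

test_that("retained-human reduction and empty-pair conventions hold", {
  # 3 humans, one image-skipped (dropped by curation upstream): 1 HH pair
  kept <- blobSet(c("present", "present", "absent", "present"))
  # drop h3 as curation would after an image skip
  kept@annotations <- Filter(function(a) a@annotatorId != "h3",
                             kept@annotations)
  sc <- pairwiseScores(kept)
  expect_equal(sum(sc$mode == "HH"), 1L)
  expect_equal(sum(sc$mode == "HAI"), 2L)
  expect_true(all(sc$value == 1))

  # one-empty pairs score 0 for dice; both-empty pairs carry no value
  sc <- pairwiseScores(blobSet(c("present", "absent", "absent", "present")))
  hh <- sc[sc$mode == "HH", ]
  expect_equal(sort(hh$value, na.last = TRUE), c(0, 0, NA))
  expect_equal(sum(hh$both_empty), 1L)
  hai <- sc[sc$mode == "HAI", ]
  expect_equal(hai$value[hai$annotator_b == "h1"], 1)
  expect_equal(hai$value[hai$annotator_b == "h2"], 0)
})

test_that("zero-noise panels agree perfectly under both metrics", {
  st <- simulateStudy(studyConfig(
    nHumans = 3, scansPerRegion = 1, width = 128, height = 96,
    humanProfile = annotatorProfile("t", translationSigma = 0,
      boundaryNoiseSigma = 0, scaleSigma = 0, pOmit = 0, pWrongKind = 0,
      pSkipImage = 0),
    aiProfile = annotatorProfile("ai", role = "ai", translationSigma = 0,
      boundaryNoiseSigma = 0, scaleSigma = 0, pOmit = 0, pWrongKind = 0,
      pSkipImage = 0)), seed = 7)
  sc <- pairwiseScores(curate(st)$kept)
  expect_true(all(sc$value[sc$metric == "dice"] == 1))
  expect_true(all(sc$value[sc$metric == "hausdorff"] == 0))
})

test_that("summaries pool raw pairs with sample sd and both-empty handling", {
  sc <- data.frame(scan_id = "s1", group_id = "g", structure_class = "nerve",
                   metric = "dice", mode = "HH",
                   annotator_a = c("a", "a", "b"), annotator_b = c("b", "c", "c"),
                   value = c(0.5, 0.7, 0.9), both_empty = FALSE)
  row <- summarizeScores(sc, by = "structure", mode = "HH")
  expect_equal(row$n_pairs, 3L)
  expect_equal(row$min, 0.5); expect_equal(row$mean, 0.7)
  expect_equal(row$median, 0.7); expect_equal(row$max, 0.9)
  expect_equal(row$sd, 0.2)

  one <- summarizeScores(sc[1, ], by = "structure", mode = "HH")
  expect_equal(one$min, one$mean)
  expect_equal(one$median, one$max)
  expect_true(is.na(one$sd))

  # both-empty excluded by default, scored perfect under the sensitivity policy
  sc2 <- rbind(sc, within(sc[1, ], { value <- NA_real_; both_empty <- TRUE }))
  ex <- summarizeScores(sc2, by = "structure", mode = "HH")
  expect_equal(ex$n_pairs, 3L); expect_equal(ex$n_both_empty, 1L)
  pf <- summarizeScores(sc2, by = "structure", mode = "HH",
                        bothEmpty = "perfect")
  expect_equal(pf$n_pairs, 4L)
  expect_equal(pf$mean, mean(c(0.5, 0.7, 0.9, 1)))

  # a scope with nothing poolable is flagged, not dropped
  sc3 <- within(sc, { value <- NA_real_; both_empty <- TRUE })
  z <- summarizeScores(sc3, by = "structure", mode = "HH")
  expect_equal(z$n_pairs, 0L)
  expect_true(is.na(z$mean))
})

test_that("summaries are invariant to annotator relabelling", {
  st <- simulateStudy(studyConfig(nHumans = 4, scansPerRegion = 1,
                                  width = 128, height = 96), seed = 9)
  kept <- curate(st)$kept
  ref <- summarizeScores(pairwiseScores(kept), by = "class",
                         mode = c("HH", "HAI"))
  # permute the human ids
  humans <- annotators(manifest(kept))
  perm <- c(h <- humans$annotator_id[humans$role == "human"])[c(3, 1, 4, 2)]
  names(perm) <- h
  kept2 <- kept
  kept2@annotations <- lapply(kept@annotations, function(a) {
    if (a@annotatorId %in% names(perm)) a@annotatorId <- unname(perm[a@annotatorId])
    a
  })
  got <- summarizeScores(pairwiseScores(kept2), by = "class",
                         mode = c("HH", "HAI"))
  ord <- function(d) d[order(d$scope, d$mode), setdiff(names(d), NULL)]
  expect_equal(ord(got), ord(ref), ignore_attr = TRUE)
})

test_that("mode comparison picks the superior mean per metric direction", {
  mk <- function(mode, metric, mean, sd) data.frame(
    scope = "s", scope_kind = "class", mode = mode, metric = metric,
    n_pairs = 10L, n_both_empty = 0L, min = 0, mean = mean, median = mean,
    max = 1, sd = sd)
  cmp <- compareModes(mk("HH", "dice", 0.80, 0.23), mk("HAI", "dice", 0.77, 0.23))
  expect_equal(cmp$superior_mean, "HH")
  expect_equal(cmp$smaller_sd, "equal")
  cmp <- compareModes(mk("HH", "dice", 0.8, 0.1), mk("HAI", "dice", 0.8, 0.2))
  expect_equal(cmp$superior_mean, "equal")
  expect_equal(cmp$smaller_sd, "HH")
  cmp <- compareModes(mk("HH", "hausdorff", 0.08, 0.13),
                      mk("HAI", "hausdorff", 0.16, 0.21))
  expect_equal(cmp$superior_mean, "HH")   # lower is better for Hausdorff
  expect_error(compareModes(mk("HH", "dice", 1, 1),
                            within(mk("HAI", "dice", 1, 1), scope <- "x")),
               "scope mismatch")
})

test_that("mean pairwise Dice decreases strictly with boundary noise", {
  scene <- diskScene()
  means <- vapply(c(0.5, 2, 5), function(sig) {
    p <- annotatorProfile("t", translationSigma = 0, boundaryNoiseSigma = sig,
                          scaleSigma = 0, pOmit = 0, pWrongKind = 0,
                          pSkipImage = 0)
    vals <- vapply(1:110, function(i) {
      a <- simulateAnnotator(scene, p, "s1", seed = 2000 + 2 * i)[[1]]
      b <- simulateAnnotator(scene, p, "s1", seed = 2001 + 2 * i)[[1]]
      dice(rasterize(a@components, 160, 160),
           rasterize(b@components, 160, 160))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
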