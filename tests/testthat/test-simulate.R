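test_that("scene generation is deterministic, bounded, and region-faithful", {
  tpl <- sceneTemplate("ACB")
  s1 <- generateScene(tpl, seed = 5)
  s2 <- generateScene(tpl, seed = 5)
  expect_identical(s1, s2)
  expect_setequal(names(s1$structures),
                  c("femoral_artery", "saphenous_nerve", "sartorius"))

  tpl <- sceneTemplate("ISB")
  for (sd in 1:300) {
    sc <- generateScene(tpl, width = 512, height = 384, seed = sd)
    for (gt in sc$structures) {
      m <- gt$components[[1]]
      expect_true(all(m[, 1] >= 0 & m[, 1] <= 512 &
                      m[, 2] >= 0 & m[, 2] <= 384))
    }
  }
  expect_error(generateScene(sceneTemplate("ISB"), width = 60, height = 60),
               "cannot fit")
})

test_that("annotator simulation honours its profile exactly at the extremes", {
  scene <- diskScene()
  zero <- annotatorProfile("z", translationSigma = 0, boundaryNoiseSigma = 0,
                           scaleSigma = 0, pOmit = 0, pWrongKind = 0,
                           pSkipImage = 0)
  a <- simulateAnnotator(scene, zero, "s1", seed = 3)[[1]]
  expect_equal(a@components[[1]], scene$structures$disk$components[[1]],
               tolerance = 1e-12, ignore_attr = TRUE)

  omit <- annotatorProfile("o", pOmit = 1, pWrongKind = 0, pSkipImage = 0)
  a <- simulateAnnotator(scene, omit, "s1", seed = 3)[[1]]
  expect_equal(a@status, "absent")
  expect_length(a@components, 0L)

  skip <- annotatorProfile("s", pSkipImage = 1)
  a <- simulateAnnotator(scene, skip, "s1", seed = 3)[[1]]
  expect_equal(a@status, "image_skipped")

  wrong <- annotatorProfile("w", pOmit = 0, pWrongKind = 1, pSkipImage = 0)
  a <- simulateAnnotator(scene, wrong, "s1", seed = 3)[[1]]
  expect_equal(a@status, "invalid_geometry")
})

test_that("error-event frequencies converge to the configured probabilities", {
  scene <- diskScene()
  p <- annotatorProfile("e", pOmit = 0.1, pWrongKind = 0.05,
                        pSkipImage = 0.08)
  n <- 1000L
  status <- vapply(seq_len(n), function(i)
    simulateAnnotator(scene, p, "s1", seed = i)[[1]]@status, character(1))
  binTol <- function(p) 3 * sqrt(p * (1 - p) / n)
  pSkip <- mean(status == "image_skipped")
  expect_lt(abs(pSkip - 0.08), binTol(0.08))
  # conditional on not skipping
  kept <- status[status != "image_skipped"]
  expect_lt(abs(mean(kept == "absent") - 0.1), 3 * sqrt(0.1 * 0.9 / length(kept)))
  expect_lt(abs(mean(kept == "invalid_geometry") - 0.9 * 0.05),
            3 * sqrt(0.045 * 0.955 / length(kept)))
})

test_that("study simulation is reproducible and sized to the default layout", {
  cfg <- studyConfig(nHumans = 3, scansPerRegion = 1, width = 128, height = 96)
  s1 <- simulateStudy(cfg, seed = 42)
  s2 <- simulateStudy(cfg, seed = 42)
  expect_equal(length(annotations(s1)), length(annotations(s2)))
  for (i in seq_along(annotations(s1)))
    expect_identical(annotations(s1)[[i]], annotations(s2)[[i]])
  s3 <- simulateStudy(cfg, seed = 43)
  same <- vapply(seq_along(annotations(s1)), function(i)
    isTRUE(all.equal(annotations(s1)[[i]]@components,
                     annotations(s3)[[i]]@components)), logical(1))
  expect_false(all(same))

  # default layout: 19 x 90 grouped potential annotations
  r <- curate(simulateStudy(studyConfig(), seed = 1))$report
  expect_equal(r@potentialAnnotations, 1900L)
  expect_equal(r@groupedPotential, 1710L)
})

test_that("translation-jitter Dice matches its semi-analytic expectation", {
  scene <- diskScene(r = 20, width = 200, height = 200)
  truth <- rasterize(scene$structures$disk$components[[1]], 200, 200)
  p <- annotatorProfile("j", translationSigma = 5, boundaryNoiseSigma = 0,
                        scaleSigma = 0, pOmit = 0, pWrongKind = 0,
                        pSkipImage = 0)
  vals <- vapply(1:300, function(i) {
    a <- simulateAnnotator(scene, p, "s1", seed = 40000 + i)[[1]]
    dice(rasterize(a@components, 200, 200), truth)
  }, numeric(1))
  expected <- expectedDiceTranslationJitter(20, 5)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("the analytic disk Dice agrees with high-resolution rasterization", {
  expect_equal(analyticDiceDisks(20, 20, 0), 1)
  expect_equal(analyticDiceDisks(15, 20, 40), 0)
  expect_equal(analyticDiceDisks(10, 30, 0),
               2 * pi * 100 / (pi * 100 + pi * 900))  # containment
  a <- rasterize(diskPolygon(480, 500, 20, 720), 1000, 1000)
  b <- rasterize(diskPolygon(490, 500, 20, 720), 1000, 1000)
  expect_lt(abs(dice(a, b) - analyticDiceDisks(20, 20, 10)), 0.005)
  expect_error(analyticDiceDisks(-1, 2, 0), "radii")
})
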