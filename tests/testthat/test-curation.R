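# helper: grouped annotation set for the C5/C6 pair with given member statuses
c5c6Set <- function(statusC5, statusC6) {
  m <- defaultManifest(nHumans = 2, scansPerRegion = 1)
  mk <- function(sid, status) {
    comps <- if (status == "present") list(squarePoly(10 + 30 * (sid == "c6_root"), 10, 15))
             else list()
    annotation("expert01", "ISB_01", sid, "region", components = comps,
               status = status, groupId = "c5_c6")
  }
  applyGrouping(annotationSet(list(mk("c5_root", statusC5),
                                   mk("c6_root", statusC6)), m))
}

test_that("grouping merges member structures with the status dominance rule", {
  g <- annotations(c5c6Set("present", "present"))
  expect_length(g, 1L)
  expect_equal(g[[1]]@structureId, "c5_c6")
  expect_equal(g[[1]]@status, "present")
  expect_length(g[[1]]@components, 2L)

  g <- annotations(c5c6Set("present", "absent"))
  expect_equal(g[[1]]@status, "present")
  expect_length(g[[1]]@components, 1L)

  g <- annotations(c5c6Set("invalid_geometry", "absent"))
  expect_equal(g[[1]]@status, "invalid_geometry")

  # full 4x4 enumeration against an independent statement of the merge rules
  statuses <- annotationStatuses()
  mergeOracle <- function(s1, s2) {
    s <- c(s1, s2)
    if ("present" %in% s) "present"
    else if (identical(s, rep("image_skipped", 2))) "image_skipped"
    else if ("invalid_geometry" %in% s) "invalid_geometry"
    else "absent"
  }
  for (s1 in statuses) for (s2 in statuses) {
    got <- annotations(c5c6Set(s1, s2))[[1]]@status
    expect_equal(got, mergeOracle(s1, s2),
                 label = sprintf("merge(%s, %s) = %s", s1, s2, got))
  }
})

test_that("an error-free study is fully retained with a conserved audit", {
  base <- annotatorProfile("t", pOmit = 0, pWrongKind = 0, pSkipImage = 0)
  st <- simulateStudy(studyConfig(nHumans = 4, scansPerRegion = 2,
                                  humanProfile = base), seed = 3)
  r <- curate(st)
  expect_equal(r$report@totalRemoved, 0L)
  expect_equal(r$report@analysed, r$report@groupedPotential)
  expect_equal(r$report@groupedPotential, 4L * 18L * 2L)
  expect_equal(r$report@potentialAnnotations, 4L * 20L * 2L)
})

test_that("a whole-image skip removes that scan's grouped entries", {
  base <- annotatorProfile("t", pOmit = 0, pWrongKind = 0, pSkipImage = 0)
  st <- simulateStudy(studyConfig(nHumans = 3, scansPerRegion = 1,
                                  width = 128, height = 96,
                                  humanProfile = base), seed = 4)
  # expert01 returns no annotations at all for the ISB scan
  st@annotations <- Filter(function(a)
    !(a@annotatorId == "expert01" && a@scanId == "ISB_01"), st@annotations)
  r <- curate(st)
  expect_equal(r$report@discardedImageSkips, 3L)  # 3 grouped ISB structures
  expect_equal(r$report@discardedInvalidGeometry, 0L)
  expect_equal(r$report@analysed, r$report@groupedPotential - 3L)
  keptIds <- vapply(annotations(r$kept), function(a) a@annotatorId, character(1))
  keptScans <- vapply(annotations(r$kept), function(a) a@scanId, character(1))
  expect_false(any(keptIds == "expert01" & keptScans == "ISB_01"))
})

test_that("curation conserves counts, is idempotent, and leaves geometry alone", {
  for (sd in 1:2) {
    st <- simulateStudy(studyConfig(nHumans = 4, scansPerRegion = 1,
      humanProfile = annotatorProfile("t", pOmit = 0.2, pWrongKind = 0.1,
                                      pSkipImage = 0.1)), seed = sd)
    r <- curate(st)
    expect_equal(r$report@analysed + r$report@totalRemoved,
                 r$report@groupedPotential)
    # idempotence on the kept collection
    r2 <- curate(r$kept)
    key <- function(a) paste(a@annotatorId, a@scanId, a@groupId, a@status)
    expect_setequal(vapply(annotations(r2$kept), key, character(1)),
                    vapply(annotations(r$kept), key, character(1)))
    # geometry of kept entries is untouched relative to the grouped input
    grouped <- applyGrouping(st)
    gkey <- vapply(annotations(grouped), function(a)
      paste(a@annotatorId, a@scanId, a@groupId), character(1))
    for (a in annotations(r$kept)) {
      if (a@status != "present") next
      src <- annotations(grouped)[[match(
        paste(a@annotatorId, a@scanId, a@groupId), gkey)]]
      expect_identical(a@components, src@components)
    }
  }
})

test_that("unknown annotators are rejected", {
  m <- tinyManifest()
  set <- annotationSet(list(
    annotation("nobody", "s1", "blob", "region", status = "absent")), m)
  expect_error(curate(set), "nobody")
})

test_that("the replica study reproduces the full accounting chain", {
  r <- curate(replicaStudy(seed = 1))$report
  expect_equal(r@potentialAnnotations, 1900L)
  expect_equal(r@groupedPotential, 1710L)
  expect_equal(r@discardedImageSkips, 5L)
  expect_equal(r@discardedInvalidGeometry, 26L)
  expect_equal(r@totalRemoved, 31L)
  expect_equal(r@analysed, 1679L)
})
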