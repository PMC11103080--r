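# Independent oracles and small fixture builders shared across tests.

# Even-odd point-in-polygon by per-point ray casting -- deliberately written
# as the classic scalar crossing loop, independent of the scanline rasterizer.
pipOracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- poly[i, 1] + (py - yi) * (poly[j, 1] - poly[i, 1]) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Exhaustive double-loop directed Hausdorff over all point pairs.
bruteDirectedHausdorff <- function(a, b) {
  worst <- 0
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
    if (best > worst) worst <- best
  }
  worst
}

squarePoly <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# A 2-human + AI manifest over a single ISB-like scan with one region and one
# line structure, for hand-constructed annotation fixtures.
tinyManifest <- function(nHumans = 3, width = 100, height = 80) {
  studyManifest(
    annotators = data.frame(
      annotator_id = c(sprintf("h%d", seq_len(nHumans)), "ai"),
      role = c(rep("human", nHumans), "ai")),
    scans = data.frame(scan_id = "s1", region = "ISB",
                       width = width, height = height),
    structures = data.frame(
      structure_id = c("blob", "plane"),
      display_name = c("Blob", "Plane"),
      region = "ISB",
      structure_class = c("nerve", "fascia_serosa"),
      quantitative = TRUE))
}

# Fast small-study configuration used by simulation-property tests: the full
# six-region layout at reduced panel and image size.
smallStudyConfig <- function(nHumans = 6, scansPerRegion = 2,
                             width = 192, height = 144, ...) {
  studyConfig(nHumans = nHumans, scansPerRegion = scansPerRegion,
              width = width, height = height, ...)
}

# One-disk scene at difficulty/size factor 1, for controlled perturbation
# experiments (radius-20 disk centred in a margin-safe image).
diskScene <- function(r = 20, width = 160, height = 160, n = 96) {
  structure(list(
    region = "ISB", width = width, height = height,
    structures = list(disk = list(
      kind = "region", class = "artery", difficulty = 1, sizeFactor = 1,
      components = list(diskPolygon(width / 2, height / 2, r, n))))),
    class = "scene")
}
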