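#' @include annotations.R
NULL

#' Construct an annotator profile
#'
#' @param annotatorId key.
#' @param role `"human"` or `"ai"`.
#' @param translationSigma Gaussian jitter of the structure position, px.
#' @param boundaryNoiseSigma smooth boundary perturbation amplitude, px.
#' @param scaleSigma sd of log area scale (log-normal area jitter).
#' @param pOmit probability of marking a visible structure absent.
#' @param pWrongKind probability of annotating with the wrong geometry kind.
#' @param pSkipImage probability of skipping a whole scan.
#' @return An [AnnotatorProfile-class].
#' @export
annotatorProfile <- function(annotatorId, role = "human",
                             translationSigma = 2, boundaryNoiseSigma = 2.5,
                             scaleSigma = 0.05, pOmit = 0.03,
                             pWrongKind = 0.015, pSkipImage = 0.003) {
  new("AnnotatorProfile", annotatorId = annotatorId, role = role,
      translationSigma = translationSigma,
      boundaryNoiseSigma = boundaryNoiseSigma, scaleSigma = scaleSigma,
      pOmit = pOmit, pWrongKind = pWrongKind, pSkipImage = pSkipImage)
}

#' Default per-class difficulty multipliers
#'
#' Multiplies every annotator's noise sigmas per structure class. Arteries are
#' the easiest targets on B-mode ultrasound (anechoic, pulsatile, sharp
#' walls), muscles intermediate, nerves hardest (small, isoechoic with
#' surroundings, anatomically variable); fascial planes sit between muscle and
#' nerve. The agreement ordering artery > muscle > nerve then emerges from the
#' simulation rather than being hard-coded.
#'
#' @return Named numeric vector over the four structure classes.
#' @export
defaultClassDifficulty <- function() {
  c(artery = 0.7, muscle = 1.4, nerve = 3, fascia_serosa = 1.5)
}

## shoelace area of an implicitly closed polygon
.polygonArea <- function(m) {
  n <- nrow(m)
  j <- c(seq_len(n)[-1], 1L)
  sum(m[, 1] * m[j, 2] - m[j, 1] * m[, 2]) / 2
}

## deterministic sub-seed derivation, kept below 2^31
.deriveSeed <- function(master, i, j = 0L) {
  (as.numeric(master) %% 1013904223 * 1000003 + i * 10007 + j * 101) %% 2147483647
}

#' Regular polygon approximation of a disk
#'
#' @param cx,cy centre, px.
#' @param r radius, px.
#' @param n number of vertices.
#' @return An n x 2 vertex matrix.
#' @export
diskPolygon <- function(cx, cy, r, n = 96L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(t), cy + r * sin(t))
}

## smooth zero-mean noise along a closed parameter t in [0, 2pi): low-order
## Fourier series with Gaussian coefficients, unit marginal sd
.fourierNoise <- function(t, nHarmonics = 3L) {
  v <- numeric(length(t))
  for (k in seq_len(nHarmonics))
    v <- v + stats::rnorm(1) * cos(k * t) + stats::rnorm(1) * sin(k * t)
  v / sqrt(nHarmonics)
}

## per-class ground-truth size parameters (px, for a 512x384 scene; scaled by
## image size for other dimensions)
.classShape <- function(cls) {
  switch(cls,
    artery = list(rx = c(15, 25), aspect = c(0.85, 1), wobble = 0.02),
    nerve  = list(rx = c(9, 16),  aspect = c(0.6, 1),  wobble = 0.08),
    muscle = list(rx = c(45, 70), aspect = c(0.35, 0.6), wobble = 0.06))
}

#' Build a scene template for one block region
#'
#' A scene template lists the structures to draw in one region together with
#' their parametric ground-truth generators: elliptical blobs with harmonic
#' boundary perturbation for arteries, muscles and nerves, smooth open curves
#' spanning the image for fascial/serosal planes. Per-class difficulty
#' multipliers (applied to annotator noise, see
#' [defaultClassDifficulty()]) travel with the template.
#'
#' @param region one of `blockRegions()`.
#' @param structures a structure table (defaults to the standard catalogue);
#'   only quantitative structures of `region` are drawn.
#' @param classDifficulty named multipliers per structure class.
#' @return A list of class `sceneTemplate`.
#' @export
sceneTemplate <- function(region, structures = .defaultStructureTable(),
                          classDifficulty = defaultClassDifficulty()) {
  stopifnot(region %in% .REGIONS)
  st <- structures[structures$region == region & structures$quantitative, ,
                   drop = FALSE]
  if (is.null(st$geometry_kind))
    st$geometry_kind <- .kindForClass(st$structure_class)
  structure(list(region = region, structures = st,
                 classDifficulty = classDifficulty),
            class = "sceneTemplate")
}

#' Generate the ground-truth scene for one scan
#'
#' Draws one ground-truth geometry per structure in the template,
#' deterministically for a given seed. Region structures are ellipse-like
#' blobs with low-order harmonic boundary perturbation, sized per class
#' (arteries small and round, nerves small, muscles large and elongated);
#' line structures are smooth open curves crossing most of the image width.
#' All geometry lies within the image bounds; an error is raised if a
#' structure cannot fit.
#'
#' @param template a [sceneTemplate()].
#' @param width,height image dimensions, px.
#' @param seed RNG seed.
#' @return A list of class `scene` with one entry per structure: `kind`,
#'   `class`, `difficulty`, `components`.
#' @export
generateScene <- function(template, width = 512L, height = 384L, seed = 1L) {
  stopifnot(inherits(template, "sceneTemplate"))
  set.seed(seed)
  if (width < 64 || height < 64)
    stop("structures cannot fit in a ", width, "x", height,
         " image; the smallest supported scan is 64x64 px")
  sc <- min(width / 512, height / 384)   # size scale for non-default images
  st <- template$structures
  out <- list()
  for (i in seq_len(nrow(st))) {
    cls <- st$structure_class[i]
    kind <- st$geometry_kind[i]
    if (kind == "region") {
      p <- .classShape(cls)
      rx <- stats::runif(1, p$rx[1], p$rx[2]) * sc
      ry <- rx * stats::runif(1, p$aspect[1], p$aspect[2])
      margin <- max(rx, ry) * 1.25 + 4
      if (2 * margin >= width || 2 * margin >= height)
        stop("structure '", st$structure_id[i], "' cannot fit in a ",
             width, "x", height, " image")
      cx <- stats::runif(1, margin, width - margin)
      cy <- stats::runif(1, margin, height - margin)
      theta <- stats::runif(1, 0, pi)
      t <- seq(0, 2 * pi, length.out = 49L)[-49L]
      wob <- 1 + p$wobble * .fourierNoise(t)
      ex <- rx * wob * cos(t); ey <- ry * wob * sin(t)
      comp <- cbind(cx + ex * cos(theta) - ey * sin(theta),
                    cy + ex * sin(theta) + ey * cos(theta))
    } else {
      x <- seq(0.08 * width, 0.92 * width, length.out = 25L)
      y0 <- stats::runif(1, 0.25 * height, 0.75 * height)
      amp <- stats::runif(1, 0.02, 0.06) * height
      ph <- stats::runif(2, 0, 2 * pi)
      y <- y0 + amp * sin(2 * pi * x / width + ph[1]) +
        0.5 * amp * sin(4 * pi * x / width + ph[2])
      comp <- cbind(x, y)
    }
    comp[, 1] <- pmin(pmax(comp[, 1], 0), width)
    comp[, 2] <- pmin(pmax(comp[, 2], 0), height)
    ## annotator noise scales with structure size (relative to a radius-20
    ## disk), so per-class agreement is governed by the difficulty multiplier
    ## rather than by how large the class's structures happen to be
    sizeFactor <- if (kind == "region")
      sqrt(abs(.polygonArea(comp)) / pi) / 20 else 1
    out[[st$structure_id[i]]] <-
      list(kind = kind, class = cls,
           difficulty = unname(template$classDifficulty[cls]),
           sizeFactor = sizeFactor,
           components = list(comp))
  }
  structure(list(region = template$region, width = width, height = height,
                 structures = out), class = "scene")
}

## perturb one ground-truth geometry according to a profile (noise sigmas
## already multiplied by class difficulty)
.perturbGeometry <- function(comps, kind, translationSigma, boundarySigma,
                             scaleSigma, width, height) {
  dxy <- stats::rnorm(2, 0, translationSigma)
  areaScale <- exp(stats::rnorm(1, 0, scaleSigma))
  linScale <- sqrt(areaScale)
  lapply(comps, function(m) {
    ctr <- colMeans(m)
    m <- sweep(sweep(m, 2, ctr), 2, c(linScale, linScale), "*")
    if (kind == "region") {
      rel <- m
      r <- sqrt(rowSums(rel^2))
      t <- atan2(rel[, 2], rel[, 1])
      ord <- order(t)          # noise indexed along the outline parameter
      noise <- numeric(length(t))
      noise[ord] <- boundarySigma * .fourierNoise(sort(t))
      rNew <- pmax(r + noise, 0.1 * r)   # clip to avoid self-intersection
      m <- cbind(rNew * cos(t), rNew * sin(t))
    } else {
      ## perpendicular smooth noise along the open curve
      n <- nrow(m)
      tt <- seq(0, pi, length.out = n)   # half period: open curve
      noise <- boundarySigma * .fourierNoise(tt)
      d <- rbind(m[2, ] - m[1, ], m[-1, ] - m[-n, ])
      len <- pmax(sqrt(rowSums(d^2)), 1e-9)
      normal <- cbind(-d[, 2] / len, d[, 1] / len)
      m <- m + noise * normal
    }
    m <- sweep(m, 2, ctr + dxy, "+")
    m[, 1] <- pmin(pmax(m[, 1], 0), width)
    m[, 2] <- pmin(pmax(m[, 2], 0), height)
    m
  })
}

#' Simulate one annotator's annotations of a scene
#'
#' Applies the profile's error processes and noise to the ground truth,
#' deterministically for a given seed: with probability `pSkipImage` the whole
#' scan is skipped (every structure `image_skipped`); otherwise each structure
#' independently is omitted (`absent`) with `pOmit`, flagged
#' `invalid_geometry` with `pWrongKind` (the wrong-kind drawing itself is
#' discarded, as at load time), or else drawn as the ground truth perturbed by
#' translation jitter, log-normal area scale jitter and smooth correlated
#' boundary noise. Each sigma is multiplied by the structure's class
#' difficulty.
#'
#' @param scene a [generateScene()] result.
#' @param profile an [AnnotatorProfile-class].
#' @param scanId scan key recorded on the annotations.
#' @param seed RNG seed.
#' @param groupIds optional named map structure_id -> group_id.
#' @return List of [Annotation-class] objects, one per structure.
#' @export
simulateAnnotator <- function(scene, profile, scanId, seed = 1L,
                              groupIds = NULL) {
  stopifnot(inherits(scene, "scene"), is(profile, "AnnotatorProfile"))
  set.seed(seed)
  skip <- stats::runif(1) < profile@pSkipImage
  out <- vector("list", length(scene$structures))
  names(out) <- names(scene$structures)
  for (sid in names(scene$structures)) {
    gt <- scene$structures[[sid]]
    gid <- if (!is.null(groupIds) && sid %in% names(groupIds))
      unname(groupIds[[sid]]) else sid
    if (skip) {
      out[[sid]] <- annotation(profile@annotatorId, scanId, sid,
                               geometryKind = gt$kind,
                               status = "image_skipped", groupId = gid)
      next
    }
    u <- stats::runif(2)
    if (u[1] < profile@pOmit) {
      status <- "absent"; comps <- list()
    } else if (u[2] < profile@pWrongKind) {
      status <- "invalid_geometry"; comps <- list()
    } else {
      status <- "present"
      mult <- gt$difficulty *
        (if (is.null(gt$sizeFactor)) 1 else gt$sizeFactor)
      comps <- .perturbGeometry(gt$components, gt$kind,
                                profile@translationSigma * mult,
                                profile@boundaryNoiseSigma * mult,
                                profile@scaleSigma * mult,
                                scene$width, scene$height)
    }
    out[[sid]] <- annotation(profile@annotatorId, scanId, sid,
                             geometryKind = gt$kind, components = comps,
                             status = status, groupId = gid)
  }
  unname(out)
}

#' Study-level simulation settings
#'
#' @param nHumans number of human annotators (default 19, the standard expert
#'   panel size).
#' @param scansPerRegion scans per block region (default 5).
#' @param width,height scan dimensions, px (default 512 x 384,
#'   landscape, ultrasound-like).
#' @param classDifficulty per-class noise multipliers.
#' @param humanProfile template [AnnotatorProfile-class] whose sigmas and
#'   error probabilities every human shares (ids are reassigned).
#' @param aiProfile profile of the AI annotator, or `NULL` for no AI. The
#'   default AI has a larger positional bias but smaller boundary noise and no
#'   skip/wrong-kind errors, reflecting a deterministic system.
#' @param structures structure catalogue (defaults to the standard one).
#' @return A list of class `studyConfig`.
#' @export
studyConfig <- function(nHumans = 19L, scansPerRegion = 5L,
                        width = 512L, height = 384L,
                        classDifficulty = defaultClassDifficulty(),
                        humanProfile = annotatorProfile("human_template"),
                        aiProfile = annotatorProfile(
                          "ai", role = "ai", translationSigma = 3,
                          boundaryNoiseSigma = 1, scaleSigma = 0.03,
                          pOmit = 0.02, pWrongKind = 0, pSkipImage = 0),
                        structures = .defaultStructureTable()) {
  stopifnot(nHumans >= 2L, scansPerRegion >= 1L)
  structure(list(nHumans = as.integer(nHumans),
                 scansPerRegion = as.integer(scansPerRegion),
                 width = as.integer(width), height = as.integer(height),
                 classDifficulty = classDifficulty,
                 humanProfile = humanProfile, aiProfile = aiProfile,
                 structures = structures),
            class = "studyConfig")
}

#' Simulate a complete multi-annotator study
#'
#' Generates a full, loadable study: the manifest, one ground-truth scene per
#' scan, and annotations by every human (sharing the configured profile) and
#' the AI annotator. Fully deterministic from the master seed: scene and
#' annotator seeds are derived per scan and per annotator.
#'
#' @param config a [studyConfig()].
#' @param seed master seed.
#' @return An ungrouped [AnnotationSet-class] (manifest included). The
#'   ground-truth scenes are attached as attribute `"scenes"`.
#' @examples
#' study <- simulateStudy(studyConfig(nHumans = 3, scansPerRegion = 1), seed = 1)
#' length(annotations(study))
#' @export
simulateStudy <- function(config = studyConfig(), seed = 1L) {
  stopifnot(inherits(config, "studyConfig"))
  m <- defaultManifest(nHumans = config$nHumans,
                       scansPerRegion = config$scansPerRegion,
                       width = config$width, height = config$height,
                       ai = !is.null(config$aiProfile))
  m@structures <- studyManifest(m@annotators, m@scans,
                                config$structures)@structures
  validObject(m)
  gmap <- stats::setNames(m@structures$group_id, m@structures$structure_id)
  humans <- m@annotators$annotator_id[m@annotators$role == "human"]
  profiles <- lapply(seq_along(humans), function(i) {
    p <- config$humanProfile
    p@annotatorId <- humans[i]
    p
  })
  if (!is.null(config$aiProfile)) {
    ai <- config$aiProfile
    ai@annotatorId <- m@annotators$annotator_id[m@annotators$role == "ai"]
    profiles <- c(profiles, ai)
  }
  templates <- lapply(stats::setNames(.REGIONS, .REGIONS), sceneTemplate,
                      structures = config$structures,
                      classDifficulty = config$classDifficulty)
  anns <- list()
  scenes <- list()
  for (si in seq_len(nrow(m@scans))) {
    scanId <- m@scans$scan_id[si]
    scene <- generateScene(templates[[m@scans$region[si]]],
                           config$width, config$height,
                           seed = .deriveSeed(seed, si, 0L))
    scenes[[scanId]] <- scene
    for (ai in seq_along(profiles)) {
      anns <- c(anns, simulateAnnotator(scene, profiles[[ai]], scanId,
                                        seed = .deriveSeed(seed, si, ai),
                                        groupIds = gmap))
    }
  }
  out <- annotationSet(anns, m, grouped = FALSE)
  attr(out, "scenes") <- scenes
  out
}

#' Deterministic replica study with a known error ledger
#'
#' A synthetic 19-expert study whose error events are placed deterministically
#' rather than drawn: one annotator skips one interscalene scan and one
#' erector spinae plane scan entirely, and 26 wrong-geometry-kind annotations
#' are spread (seeded, uniformly) over distinct ungrouped structures,
#' annotators and scans. Under the standard catalogue this fixes the
#' annotation accounting at 1900 potential ungrouped annotations, 1710 after
#' grouping (19 x 90), 31 removed (5 whole-image skips + 26 wrong-kind), and
#' 1679 analysed — useful as an end-to-end audit fixture.
#'
#' @param seed master seed (drives geometry and the wrong-kind placement).
#' @param nWrongKind number of wrong-kind annotations to place.
#' @return An ungrouped [AnnotationSet-class].
#' @export
replicaStudy <- function(seed = 1L, nWrongKind = 26L) {
  base <- annotatorProfile("human_template", pOmit = 0, pWrongKind = 0,
                           pSkipImage = 0)
  aiP <- annotatorProfile("ai", role = "ai", translationSigma = 3,
                          boundaryNoiseSigma = 1, scaleSigma = 0.03,
                          pOmit = 0, pWrongKind = 0, pSkipImage = 0)
  cfg <- studyConfig(humanProfile = base, aiProfile = aiP)
  study <- simulateStudy(cfg, seed = seed)
  m <- study@manifest
  st <- m@structures

  skipper <- "expert01"
  skipScans <- c("ISB_01", "ESPB_01")

  ## eligible cells for wrong-kind events: singleton quantitative groups,
  ## human annotators, not on the skipped scans of the skipping annotator
  singletons <- st$structure_id[st$quantitative &
                                  st$group_id == st$structure_id]
  humans <- m@annotators$annotator_id[m@annotators$role == "human"]
  cells <- expand.grid(annotator = humans, scan = m@scans$scan_id,
                       stringsAsFactors = FALSE)
  cells <- merge(cells, m@scans[, c("scan_id", "region")],
                 by.x = "scan", by.y = "scan_id")
  cells <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sids <- intersect(singletons,
                      st$structure_id[st$region == cells$region[i]])
    if (!length(sids)) return(NULL)
    data.frame(annotator = cells$annotator[i], scan = cells$scan[i],
               structure = sids, stringsAsFactors = FALSE)
  }))
  cells <- cells[!(cells$annotator == skipper & cells$scan %in% skipScans), ]
  set.seed(.deriveSeed(seed, 999L, 1L))
  chosen <- cells[sample.int(nrow(cells), nWrongKind), ]

  key <- vapply(study@annotations, function(a)
    paste(a@annotatorId, a@scanId, a@structureId, sep = "\r"), character(1))
  anns <- study@annotations
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    if (a@annotatorId == skipper && a@scanId %in% skipScans) {
      anns[[i]] <- annotation(a@annotatorId, a@scanId, a@structureId,
                              geometryKind = a@geometryKind,
                              status = "image_skipped", groupId = a@groupId)
    }
  }
  hit <- match(paste(chosen$annotator, chosen$scan, chosen$structure,
                     sep = "\r"), key)
  for (i in hit) {
    a <- anns[[i]]
    anns[[i]] <- annotation(a@annotatorId, a@scanId, a@structureId,
                            geometryKind = a@geometryKind,
                            status = "invalid_geometry", groupId = a@groupId)
  }
  annotationSet(anns, m, grouped = FALSE)
}

#' Expected Dice of a jittered disk annotation (semi-analytic)
#'
#' The expected Dice overlap between a disk of radius `r` and a copy whose
#' centre is displaced by a 2-D Gaussian jitter with per-axis sd `sigma`: the
#' centre distance is then Rayleigh(`sigma`)-distributed, and the expectation
#' is the closed-form lens Dice [analyticDiceDisks()] integrated numerically
#' against that density. Serves as the independent oracle for the simulated
#' translation-jitter experiment.
#'
#' @param r disk radius, px.
#' @param sigma per-axis translation jitter sd, px.
#' @return Expected Dice in \[0, 1\].
#' @export
expectedDiceTranslationJitter <- function(r, sigma) {
  if (sigma == 0) return(1)
  f <- function(d) analyticDiceDisks(r, r, d) *
    d / sigma^2 * exp(-d^2 / (2 * sigma^2))
  stats::integrate(f, 0, 2 * r, rel.tol = 1e-8)$value
}
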