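#' @import methods
NULL

## Controlled vocabularies used across the study data model. Six 'Plan A'
## peripheral nerve block regions; four structure classes; two annotation
## geometry kinds; four annotation statuses.
.REGIONS  <- c("ISB", "AxB", "ESPB", "RSB", "ACB", "SNB")
.CLASSES  <- c("artery", "muscle", "nerve", "fascia_serosa")
.KINDS    <- c("region", "line")
.STATUSES <- c("present", "absent", "invalid_geometry", "image_skipped")

#' Block regions, structure classes, geometry kinds and statuses
#'
#' Controlled vocabularies of the study data model. `blockRegions()` returns
#' the six supported nerve-block regions (interscalene, axillary, erector
#' spinae plane, rectus sheath, adductor canal, popliteal sciatic);
#' `structureClasses()` the four structure classes; `geometryKinds()` the two
#' annotation geometry kinds; `annotationStatuses()` the four per-annotation
#' status flags.
#'
#' @return A character vector.
#' @export
blockRegions <- function() .REGIONS

#' @rdname blockRegions
#' @export
structureClasses <- function() .CLASSES

#' @rdname blockRegions
#' @export
geometryKinds <- function() .KINDS

#' @rdname blockRegions
#' @export
annotationStatuses <- function() .STATUSES

## The geometry kind implied by a structure class: enclosed regions for
## arteries/muscles/nerves, single lines for fascial/serosal planes.
.kindForClass <- function(cls) ifelse(cls == "fascia_serosa", "line", "region")

#' StudyManifest: annotators, scans, structures and grouping of one study
#'
#' The manifest describes a multi-annotator annotation study: the annotator
#' panel (human experts plus at most one AI annotator), the scans (with pixel
#' dimensions, required because coordinates are validated against them), the
#' anatomical structure list with class/geometry kind/region, and the grouping
#' table mapping structures analysed together (for example the C5 and C6 nerve
#' roots, or the anterior and posterior layers of the rectus sheath) onto a
#' single `group_id`.
#'
#' @slot annotators data.frame with columns `annotator_id`, `role`
#'   (`"human"` or `"ai"`).
#' @slot scans data.frame with columns `scan_id`, `region`, `width`, `height`
#'   (pixels).
#' @slot structures data.frame with columns `structure_id`, `display_name`,
#'   `region`, `structure_class`, `geometry_kind`, `group_id`, `quantitative`
#'   (logical; structures assessed only qualitatively are flagged FALSE and
#'   excluded from pairwise scoring and the audit).
#'
#' @seealso [loadManifest()], [defaultManifest()], [groupTable()]
#' @export
setClass("StudyManifest",
  representation(
    annotators = "data.frame",
    scans      = "data.frame",
    structures = "data.frame"
  )
)

.validStudyManifest <- function(object) {
  bad <- character()
  an <- object@annotators; sc <- object@scans; st <- object@structures
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      bad <<- c(bad, sprintf("%s: missing column(s) %s", what,
                             paste(miss, collapse = ", ")))
    length(miss) == 0L
  }
  if (need(an, c("annotator_id", "role"), "annotators")) {
    if (anyDuplicated(an$annotator_id))
      bad <- c(bad, "annotators: duplicated annotator_id")
    if (!all(an$role %in% c("human", "ai")))
      bad <- c(bad, "annotators: role must be 'human' or 'ai'")
    if (sum(an$role == "ai") > 1L)
      bad <- c(bad, "annotators: more than one AI annotator")
    if (sum(an$role == "human") < 2L)
      bad <- c(bad, "annotators: at least 2 human annotators required for human-human comparison")
  }
  if (need(sc, c("scan_id", "region", "width", "height"), "scans")) {
    if (anyDuplicated(sc$scan_id)) bad <- c(bad, "scans: duplicated scan_id")
    if (!all(sc$region %in% .REGIONS))
      bad <- c(bad, sprintf("scans: unknown region(s) %s",
                            paste(unique(setdiff(sc$region, .REGIONS)), collapse = ", ")))
    if (!all(sc$width > 0 & sc$height > 0))
      bad <- c(bad, "scans: width and height must be positive")
  }
  if (need(st, c("structure_id", "display_name", "region", "structure_class",
                 "geometry_kind", "group_id", "quantitative"), "structures")) {
    if (anyDuplicated(st$structure_id))
      bad <- c(bad, "structures: duplicated structure_id")
    if (!all(st$structure_class %in% .CLASSES))
      bad <- c(bad, "structures: unknown structure_class")
    if (!all(st$geometry_kind %in% .KINDS))
      bad <- c(bad, "structures: unknown geometry_kind")
    wrong <- st$geometry_kind != .kindForClass(st$structure_class)
    if (any(wrong))
      bad <- c(bad, sprintf(
        "structures: geometry_kind inconsistent with structure_class for %s (region kind for artery/muscle/nerve, line kind for fascia_serosa)",
        paste(st$structure_id[wrong], collapse = ", ")))
    if (!all(st$region %in% .REGIONS))
      bad <- c(bad, "structures: unknown region")
    ## grouped members must share region and geometry kind
    for (g in unique(st$group_id)) {
      m <- st[st$group_id == g, ]
      if (length(unique(m$geometry_kind)) > 1L)
        bad <- c(bad, sprintf("structures: group '%s' mixes geometry kinds", g))
      if (length(unique(m$region)) > 1L)
        bad <- c(bad, sprintf("structures: group '%s' spans regions", g))
    }
    if (nrow(sc) && length(setdiff(sc$region, st$region)) == 0L) {
      empty <- setdiff(unique(st$region), unique(sc$region))
      if (length(empty))
        bad <- c(bad, sprintf("regions without scans: %s", paste(empty, collapse = ", ")))
    }
  }
  if (length(bad)) bad else TRUE
}

setValidity("StudyManifest", .validStudyManifest)

#' Annotation: one annotator's geometry for one structure on one scan
#'
#' Components hold the drawn geometry in pixel coordinates (origin at the
#' top-left corner, x rightward, y downward): each component is a two-column
#' matrix of vertices, a closed polygon (implicitly closed, last vertex joins
#' the first) for region-kind structures or an open polyline for line-kind
#' structures. The status flag distinguishes a drawn annotation (`present`)
#' from a structure deemed not visible (`absent`), an annotation drawn with the
#' wrong geometry kind (`invalid_geometry`, geometry discarded), and a scan the
#' annotator skipped entirely (`image_skipped`).
#'
#' @slot annotatorId,scanId,structureId,groupId character keys.
#' @slot geometryKind `"region"` or `"line"`.
#' @slot status one of `annotationStatuses()`.
#' @slot components list of numeric matrices with columns x, y; empty unless
#'   status is `present`.
#' @export
setClass("Annotation",
  representation(
    annotatorId  = "character",
    scanId       = "character",
    structureId  = "character",
    groupId      = "character",
    geometryKind = "character",
    status       = "character",
    components   = "list"
  )
)

.validAnnotation <- function(object) {
  bad <- character()
  if (!object@status %in% .STATUSES)
    bad <- c(bad, sprintf("unknown status '%s'", object@status))
  if (!object@geometryKind %in% .KINDS)
    bad <- c(bad, sprintf("unknown geometry kind '%s'", object@geometryKind))
  if (object@status == "present") {
    if (!length(object@components))
      bad <- c(bad, "status 'present' requires non-empty components")
    minv <- if (object@geometryKind == "region") 3L else 2L
    for (comp in object@components) {
      if (!is.matrix(comp) || ncol(comp) != 2L || !is.numeric(comp))
        bad <- c(bad, "each component must be a numeric matrix with 2 columns")
      else if (nrow(comp) < minv)
        bad <- c(bad, sprintf("component with %d vertices; %s kind needs >= %d",
                              nrow(comp), object@geometryKind, minv))
    }
  } else if (length(object@components)) {
    bad <- c(bad, sprintf("status '%s' requires empty components", object@status))
  }
  if (length(bad)) bad else TRUE
}

setValidity("Annotation", .validAnnotation)

#' AnnotationSet: a collection of annotations bound to a manifest
#'
#' @slot annotations list of [Annotation-class] objects.
#' @slot manifest the [StudyManifest-class] the annotations belong to.
#' @slot grouped logical flag; TRUE once [applyGrouping()] has merged member
#'   structures into their analysis groups.
#' @slot curated logical flag; TRUE once [curate()] has applied the
#'   inclusion/exclusion rules (curation is then a no-op, making it
#'   idempotent).
#' @export
setClass("AnnotationSet",
  representation(
    annotations = "list",
    manifest    = "StudyManifest",
    grouped     = "logical",
    curated     = "logical"
  ),
  prototype(grouped = FALSE, curated = FALSE)
)

.validAnnotationSet <- function(object) {
  ok <- vapply(object@annotations, is, logical(1), class2 = "Annotation")
  if (!all(ok)) return("annotations must all be Annotation objects")
  TRUE
}
setValidity("AnnotationSet", .validAnnotationSet)

#' RasterMask: a binary pixel mask at scan resolution
#'
#' @slot grid logical matrix, `height` rows by `width` columns; `grid[i, j]`
#'   covers the pixel whose centre is at (j - 0.5, i - 0.5).
#' @slot scanId scan key (may be `NA` for free-standing masks).
#' @export
setClass("RasterMask",
  representation(grid = "matrix", scanId = "character"))

#' PointChain: a resampled polyline as an ordered point set
#'
#' @slot points numeric matrix (n x 2) of pixel coordinates.
#' @slot spacing resampling spacing in pixels (`NA` if not resampled).
#' @export
setClass("PointChain",
  representation(points = "matrix", spacing = "numeric"))

#' AuditReport: the annotation-accounting chain of a curated study
#'
#' Tracks annotations from the raw per-structure count, through grouping, to
#' the analysed set: `analysed = groupedPotential - totalRemoved` and
#' `totalRemoved = discardedImageSkips + discardedInvalidGeometry` always hold.
#' Counts cover human annotators only; AI output is never curated away.
#'
#' @slot potentialAnnotations humans x ungrouped quantitative structure
#'   instances.
#' @slot groupedPotential humans x grouped structure instances.
#' @slot discardedImageSkips grouped entries removed because the annotator left
#'   a whole scan unannotated.
#' @slot discardedInvalidGeometry grouped entries removed as wrong-kind
#'   annotations.
#' @slot totalRemoved,analysed derived totals.
#' @export
setClass("AuditReport",
  representation(
    potentialAnnotations     = "integer",
    groupedPotential         = "integer",
    discardedImageSkips      = "integer",
    discardedInvalidGeometry = "integer",
    totalRemoved             = "integer",
    analysed                 = "integer"
  )
)

.validAuditReport <- function(object) {
  bad <- character()
  if (object@totalRemoved != object@discardedImageSkips + object@discardedInvalidGeometry)
    bad <- c(bad, "totalRemoved != discardedImageSkips + discardedInvalidGeometry")
  if (object@analysed != object@groupedPotential - object@totalRemoved)
    bad <- c(bad, "analysed != groupedPotential - totalRemoved")
  if (length(bad)) bad else TRUE
}
setValidity("AuditReport", .validAuditReport)

#' VoteMap: per-pixel count of annotators covering each pixel
#'
#' @slot counts integer matrix (height x width); every cell between 0 and
#'   `nAnnotators`.
#' @slot nAnnotators number of annotators that contributed.
#' @slot scanId,groupId keys identifying the scan and structure group.
#' @export
setClass("VoteMap",
  representation(counts = "matrix", nAnnotators = "integer",
                 scanId = "character", groupId = "character"))

.validVoteMap <- function(object) {
  if (any(object@counts < 0L) || any(object@counts > object@nAnnotators))
    return("counts must lie in [0, nAnnotators]")
  TRUE
}
setValidity("VoteMap", .validVoteMap)

#' AnnotatorProfile: simulation parameters for one synthetic annotator
#'
#' Governs how a simulated annotator departs from the ground truth: Gaussian
#' jitter of the structure position (`translationSigma`, px), smooth correlated
#' boundary noise (`boundaryNoiseSigma`, px; radial for region outlines,
#' perpendicular for lines), log-normal area scale jitter (`scaleSigma`,
#' dimensionless sd of log area), and the three error processes observed in
#' expert panels: omitting a visible structure (`pOmit`), annotating with the
#' wrong geometry kind (`pWrongKind`), and skipping a whole scan
#' (`pSkipImage`).
#'
#' @slot annotatorId key.
#' @slot role `"human"` or `"ai"`.
#' @slot translationSigma,boundaryNoiseSigma,scaleSigma non-negative numerics.
#' @slot pOmit,pWrongKind,pSkipImage probabilities in \[0, 1\].
#' @seealso [annotatorProfile()], [simulateAnnotator()]
#' @export
setClass("AnnotatorProfile",
  representation(
    annotatorId        = "character",
    role               = "character",
    translationSigma   = "numeric",
    boundaryNoiseSigma = "numeric",
    scaleSigma         = "numeric",
    pOmit              = "numeric",
    pWrongKind         = "numeric",
    pSkipImage         = "numeric"
  )
)

.validAnnotatorProfile <- function(object) {
  bad <- character()
  if (!object@role %in% c("human", "ai")) bad <- c(bad, "role must be 'human' or 'ai'")
  for (s in c("translationSigma", "boundaryNoiseSigma", "scaleSigma"))
    if (slot(object, s) < 0) bad <- c(bad, paste(s, "must be >= 0"))
  for (p in c("pOmit", "pWrongKind", "pSkipImage")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) bad <- c(bad, paste(p, "must be in [0, 1]"))
  }
  if (length(bad)) bad else TRUE
}
setValidity("AnnotatorProfile", .validAnnotatorProfile)
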