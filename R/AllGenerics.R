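#' @include AllClasses.R
NULL

#' Accessors for study objects
#'
#' `annotators()`, `scans()` and `structures()` return the corresponding
#' manifest tables; `groupTable()` the structure_id -> group_id mapping;
#' `annotations()` the list of [Annotation-class] objects in an
#' [AnnotationSet-class]; `manifest()` the bound [StudyManifest-class];
#' `maskGrid()` the logical pixel grid of a [RasterMask-class];
#' `voteCounts()` the integer count matrix of a [VoteMap-class];
#' `chainPoints()` the point matrix of a [PointChain-class].
#'
#' @param x the object.
#' @return A data.frame, list or matrix as described.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("annotators", function(x) standardGeneric("annotators"))
#' @rdname accessors
#' @export
setGeneric("scans", function(x) standardGeneric("scans"))
#' @rdname accessors
#' @export
setGeneric("structures", function(x) standardGeneric("structures"))
#' @rdname accessors
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))
#' @rdname accessors
#' @export
setGeneric("voteCounts", function(x) standardGeneric("voteCounts"))
#' @rdname accessors
#' @export
setGeneric("chainPoints", function(x) standardGeneric("chainPoints"))

#' @rdname accessors
setMethod("annotators", "StudyManifest", function(x) x@annotators)
#' @rdname accessors
setMethod("scans", "StudyManifest", function(x) x@scans)
#' @rdname accessors
setMethod("structures", "StudyManifest", function(x) x@structures)
#' @rdname accessors
setMethod("groupTable", "StudyManifest", function(x) {
  st <- x@structures
  data.frame(structure_id = st$structure_id, group_id = st$group_id,
             stringsAsFactors = FALSE)
})
#' @rdname accessors
setMethod("annotations", "AnnotationSet", function(x) x@annotations)
#' @rdname accessors
setMethod("manifest", "AnnotationSet", function(x) x@manifest)
#' @rdname accessors
setMethod("maskGrid", "RasterMask", function(x) x@grid)
#' @rdname accessors
setMethod("voteCounts", "VoteMap", function(x) x@counts)
#' @rdname accessors
setMethod("chainPoints", "PointChain", function(x) x@points)

setMethod("show", "StudyManifest", function(object) {
  st <- object@structures
  cat("StudyManifest\n")
  cat(sprintf("  annotators: %d (%d human, %d ai)\n",
              nrow(object@annotators),
              sum(object@annotators$role == "human"),
              sum(object@annotators$role == "ai")))
  cat(sprintf("  scans: %d across %d region(s)\n",
              nrow(object@scans), length(unique(object@scans$region))))
  cat(sprintf("  structures: %d (%d quantitative), %d analysis group(s)\n",
              nrow(st), sum(st$quantitative),
              length(unique(st$group_id[st$quantitative]))))
})

setMethod("show", "AnnotationSet", function(object) {
  stat <- table(factor(vapply(object@annotations, function(a) a@status,
                              character(1)), levels = .STATUSES))
  cat(sprintf("AnnotationSet of %d annotations (%s)\n",
              length(object@annotations),
              if (object@grouped) "grouped" else "ungrouped"))
  cat("  status:", paste(sprintf("%s=%d", names(stat), stat), collapse = ", "), "\n")
})

setMethod("show", "RasterMask", function(object) {
  cat(sprintf("RasterMask %dx%d, %d set pixel(s)\n",
              ncol(object@grid), nrow(object@grid), sum(object@grid)))
})

setMethod("show", "PointChain", function(object) {
  cat(sprintf("PointChain of %d points (spacing %s px)\n",
              nrow(object@points), format(object@spacing)))
})

setMethod("show", "AuditReport", function(object) {
  cat(format(object), sep = "\n")
})

setMethod("show", "VoteMap", function(object) {
  cat(sprintf("VoteMap %dx%d for scan %s, group %s; %d annotators, max vote %d\n",
              ncol(object@counts), nrow(object@counts), object@scanId,
              object@groupId, object@nAnnotators, max(object@counts)))
})

setMethod("show", "AnnotatorProfile", function(object) {
  cat(sprintf(
    "AnnotatorProfile %s (%s): translation %.2f px, boundary %.2f px, scale %.3f, p(omit)=%.3f, p(wrong kind)=%.3f, p(skip image)=%.3f\n",
    object@annotatorId, object@role, object@translationSigma,
    object@boundaryNoiseSigma, object@scaleSigma, object@pOmit,
    object@pWrongKind, object@pSkipImage))
})
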