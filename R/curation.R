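#' @include annotations.R
NULL

## Status of a merged group: present dominates; a group whose members were all
## image_skipped is image_skipped; invalid_geometry dominates absent (a
## wrong-kind drawing was made, so the group was not "deemed not visible").
.mergeStatus <- function(statuses) {
  if (any(statuses == "present")) "present"
  else if (all(statuses == "image_skipped")) "image_skipped"
  else if (any(statuses == "invalid_geometry")) "invalid_geometry"
  else "absent"
}

#' Merge member structures into their analysis groups
#'
#' Structures analysed together (for example the C5 and C6 nerve roots, or the
#' anterior and posterior rectus sheath layers) are merged per (annotator,
#' scan, group): the components of present members are concatenated (region
#' groups are later rasterized as the union mask, line groups pooled as one
#' point set), and the group status follows the dominance rule present >
#' (all-skipped) image_skipped > invalid_geometry > absent. Member structures
#' missing from the collection are treated as absent.
#'
#' @param set an ungrouped [AnnotationSet-class].
#' @return A grouped [AnnotationSet-class] with one annotation per (annotator,
#'   scan, group) occurring in the input.
#' @export
applyGrouping <- function(set) {
  stopifnot(is(set, "AnnotationSet"))
  if (set@grouped) return(set)
  m <- set@manifest
  st <- m@structures
  key <- vapply(set@annotations, function(a)
    paste(a@annotatorId, a@scanId, a@groupId, sep = "\r"), character(1))
  merged <- lapply(split(seq_along(key), key), function(idx) {
    members <- set@annotations[idx]
    kinds <- unique(vapply(members, function(a) a@geometryKind, character(1)))
    if (length(kinds) > 1L)
      stop("group '", members[[1L]]@groupId, "' mixes geometry kinds")
    status <- .mergeStatus(vapply(members, function(a) a@status, character(1)))
    comps <- if (status == "present")
      do.call(c, lapply(members, function(a) a@components))
    else list()
    g <- members[[1L]]@groupId
    annotation(members[[1L]]@annotatorId, members[[1L]]@scanId,
               structureId = g, geometryKind = kinds, components = comps,
               status = status, groupId = g)
  })
  names(merged) <- NULL
  annotationSet(merged, m, grouped = TRUE)
}

#' Construct an audit report
#'
#' @param potential,groupedPotential,imageSkips,invalidGeometry counts.
#' @return An [AuditReport-class].
#' @export
auditReport <- function(potential, groupedPotential, imageSkips,
                        invalidGeometry) {
  new("AuditReport",
      potentialAnnotations = as.integer(potential),
      groupedPotential = as.integer(groupedPotential),
      discardedImageSkips = as.integer(imageSkips),
      discardedInvalidGeometry = as.integer(invalidGeometry),
      totalRemoved = as.integer(imageSkips + invalidGeometry),
      analysed = as.integer(groupedPotential - imageSkips - invalidGeometry))
}

#' Apply the inclusion/exclusion rules and produce the accounting audit
#'
#' Implements the study inclusion rules on a grouped annotation collection
#' (grouping is applied first if needed), per human annotator and scan:
#' if every grouped quantitative structure on a scan is unannotated (absent or
#' skipped), the whole scan is assumed to have been omitted in error and all
#' its entries are removed and counted as image skips; wrong-kind
#' (`invalid_geometry`) entries are removed and counted; remaining absent
#' entries are kept as "not visible" annotations. Missing (annotator, scan,
#' group) entries are materialized as absent before the rules run. The AI
#' annotator is exempt: an empty AI output is a genuine "not highlighted"
#' prediction and is kept as absent. Structures flagged non-quantitative in
#' the manifest are dropped without counting.
#'
#' @param set an [AnnotationSet-class] (grouped or ungrouped).
#' @return A list with elements `kept` (the curated, grouped
#'   [AnnotationSet-class]) and `report` (an [AuditReport-class]).
#' @examples
#' study <- simulateStudy(studyConfig(nHumans = 3, scansPerRegion = 1), seed = 1)
#' curate(study)$report
#' @export
curate <- function(set) {
  stopifnot(is(set, "AnnotationSet"))
  if (set@curated) {
    ## already curated: a second pass cannot distinguish removed entries from
    ## never-annotated ones, so curation is defined as a no-op here
    return(list(kept = set,
                report = auditReport(0L, 0L, 0L, 0L)))
  }
  set <- applyGrouping(set)
  m <- set@manifest
  ids <- vapply(set@annotations, function(a) a@annotatorId, character(1))
  known <- ids %in% m@annotators$annotator_id
  if (!all(known))
    stop("annotator(s) not in manifest: ",
         paste(unique(ids[!known]), collapse = ", "))

  st <- m@structures
  quantStructures <- st[st$quantitative, , drop = FALSE]
  groups <- .groupedStructures(m)                 # one row per analysis group
  humans <- m@annotators$annotator_id[m@annotators$role == "human"]
  aiIds  <- m@annotators$annotator_id[m@annotators$role == "ai"]

  ## index existing grouped entries
  key <- vapply(set@annotations, function(a)
    paste(a@annotatorId, a@scanId, a@groupId, sep = "\r"), character(1))
  lookup <- stats::setNames(seq_along(key), key)

  nScansPerRegion <- table(m@scans$region)
  nQuantPerRegion <- table(factor(quantStructures$region, levels = .REGIONS))
  nGroupPerRegion <- table(factor(groups$region, levels = .REGIONS))
  potential <- sum(nQuantPerRegion * nScansPerRegion[names(nQuantPerRegion)]) *
    length(humans)
  groupedPotential <- sum(nGroupPerRegion * nScansPerRegion[names(nGroupPerRegion)]) *
    length(humans)

  kept <- list()
  skips <- 0L; invalid <- 0L
  for (annId in c(humans, aiIds)) {
    isHuman <- annId %in% humans
    for (si in seq_len(nrow(m@scans))) {
      scanId <- m@scans$scan_id[si]
      gids <- groups$group_id[groups$region == m@scans$region[si]]
      if (!length(gids)) next
      entries <- lapply(gids, function(g) {
        i <- lookup[paste(annId, scanId, g, sep = "\r")]
        if (is.na(i))
          annotation(annId, scanId, g,
                     geometryKind = groups$geometry_kind[groups$group_id == g],
                     status = "absent", groupId = g)
        else set@annotations[[i]]
      })
      statuses <- vapply(entries, function(a) a@status, character(1))
      if (isHuman && all(statuses %in% c("absent", "image_skipped"))) {
        skips <- skips + length(entries)        # whole image omitted in error
        next
      }
      if (isHuman) {
        bad <- statuses == "invalid_geometry"
        invalid <- invalid + sum(bad)
        entries <- entries[!bad]
      }
      kept <- c(kept, entries)
    }
  }
  list(kept = annotationSet(kept, m, grouped = TRUE, curated = TRUE),
       report = auditReport(potential, groupedPotential, skips, invalid))
}

#' @describeIn curate format an [AuditReport-class] as a text block.
#' @param x an [AuditReport-class].
#' @param ... unused.
#' @export
format.AuditReport <- function(x, ...) {
  c("Annotation accounting audit",
    sprintf("  potential structure annotations (ungrouped): %d",
            x@potentialAnnotations),
    sprintf("  after grouping:                              %d",
            x@groupedPotential),
    sprintf("  removed as whole-image skips:                %d",
            x@discardedImageSkips),
    sprintf("  removed as wrong-kind annotations:           %d",
            x@discardedInvalidGeometry),
    sprintf("  total removed:                               %d",
            x@totalRemoved),
    sprintf("  collected and analysed:                      %d", x@analysed))
}

setMethod("format", "AuditReport", function(x, ...) format.AuditReport(x, ...))

#' Serialize an audit report to JSON
#'
#' @param report an [AuditReport-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAuditReport <- function(report, path) {
  jsonlite::write_json(list(
    potential_annotations = report@potentialAnnotations,
    grouped_potential = report@groupedPotential,
    discarded_image_skips = report@discardedImageSkips,
    discarded_invalid_geometry = report@discardedInvalidGeometry,
    total_removed = report@totalRemoved,
    analysed = report@analysed), path, auto_unbox = TRUE)
  invisible(path)
}
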