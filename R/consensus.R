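#' @include agreement.R
NULL

#' Pixel-vote consensus map across human annotators
#'
#' For one scan and one region-kind structure group, counts per pixel how many
#' human annotators' rasterized annotations cover it (an annotator who deemed
#' the structure not visible contributes zero everywhere). The sum over cells
#' equals the summed individual mask areas, and the map is invariant to
#' annotator ordering.
#'
#' @param set a curated, grouped [AnnotationSet-class].
#' @param scanId,groupId which scan and structure group to tally.
#' @return A [VoteMap-class].
#' @export
voteMap <- function(set, scanId, groupId) {
  stopifnot(is(set, "AnnotationSet"), set@grouped)
  m <- set@manifest
  sc <- .scanRow(m, scanId)
  groups <- .groupedStructures(m)
  kind <- groups$geometry_kind[match(groupId, groups$group_id)]
  if (is.na(kind)) stop("unknown group_id: ", groupId)
  if (kind != "region")
    stop("vote maps are area-based; group '", groupId, "' is line-kind")
  humans <- m@annotators$annotator_id[m@annotators$role == "human"]
  sel <- Filter(function(a)
    a@scanId == scanId && a@groupId == groupId && a@annotatorId %in% humans,
    set@annotations)
  counts <- matrix(0L, sc$height, sc$width)
  for (a in sel) {
    if (a@status != "present") next
    counts <- counts + rasterize(a@components, sc$width, sc$height, scanId)@grid
  }
  new("VoteMap", counts = counts, nAnnotators = length(sel),
      scanId = scanId, groupId = groupId)
}

#' Render a vote map as a colour-ramped PNG with optional AI overlay
#'
#' Vote counts are mapped onto a perceptually uniform sequential ramp
#' (viridis) over 1..`nAnnotators`; zero-vote pixels show the background. The
#' AI annotator's mask, if given, is blended on top as a semi-transparent
#' white fill. Output is deterministic given the inputs.
#'
#' @param vote a [VoteMap-class].
#' @param aiMask optional [RasterMask-class] (same dimensions).
#' @param path output PNG path.
#' @param background background grey level in \[0, 1\].
#' @param aiAlpha opacity of the AI overlay.
#' @return `path`, invisibly.
#' @export
renderOverlay <- function(vote, aiMask = NULL, path, background = 0.08,
                          aiAlpha = 0.55) {
  stopifnot(is(vote, "VoteMap"))
  counts <- vote@counts
  h <- nrow(counts); w <- ncol(counts)
  if (!is.null(aiMask)) {
    g <- maskGrid(aiMask)
    if (!all(dim(g) == dim(counts)))
      stop("AI mask dimensions do not match the vote map")
  }
  nlev <- max(1L, vote@nAnnotators)
  ramp <- grDevices::col2rgb(grDevices::hcl.colors(nlev, "viridis")) / 255
  img <- array(background, dim = c(h, w, 3L))
  idx <- which(counts > 0L)
  if (length(idx)) {
    lv <- pmin(counts[idx], nlev)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- ramp[ch, lv]
      img[, , ch] <- plane
    }
  }
  if (!is.null(aiMask)) {
    on <- which(maskGrid(aiMask))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[on] <- (1 - aiAlpha) * plane[on] + aiAlpha * 1
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
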