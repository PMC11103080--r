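#' @include AllClasses.R
NULL

## Crossing-number scan of one polygon onto the pixel grid. A pixel with
## centre (j - 0.5, i - 0.5) is inside iff a ray cast in +x crosses an odd
## number of edges (even-odd rule; robust to self-intersecting hand-drawn
## outlines). Edges are treated half-open in y so vertices are not counted
## twice.
.rasterizeOne <- function(poly, width, height) {
  px <- seq_len(width) - 0.5
  py <- seq_len(height) - 0.5
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  nxt <- c(seq_len(n)[-1], 1L)
  x2 <- x1[nxt]; y2 <- y1[nxt]
  cross <- matrix(0L, height, width)
  for (e in seq_len(n)) {
    ya <- y1[e]; yb <- y2[e]
    if (ya == yb) next
    lo <- min(ya, yb); hi <- max(ya, yb)
    rows <- which(py >= lo & py < hi)
    if (!length(rows)) next
    xint <- x1[e] + (py[rows] - ya) / (yb - ya) * (x2[e] - x1[e])
    cross[rows, ] <- cross[rows, ] + outer(xint, px, ">")
  }
  cross %% 2L == 1L
}

#' Rasterize closed polygons to a binary pixel mask
#'
#' A pixel (row i, column j) is set iff its centre (j - 0.5, i - 0.5) lies
#' inside the union of the polygons, each filled under the even-odd rule.
#' Polygons are implicitly closed. An empty component list yields an all-zero
#' mask.
#'
#' @param components a single two-column vertex matrix, or a list of them;
#'   each polygon needs at least 3 vertices.
#' @param width,height mask dimensions in pixels.
#' @param scanId optional scan key recorded on the mask.
#' @return A [RasterMask-class].
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
#' sum(maskGrid(rasterize(sq, 100, 100)))  # 100
#' @export
rasterize <- function(components, width, height, scanId = NA_character_) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("width and height must be positive")
  width <- as.integer(width); height <- as.integer(height)
  if (is.matrix(components)) components <- list(components)
  grid <- matrix(FALSE, height, width)
  for (poly in components) {
    if (!is.matrix(poly) || ncol(poly) != 2L)
      stop("each polygon must be a two-column vertex matrix")
    if (nrow(poly) < 3L) stop("polygons need at least 3 vertices")
    grid <- grid | .rasterizeOne(poly, width, height)
  }
  new("RasterMask", grid = grid, scanId = scanId)
}

#' Dice overlap coefficient of two binary masks
#'
#' Twice the overlap area divided by the sum of the two areas, computed on the
#' pixel grid: 1 = identical annotations, 0 = disjoint. When exactly one mask
#' is empty the score is 0 (one-sided disagreement). When both are empty the
#' metric is undefined and `bothEmpty` is returned (default `NA`; pooled
#' summaries exclude such pairs and count them separately).
#'
#' @param a,b [RasterMask-class] objects (or logical matrices) with identical
#'   dimensions.
#' @param bothEmpty value returned when both masks are empty.
#' @return A score in \[0, 1\] (or `bothEmpty`).
#' @export
dice <- function(a, b, bothEmpty = NA_real_) {
  ga <- if (is(a, "RasterMask")) a@grid else a
  gb <- if (is(b, "RasterMask")) b@grid else b
  if (!all(dim(ga) == dim(gb)))
    stop(sprintf("mask dimension mismatch: %dx%d vs %dx%d",
                 nrow(ga), ncol(ga), nrow(gb), ncol(gb)))
  na <- sum(ga); nb <- sum(gb)
  if (na + nb == 0L) return(bothEmpty)
  2 * sum(ga & gb) / (na + nb)
}

#' Resample a polyline at fixed arc-length spacing
#'
#' Places points along the polyline so that consecutive points are no farther
#' apart than `spacing`, keeping every original vertex (in particular the
#' endpoints). Each segment is subdivided into equal pieces of length at most
#' `spacing`. Multi-part lines (a list of vertex matrices) are resampled per
#' part and the points pooled.
#'
#' @param points a two-column vertex matrix with >= 2 rows, or a list of them.
#' @param spacing maximum gap between consecutive points, pixels (> 0).
#' @return A [PointChain-class].
#' @examples
#' nrow(chainPoints(resampleChain(rbind(c(0, 0), c(10, 0)), 1)))  # 11
#' @export
resampleChain <- function(points, spacing = 0.5) {
  if (spacing <= 0) stop("spacing must be > 0")
  parts <- if (is.matrix(points)) list(points) else points
  out <- lapply(parts, function(p) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 2L)
      stop("each polyline part needs a two-column matrix with >= 2 vertices")
    segs <- lapply(seq_len(nrow(p) - 1L), function(i) {
      a <- p[i, ]; b <- p[i + 1L, ]
      len <- sqrt(sum((b - a)^2))
      if (len == 0) return(NULL)
      k <- ceiling(len / spacing)
      t <- seq_len(k) / k     # excludes t = 0: the previous point covers it
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    })
    rbind(p[1, , drop = FALSE], do.call(rbind, segs))
  })
  pts <- do.call(rbind, out)
  dimnames(pts) <- NULL
  new("PointChain", points = pts, spacing = spacing)
}

.chainMatrix <- function(x) {
  if (is(x, "PointChain")) x@points
  else if (is.matrix(x)) x
  else stop("expected a PointChain or point matrix")
}

#' Directed and normalized Hausdorff distance between polylines
#'
#' `directedHausdorff(a, b)` is the maximum over points of `a` of the minimum
#' Euclidean distance to any point of `b`, on resampled point chains.
#' `hausdorffScore()` normalizes it to \[0, 1\] by an image-size denominator
#' (0 = complete agreement, 1 = lines separated by the maximum length/width of
#' the image): with `symmetrize = TRUE` (default) the raw distance is the
#' maximum of both directed distances (the standard Hausdorff metric); with
#' `FALSE`, only a-to-b is used. The denominator is `max(width, height)` in
#' `"max_side"` mode or the image diagonal in `"diagonal"` mode; the score is
#' clamped at 1.
#'
#' @param a,b [PointChain-class] objects (or point matrices), non-empty.
#' @return `directedHausdorff()`: a distance in pixels; `hausdorffScore()`: a
#'   score in \[0, 1\].
#' @export
directedHausdorff <- function(a, b) {
  pa <- .chainMatrix(a); pb <- .chainMatrix(b)
  if (!nrow(pa) || !nrow(pb)) stop("empty point chain")
  ## chunk rows of a to bound the distance-matrix memory
  chunk <- max(1L, floor(4e6 / nrow(pb)))
  worst <- 0
  for (i0 in seq(1L, nrow(pa), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(pa))
    d2 <- outer(pa[idx, 1], pb[, 1], "-")^2 + outer(pa[idx, 2], pb[, 2], "-")^2
    worst <- max(worst, sqrt(max(apply(d2, 1L, min))))
  }
  worst
}

#' @rdname directedHausdorff
#' @param width,height image dimensions in pixels.
#' @param symmetrize use the symmetric (max of both directions) distance?
#' @param denominator `"max_side"` or `"diagonal"`.
#' @export
hausdorffScore <- function(a, b, width, height, symmetrize = TRUE,
                           denominator = c("max_side", "diagonal")) {
  denominator <- match.arg(denominator)
  raw <- directedHausdorff(a, b)
  if (symmetrize) raw <- max(raw, directedHausdorff(b, a))
  den <- if (denominator == "max_side") max(width, height)
         else sqrt(width^2 + height^2)
  min(1, raw / den)
}

#' Closed-form Dice coefficient of two offset disks
#'
#' The Dice overlap of two disks of radii `rA` and `rB` whose centres are `d`
#' apart, via the circular-lens intersection area. Used as an independent
#' analytic oracle for the rasterized Dice computation and for the expected
#' agreement under translation jitter.
#'
#' @param rA,rB disk radii in pixels (> 0).
#' @param d centre distance in pixels (>= 0).
#' @return A score in \[0, 1\].
#' @export
analyticDiceDisks <- function(rA, rB, d) {
  if (any(rA <= 0) || any(rB <= 0) || any(d < 0))
    stop("radii must be > 0 and distance >= 0")
  lens <- function(r1, r2, d) {
    if (d >= r1 + r2) return(0)
    if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
    a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
    a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
    a3 <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) *
                            (d - r1 + r2) * (d + r1 + r2)))
    a1 + a2 - a3
  }
  inter <- mapply(lens, rA, rB, d)
  2 * inter / (pi * rA^2 + pi * rB^2)
}
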