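#' @include AllClasses.R manifest.R
NULL

#' Create a single annotation
#'
#' @param annotatorId,scanId,structureId character keys.
#' @param geometryKind `"region"` or `"line"`; usually derived from the
#'   manifest via `kindOf`.
#' @param components list of two-column vertex matrices (or a single matrix);
#'   empty unless `status = "present"`.
#' @param status one of `annotationStatuses()`.
#' @param groupId analysis group; defaults to `structureId`.
#' @return An [Annotation-class].
#' @export
annotation <- function(annotatorId, scanId, structureId, geometryKind,
                       components = list(), status = "present",
                       groupId = structureId) {
  if (is.matrix(components)) components <- list(components)
  components <- lapply(components, function(m) {
    m <- as.matrix(m); dimnames(m) <- NULL; storage.mode(m) <- "double"; m
  })
  new("Annotation", annotatorId = annotatorId, scanId = scanId,
      structureId = structureId, groupId = groupId,
      geometryKind = geometryKind, status = status, components = components)
}

#' Bundle annotations with their manifest
#'
#' @param annotations list of [Annotation-class] objects.
#' @param manifest the governing [StudyManifest-class].
#' @param grouped have member structures already been merged into groups?
#' @param curated have the curation rules already been applied?
#' @return An [AnnotationSet-class].
#' @export
annotationSet <- function(annotations, manifest, grouped = FALSE,
                          curated = FALSE) {
  new("AnnotationSet", annotations = annotations, manifest = manifest,
      grouped = grouped, curated = curated)
}

## Manifest lookups ---------------------------------------------------------

.scanRow <- function(manifest, scanId) {
  i <- match(scanId, manifest@scans$scan_id)
  if (is.na(i)) stop("unknown scan_id: ", scanId)
  manifest@scans[i, ]
}

.structureRow <- function(manifest, structureId) {
  i <- match(structureId, manifest@structures$structure_id)
  if (is.na(i)) stop("unknown structure_id: ", structureId)
  manifest@structures[i, ]
}

.checkBounds <- function(ann, manifest) {
  sc <- .scanRow(manifest, ann@scanId)
  for (comp in ann@components) {
    if (any(comp[, 1] < 0 | comp[, 1] > sc$width |
            comp[, 2] < 0 | comp[, 2] > sc$height))
      stop(sprintf(
        "coordinates outside image bounds [0,%d]x[0,%d] for annotator %s, scan %s, structure %s",
        sc$width, sc$height, ann@annotatorId, ann@scanId, ann@structureId))
  }
  invisible(TRUE)
}

## GeoJSON exchange ---------------------------------------------------------
## One FeatureCollection per (annotator, scan); each Feature carries
## properties {annotator_id, scan_id, structure_id, status} and a Polygon/
## MultiPolygon (region kind), LineString/MultiLineString (line kind) or null
## geometry (absent / invalid_geometry / image_skipped). Pixel coordinates,
## no CRS, written to 0.01 px.

.ringOut <- function(m) {
  m <- round(m, 2)
  m <- rbind(m, m[1, , drop = FALSE])        # GeoJSON rings are closed
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

.lineOut <- function(m) {
  m <- round(m, 2)
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

.featureOut <- function(ann) {
  geom <- NULL
  if (ann@status == "present") {
    if (ann@geometryKind == "region") {
      polys <- lapply(ann@components, function(m) list(.ringOut(m)))
      geom <- if (length(polys) == 1L)
        list(type = "Polygon", coordinates = polys[[1L]])
      else list(type = "MultiPolygon", coordinates = polys)
    } else {
      lines <- lapply(ann@components, .lineOut)
      geom <- if (length(lines) == 1L)
        list(type = "LineString", coordinates = lines[[1L]])
      else list(type = "MultiLineString", coordinates = lines)
    }
  }
  list(type = "Feature", geometry = geom,
       properties = list(annotator_id = ann@annotatorId,
                         scan_id = ann@scanId,
                         structure_id = ann@structureId,
                         status = ann@status))
}

.coordsIn <- function(x) {
  m <- do.call(rbind, lapply(x, function(p) c(p[[1]], p[[2]])))
  storage.mode(m) <- "double"
  m
}

.featureIn <- function(feat, manifest) {
  pr <- feat$properties
  for (k in c("annotator_id", "scan_id", "structure_id", "status"))
    if (is.null(pr[[k]]))
      stop("annotation feature missing property '", k, "'")
  st <- .structureRow(manifest, pr$structure_id)
  kind <- st$geometry_kind
  status <- pr$status
  comps <- list()
  g <- feat$geometry
  if (!is.null(g) && status == "present") {
    gtype <- g$type
    drawnKind <- switch(gtype,
      Polygon = , MultiPolygon = "region",
      LineString = , MultiLineString = "line",
      stop("unsupported geometry type: ", gtype))
    if (drawnKind != kind) {
      ## wrong geometry kind: keep the flag, discard the geometry
      warning(sprintf(
        "wrong-kind annotation (%s drawn for %s-kind structure) by %s on %s/%s; flagged invalid_geometry",
        gtype, kind, pr$annotator_id, pr$scan_id, pr$structure_id))
      status <- "invalid_geometry"
    } else if (kind == "region") {
      rings <- if (gtype == "Polygon") list(g$coordinates)
               else g$coordinates
      comps <- unlist(lapply(rings, function(poly)
        lapply(poly, .coordsIn)), recursive = FALSE)
      comps <- lapply(comps, function(m) {
        if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ]))
          m <- m[-nrow(m), , drop = FALSE]   # drop GeoJSON closing vertex
        m
      })
      short <- vapply(comps, nrow, integer(1)) < 3L
      if (any(short)) {
        warning(sprintf(
          "polygon with < 3 vertices by %s on %s/%s; flagged invalid_geometry",
          pr$annotator_id, pr$scan_id, pr$structure_id))
        status <- "invalid_geometry"
        comps <- list()
      }
    } else {
      lines <- if (gtype == "LineString") list(g$coordinates)
               else g$coordinates
      comps <- lapply(lines, .coordsIn)
      if (any(vapply(comps, nrow, integer(1)) < 2L)) {
        warning(sprintf(
          "polyline with < 2 vertices by %s on %s/%s; flagged invalid_geometry",
          pr$annotator_id, pr$scan_id, pr$structure_id))
        status <- "invalid_geometry"
        comps <- list()
      }
    }
  } else if (status == "present") {
    stop("feature with status 'present' but null geometry for ",
         pr$structure_id)
  }
  ann <- annotation(pr$annotator_id, pr$scan_id, pr$structure_id,
                    geometryKind = kind, components = comps, status = status,
                    groupId = st$group_id)
  .checkBounds(ann, manifest)
  ann
}

#' Read and write annotation collections (GeoJSON exchange format)
#'
#' Annotations travel as one GeoJSON FeatureCollection per (annotator, scan),
#' named `<annotator_id>__<scan_id>.geojson`. Region-kind structures are
#' Polygon/MultiPolygon features, line-kind structures LineString/
#' MultiLineString; structures deemed not visible, drawn with the wrong
#' geometry kind, or on skipped scans carry a null geometry and their status
#' in the properties. Coordinates are pixels (no CRS), written to 0.01 px.
#' On load, a feature whose drawn geometry type contradicts the structure's
#' declared kind — or a polygon with fewer than 3 vertices — is flagged
#' `invalid_geometry` with a warning and its geometry discarded; coordinates
#' outside the scan's pixel bounds are an error naming the offending
#' annotator/scan/structure.
#'
#' @param path a directory of `.geojson` files, or a single file.
#' @param manifest the [StudyManifest-class] to validate against.
#' @return `loadAnnotations()` returns an ungrouped [AnnotationSet-class];
#'   `writeAnnotations()` returns the directory invisibly.
#' @export
loadAnnotations <- function(path, manifest) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.geojson$", full.names = TRUE)
  else path
  if (!length(files)) stop("no .geojson files found under ", path)
  anns <- list()
  for (f in sort(files)) {
    fc <- jsonlite::read_json(f, simplifyVector = FALSE)
    if (!identical(fc$type, "FeatureCollection"))
      stop("not a GeoJSON FeatureCollection: ", f)
    anns <- c(anns, lapply(fc$features, .featureIn, manifest = manifest))
  }
  annotationSet(anns, manifest, grouped = FALSE)
}

#' @rdname loadAnnotations
#' @param set an [AnnotationSet-class].
#' @export
writeAnnotations <- function(set, path) {
  stopifnot(is(set, "AnnotationSet"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  key <- vapply(set@annotations, function(a)
    paste(a@annotatorId, a@scanId, sep = "__"), character(1))
  for (k in sort(unique(key))) {
    group <- set@annotations[key == k]
    ord <- order(vapply(group, function(a) a@structureId, character(1)))
    fc <- list(type = "FeatureCollection",
               features = lapply(group[ord], .featureOut))
    jsonlite::write_json(fc, file.path(path, paste0(k, ".geojson")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = FALSE)
  }
  invisible(path)
}

#' Write or load a complete study (manifest + annotations)
#'
#' A study directory holds `manifest.yaml` and an `annotations/` subdirectory
#' in the GeoJSON exchange format.
#'
#' @param set an [AnnotationSet-class].
#' @param dir study directory.
#' @return `writeStudy()` returns `dir` invisibly; `loadStudy()` an
#'   [AnnotationSet-class].
#' @export
writeStudy <- function(set, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeManifest(set@manifest, file.path(dir, "manifest.yaml"))
  writeAnnotations(set, file.path(dir, "annotations"))
  invisible(dir)
}

#' @rdname writeStudy
#' @export
loadStudy <- function(dir) {
  m <- loadManifest(file.path(dir, "manifest.yaml"))
  loadAnnotations(file.path(dir, "annotations"), m)
}
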