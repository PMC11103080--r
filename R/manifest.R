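#' @include AllClasses.R
NULL

#' Construct a study manifest from its component tables
#'
#' @param annotators data.frame with columns `annotator_id`, `role`.
#' @param scans data.frame with columns `scan_id`, `region`, `width`, `height`.
#' @param structures data.frame with columns `structure_id`, `display_name`,
#'   `region`, `structure_class`, `geometry_kind`, `group_id`, `quantitative`.
#'   `geometry_kind`, `group_id` and `quantitative` may be omitted: the kind is
#'   derived from the class, `group_id` defaults to `structure_id` (ungrouped)
#'   and `quantitative` to `TRUE`.
#' @return A validated [StudyManifest-class].
#' @export
studyManifest <- function(annotators, scans, structures) {
  structures <- as.data.frame(structures, stringsAsFactors = FALSE)
  if (is.null(structures$geometry_kind))
    structures$geometry_kind <- .kindForClass(structures$structure_class)
  if (is.null(structures$group_id))
    structures$group_id <- structures$structure_id
  structures$group_id <- ifelse(is.na(structures$group_id),
                                structures$structure_id, structures$group_id)
  if (is.null(structures$quantitative)) structures$quantitative <- TRUE
  if (is.null(structures$display_name))
    structures$display_name <- structures$structure_id
  obj <- new("StudyManifest",
             annotators = as.data.frame(annotators, stringsAsFactors = FALSE),
             scans      = as.data.frame(scans, stringsAsFactors = FALSE),
             structures = structures)
  obj
}

## Structure catalogue of the default study: 20 quantitative structures over
## the six block regions (grouped to 18 analysis units: C5+C6 nerve roots and
## the two rectus sheath layers each merge), plus the pleura, which is
## assessed qualitatively only.
.defaultStructureTable <- function() {
  rbind(
    data.frame(structure_id = "c5_root",  display_name = "C5 nerve root",
               region = "ISB", structure_class = "nerve", group_id = "c5_c6",
               quantitative = TRUE),
    data.frame(structure_id = "c6_root",  display_name = "C6 nerve root",
               region = "ISB", structure_class = "nerve", group_id = "c5_c6",
               quantitative = TRUE),
    data.frame(structure_id = "scalenus_anterior", display_name = "Scalenus anterior",
               region = "ISB", structure_class = "muscle", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "scalenus_medius", display_name = "Scalenus medius",
               region = "ISB", structure_class = "muscle", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "axillary_artery", display_name = "Axillary artery",
               region = "AxB", structure_class = "artery", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "median_nerve", display_name = "Median nerve",
               region = "AxB", structure_class = "nerve", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "musculocutaneous_nerve",
               display_name = "Musculocutaneous nerve",
               region = "AxB", structure_class = "nerve", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "radial_nerve", display_name = "Radial nerve",
               region = "AxB", structure_class = "nerve", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "ulnar_nerve", display_name = "Ulnar nerve",
               region = "AxB", structure_class = "nerve", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "conjoint_tendon_fascia",
               display_name = "Fascia over conjoint tendon",
               region = "AxB", structure_class = "fascia_serosa", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "erector_spinae_muscle",
               display_name = "Erector spinae muscle group",
               region = "ESPB", structure_class = "muscle", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "transverse_process", display_name = "Transverse process",
               region = "ESPB", structure_class = "fascia_serosa", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "pleura", display_name = "Pleura",
               region = "ESPB", structure_class = "fascia_serosa", group_id = NA,
               quantitative = FALSE),
    data.frame(structure_id = "rectus_abdominis", display_name = "Rectus abdominis",
               region = "RSB", structure_class = "muscle", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "rectus_sheath_anterior",
               display_name = "Rectus sheath (anterior layer)",
               region = "RSB", structure_class = "fascia_serosa",
               group_id = "rectus_sheath", quantitative = TRUE),
    data.frame(structure_id = "rectus_sheath_posterior",
               display_name = "Rectus sheath (posterior layer)",
               region = "RSB", structure_class = "fascia_serosa",
               group_id = "rectus_sheath", quantitative = TRUE),
    data.frame(structure_id = "peritoneum", display_name = "Peritoneum",
               region = "RSB", structure_class = "fascia_serosa", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "femoral_artery", display_name = "Femoral artery",
               region = "ACB", structure_class = "artery", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "saphenous_nerve", display_name = "Saphenous nerve",
               region = "ACB", structure_class = "nerve", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "sartorius", display_name = "Sartorius",
               region = "ACB", structure_class = "muscle", group_id = NA,
               quantitative = TRUE),
    data.frame(structure_id = "sciatic_nerve", display_name = "Sciatic nerve",
               region = "SNB", structure_class = "nerve", group_id = NA,
               quantitative = TRUE)
  )
}

#' The default study manifest
#'
#' A panel of 19 human experts plus one AI annotator, five scans in each of
#' the six block regions (30 scans), and the standard 21-entry structure
#' catalogue: 20 quantitative structures grouped into 18 analysis units
#' (C5+C6 nerve roots and anterior+posterior rectus sheath layers are merged),
#' plus the pleura, which enters the qualitative assessment only.
#'
#' @param nHumans number of human annotators.
#' @param scansPerRegion number of scans per block region.
#' @param width,height scan pixel dimensions (all scans share them here;
#'   manifests loaded from disk may vary per scan).
#' @param ai include the AI annotator?
#' @return A [StudyManifest-class].
#' @examples
#' m <- defaultManifest()
#' nrow(scans(m))       # 30
#' nrow(structures(m))  # 21 (20 quantitative + pleura)
#' @export
defaultManifest <- function(nHumans = 19L, scansPerRegion = 5L,
                            width = 512L, height = 384L, ai = TRUE) {
  ann <- data.frame(
    annotator_id = c(sprintf("expert%02d", seq_len(nHumans)), if (ai) "ai"),
    role = c(rep("human", nHumans), if (ai) "ai"),
    stringsAsFactors = FALSE)
  sc <- do.call(rbind, lapply(.REGIONS, function(r)
    data.frame(scan_id = sprintf("%s_%02d", r, seq_len(scansPerRegion)),
               region = r, width = as.integer(width),
               height = as.integer(height), stringsAsFactors = FALSE)))
  studyManifest(ann, sc, .defaultStructureTable())
}

.manifestKeys <- c("annotators", "scans", "structures", "grouping")

#' Read and write study manifests
#'
#' The on-disk manifest is a YAML (`.yml`/`.yaml`) or JSON (`.json`) document
#' with top-level keys `annotators` (list of `{annotator_id, role}`), `scans`
#' (list of `{scan_id, region, width, height}`), `structures` (list of
#' `{structure_id, display_name, region, structure_class, geometry_kind,
#' quantitative}`) and optional `grouping` (map structure_id -> group_id;
#' ungrouped structures default to their own id). Unknown top-level keys are
#' rejected. Validation is total: either a manifest satisfying every
#' invariant is returned, or an error listing all violations is raised.
#'
#' @param path file path; the extension selects YAML or JSON.
#' @return `loadManifest()` returns a validated [StudyManifest-class];
#'   `writeManifest()` returns `path` invisibly.
#' @export
loadManifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  raw <- tryCatch(.readStructured(path),
                  error = function(e) stop("manifest parse failure in '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  unknown <- setdiff(names(raw), .manifestKeys)
  if (length(unknown))
    stop("manifest format error: unknown key(s) ", paste(unknown, collapse = ", "))
  for (k in c("annotators", "scans", "structures"))
    if (is.null(raw[[k]]))
      stop("manifest format error: missing key '", k, "'")
  toDf <- function(x, what) {
    rows <- lapply(x, function(rec) as.data.frame(rec, stringsAsFactors = FALSE))
    cols <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("manifest format error: empty '", what, "'")
    out
  }
  st <- toDf(raw$structures, "structures")
  if (!is.null(raw$grouping)) {
    gt <- unlist(raw$grouping)
    missing <- setdiff(names(gt), st$structure_id)
    if (length(missing))
      stop("manifest format error: grouping refers to unknown structure_id ",
           paste(missing, collapse = ", "))
    st$group_id <- ifelse(st$structure_id %in% names(gt),
                          gt[st$structure_id], st$structure_id)
  }
  m <- studyManifest(toDf(raw$annotators, "annotators"),
                     toDf(raw$scans, "scans"), st)
  validObject(m)
  m
}

#' @rdname loadManifest
#' @param manifest a [StudyManifest-class].
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "StudyManifest"))
  st <- manifest@structures
  grouped <- st[st$group_id != st$structure_id, , drop = FALSE]
  doc <- list(
    annotators = unname(apply(manifest@annotators, 1, as.list)),
    scans = lapply(seq_len(nrow(manifest@scans)), function(i) {
      r <- manifest@scans[i, ]
      list(scan_id = r$scan_id, region = r$region,
           width = as.integer(r$width), height = as.integer(r$height))
    }),
    structures = lapply(seq_len(nrow(st)), function(i) {
      r <- st[i, ]
      list(structure_id = r$structure_id, display_name = r$display_name,
           region = r$region, structure_class = r$structure_class,
           geometry_kind = r$geometry_kind, quantitative = r$quantitative)
    }))
  if (nrow(grouped))
    doc$grouping <- as.list(stats::setNames(grouped$group_id, grouped$structure_id))
  .writeStructured(doc, path)
  invisible(path)
}

.isYaml <- function(path) grepl("\\.ya?ml$", path, ignore.case = TRUE)

.readStructured <- function(path) {
  if (.isYaml(path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
}

.writeStructured <- function(x, path) {
  if (.isYaml(path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                            digits = NA)
}

## Grouped (quantitative) structure table: one row per analysis group.
.groupedStructures <- function(manifest) {
  st <- manifest@structures
  st <- st[st$quantitative, , drop = FALSE]
  agg <- st[!duplicated(st$group_id), c("group_id", "region",
                                        "structure_class", "geometry_kind")]
  rownames(agg) <- NULL
  agg
}
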