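#' @include agreement.R consensus.R
NULL

#' Run the full agreement pipeline on a study
#'
#' Executes curate -> pairwise scoring -> summaries (by structure and by
#' class, HH and HAI) -> mode comparison, and optionally consensus overlay
#' rendering, writing everything under `outDir`: `audit.json` / `audit.txt`,
#' `pair_scores.csv`, `summary_structure.csv`, `summary_class.csv`,
#' `comparison_structure.csv`, `comparison_class.csv`, consensus PNGs under
#' `consensus/`, and `run_log.txt` capturing the options and package version.
#' Identical inputs and options produce identical outputs.
#'
#' @param study an [AnnotationSet-class], or a study directory for
#'   [loadStudy()].
#' @param outDir output directory (created if needed).
#' @param config a [metricsConfig()].
#' @param modes comparison modes to compute.
#' @param consensus `"none"` to skip overlay rendering, or a character vector
#'   of `"<scan_id>/<group_id>"` picks, or `"all"` for every region-kind
#'   group on every scan.
#' @return Invisibly, a list with `audit`, `scores`, `summaryStructure`,
#'   `summaryClass`, `comparisonStructure`, `comparisonClass`.
#' @export
runPipeline <- function(study, outDir, config = metricsConfig(),
                        modes = c("HH", "HAI"), consensus = "none") {
  if (is.character(study)) study <- loadStudy(study)
  stopifnot(is(study, "AnnotationSet"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  cur <- stage("curate", curate(study))
  writeAuditReport(cur$report, file.path(outDir, "audit.json"))
  writeLines(format(cur$report), file.path(outDir, "audit.txt"))

  scores <- stage("score", pairwiseScores(cur$kept, config, modes = modes))
  utils::write.csv(scores, file.path(outDir, "pair_scores.csv"),
                   row.names = FALSE)

  sumSt <- stage("summarize",
                 summarizeScores(scores, by = "structure", mode = modes,
                                 bothEmpty = config$bothEmpty))
  sumCl <- stage("summarize",
                 summarizeScores(scores, by = "class", mode = modes,
                                 bothEmpty = config$bothEmpty))
  utils::write.csv(sumSt, file.path(outDir, "summary_structure.csv"),
                   row.names = FALSE)
  utils::write.csv(sumCl, file.path(outDir, "summary_class.csv"),
                   row.names = FALSE)

  cmpSt <- cmpCl <- NULL
  if (all(c("HH", "HAI") %in% modes)) {
    cmpSt <- stage("compare", compareModes(
      sumSt[sumSt$mode == "HH", ], sumSt[sumSt$mode == "HAI", ]))
    cmpCl <- stage("compare", compareModes(
      sumCl[sumCl$mode == "HH", ], sumCl[sumCl$mode == "HAI", ]))
    utils::write.csv(cmpSt, file.path(outDir, "comparison_structure.csv"),
                     row.names = FALSE)
    utils::write.csv(cmpCl, file.path(outDir, "comparison_class.csv"),
                     row.names = FALSE)
  }

  if (!identical(consensus, "none")) {
    m <- study@manifest
    aiId <- m@annotators$annotator_id[m@annotators$role == "ai"]
    groups <- .groupedStructures(m)
    picks <- if (identical(consensus, "all")) {
      regionGroups <- groups[groups$geometry_kind == "region", ]
      unlist(lapply(seq_len(nrow(m@scans)), function(si) {
        g <- regionGroups$group_id[regionGroups$region == m@scans$region[si]]
        paste(m@scans$scan_id[si], g, sep = "/")
      }))
    } else consensus
    cdir <- file.path(outDir, "consensus")
    if (!dir.exists(cdir)) dir.create(cdir)
    for (p in picks) {
      parts <- strsplit(p, "/", fixed = TRUE)[[1L]]
      stage("consensus", {
        vm <- voteMap(cur$kept, parts[1L], parts[2L])
        aiMask <- NULL
        if (length(aiId)) {
          aiAnn <- Filter(function(a)
            a@annotatorId == aiId && a@scanId == parts[1L] &&
              a@groupId == parts[2L] && a@status == "present",
            cur$kept@annotations)
          if (length(aiAnn)) {
            sc <- .scanRow(m, parts[1L])
            aiMask <- rasterize(aiAnn[[1L]]@components, sc$width, sc$height)
          }
        }
        renderOverlay(vm, aiMask,
                      file.path(cdir, paste0(parts[1L], "_", parts[2L], ".png")))
      })
    }
  }

  writeLines(c(
    sprintf("sonoAgree %s", as.character(utils::packageVersion("sonoAgree"))),
    sprintf("resampleSpacing: %g", config$resampleSpacing),
    sprintf("symmetrize: %s", config$symmetrize),
    sprintf("denominator: %s", config$denominator),
    sprintf("bothEmpty: %s", config$bothEmpty),
    sprintf("modes: %s", paste(modes, collapse = ",")),
    sprintf("consensus: %s", paste(consensus, collapse = ","))),
    file.path(outDir, "run_log.txt"))

  invisible(list(audit = cur$report, scores = scores,
                 summaryStructure = sumSt, summaryClass = sumCl,
                 comparisonStructure = cmpSt, comparisonClass = cmpCl))
}
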