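#' @include curation.R geometry.R
NULL

#' Metric configuration
#'
#' Collects the tunable metric options with their defaults: Hausdorff
#' resampling spacing 0.5 px (so the point-set distance approximates the curve
#' distance to sub-pixel accuracy however sparsely vertices were placed),
#' symmetric Hausdorff (max of both directed distances, the standard metric;
#' `symmetrize = FALSE` restores the literal one-directional procedure),
#' normalization by the longer image side (`"diagonal"` available), and
#' exclusion of both-empty pairs from score pools (`"perfect"` scores them
#' 1 for Dice / 0 for Hausdorff instead, for sensitivity analysis).
#'
#' @param resampleSpacing pixels between resampled polyline points.
#' @param symmetrize logical.
#' @param denominator `"max_side"` or `"diagonal"`.
#' @param bothEmpty `"exclude"` or `"perfect"`.
#' @return A named list of class `metricsConfig`.
#' @export
metricsConfig <- function(resampleSpacing = 0.5, symmetrize = TRUE,
                          denominator = c("max_side", "diagonal"),
                          bothEmpty = c("exclude", "perfect")) {
  stopifnot(resampleSpacing > 0)
  structure(list(resampleSpacing = resampleSpacing,
                 symmetrize = isTRUE(symmetrize),
                 denominator = match.arg(denominator),
                 bothEmpty = match.arg(bothEmpty)),
            class = "metricsConfig")
}

#' Pairwise agreement scores across the annotator panel
#'
#' For every scan and grouped quantitative structure, compares each retained
#' human annotation with every other (mode `HH`, all unordered pairs) and the
#' AI annotation with every human (mode `HAI`). Region-kind groups are
#' rasterized (grouped members as the union mask) and scored with [dice()];
#' line-kind groups are resampled into pooled point chains and scored with
#' [hausdorffScore()]. A pair in which exactly one annotation is empty scores
#' 0 (Dice) or 1 (Hausdorff score); a pair in which both annotators deemed the
#' structure not visible is flagged `both_empty` with no value and is excluded
#' from pooled summaries.
#'
#' @param kept a curated, grouped [AnnotationSet-class] (the `kept` element of
#'   [curate()]).
#' @param config a [metricsConfig()].
#' @param modes which comparison modes to produce.
#' @return A data.frame with columns `scan_id`, `group_id`, `structure_class`,
#'   `metric`, `mode`, `annotator_a`, `annotator_b`, `value`, `both_empty`.
#' @export
pairwiseScores <- function(kept, config = metricsConfig(),
                           modes = c("HH", "HAI")) {
  stopifnot(is(kept, "AnnotationSet"), kept@grouped)
  modes <- match.arg(modes, several.ok = TRUE)
  m <- kept@manifest
  humans <- m@annotators$annotator_id[m@annotators$role == "human"]
  aiId <- m@annotators$annotator_id[m@annotators$role == "ai"]
  if ("HAI" %in% modes && !length(aiId))
    stop("AI-human comparison requested but the manifest has no AI annotator")
  groups <- .groupedStructures(m)

  anns <- kept@annotations
  scanOf <- vapply(anns, function(a) a@scanId, character(1))
  groupOf <- vapply(anns, function(a) a@groupId, character(1))
  annOf <- vapply(anns, function(a) a@annotatorId, character(1))

  rows <- list()

  for (si in seq_len(nrow(m@scans))) {
    scanId <- m@scans$scan_id[si]
    w <- m@scans$width[si]; h <- m@scans$height[si]
    gs <- groups[groups$region == m@scans$region[si], , drop = FALSE]
    for (gi in seq_len(nrow(gs))) {
      g <- gs$group_id[gi]
      kind <- gs$geometry_kind[gi]
      metric <- if (kind == "region") "dice" else "hausdorff"
      sel <- which(scanOf == scanId & groupOf == g)
      if (!length(sel)) next
      byAnn <- stats::setNames(anns[sel], annOf[sel])
      retainedHumans <- intersect(humans, names(byAnn))
      ## geometry realized once per annotator
      geom <- lapply(byAnn, function(a) {
        if (a@status != "present") return(NULL)
        if (kind == "region") rasterize(a@components, w, h, scanId)
        else resampleChain(a@components, config$resampleSpacing)
      })
      score <- function(ga, gb) {
        if (is.null(ga) && is.null(gb)) return(NA_real_)       # both empty
        if (is.null(ga) || is.null(gb))
          return(if (metric == "dice") 0 else 1)               # one-sided
        if (metric == "dice") dice(ga, gb)
        else hausdorffScore(ga, gb, w, h, symmetrize = config$symmetrize,
                            denominator = config$denominator)
      }
      pa <- character(); pb <- character(); pm <- character()
      if ("HH" %in% modes && length(retainedHumans) >= 2L) {
        cmb <- utils::combn(retainedHumans, 2L)
        pa <- c(pa, cmb[1L, ]); pb <- c(pb, cmb[2L, ])
        pm <- c(pm, rep("HH", ncol(cmb)))
      }
      if ("HAI" %in% modes && aiId %in% names(byAnn) &&
          length(retainedHumans)) {
        pa <- c(pa, rep(aiId, length(retainedHumans)))
        pb <- c(pb, retainedHumans)
        pm <- c(pm, rep("HAI", length(retainedHumans)))
      }
      if (!length(pa)) next
      v <- mapply(function(a, b) score(geom[[a]], geom[[b]]), pa, pb)
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = scanId, group_id = g,
        structure_class = gs$structure_class[gi],
        metric = metric, mode = pm, annotator_a = pa, annotator_b = pb,
        value = unname(v), both_empty = is.na(v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.poolStats <- function(v, scope, scopeKind, mode, metric, nBothEmpty,
                       bothEmpty = "exclude") {
  if (bothEmpty == "perfect") {
    fill <- if (metric == "dice") 1 else 0
    v <- c(v, rep(fill, nBothEmpty))
    nBothEmpty <- 0L
  }
  n <- length(v)
  data.frame(
    scope = scope, scope_kind = scopeKind, mode = mode, metric = metric,
    n_pairs = n, n_both_empty = nBothEmpty,
    min = if (n) min(v) else NA_real_,
    mean = if (n) mean(v) else NA_real_,
    median = if (n) stats::median(v) else NA_real_,
    max = if (n) max(v) else NA_real_,
    sd = if (n > 1L) stats::sd(v) else NA_real_,   # sample sd; undefined for n <= 1
    stringsAsFactors = FALSE)
}

#' Pool pairwise scores into summary rows
#'
#' Pools raw pairwise values over all scans of a structure group (`by =
#' "structure"`) or over all structures of a class (`by = "class"`) and
#' reports min, mean, median, max and the sample standard deviation with the
#' contributing pair count. Both-empty pairs are excluded from pooling (or
#' scored as perfect agreement under `bothEmpty = "perfect"`) and reported in
#' `n_both_empty`. A scope with no poolable scores yields a row with
#' `n_pairs = 0` and `NA` statistics rather than being dropped; `sd` is `NA`
#' for a single-score pool.
#'
#' @param scores output of [pairwiseScores()].
#' @param by `"structure"` or `"class"`.
#' @param mode `"HH"`, `"HAI"` or both (rows per mode).
#' @param bothEmpty `"exclude"` or `"perfect"`.
#' @return A data.frame with columns `scope`, `scope_kind`, `mode`, `metric`,
#'   `n_pairs`, `n_both_empty`, `min`, `mean`, `median`, `max`, `sd`.
#' @export
summarizeScores <- function(scores, by = c("structure", "class"),
                            mode = c("HH", "HAI"),
                            bothEmpty = c("exclude", "perfect")) {
  by <- match.arg(by)
  mode <- match.arg(mode, several.ok = TRUE)
  bothEmpty <- match.arg(bothEmpty)
  scopeCol <- if (by == "structure") "group_id" else "structure_class"
  out <- list()
  for (md in mode) {
    sub <- scores[scores$mode == md, , drop = FALSE]
    for (sc in unique(sub[[scopeCol]])) {
      rows <- sub[sub[[scopeCol]] == sc, , drop = FALSE]
      metric <- unique(rows$metric)
      if (length(metric) > 1L)
        stop("scope '", sc, "' mixes metrics; summarize by structure instead")
      v <- rows$value[!rows$both_empty]
      out[[length(out) + 1L]] <-
        .poolStats(v, sc, by, md, metric, sum(rows$both_empty), bothEmpty)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare human-human with AI-human summaries
#'
#' Per scope, reports which comparison mode has the superior mean (higher for
#' Dice, lower for the Hausdorff score; ties are `"equal"`) and which has the
#' smaller standard deviation (less variation).
#'
#' @param rowsHH,rowsHAI [summarizeScores()] outputs for modes HH and HAI over
#'   the same scopes.
#' @return A data.frame with columns `scope`, `metric`, `mean_hh`, `mean_hai`,
#'   `superior_mean`, `sd_hh`, `sd_hai`, `smaller_sd`.
#' @export
compareModes <- function(rowsHH, rowsHAI) {
  if (!setequal(rowsHH$scope, rowsHAI$scope))
    stop("scope mismatch between HH and HAI summaries")
  rowsHAI <- rowsHAI[match(rowsHH$scope, rowsHAI$scope), , drop = FALSE]
  better <- function(hh, hai, metric) {
    if (is.na(hh) || is.na(hai)) return(NA_character_)
    if (hh == hai) return("equal")
    higherIsBetter <- metric == "dice"
    if ((hh > hai) == higherIsBetter) "HH" else "HAI"
  }
  superior <- mapply(better, rowsHH$mean, rowsHAI$mean, rowsHH$metric)
  smaller <- mapply(function(a, b) {
    if (is.na(a) || is.na(b)) NA_character_
    else if (a == b) "equal" else if (a < b) "HH" else "HAI"
  }, rowsHH$sd, rowsHAI$sd)
  data.frame(scope = rowsHH$scope, metric = rowsHH$metric,
             mean_hh = rowsHH$mean, mean_hai = rowsHAI$mean,
             superior_mean = superior,
             sd_hh = rowsHH$sd, sd_hai = rowsHAI$sd, smaller_sd = smaller,
             stringsAsFactors = FALSE)
}

#' Render summary rows the way agreement tables are usually printed
#'
#' Rounds scores to 2 decimals at presentation time only (internal values stay
#' full precision) and lays rows out as scope x (min, mean, median, max, sd).
#'
#' @param rows [summarizeScores()] output.
#' @return A character vector of formatted lines.
#' @export
formatSummary <- function(rows) {
  f <- function(x) ifelse(is.na(x), "  NA", sprintf("%.2f", x))
  c(sprintf("%-28s %-4s %-9s %6s %6s %6s %6s %6s %6s",
            "scope", "mode", "metric", "n", "min", "mean", "median", "max", "sd"),
    sprintf("%-28s %-4s %-9s %6d %6s %6s %6s %6s %6s",
            rows$scope, rows$mode, rows$metric, rows$n_pairs, f(rows$min),
            f(rows$mean), f(rows$median), f(rows$max), f(rows$sd)))
}
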