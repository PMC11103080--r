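#' @include manifest.R
NULL

.OUTCOMES <- c("TP", "TN", "FP", "FN")
.JUDGMENTS <- c("increase", "no_change", "decrease")
.RISK_EVENTS <- list(
  nerve_trauma        = c("ISB", "AxB", "ACB", "SNB"),
  last_arterial       = c("ISB", "AxB", "ACB", "SNB"),
  pneumothorax_pleura = c("ISB", "ESPB"),
  peritoneal_violation = c("RSB"),
  block_failure       = .REGIONS)

#' Adverse-event types applicable per block region
#'
#' Risk-modification judgments are only collected for events that can occur
#' at a given block site: nerve trauma and intravascular (local anaesthetic
#' systemic toxicity) events where nerves/vessels are targeted, pneumothorax
#' where the pleura is nearby (interscalene, erector spinae plane),
#' peritoneal violation for the rectus sheath block, block failure
#' everywhere.
#'
#' @return Named list: event type -> character vector of regions.
#' @export
riskEvents <- function() .RISK_EVENTS

#' Load qualitative assessments from CSV
#'
#' One row per expert x scan x structure. Required columns: `expert_id`,
#' `region`, `structure_id`, `outcome` (TP/TN/FP/FN, or empty when
#' unrecorded). Optional: `scan_id`, `subjective_score` (integer 0-10,
#' attached per expert per block region), and one `risk_<event>` column per
#' applicable event type with values increase/no_change/decrease.
#'
#' @param path CSV file.
#' @return A validated data.frame of assessments.
#' @export
loadQualAssessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "region", "structure_id", "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("assessment CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df$outcome[df$outcome == ""] <- NA_character_
  bad <- !is.na(df$outcome) & !df$outcome %in% .OUTCOMES
  if (any(bad)) stop("invalid outcome value(s): ",
                     paste(unique(df$outcome[bad]), collapse = ", "))
  if (!all(df$region %in% .REGIONS))
    stop("invalid region value(s) in assessments")
  for (ev in names(.RISK_EVENTS)) {
    col <- paste0("risk_", ev)
    if (col %in% names(df)) {
      df[[col]][df[[col]] == ""] <- NA_character_
      badj <- !is.na(df[[col]]) & !df[[col]] %in% .JUDGMENTS
      if (any(badj)) stop("invalid risk judgment in column ", col)
    }
  }
  if ("subjective_score" %in% names(df)) {
    s <- df$subjective_score
    if (any(!is.na(s) & (s < 0 | s > 10)))
      stop("subjective_score outside 0-10")
  }
  df
}

#' Qualitative accuracy rates for one structure
#'
#' The proportions of expert assessments judging the AI overlay correct
#' ((TP+TN)/total), a false positive (FP/total) and a false negative
#' (FN/total). The denominator is the number of recorded assessments (rows
#' with a non-missing outcome), which may be smaller than the nominal panel
#' size.
#'
#' @param assessments data.frame as from [loadQualAssessments()].
#' @param structureId structure to score.
#' @return A list with `accuracy`, `fp_rate`, `fn_rate` (proportions in
#'   \[0, 1\], `NA` when nothing is recorded), `n_correct`, `n_fp`, `n_fn`,
#'   `denominator`.
#' @export
accuracyRates <- function(assessments, structureId) {
  rows <- assessments[assessments$structure_id == structureId, , drop = FALSE]
  out <- rows$outcome[!is.na(rows$outcome)]
  d <- length(out)
  list(
    accuracy = if (d) sum(out %in% c("TP", "TN")) / d else NA_real_,
    fp_rate  = if (d) sum(out == "FP") / d else NA_real_,
    fn_rate  = if (d) sum(out == "FN") / d else NA_real_,
    n_correct = sum(out %in% c("TP", "TN")),
    n_fp = sum(out == "FP"), n_fn = sum(out == "FN"),
    denominator = d)
}

#' Risk-modification tally for one structure or region
#'
#' Proportions of recorded judgments that the AI overlay would increase,
#' leave unchanged, or decrease the risk of the given adverse event. The
#' event must be applicable to the scope's region (see [riskEvents()]).
#'
#' @param assessments data.frame with a `risk_<event>` column.
#' @param scope a `structure_id` or a region code.
#' @param event one of `names(riskEvents())`.
#' @return A list with `proportions` (named increase/no_change/decrease,
#'   summing to 1), `counts` and `denominator`.
#' @export
riskTally <- function(assessments, scope, event) {
  if (!event %in% names(.RISK_EVENTS))
    stop("unknown event type: ", event)
  if (scope %in% .REGIONS) {
    region <- scope
    rows <- assessments[assessments$region == scope, , drop = FALSE]
  } else {
    rows <- assessments[assessments$structure_id == scope, , drop = FALSE]
    region <- unique(rows$region)
  }
  if (length(region) == 1L && !region %in% .RISK_EVENTS[[event]])
    stop("event '", event, "' is not applicable in region '", region, "'")
  col <- paste0("risk_", event)
  if (!col %in% names(assessments))
    stop("assessments lack column ", col)
  j <- rows[[col]][!is.na(rows[[col]])]
  counts <- vapply(.JUDGMENTS, function(x) sum(j == x), integer(1))
  d <- length(j)
  list(proportions = if (d) counts / d else rep(NA_real_, 3L),
       counts = counts, denominator = d)
}

#' Summary of subjective 0-10 block scores
#'
#' @param scores numeric vector of per-expert scores (0-10).
#' @return A list with `mean`, `min`, `max`, `sd` (sample sd, `NA` for fewer
#'   than 2 scores) and `n`.
#' @export
subjectiveSummary <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (any(scores < 0 | scores > 10)) stop("scores must lie in 0-10")
  n <- length(scores)
  list(mean = if (n) mean(scores) else NA_real_,
       min = if (n) min(scores) else NA_real_,
       max = if (n) max(scores) else NA_real_,
       sd = if (n > 1L) stats::sd(scores) else NA_real_,
       n = n)
}

#' Expand printed qualitative count cells into per-expert records
#'
#' Published qualitative tables report cells as percentages with counts, e.g.
#' accuracy 86.7 (13/15). This helper reconstitutes a per-expert assessment
#' table from such counts so the rate computations can be re-run on them:
#' for each structure it creates `denominator` recorded rows (correct
#' outcomes are labelled TP — TP and TN are not separable in a combined
#' (TP+TN) cell, which leaves all rates unchanged) and pads unrecorded rows
#' with `NA` up to the nominal panel size.
#'
#' @param counts data.frame with columns `region`, `structure_id`, `measure`
#'   (`"accuracy"`, `"fp"`, `"fn"`, or `"risk"`), `event` (risk rows),
#'   `judgment` (risk rows), `numerator`, `denominator`.
#' @param panelSize nominal number of assessments per structure.
#' @return An assessment data.frame as accepted by [accuracyRates()] and
#'   [riskTally()].
#' @export
expandQualCounts <- function(counts, panelSize = 15L) {
  out <- list()
  for (sid in unique(counts$structure_id)) {
    sub <- counts[counts$structure_id == sid, , drop = FALSE]
    region <- unique(sub$region)
    n <- max(sub$denominator, panelSize)
    rows <- data.frame(
      expert_id = sprintf("expert%d", ((seq_len(n) - 1L) %% 3L) + 1L),
      scan_id = sprintf("scan%d", ((seq_len(n) - 1L) %/% 3L) + 1L),
      region = region, structure_id = sid,
      outcome = NA_character_, stringsAsFactors = FALSE)
    acc <- sub[sub$measure %in% c("accuracy", "fp", "fn"), , drop = FALSE]
    if (nrow(acc)) {
      den <- unique(acc$denominator)
      if (length(den) != 1L)
        stop("inconsistent accuracy denominators for ", sid)
      lab <- c(rep("TP", acc$numerator[acc$measure == "accuracy"]),
               rep("FP", sum(acc$numerator[acc$measure == "fp"])),
               rep("FN", sum(acc$numerator[acc$measure == "fn"])))
      if (length(lab) != den)
        stop("accuracy cells for ", sid, " do not sum to their denominator")
      rows$outcome[seq_len(den)] <- lab
    }
    risk <- sub[sub$measure == "risk", , drop = FALSE]
    for (ev in unique(risk$event)) {
      rr <- risk[risk$event == ev, , drop = FALSE]
      den <- unique(rr$denominator)
      if (length(den) != 1L || sum(rr$numerator) != den)
        stop("risk cells for ", sid, "/", ev,
             " do not sum to their denominator")
      lab <- rep(rr$judgment, rr$numerator)
      col <- paste0("risk_", ev)
      if (!col %in% names(rows)) rows[[col]] <- NA_character_
      rows[[col]][seq_len(den)] <- lab
    }
    out[[length(out) + 1L]] <- rows
  }
  cols <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bundled qualitative assessment counts
#'
#' The printed count cells of a 15-assessment (three experts, up to five
#' scans) qualitative evaluation of AI structure highlighting across the six
#' block regions: accuracy (TP+TN, FP, FN) per structure and
#' risk-modification tallies for the applicable adverse events. Two radial
#' nerve assessments were unrecorded, so its denominators are 13.
#'
#' @return A counts data.frame (see [expandQualCounts()]).
#' @export
qualitativeCounts <- function() {
  utils::read.csv(system.file("extdata", "qualitative_counts.csv",
                              package = "sonoAgree"),
                  stringsAsFactors = FALSE)
}
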