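# Majority-vote ensemble classification of missense variants: the fraction of
# benign verdicts among 15 pathogenicity predictors is compared against three
# operating-mode thresholds to call Pathogenic vs VUS.

#' Canonical predictor panel
#'
#' The 15 pathogenicity predictors whose verdicts feed the ensemble
#' classifier, in canonical column order.
#'
#' @return Character vector of 15 predictor names.
#' @export
predictor_panel <- function() {
  c("SIFT", "PolyPhen2", "LRT", "MutationTaster", "MutationAssessor",
    "PROVEAN", "MetaSVM", "M-CAP", "Revel", "MutPred", "MVP", "DEOGEN2",
    "ClinPred", "LIST-S2", "CADD")
}

#' Default operating-mode thresholds
#'
#' Pathogenic-to-VUS rate thresholds for the three classifier operating
#' modes: `high_coverage` (0.40), `intermediate` (0.24) and `low_fpr`
#' (0.08). A variant whose benign-verdict rate is at or below the mode's
#' threshold is called Pathogenic in that mode, otherwise VUS. The reported
#' false-positive rates attached as metadata (11.5% at low-FPR, 20% at
#' intermediate) are informational only and never enter the computation.
#'
#' @return An object of class `mode_thresholds`.
#' @export
mode_thresholds <- function(high_coverage = 0.40, intermediate = 0.24,
                            low_fpr = 0.08) {
  if (!(high_coverage > intermediate && intermediate > low_fpr && low_fpr > 0))
    stop_vuscope("thresholds must satisfy high_coverage > intermediate > low_fpr > 0",
                 class = "vuscope_parameter_error")
  structure(list(high_coverage = high_coverage, intermediate = intermediate,
                 low_fpr = low_fpr,
                 reported_fpr = c(low_fpr = 11.5, intermediate = 20)),
            class = "mode_thresholds")
}

#' Construct a per-variant predictor verdict set
#'
#' @param variant_id protein-level label, e.g. `"P471L"`.
#' @param verdicts character vector of length 15 over `{"B","P","NA"}`, named
#'   by (or ordered as) [predictor_panel()].
#' @param scores optional numeric predictor scores in `[0,1]` (metadata only;
#'   verdicts are explicit inputs and are never derived from scores).
#' @param cdna optional HGVS c. string.
#' @return An object of class `variant_score_set`.
#' @export
variant_score_set <- function(variant_id, verdicts, scores = NULL,
                              cdna = NA_character_) {
  panel <- predictor_panel()
  if (!is.null(names(verdicts))) {
    if (!setequal(names(verdicts), panel))
      stop_vuscope("verdict names must be exactly the 15 canonical predictors",
                   class = "vuscope_format_error")
    verdicts <- verdicts[panel]
  }
  verdicts <- as.character(verdicts)
  verdicts[is.na(verdicts)] <- "NA"
  if (length(verdicts) != length(panel))
    stop_vuscope("variant %s: expected %d predictor verdicts, got %d",
                 variant_id, length(panel), length(verdicts),
                 class = "vuscope_format_error")
  bad <- setdiff(unique(verdicts), c("B", "P", "NA"))
  if (length(bad))
    stop_vuscope("variant %s: invalid verdict token(s): %s",
                 variant_id, paste(bad, collapse = ", "),
                 class = "vuscope_format_error")
  if (all(verdicts == "NA"))
    stop_vuscope("variant %s: all 15 verdicts are NA; rate undefined",
                 variant_id, class = "vuscope_undefined_rate_error")
  if (is.null(scores)) scores <- rep(NA_real_, length(panel))
  structure(list(variant_id = variant_id, cdna = cdna,
                 entries = data.frame(predictor = panel, verdict = verdicts,
                                      score = as.numeric(scores))),
            class = "variant_score_set")
}

#' @export
print.variant_score_set <- function(x, ...) {
  tab <- table(factor(x$entries$verdict, levels = c("B", "P", "NA")))
  cat(sprintf("<variant_score_set> %s (%s): %d B / %d P / %d NA\n",
              x$variant_id, x$cdna, tab[["B"]], tab[["P"]], tab[["NA"]]))
  invisible(x)
}

#' Read a predictor verdict table
#'
#' Parses a TSV with columns `variant_id`, `cdna`, and for each of the 15
#' canonical predictors a `<predictor>_verdict` column over `{B, P, NA}`
#' (plus an optional `<predictor>_score` column). One row per variant.
#'
#' @param path path to the TSV file.
#' @return A list of [variant_score_set()] objects, in file order.
#' @export
parse_predictor_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          colClasses = "character", na.strings = NULL)
  panel <- predictor_panel()
  vcols <- paste0(panel, "_verdict")
  missing_cols <- setdiff(vcols, names(df))
  if (length(missing_cols))
    stop_vuscope("predictor table lacks verdict column(s): %s",
                 paste(missing_cols, collapse = ", "),
                 class = "vuscope_format_error")
  extra <- grep("_verdict$", names(df), value = TRUE)
  unknown <- setdiff(sub("_verdict$", "", extra), panel)
  if (length(unknown))
    stop_vuscope("unknown predictor(s) in table: %s",
                 paste(unknown, collapse = ", "),
                 class = "vuscope_format_error")
  if (nrow(df) == 0) return(list())
  scols <- paste0(panel, "_score")
  has_scores <- all(scols %in% names(df))
  lapply(seq_len(nrow(df)), function(i) {
    scores <- if (has_scores)
      suppressWarnings(as.numeric(unlist(df[i, scols]))) else NULL
    variant_score_set(df$variant_id[i],
                      stats::setNames(unlist(df[i, vcols]), panel),
                      scores = scores,
                      cdna = if ("cdna" %in% names(df)) df$cdna[i]
                             else NA_character_)
  })
}

#' Benign-verdict rate of a variant
#'
#' The rate is B/(B+P): the fraction of benign verdicts among the non-missing
#' predictor verdicts. NA verdicts are excluded from both numerator and
#' denominator. Classification always uses the unrounded rate; only reports
#' round it (half-up, two decimals).
#'
#' @param scores a [variant_score_set()].
#' @return The unrounded rate in `[0,1]`.
#' @export
compute_rate <- function(scores) {
  stopifnot(inherits(scores, "variant_score_set"))
  v <- scores$entries$verdict
  nb <- sum(v == "B"); np <- sum(v == "P")
  if (nb + np == 0)
    stop_vuscope("variant %s: no non-NA verdicts; rate undefined",
                 scores$variant_id, class = "vuscope_undefined_rate_error")
  nb / (nb + np)
}

#' Classify a benign-verdict rate under one operating mode
#'
#' Calls Pathogenic when the rate is at or below the mode's threshold
#' (ties at the threshold go to Pathogenic), otherwise VUS. There is no
#' benign output class: the classifier's codomain is `{"P", "VUS"}`.
#'
#' @param rate benign-verdict rate in `[0,1]` (unrounded).
#' @param thresholds a [mode_thresholds()] object.
#' @param mode one of `"high_coverage"`, `"intermediate"`, `"low_fpr"`.
#' @return `"P"` or `"VUS"`.
#' @export
classify <- function(rate, thresholds = mode_thresholds(),
                     mode = c("high_coverage", "intermediate", "low_fpr")) {
  if (length(mode) != 1 ||
      !mode %in% c("high_coverage", "intermediate", "low_fpr"))
    stop_vuscope("unknown mode: %s", paste(mode, collapse = "/"),
                 class = "vuscope_parameter_error")
  check_prob(rate, "rate")
  if (rate <= thresholds[[mode]]) "P" else "VUS"
}

#' Classify every variant in a table under all three modes
#'
#' @param table list of [variant_score_set()] objects.
#' @param thresholds a [mode_thresholds()] object.
#' @return A data.frame with one row per variant: verdict counts, the
#'   unrounded and reported (2 dp, half-up) rate, and the three mode
#'   verdicts, in input order.
#' @export
classify_all <- function(table, thresholds = mode_thresholds()) {
  if (length(table) == 0)
    stop_vuscope("empty variant table", class = "vuscope_parameter_error")
  rows <- lapply(table, function(s) {
    v <- s$entries$verdict
    rate <- tryCatch(compute_rate(s), error = function(e)
      stop_vuscope("variant %s: %s", s$variant_id, conditionMessage(e),
                   class = "vuscope_undefined_rate_error"))
    data.frame(variant_id = s$variant_id, cdna = s$cdna,
               n_benign = sum(v == "B"), n_pathogenic = sum(v == "P"),
               n_na = sum(v == "NA"), rate = rate,
               rate_reported = round_half_up(rate, 2),
               high_coverage = classify(rate, thresholds, "high_coverage"),
               intermediate = classify(rate, thresholds, "intermediate"),
               low_fpr = classify(rate, thresholds, "low_fpr"))
  })
  do.call(rbind, rows)
}
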