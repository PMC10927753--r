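# Descriptive cohort statistics and qualitative cosegregation evaluation.
# The cosegregation call is a tally over tested relatives, not a
# likelihood method: a variant is "excluded" as soon as a tested affected
# relative lacks it, "consistent" when at least one affected relative
# besides the proband carries it (and none excludes it), and
# "uninformative" otherwise.

#' Read a proband cohort table
#'
#' TSV dialect with columns `family_id`, `genotype_cdna`, `classification`
#' (`P/LP` or `VUS`), `age_at_diagnosis`, `tumor_phenotype`, `bilateral`,
#' `other_tumors`, `bc_fdr`, `bc_sdr`, `other_family_tumors`, `sex`. The
#' packaged fixture `table1.tsv` transcribes the study cohort.
#'
#' @param path TSV file.
#' @return data.frame of typed records, classification normalized to
#'   `P_LP`/`VUS`.
#' @export
load_cohort <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  req <- c("family_id", "genotype_cdna", "classification",
           "age_at_diagnosis", "tumor_phenotype", "bilateral",
           "other_tumors", "bc_fdr", "bc_sdr")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_vuscope("cohort table lacks column(s): %s",
                 paste(miss, collapse = ", "),
                 class = "vuscope_format_error")
  df$classification <- toupper(gsub("[ /-]", "_", df$classification))
  bad <- setdiff(unique(df$classification), c("P_LP", "VUS"))
  if (length(bad))
    stop_vuscope("unknown classification token(s): %s",
                 paste(bad, collapse = ", "),
                 class = "vuscope_format_error")
  df$age_at_diagnosis <- as.numeric(df$age_at_diagnosis)
  if (any(!is.finite(df$age_at_diagnosis) | df$age_at_diagnosis <= 0))
    stop_vuscope("ages must be positive numbers",
                 class = "vuscope_validation_error")
  df$bc_fdr <- as.integer(df$bc_fdr)
  df$bc_sdr <- as.integer(df$bc_sdr)
  if (any(df$bc_fdr < 0 | df$bc_sdr < 0, na.rm = TRUE))
    stop_vuscope("relative counts must be non-negative",
                 class = "vuscope_validation_error")
  df$bilateral <- tolower(df$bilateral) %in% c("yes", "true", "1")
  df$other_tumors <- tolower(df$other_tumors) %in% c("yes", "true", "1")
  df
}

#' Prevalence of a classification among tested patients
#'
#' `100 * n_matching / n_tested`, reported half-up to two decimals.
#'
#' @param records cohort data.frame from [load_cohort()].
#' @param n_tested number of patients tested.
#' @param classification `"P_LP"` or `"VUS"`.
#' @return List with `count`, `n_tested`, `percent` (2 dp).
#' @export
prevalence <- function(records, n_tested, classification) {
  if (n_tested <= 0)
    stop_vuscope("n_tested must be positive",
                 class = "vuscope_parameter_error")
  count <- if (nrow(records)) sum(records$classification == classification)
           else 0L
  if (count > n_tested)
    stop_vuscope("more matching records (%d) than tested patients (%d)",
                 count, n_tested, class = "vuscope_parameter_error")
  list(count = count, n_tested = n_tested,
       percent = round_half_up(100 * count / n_tested, 2))
}

#' Descriptive summary of one classification subset
#'
#' Mean age rounded half-up to one decimal, age range, phenotype counts,
#' bilateral count and totals of affected first-/second-degree relatives.
#'
#' @param records cohort data.frame.
#' @param classification `"P_LP"` or `"VUS"`.
#' @return List summary; `n = 0` marks an empty subset.
#' @export
describe <- function(records, classification) {
  sub <- records[records$classification == classification, , drop = FALSE]
  if (nrow(sub) == 0)
    return(list(n = 0L, classification = classification))
  list(classification = classification, n = nrow(sub),
       mean_age = round_half_up(mean(sub$age_at_diagnosis), 1),
       age_range = range(sub$age_at_diagnosis),
       n_distinct_genotypes = length(unique(sub$genotype_cdna)),
       phenotype_counts = table(sub$tumor_phenotype),
       bilateral_count = sum(sub$bilateral),
       fdr_total = sum(sub$bc_fdr), sdr_total = sum(sub$bc_sdr))
}

#' Construct a pedigree
#'
#' @param individuals list of lists with fields `id`, `sex`, `father`,
#'   `mother`, `affected`, `cancer_type`, `age_dx`, `tested`, `carrier`
#'   (`NULL`/NA when untested).
#' @param proband id of the proband.
#' @return Object of class `pedigree` (a validated data.frame plus the
#'   proband id).
#' @export
pedigree <- function(individuals, proband) {
  df <- do.call(rbind, lapply(individuals, function(p)
    data.frame(id = p$id, sex = p$sex %||% NA_character_,
               father = p$father %||% NA_character_,
               mother = p$mother %||% NA_character_,
               affected = isTRUE(p$affected),
               cancer_type = p$cancer_type %||% NA_character_,
               age_dx = p$age_dx %||% NA_real_,
               tested = isTRUE(p$tested),
               carrier = if (is.null(p$carrier) || is.na(p$carrier)) NA
                         else isTRUE(p$carrier))))
  if (anyDuplicated(df$id))
    stop_vuscope("duplicate individual ids", class = "vuscope_input_error")
  for (col in c("father", "mother")) {
    bad <- !is.na(df[[col]]) & !df[[col]] %in% df$id
    if (any(bad))
      stop_vuscope("unresolved %s reference for %s", col,
                   paste(df$id[bad], collapse = ", "),
                   class = "vuscope_input_error")
  }
  half <- xor(is.na(df$father), is.na(df$mother))
  if (any(half))
    stop_vuscope("non-founder must list both parents: %s",
                 paste(df$id[half], collapse = ", "),
                 class = "vuscope_input_error")
  # acyclicity: repeatedly remove founders; leftovers mean a cycle
  ids <- df$id
  parents <- split(c(df$father, df$mother), rep(df$id, 2))
  placed <- character(0)
  repeat {
    ready <- ids[!ids %in% placed &
                   vapply(ids, function(i) {
                     p <- parents[[i]]
                     all(is.na(p) | p %in% placed)
                   }, logical(1))]
    if (!length(ready)) break
    placed <- c(placed, ready)
  }
  if (length(placed) < length(ids))
    stop_vuscope("cyclic parentage involving: %s",
                 paste(setdiff(ids, placed), collapse = ", "),
                 class = "vuscope_input_error")
  if (!proband %in% df$id)
    stop_vuscope("proband %s not in pedigree", proband,
                 class = "vuscope_input_error")
  structure(list(individuals = df, proband = proband), class = "pedigree")
}

#' Read a pedigree from JSON
#'
#' @param path JSON file with `proband` and `individuals` fields.
#' @return A [pedigree()].
#' @export
load_pedigree <- function(path) {
  j <- jsonlite::read_json(path)
  pedigree(j$individuals, proband = j$proband)
}

#' Qualitative cosegregation evaluation
#'
#' Verdict over tested relatives of a tested carrier proband: `excluded`
#' when any tested affected relative is a non-carrier; `consistent` when
#' at least one tested affected relative besides the proband carries the
#' variant and none excludes it; `uninformative` otherwise. Exclusion
#' dominates consistency. Untested individuals never influence the
#' verdict.
#'
#' @param ped a [pedigree()].
#' @return Object of class `cosegregation_result` with the tested-relative
#'   tallies and the verdict.
#' @export
cosegregation <- function(ped) {
  df <- ped$individuals
  pro <- df[df$id == ped$proband, ]
  if (!pro$tested || !isTRUE(pro$carrier))
    stop_vuscope("proband must be a tested carrier",
                 class = "vuscope_input_error")
  rel <- df[df$id != ped$proband & df$tested, , drop = FALSE]
  aff_car <- sum(rel$affected & rel$carrier %in% TRUE)
  aff_non <- sum(rel$affected & rel$carrier %in% FALSE)
  unaff_car <- sum(!rel$affected & rel$carrier %in% TRUE)
  verdict <- if (aff_non > 0) "excluded"
             else if (aff_car > 0) "consistent"
             else "uninformative"
  structure(list(n_tested_affected_carriers = aff_car,
                 n_tested_affected_noncarriers = aff_non,
                 n_tested_unaffected_carriers = unaff_car,
                 verdict = verdict),
            class = "cosegregation_result")
}

#' Cohort report with documented discrepancy flags
#'
#' Computes prevalences and subset summaries under one consistent rounding
#' rule (half-up) and reports them as computed; published figures derived
#' under different implicit conventions are not silently matched.
#'
#' @param records cohort data.frame.
#' @param n_tested number of patients tested.
#' @return List with per-class prevalence and summaries plus a
#'   `distinct_genotypes` count.
#' @export
cohort_report <- function(records, n_tested) {
  list(n_records = nrow(records),
       distinct_genotypes = length(unique(records$genotype_cdna)),
       prevalence_p_lp = prevalence(records, n_tested, "P_LP"),
       prevalence_vus = prevalence(records, n_tested, "VUS"),
       summary_p_lp = describe(records, "P_LP"),
       summary_vus = describe(records, "VUS"))
}
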