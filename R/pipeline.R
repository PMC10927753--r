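# Orchestrates the analysis stages into one reproducible run that merges
# per-variant evidence into dossiers. Dossiers report evidence lines only
# and never auto-combine them into a single pathogenicity call: evidence
# integration is left to the reader.

RUN_CONFIG_KEYS <- c("output_dir", "seed", "classifier", "conservation",
                     "structgeo", "trajstab", "cohort", "log_level")

#' Read and validate a run configuration
#'
#' YAML with top-level keys `output_dir`, `seed`, `log_level` and one
#' block per stage (`classifier`, `conservation`, `structgeo`,
#' `trajstab`, `cohort`), each with an `enabled` flag plus stage
#' parameters. Unknown top-level keys are rejected. The configuration
#' round-trips serialize/parse.
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config config list (e.g. built in code).
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop_vuscope("unknown config key(s): %s", paste(unknown, collapse = ", "),
                 class = "vuscope_parameter_error")
  if (is.null(config$output_dir))
    stop_vuscope("config needs output_dir", class = "vuscope_parameter_error")
  config$seed <- config$seed %||% 1
  config
}

stage_enabled <- function(config, stage) {
  isTRUE(config[[stage]]$enabled %||% !is.null(config[[stage]]))
}

hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full per-variant evidence pipeline
#'
#' Executes the enabled stages against the configured inputs and writes,
#' under `output_dir`: `dossiers.tsv` (one evidence row per variant),
#' `dossiers/<variant>.json`, `manifest.json` (config hash, input file
#' hashes, package version) and `run.log`. Fields of a disabled stage are
#' marked `"not-run"`. Re-running with the same config and inputs
#' reproduces the TSV/JSON outputs byte for byte (the log carries
#' timestamps and is excluded from that guarantee). A failing stage
#' aborts the run with the stage named.
#'
#' @param config list (see [read_run_config()]) or path to a YAML file.
#' @return Invisibly, a list with `dossiers` (data.frame) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- config$output_dir
  dir.create(file.path(out_dir, "dossiers"), recursive = TRUE,
             showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(stage, msg)
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage, msg), file = logf, append = TRUE)
  cat("", file = logf)
  run_stage <- function(stage, expr) {
    log_line(stage, sprintf("start (params: %s)",
      jsonlite::toJSON(config[[stage]], auto_unbox = TRUE, force = TRUE)))
    res <- tryCatch(expr, error = function(e)
      stop_vuscope("stage '%s' failed: %s", stage, conditionMessage(e),
                   class = "vuscope_stage_error"))
    log_line(stage, "done")
    res
  }

  inputs <- character(0)
  note_input <- function(path) {
    if (!file.exists(path))
      stop_vuscope("input file not found: %s", path,
                   class = "vuscope_input_error")
    inputs[[path]] <<- unname(tools::md5sum(path))
  }

  # classifier drives the variant list
  classifier_res <- NULL
  if (stage_enabled(config, "classifier")) {
    classifier_res <- run_stage("classifier", {
      note_input(config$classifier$table)
      classify_all(parse_predictor_table(config$classifier$table))
    })
  }
  variants <- if (!is.null(classifier_res)) classifier_res$variant_id
              else names(config$conservation$positions) %||% character(0)

  conservation_res <- NULL
  if (stage_enabled(config, "conservation")) {
    conservation_res <- run_stage("conservation", {
      note_input(config$conservation$msa)
      aln <- parse_alignment(config$conservation$msa)
      pos <- config$conservation$positions
      rep <- conservation_report(aln, unlist(pos))
      rep$variant_id <- names(pos)
      rep
    })
  }

  structgeo_res <- NULL
  if (stage_enabled(config, "structgeo")) {
    structgeo_res <- run_stage("structgeo", {
      note_input(config$structgeo$pdb)
      s <- parse_pdb(config$structgeo$pdb)
      lapply(config$structgeo$sites, function(site) {
        res <- c(site$chain, site$resno)
        out <- list(
          exposure = relative_exposure(s, res),
          hbonds = find_hbonds(s),
          salt_bridges = find_salt_bridges(s),
          cation_pi = find_cation_pi(s))
        if (!is.null(site$mutate))
          out$clash <- substitution_clash_screen(s, res, site$mutate)
        if (length(unique(s$atoms$chain)) > 1)
          out$min_interchain <- min_interchain_distance(s, res)
        out
      })
    })
  }

  trajstab_res <- NULL
  if (stage_enabled(config, "trajstab")) {
    trajstab_res <- run_stage("trajstab", {
      cfg <- config$trajstab
      lapply(cfg$variants, function(v) {
        verdicts <- list(); dimers <- character(0)
        for (k in seq_along(v$replicas)) {
          r <- v$replicas[[k]]
          note_input(r$traj); note_input(r$ref)
          traj <- load_trajectory(r$traj, r$ref,
                                  replica_id = sprintf("r%d", k))
          sel <- local_selection(traj$reference,
                                 c(v$site$chain, v$site$resno),
                                 radius = cfg$radius %||% 1.0)
          mat <- rmsd_matrix(traj, sel)
          cl <- cluster_frames(mat, cutoff = cfg$cluster_cutoff %||% 0.15)
          verdicts[[k]] <- stability_verdict(cl,
                                             replica_id = sprintf("r%d", k))
          if (length(unique(traj$reference$atoms$chain)) > 1)
            dimers[k] <- dimer_state(traj)
        }
        list(summary = replica_summary(verdicts,
                                       if (length(dimers)) dimers else NULL),
             verdicts = verdicts)
      })
    })
  }

  cohort_res <- NULL
  if (stage_enabled(config, "cohort")) {
    cohort_res <- run_stage("cohort", {
      note_input(config$cohort$table)
      rec <- load_cohort(config$cohort$table)
      out <- cohort_report(rec, config$cohort$n_tested)
      out$records <- rec
      out$cosegregation <- lapply(config$cohort$pedigrees, function(p) {
        note_input(p)
        cosegregation(load_pedigree(p))
      })
      out
    })
  }

  not_run <- "not-run"
  dossiers <- lapply(variants, function(v) {
    d <- list(variant_id = v)
    if (!is.null(classifier_res)) {
      row <- classifier_res[classifier_res$variant_id == v, ]
      d$classifier <- list(provenance = "classifier",
                           rate = row$rate, rate_reported = row$rate_reported,
                           n_benign = row$n_benign,
                           n_pathogenic = row$n_pathogenic, n_na = row$n_na,
                           verdicts = list(high_coverage = row$high_coverage,
                                           intermediate = row$intermediate,
                                           low_fpr = row$low_fpr))
      d$cdna <- row$cdna
    } else d$classifier <- not_run
    if (!is.null(conservation_res) &&
        v %in% conservation_res$variant_id) {
      row <- conservation_res[conservation_res$variant_id == v, ]
      d$conservation <- list(provenance = "conservation",
                             category = row$category,
                             info_bits = row$info_bits,
                             ref_frequency = row$ref_frequency,
                             ref_rank = row$ref_rank)
    } else d$conservation <- not_run
    if (!is.null(structgeo_res) && v %in% names(structgeo_res)) {
      sg <- structgeo_res[[v]]
      d$structural <- list(provenance = "structgeo",
                           exposure_class = sg$exposure$class,
                           exposure_ratio = sg$exposure$ratio,
                           n_hbonds = nrow(sg$hbonds),
                           n_salt_bridges = nrow(sg$salt_bridges),
                           n_cation_pi = nrow(sg$cation_pi),
                           clash = sg$clash %||% NULL,
                           min_interchain = sg$min_interchain %||% NULL)
    } else d$structural <- not_run
    if (!is.null(trajstab_res) && v %in% names(trajstab_res)) {
      ts <- trajstab_res[[v]]
      d$trajectory <- list(provenance = "trajstab",
                           fraction_text = ts$summary$fraction_text,
                           per_replica = as.list(ts$summary$per_replica),
                           dimer_states = ts$summary$dimer_states)
    } else d$trajectory <- not_run
    d
  })
  names(dossiers) <- variants

  for (v in variants) {
    jsonlite::write_json(dossiers[[v]],
                         file.path(out_dir, "dossiers",
                                   paste0(gsub("[^A-Za-z0-9_.-]", "_", v),
                                          ".json")),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         digits = NA)
  }

  flat <- do.call(rbind, lapply(dossiers, function(d) {
    data.frame(
      variant_id = d$variant_id,
      rate = if (is.list(d$classifier)) d$classifier$rate_reported else not_run,
      high_coverage = if (is.list(d$classifier))
        d$classifier$verdicts$high_coverage else not_run,
      intermediate = if (is.list(d$classifier))
        d$classifier$verdicts$intermediate else not_run,
      low_fpr = if (is.list(d$classifier))
        d$classifier$verdicts$low_fpr else not_run,
      conservation = if (is.list(d$conservation))
        d$conservation$category else not_run,
      exposure = if (is.list(d$structural))
        d$structural$exposure_class else not_run,
      trajectory_stable = if (is.list(d$trajectory))
        d$trajectory$fraction_text else not_run)
  }))
  utils::write.table(flat, file.path(out_dir, "dossiers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(config_hash = hash_obj(config),
                   input_hashes = as.list(inputs),
                   package_version = as.character(
                     utils::packageVersion("vuscope")),
                   seed = config$seed,
                   stages_run = Filter(function(s) stage_enabled(config, s),
                                       c("classifier", "conservation",
                                         "structgeo", "trajstab", "cohort")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(cohort_res))
    jsonlite::write_json(
      list(n_records = cohort_res$n_records,
           distinct_genotypes = cohort_res$distinct_genotypes,
           prevalence_p_lp = cohort_res$prevalence_p_lp,
           prevalence_vus = cohort_res$prevalence_vus,
           cosegregation = lapply(cohort_res$cosegregation, unclass)),
      file.path(out_dir, "cohort.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  invisible(list(dossiers = flat, dossiers_full = dossiers,
                 manifest = manifest, cohort = cohort_res))
}
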