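#' Survey run configuration
#'
#' Bundles every knob of a survey run. All analysis outputs embed a digest
#' of this configuration in their header comment, so tables are traceable
#' to the exact settings that produced them.
#'
#' @param genbank Path(s) to GenBank flat file(s).
#' @param metadata Path to the metadata TSV (columns `accession`, `family`,
#'   `baltimore_type`, `host_category`, optional `segment_group`).
#' @param out_dir Output directory for the tables.
#' @param scores Optional per-residue score TSV from an external predictor
#'   (see [read_score_table()]).
#' @param host_disorder Optional host proteome disorder TSV (columns
#'   `host_category`, `host_mean`, `host_min`, `host_max`); defaults to the
#'   literature constants shipped with the package.
#' @param window,threshold,strict_gt Predictor and calling parameters.
#' @param min_family_size Families must exceed this size to be tabulated.
#' @param qc_k MAD multiplier for the annotation QC.
#' @param qc_policy `"flag-family"` or `"flag-genome"`.
#' @param overlap_denominator `"covered"` or `"genome"`.
#' @param seed Seed recorded in output headers (the survey itself is
#'   deterministic).
#' @return Object of class `RunConfig`.
#' @export
survey_config <- function(genbank, metadata, out_dir,
                          scores = NULL, host_disorder = NULL,
                          window = 25L, threshold = 0.5, strict_gt = FALSE,
                          min_family_size = 10L, qc_k = 3,
                          qc_policy = "flag-family",
                          overlap_denominator = "covered", seed = 1L) {
  structure(
    list(genbank = genbank, metadata = metadata, out_dir = out_dir,
         scores = scores, host_disorder = host_disorder,
         window = as.integer(window), threshold = threshold,
         strict_gt = strict_gt, min_family_size = as.integer(min_family_size),
         qc_k = qc_k, qc_policy = qc_policy,
         overlap_denominator = overlap_denominator, seed = as.integer(seed)),
    class = "RunConfig")
}

config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  keep <- unclass(config)
  keep$out_dir <- NULL            # where output lands is not analysis state
  writeLines(jsonlite::toJSON(keep, auto_unbox = TRUE,
                              null = "null", digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

table_header <- function(config, digest) {
  c(sprintf("# predictor=pairwise-propensity window=%d threshold=%g strict_gt=%s",
            config$window, config$threshold, config$strict_gt),
    sprintf("# seed=%d package=virodisorder %s config_digest=%s",
            config$seed, as.character(utils::packageVersion("virodisorder")),
            digest))
}

write_survey_table <- function(tab, path, config, digest, round_pct = NULL) {
  if (!is.null(round_pct))
    for (cc in intersect(round_pct, names(tab)))
      tab[[cc]] <- round(tab[[cc]], 1)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(table_header(config, digest), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

default_host_disorder <- function() {
  path <- system.file("extdata", "host_disorder.tsv",
                      package = "virodisorder", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Run the full disorder survey
#'
#' End-to-end orchestration: parse the genome records, run the
#' residue-vs-size annotation QC, apply the survey filters, score disorder,
#' compute composition and overlap, and write the five analysis tables
#' (types, families, disorder-composition correlations, hosts, variance
#' attribution) plus the per-genome intermediates. Counts are logged at
#' every stage and conserved: every input genome appears either in the
#' analysis set or among the exclusions.
#'
#' @param config A [survey_config()].
#' @return Invisibly, a list with the observation frame, the five tables
#'   and the `SurveySet`.
#' @export
run_survey <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(config)
  meta <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)

  lines <- unlist(lapply(config$genbank, readLines))
  genomes <- parse_genome_records(text = lines, metadata = meta)
  message(sprintf("parsed %d genomes from %d file(s)",
                  length(genomes), length(config$genbank)))

  flags <- if (length(genomes) >= 10L)
    qc_residue_vs_genome(genomes, k = config$qc_k) else NULL
  survey <- build_survey_set(genomes, flags,
                             min_family_size = config$min_family_size,
                             qc_policy = config$qc_policy)
  message(sprintf("excluded %d genome(s): %s",
                  length(survey$exclusions),
                  if (length(survey$exclusions))
                    paste(names(table(survey$exclusions)),
                          table(survey$exclusions), collapse = ", ")
                  else "none"))
  if (length(survey$genomes) == 0L)
    stop("no genomes left after exclusions; nothing to analyse")
  write_survey_set(survey, genomes, file.path(config$out_dir, "survey_set.tsv"))

  spec <- default_predictor(window = config$window)
  ext_scores <- if (!is.null(config$scores))
    read_score_table(config$scores) else NULL
  dis <- disorder_table(survey$genomes, spec, config$threshold,
                        config$strict_gt, scores = ext_scores)
  prot_dis <- protein_disorder_table(survey$genomes, spec, config$threshold,
                                     config$strict_gt, scores = ext_scores)
  comp <- composition_table(survey$genomes,
                            denominator = config$overlap_denominator)
  obs <- make_observations(survey$genomes, dis, comp)
  message(sprintf("scored %d genomes / %d proteins; %d families tabulated",
                  nrow(obs), nrow(prot_dis), length(survey$tabulated_families)))

  write_survey_table(dis, file.path(config$out_dir, "disorder_per_genome.tsv"),
                     config, digest)
  write_survey_table(prot_dis,
                     file.path(config$out_dir, "disorder_per_protein.tsv"),
                     config, digest)
  write_survey_table(comp,
                     file.path(config$out_dir, "composition_per_genome.tsv"),
                     config, digest)

  pct_cols <- c("mean_D", "sd_D", "min_D", "max_D", "range_D")
  t1 <- group_summaries(obs, "baltimore_type")
  t2 <- group_summaries(obs, "family", groups = survey$tabulated_families)
  t3 <- composition_disorder_correlations(obs)
  host_tab <- if (!is.null(config$host_disorder))
    utils::read.delim(config$host_disorder, stringsAsFactors = FALSE,
                      comment.char = "#")
  else default_host_disorder()
  t4 <- group_summaries(obs, "host_category", host_table = host_tab)
  t5 <- variance_attribution(obs)
  write_survey_table(t1, file.path(config$out_dir, "table1_types.tsv"),
                     config, digest, round_pct = pct_cols)
  write_survey_table(t2, file.path(config$out_dir, "table2_families.tsv"),
                     config, digest, round_pct = pct_cols)
  write_survey_table(t3, file.path(config$out_dir, "table3_composition.tsv"),
                     config, digest)
  write_survey_table(t4, file.path(config$out_dir, "table4_hosts.tsv"),
                     config, digest, round_pct = pct_cols)
  write_survey_table(t5, file.path(config$out_dir, "tableS3_attribution.tsv"),
                     config, digest)

  invisible(list(observations = obs, survey = survey,
                 tables = list(types = t1, families = t2, composition = t3,
                               hosts = t4, attribution = t5)))
}

#' Per-protein disorder report for one genome
#'
#' Lists every protein's length and percent disorder and flags the most
#' disordered protein above a length floor (the analogue of picking each
#' family's most disordered protein of more than 200 residues). Ties are
#' broken in favour of the longer protein.
#'
#' @param genomes List of `GenomeRecord` objects (e.g. a corpus or an
#'   analysis set).
#' @param accession Accession of the genome to explain.
#' @param spec,threshold,strict_gt Predictor settings.
#' @param length_floor Only proteins strictly longer than this many
#'   residues are eligible for the flag (default 200).
#' @return List with `table` (protein_id, L_i, n_disordered, D_i,
#'   flagged) and `flagged` (the flagged protein_id, or `NA` with a note
#'   when no protein exceeds the floor).
#' @export
explain_genome <- function(genomes, accession, spec = default_predictor(),
                           threshold = 0.5, strict_gt = FALSE,
                           length_floor = 200L) {
  acc <- vapply(genomes, `[[`, character(1), "accession")
  hit <- which(acc == accession)
  if (length(hit) == 0L)
    stop(sprintf("unknown accession '%s'", accession))
  gd <- genome_disorder(genomes[[hit]], spec, threshold, strict_gt)
  tab <- gd$per_protein
  eligible <- tab$L_i > length_floor
  flagged <- NA_character_
  note <- NULL
  if (any(eligible)) {
    cand <- tab[eligible, ]
    cand <- cand[order(-cand$D_i, -cand$L_i), ]
    flagged <- cand$protein_id[1L]
  } else {
    note <- sprintf("no protein longer than %d residues", length_floor)
  }
  tab$flagged <- tab$protein_id == flagged & !is.na(flagged)
  list(table = tab, flagged = flagged, note = note)
}
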