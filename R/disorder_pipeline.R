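#' Disorder summary for one genome
#'
#' Scores every protein of a genome and pools residues into the whole-genome
#' percent disorder. Polyproteins are scored intact by default
#' (`polyprotein = "whole"`); with `polyprotein = "cleaved"` each annotated
#' mat_peptide is scored independently and replaces its parent in the pool.
#' Cleaved-peptide residues are never double-counted alongside their parent.
#'
#' @param genome A `GenomeRecord`.
#' @param spec Predictor specification from [default_predictor()].
#' @param threshold,strict_gt Passed to [call_disordered()].
#' @param polyprotein `"whole"` or `"cleaved"`.
#' @param scores Optional named list of external per-residue score vectors
#'   (from [read_score_table()]); proteins present in the list use the
#'   external scores instead of the built-in predictor.
#' @return A `GenomeDisorderSummary` (see [percent_disorder_genome()]).
#' @export
genome_disorder <- function(genome, spec = default_predictor(),
                            threshold = 0.5, strict_gt = FALSE,
                            polyprotein = c("whole", "cleaved"),
                            scores = NULL) {
  polyprotein <- match.arg(polyprotein)
  prot <- genome$proteins
  if (nrow(prot) == 0L)
    stop(sprintf("genome '%s' has no proteins", genome$accession))
  units <- Map(function(id, seq) list(id = id, seq = seq),
               prot$protein_id, prot$sequence)
  if (polyprotein == "cleaved") {
    peps <- Filter(function(f) isTRUE(f$is_mat_peptide) &&
                     !is.na(f$parent_protein_id), genome$cds)
    parents <- unique(vapply(peps, `[[`, character(1), "parent_protein_id"))
    units <- Filter(function(u) !u$id %in% parents, units)
    units <- c(units, lapply(peps, function(f)
      list(id = f$protein_id, seq = f$translation)))
  }
  profiles <- lapply(units, function(u) {
    ext <- if (!is.null(scores)) scores[[u$id]] else NULL
    disorder_profile(u$id, u$seq, spec, threshold, strict_gt, scores = ext)
  })
  percent_disorder_genome(unname(profiles), genome$accession)
}

#' Per-genome disorder table for a corpus
#'
#' Runs [genome_disorder()] over every genome. For genomes carrying at least
#' one polyprotein with annotated cleavage products the table additionally
#' reports the genome-level percent disorder under both polyprotein
#' conventions (`D_polyprotein_whole`, identical to `D`, and
#' `D_polyprotein_cleaved`); both are `NA` for genomes without polyproteins.
#'
#' @inheritParams genome_disorder
#' @param genomes List of `GenomeRecord` objects.
#' @return Data frame with columns `accession`, `N`, `total_residues`,
#'   `disordered_residues`, `D`, `D_polyprotein_whole`,
#'   `D_polyprotein_cleaved`.
#' @export
disorder_table <- function(genomes, spec = default_predictor(),
                           threshold = 0.5, strict_gt = FALSE,
                           scores = NULL) {
  rows <- lapply(genomes, function(g) {
    whole <- genome_disorder(g, spec, threshold, strict_gt, "whole", scores)
    has_poly <- any(g$proteins$is_polyprotein)
    d_cleaved <- if (has_poly)
      genome_disorder(g, spec, threshold, strict_gt, "cleaved", scores)$D
    else NA_real_
    data.frame(accession = whole$accession, N = whole$N,
               total_residues = whole$total_residues,
               disordered_residues = whole$disordered_residues,
               D = whole$D,
               D_polyprotein_whole = if (has_poly) whole$D else NA_real_,
               D_polyprotein_cleaved = d_cleaved,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-protein disorder table for a corpus
#'
#' @inheritParams disorder_table
#' @return Data frame with columns `accession`, `protein_id`, `L_i`,
#'   `n_disordered`, `D_i`.
#' @export
protein_disorder_table <- function(genomes, spec = default_predictor(),
                                   threshold = 0.5, strict_gt = FALSE,
                                   scores = NULL) {
  rows <- lapply(genomes, function(g) {
    gd <- genome_disorder(g, spec, threshold, strict_gt, "whole", scores)
    cbind(accession = g$accession, gd$per_protein, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
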