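#' @importFrom IRanges IRanges reduce coverage width
#' @importFrom S4Vectors runValue runLength
NULL

#' Base composition of a nucleotide sequence
#'
#' Fractions of A, C, G and T over the unambiguous positions of the
#' sequence as deposited (sense strand); ambiguity codes are counted
#' separately and excluded from the denominator.
#'
#' @param seq Nucleotide string (U is treated as T).
#' @return Object of class `BaseComposition`: list with `A`, `C`, `G`, `T`
#'   fractions, `n_sites` (unambiguous) and `n_ambiguous`.
#' @export
base_composition <- function(seq) {
  if (length(seq) != 1L || nchar(seq) < 1L) stop("need a non-empty sequence")
  chars <- strsplit(chartr("Uu", "Tt", toupper(seq)), "", fixed = TRUE)[[1L]]
  counts <- c(A = sum(chars == "A"), C = sum(chars == "C"),
              G = sum(chars == "G"), T = sum(chars == "T"))
  n <- sum(counts)
  if (n == 0L) stop("sequence contains no unambiguous A/C/G/T bases")
  structure(
    c(as.list(counts / n),
      list(n_sites = n, n_ambiguous = length(chars) - n)),
    class = "BaseComposition")
}

#' @export
print.BaseComposition <- function(x, ...) {
  cat(sprintf("<BaseComposition over %d sites: A=%.3f C=%.3f G=%.3f T=%.3f (%d ambiguous)>\n",
              x$n_sites, x$A, x$C, x$G, x$T, x$n_ambiguous))
  invisible(x)
}

#' Four-fold degenerate codon boxes of a genetic code
#'
#' Returns the dinucleotide prefixes XY for which all four codons XYA, XYC,
#' XYG, XYT encode the same amino acid and none is a stop; the third
#' position of such codons is a four-fold degenerate (fully synonymous)
#' site.
#'
#' @param genetic_code Named character vector mapping all 64 codons to
#'   one-letter amino acids (`*` for stops); defaults to the standard code.
#' @return Sorted character vector of prefixes (8 for the standard code).
#' @export
fourfold_codon_set <- function(genetic_code = Biostrings::GENETIC_CODE) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  if (!all(all_codons %in% names(genetic_code)))
    stop("genetic code table is incomplete: all 64 codons are required")
  prefixes <- as.vector(outer(bases, bases, paste0))
  keep <- vapply(prefixes, function(p) {
    aas <- genetic_code[paste0(p, bases)]
    length(unique(aas)) == 1L && !any(aas == "*")
  }, logical(1))
  sort(prefixes[keep])
}

#' Base composition at four-fold degenerate third positions
#'
#' Pools the third-position bases of all codons whose prefix lies in the
#' four-fold degenerate set, across all supplied coding sequences of a
#' genome, and computes the base composition of that pool. Codons
#' containing ambiguity codes are skipped; coding sequences whose length is
#' not a multiple of three are dropped with a warning.
#'
#' @param cds_list Character vector of in-frame coding-strand sequences.
#' @param genetic_code Genetic code table (standard code by default).
#' @return A `BaseComposition` with an extra field `n_codons`, the number of
#'   four-fold degenerate codons pooled.
#' @export
fourfold_site_composition <- function(cds_list,
                                      genetic_code = Biostrings::GENETIC_CODE) {
  cds_list <- as.character(cds_list)
  if (length(cds_list) == 0L)
    stop("no CDS supplied: cannot compute four-fold site composition")
  ok_len <- nchar(cds_list) %% 3L == 0L & nchar(cds_list) > 0L
  if (any(!ok_len))
    warning(sprintf("%d CDS with length not divisible by 3 skipped",
                    sum(!ok_len)))
  cds_list <- cds_list[ok_len]
  if (length(cds_list) == 0L)
    stop("no CDS supplied: cannot compute four-fold site composition")
  ffset <- fourfold_codon_set(genetic_code)
  third <- unlist(lapply(cds_list, function(s) {
    s <- chartr("Uu", "Tt", toupper(s))
    starts <- seq(1L, nchar(s) - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    codons <- codons[!grepl("[^ACGT]", codons)]
    sel <- substr(codons, 1L, 2L) %in% ffset
    substr(codons[sel], 3L, 3L)
  }), use.names = FALSE)
  if (length(third) == 0L)
    stop("no four-fold degenerate codons found in the supplied CDS")
  comp <- base_composition(paste(third, collapse = ""))
  comp$n_codons <- length(third)
  comp
}

#' Fraction of coding positions covered by overlapping genes
#'
#' Computes, strand-agnostically, the fraction of genomic positions covered
#' by two or more CDS features. The default denominator is the number of
#' positions covered by at least one CDS; `denominator = "genome"` divides
#' by genome size instead (always <= the covered-denominator value).
#'
#' @param cds List of CDS features (as in a `GenomeRecord`); mat_peptide
#'   features are ignored since they lie inside their parent by definition.
#' @param genome_size Total genome length in nt.
#' @param denominator `"covered"` (default) or `"genome"`.
#' @return Overlap fraction in \[0, 1\]; 0 for an empty CDS list.
#' @export
overlap_fraction <- function(cds, genome_size,
                             denominator = c("covered", "genome")) {
  denominator <- match.arg(denominator)
  cds <- Filter(function(f) !isTRUE(f$is_mat_peptide), cds)
  if (length(cds) == 0L) return(0)
  seg <- vapply(cds, `[[`, character(1), "segment")
  covered <- 0L
  depth2 <- 0L
  for (s in unique(seg)) {
    ivs <- do.call(rbind, lapply(cds[seg == s], `[[`, "intervals"))
    ir <- IRanges(start = as.integer(ivs[, 1]) + 1L,
                  end = as.integer(ivs[, 2]))
    covered <- covered + sum(width(reduce(ir)))
    cov <- coverage(ir)
    depth2 <- depth2 + sum(runLength(cov)[runValue(cov) >= 2L])
  }
  if (denominator == "covered") {
    if (covered == 0L) return(0)
    depth2 / covered
  } else {
    depth2 / genome_size
  }
}

#' Composition summary of one genome
#'
#' Total-site base composition on the deposited strand (pooled across
#' segments), four-fold degenerate third-position composition pooled over
#' the genome's CDS (coding strand), and the gene-overlap fraction.
#'
#' @param genome A `GenomeRecord`.
#' @inheritParams overlap_fraction
#' @inheritParams fourfold_site_composition
#' @return Object of class `GenomeCompositionSummary`: list with `accession`,
#'   `total` and `fourfold` (`BaseComposition`), `n_fourfold_codons` and
#'   `overlap_fraction`. When no four-fold codon exists the `fourfold`
#'   fields are `NA` with a warning rather than an error, so corpus-level
#'   tables stay total.
#' @export
genome_composition <- function(genome,
                               genetic_code = Biostrings::GENETIC_CODE,
                               denominator = c("covered", "genome")) {
  total <- base_composition(paste(unlist(genome$segments), collapse = ""))
  main <- Filter(function(f) !isTRUE(f$is_mat_peptide) && isTRUE(f$length_ok),
                 genome$cds)
  cds_seqs <- vapply(main, function(f)
    extract_feature_seq(genome$segments[[f$segment]], f$intervals, f$strand),
    character(1))
  ff <- tryCatch(fourfold_site_composition(cds_seqs, genetic_code),
                 error = function(e) {
                   warning(sprintf("genome '%s': %s", genome$accession,
                                   conditionMessage(e)))
                   NULL
                 })
  structure(
    list(accession = genome$accession, total = total, fourfold = ff,
         n_fourfold_codons = if (is.null(ff)) 0L else ff$n_codons,
         overlap_fraction = overlap_fraction(genome$cds, genome$genome_size,
                                             denominator)),
    class = "GenomeCompositionSummary")
}

#' Per-genome composition table for a corpus
#'
#' @param genomes List of `GenomeRecord` objects.
#' @inheritParams genome_composition
#' @return Data frame with one row per genome: `accession`, total-site
#'   fractions `A`, `C`, `G`, `T`, four-fold fractions `A4`, `C4`, `G4`,
#'   `T4`, `n_fourfold_codons` and `overlap_fraction`.
#' @export
composition_table <- function(genomes,
                              genetic_code = Biostrings::GENETIC_CODE,
                              denominator = c("covered", "genome")) {
  rows <- lapply(genomes, function(g) {
    cs <- genome_composition(g, genetic_code, denominator)
    data.frame(
      accession = cs$accession,
      A = cs$total$A, C = cs$total$C, G = cs$total$G, T = cs$total$T,
      A4 = if (is.null(cs$fourfold)) NA_real_ else cs$fourfold$A,
      C4 = if (is.null(cs$fourfold)) NA_real_ else cs$fourfold$C,
      G4 = if (is.null(cs$fourfold)) NA_real_ else cs$fourfold$G,
      T4 = if (is.null(cs$fourfold)) NA_real_ else cs$fourfold$T,
      n_fourfold_codons = cs$n_fourfold_codons,
      overlap_fraction = cs$overlap_fraction,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
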