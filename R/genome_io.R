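#' @importFrom utils head read.delim write.table
#' @importFrom stats median setNames
NULL

BALTIMORE_TYPES <- c("ssDNA", "dsDNA", "ssRNAp", "ssRNAn", "dsRNA",
                     "ssRNA-RT", "dsDNA-RT", "satellite")

#' Assemble genome records from a GenBank flat file
#'
#' Parses a multi-record GenBank flat file and assembles one `GenomeRecord`
#' per genome. Records sharing a `segment_group` value in the metadata table
#' are merged into one multi-segment genome; without a grouping column every
#' LOCUS is its own genome. CDS translations are taken from the
#' `/translation` qualifier when present and otherwise translated from the
#' coordinates with the configured genetic code; when both are available and
#' disagree, a warning is raised and the annotated translation is kept.
#' `mat_peptide` features are attached to the CDS that contains them
#' (same segment, same strand, coordinate containment).
#'
#' @param path Path to a GenBank flat file (or a character vector of lines
#'   via `text`).
#' @param metadata Optional data frame with columns `accession`, `family`,
#'   `baltimore_type`, `host_category` and optionally `segment_group`.
#' @param text GenBank text given directly instead of `path`.
#' @param genetic_code Genetic code table for in-house translation (NCBI
#'   table 1 by default).
#' @return List of `GenomeRecord` objects. Each has fields `accession`,
#'   `family`, `baltimore_type`, `host_category`, `segments` (named list of
#'   nucleotide strings), `genome_size`, `cds` (list of CDS/mat_peptide
#'   features) and `proteins` (data frame with `protein_id`, `sequence`,
#'   `is_polyprotein`).
#' @export
parse_genome_records <- function(path = NULL, metadata = NULL, text = NULL,
                                 genetic_code = Biostrings::GENETIC_CODE) {
  lines <- if (is.null(text)) readLines(path) else text
  raw <- read_genbank_raw(lines)
  acc <- vapply(raw, `[[`, character(1), "accession")

  group <- acc
  if (!is.null(metadata) && "segment_group" %in% names(metadata)) {
    m <- match(acc, metadata$accession)
    sg <- metadata$segment_group[m]
    use <- !is.na(sg) & nzchar(sg)
    group[use] <- sg[use]
  }
  lapply(split(seq_along(raw), factor(group, levels = unique(group))),
         function(ix) assemble_genome(raw[ix], metadata, genetic_code))
}

assemble_genome <- function(records, metadata, genetic_code) {
  segments <- lapply(records, `[[`, "sequence")
  names(segments) <- vapply(records, `[[`, character(1), "accession")
  accession <- names(segments)[1L]
  meta <- list(family = NA_character_, baltimore_type = NA_character_,
               host_category = NA_character_)
  if (!is.null(metadata)) {
    m <- match(names(segments)[1L], metadata$accession)
    if (!is.na(m)) {
      meta$family <- as.character(metadata$family[m])
      meta$baltimore_type <- as.character(metadata$baltimore_type[m])
      meta$host_category <- as.character(metadata$host_category[m])
      if ("segment_group" %in% names(metadata) &&
          !is.na(metadata$segment_group[m]) && nzchar(metadata$segment_group[m]))
        accession <- as.character(metadata$segment_group[m])
    }
  }
  if (!is.na(meta$baltimore_type) &&
      !meta$baltimore_type %in% BALTIMORE_TYPES)
    stop(sprintf("genome '%s': unknown Baltimore type '%s'",
                 accession, meta$baltimore_type))

  cds <- list()
  nts <- character()
  annots <- character()          # /translation qualifier or NA
  loci <- character()
  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    seg_name <- rec$accession
    for (f in rec$features) {
      if (!f$key %in% c("CDS", "mat_peptide")) next
      if (max(f$intervals[, 2]) > rec$length || min(f$intervals[, 1]) < 0)
        stop(sprintf("LOCUS '%s': feature coordinates outside the segment",
                     rec$locus))
      clen <- sum(f$intervals[, 2] - f$intervals[, 1])
      feat <- list(
        segment = seg_name, strand = f$strand, intervals = f$intervals,
        product = if (!is.null(f$qualifiers$product)) f$qualifiers$product else NA_character_,
        protein_id = if (!is.null(f$qualifiers$protein_id)) f$qualifiers$protein_id else NA_character_,
        is_mat_peptide = identical(f$key, "mat_peptide"),
        parent_protein_id = NA_character_,
        length_ok = (clen %% 3L == 0L) || identical(f$key, "mat_peptide"),
        translation = NA_character_)
      if (!feat$length_ok)
        warning(sprintf("LOCUS '%s': CDS length %d not divisible by 3",
                        rec$locus, clen))
      cds[[length(cds) + 1L]] <- feat
      nts[length(cds)] <- extract_feature_seq(rec$sequence, f$intervals,
                                              f$strand)
      ann <- f$qualifiers$translation
      annots[length(cds)] <- if (!is.null(ann) &&
                                 !identical(f$key, "mat_peptide"))
        ann else NA_character_
      loci[length(cds)] <- rec$locus
    }
  }
  if (length(cds)) {
    inhouse <- translate_cds(nts, genetic_code)   # one batched call
    for (i in seq_along(cds)) {
      if (!is.na(annots[i])) {
        if (!identical(annots[i], inhouse[i]))
          warning(sprintf(
            "LOCUS '%s': /translation conflicts with coordinate translation; annotation kept",
            loci[i]))
        cds[[i]]$translation <- annots[i]
      } else {
        cds[[i]]$translation <- inhouse[i]
      }
    }
  }
  cds <- attach_mat_peptides(cds)

  main <- !vapply(cds, `[[`, logical(1), "is_mat_peptide")
  has_pep <- vapply(seq_along(cds), function(i)
    any(vapply(cds, function(f)
      identical(f$parent_protein_id, cds[[i]]$protein_id) &&
        isTRUE(f$is_mat_peptide), logical(1))), logical(1))
  proteins <- data.frame(
    protein_id = vapply(cds[main], `[[`, character(1), "protein_id"),
    sequence = vapply(cds[main], `[[`, character(1), "translation"),
    is_polyprotein = has_pep[main],
    stringsAsFactors = FALSE)

  structure(
    list(accession = accession, family = meta$family,
         baltimore_type = meta$baltimore_type,
         host_category = meta$host_category,
         segments = segments,
         genome_size = sum(vapply(segments, nchar, integer(1))),
         cds = cds, proteins = proteins),
    class = "GenomeRecord")
}

# Assign each mat_peptide a parent CDS by coordinate containment on the same
# segment and strand; fill in default protein ids where absent.
attach_mat_peptides <- function(cds) {
  if (length(cds) == 0L) return(cds)
  for (i in seq_along(cds)) {
    if (is.na(cds[[i]]$protein_id))
      cds[[i]]$protein_id <- sprintf("cds_%03d", i)
  }
  main_ix <- which(!vapply(cds, `[[`, logical(1), "is_mat_peptide"))
  for (i in seq_along(cds)) {
    f <- cds[[i]]
    if (!f$is_mat_peptide) next
    for (j in main_ix) {
      p <- cds[[j]]
      if (identical(p$segment, f$segment) && identical(p$strand, f$strand) &&
          min(f$intervals[, 1]) >= min(p$intervals[, 1]) &&
          max(f$intervals[, 2]) <= max(p$intervals[, 2])) {
        cds[[i]]$parent_protein_id <- p$protein_id
        break
      }
    }
  }
  cds
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("<GenomeRecord %s: %s/%s, %d nt in %d segment(s), %d protein(s)>\n",
              x$accession, x$family, x$baltimore_type, x$genome_size,
              length(x$segments), nrow(x$proteins)))
  invisible(x)
}

total_residues <- function(genome)
  sum(nchar(genome$proteins$sequence))

#' Siegel repeated-median regression
#'
#' Robust straight-line fit: for each point the median pairwise slope to all
#' other points is taken, the overall slope is the median of those medians,
#' and the intercept is the median of `y - slope * x`. Breakdown point 50%,
#' which is what lets the annotation QC detect gross outliers without being
#' pulled by them.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @return List with `slope` and `intercept`.
#' @export
siegel_regression <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  med_i <- vapply(seq_len(n), function(i) {
    s <- (y[-i] - y[i]) / (x[-i] - x[i])
    s <- s[is.finite(s)]
    if (length(s) == 0L) return(NA_real_)
    median(s)
  }, numeric(1))
  slope <- median(med_i, na.rm = TRUE)
  list(slope = slope, intercept = median(y - slope * x))
}

#' Flag genomes whose annotated residue count is inconsistent with size
#'
#' Fits a robust log10-log10 trend of total encoded residues versus genome
#' size (Siegel repeated-median regression) and flags genomes whose residual
#' from the trend exceeds `k` median absolute deviations: over-annotated
#' genomes as `excess_residues`, under-annotated ones as `deficit_residues`.
#'
#' @param genomes List of `GenomeRecord` objects (>= 10, otherwise the trend
#'   has too little support and an error instructs the caller to skip QC).
#' @param k MAD multiplier (default 3).
#' @return Named character vector (accession -> one of `ok`,
#'   `excess_residues`, `deficit_residues`).
#' @export
qc_residue_vs_genome <- function(genomes, k = 3) {
  if (length(genomes) < 10L)
    stop("fewer than 10 genomes: skip the residue-vs-size QC")
  size <- vapply(genomes, `[[`, numeric(1), "genome_size")
  res <- vapply(genomes, total_residues, numeric(1))
  if (any(res <= 0))
    res[res <= 0] <- 1          # log-safe; zero-protein genomes are extreme deficits
  x <- log10(size)
  y <- log10(res)
  fit <- siegel_regression(x, y)
  r <- y - (fit$intercept + fit$slope * x)
  r <- r - median(r)
  s <- 1.4826 * median(abs(r))
  cut <- k * s + 1e-8           # guard for exactly-on-trend synthetic sets
  out <- rep("ok", length(genomes))
  out[r > cut] <- "excess_residues"
  out[r < -cut] <- "deficit_residues"
  names(out) <- vapply(genomes, `[[`, character(1), "accession")
  out
}

#' Apply the survey inclusion filters
#'
#' Removes satellite viruses and QC-flagged genomes from the analysis set
#' and determines which families are large enough for family-level tables.
#' Under the `flag-family` policy (the default) every member of a family
#' containing a QC-flagged genome is excluded; `flag-genome` drops only the
#' flagged genomes themselves. Families with `min_family_size` or fewer
#' members are kept in the all-virus analysis set but omitted from the list
#' of tabulated families (strictly-greater-than rule).
#'
#' @param genomes List of `GenomeRecord` objects carrying family and
#'   Baltimore type.
#' @param flags Optional result of [qc_residue_vs_genome()].
#' @param min_family_size Families must exceed this size to be tabulated
#'   (default 10).
#' @param qc_policy `"flag-family"` or `"flag-genome"`.
#' @return Object of class `SurveySet`: list with `genomes` (analysis set),
#'   `exclusions` (named character vector accession -> `satellite` or
#'   `qc_outlier`), `tabulated_families`, `min_family_size`.
#' @export
build_survey_set <- function(genomes, flags = NULL, min_family_size = 10L,
                             qc_policy = c("flag-family", "flag-genome")) {
  qc_policy <- match.arg(qc_policy)
  acc <- vapply(genomes, `[[`, character(1), "accession")
  fam <- vapply(genomes, `[[`, character(1), "family")
  type <- vapply(genomes, `[[`, character(1), "baltimore_type")
  if (anyNA(fam) || anyNA(type))
    stop("every genome must carry family and baltimore_type metadata")

  reason <- setNames(rep(NA_character_, length(genomes)), acc)
  reason[type == "satellite"] <- "satellite"
  if (!is.null(flags)) {
    flagged <- names(flags)[flags != "ok"]
    if (qc_policy == "flag-family") {
      bad_fam <- unique(fam[acc %in% flagged])
      hit <- fam %in% bad_fam & is.na(reason)
    } else {
      hit <- acc %in% flagged & is.na(reason)
    }
    reason[hit] <- "qc_outlier"
  }
  keep <- is.na(reason)
  kept_fam <- fam[keep]
  tab <- table(kept_fam)
  structure(
    list(genomes = genomes[keep],
         exclusions = reason[!keep],
         tabulated_families = sort(names(tab)[tab > min_family_size]),
         min_family_size = as.integer(min_family_size)),
    class = "SurveySet")
}

#' @export
print.SurveySet <- function(x, ...) {
  cat(sprintf("<SurveySet: %d genomes (%d excluded), %d tabulated families>\n",
              length(x$genomes), length(x$exclusions),
              length(x$tabulated_families)))
  invisible(x)
}

#' Write the per-genome survey table
#'
#' One row per input genome (analysis set and exclusions alike) with
#' accession, family, type, host, size, protein and residue counts and the
#' exclusion reason, so that stage counts are conserved.
#'
#' @param survey A [build_survey_set()] result.
#' @param all_genomes The full pre-filter genome list (to report exclusions).
#' @param path Output TSV path.
#' @return The table, invisibly.
#' @export
write_survey_set <- function(survey, all_genomes, path) {
  rows <- lapply(all_genomes, function(g) data.frame(
    accession = g$accession, family = g$family,
    baltimore_type = g$baltimore_type, host_category = g$host_category,
    size_nt = g$genome_size, n_proteins = nrow(g$proteins),
    n_residues = total_residues(g),
    exclusion_reason = if (g$accession %in% names(survey$exclusions))
      survey$exclusions[[g$accession]] else "",
    stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Write / read a genome set as metadata TSV plus protein FASTA
#'
#' Compact interchange representation: `genomes.tsv` holds accession,
#' family, Baltimore type, host and per-segment lengths; `proteins.fasta`
#' holds every protein as `accession|protein_id`. Reading it back
#' reconstructs the survey-relevant fields (sequences of the genome itself
#' are not retained; use [write_genbank()] for full fidelity).
#'
#' @param genomes List of `GenomeRecord` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_set <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- do.call(rbind, lapply(genomes, function(g) data.frame(
    accession = g$accession, family = g$family,
    baltimore_type = g$baltimore_type, host_category = g$host_category,
    genome_size = g$genome_size,
    segment_lengths = paste(vapply(g$segments, nchar, integer(1)),
                            collapse = ","),
    stringsAsFactors = FALSE)))
  write.table(meta, file.path(dir, "genomes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  seqs <- unlist(lapply(genomes, function(g) {
    if (nrow(g$proteins) == 0L) return(character())
    setNames(g$proteins$sequence,
             paste(g$accession, g$proteins$protein_id, sep = "|"))
  }))
  writeXStringSet(AAStringSet(seqs), file.path(dir, "proteins.fasta"))
  invisible(dir)
}

#' @rdname write_genome_set
#' @export
read_genome_set <- function(dir) {
  meta <- read.delim(file.path(dir, "genomes.tsv"), stringsAsFactors = FALSE)
  aa <- readAAStringSet(file.path(dir, "proteins.fasta"))
  ids <- strsplit(names(aa), "|", fixed = TRUE)
  pacc <- vapply(ids, `[[`, character(1), 1L)
  pid <- vapply(ids, `[[`, character(1), 2L)
  lapply(seq_len(nrow(meta)), function(i) {
    sel <- pacc == meta$accession[i]
    seg_len <- as.integer(strsplit(as.character(meta$segment_lengths[i]),
                                   ",")[[1L]])
    structure(
      list(accession = meta$accession[i], family = meta$family[i],
           baltimore_type = meta$baltimore_type[i],
           host_category = meta$host_category[i],
           segments = setNames(vector("list", length(seg_len)),
                               paste0(meta$accession[i], "_S", seq_along(seg_len))),
           segment_lengths = seg_len,
           genome_size = meta$genome_size[i],
           cds = list(),
           proteins = data.frame(protein_id = pid[sel],
                                 sequence = as.character(aa[sel]),
                                 is_polyprotein = FALSE,
                                 stringsAsFactors = FALSE)),
      class = "GenomeRecord")
  })
}
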