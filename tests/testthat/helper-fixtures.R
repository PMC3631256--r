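# Shared fixtures. Corpora are memoised so expensive builds run once per
# test session regardless of how many files use them.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The default study corpus (all families, planted outliers), fixed seed.
default_corpus <- function() {
  memoise_fixture("default_corpus", function()
    simulate_corpus(default_config(), seed = 20100510 %% 99991))
}

# Post-QC analysis objects for the default corpus.
default_analysis <- function() {
  memoise_fixture("default_analysis", function() {
    corp <- default_corpus()
    flags <- qc_residue_vs_genome(corp$genomes)
    survey <- build_survey_set(corp$genomes, flags)
    dis <- disorder_table(survey$genomes)
    comp <- composition_table(survey$genomes)
    list(corpus = corp, flags = flags, survey = survey,
         disorder = dis, composition = comp,
         obs = make_observations(survey$genomes, dis, comp))
  })
}

# A small three-family corpus for fast structural tests.
small_config <- function() {
  cfg <- default_config()[c(1, 4, 7, 16), ]   # small ssDNA, polyprotein-rich
  cfg$n_genomes <- c(12L, 12L, 8L, 4L)        # ssRNAp, segmented, satellites
  cfg
}

small_corpus <- function() {
  memoise_fixture("small_corpus", function() simulate_corpus(small_config(), seed = 424L))
}

small_corpus_dir <- function() {
  memoise_fixture("small_corpus_dir", function() {
    d <- file.path(tempdir(), "virodisorder-small-corpus")
    write_corpus(small_corpus(), d)
    d
  })
}

# Independent oracle: a codon prefix is four-fold degenerate iff every
# third-base substitution leaves the translation unchanged and stop-free.
brute_force_fourfold <- function(code) {
  bases <- c("A", "C", "G", "T")
  out <- character()
  for (b1 in bases) for (b2 in bases) {
    aas <- vapply(bases, function(b3) unname(code[paste0(b1, b2, b3)]), "")
    if (length(unique(aas)) == 1 && all(aas != "*"))
      out <- c(out, paste0(b1, b2))
  }
  sort(out)
}

# Independent oracle: naive double-loop windowed mean pairwise energy.
naive_scores <- function(sequence, spec) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  aa20 <- names(disorder_propensity())
  half <- (spec$window - 1) %/% 2
  n <- length(chars)
  sapply(seq_len(n), function(r) {
    if (!chars[r] %in% aa20) return(spec$neutral_score)
    win <- max(1, r - half):min(n, r + half)
    win <- win[chars[win] %in% aa20]
    if (length(win) == 0) return(spec$neutral_score)
    e <- mean(sapply(win, function(j) spec$energy[chars[r], chars[j]]))
    stats::plogis((-e - spec$midpoint) / spec$tau)
  })
}

# A hand-built GenBank record: 1200 nt, one plus-strand CDS (301..600),
# one minus-strand CDS, and a polyprotein (601..1200, minus stop) with
# three mat_peptides.
fixture_genbank <- function() {
  set.seed(99)
  prot1 <- suppressWarnings(synth_protein(99, 0.5))
  nt1 <- paste0(back_translate(prot1, c(A = .25, C = .25, G = .25, T = .25)),
                "TAA")
  prot2 <- synth_protein(60, 0)
  nt2 <- paste0(back_translate(prot2, c(A = .25, C = .25, G = .25, T = .25)),
                "TGA")
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  poly <- synth_protein(180, 0.4)
  nt3 <- paste0(back_translate(poly, c(A = .25, C = .25, G = .25, T = .25)),
                "TAG")
  seqs <- list(
    head = paste(sample(c("A", "C", "G", "T"), 57, TRUE), collapse = ""),
    cds1 = nt1,                       # 301..600 needs 300 nt at offset 300
    mid = paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
    cds2 = rc(nt2),                   # minus strand
    poly = nt3)
  full <- paste(unlist(seqs), collapse = "")
  o1 <- nchar(seqs$head)                                # cds1 0-based start
  o2 <- o1 + nchar(nt1) + nchar(seqs$mid)
  o3 <- o2 + nchar(seqs$cds2)
  lines <- c(
    sprintf("LOCUS       FIX00001             %d bp    DNA     linear   VRL 01-JAN-2000",
            nchar(full)),
    "DEFINITION  hand-built fixture record.",
    "ACCESSION   FIX00001",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(full)),
    sprintf("     CDS             %d..%d", o1 + 1, o1 + nchar(nt1)),
    "                     /protein_id=\"fix_p1\"",
    sprintf("                     /translation=\"%s\"", prot1),
    sprintf("     CDS             complement(%d..%d)", o2 + 1, o2 + nchar(seqs$cds2)),
    "                     /protein_id=\"fix_p2\"",
    sprintf("     CDS             %d..%d", o3 + 1, o3 + nchar(nt3)),
    "                     /protein_id=\"fix_poly\"",
    sprintf("                     /translation=\"%s\"", poly),
    sprintf("     mat_peptide     %d..%d", o3 + 1, o3 + 180),
    "                     /protein_id=\"fix_m1\"",
    sprintf("     mat_peptide     %d..%d", o3 + 181, o3 + 360),
    "                     /protein_id=\"fix_m2\"",
    sprintf("     mat_peptide     %d..%d", o3 + 361, o3 + 540),
    "                     /protein_id=\"fix_m3\"",
    "ORIGIN",
    virodisorder:::format_origin(full),
    "//")
  list(lines = lines, prot1 = prot1, prot2 = prot2, poly = poly,
       full = full, cds1_start0 = o1, len = nchar(full))
}

fixture_metadata <- function(accession = "FIX00001") {
  data.frame(accession = accession, family = "Fixvirus",
             baltimore_type = "dsDNA", host_category = "Vertebrates",
             segment_group = "", stringsAsFactors = FALSE)
}
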