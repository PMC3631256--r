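#' @importFrom Biostrings DNAString DNAStringSet translate reverseComplement
#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
NULL

# --- location strings ---------------------------------------------------

# Parse a GenBank location string ("101..1300", "join(1..30,40..60)",
# "complement(join(...))", with <,> partial markers tolerated) into a list
# with `strand` and an integer matrix of 0-based half-open intervals in
# ascending genomic order. GenBank coordinates are 1-based inclusive; this
# is the single point where the convention is converted.
parse_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  if (grepl("[a-z(]", loc))
    stop(sprintf("unsupported location string: '%s'", loc))
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  ivs <- t(vapply(parts, function(p) {
    ab <- as.numeric(strsplit(p, "..", fixed = TRUE)[[1L]])
    if (length(ab) == 1L) ab <- c(ab, ab)
    if (anyNA(ab) || ab[1] > ab[2]) stop(sprintf("bad span '%s'", p))
    c(ab[1] - 1, ab[2])            # 0-based half-open
  }, numeric(2)))
  dimnames(ivs) <- list(NULL, c("start", "end"))
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  list(strand = strand, intervals = ivs)
}

format_location <- function(strand, intervals) {
  spans <- apply(intervals, 1L, function(iv)
    sprintf("%d..%d", as.integer(iv[1]) + 1L, as.integer(iv[2])))
  loc <- if (length(spans) > 1L)
    sprintf("join(%s)", paste(spans, collapse = ",")) else spans
  if (strand == "-") sprintf("complement(%s)", loc) else loc
}

# --- flat-file reading --------------------------------------------------

# Split GenBank flat-file lines into raw records: accession, declared
# length, sequence (U normalised to T), and a list of features (key,
# strand, intervals, qualifiers).
read_genbank_raw <- function(lines) {
  ends <- grep("^//", lines)
  if (length(ends) == 0L) stop("no GenBank record terminator '//' found")
  starts <- c(1L, ends[-length(ends)] + 1L)
  lapply(seq_along(ends), function(i) {
    block <- lines[starts[i]:ends[i]]
    block <- block[nzchar(trimws(block)) | seq_along(block) == length(block)]
    parse_one_record(block)
  })
}

parse_one_record <- function(block) {
  locus_line <- grep("^LOCUS", block, value = TRUE)
  if (length(locus_line) == 0L) stop("record without LOCUS line")
  fl <- strsplit(trimws(locus_line[1L]), "[[:space:]]+")[[1L]]
  locus <- fl[2]
  declared_len <- suppressWarnings(as.integer(fl[3]))
  if (is.na(declared_len))
    stop(sprintf("malformed LOCUS line for '%s': missing length", locus))
  acc_line <- grep("^ACCESSION", block, value = TRUE)
  accession <- if (length(acc_line))
    strsplit(trimws(acc_line[1L]), "[[:space:]]+")[[1L]][2] else locus
  if (is.na(accession)) accession <- locus

  fstart <- grep("^FEATURES", block)
  ostart <- grep("^ORIGIN", block)
  if (length(ostart) == 0L)
    stop(sprintf("record '%s' has no ORIGIN section", locus))
  features <- list()
  if (length(fstart)) {
    flines <- block[(fstart[1L] + 1L):(ostart[1L] - 1L)]
    features <- parse_feature_table(flines, locus)
  }
  seq_lines <- block[(ostart[1L] + 1L):length(block)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- chartr("U", "T", sequence)
  if (nchar(sequence) != declared_len)
    warning(sprintf("LOCUS '%s': declared length %d but %d bases read",
                    locus, declared_len, nchar(sequence)))
  list(accession = accession, locus = locus, length = nchar(sequence),
       sequence = sequence, features = features)
}

parse_feature_table <- function(flines, locus) {
  is_key <- grepl("^ {1,10}[A-Za-z_'-]+ {2,}", flines) &
    !grepl("^ {12,}", flines)
  idx <- which(is_key)
  if (length(idx) == 0L) return(list())
  lapply(seq_along(idx), function(k) {
    from <- idx[k]
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(flines)
    chunk <- flines[from:to]
    head_parts <- strsplit(trimws(chunk[1L]), "[[:space:]]+")[[1L]]
    key <- head_parts[1L]
    rest <- trimws(sub(sprintf("^\\s*%s\\s*", key), "", chunk[1L]))
    cont <- if (length(chunk) > 1L) trimws(chunk[-1L]) else character()
    # location may continue over lines until the first qualifier
    qual_at <- which(startsWith(cont, "/"))
    loc_extra <- if (length(qual_at)) head(cont, qual_at[1L] - 1L) else cont
    loc_str <- paste(c(rest, loc_extra), collapse = "")
    quals <- list()
    if (length(qual_at)) {
      qlines <- cont[qual_at[1L]:length(cont)]
      starts <- which(startsWith(qlines, "/"))
      for (qi in seq_along(starts)) {
        qfrom <- starts[qi]
        qto <- if (qi < length(starts)) starts[qi + 1L] - 1L else length(qlines)
        qtext <- paste(qlines[qfrom:qto], collapse = if (qi) "" else "")
        qtext <- sub("^/", "", qtext)
        eq <- regexpr("=", qtext, fixed = TRUE)
        if (eq > 0) {
          qname <- substr(qtext, 1L, eq - 1L)
          qval <- substr(qtext, eq + 1L, nchar(qtext))
          qval <- gsub("^\"|\"$", "", qval)
          if (qname == "translation") qval <- gsub("[[:space:]]", "", qval)
        } else {
          qname <- qtext
          qval <- TRUE
        }
        quals[[qname]] <- qval
      }
    }
    loc <- tryCatch(parse_location(loc_str), error = function(e)
      stop(sprintf("LOCUS '%s': %s", locus, conditionMessage(e))))
    list(key = key, strand = loc$strand, intervals = loc$intervals,
         qualifiers = quals)
  })
}

# --- sequence extraction / translation ----------------------------------

# Concatenate a feature's intervals from its segment sequence, in coding
# orientation (reverse-complemented for minus-strand features).
extract_feature_seq <- function(segment_seq, intervals, strand) {
  pieces <- apply(intervals, 1L, function(iv)
    substr(segment_seq, as.integer(iv[1]) + 1L, as.integer(iv[2])))
  nt <- paste(pieces, collapse = "")
  if (strand == "-") {
    comp <- chartr("ACGTRYKMBVDHacgtrykmbvdh",
                   "TGCAYRMKVBHDtgcayrmkvbhd", nt)
    nt <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }
  nt
}

translate_cds <- function(nt, genetic_code = Biostrings::GENETIC_CODE) {
  n3 <- (nchar(nt) %/% 3L) * 3L
  if (all(n3 == 0L)) return(character(length(nt)))
  aa <- as.character(translate(DNAStringSet(substr(nt, 1L, n3)),
                               genetic.code = genetic_code,
                               if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

# --- writing ------------------------------------------------------------

wrap_qualifier <- function(name, value, width = 58L) {
  text <- sprintf("/%s=\"%s\"", name, value)
  out <- character()
  while (nchar(text) > width) {
    out <- c(out, substr(text, 1L, width))
    text <- substr(text, width + 1L, nchar(text))
  }
  c(out, text)
}

format_origin <- function(sequence) {
  n <- nchar(sequence)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    line <- substr(sequence, s, min(n, s + 59L))
    blocks <- substring(line, seq(1L, nchar(line), 10L),
                        pmin(nchar(line), seq(10L, nchar(line) + 9L, 10L)))
    sprintf("%9d %s", s, tolower(paste(blocks, collapse = " ")))
  }, character(1))
}

#' Write genome records as a multi-record GenBank flat file
#'
#' Serialises each segment of each [GenomeRecord] as one LOCUS with its CDS
#' and mat_peptide features (product, protein_id and translation
#' qualifiers), so that the corpus round-trips through
#' [parse_genome_records()].
#'
#' @param genomes List of `GenomeRecord` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genomes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (g in genomes) {
    for (si in seq_along(g$segments)) {
      seg_name <- names(g$segments)[si]
      seg_seq <- g$segments[[si]]
      lines <- c(
        sprintf("LOCUS       %-16s %d bp    DNA     linear   VRL 01-JAN-2000",
                seg_name, nchar(seg_seq)),
        sprintf("DEFINITION  %s synthetic viral genome segment.", g$family),
        sprintf("ACCESSION   %s", seg_name),
        "FEATURES             Location/Qualifiers",
        sprintf("     source          1..%d", nchar(seg_seq)))
      for (f in g$cds) {
        if (!identical(f$segment, seg_name)) next
        key <- if (isTRUE(f$is_mat_peptide)) "mat_peptide" else "CDS"
        lines <- c(lines,
          sprintf("     %-15s %s", key, format_location(f$strand, f$intervals)))
        qual_lines <- character()
        if (!is.null(f$product) && !is.na(f$product))
          qual_lines <- c(qual_lines, wrap_qualifier("product", f$product))
        if (!is.null(f$protein_id) && !is.na(f$protein_id))
          qual_lines <- c(qual_lines, wrap_qualifier("protein_id", f$protein_id))
        if (!isTRUE(f$is_mat_peptide) && !is.null(f$translation) &&
            !is.na(f$translation))
          qual_lines <- c(qual_lines, wrap_qualifier("translation", f$translation))
        lines <- c(lines, paste0(strrep(" ", 21L), qual_lines))
      }
      lines <- c(lines, "ORIGIN", format_origin(seg_seq), "//")
      writeLines(lines, con)
    }
  }
  invisible(path)
}
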