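#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

# Residue pools used by the generator: strongly order-promoting and strongly
# disorder-promoting under the packaged propensity scale, chosen far enough
# from the score threshold that block-built proteins are called exactly
# block-wise by the default predictor.
.ORDER_POOL <- c("W", "F", "Y", "I", "M")
.DISORDER_POOL <- c("P", "E", "K", "S", "Q")

#' Default synthetic corpus configuration
#'
#' One row per synthetic viral family, emulating the between- and
#' within-family structure of a real survey corpus: family mean disorder
#' spanning roughly 3-30%, genome sizes from 2 kb to 150 kb, every
#' Baltimore class represented, size-disorder correlations of both signs,
#' one segmented family, a small satellite group, and one family flagged to
#' receive planted annotation outliers (two genomes with 10x excess encoded
#' residues, one with a 10x deficit). Synonymous composition bias is
#' coupled to the family disorder level (C-favouring and T-avoiding as
#' disorder rises), so the generator reproduces the qualitative
#' disorder-composition sign pattern at both site classes.
#'
#' @return Data frame of class `family_truth` with columns `family`,
#'   `baltimore_type`, `host_category`, `n_genomes`, `mean_log_size`,
#'   `sd_log_size`, `target_mean_D`, `sd_D`, `size_disorder_rho`,
#'   `bias_A`, `bias_C`, `bias_G`, `bias_T`, `overlap_target`,
#'   `n_segments`, `plant_outliers`.
#' @export
default_config <- function() {
  fam <- data.frame(
    family = c("Circolike", "Geminilike", "Anellolike", "Picornalike",
               "Virgalike", "Coronalike", "Bunyalike", "Rhabdolike",
               "Reolike", "Sipholike", "Herpeslike", "Poxlike",
               "Retrolike", "Caulilike", "Phycolike", "Satellitelike"),
    baltimore_type = c("ssDNA", "ssDNA", "ssDNA", "ssRNAp",
                       "ssRNAp", "ssRNAp", "ssRNAn", "ssRNAn",
                       "dsRNA", "dsDNA", "dsDNA", "dsDNA",
                       "ssRNA-RT", "dsDNA-RT", "dsDNA", "satellite"),
    host_category = c("Vertebrates", "Plants", "Vertebrates", "Vertebrates",
                      "Plants", "Vertebrates", "Vert/Invert", "Vert/Invert",
                      "Vert/Invert/Plants", "Bacteria", "Vertebrates",
                      "Vertebrates", "Vertebrates", "Plants", "Plants",
                      "Plants"),
    n_genomes = c(50L, 50L, 50L, 50L, 50L, 40L, 45L, 40L,
                  40L, 60L, 15L, 15L, 40L, 36L, 12L, 6L),
    mean_log_size = log(1000 * c(2.0, 3.6, 3.3, 7.7, 8.1, 29.3, 14.0, 12.4,
                                 23.5, 47.8, 150, 120, 8.4, 7.8, 30, 1.2)),
    sd_log_size = c(0.20, 0.15, 0.12, 0.06, 0.10, 0.05, 0.10, 0.10,
                    0.12, 0.20, 0.15, 0.15, 0.15, 0.06, 0.15, 0.10),
    target_mean_D = c(12.8, 18.6, 29.5, 6.5, 4.9, 3.7, 2.9, 7.3,
                      6.2, 12.8, 17.9, 5.6, 17.9, 14.6, 10.0, 15.0),
    sd_D = c(5.0, 3.1, 7.0, 2.5, 2.4, 1.3, 1.2, 1.3,
             1.5, 3.9, 5.4, 2.7, 6.0, 4.2, 3.0, 3.0),
    size_disorder_rho = c(0.10, -0.38, 0.25, 0.59, 0.78, 0.29, 0.06, -0.08,
                          0.16, 0.55, 0.48, 0.11, -0.17, 0.08, 0.20, 0.00),
    overlap_target = c(0.15, 0.20, 0.20, 0.15, 0.15, 0.10, 0.10, 0.05,
                       0.05, 0.05, 0.05, 0.05, 0.10, 0.10, 0.10, 0.10),
    n_segments = c(1L, 1L, 1L, 1L, 1L, 1L, 3L, 1L,
                   1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    plant_outliers = c(rep(FALSE, 14L), TRUE, FALSE),
    stringsAsFactors = FALSE)
  # synonymous bias coupled to the family disorder level
  d <- fam$target_mean_D
  fam$bias_C <- 0.15 + 0.012 * d
  fam$bias_T <- 0.45 - 0.012 * d
  fam$bias_G <- 0.20 + 0.002 * d
  fam$bias_A <- 1 - fam$bias_C - fam$bias_T - fam$bias_G
  class(fam) <- c("family_truth", "data.frame")
  fam
}

#' Write / read a generator configuration file
#'
#' Flat TSV with full-precision numerics (`%.17g`), so a configuration
#' round-trips losslessly.
#'
#' @param config A `family_truth` data frame.
#' @param path File path.
#' @return `read_config` returns the configuration; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  out <- config
  for (cc in names(out))
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ref <- default_config()
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = setNames(
                      vapply(ref, function(x) class(x)[1], character(1)),
                      names(ref))[
                        intersect(names(ref), names(read.delim(path, nrows = 1)))])
  class(tab) <- c("family_truth", "data.frame")
  tab
}

#' Synthesise a protein with a prescribed disorder fraction
#'
#' Builds a sequence from alternating blocks drawn from an order-promoting
#' and a disorder-promoting residue pool. Block lengths are at least three
#' times the predictor window (so windowed scores are block-wise clean),
#' except that a pool whose total residue count is below one block length
#' is placed as a single contiguous run; when the protein is too short to
#' hold one full block of each pool at all, the constraint is relaxed with
#' a warning. The disordered-pool share of residues equals
#' `disorder_fraction` up to stochastic rounding. Uses the session RNG.
#'
#' @param length Protein length in residues (>= predictor window).
#' @param disorder_fraction Target fraction in \[0, 1\].
#' @param window Predictor window the blocks must dominate (default 25).
#' @return Amino-acid string.
#' @export
synth_protein <- function(length, disorder_fraction, window = 25L) {
  stopifnot(length >= window, disorder_fraction >= 0, disorder_fraction <= 1)
  B <- 3L * window
  nd <- floor(length * disorder_fraction)
  if (runif(1) < length * disorder_fraction - nd) nd <- nd + 1L
  nd <- min(max(nd, 0L), length)
  no <- length - nd
  if (nd > 0L && no > 0L && length < 2L * B)
    warning("block-length constraint relaxed: protein too short for full blocks")
  rd <- nd; ro <- no
  cur <- sample(c("d", "o"), 1L, prob = c(max(nd, 1e-9), max(no, 1e-9)))
  pieces <- character()
  while (rd + ro > 0L) {
    if (cur == "d" && rd == 0L) cur <- "o"
    if (cur == "o" && ro == 0L) cur <- "d"
    if (cur == "d") {
      take <- min(rd, B + sample.int(B, 1L))
      pieces <- c(pieces, paste(sample(.DISORDER_POOL, take, replace = TRUE),
                                collapse = ""))
      rd <- rd - take
      cur <- "o"
    } else {
      take <- min(ro, B + sample.int(B, 1L))
      pieces <- c(pieces, paste(sample(.ORDER_POOL, take, replace = TRUE),
                                collapse = ""))
      ro <- ro - take
      cur <- "d"
    }
  }
  paste(pieces, collapse = "")
}

# Codon choices and sampling weights for one amino acid under a base bias:
# each synonymous codon is weighted by the product of the bias at the
# positions where the synonymous set varies.
codon_weights <- function(aa, bias, genetic_code) {
  codons <- names(genetic_code)[genetic_code == aa]
  if (length(codons) == 0L)
    stop(sprintf("no codon encodes residue '%s' in this genetic code", aa))
  if (length(codons) == 1L) return(list(codons = codons, w = 1))
  mat <- do.call(rbind, strsplit(codons, ""))
  varying <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
  w <- apply(mat[, varying, drop = FALSE], 1L, function(bb) prod(bias[bb]))
  if (sum(w) <= 0) w <- rep(1, length(codons))
  list(codons = codons, w = w)
}

#' Back-translate a protein under a synonymous base bias
#'
#' Chooses a synonymous codon for every residue with probability
#' proportional to the bias at the codon positions that vary within the
#' residue's synonymous set, so the third-position composition at four-fold
#' degenerate sites converges to the bias vector as length grows. The
#' resulting CDS translates back to the protein exactly.
#'
#' @param protein Amino-acid string (no stops).
#' @param bias Named non-negative vector `c(A=, C=, G=, T=)`.
#' @param genetic_code Genetic code table (standard code by default).
#' @return Nucleotide string of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein, bias,
                           genetic_code = Biostrings::GENETIC_CODE) {
  bias <- bias[c("A", "C", "G", "T")]
  if (anyNA(bias) || any(bias < 0) || sum(bias) <= 0)
    stop("`bias` must be a non-negative named A/C/G/T vector")
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  out <- character(length(aa))
  for (a in unique(aa)) {
    cw <- codon_weights(a, bias, genetic_code)
    pos <- which(aa == a)
    out[pos] <- if (length(cw$codons) == 1L) cw$codons else
      sample(cw$codons, length(pos), replace = TRUE, prob = cw$w)
  }
  paste(out, collapse = "")
}

sample_stop <- function(bias) {
  stops <- c("TAA", "TAG", "TGA")
  w <- vapply(stops, function(cd)
    bias[[substr(cd, 2, 2)]] * bias[[substr(cd, 3, 3)]], numeric(1))
  if (sum(w) <= 0) w <- rep(1, 3)
  sample(stops, 1L, prob = w)
}

random_nt <- function(n, bias) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = bias),
        collapse = "")
}

make_cds_feature <- function(segment, start0, end0, strand, protein_id,
                             translation, product = "hypothetical protein",
                             is_mat_peptide = FALSE,
                             parent_protein_id = NA_character_) {
  list(segment = segment, strand = strand,
       intervals = matrix(c(start0, end0), nrow = 1,
                          dimnames = list(NULL, c("start", "end"))),
       product = product, protein_id = protein_id,
       is_mat_peptide = is_mat_peptide,
       parent_protein_id = parent_protein_id,
       length_ok = TRUE, translation = translation)
}

# Build one synthetic genome: lay genes sequentially (with gaps) across the
# requested number of segments, add nested overlapping CDS to reach the
# family overlap target, optionally make the first gene a polyprotein with
# three mat_peptides, and apply planted annotation defects.
build_synth_genome <- function(accession, fam, size, target_D, bias,
                               with_polyprotein = FALSE,
                               outlier = c("none", "excess", "deficit"),
                               window = 25L) {
  outlier <- match.arg(outlier)
  frac <- target_D / 100
  min_gene_aa <- 160L          # >= two full predictor blocks
  # Budget the primary (non-overlapping) coding so that total encoded
  # residues, including the nested overlapping genes added below, come to
  # ~coding_frac * size / 3 regardless of the family overlap target; the
  # annotation QC then sees one common residue-vs-size trend, with
  # realistic per-genome scatter in coding density.
  coding_frac <- runif(1, 0.70, 0.95)
  coding_budget <- round(coding_frac * size / (1 + fam$overlap_target))

  # --- choose protein lengths to consume the budget -----------------------
  lengths <- integer()
  repeat {
    lengths <- c(lengths, max(min_gene_aa, round(exp(rnorm(1, log(260), 0.35)))))
    if (3 * sum(lengths + 1) + 40 * length(lengths) >= coding_budget) break
  }
  target_aa <- max(min_gene_aa,
                   (coding_budget - 40L * length(lengths)) %/% 3L -
                     length(lengths))
  if (with_polyprotein)
    lengths[1] <- max(330L, min(600L, lengths[1], target_aa))
  if (length(lengths) > 1L) {
    rest_aa <- target_aa - if (with_polyprotein) lengths[1] else 0L
    ix <- if (with_polyprotein) -1L else seq_along(lengths)
    if (rest_aa < min_gene_aa) {
      lengths <- lengths[1L] + max(0L, rest_aa)   # fold remainder into gene 1
    } else {
      sub <- lengths[ix]
      sub <- pmax(min_gene_aa, round(sub * rest_aa / sum(sub)))
      # trim genes that no longer fit after the minimum-length floor
      while (sum(sub) > rest_aa && length(sub) > 1L) sub <- sub[-length(sub)]
      sub[length(sub)] <- max(min_gene_aa,
                              sub[length(sub)] + rest_aa - sum(sub))
      lengths <- if (with_polyprotein) c(lengths[1], sub) else sub
    }
  } else {
    lengths[1] <- if (with_polyprotein) max(330L, target_aa) else target_aa
  }
  if (outlier == "deficit") {
    keep_aa <- max(min_gene_aa, round(size / 30))
    csum <- cumsum(lengths)
    k <- which(csum >= keep_aa)[1]
    if (is.na(k)) k <- length(lengths)
    lengths <- lengths[seq_len(k)]
  }
  n_genes <- length(lengths)

  # --- synthesise proteins and coding sequences -------------------------
  proteins <- vapply(lengths, function(L)
    synth_protein(L, frac, window), character(1))
  cds_nt <- vapply(seq_len(n_genes), function(i)
    paste0(back_translate(proteins[i], bias), sample_stop(bias)),
    character(1))

  # --- assign genes to segments and lay them out ------------------------
  nseg <- fam$n_segments
  seg_of <- rep(seq_len(nseg), length.out = n_genes)
  seg_names <- if (nseg == 1L) accession else
    paste0(accession, "S", seq_len(nseg))
  segments <- setNames(vector("list", nseg), seg_names)
  cds <- list()
  prot_rows <- list()
  coding_per_seg <- vapply(seq_len(nseg), function(s)
    sum(nchar(cds_nt[seg_of == s])), numeric(1))
  extra <- size - sum(nchar(cds_nt))
  filler_share <- if (nseg == 1L) extra else
    round(extra * (coding_per_seg + 1) / sum(coding_per_seg + 1))
  pid_n <- 0L
  for (s in seq_len(nseg)) {
    idx <- which(seg_of == s)
    gaps_n <- length(idx) + 1L
    gap_budget <- max(0L, if (nseg == 1L) extra else filler_share[s])
    gap_sizes <- if (gaps_n == 1L) gap_budget else {
      cuts <- sort(sample.int(max(gap_budget, 1L), gaps_n - 1L, replace = TRUE))
      diff(c(0L, cuts, gap_budget))
    }
    pos <- 0L
    pieces <- character()
    for (k in seq_along(idx)) {
      g <- idx[k]
      gap <- random_nt(gap_sizes[k], bias)
      pieces <- c(pieces, gap)
      pos <- pos + nchar(gap)
      start0 <- pos
      pieces <- c(pieces, cds_nt[g])
      pos <- pos + nchar(cds_nt[g])
      pid_n <- pid_n + 1L
      pid <- sprintf("%s_p%03d", accession, pid_n)
      cds[[length(cds) + 1L]] <- make_cds_feature(
        seg_names[s], start0, pos, "+", pid, proteins[g])
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        protein_id = pid, sequence = proteins[g],
        is_polyprotein = FALSE, stringsAsFactors = FALSE)
      if (with_polyprotein && g == 1L) {
        prot_rows[[length(prot_rows)]]$is_polyprotein <- TRUE
        L <- lengths[g]
        b1 <- L %/% 3L
        b2 <- 2L * (L %/% 3L)
        bounds <- rbind(c(0L, b1), c(b1, b2), c(b2, L))
        for (pp in seq_len(3L)) {
          ps <- start0 + 3L * bounds[pp, 1]
          pe <- start0 + 3L * bounds[pp, 2]
          cds[[length(cds) + 1L]] <- make_cds_feature(
            seg_names[s], ps, pe, "+",
            sprintf("%s_m%d", pid, pp),
            substr(proteins[g], bounds[pp, 1] + 1L, bounds[pp, 2]),
            product = "mature peptide", is_mat_peptide = TRUE,
            parent_protein_id = pid)
        }
      }
    }
    tail_gap <- random_nt(max(0L, gap_sizes[gaps_n]), bias)
    pieces <- c(pieces, tail_gap)
    segments[[s]] <- paste(pieces, collapse = "")
  }

  # --- nested overlapping CDS to reach the family overlap target --------
  covered <- sum(nchar(cds_nt))
  needed <- fam$overlap_target * covered
  depth2 <- 0
  main_ix <- which(!vapply(cds, `[[`, logical(1), "is_mat_peptide"))
  guard <- 0L
  while (depth2 < needed && guard < 200L) {
    guard <- guard + 1L
    j <- main_ix[sample.int(length(main_ix), 1L)]
    parent <- cds[[j]]
    plen_aa <- nchar(parent$translation)
    if (plen_aa < 160L) next
    hi <- min(plen_aa - 20L, 400L,
              max(40L, as.integer(ceiling((needed - depth2) / 3))))
    sub_aa <- if (hi <= 40L) 40L else 39L + sample.int(hi - 39L, 1L)
    off_aa <- sample.int(plen_aa - sub_aa, 1L)
    ps <- parent$intervals[1, 1] + 3L * off_aa
    pe <- ps + 3L * sub_aa
    pid_n <- pid_n + 1L
    pid <- sprintf("%s_p%03d", accession, pid_n)
    sub_seq <- substr(parent$translation, off_aa + 1L, off_aa + sub_aa)
    cds[[length(cds) + 1L]] <- make_cds_feature(
      parent$segment, ps, pe, "+", pid, sub_seq,
      product = "overlapping protein")
    prot_rows[[length(prot_rows) + 1L]] <- data.frame(
      protein_id = pid, sequence = sub_seq,
      is_polyprotein = FALSE, stringsAsFactors = FALSE)
    depth2 <- depth2 + 3L * sub_aa
  }

  # --- planted 10x annotation excess ------------------------------------
  if (outlier == "excess") {
    base_cds <- cds[!vapply(cds, `[[`, logical(1), "is_mat_peptide")]
    base_prot <- do.call(rbind, prot_rows)
    for (rep_i in seq_len(9L)) {
      for (f in base_cds) {
        pid_n <- pid_n + 1L
        pid <- sprintf("%s_p%03d", accession, pid_n)
        f$protein_id <- pid
        cds[[length(cds) + 1L]] <- f
        prot_rows[[length(prot_rows) + 1L]] <- data.frame(
          protein_id = pid, sequence = f$translation,
          is_polyprotein = FALSE, stringsAsFactors = FALSE)
      }
    }
  }

  structure(
    list(accession = accession, family = fam$family,
         baltimore_type = fam$baltimore_type,
         host_category = fam$host_category,
         segments = segments,
         genome_size = sum(vapply(segments, nchar, integer(1))),
         cds = cds, proteins = do.call(rbind, prot_rows)),
    class = "GenomeRecord")
}

derive_seed <- function(seed, i)
  as.integer((as.numeric(seed) * 1000003 + i * 10007) %% 2147483629)

#' Simulate a synthetic viral genome corpus
#'
#' Generates, per family in the configuration, genome sizes (lognormal) and
#' per-genome target disorder coupled to log-size through a Gaussian copula
#' that hits the configured Spearman correlation regardless of the
#' marginals. Each genome is partitioned into CDS (with nested overlapping
#' genes inserted to meet the family overlap target and one polyprotein
#' with mat_peptides per family), disorder is induced through amino-acid
#' choice and composition through synonymous-codon choice, and annotation
#' outliers are planted where configured. A single root seed with
#' per-family derived streams makes the corpus reproducible bit-for-bit,
#' and adding a family never perturbs the others.
#'
#' @param config A [default_config()]-style `family_truth` data frame.
#' @param seed Integer root seed.
#' @return Object of class `SyntheticCorpus`: list with `genomes`,
#'   `config`, `realized` (per-genome truth: accession, family, drawn size,
#'   target disorder, planted outlier kind) and `seed`.
#' @export
simulate_corpus <- function(config = default_config(), seed = 1L) {
  stopifnot(is.data.frame(config), nrow(config) >= 1L)
  genomes <- list()
  realized <- list()
  for (i in seq_len(nrow(config))) {
    fam <- config[i, ]
    set.seed(derive_seed(seed, i))
    n <- fam$n_genomes
    r <- 2 * sin(pi * fam$size_disorder_rho / 6)   # copula parameter
    z1 <- rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    sizes <- round(exp(fam$mean_log_size + fam$sd_log_size * z1))
    target_D <- pmin(95, pmax(0.5, fam$target_mean_D + fam$sd_D * z2))
    min_size <- 3L * (160L + 1L) + 200L
    if (any(sizes < min_size))
      stop(sprintf("family '%s': configured sizes too small to hold a gene",
                   fam$family))
    bias <- c(A = fam$bias_A, C = fam$bias_C, G = fam$bias_G, T = fam$bias_T)
    outlier <- rep("none", n)
    if (isTRUE(fam$plant_outliers) && n >= 3L)
      outlier[1:3] <- c("excess", "excess", "deficit")
    for (g in seq_len(n)) {
      acc <- sprintf("V%02dG%03d", i, g)
      genomes[[length(genomes) + 1L]] <- build_synth_genome(
        acc, fam, sizes[g], target_D[g], bias,
        with_polyprotein = (g == 1L && fam$baltimore_type != "satellite"),
        outlier = outlier[g])
      realized[[length(realized) + 1L]] <- data.frame(
        accession = acc, family = fam$family,
        baltimore_type = fam$baltimore_type,
        host_category = fam$host_category,
        size_drawn = sizes[g], target_D = target_D[g],
        outlier = outlier[g], stringsAsFactors = FALSE)
    }
  }
  structure(
    list(genomes = genomes, config = config,
         realized = do.call(rbind, realized), seed = seed),
    class = "SyntheticCorpus")
}

#' @export
print.SyntheticCorpus <- function(x, ...) {
  cat(sprintf("<SyntheticCorpus: %d genomes in %d families (seed %d)>\n",
              length(x$genomes), nrow(x$config), x$seed))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits the corpus as a multi-record GenBank flat file plus the metadata
#' TSV consumed by [parse_genome_records()], the generator configuration,
#' and the per-genome truth as JSON.
#'
#' @param corpus A [simulate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genbank(corpus$genomes, file.path(dir, "corpus.gb"))
  meta <- do.call(rbind, lapply(corpus$genomes, function(g) data.frame(
    accession = names(g$segments),
    family = g$family, baltimore_type = g$baltimore_type,
    host_category = g$host_category, segment_group = g$accession,
    stringsAsFactors = FALSE)))
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_config(corpus$config, file.path(dir, "config.tsv"))
  jsonlite::write_json(
    list(seed = corpus$seed, realized = corpus$realized),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
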