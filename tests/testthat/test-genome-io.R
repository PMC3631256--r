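test_that("a hand-built record parses into the expected genome", {
  fx <- fixture_genbank()
  gs <- parse_genome_records(text = fx$lines, metadata = fixture_metadata())
  expect_length(gs, 1L)
  g <- gs[[1]]
  expect_equal(g$genome_size, fx$len)
  expect_equal(g$family, "Fixvirus")
  # 300 nt CDS -> 99 aa with the stop removed; translation matches qualifier
  expect_equal(nchar(g$proteins$sequence[g$proteins$protein_id == "fix_p1"]),
               99L)
  expect_equal(g$proteins$sequence[g$proteins$protein_id == "fix_p1"],
               fx$prot1)
  # minus-strand CDS translated from the reverse complement
  expect_equal(g$proteins$sequence[g$proteins$protein_id == "fix_p2"],
               fx$prot2)
  # GenBank 1-based inclusive converted to 0-based half-open at one point
  cds1 <- Filter(function(f) identical(f$protein_id, "fix_p1"), g$cds)[[1]]
  expect_equal(unname(cds1$intervals[1, ]), c(fx$cds1_start0,
                                              fx$cds1_start0 + 300))
})

test_that("mat_peptides attach to their polyprotein by containment", {
  fx <- fixture_genbank()
  g <- parse_genome_records(text = fx$lines, metadata = fixture_metadata())[[1]]
  expect_true(g$proteins$is_polyprotein[g$proteins$protein_id == "fix_poly"])
  peps <- Filter(function(f) isTRUE(f$is_mat_peptide), g$cds)
  expect_length(peps, 3L)
  expect_true(all(vapply(peps, `[[`, character(1), "parent_protein_id") ==
                    "fix_poly"))
  concat <- sum(vapply(peps, function(f) nchar(f$translation), integer(1)))
  expect_lte(concat, nchar(fx$poly))
  expect_equal(paste(vapply(peps, `[[`, character(1), "translation"),
                     collapse = ""), fx$poly)
})

test_that("records sharing a segment group merge into one genome", {
  fx <- fixture_genbank()
  two <- c(fx$lines, sub("FIX00001", "FIX00002", fx$lines))
  meta <- rbind(fixture_metadata("FIX00001"), fixture_metadata("FIX00002"))
  meta$segment_group <- "FIXPAIR"
  gs <- parse_genome_records(text = two, metadata = meta)
  expect_length(gs, 1L)
  expect_equal(gs[[1]]$accession, "FIXPAIR")
  expect_equal(gs[[1]]$genome_size, 2L * fx$len)
  expect_length(gs[[1]]$segments, 2L)
  # without grouping each record is its own genome
  meta$segment_group <- ""
  expect_length(parse_genome_records(text = two, metadata = meta), 2L)
})

test_that("translation conflicts warn but keep the annotation", {
  fx <- fixture_genbank()
  bad <- sub(sprintf("/translation=\"%s\"", fx$prot1),
             sprintf("/translation=\"%s\"", chartr("EK", "KE", fx$prot1)),
             fx$lines, fixed = TRUE)
  expect_warning(
    gs <- parse_genome_records(text = bad, metadata = fixture_metadata()),
    "conflicts")
  expect_equal(gs[[1]]$proteins$sequence[1], chartr("EK", "KE", fx$prot1))
})

test_that("malformed records fail naming the locus", {
  fx <- fixture_genbank()
  broken <- sub("^LOCUS       FIX00001 +\\d+", "LOCUS       FIX00001 oops",
                fx$lines)
  expect_error(parse_genome_records(text = broken), "FIX00001")
  outside <- sub("     CDS             58..357",
                 sprintf("     CDS             58..%d", fx$len + 500),
                 fx$lines, fixed = TRUE)
  if (!identical(outside, fx$lines))
    expect_error(parse_genome_records(text = outside), "outside")
})

test_that("genome sets round-trip through TSV + FASTA", {
  corp <- small_corpus()
  gs <- corp$genomes[1:6]
  d <- tempfile()
  write_genome_set(gs, d)
  back <- read_genome_set(d)
  expect_equal(vapply(back, `[[`, character(1), "accession"),
               vapply(gs, `[[`, character(1), "accession"))
  for (i in seq_along(gs)) {
    expect_equal(back[[i]]$family, gs[[i]]$family)
    expect_equal(back[[i]]$baltimore_type, gs[[i]]$baltimore_type)
    expect_equal(back[[i]]$genome_size, gs[[i]]$genome_size)
    expect_setequal(back[[i]]$proteins$sequence, gs[[i]]$proteins$sequence)
  }
})

test_that("siegel regression resists gross outliers", {
  set.seed(41)
  x <- runif(50, 3, 6)
  y <- 1.5 * x - 2 + rnorm(50, sd = 0.01)
  y[1:5] <- y[1:5] + 10            # 10% gross outliers
  fit <- siegel_regression(x, y)
  expect_equal(fit$slope, 1.5, tolerance = 0.05)
  expect_equal(fit$intercept, -2, tolerance = 0.2)
})

make_toy_genome <- function(accession, size, n_res, family = "F",
                            type = "dsDNA") {
  structure(list(accession = accession, family = family,
                 baltimore_type = type, host_category = "Vertebrates",
                 segments = setNames(list(NULL), accession),
                 genome_size = size, cds = list(),
                 proteins = data.frame(protein_id = "p1",
                                       sequence = strrep("A", n_res),
                                       is_polyprotein = FALSE)),
            class = "GenomeRecord")
}

test_that("residue-vs-size QC flags exactly the planted outliers", {
  set.seed(43)
  sizes <- round(exp(runif(50, log(2e3), log(2e5))))
  noise <- runif(50, 0.9, 1.1)     # clean set: +-10% annotation noise
  gs <- lapply(seq_along(sizes), function(i)
    make_toy_genome(sprintf("G%02d", i), sizes[i],
                    round(sizes[i] / 3 * noise[i])))
  expect_true(all(qc_residue_vs_genome(gs, k = 3) == "ok"))
  # direct MAD oracle on the same residuals confirms no flag is expected
  x <- log10(sizes); y <- log10(round(sizes / 3 * noise))
  fit <- siegel_regression(x, y)
  r <- y - fit$intercept - fit$slope * x; r <- r - median(r)
  expect_true(all(abs(r) <= 3 * 1.4826 * median(abs(r)) + 1e-8))

  gs[[7]] <- make_toy_genome("G07", sizes[7], round(10 * sizes[7] / 3))
  gs[[13]] <- make_toy_genome("G13", sizes[13], round(sizes[13] / 30))
  flags <- qc_residue_vs_genome(gs, k = 3)
  expect_equal(unname(flags[c("G07", "G13")]),
               c("excess_residues", "deficit_residues"))
  expect_true(all(flags[-c(7, 13)] == "ok"))
  expect_error(qc_residue_vs_genome(gs[1:5]), "skip")
})

test_that("survey set filters satellites, QC families and small families", {
  gs <- c(
    lapply(1:11, function(i) make_toy_genome(sprintf("A%02d", i), 1e4, 3e3,
                                             family = "FamA")),
    lapply(1:10, function(i) make_toy_genome(sprintf("B%02d", i), 1e4, 3e3,
                                             family = "FamB")),
    lapply(1:5, function(i) make_toy_genome(sprintf("S%02d", i), 1e3, 300,
                                            family = "FamS",
                                            type = "satellite")))
  ss <- build_survey_set(gs, min_family_size = 10)
  # 11-member family is tabulated, 10-member family is not (strictly >10)
  expect_identical(ss$tabulated_families, "FamA")
  expect_equal(sum(ss$exclusions == "satellite"), 5L)
  # partition invariant: analysis + exclusions = input
  expect_equal(length(ss$genomes) + length(ss$exclusions), length(gs))
  # flag-family policy removes the whole family of a flagged genome
  flags <- setNames(rep("ok", length(gs)),
                    vapply(gs, `[[`, character(1), "accession"))
  flags["B03"] <- "excess_residues"
  ss2 <- build_survey_set(gs, flags, qc_policy = "flag-family")
  expect_equal(sum(ss2$exclusions == "qc_outlier"), 10L)
  ss3 <- build_survey_set(gs, flags, qc_policy = "flag-genome")
  expect_equal(sum(ss3$exclusions == "qc_outlier"), 1L)
  expect_equal(length(ss2$genomes) + length(ss2$exclusions), length(gs))
})

test_that("the survey table conserves stage counts", {
  corp <- small_corpus()
  ss <- build_survey_set(corp$genomes)
  path <- tempfile(fileext = ".tsv")
  tab <- write_survey_set(ss, corp$genomes, path)
  expect_equal(nrow(tab), length(corp$genomes))
  expect_equal(sum(tab$exclusion_reason == ""), length(ss$genomes))
  reread <- utils::read.delim(path)
  expect_equal(nrow(reread), length(corp$genomes))
})
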