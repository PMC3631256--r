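test_that("the default configuration spans the intended corpus structure", {
  cfg <- default_config()
  analysis <- cfg[cfg$baltimore_type != "satellite", ]
  expect_gte(nrow(analysis), 12L)
  expect_lte(min(analysis$target_mean_D), 3.5)
  expect_gte(max(analysis$target_mean_D), 29)
  # every Baltimore class represented
  expect_setequal(unique(cfg$baltimore_type),
                  c("ssDNA", "dsDNA", "ssRNAp", "ssRNAn", "dsRNA",
                    "ssRNA-RT", "dsDNA-RT", "satellite"))
  expect_true(any(cfg$size_disorder_rho > 0) && any(cfg$size_disorder_rho < 0))
  expect_equal(sum(cfg$plant_outliers), 1L)
  expect_true(all(abs(cfg$bias_A + cfg$bias_C + cfg$bias_G + cfg$bias_T - 1)
                  < 1e-12))
  expect_true(all(exp(cfg$mean_log_size) >= 1e3 &
                    exp(cfg$mean_log_size) <= 2e5))
})

test_that("configurations round-trip losslessly through the config file", {
  cfg <- default_config()
  path <- tempfile(fileext = ".tsv")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back, cfg)
  expect_identical(back$mean_log_size, cfg$mean_log_size)   # bit-exact doubles
})

test_that("synthetic proteins hit their disorder fraction end to end", {
  spec <- default_predictor()
  set.seed(111)
  d0 <- percent_disorder_protein(
    call_disordered(predict_scores(synth_protein(600, 0), spec)))
  expect_lt(d0, 10)
  d1 <- percent_disorder_protein(
    call_disordered(predict_scores(synth_protein(600, 1), spec)))
  expect_gt(d1, 90)
  ds <- replicate(30, percent_disorder_protein(
    call_disordered(predict_scores(synth_protein(1000, 0.5), spec))))
  expect_lt(abs(mean(ds) - 50), 5)
  expect_warning(synth_protein(100, 0.5), "relaxed")
})

test_that("back-translation is exact and converges to the bias", {
  set.seed(113)
  # forced: all-C bias on poly-Ala gives GCC everywhere
  expect_equal(back_translate(strrep("A", 5), c(A = 0, C = 1, G = 0, T = 0)),
               strrep("GCC", 5))
  # round trip for random proteins
  aa20 <- names(disorder_propensity())
  for (i in 1:5) {
    prot <- paste(sample(aa20, 150, TRUE), collapse = "")
    nt <- back_translate(prot, c(A = .3, C = .2, G = .3, T = .2))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    expect_identical(aa, prot)
  }
  # uniform bias: four-fold third positions near 0.25 each
  prot <- paste(sample(c("A", "G", "P", "T", "V"), 10000, TRUE), collapse = "")
  nt <- back_translate(prot, c(A = .25, C = .25, G = .25, T = .25))
  ff <- fourfold_site_composition(nt)
  expect_gte(ff$n_codons, 10000L)
  for (b in c("A", "C", "G", "T"))
    expect_lt(abs(ff[[b]] - 0.25), 0.02)
  expect_error(back_translate("A", c(A = -1, C = 1, G = 0, T = 0)),
               "non-negative")
})

test_that("corpus simulation is bit-reproducible from (config, seed)", {
  cfg <- small_config()
  c1 <- simulate_corpus(cfg, seed = 7)
  c2 <- simulate_corpus(cfg, seed = 7)
  expect_identical(c1$realized, c2$realized)
  expect_identical(lapply(c1$genomes, `[[`, "segments"),
                   lapply(c2$genomes, `[[`, "segments"))
  d1 <- tempfile(); d2 <- tempfile()
  write_corpus(c1, d1); write_corpus(c2, d2)
  expect_identical(readLines(file.path(d1, "corpus.gb")),
                   readLines(file.path(d2, "corpus.gb")))
  c3 <- simulate_corpus(cfg, seed = 8)
  expect_false(identical(c1$realized$size_drawn, c3$realized$size_drawn))
})

test_that("per-family seed streams isolate families from each other", {
  cfg <- small_config()
  c_all <- simulate_corpus(cfg, seed = 5)
  c_sub <- simulate_corpus(cfg[c(1, 3, 4), ], seed = 5)
  # dropping family 2 leaves the genomes of family 1 untouched
  fam1_all <- Filter(function(g) g$family == cfg$family[1], c_all$genomes)
  fam1_sub <- Filter(function(g) g$family == cfg$family[1], c_sub$genomes)
  expect_identical(lapply(fam1_all, `[[`, "segments"),
                   lapply(fam1_sub, `[[`, "segments"))
})

test_that("emitted records parse back with zero warnings", {
  d <- small_corpus_dir()
  meta <- utils::read.delim(file.path(d, "metadata.tsv"))
  expect_no_warning(
    gs <- parse_genome_records(file.path(d, "corpus.gb"), meta))
  corp <- small_corpus()
  expect_length(gs, length(corp$genomes))
  ords <- match(vapply(corp$genomes, `[[`, character(1), "accession"),
                vapply(gs, `[[`, character(1), "accession"))
  expect_false(anyNA(ords))
  for (i in seq_along(corp$genomes)) {
    g0 <- corp$genomes[[i]]; g1 <- gs[[ords[i]]]
    expect_equal(g1$genome_size, g0$genome_size)
    expect_setequal(g1$proteins$sequence, g0$proteins$sequence)
  }
  # the segmented family merges back into multi-segment genomes
  seg <- Filter(function(g) length(g$segments) == 3, gs)
  expect_gt(length(seg), 0)
})

test_that("a family with negative size-disorder coupling shows it in the pipeline", {
  cfg <- default_config()[2, ]     # rho = -0.38, n = 50
  cfg$size_disorder_rho <- -0.6
  cfg$n_genomes <- 60L
  corp <- simulate_corpus(cfg, seed = 17)
  dis <- disorder_table(corp$genomes)
  obs <- make_observations(corp$genomes, dis,
                           composition_table(corp$genomes))
  sp <- spearman_cor(obs$S, obs$D)
  expect_lt(sp$rho, 0)
  expect_lt(sp$p, 0.05)
})

test_that("planted annotation outliers are exactly the flagged set", {
  corp <- default_corpus()
  flags <- qc_residue_vs_genome(corp$genomes, k = 3)
  planted <- sort(corp$realized$accession[corp$realized$outlier != "none"])
  flagged <- sort(names(flags)[flags != "ok"])
  expect_identical(flagged, planted)
  expect_equal(unname(flags[corp$realized$accession[
    corp$realized$outlier == "excess"]]),
    rep("excess_residues", 2))
  expect_equal(unname(flags[corp$realized$accession[
    corp$realized$outlier == "deficit"]]), "deficit_residues")
})

test_that("clean corpora yield zero QC flags", {
  cfg <- small_config()
  cfg$plant_outliers <- FALSE
  corp <- simulate_corpus(cfg, seed = 19)
  flags <- qc_residue_vs_genome(corp$genomes, k = 3)
  expect_true(all(flags == "ok"))
})
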