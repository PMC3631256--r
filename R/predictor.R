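#' @importFrom stats plogis
NULL

# The twenty standard residues, ordered from most order-promoting to most
# disorder-promoting according to the packaged composition-based disorder
# propensity scale (negative = order-promoting, positive = disorder-promoting).
.AA20 <- c("W", "F", "Y", "I", "M", "L", "V", "C", "N", "T",
           "A", "G", "R", "D", "H", "Q", "S", "K", "E", "P")

.DISORDER_PROPENSITY <- c(
  W = -0.884, F = -0.697, Y = -0.510, I = -0.486, M = -0.397,
  L = -0.326, V = -0.121, C = -0.020, N = -0.007, T =  0.059,
  A =  0.060, G =  0.166, R =  0.180, D =  0.192, H =  0.303,
  Q =  0.318, S =  0.341, K =  0.586, E =  0.736, P =  0.987)

#' Per-residue disorder propensity scale
#'
#' Returns the packaged per-residue disorder propensity values used to build
#' the default predictor's pairwise energy table. Negative values mark
#' order-promoting residues (W the strongest), positive values
#' disorder-promoting ones (P the strongest); the sign of the propensity is
#' exactly the side of the 0.5 score threshold on which the corresponding
#' homopolymer falls under the default calibration.
#'
#' @return Named numeric vector of length 20.
#' @export
disorder_propensity <- function() .DISORDER_PROPENSITY

#' Construct a disorder predictor specification
#'
#' The predictor estimates, for every residue, the mean pairwise interaction
#' energy between that residue and all residues inside a sliding window
#' (a quadratic form in the local amino-acid composition), then maps the
#' energy to a disorder score in \[0, 1\] through a monotone decreasing
#' logistic calibration: lower estimated interaction energy means a higher
#' disorder score. The pairwise energy table is
#' `E[a, b] = -(p(a) + p(b)) / 2` where `p` is the packaged disorder
#' propensity, so it is symmetric by construction.
#'
#' Per-residue scores from an external predictor (e.g. real IUPred output)
#' can replace this built-in model throughout the pipeline; see
#' [read_score_table()].
#'
#' @param window Odd positive integer; residues within `(window - 1) / 2`
#'   positions contribute to a residue's energy (truncated at the termini,
#'   no padding). Default 25.
#' @param tau Positive calibration temperature: `score = plogis((-E - midpoint) / tau)`.
#' @param midpoint Calibration midpoint on the (negated) energy scale.
#' @param neutral_score Score assigned to ambiguity codes (X, B, Z, J, U, O);
#'   the default 0 is conservative in that ambiguous residues never inflate
#'   disorder.
#' @return An object of class `PredictorSpec`.
#' @export
default_predictor <- function(window = 25L, tau = 0.15, midpoint = 0,
                              neutral_score = 0) {
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd positive integer")
  if (!is.numeric(tau) || tau <= 0)
    stop("`tau` must be positive (monotone decreasing calibration)")
  p <- .DISORDER_PROPENSITY
  energy <- -outer(p, p, "+") / 2
  dimnames(energy) <- list(names(p), names(p))
  stopifnot(isTRUE(all.equal(energy, t(energy))))
  structure(
    list(name = "pairwise-propensity", window = window, energy = energy,
         tau = tau, midpoint = midpoint, neutral_score = neutral_score),
    class = "PredictorSpec")
}

#' @export
print.PredictorSpec <- function(x, ...) {
  cat(sprintf("<PredictorSpec '%s': window=%d, tau=%g, midpoint=%g, neutral=%g>\n",
              x$name, x$window, x$tau, x$midpoint, x$neutral_score))
  invisible(x)
}

.calibrate <- function(energy, spec) plogis((-energy - spec$midpoint) / spec$tau)

#' Predict per-residue disorder scores
#'
#' Deterministically scores every residue of an amino-acid sequence. A
#' residue's energy is the mean of the pairwise energy between it and every
#' standard residue inside its window (the residue itself included); the
#' window is truncated at the termini. Ambiguity codes receive
#' `spec$neutral_score` and are excluded from their neighbours' window
#' composition.
#'
#' @param sequence Single amino-acid string (upper or lower case).
#' @param spec A [default_predictor()] specification.
#' @return Numeric vector of scores in \[0, 1\], one per residue.
#' @export
predict_scores <- function(sequence, spec = default_predictor()) {
  stopifnot(inherits(spec, "PredictorSpec"))
  if (length(sequence) != 1L || is.na(sequence))
    stop("`sequence` must be a single string")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n == 0L) stop("empty sequence")
  half <- (spec$window - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)

  idx <- match(chars, .AA20)            # NA for ambiguity codes
  standard <- !is.na(idx)
  # windowed composition counts per standard letter, by cumulative sums
  counts <- matrix(0, nrow = n, ncol = 20L, dimnames = list(NULL, .AA20))
  for (b in seq_len(20L)) {
    cs <- c(0L, cumsum(as.integer(standard & idx == b)))
    counts[, b] <- cs[hi + 1L] - cs[lo]
  }
  denom <- rowSums(counts)
  scores <- rep(spec$neutral_score, n)
  ok <- standard & denom > 0
  if (any(ok)) {
    esum <- rowSums(counts[ok, , drop = FALSE] * spec$energy[idx[ok], , drop = FALSE])
    scores[ok] <- .calibrate(esum / denom[ok], spec)
  }
  pmin(1, pmax(0, scores))
}

#' Call residues disordered
#'
#' Converts per-residue scores to binary disorder calls. The default follows
#' the inclusive threshold convention (score >= threshold is disordered);
#' `strict_gt = TRUE` switches to a strict "greater than" cut-off.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Score threshold in (0, 1); default 0.5.
#' @param strict_gt Use `>` instead of `>=` at the boundary.
#' @return Logical vector of the same length.
#' @export
call_disordered <- function(scores, threshold = 0.5, strict_gt = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie strictly inside (0, 1)")
  if (any(scores < 0 | scores > 1, na.rm = TRUE))
    stop("scores must lie in [0, 1]")
  if (strict_gt) scores > threshold else scores >= threshold
}

#' Percent disorder of one protein
#'
#' @param calls Logical disorder calls for each residue.
#' @return Percent disorder in \[0, 100\]: `100 * sum(calls) / length(calls)`.
#' @export
percent_disorder_protein <- function(calls) {
  if (length(calls) == 0L) stop("no residues: cannot compute percent disorder")
  100 * sum(calls) / length(calls)
}

#' Build a per-protein disorder profile
#'
#' Scores a protein, applies the threshold, and packages scores, calls,
#' length and percent disorder.
#'
#' @inheritParams predict_scores
#' @inheritParams call_disordered
#' @param protein_id Identifier carried through to outputs.
#' @param scores Optional pre-computed scores (external predictor); when
#'   supplied, `sequence` may be omitted and `spec` is ignored.
#' @return Object of class `DisorderProfile` with fields `protein_id`,
#'   `scores`, `threshold`, `calls`, `L_i`, `D_i`.
#' @export
disorder_profile <- function(protein_id, sequence = NULL,
                             spec = default_predictor(),
                             threshold = 0.5, strict_gt = FALSE,
                             scores = NULL) {
  if (is.null(scores)) scores <- predict_scores(sequence, spec)
  calls <- call_disordered(scores, threshold, strict_gt)
  structure(
    list(protein_id = protein_id, scores = scores, threshold = threshold,
         calls = calls, L_i = length(scores),
         D_i = percent_disorder_protein(calls)),
    class = "DisorderProfile")
}

#' Pool disorder over a genome's proteins
#'
#' Computes whole-genome percent disorder by pooling residues across all
#' proteins (the count of disordered residues over the total residue count),
#' which is algebraically identical to the residue-length-weighted mean of
#' the per-protein percentages.
#'
#' @param profiles List of [disorder_profile()] objects.
#' @param accession Genome accession carried through to outputs.
#' @return Object of class `GenomeDisorderSummary` with fields `accession`,
#'   `N`, `total_residues`, `disordered_residues`, `D` and a `per_protein`
#'   data frame.
#' @export
percent_disorder_genome <- function(profiles, accession = NA_character_) {
  if (length(profiles) == 0L) stop("no proteins: cannot compute genome disorder")
  stopifnot(all(vapply(profiles, inherits, logical(1), "DisorderProfile")))
  L <- vapply(profiles, function(p) p$L_i, numeric(1))
  ndis <- vapply(profiles, function(p) sum(p$calls), numeric(1))
  per_protein <- data.frame(
    protein_id = vapply(profiles, function(p) p$protein_id, character(1)),
    L_i = L, n_disordered = ndis,
    D_i = vapply(profiles, function(p) p$D_i, numeric(1)),
    stringsAsFactors = FALSE)
  structure(
    list(accession = accession, N = length(profiles),
         total_residues = sum(L), disordered_residues = sum(ndis),
         D = 100 * sum(ndis) / sum(L), per_protein = per_protein),
    class = "GenomeDisorderSummary")
}

#' @export
print.GenomeDisorderSummary <- function(x, ...) {
  cat(sprintf("<GenomeDisorderSummary %s: %d proteins, %d residues, D = %.2f%%>\n",
              x$accession, x$N, x$total_residues, x$D))
  invisible(x)
}

#' Polyprotein disorder computed two ways
#'
#' For a polyprotein precursor with annotated cleavage products, percent
#' disorder is computed (a) on the intact polyprotein and (b) by scoring
#' each cleaved peptide independently and dividing the pooled disordered
#' count by the total cleaved length. The two differ only through window
#' effects at cleavage boundaries; the survey pipeline uses the intact
#' value by default.
#'
#' @param parent Amino-acid string of the intact polyprotein.
#' @param peptides Character vector of cleaved peptide sequences.
#' @param offsets 1-based start positions of each peptide within the parent.
#'   If `NULL`, each peptide is located by exact string search (first match).
#' @inheritParams disorder_profile
#' @return List with `D_whole` (intact polyprotein), `D_cleaved` (pooled over
#'   cleaved peptides), `D_whole_covered` (intact scores restricted to
#'   peptide-covered positions, for like-for-like comparison) and `coverage`
#'   (fraction of parent residues covered by peptides).
#' @export
polyprotein_disorder_two_ways <- function(parent, peptides, offsets = NULL,
                                          spec = default_predictor(),
                                          threshold = 0.5, strict_gt = FALSE) {
  if (length(peptides) == 0L) stop("no cleaved peptides supplied")
  if (is.null(offsets)) {
    offsets <- vapply(peptides, function(p)
      as.integer(regexpr(p, parent, fixed = TRUE)), integer(1), USE.NAMES = FALSE)
    if (any(offsets < 1L))
      stop("peptide not found within the parent polyprotein")
  }
  np <- nchar(parent)
  for (k in seq_along(peptides)) {
    end <- offsets[k] + nchar(peptides[k]) - 1L
    if (offsets[k] < 1L || end > np ||
        substr(parent, offsets[k], end) != peptides[k])
      stop(sprintf("peptide %d is not a substring of the parent at position %d",
                   k, offsets[k]))
  }
  parent_scores <- predict_scores(parent, spec)
  parent_calls <- call_disordered(parent_scores, threshold, strict_gt)
  D_whole <- percent_disorder_protein(parent_calls)

  pep_calls <- lapply(peptides, function(p)
    call_disordered(predict_scores(p, spec), threshold, strict_gt))
  total_cleaved <- sum(nchar(peptides))
  D_cleaved <- 100 * sum(vapply(pep_calls, sum, numeric(1))) / total_cleaved

  covered <- logical(np)
  for (k in seq_along(peptides))
    covered[offsets[k]:(offsets[k] + nchar(peptides[k]) - 1L)] <- TRUE
  D_whole_covered <- if (any(covered))
    percent_disorder_protein(parent_calls[covered]) else NA_real_

  list(D_whole = D_whole, D_cleaved = D_cleaved,
       D_whole_covered = D_whole_covered, coverage = mean(covered))
}

#' Read a table of externally computed per-residue scores
#'
#' Accepts the interchange format for dropping in scores from an external
#' disorder predictor: a TSV with columns `protein_id`, `position` (1-based)
#' and `score`.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping protein_id to a numeric score vector ordered
#'   by position.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "score")
  if (!all(need %in% names(tab)))
    stop("score table must have columns protein_id, position, score")
  out <- lapply(split(tab, tab$protein_id), function(d) {
    d <- d[order(d$position), ]
    if (!identical(d$position, seq_len(nrow(d))))
      stop(sprintf("scores for '%s' do not cover positions 1..L contiguously",
                   d$protein_id[1]))
    d$score
  })
  out
}
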