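---
title: "Methods: surveying intrinsic disorder across viral proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying intrinsic disorder across viral proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virodisorder)
```

## The survey model

The pipeline quantifies, for each annotated viral genome, the percentage
of encoded residues predicted to be intrinsically disordered, and then
asks how that quantity is structured by genome size, base composition,
viral type, host and family. The unit of observation is the genome: per
protein $i$ of length $L_i$, the per-residue score $S$ is thresholded at
$S_{Th}$ and

$$D_i = 100 \cdot \frac{\#\{r : S_r \ge S_{Th}\}}{L_i},$$

while the genome-level statistic pools residues across all $N$ proteins
rather than averaging the $D_i$:

$$D = 100 \cdot \frac{\sum_i \#\{r : S_r \ge S_{Th}\}}{\sum_i L_i}.$$

Pooling equals the $L_i$-weighted mean of the $D_i$, an identity the test
suite asserts to $10^{-9}$ on every simulated genome. Thresholding is
inclusive at the boundary ($S = S_{Th}$ counts as disordered); the
published descriptions of this statistic use both conventions in
different places, so a `strict_gt` flag switches to the strict reading.
At $S_{Th} = 0.5$ the choice is immaterial in practice because scores
land exactly on the threshold with probability zero.

### The built-in predictor, and what it is not

The disorder predictor estimates, for each residue, the mean pairwise
interaction energy between that residue and its neighbours within a
sliding window — a quadratic form in the local amino-acid composition —
and maps the energy through a monotone decreasing logistic calibration to
$[0,1]$. The pairwise energy table is built from a packaged per-residue
disorder propensity scale (W most order-promoting, P most
disorder-promoting): $E[a,b] = -(p_a + p_b)/2$, symmetric by
construction. For a homopolymer of residue $a$ every window is pure $a$,
so the score is exactly $\mathrm{plogis}(p_a / \tau)$, and the sign of
$p_a$ decides the side of the 0.5 threshold — a property the tests assert
for all twenty residues.

This predictor is the package's own: it shares the architecture of
energy-estimation predictors (windowed pairwise energy, monotone
calibration) but not any published parameter set. Results on real
proteins will differ from IUPred's in detail, which is why every stage
accepts externally computed per-residue scores
(`read_score_table()`, the `scores` argument of `run_survey()`): drop in
real predictor output and the rest of the survey is unchanged.

Tunable parameters, with defaults:

* `window = 25` residues (odd; truncated at termini, no padding). Wide
  enough that single residues do not flip calls, narrow enough to keep
  prediction local.
* `tau = 0.15`, `midpoint = 0`: calibration temperature and midpoint on
  the negated-energy scale. The midpoint at 0 places the 20 homopolymers
  on the threshold side given by the propensity sign.
* `neutral_score = 0` for ambiguity codes (X, B, Z, J, U, O): ambiguous
  residues are counted in $L_i$ but never inflate disorder; they are also
  excluded from neighbours' window composition.
* `threshold = 0.5` ($S_{Th}$), `strict_gt = FALSE`.

Polyproteins are scored two ways: intact, and as independently scored
cleaved mat_peptides with the disordered counts pooled over the total
cleaved length. Only window-straddling positions at cleavage boundaries
can differ between the routes, bounding the discrepancy by
$100 \cdot N_{pep}(w-1)/L$; with a window-1 predictor the routes agree
exactly. The pipeline default is the intact value, and cleaved-peptide
residues are never double-counted alongside their parent.

## Composition and overlapping genes

Total base composition is computed on the deposited genome strand, pooled
across segments, because strand asymmetry (unequal frequencies of
complementary bases) is an effect only visible on a fixed strand — the
reason the regressions use all four base fractions rather than G+C alone.
Four-fold degenerate composition is necessarily computed on each CDS's
coding strand: third positions of codons in the eight fully degenerate
boxes of the standard code ({CT, GT, TC, CC, AC, GC, CG, GG}; the set is
derived from the code table at run time and checked against brute force).
Sites are pooled genome-wide across CDS; a per-gene option exists via
`fourfold_site_composition()` on single sequences. Codons containing
ambiguity codes are skipped; CDS whose length is not a multiple of three
are dropped from this computation with a warning. U is normalised to T at
parse time, so RNA virus records need no special-casing.

The overlap fraction is the strand-agnostic fraction of positions covered
by two or more CDS, with the positions covered by at least one CDS as the
default denominator (`denominator = "genome"` divides by genome length
instead and is never larger). mat_peptides are excluded — they lie inside
their parent by definition and would otherwise fake overlap.

## Statistical ladder

* **Spearman correlations** use midranks for ties; p-values come from the
  exact null distribution for $n \le 20$ without ties (via
  `stats::cor.test`) and the t-approximation otherwise.
* **The nested size model** fits `D ~ A + C + G` and `D ~ A + C + G + S`
  by OLS. T is dropped as the reference to break the sum-to-one
  collinearity of the four fractions — chosen because T is the strongest
  negative correlate of disorder, making the remaining coefficients
  interpretable against it. $\Delta R^2$ is the difference of adjusted
  $R^2$ and may legitimately be negative (adjustment penalty) when size
  adds nothing. The size term's t-test p-value is reported alongside.
  A `response = "rank"` option regresses the rank of D, making results
  invariant to monotone transforms.
* **Bonferroni correction** is scoped to the table being reported (the
  number of types, families or hosts in that table), matching each
  table's own correction family.
* **Variance attribution** fits one OLS model per predictor set on the
  common complete rows (so the adjusted $R^2$ are comparable), with
  categorical predictors as factors. This is the package's reading of a
  general-linear-model variance decomposition; with unbalanced groups the
  attribution to a factor depends on what else is in the model, which is
  why the output keeps each predictor set explicit.
* **Family-mean analyses** weight every family equally (one row per
  family), the appropriate view when family sizes differ by an order of
  magnitude.

### Survey filters

Satellite genomes are excluded outright. The annotation QC fits
$\log_{10}(\text{residues})$ against $\log_{10}(\text{genome size})$ by
Siegel repeated-median regression — chosen over least squares because the
planted/suspected outliers it must flag would otherwise leverage the fit —
and flags genomes beyond $k = 3$ MADs (a `1e-8` guard is added to the cut
so that exactly-on-trend synthetic sets do not flag on floating-point
noise). The default policy excludes the whole family containing a flagged
genome (`flag-family`), since systematic annotation problems are
family-level phenomena; `flag-genome` drops only the flagged records.
Families must have strictly more than `min_family_size = 10` members to
be tabulated at family level, but their genomes remain in all-virus
analyses; whether historical surveys removed them entirely is ambiguous,
so the accounting is explicit and configurable rather than guessed.

## The synthetic corpus: what it emulates and what it does not

`default_config()` defines 16 families (14 analysable, one satellite
group, one family carrying planted annotation outliers) spanning family
mean disorder ~3–30%, genome sizes 2–150 kb, all seven Baltimore
replication classes plus satellites, within-family size–disorder rank
correlations of both signs, one tri-segmented family, one polyprotein
with three mat_peptides per family, and nested overlapping genes tuned to
per-family overlap targets. Disorder is induced through amino-acid choice
(alternating blocks from strongly order- and disorder-promoting pools,
block length three windows so calls are block-wise clean) while
composition is induced through synonymous codon choice — the two
mechanisms are deliberately decoupled so null corpora (composition bias
without disorder linkage, or vice versa) can be generated for the
statistical tests. The synonymous bias is coupled to family disorder
(C-favouring, T-avoiding as disorder rises), reproducing the qualitative
C-positive / T-negative correlation pattern at both site classes.

Sizes are lognormal per family; the size–disorder coupling uses a
Gaussian copula with $r = 2\sin(\pi\rho/6)$ so the target Spearman
$\rho$ is achieved regardless of the marginals. Per-genome coding density
is drawn uniformly from 0.70–0.95 of genome length (divided by
$1+\text{overlap target}$ so total encoded residues follow one common
residues-vs-size trend), which is what gives the QC a realistic residual
spread to estimate its MAD from. Planted outliers multiply annotated
residues tenfold (duplicated CDS annotations) or truncate them to
one-thirtieth of genome length — an order of magnitude beyond the QC cut
in both directions. A single root seed derives one stream per family, so
adding a family never perturbs the others, and a corpus is reproducible
bit-for-bit from `(config, seed)`.

What the generator does **not** emulate: real gene content, family-true
codon usage, transition/transversion structure, evolutionary covariance
between related genomes (phylogenetic non-independence), annotation
noise other than the planted defects, and any realistic relationship
between a protein's sequence and its biological function. Consequently,
passing tests demonstrate that the pipeline's estimators recover known
structure of this kind — not that the built-in predictor matches any
published predictor on real proteins, nor that effect sizes on real
corpora will resemble the synthetic ones.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GenBank's 1-based
  inclusive notation is converted at exactly one point in the parser, and
  the writer inverts it, so corpora round-trip.
* Segmented genomes merge into one record via a `segment_group` metadata
  column; without it, each record is its own genome (matching how genome
  databases count records).
* Stop codons are excluded from residue counts; `/translation`
  qualifiers win over in-house translation when both exist and disagree
  (with a warning), since curated annotation may encode exceptions the
  standard code cannot.
* The genetic code defaults to the standard table and is configurable
  per call.
* Tables report percentages at 0.1 resolution while intermediate files
  keep full precision; every output embeds the predictor name, window,
  threshold, seed and a digest of the run configuration, and regenerating
  with the same inputs is byte-identical.
* Problem sizes used by the shipped analyses: the default corpus is ~600
  genomes (~13 Mb of sequence, ~13,000 proteins); the model calibration
  uses n = 300 observations with 400 null and 200 power replicates.
  These sizes were chosen so the whole study re-runs in a few minutes on
  a laptop while leaving the Monte-Carlo error of the calibration checks
  well inside their acceptance margins.

## Known limitations

* The built-in predictor is a structural stand-in sharing the windowed
  pairwise-energy architecture, not a reimplementation of any published
  parameter set; absolute disorder levels on real proteomes should be
  computed with an external predictor through the score interface.
* Variance attribution uses plain OLS adjusted $R^2$; with strongly
  unbalanced factors a different sum-of-squares convention would shift
  the attribution (the predictor sets are reported explicitly for this
  reason).
* No phylogenetic correction: genomes within a family are treated as
  independent observations, as in family-stratified descriptive surveys.
* The GenBank parser covers the record subset the survey needs (LOCUS,
  FEATURES with CDS/mat_peptide, ORIGIN; join/complement locations); it
  is not a general-purpose flat-file reader.
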