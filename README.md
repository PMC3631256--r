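# virodisorder

Viruses differ enormously in how much of their proteome is intrinsically
disordered — from a few percent of residues in some RNA virus families to
around a third in some small ssDNA families — and that variation does not
simply track the disorder of their hosts. Understanding it requires
surveying predicted disorder across many annotated viral genomes and then
separating the contributions of genome size, nucleotide composition, viral
type, host and family. `virodisorder` implements that survey as a tested R
pipeline, for virologists and molecular evolution researchers who want to
run it on annotated genome sets (GenBank flat files) or to study its
statistical behaviour on simulated corpora with known ground truth.

## What it computes

**Percent disorder.** A pluggable per-residue disorder predictor assigns
each residue of protein *i* a score *S* ∈ [0, 1]; residues with *S* ≥
*S*<sub>Th</sub> (default 0.5) are called disordered. Per protein,

&nbsp;&nbsp;&nbsp;&nbsp;*D*<sub>i</sub> = 100 · (# residues with *S* ≥ *S*<sub>Th</sub>) / *L*<sub>i</sub>,

and per genome, residues are pooled over all *N* proteins:

&nbsp;&nbsp;&nbsp;&nbsp;*D* = 100 · Σ<sub>i</sub> (# disordered in protein *i*) / Σ<sub>i</sub> *L*<sub>i</sub>,

which is identically the length-weighted mean of the *D*<sub>i</sub>.
The built-in predictor estimates each residue's mean pairwise interaction
energy within a sliding window (a quadratic form in local amino-acid
composition) and maps it through a monotone decreasing calibration;
externally computed per-residue scores (e.g. from IUPred) can be dropped
in via a TSV interface. Polyprotein precursors are scored both intact and
as their cleaved mat_peptide products; the intact value is the default.

**Composition and overlap.** Per genome: base fractions of A, C, G, T on
the deposited strand; the same fractions restricted to third positions of
four-fold degenerate codons (the eight codon boxes whose third base never
changes the amino acid — sites that reflect compositional pressure free of
protein-level selection); and the fraction of coding positions covered by
two or more CDS (overlapping reading frames).

**Statistics.** Spearman rank correlations of disorder with genome size
and with each base fraction at both site classes; a nested OLS ladder —
disorder ~ bases (A, C, G; T as reference) versus disorder ~ bases + size —
whose adjusted-R² difference ΔR² = R²<sub>BS</sub> − R²<sub>B</sub>
measures the genome-size effect once composition is allowed for;
Bonferroni correction scoped to each summary table; and adjusted-R²
variance attribution across predictor sets ({bases}, {size}, {type},
{host}, {family}, …).

**QC and filters.** A robust (Siegel repeated-median) log–log trend of
encoded residues versus genome size flags mis-annotated genomes beyond
*k* = 3 MADs; satellites are excluded; families need more than 10 members
to be tabulated.

**Synthetic corpora.** `simulate_corpus()` generates GenBank-serialisable
genomes from a family-level configuration with known mean disorder,
lognormal sizes, size–disorder rank correlation enforced through a
Gaussian copula, synonymous codon bias, nested overlapping genes,
polyproteins with mat_peptides, segmented genomes, satellites and planted
annotation outliers — ground truth for every pipeline stage.

## Worked example

The analysis scripts run the whole study end to end from the repository
root:

```sh
Rscript analysis/01_simulate.R        # corpus  -> results/corpus/
Rscript analysis/02_survey.R          # tables  -> results/survey/
Rscript analysis/03_truth_recovery.R  # truth   -> results/truth_recovery.tsv
Rscript analysis/04_calibration.R     # nulls   -> results/calibration.tsv
```

Output of a run (seed 1205):

```
Simulated 599 genomes across 16 families (seed 1205).
Planted annotation outliers: V15G001, V15G002, V15G003.
parsed 599 genomes from 1 file(s)
excluded 18 genome(s): qc_outlier 12, satellite 6
scored 581 genomes / 12942 proteins; 14 families tabulated
Analysed 581 genomes; mean disorder 11.9% (sd 9.0), range 0.2-51.8%.
Family mean disorder spans 2.5% to 31.7% over 14 tabulated families.
All-virus Spearman correlation of disorder with genome size: rho = -0.41 (p = 1e-24).
QC: 3 planted outliers, 3 flagged, exact match: TRUE.
Family mean disorder recovery: Spearman rho = 0.998, max |error| = 2.17 points.
Null: size-term rejection rate at alpha=0.05 is 0.040 over 400 reps (nominal 0.05).
Planted effect: detected (p < 0.05) in 100% of 200 reps; median delta-R2 = 0.089.
```

Reading this: the annotation QC removed exactly the three genomes whose
gene annotations were deliberately corrupted (plus their family, under the
flag-family policy) and the six satellites; the surviving 581 genomes show
the configured spread of disorder (family means ~3–30%); family means
estimated by the pipeline rank-correlate at 0.998 with the generator's
targets; and the nested-model size term is calibrated (4% type-I error at
α = 0.05) yet detects a planted standardised size effect of −0.3 every
time.

On real data, point `survey_config()` at your own GenBank file(s) plus a
metadata TSV (`accession`, `family`, `baltimore_type`, `host_category`,
optional `segment_group`) and call `run_survey()`; per-residue scores from
an external predictor can replace the built-in one via the `scores`
argument.

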