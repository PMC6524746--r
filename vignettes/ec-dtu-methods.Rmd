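---
title: "Testing differential transcript usage on equivalence class counts"
author: "ecdtu package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential transcript usage on equivalence class counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdtu)
```

# The problem and the counting unit

Differential transcript usage (DTU) is a change, between biological
conditions, in the relative proportions of a gene's transcript isoforms,
irrespective of any change in total gene expression. Count-based DTU tests
need a *counting bin*: a feature whose per-sample read counts can be
compared across a gene. Two bins are classical — disjoint exon parts
(obtained by genome alignment and annotation flattening) and estimated
transcript counts (obtained by pseudo-alignment plus an inferential
abundance step). This package implements a third choice: the
**equivalence class** (or transcript compatibility class), the set of
transcripts a read is compatible with under pseudo-alignment. All reads
sharing a compatibility set form one class, and the per-sample counts of
these classes ("equivalence class counts", ECCs) are the features tested.

Equivalence classes sit between the two classical bins. They are produced
directly by lightweight aligners with no abundance estimation, only
observed classes exist (far fewer than the combinatorial possibilities,
and typically fewer than exon parts), and — because no EM step spreads a
read's mass across transcripts — their replicate-to-replicate variance
resembles exon counts rather than estimated transcript counts. Both
properties are checked empirically by this package's test suite on
simulated data: per gene, expressed transcripts ≤ expressed classes ≤
expressed exon bins on average, and the mean cross-replicate
log2(variance/mean) of class counts is below that of EM transcript
counts.

# Pipeline

1. **Parse** per-sample equivalence-class output (Salmon `eq_classes.txt`,
   plain or weighted dialect, or a kallisto pseudo-batch directory), or
   produce classes internally with the built-in k-mer pseudo-aligner.
2. **Match** classes across samples by a canonical key (member transcript
   ids, C-locale sorted, joined with `|`) into one integer matrix; a
   sample lacking a class contributes a zero.
3. **Annotate** each class with the unique gene of its transcripts;
   classes spanning more than one gene (`AMBIGUOUS`) are removed, classes
   with unannotated transcripts (`UNKNOWN`) are removed with a warning or
   rejected in strict mode. No abundance filtering is applied by default;
   a DRIMSeq-style expression filter is available opt-in.
4. **Test** each gene for differential class usage with a negative
   binomial GLM on the this-versus-others representation (below), and
   aggregate feature p-values into gene-level q-values.

The two comparator branches share step 4 and differ in the features:
EM-estimated transcript counts (scaledTPM) and flattened exon-bin counts.

# The statistical model

For feature *i* of gene *g*, each sample contributes two observations:
the feature's count ("this") and the summed count of the gene's remaining
features ("others"). Counts are modelled as negative binomial with
log-link mean

\[ \log \mu = \text{sample effect} + \text{bin effect} +
   (\text{condition} \times \text{bin}) \]

with a per-sample log size-factor offset (median-of-ratios
normalisation). The condition main effect is absorbed by the sample
effects; the interaction term carries differential usage. The null model
drops the interaction, and twice the log-likelihood difference is
compared against a chi-squared distribution with (number of conditions −
1) degrees of freedom. GLMs are fit by ridge-stabilised iteratively
reweighted least squares (ridge 1e-6, coefficient-change tolerance 1e-8,
at most 100 iterations); a non-converged feature is flagged and excluded
from the call surface.

**Dispersion.** Each feature's NB dispersion is estimated by maximising
the Cox–Reid adjusted profile likelihood (the NB log-likelihood at
refitted means minus \(\tfrac12 \log\det X^\top W X\)), bounded in
\([10^{-8}, 10]\). A parametric trend \(\alpha(\mu) = a_1/\mu + a_0\) is
fitted across features by iterative gamma regression with outlier
exclusion (ratio outside \([10^{-4}, 15]\)); when nearly all estimates
sit at the floor the trend falls back to the median estimate. Each
dispersion is then shrunk towards the trend as the posterior mode under a
log-normal prior whose variance is the spread of log residuals minus the
approximate sampling variance of a log dispersion estimate
(`trigamma((m − p)/2)`), floored at 0.25. Features whose log MLE exceeds
the trend by more than two residual SDs are dispersion outliers and keep
their MLE. This is the documented estimation strategy of the exon-usage
testing tradition; bit-level agreement with any specific implementation
of it is deliberately not a goal — the test surface is calibration and
power, which the suite measures directly.

**Gene aggregation.** A gene's p-value is the Šidák combination of its
*F* tested features, \(p_g = 1 - (1 - \min_i p_i)^F\), followed by
Benjamini–Hochberg across genes. With one feature per gene this reduces
exactly to BH of the feature p-values. The type-I calibration of the
gene-level p-value is verified on null NB simulations (500 genes, 3 vs 3,
20 seeded replicates): the observed rate of \(p_g < 0.05\) must fall in
the binomial 95% envelope around 0.05 in at least 18 of 20 replicates.
On the q-value scale a correctly FDR-controlling procedure calls
essentially no genes under a global null, and the suite asserts exactly
that (fraction with \(q < 0.05\) at most 0.075). Dependence of feature
p-values within a gene makes the Šidák step conservative in principle;
empirically the calibration sits close to nominal at these sample sizes.

# EM transcript quantification (comparator branch)

Transcript abundances are estimated from a sample's class counts by the
standard equivalence-class-level EM on read fractions \(\alpha\):

\[ \alpha_t \leftarrow \frac{1}{N} \sum_e n_e
   \frac{\alpha_t / \ell_t}{\sum_{t' \in e} \alpha_{t'} / \ell_{t'}} \]

with effective lengths \(\ell_t = \max(L_t - \bar f + 1, 1)\) for mean
fragment length \(\bar f\). This is EM for the observed-data
log-likelihood \(\sum_e n_e \log \sum_{t \in e} \alpha_t/\ell_t\), so the
likelihood is non-decreasing (asserted every iteration in tests) and
total estimated counts equal total assigned reads. Iteration stops when
the largest abundance change drops below 1e-8 (cap 1000 iterations);
uniform initialisation suffices since the likelihood is concave in this
parametrisation up to reparametrisation. TPM renormalises
\(\alpha/\ell\) to one million; scaledTPM counts rescale TPM to the
sample's library size and are rounded to integers before testing. The
tests pin the estimator to a grid search of the same likelihood on
two-transcript problems (1e-4) and to truth recovery within ±0.02 on a
3-isoform gene with 50,000 error-free reads.

# Exon-bin counting (comparator branch)

Per gene, all transcript exons are projected onto the genome and cut at
every distinct boundary, yielding disjoint exon parts labelled with their
covering transcripts; parts overlapping a *different* gene on the same
strand are excluded. A read increments every bin of its gene it overlaps
by at least one base. Bin counting consumes the simulator's true genomic
read intervals rather than re-aligned positions: the package deliberately
isolates the counting-unit comparison from aligner noise, which it does
not model. Flattening is verified against a per-base labelling oracle.

# The built-in pseudo-aligner

A k-mer index (2-bit encoded, k ≤ 31, C++ backend) maps every reference
k-mer to the set of transcripts containing it. A read's class is the
intersection of those sets over all its k-mers *present in the index*;
absent k-mers are skipped — the lightweight-aligner convention, which
keeps assignment robust at exon-junction edges of toy references — and a
read with no informative k-mer, or an empty intersection, is unassigned.
Paired mates' sets are intersected; a mate with no informative k-mer
contributes no constraint. Reads are forward-strand by default (matching
the simulator); a `stranded = "both"` mode unions forward and
reverse-complement assignments. On error-free reads from repeat-free
references the assignment provably contains the source transcript, and
the suite checks exact agreement with a substring-containment oracle on
25 random toy transcriptomes.

Default k is 31, as for realistic references; tiny unit-test references
use smaller k so that short exons still carry unique k-mers.

# The simulator and what it does (and does not) emulate

`simConfig()` defaults define the "switch-mini" study conditions used
throughout testing: 200 genes on one synthetic chromosome, 2–5 isoforms
per gene built as distinct exon subsets sharing an anchor exon (plus a
private exon per isoform when the gene has enough exons), 3–12 exons of
100–600 bp, error-free 100 bp single-end reads, 400,000 expected reads
per sample, two conditions with three replicates each, NB dispersion
0.05, and DTU induced in 10% of genes by exchanging the expression of the
two most abundant transcripts (ties broken by transcript id). The switch
leaves per-gene totals unchanged, so the signal is pure usage without
differential gene expression. Relative gene expression is log-normal
(meanlog 0, sdlog 1) and isoform proportions are symmetric Dirichlet
(gamma shape 2) — unremarkable, field-standard choices for a toy
transcriptome; sizes are chosen so the full three-branch pipeline runs in
minutes on one core.

Two generation paths share one NB transcript-count draw: the *read path*
materialises reads with per-read truth (source transcript, offset,
spliced genomic interval), and the *fast path* pseudo-aligns every read
start position once and distributes each transcript's counts over classes
multinomially. The two paths agree in distribution (checked within
sampling error), and the fast path makes statistics-heavy experiments
cheap.

What the simulator does **not** emulate: sequencing errors and quality
profiles, GC/positional/fragment-length bias, intron retention or novel
junctions, expressed-but-unannotated transcripts, and
condition-dependent gene expression. Passing tests therefore demonstrate
correctness of the algorithms and the qualitative orderings under clean
conditions, not robustness to real-data artefacts — reference
incompleteness in particular shifts real equivalence classes in ways no
test here measures.

# Numerical and design choices

- **Canonical keys** sort transcript ids with radix (C-locale) ordering
  so row keys are platform-independent.
- **Coordinates** are 1-based closed throughout, the native convention
  of the interval containers used; GTF I/O therefore needs no
  conversion.
- **Unknown transcripts** in gene annotation default to drop-with-warning
  rather than error: a strict mode exists for pipelines where the
  reference and the transcript-to-gene map are built together and any
  mismatch is a bug.
- **Zero-count rows** are retained by matrix construction; downstream
  steps decide (all-zero features are flagged untestable).
- **Single-feature genes** cannot be tested (no "others" row) and are
  reported as untested rather than silently dropped.
- **Expression filtering** is opt-in (`filter = "drimseq"`, thresholds
  feature count ≥ 10 in ≥ 3 samples within genes with total ≥ 10 in ≥ 6
  samples); the default pipeline applies none, keeping the multi-gene
  removal the only filter.
- **Evaluation universes**: untested genes are excluded from a method's
  universe and truth sets are intersected with it, so branches are scored
  on comparable gene sets. TPR against an empty truth is reported
  missing; FDR with no calls is 0 by convention. Rank-order ties break
  lexicographically by gene id.
- **Subset experiments** redraw the whole iteration set until every
  sample appears at least once, and are fully seeded.

# Problem sizes used by the checks

The acceptance-style checks run, per seed: the full switch-mini dataset
(three branches end to end); 20 replicates of a 500-gene null for
calibration; 25 toy transcriptomes for pseudo-alignment concordance; and
a 50,000-read EM recovery experiment. These sizes keep the whole suite
within a coffee break on a single core while leaving the binomial
envelopes tight enough to be meaningful.

# Known limitations

- The gene-level aggregation is the Šidák/BH approximation of
  expected-false-positive-grid procedures used elsewhere; agreement with
  any specific implementation's q-values is untested.
- Only single-factor, two-or-more-group designs are supported; no
  covariates, no paired designs.
- The pseudo-aligner is deliberately minimal: no de Bruijn graph
  skipping heuristics, no fragment-length-weighted classes, no
  orientation filters beyond optional reverse-complement union.
- The native k-mer index lives in process memory and does not survive
  serialisation; rebuild it per session.

# A minimal session

```{r example, eval = FALSE}
cfg <- simConfig(nGenes = 50, depth = 1e5, seed = 1)
ds  <- simulateDataset(cfg, what = "ec")
ecm <- filterMultiGene(annotateGenes(ds$ec$matrix, ds$annotation))
res <- runDTU(ecm, ds$conditions)
head(res$genes)
tprFdr(geneQValues(res), dtuGenes(ds$truth))
```
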