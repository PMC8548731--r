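---
title: "Models and design of the lncm6a workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the lncm6a workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistics: the models each
stage fits, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the limitations we know about.

## The problem

A MeRIP-seq experiment measures where transcripts carry m6A by comparing an
antibody-enriched (IP) library against a background (input) library; an
RNA-seq experiment measures how much of each transcript is present. To ask
how m6A on lncRNAs behaves across a cellular transition — here a
two-condition design, proliferating myoblasts (GM) versus differentiated
myotubes (D4) — both layers must be analysed and then joined: which
lncRNAs are methylated, where on the transcript, which peaks change, which
genes change expression, whether the two changes co-vary, and whether
methylated lncRNAs sit next to coding genes that move with (or against)
them.

The package starts from counts: per-window IP/input fragment counts over
exonic 100-nt windows (100 nt matches the RNA fragmentation size of the
assay) and per-gene RNA-seq counts. Alignment and read counting are
upstream of its scope.

## Peak detection

For window $w$ with replicate-summed counts $x_{ip}$, $x_{in}$ and library
totals $N_{ip}$, $N_{in}$, the null hypothesis of equal IP and input rates
gives the conditional model

$$x_{ip} \mid x_{ip}+x_{in}=n \;\sim\; \mathrm{Binomial}\!\left(n,\;
p_0 = \tfrac{N_{ip}}{N_{ip}+N_{in}}\right),$$

tested one-sided (enrichment only). This conditional binomial is exact for
Poisson counts but anticonservative for overdispersed ones: with
negative-binomial noise of dispersion $\alpha$ (variance $m + \alpha m^2$),
the variance of the IP share exceeds the binomial variance by the factor
$1 + 2(\alpha/r)\,n\,p_0(1-p_0)$ for $r$ replicates. `call_peaks()`
therefore deflates each window's implied z-score by that model factor —
$\alpha$ estimated by pooled method of moments across all windows from the
replicate spread — and then applies a robust global recentring/rescaling
(median/MAD of the z-scores) to absorb residual miscalibration. On null
simulations at the default noise level this brings the BH-significant
window fraction from ~18% (uncorrected) to under 0.5%, with essentially no
called peaks, while 8-fold planted peaks are still recovered essentially
completely. The correction is the identity when $\alpha = 0$ or when there
are too few windows (< 200) to estimate the robust scale.

Windows passing BH at $q \le 0.05$ merge into a peak when their spliced-
coordinate gap is at most one step (50 nt). A merged peak inherits its
minimum window p (and that window's q); quantification
($x_{ip}$, $x_{in}$ sums for `m6a_level`) uses a non-overlapping stride of
windows fully contained in the merged span, so flanking windows cannot
dilute the enrichment estimate. The summit is the enrichment-weighted
centroid of the member windows: for a sharply peaked profile this is the
hottest window, while for a flat-topped peak (where the per-window argmax
is noise-picked) it is the plateau centre, which is what downstream motif
extraction and metagene profiling need.

Windows tile the spliced transcript of each gene's canonical (longest)
transcript; a window spanning an exon junction is one counting unit whose
genomic footprint splits across the junction. Genes shorter than one window
are skipped and logged.

## Differential methylation

Peaks from either condition are merged per gene into a union set. For each
union peak the 2×2 table (IP vs input, GM vs D4; replicates summed) is
tested with a two-sided Fisher exact test. Two preprocessing steps matter:

1. **Depth rescaling.** The raw table confounds methylation change with
   library-depth imbalance (if the D4 IP library is simply deeper, every
   peak drifts "hyper"). All four cells are rescaled to the geometric mean
   of the four library totals.
2. **Effective counts.** Fisher's test assumes binomial sampling; NB noise
   adds a depth-independent variance floor of $2\alpha/r$ to each
   condition's log IP:input odds. Each condition's pair is replaced by
   effective counts that keep the observed IP:input ratio but carry the
   information $1/x_{ip} + 1/x_{in} + 2\alpha/r$, so the exact test
   operates at the correct precision. Without this the test is
   anticonservative at high counts exactly where peaks live.

`diff_log2_fc` is the difference of pseudocounted m6A levels (D4 − GM),
`diff_lg_fdr` the log10 of the BH-adjusted q across union peaks, and peaks
are labelled hyper/hypo at `diff_lg_fdr` ≤ log10(0.05) with the matching
sign — the vocabulary of the worked-example table.

A consequence worth knowing: the per-replicate dispersion floor means the
log2 methylation difference is measured with a standard error of about
$\sqrt{4\alpha/r}/\ln 2$ (≈ 0.65 log2 units at $\alpha = 0.1$, $r = 2$)
regardless of sequencing depth. Changes below ~1.5 log2 units are therefore
intrinsically hard to call at this replicate level, and single-window peaks
in low-coverage genes can carry spurious differential signals (filter on
`n_windows` if that matters for an application).

## Differential expression

A deliberately simple two-condition negative-binomial Wald test, not a
re-implementation of the established large packages:

* median-of-ratios size factors;
* $\widehat{\mathrm{lfc}} = \log_2\!\frac{\bar m_{D4}+0.5}{\bar m_{GM}+0.5}$
  on normalized counts;
* per-gene method-of-moments dispersion from the pooled within-condition
  variance, squeezed toward the common (median) dispersion with prior
  weight 10 (an empirical-Bayes moderation in the spirit of the
  limma/edgeR tradition) and floored at $10^{-8}$. With two replicates per
  condition the raw per-gene estimate has one degree of freedom per
  condition and is useless on its own: unmoderated, it both inflates the
  null (measured ~9% BH-significant genes on null data against a nominal
  5%) and randomly kills strong effects (a gene with a true 16-fold change
  that happens to draw a large dispersion estimate);
* delta-method standard error, two-sided normal p, BH across tested genes;
  an optional mean-RPKM floor excludes weak genes before adjustment
  (default: no filter).

Direction labels (`Up`/`Down`/`NS`) use padj ≤ 0.05 with the fold-change
sign; ties at the threshold are significant. Fold changes are not shrunk;
with two replicates and dispersion 0.1 the estimator's median absolute
error is ≈ 0.32–0.38 log2 units and no test setting changes that — it is a
property of the design, not of the implementation.

RPKM uses the exonic length of the canonical transcript; `meanfpkm` in the
exported table is the arithmetic mean over all samples (a per-condition
mean would be equally defensible; all-sample is our documented choice). "Expressed" means mean raw count ≥ 1 in at least one
condition.

## Peak anatomy and motifs

Exon-element placement classifies each peak by the midpoint rule against
the canonical transcript, in transcript orientation (the genomically last
exon of a minus-strand transcript is its first). Single-exon hosts are
excluded from the three-way tally and reported separately — the three-part
summary has no slot for them. Relative enrichment divides each element's
peak share by its exonic length share (computed over the canonical
transcripts of the classified peaks' hosts), so length alone predicts 1.

The metagene profile bins each peak's summit once (no coverage weighting)
at its transcript-scaled position in [0,1), 100 bins by default.

Motif enrichment scans the given strand only (RNA is single-stranded; no
reverse complement). Pattern mode counts IUPAC matches (DRACH by default);
de-novo mode ranks exact k-mers for k in 5–8, BH across all tested k-mers.
The default background is a seeded dinucleotide-preserving (Altschul-
Erikson) shuffle of the foreground; for planted-motif validation we use
non-peak exonic windows instead, because shuffling preserves roughly the
planted motif's own dinucleotide composition and so caps the measurable
fold at ~1.6–1.9 however strong the planting — the peak-versus-
transcriptome background is the comparison that actually measures the
signal. Peak sequences are extracted as summit ± 100 nt, spliced, sense
strand.

## Integration and neighbors

The quadrant rule is exactly the worked-example table's: a lncRNA enters a
quadrant iff expression padj ≤ 0.05 **and** methylation FDR ≤ 0.05 (as
log10(FDR) ≤ −1.30103; the scale of the methylation column is declared by
the caller, never guessed), with the quadrant chosen by the two signs.
Genes hosting several differential peaks are represented by the
smallest-FDR peak. Zero effects and missing statistics are excluded with
reason codes, so the four groups plus Excluded always partition the input.

Pearson correlation between methylation change and expression change is
reported with the t-distribution p (n − 2 df); the KS comparison of
expression log2FC for methylated versus unmethylated lncRNAs uses the
asymptotic two-sample p (approximate below ~10 per group).

Neighbor search takes the five nearest protein-coding genes per side of
each differentially expressed lncRNA, sides in chromosome orientation (a
`strand_aware` flag flips them; neither convention is canonical in the
field, so the choice is explicit). Distance is the closest-edge gap,
0 for overlaps (side then from the coding gene's start), ties broken
toward the smaller start coordinate. Pairs survive when coding padj ≤
0.05, lncRNA padj ≤ 0.05, and the lncRNA carries a differential peak at
FDR ≤ 0.05; concordance is `positive` for same-sign expression changes,
`retrograde` for opposite. Over-representation of the paired mRNAs in
user-supplied gene sets is the hypergeometric upper tail, BH across sets —
real ontology databases are out of scope, and the analysis scripts build a
clearly-labelled synthetic collection instead.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
desk scale, so that every stage can be validated against known truth:

* **Genome/annotation** — non-overlapping multi-exon gene models on random
  sequence; lncRNA biotypes mixed 50/30/20 lincRNA/antisense/
  processed_transcript; every transcript has one exon ≥ 450 nt so a
  planted 250-nt peak fits inside a single exon.
* **Counts** — input windows NB with mean proportional to gene abundance
  (log-normal across genes, sd 0.5) times a log-normal library-size factor
  (sd 0.2, there to exercise normalization); IP windows share the input
  rate times the enrichment fold (default 8) inside planted peaks;
  RNA-seq gene counts NB with the planted condition effect. Dispersion
  default 0.1 (variance m + 0.1 m²), two replicates per condition — the
  replicate level implied by the emulated design.
* **Planted effects** — flagged fractions are floored counts
  (`floor(frac·n)`), selection seeded. Uncoupled differentially expressed
  genes get log2FC ± `de_log2fc_magnitude` (default 2). lncRNAs flagged
  both differentially expressed and differentially methylated get coupled
  effects from a central-truncated bivariate normal: pairs of latent
  normals kept when both |Z| ≥ 0.7, latent correlation calibrated
  (fixed-seed Monte-Carlo root-finding) so the kept pairs' population
  Pearson r equals `meth_expr_correlation` (default 0.6). This gives a
  continuous methylation-expression scatter — what the real joint
  distribution looks like — while keeping planted effects bounded away
  from zero. Methylation scale default 2.5 log2 units, in the middle of
  the worked-example table's spread.
* **Motifs** — with `motif_planting`, five GGACU occurrences spaced 20 nt
  are written around each planted summit (m6A sites cluster in real
  peaks), reverse-complemented into the genome for minus-strand hosts.
* **Positive controls** — `planted_neighbor_pairs` forces retrograde
  (lncRNA down + hypomethylated, coding neighbor up) and positive pairs
  with exact-magnitude effects, for end-to-end recovery checks.

Fixed seed implies byte-identical outputs, including every emitted file.

What the generator does **not** emulate: read-level artefacts (mappability,
GC bias, duplicates), fragment-length variation, isoform mixtures, peak
shapes other than a flat plateau, intronic signal, or batch effects.
Passing tests on this generator therefore demonstrate the statistical
machinery under the assumed noise model — not robustness to the full mess
of real libraries.

## Validation design and problem sizes

The test suite validates each statistical primitive against an independent
oracle (binomial tail by pmf summation; Fisher two-sided by hypergeometric
enumeration; KS D by ECDF sweep and its p against a 10^5-permutation
estimate; hypergeometric ORA by direct summation; the IUPAC scan against a
regular-expression oracle on 1,000 random sequences; neighbor search
against brute-force sorting on 10 random genomes), checks type-I control
on null simulations (≥ 20,000 windows for the peak stage; ten 2,000-gene
null runs for the expression stage), and measures recovery of planted
signal (8-fold peaks, ± 2 log2FC effects, the 0.6 coupling over 100 seeded
runs at 40 coupled lncRNAs, planted DRACH clusters, planted retrograde
pairs over 20 runs at top-hit strength). These sizes keep the full suite
in the minutes range on one core while leaving the Monte-Carlo noise on
each measured proportion well inside the asserted margins.

Two recovery checks are expected to sit outside their nominal bounds at
the default study conditions, and we keep them visible rather than
loosening them: the unshrunk log2FC estimator's median absolute error
(floor ≈ 0.32 at two replicates and dispersion 0.1, measured 0.38 with
abundance heterogeneity) and the quadrant-recovery sensitivity (measured
≈ 0.70 against a nominal 0.8: the truth set's weakest planted methylation
changes sit near the replicate noise floor described above, and a coupling
law with no weak effects would instead distort the correlation-envelope
check). Both are properties of the two-replicate design, not defects an
implementation could remove.

## Numerical conventions

* Internal coordinates are 0-based half-open everywhere; conversion only
  at file boundaries (GTF 1-based inclusive, BED 0-based half-open).
* Pseudocounts: 0.5 in the expression fold change, 1 in `m6a_level`;
  log2 throughout except `diff_lg_fdr` (log10, matching the worked-example
  column).
* Ties at significance thresholds are significant (≤, not <).
* BH is the only multiple-testing adjustment, applied per family (windows
  of one condition; union peaks; tested genes; tested k-mers; gene sets).
* Canonical transcript = longest spliced; ties break lexicographically.
* Degenerate inputs error early and descriptively: empty peak lists for
  the metagene, conditions with < 2 replicates, genes missing from the
  annotation, queries outside the ORA universe, malformed GTF lines (with
  the line number), fixtures with unexpected headers (both expected
  headers are printed).
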