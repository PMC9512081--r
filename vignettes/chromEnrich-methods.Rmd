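---
title: "Statistical methods for peak-proximity enrichment, window-based repeat
  enrichment and permutation nulls"
author: "chromEnrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromEnrich methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`chromEnrich` implements the statistical layer that sits between peak calls
and biological conclusions in regulatory-genomics studies built on CUT&RUN,
ChIP-seq and ATAC-seq: deciding whether a gene set lies unusually close to a
set of binding peaks, whether a repeat family is over-represented inside
peaks, whether several factors co-occupy more loci than chance allows, and
whether chromatin signal over gene bodies differs between genotypes.
Upstream steps -- alignment, peak calling, differential expression -- are
out of scope; their outputs (BED peak files, gene lists, bedGraph coverage)
are this package's inputs.

All coordinates are 0-based half-open on disk (BED convention) and 1-based
closed in memory (`GRanges` convention); overlap always means at least one
shared base, so `[0,100)` and `[100,200)` do not overlap, but they do merge
at gap 0, matching `bedtools merge`.

# The proximity gene-set enrichment model

For a gene universe $U$ (typically all protein-coding or all expressed
genes), two indicator vectors are formed: membership in a gene set $S$, and
proximity of the gene body to any peak within a distance cutoff $D$
(default 50 kb). The resulting $2\times2$ table
$(a, b, c, d)$ -- in-set and proximal, in-set only, proximal only,
neither -- is summarised by the sample odds ratio $ad/bc$ and the
two-sided Fisher exact test; $q$-values are Benjamini–Hochberg, computed
across exactly the family of sets passed in one call and never pooled
across calls.

Conventions that matter for cross-implementation agreement:

* **Proximity is anchored on the gene body, not the TSS.** A gene is
  proximal when a peak overlaps its body extended by $D$ on both sides.
  This makes `proximalGeneIds(peaks, genes, D)` and
  "`extendGenes(genes, D)` overlapping peaks" provably the same rule
  (`proximalGeneIds(…, 0)` is exactly body overlap). The alternative
  "gap $\le D$" formulation differs only when a gap equals the cutoff
  exactly; we chose the formulation that keeps the two published ways of
  phrasing the rule interchangeable. Nearest-gene assignment
  (`nearestGeneTss`), by contrast, is TSS-anchored with a peak-midpoint
  reference and a 1,000 kb cap -- the single-nearest-gene convention of
  region-association tools -- because distance histograms are conventionally
  drawn around the TSS, signed and orientation-aware (upstream negative).
* **The odds ratio is the sample OR,** not the conditional-MLE estimate
  that `fisher.test` reports as its estimate. Zero-margin tables report
  `Inf` (when $ad>0$) or `NA` (when both products vanish); a
  Haldane–Anscombe 0.5 correction is available behind `haldane = TRUE`,
  default off.
* **The two-sided Fisher p uses the point-probability rule**: with margins
  fixed, sum the hypergeometric probabilities of all tables whose point
  probability is at most the observed one, with a relative tie tolerance of
  $10^{-7}$. This is the dominant convention (shared by `fisher.test`), and
  is stated explicitly so ports in other languages can match it. The
  in-package implementation is vectorised over `dhyper`; the test suite
  checks it against an independent `lchoose`-based enumeration over every
  table with margins up to 30 (at $10^{-9}$) and against
  `stats::fisher.test` on random tables.

# Window-based repeat-family enrichment

The genome is tiled into non-overlapping fixed-size windows (default
100 bp). Trailing partial windows are dropped so that all retained windows
are equal-sized, exchangeable units; windows overlapping a blacklist by at
least one base are removed. Each retained window is flagged for overlap
(default: any overlap, $\ge 1$ bp; a minimum-base threshold is exposed via
`minOverlap`) with each repeat family and with the peak set, and each
family's window-count table is tested exactly as above. Windows -- not
bases and not peaks -- are the counting unit, so a long peak contributes as
many peak-positive windows as it spans. `enrichmentByPeakClass` repeats the
analysis per chromatin class after `classifyPeaks`, which labels a peak
heterochromatic iff it overlaps the heterochromatin-mark set (H4K20me3-type
evidence); accessible-chromatin and H3K27ac overlaps are reported as QC
fractions but never drive the dichotomy. BH correction is applied within
one class's family of tests.

# Empirical p-values

Both resampling routes use the add-one convention
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + R)$, whose floor is
$1/(R+1)$ -- with $R = 1000$ the smallest reportable value is
$1/1001 \approx 0.000999$, which is how a "$p < 0.001$" claim is
reproduced exactly. Ties count against the observation. The raw exceedance
count $k$ is kept in every result object so the alternative $k/R$
convention can be recovered.

* `geneSetResamplingTest` scores the percentage of target-set genes
  proximal to peaks, against $R$ sets drawn uniformly without replacement
  from a background pool. Draws are matched to the target-set size by
  default; a fixed size (such as the 512 used with expressed-gene pools) is
  available via `matchSize`.
* `multiwayOverlapPermutationTest` counts consensus loci -- maximal regions
  where at least `minSupport` of the input sets cover a base -- and
  compares against $R$ rounds of independently shuffling every set. The
  shuffle re-places each interval uniformly on its own chromosome, length
  preserved, rejecting placements that touch excluded regions (cap 1,000
  attempts, then a loud error). Keeping intervals on their chromosome of
  origin is the conservative default for a genome with chromosome-scale
  composition differences; shuffled intervals may overlap each other.
  Consensus defaults to full intersection (`minSupport = length(sets)`)
  with the majority rule available through the argument, since published
  "consensus across replicates and antibodies" phrasing rarely pins the
  support rule.

Determinism: every stochastic function takes an explicit integer seed and
restores the caller's RNG state (`withr::with_seed`). The permutation
test's draw order is fixed (replicates outer, chromosomes inner, sets
innermost) so results are reproducible within this implementation;
bit-level agreement across languages is not promised, only within-package
determinism.

# Two-condition signal comparison

`binLog2Ratio` tiles the genome into bins (default 50 bp; 50 kb is typical
for browser-scale views), computes each track's mean coverage per bin and
reports $\log_2((m_A + \psi)/(m_B + \psi))$ with pseudocount $\psi = 1$ by
default (the default of the common coverage-comparison tool); $\psi = 0$ is
allowed only when no bin has zero coverage. A bin belongs to a region iff
its midpoint falls in the region -- the single aggregation convention,
chosen to avoid double-counting bins that straddle region edges.
`geneBodyRatioComparison` then compares DE classes with a Student t test
(Welch available). The default unit entering the t test is the per-gene
mean -- one value per gene -- because per-bin testing pseudoreplicates
(bins within a gene are strongly dependent) and yields the absurdly small
p-values sometimes quoted from such analyses; `unit = "bin"` computes that
variant anyway for comparability, and no attempt is made to reproduce any
specific published per-bin p-value. Genes whose bodies contain no bin
midpoint get `NA` and drop out; a class with fewer than two values skips
its contrast with a message.

# The synthetic-study generator

`generateStudy` builds a complete study from a single master seed with
named substreams (genes, blacklist, target set, decoys, peaks,
co-occupancy, repeats, WT signal, KO signal, up set), so nulling or
re-parameterising one component never perturbs another's draws -- the
property that makes paired planted/null comparisons exact.

Default study conditions, chosen once as a realistic desk-scale analogue
of a mammalian regulatory-genomics study and then left alone:

* **Genome**: 5 chromosomes of 60 Mb. Large enough that ~600 peaks are
  sparse (as real peak sets are), small enough that the full pipeline runs
  in seconds to minutes.
* **Genes**: 2,000 non-overlapping genes, lengths log-uniform on 1–10 kb,
  minimum intergenic gap 110 kb. The gap is deliberately larger than
  `placement_window + maxDistance + peak length` so that a peak planted for
  one gene cannot leak proximity onto a neighbour; the planted odds ratio
  is then interpretable. Twenty clusters of 3 genes within 100 kb are the
  deliberate exception, emulating the clustered co-regulated genes real
  studies highlight; they are a small minority (3%) so cluster spillover
  barely attenuates the planted effect.
* **Planted proximity**: each target gene receives a peak with probability
  $p_t$ and each non-target gene with probability $p_{nt} = 0.15$, where
  $p_t$ is derived from a planted odds ratio (default 5) via
  $\mathrm{logit}(p_t) = \log\omega + \mathrm{logit}(p_{nt})$. Uniform
  background peaks (100) and shared co-occupancy loci (150) add proximity
  to targets and non-targets alike, so the realised sample OR is attenuated
  below $\omega$ (median $\approx 3.7$ for $\omega = 5$, $\approx 1.6$ for
  $\omega = 2$ in 20-seed pre-build simulations) -- an expected and
  documented feature of planting via placement rather than via the final
  table.
* **Co-occupancy**: 150 shared loci copied into all three peak tracks with
  independent ±50 bp jitter. Against a 300 Mb genome, the three-way
  shuffled null is essentially zero, so the permutation floor
  $p = 1/(R+1)$ is attained with overwhelming probability.
* **Repeats**: three families; LINE_like carries a 12× within-peak density
  excess (planted), SINE_like and LTR_like are neutral.
* **Signal**: Poisson counts per 50 bp bin, $\lambda = 20$; the KO track
  multiplies $\lambda$ by 0.5 over down-class (target) gene bodies and by
  2 over a 100-gene up class. With $\psi = 1 \ll \lambda$, the expected
  down-class mean is $\log_2((0.5\lambda + 1)/(\lambda + 1)) \approx
  -0.93$, within the ±0.15 recovery band around $-1$; Poisson noise was
  chosen over negative binomial as the simplest model that exercises the
  ratio/t-test stage (an overdispersed variant would only widen per-gene
  variance, which the per-gene unit already absorbs).

What the generator does **not** emulate: sequence content (no FASTA/reads/
motifs), chromatin-domain structure, GC or mappability bias, overdispersed
counts, and correlated peak placement beyond the planted structures.
Passing tests therefore demonstrate the statistical machinery's
correctness and calibration under a known truth, not robustness to every
artefact of real sequencing data.

`nullVariant` destroys exactly one planted structure -- target set redrawn
uniformly, peaks re-shuffled, or KO regenerated at fold 1 -- and is the
basis of the calibration tests: under null gene sets the Fisher p-rate at
0.05 stays within its binomial band (the exact test is discretely
conservative), and both empirical-p routes are approximately uniform.

# Problem sizes used in the test suite

The acceptance-level checks run at the sizes their claims state: the
Fisher/enumeration sweep covers every table with margins up to 30
(~30,000 margin triples); interval arithmetic is checked against per-base
bitmaps on 500 random fixtures over ≤10 kb genomes; calibration uses 200
null gene-set replicates for the Fisher rate and 100 seeds each (199
resamples/permutations per seed) for the empirical-p uniformity bands;
parameter recovery uses 50 seeds per planted odds ratio and 50 seeds for
the repeat-family detection rates; the two printed-value checks run the
full $R = 1000$. Unit tests use a scaled-down study (2 × 5 Mb genome, 60
genes) where only mechanics, not calibrated rates, are at stake.

# Known limitations

* **The window-level Fisher test is anti-conservative under spatial
  clumping.** A repeat instance or peak spanning several windows turns its
  windows positive as a block, so co-positive windows arrive in clumps and
  the variance of the co-occurrence count exceeds the hypergeometric
  variance the exact test assumes (in our null simulations with 150–600 bp
  features over 100 bp windows, standardised excess counts have standard
  deviation ≈ 1.8 instead of 1, i.e. ≈ 3× variance inflation, and a
  truly neutral family reaches q < 0.05 in roughly a fifth of seeds; with
  features confined to single windows the inflation disappears). This is a
  property of the window-counting procedure itself — any analysis that
  tiles a genome into windows smaller than its features and treats windows
  as exchangeable inherits it — and it means window-level q-values for
  weakly enriched families should be read as rankings rather than
  calibrated error rates. Strongly planted enrichments (odds ratios well
  above the clumping noise) are unaffected in practice.
* The Fisher implementation enumerates the hypergeometric support per
  table; for the window-count tables (~3 × 10⁶ windows) the support is
  large but `dhyper` remains vectorised and fast. Conditional-MLE odds
  ratios and exact confidence intervals are out of scope.
* `shuffleIntervals` rejection sampling assumes exclusions leave room for
  every interval; pathological exclusion coverage fails loudly after 1,000
  attempts rather than degrading silently.
* bigWig input is not parsed; convert coverage to bedGraph with standard
  tooling (`bigWigToBedGraph`) first.
* The interval-permutation null preserves interval lengths and chromosome
  assignment but not local context (GC, segmentation); segmentation-aware
  nulls are deliberately out of scope.
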