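---
title: "Breakpoint analysis for gene fusion discovery: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint analysis for gene fusion discovery: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakscan)
```

## The idea

A chromosomal rearrangement that fuses two genes changes two measurable
things about each partner. At the RNA level, the fused portion of a 3'
partner is transcribed from its new 5' promoter — often far more strongly
than its native promoter — so exons distal to the junction are elevated
relative to proximal ones (a 5' partner shows the mirror image). At the DNA
level, unbalanced rearrangements change copy number on one side of the
junction, so a copy-number segment boundary falls *inside* the gene body.
breakscan scans for both signatures, filters them against a list of known
cancer genes annotated with their fusion role (5' or 3' partner), and then
identifies the partner gene directly from paired-end RNA-seq.

Coordinates are 0-based half-open internally; on disk, BED stays 0-based
while GFF3 and SEG are 1-based. Exons are stored in transcript order
(reversed genomic order on the minus strand) so that "proximal/distal"
always means 5'/3' of the transcript; this is what makes the direction
filters strand-correct.

## RNA breakpoint analysis

For one gene in one sample, the exon profile is the ordered vector of log2
expression values. At every junction $j$ the walking test compares exons
$1..j$ with $j{+}1..m$ using a classical pooled-variance two-sample t-test,
two-sided, with $m-2$ degrees of freedom. Pooled rather than Welch: exon
counts per side are small (down to 2), where the classical test is the
textbook default and the equal-variance assumption is reasonable for probes
of one gene measured on one array.

Choices that matter:

* `min_group = 2` exons per side — a variance needs two points, so genes
  with fewer than 4 exons are skipped (and counted). With missing values
  dropped per gene, group sizes may be unequal; junction indices always
  refer to the original exon numbering.
* The Bonferroni family is the number of junction tests *actually performed
  per sample* across the scanned gene set, recorded on every call. With a
  ~300-gene list of 8–20-exon genes this lands in the low thousands,
  matching the per-platform family sizes a fixed candidate list produces.
  We record the realized family size rather than asserting a constant,
  because exon-count filtering changes it.
* Per (gene, sample) only the minimum-P junction is reported; ties go to
  the most 5' junction (deterministic).
* The t statistic is mean(distal) − mean(proximal) over the pooled SE, so
  $t > 0$ means distal elevation; the direction filter keeps
  `distal_elevated` for `three_prime`/`either` roles and
  `proximal_elevated` for `five_prime`/`either`.
* Degenerate profiles: zero pooled variance with equal means reports
  $t = 0, p = 1$; with unequal means the test is off the t scale entirely,
  so the call is flagged and given the smallest representable P rather than
  a fabricated statistic.

Internally the scan is vectorised over samples with centred cumulative
sums; the test suite certifies equality with junction-by-junction `t.test`
calls to 1e-12 relative tolerance, plus the reversal symmetry (junction
$j \to m-j$, $t \to -t$, P invariant).

## DNA breakpoint analysis

### Segmentation

Probe-level log2 ratios are fitted with the 1-D fused lasso: total-variation
denoising

$$\min_x \tfrac12\sum_i (x_i - y_i)^2 + \lambda_2 \sum_i |x_{i+1} - x_i|$$

followed by soft-thresholding with $\lambda_1$, which is exactly the
fused-lasso solution and makes copy-neutral probes *exactly* zero — the
smoothing walk's neutrality test is evaluated on fitted values precisely so
that "log2 ratio = 0" is meaningful rather than vacuous on noisy data. The
TV solver is a direct O(n) single-pass algorithm in C++; the tests certify
exact optimality through the KKT conditions and cross-check an independent
box-constrained dual QP solved with `optim(L-BFGS-B)`.

$\lambda_2$ is calibrated per track: probe ratios are mean-centred (so true
alteration mass cannot drag the null fit off zero), shuffled within the
chromosome (20 permutations, seeded), and the smallest penalty on a
half-octave log grid whose expected null non-neutral probe rate is ≤ the
FDR target (default 1%) is chosen. The grid step matters: with octave
spacing the chosen penalty can overshoot the FDR-minimal one by 2x, which
over-smears short high-level events; half-octave spacing caps the overshoot
near 40%. $\lambda_1$ defaults to 0.1 log2 units — well below the 0.3
amplitude floor for reportable CNAs, so it decides neutrality, never
segment acceptance.

### Copy-number smoothing

The walk over each chromosome:

1. The next candidate CNA is the next non-zero same-sign run of the fitted
   signal. Because the fusion penalty smears short events over neutral
   neighbours, the candidate's boundaries are refined against the *raw*
   ratios as the maximal-scoring contiguous stretch of signed ratio minus
   `theta` (Kadane's algorithm) — single noisy edge probes cannot then
   truncate or pad the event.
2. Acceptance: raw |mean| ≥ `theta` (0.3) over ≥ `min_len` (50) probes, or
   ≥ `high_theta` (1.0) over ≥ `high_min_len` (10) probes (high-level).
3. Walk-down: the lower boundary is the first position whose own fitted
   value has left the CNA (exactly 0, opposite sign, or differing from the
   accepted stretch's fitted mean by ≥ `theta`) *and* where ≥ 95% of the
   window starting there (100 probes; 50 for high-level) also qualifies —
   or the chromosome end. Requiring the window and not just one probe is
   what merges noise-split segments instead of stopping at every blip; a
   window test alone, slid probe by probe, would instead fire up to 5
   probes early (once ≤ 5% of the window is still CNA) and truncate every
   segment, so the current-position condition is essential to reproduce
   exact boundaries on clean signals. The boundary lands on the first probe
   of the terminating window (deterministic tie-break).
4. The final segment mean is recomputed from raw ratios between the
   refined boundaries; `level` is `high` iff |mean| ≥ 1.0. The mean-shift
   criterion in step 3 compares fitted values to the *fitted* mean of the
   accepted stretch — comparing shrunken fitted values against the raw mean
   would make strong events terminate on themselves.

Segment boundaries strictly inside a gene span become breakpoints. The
altered transcript end (is the gene's 5' or 3' end inside the CNA?) is
computed in transcript orientation, and the census filter mirrors known
fusion geometry: a 3'-partner kinase requires gain of its 3' end or loss of
its 5' end; 5' partners the mirror image; `either` passes both. Focality
(default: segment under 1,000 probes) is reported for prioritisation only —
the threshold is a convention, not a biological constant, so it never
excludes a call.

## Paired-end fusion-partner nomination

The pipeline is seeded with a candidate gene (from RBA/DBA), not run
genome-wide. Stages: extract pairs with exactly one read in the candidate's
exons and the mate elsewhere or unmapped; nominate partners by the gene the
mate overlaps (ambiguous overlaps assign to all and are flagged; intergenic
mates fall into 100-kb bins); remove immediately adjacent same-strand
partners (readthrough transcripts — same-strand pairs with an intervening
gene survive, the geometry of a genuine ~1 Mb rearrangement); rescue
unmapped mates by ungapped alignment (both strands) across every ordered
exon-pair junction sequence of the two genes, built from read-length−1 nt
of context on each side, with ≤ 2 mismatches.

Decisions the data forced:

* **Consensus junction.** A chimeric read with only a few nucleotides
  beyond the junction matches several exon pairs within tolerance, so the
  junction is the modal exon pair across rescued reads (ties: fewest total
  mismatches, then lowest pair), not any single read's best hit.
* **Junction without chimeric reads:** the nearest exon boundaries
  compatible with every supporting pair (smallest 5' exon end at or beyond
  all 5'-side reads; largest 3' exon start at or before all 3'-side reads).
* **Insert estimate:** fragment length in fusion-transcript coordinates —
  distance from each read's inner end to the junction plus both read
  lengths; candidates need a median in [100, 400] nt and ≥ 2 supporting
  reads (discordant pairs and chimeric reads pooled).
* **Orientation:** both 5'/3' assignments of the pair are evaluated and the
  better-supported one kept (ties favour chimeric evidence, then the anchor
  as 5'). Junctions are restricted to annotated exon boundaries in the
  sense orientation; intra-gene events (EGFRvIII-like exon skips) are out
  of scope for the partner scan.
* **Frame:** in-frame iff the 5' gene's coding length to the junction and
  the 3' gene's coding offset at re-entry agree modulo 3; junctions in a
  UTR on either side are `unknown` (a 3' gene entered in its 5'UTR may
  still translate from an internal start codon).
* Mapped reads with an NM tag above 2 are demoted to unmapped (and thus
  eligible for rescue), mirroring an aligner restricted to ≤ 2 mismatches;
  without NM tags the filter is skipped.

## Supervised signature

Genes pass with |Pearson R| ≥ 0.5 against the binary class label, two-tailed
pooled t-test P < 0.001, and ≥ 2-fold change (computed as
$2^{|\Delta \text{log2 mean}|}$, two-sided; the elevated direction is
reported as a flag). The FDR is the *global* estimator — mean pass count
over label permutations (class sizes preserved) divided by the observed
count — rather than a per-gene q-value; with zero observed passes it is
reported as 1 when permutations produce passes and NA otherwise. The
permutation stream is seeded and isolated from the caller's RNG, so results
are bit-reproducible and gene-order invariant.

## What the synthetic data does and does not show

The generators emulate the statistical structure of the real inputs: exon
profiles as i.i.d. Gaussian noise around cohort-centred zero with planted
distal steps; copy-number tracks as piecewise-constant means plus Gaussian
probe noise; transcriptomes as random-nucleotide multi-exon genes with
planted chimeric transcripts, Gaussian insert sizes, per-base substitution
errors, and junction-spanning reads left unmapped to exercise rescue.
Default study conditions: ~300-gene candidate sets with 8–20 exons, exon
noise 0.3 log2 units; 440-probe chromosomes with probe noise 0.15 and
planted events of amplitude 0.8 x 120 probes (plus 1.4 x 12 high-level and
sub-threshold decoys); fusion libraries of 10–100 pairs, insert 200–350 ±
30 nt, 75-nt reads, 1% error, with single-pair and 500-nt-insert decoys.

Real data violate these assumptions in known ways the suite does not test:
exon-level expression is heteroscedastic and probe effects are correlated;
aCGH noise has waviness and GC structure; real transcriptomes have homology
(pseudogenes, paralogues) that makes chimeric rescue and partner assignment
genuinely ambiguous; and SAM records here are minimally valid (constant
qualities, `readlenM` CIGARs). Passing the suite therefore demonstrates the
algorithms' correctness and calibration under the stated noise model, not
robustness to platform artefacts — thresholds (`theta`, insert bounds,
mismatch caps) should be revisited per platform.

Problem sizes in the tests and acceptance script (200 null samples, 100
simulated chromosomes, 20 fusion libraries, 100 signature permutations) are
the package's chosen desk-scale study conditions; all seeds are explicit,
and generators restore the caller's RNG state.

## Known limitations

No microarray normalisation or platform annotation mapping (inputs are
assumed normalised and cohort-centred); no allele-specific copy number, LOH
or GC correction; no de novo alignment or genome-wide unbiased fusion
calling; no splice-aware (gapped) alignment in rescue — junctions are
exon-boundary only. The shipped census structure is synthetic: real
analyses should supply their own cancer-gene list with fusion-role
annotations, since licensing and version drift make bundling one
inappropriate.
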