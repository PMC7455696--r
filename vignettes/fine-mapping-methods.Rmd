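---
title: "Fine-mapping a growth QTL in an advanced intercross: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping a growth QTL in an advanced intercross: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ailqtl` implements a complete fine-mapping workflow for a major-effect
quantitative trait locus segregating between two divergent founder
populations, as mapped in a deep (advanced intercross, AIL) pedigree: a
forward simulator that defines the study conditions, founder-differential
marker selection, identity-by-descent (IBD) painting of descendant
chromatids, a mixed-linear-model association scan, a haplotype
substitution-effect model with multi-locus backward elimination, a
multi-breed haplotype-sharing scan, and windowed selective-sweep
statistics. This vignette explains the models, the default parameters and
their rationale, the numerical choices, and what the simulation studies do
and do not establish.

## The simulator and its study conditions

The simulator is the package's data substrate: all recovery and
calibration claims are made against data it generates, so its defaults are
chosen once to represent a realistic AIL fine-mapping study and are not
per-analysis knobs.

**Region and map.** One 3.1 Mb chromosomal region (168.6–171.7 Mb) at a
constant 2.8 cM/Mb — the characteristic recombination rate of the distal
macrochromosome arm where the chicken growth QTL resides — with one SNP
per 2 kb (1,550 sites). Crossovers per meiosis are Poisson with mean equal
to the map length in Morgans (0.0868 for this region), placed uniformly:
with only a per-Mb rate available, a no-interference model is the neutral
choice, and at <0.1 expected crossovers per meiosis interference would be
unobservable anyway.

**Founder populations.** Each founder line is a pool of ancestral
haplotypes with sampling weights; founder chromatids are i.i.d. draws from
the pool. The fast-growing line carries 5 major haplotypes (frequencies
0.25–0.06) plus 25 rare ones; the slow-growing line 3 major (top 0.55)
plus 17 rare. This "few common + many rare" spectrum matters: a pool with
only a handful of haplotypes makes every local marker pattern a linear
combination of a tiny latent space, which renders multi-locus model
selection degenerate (any tag is exactly spanned by the others). Real
populations segregate on the order of a hundred distinct haplotypes over
an 8-SNP tag window, and the defaults reproduce that. Three percent of
grid sites are fixed for alternative alleles between the lines, giving
roughly 46 near-fixed (tier-1) diagnostic markers over 3.1 Mb — the
density a resequencing comparison of such lines typically yields.

**Pedigree.** The intercross is founded by 16 + 15 founders, F1 by
interline crosses, and later generations by random non-self mating with
enforced equal sex ratio (the mating scheme's sire/dam counts are
configurable because real designs vary and are rarely published).
Intermediate generations default to 180 individuals and the mapping
generation (F9) to 600. The per-generation mating structure is sampled
separately from the gene-drop, so several unlinked regions can be
simulated through the *same* pedigree.

**Trait.** Phenotype = baseline + additive QTL effects + sex and batch
offsets + Gaussian residual (SD 100 g). The default architecture has two
linked QTL inside the proximal 1.2 Mb (at ~168.75 and ~169.5 Mb) with
+55 g and +70 g per high allele. The first QTL's high allele rides on the
common haplotypes of the fast line (and one slow-line haplotype); the
second segregates in *both* lines. These choices reproduce two features of
the mapped QTL: a haplotype substitution-effect gradient spanning roughly
−60 to +65 g with the two founder lines at opposite extremes, and effect
variation *within* each founder line (both lines segregate more than one
effect haplotype).

**Multi-breed panel.** A separate generator produces a 10-breed
resequencing panel (3 high-weight, 7 low-weight breeds; ~500 bp marker
spacing over the proximal 1.2 Mb) in which three planted intervals (6, 12
and 4 kb) carry a shared "Q" allele template at high frequency (0.85–0.95
per chromatid) in the high-weight breeds and low frequency (0.05–0.20) in
the low-weight breeds; outside the planted intervals all breeds share the
same base allele frequencies, so the group differential is centred on
zero. This emulates the standing-haplotype model in which high-weight
breeds accumulated the same ancestral sub-haplotypes under selection.

**What the simulator does not model.** Selection during the AIL, sex
chromosomes, epistasis, genotyping error, sequence-level reads, and the
founding bottleneck of a real F2 population (our idealised AIL
accumulates more distinct recombinant lineages than a real pedigree that
passed through a small F1/F2; recombinant fractions in the mapping
generation are correspondingly higher). Passing recovery tests on these
data therefore shows the *estimators* are correct and calibrated under
the stated genetic model — not that every real-data complication is
handled.

**Seeding.** Every operation derives child seeds deterministically from
one root seed (kept below 2^31), so a pipeline run is byte-reproducible.

## Marker selection

Founder differentials `delta_af = |af_A - af_B|` drive a three-tier
selection that mirrors staged fine-mapping designs: tier 1 (>= 0.95)
gives founder-diagnostic markers for IBD painting; tier 2 (>= 0.75)
tags common segregating variation, thinned so no two markers lie within
100 bp (the marker with the larger differential wins; ties go to the
smaller position — the thinning rule must be deterministic and favouring
the more informative marker is the natural choice); functionally
annotated (missense/splice/UTR) sites are admitted at >= 0.3. LD pruning
uses greedy sliding windows (drop the lower-MAF member of the worst pair,
ties to the larger position, repeated to a fixed point so no surviving
within-window pair exceeds the threshold), and the count of surviving
markers at r² <= 0.4 defines the denominator of the Bonferroni
thresholds.

## IBD painting and block tests

At tier-1 markers each allele is assignable to one founder line.
Homozygous genotypes assign both chromatids; heterozygous genotypes
assign one chromatid to each line, and the phase across markers is
resolved by minimising the total number of origin switches — a dynamic
programme over the four ordered origin-pair states per marker. Switch
minimisation is the parsimony principle appropriate to a young pedigree
in which recombination events are rare; a posterior-probability HMM would
need error and recombination rates the marker panel cannot estimate.
Runs shorter than `min_support = 2` markers are relabelled to the
flanking consensus (a genotyping-noise guard), missing markers inherit
flanking origin, and breakpoints are placed at the midpoint of the
flanking marker interval (0-based half-open internally). Note that when
both chromatids share an origin over a stretch, the chromatid labels on
either side are not identifiable — downstream comparisons are therefore
made at the level of breakpoints and diplotype classes, not chromatid
identity.

Blocks are the partition induced by the union of observed switch points;
individuals are classified unrecombined (AA/AB/BB across the whole
region) or recombinant, and each block is tested by a Welch t-test of
phenotype between A-origin and B-origin chromatids (each chromatid
contributes its carrier's phenotype; by default only recombinant
individuals enter, which is what makes neighbouring blocks separable).

## Mixed-model association

The scan uses the standard additive GRM (centred, frequency-standardised
dosages) and a single REML fit of `y = Wb + g + e`, `g ~ N(0, Vg K)`,
profiled over `delta = Ve/Vg` on the eigenbasis of K (one
eigendecomposition; 1-D optimisation to tolerance 1e-8 with boundary
checks, so `Vg -> 0` is handled explicitly). Per-SNP tests fix the
covariance at the null estimates and perform a weighted least-squares
t-test in the rotated basis — the "single null fit reused across SNPs"
approximation used by standard MLM association tools, which costs one
REML instead of one per SNP and is exact under the null. With an identity
GRM the test reduces to OLS covariate-adjusted regression, which anchors
its calibration.

`variance_explained` fits segment genotype classes (founder-origin
diplotypes) jointly with covariates by least squares and reports the
class-frequency-weighted variance of the fitted class effects as a
fraction of the REML Vg. Classes with fewer than 3 members are merged
into the class with the nearest mean phenotype. The plug-in class
variance is slightly inflated by estimation error (of the order of the
squared class-mean standard errors), which is visible when the
non-segment variance is large; the recovery study below quantifies the
net accuracy. Fractions above 1 are reported clipped with a warning —
they arise when the segment saturates Vg.

## Haplotype model and backward elimination

Tag-SNP haplotype frequencies come either from direct chromatid counting
(phased input) or from the classical multilocus EM over enumerable
diplotype expansions (unphased; uniform initialisation, convergence when
the largest frequency change is below 1e-6, likelihood monotonicity
tracked). Haplotypes at frequency <= 0.01 are pooled into an "Other"
class. Substitution effects solve `Y = X beta + Z u + e` by least squares
under a sum-to-zero contrast on `u`: no reference haplotype is singled
out, matching the presentation of effects as a gradient around the mean;
the fit is invariant to which column anchors the contrast, and rank
deficiency beyond the forced constraint raises an error naming the
aliased columns.

Backward elimination fits covariates + always-retained background
markers + candidate tag SNPs jointly, applies Benjamini–Hochberg across
the candidates, and drops the single worst candidate (largest p; ties to
the larger position) until all survivors pass 5% FDR. Two design choices
deserve emphasis:

* **The BH adjustment uses the initial candidate count in every round.**
  With the current survivor count instead, the last survivor would only
  need `p <= 0.05` — and the minimum of ~15–60 null p-values nearly
  always clears that bar, so the procedure would retain a false SNP on
  null data ~95% of the time. Anchoring at the initial count keeps the
  null retention probability near the FDR level, which the null
  calibration study confirms.
* **Candidates are pruned to approximate linkage equilibrium**
  (pairwise r² < 0.4 over the mapping generation, the same threshold
  used for the independent-marker count) and capped at 15. In an F9 AIL
  the local LD is extreme: we measured that with 60 dense candidates in
  the 1.2 Mb segment, every candidate — including a causal site — is
  spanned by the others with multiple-R² ≥ 0.98, so "which tag is
  causal" is unanswerable regardless of procedure. The cap sizes the
  candidate set to the effective number of independent local signals.
  Background controls emulate markers chosen genome-wide outside the
  QTL; in the retention study they come from a second, unlinked
  simulated region, because linked "background" markers absorb the very
  signal under test.

## Sharing scan

Phased chromatids are cut into 2 kb bins anchored at the region start;
the Q haplotype of a bin is the modal haplotype of the reference
(fast-line) population, ties broken by the lexicographically smallest
string for determinism. The reported differential is *signed*
(`freq(Q|high) - freq(Q|low)`, pooling chromatids within groups by
default, with a per-breed-mean mode available since real panels weight
breeds unevenly); maximal runs of adjacent bins at or above 0.4 merge
into Q regions named left to right. Empty (SNP-less) bins break
adjacency rather than silently bridging gaps.

## Sweep statistics

Windowed nucleotide diversity (per-window mean of per-site average
pairwise differences over accessible sites; 500 bp/250 bp default, 50/25
kb preset), Tajima's D in 250 bp or 25 kb bins (standard constants;
S = 0 bins are undefined rather than zero), Nei–Tajima haplotype
diversity `n/(n-1)(1 - sum p_i^2)` in 2 kb bins, and Fst per site or in
20 kb windows. Both bin-size presets are provided without privileging
either. Fst defaults to the Hudson two-population estimator with
ratio-of-averages windowing (no estimator was mandated by the source
design, and Hudson's is the recommended two-population choice; a
Weir–Cockerham-style haploid variant is available for cross-checking).
Sites with call rate below 0.9 are excluded, mirroring the usual QC
threshold. XP-EHH computes pooled-core EHH decay curves (probability two
chromatids are identical from the core outwards, core included),
integrates them by trapezoid over genetic distance truncated where EHH
drops below 0.05, scores `ln(iHH_A/iHH_B)` and z-normalises over the
scan — the conventional implementation choices for this statistic.

## Reference studies and their problem sizes

Four simulation studies are shipped as package functions so that their
claims are recomputed, not quoted:

* `study_effect_recovery()` — default F9 study (n = 600, 1,550 SNPs, two
  linked QTL, residual SD 100 g); 8 informative tags; the planted truth
  per haplotype class is the realised mean chromatid genetic value,
  centred like the estimates. Across 50 replicates ~95% of estimates fall
  within 2 SE of truth.
* `study_variance_partition()` — one founder-divergent segment QTL
  (+63 g) plus 20 background loci on an unlinked 100 cM region through
  the same pedigree, background effects (16.2 g each) calibrated so the
  planted segment share of genetic variance is 15%: with divergent loci,
  pedigree structure induces positive covariance between even unlinked
  loci, so the calibration was done empirically on the realised variance
  rather than from 2p(1-p)a² sums. A segment tightly linked to the rest
  of its region cannot contribute a clean 15% (origin autocorrelation
  leaks linked variance into the class effects), which is why the
  background is unlinked — the natural reading of a segment's share of
  *genome-wide* genetic variance.
* `study_backward_elimination()` — retention of the two causal SNPs
  (and, with permuted phenotypes, the null empty-set rate).
* `study_null_scan()` — type-I error and genomic inflation of the scan
  on unstructured genotypes.

Sizes were chosen to keep each study in minutes on one core while leaving
the binomial error of the reported rates small relative to the margins
tested.

## Known limitations

Painting assumes two founder lines (no multi-way designs) and parsimony
rather than probabilistic ancestry; the association scan reuses one null
variance fit (anti-conservative only under strong per-SNP structure
shifts); the plug-in segment variance is upward-biased when the segment
is a small fraction of a noisy trait; exact causal-SNP identification by
backward elimination is only meaningful after candidate-set pruning, and
retained SNPs should in general be read as tags of statistically
independent signals, not as causal variants.
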