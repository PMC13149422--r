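---
title: "Methods: k-mer presence/absence GWAS and phosphorus-efficiency phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer presence/absence GWAS and phosphorus-efficiency phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosgwas)
```

# Scope and model

`phosgwas` implements the computational chain of a phosphorus-efficiency
screen in the *Medicago sativa* complex: an alignment-free k-mer GWAS from
short reads to candidate-gene windows, the phenotype indices used to rank
accessions (shoot P content, PUE, STI, ΔRDM), p-distance redundancy pruning,
and root-system-architecture (RSA) trait extraction from rhizotron scan
masks. Because genotyping an outcrossing autotetraploid against a single
reference genome misses structural and presence/absence variation, markers
here are canonical 31-mers scored present/absent per accession — no
alignment, no variant calling.

## The association model

For each k-mer the trait vector $y$ (one value per accession; the mean over
replicates within a treatment) is modelled as

$$ y = \mu 1 + x\beta + u + \varepsilon, \qquad
   u \sim N(0, \sigma_g^2 K), \quad \varepsilon \sim N(0, \sigma_e^2 I), $$

where $x$ is the 0/1 presence column, and $K$ is the kinship estimated from
the marker matrix itself: $K = X_c X_c^\top / m$ over the $m$ column-centered
presence columns. The kinship formula is not prescribed by any standard — the
centered cross-product is the usual realised-relatedness estimator for a
binary marker matrix; a per-column standardised variant is available via
`kinship_from_pa(normalise = TRUE)`.

Both the null ($\beta = 0$) and alternative models are fitted by **maximum
likelihood** (not REML), because the likelihood-ratio statistic
$2(\ell_1 - \ell_0)$ compares models with different fixed effects and is only
valid on ML likelihoods. After one eigendecomposition of $K$, the profile
likelihood is a one-dimensional function of the variance ratio
$\lambda = \sigma_g^2/\sigma_e^2$, maximised on a $\log_{10}$ grid over
$[10^{-5}, 10^5]$ and refined by Brent search in the bracketing interval.
Variance components are re-optimised under the alternative for every marker
(the exact LRT); `fast = TRUE` holds $\lambda$ at its null value, which is
the usual score-test shortcut. P-values come from $\chi^2_1$ and are floored
at $10^{-300}$ rather than truncated to zero.

Significance uses two tiers: $-\log_{10} p > 5$ (strict) as the primary
criterion and, for traits where nothing clears it, the top signals at
$-\log_{10} p \ge 4$ (inclusive). No further multiple-testing correction is
applied — the fixed thresholds *are* the correction policy of this design.

## K-mer machinery

Counting is per sample: all 31-base windows of each read, windows with
ambiguous bases skipped, tallied under the canonical form (the
lexicographically smaller of the k-mer and its reverse complement) with
orientation bookkeeping. Two reading decisions were genuinely open:

* **The count floor of five is per sample**, applied to the canonical
  (orientation-summed) total. Both the floor's scope and its reference count
  are configurable (`min_count`).
* **Strand assignment** resolves each canonical k-mer to the orientation
  with the larger aggregate count across samples, ties to the canonical
  form. This majority rule is the package's interpretation of
  cross-sample strand resolution; it only affects reported sequence, never
  presence/absence.

The presence/absence matrix is the union of each sample's retained k-mers,
columns in lexicographic order of the canonical form, so construction is
invariant to sample input order. Columns with minor allele frequency
$\min(f, 1-f) < 0.01$ are removed; **monomorphic columns are always
dropped**, even at `maf_min = 0`, since a constant predictor is untestable
(at a 200-accession panel the MAF rule subsumes this; in small tests it does
not). The streamed builder (`kmer_matrix_stream()`) fuses counting, union
and filtering so that the dense matrix is only materialised for surviving
columns; it is tested equal to the modular path.

## Fragments, windows, candidate genes

Selected k-mers are merged into fragments on a bidirected overlap graph:
a k-mer and its reverse complement are one node, edges are exact
$(k{-}1)$-suffix/prefix overlaps, and only maximal unambiguous paths
(in-degree ≤ 1, out-degree ≤ 1 — the unitig rule) are merged. Ambiguity
breaks a fragment rather than being resolved greedily: determinism is worth
more than length at the 31–52 bp fragment scale this produces. Mapping is
exact substring search of the fragment and its reverse complement (no
scoring alignment); all hits are reported and multi-hit fragments are
flagged. The linkage window of a hit is the interval extended by 50 kb on
each side — edge-extension, not midpoint-centring, which reproduces the
published window/gene worked examples — clipped at contig bounds, and every
annotated gene overlapping the window by ≥ 1 bp is a candidate.
Coordinates are 1-based inclusive (GFF3 convention) throughout.

## Phenotype indices

With shoot dry matter $S$ (g/pot) and shoot P concentration $c$ (mg/g):
shoot P content $= S \cdot c$ (mg/pot), $\mathrm{PUE} = S / (S c) = 1/c$
(g DM per mg P), and for each trait
$\mathrm{STI} = Y_p Y_s / \overline{Y_p}^2$ with $\overline{Y_p}$ the mean
control (HP) performance over **all** accessions in the analysis set. The
identity $\mathrm{PUE} \times \text{shoot P content} = S$ holds per pot by
construction and is asserted in the tests. ΔRDM = mean RDM under HP − mean
RDM under LP ranks accessions **by signed value**: accessions whose roots
grow more under low P get negative ΔRDM and fall in the "Low" pool. The
10-of-30 subset choice balanced biostatus and origin in the original design
— criteria that are not computable here — so the pick is a pluggable hook
with a deterministic most-extreme default.

The mixed-model ANOVA of the original analysis (replicate as a random
effect) is deliberately approximated by a fixed-effects two-way ANOVA with
replicate as an additive block, sequential (type-I) sums of squares in the
order block, treatment, group, interaction. With three balanced replicates
the block absorbs the same variance either way; exact mixed-model p-values
are not a target of this package.

Redundancy pruning mirrors genebank practice: uncorrected p-distance over
pairwise-complete sites, a redundancy graph at similarity ≥ 99.97%, the
least-missing accession retained per connected component (ties broken
lexicographically), iterated up to three rounds.

## RSA traits

All traits are computed from a binary mask and the scan resolution
(mm/px = 25.4/dpi; 600 dpi is the default). Root length comes from the
Zhang–Suen skeleton, reduced to a unit-width 8-connected curve (greedy
deletion of 8-simple non-endpoint pixels, which removes staircase corners
and residual two-pixel bands), measured with the Vossepoel–Smeulders
estimator $0.980\,N_\perp + 1.406\,N_\times - 0.091\,N_{corner}$ — a naive
$1/\sqrt2$ step count overestimates oblique lines by up to ~8%, this
estimator is near-unbiased across orientations. No spur pruning is applied
below 3 px. The reference
software's internal formulas are not published, so diameter, volume and
surface area use the **projected-area cylinder model**:
$d = A/L$, $V = \pi (d/2)^2 L$, $S = \pi d L$ — chosen because the specific
root length unit (mm mm⁻³) forces SRL = L/V, and published trait means are
mutually consistent with $d \approx 0.5$ mm under exactly this model. A
distance-transform diameter is the natural alternative and is noted as such.
Hull geometry uses the pixel-centre convention for extents (a filled
$w \times h$ rectangle has extents $(w-1) \times (h-1)$ px); the hull *area*
adds a half-pixel boundary correction to the shoelace area of the
pixel-centre hull ($+\,P/2 + 1$, Pick's theorem). Without the correction a
thin straight bar would have hull area *below* its pixel-count area and the
convexity bound would fail on discretised masks; with it, a solid convex
region has hull area exactly equal to its pixel area, and specific hull
area = hull area / root area ≥ 1 on every non-degenerate mask. Trait tables are z-scored per column and clustered with
complete linkage on Euclidean distance; ties inside `stats::hclust` follow
its deterministic internal order.

# The synthetic-data generator

The generator defines the study conditions under which everything is
validated:

* **Panel and genome.** 200 accessions, a 200 kb single-contig genome with
  20 genes of 2 kb (the panel size matches the screen; the genome is a desk-
  scale stand-in — the real genome is ~10⁴× larger, which changes k-mer
  counting throughput but not the logic being tested).
* **Causal variant.** One insertion of length 31 (≥ k, so it creates
  unambiguous diagnostic k-mers) planted mid-gene at frequency 0.3 with
  effect β = 1.5 trait units. Insertions rather than SNPs are planted
  because a SNP only flips 31 overlapping k-mers, while an insertion yields
  a clean carrier/non-carrier k-mer partition — the cleanest
  parameter-recovery surface.
* **Background variation.** 40 neutral insertion loci at frequencies
  U(0.05, 0.95) plus private SNPs at 10⁻⁴ per base. The neutral loci give
  the marker matrix genuine polymorphism so that kinship is a meaningful
  random-effect covariance rather than a rank-1 echo of the causal locus;
  private SNPs mostly produce singleton k-mers that the MAF filter removes,
  plus a thin band of boundary-MAF columns where two accessions' SNPs fall
  within one k-mer window — realistic nuisance markers.
* **Reads.** Single-end 100 bp, 30× coverage, uniform starts, random
  strand, i.i.d. substitution errors (0 in the recovery study), constant
  quality. Read length and depth are not published for the original data;
  100 bp / 30× are configurable defaults. No restriction-site model, PCR
  duplicates, or indel errors (out of scope).
* **Phenotypes.** $y_{ij} = \mu + \sum_l \beta_l x_{il} + g_i + t_j +
  \varepsilon_{ij}$ with $g \sim N(0, \sigma_g^2 K)$ — the generative twin
  of the association model. Defaults $\mu = 10$, $\sigma_g^2 = 0.25$,
  $\sigma_e^2 = 0.75$, LP effect −1, three replicates.
* **Accessions are single haplotypes.** Real genebank accessions are
  populations of genotypes; `pool = TRUE` mixes two haplotypes per
  accession as a first-order nod to that heterogeneity.
* **Pot tables.** Trait means and LP effects follow the published
  treatment means (SDM 4.82 → 3.68 g, RDM 1.43 → 1.10 g, and a shoot P
  concentration drop whose reciprocal reproduces the ≈ 38% PUE rise), with
  accession effects loaded 0.7 on a shared vigor factor so biomass traits
  correlate across accessions as they do in real panels.
* **Root masks.** Stroked segments with round caps; analytic truth (length,
  capsule area, hull area via the capsule outlines) comes from the segment
  geometry, so trait extraction can be checked against closed forms.
  Odd stroke widths centred on pixel centres rasterise exactly; the
  resolution-doubling invariance test maps pixel centre $i \mapsto 2i - 0.5$.

What passing these tests does **not** show: performance on genome-scale
data volumes, robustness to GBS library artefacts (restriction-site bias,
duplicates, quality decay), behaviour under tetraploid dosage (markers here
are strictly presence/absence), or that the LD-window heuristic finds genes
when the true LD block exceeds 100 kb.

# Numerical choices

* Variance-ratio optimisation: 21-point log₁₀ grid on $[10^{-5}, 10^5]$,
  Brent refinement at tolerance 10⁻⁶; the genome-wide scan evaluates the
  grid for all markers simultaneously (closed-form weighted 2×2 GLS per
  $\lambda$) before refining per marker.
* Kinship is symmetrised and checked PSD to 10⁻⁸ (relative); eigenvalues
  are clipped at zero before simulation draws.
* LRT statistics are clipped at 0; p-values floored at 10⁻³⁰⁰.
* QQ expected quantiles use the half-rank convention $-\log_{10}((r-0.5)/n)$.
* Ambiguous bases: k-mer windows containing non-ACGT characters are skipped
  silently with a running tally reported on the matrix object.
* Degenerate inputs error early and explicitly: constant phenotypes,
  constant markers (flagged untestable and excluded), empty masks, zero
  skeleton length with non-zero area, zero-width strokes, infeasible gene
  packing, overlapping planted insertions.

# Problem sizes

The validation studies run at the panel scale of the original screen where
that is what is being claimed — 200 accessions, 200 kb genome, 30×
error-free reads, five seeds for the end-to-end recovery; 5 × 2,000 markers
at n = 200 for null calibration — and at miniature scale (tens of
accessions, k = 5–9) for the exhaustive oracle comparisons, where brute
force is feasible. The `analysis/` drivers use an intermediate 60-accession,
60 kb configuration that finishes in seconds while still recovering the
planted locus.

# Known limitations

* Exact reproduction of GEMMA's numbers is not attempted (its grid and
  convergence settings are unknown); the implementation is validated against
  closed forms at diagonal kinship and by null calibration instead.
* The ANOVA is a fixed-effects approximation of the original REML mixed
  model, as documented above.
* Fragment mapping is exact-match only; a fragment spanning any sequencing
  or assembly difference from the reference goes unplaced (it is retained
  and logged, mirroring loci that map to unannotated or unplaced regions).
* Published RSA trait values cannot be reproduced bit-for-bit because the
  reference software's formulas are unpublished; the cylinder-model stand-in
  is validated against analytic fixtures instead. One published
  inconsistency is noted for the record: the specific-hull-area HP summary
  appears as 26.9 in the trait table but 25.6 in the accompanying text;
  neither is a target here.
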