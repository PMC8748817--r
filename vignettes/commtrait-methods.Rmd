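---
title: "Methods: community trait aggregation, biosphere classification and RMT network inference"
author: "commtrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community trait aggregation, biosphere classification and RMT network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`commtrait`, in the spirit of a methods supplement: what each statistic is,
which decisions were genuinely open, what the synthetic generator does and
does not emulate, and what the validation suite therefore does and does not
demonstrate about real data.

## The community-level rrn copy number

The ribosomal RNA operon (*rrn*) copy number is a genomic trait tied to a
bacterium's maximum growth rate and nutrient demand: many operons support
fast ribosome production (copiotrophs), a single operon favors efficient
growth under scarcity (oligotrophs such as SAR11). The community-level
aggregate implemented by `community_rrn()` is

$$\bar n_{\mathrm{comm}} \;=\; \frac{\sum_{i=1}^{N} S_i}{\sum_{i=1}^{N} S_i / n_i},$$

with $S_i$ the read abundance and $n_i$ the copy number of OTU $i$, summed
over OTUs detected in the sample. Algebraically this is the
abundance-weighted **harmonic** mean of $n_i$. Its properties — the
invariants the test suite asserts to $10^{-12}$ — are:

* invariance to rescaling all $S_i$ (counts and relative abundances give the
  same value),
* bounds $\min_i n_i \le \bar n_{\mathrm{comm}} \le \max_i n_i$ over
  contributing OTUs,
* domination by the abundance-weighted arithmetic mean (AM–HM inequality).

A consequence worth spelling out: the harmonic form weights *organisms*, not
reads — a community dominated by single-copy oligotrophs is pinned near 1
even if a few high-copy taxa are present. `community_rrn_unweighted()`
(plain mean over detected OTUs) is provided as the abundance-free
counterpart, and `biosphere_rrn()` applies the weighted form to one
biosphere's OTUs with subset abundances.

**Unassigned OTUs.** OTUs with no database match are excluded from both the
numerator and denominator. Because this silently reweights the community,
the fraction of detected reads carried by assigned OTUs is attached to every
result as the `coverage` attribute; analyses should report it.

## Hierarchical trait assignment

`assign_rrn()` searches each OTU's lineage from the lowest assigned rank
upward. A rank matches when its taxon name is *known* to the database —
either as an explicit record or as an ancestor on some record's lineage
path, so a genus represented only through sequenced species still matches at
genus rank. The value of a matched taxon is the unweighted mean over its
child taxa where children are known (recursively down to records), else the
taxon's own record. The choice of an *unweighted* mean over distinct child
taxa (rather than over strain records) makes the value independent of how
many strains a database happens to hold per species. Copy numbers are kept
as reals; child means such as 8.5 are never rounded.

Two degenerate cases are rejected rather than guessed at: duplicate taxon
names within a rank (homonyms make the hierarchical index ambiguous) and
lineages whose assigned ranks sit below an unassigned rank. OTUs with no
match at any rank are carried with an explicit missing flag and excluded
downstream, never silently dropped from the OTU set.

## Biosphere classification

`classify_biospheres()` implements the three-way partition with thresholds
`a` (abundance cutoff, default 0.001), `f1` (fraction-of-samples cutoff,
default 0.5) and `f2` (occurrence cutoff, default 0.8):

* **abundant**: relative abundance $\ge a$ in a fraction of samples
  strictly $> f_1$, *and* present (count > 0) in a fraction strictly
  $> f_2$;
* **rare**: relative abundance $< a$ in every sample;
* **intermediate**: everything else.

The inequality directions follow the way such criteria are conventionally
printed: the abundance comparison is inclusive ($\ge$), the two
fraction-of-samples comparisons strict ($>$). "Occurred" is read as presence
(count > 0) at any abundance. Because ties at the printed boundaries are
decided by these conventions, every output row carries a `boundary_tie` flag
so borderline OTUs can be audited. The partition property (every OTU exactly
one label) and monotonicity (raising `a` can never move an OTU from rare to
abundant) are asserted over a thousand random tables in the tests.

## Distances, correlation and the partial Mantel test

* **Weighted MPD** uses pair weights $p_i p_j$ over unordered distinct pairs
  $i \ne j$, normalized by the summed weights. This is the common
  "abundance-weighted MPD" convention; note that `picante::mpd()` averages
  over ordered pairs *including* self-pairs (distance 0, weight $p_i^2$), so
  its value equals ours times $1 - \sum_i p_i^2$ — the test suite uses
  exactly that identity as a cross-check.
* **Weighted UniFrac** is the normalized branch-sum form
  $\sum_b l_b\,\lvert A_b - B_b\rvert \,/\, \sum_b l_b\,(A_b + B_b)$ over
  tree branches, with $A_b$ the summed relative abundance below branch $b$.
  It is 0 for identical abundance vectors, 1 for phylogenetically disjoint
  communities, symmetric, and bounded in $[0,1]$, which makes values
  comparable across sample pairs.
* **Partial Mantel.** The statistic is the partial correlation of the
  off-diagonal entries of distance matrices $A$ and $B$ given $C$.
  Significance comes from permuting the sample order of $A$ (rows and
  columns jointly) and recomputing the statistic, with the one-sided
  "greater" p-value $(1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$ —
  one-sided because the scientific hypothesis (trait–nutrient linkage after
  controlling phylogeny) is directional. Permutations default to 999 and the
  RNG seed is a required argument, so p-values are bit-reproducible.
  Degenerate inputs (zero off-diagonal variance, $|r|=1$ with the control)
  raise errors rather than returning NaN. Calibration: over 1,000
  independent-matrix null replicates at $n=20$ the empirical type-I rate at
  $\alpha=0.05$ is computed by both the test suite and the acceptance
  script; raw-matrix permutation is known to be only approximately exact for
  partial Mantel, and the observed rate (around 0.04–0.06 depending on the
  seed) is asserted within ±0.02 of nominal.
* Missing environmental values propagate as complete-case deletion with a
  logged count; Pearson correlations report the `n` actually used.

## RMT threshold selection

The network threshold is chosen spectrally rather than by a fixed
correlation or p-value cutoff. The reasoning: the eigenvalue
nearest-neighbour spacing distribution (NNSD) of a noise-dominated symmetric
matrix follows the Gaussian orthogonal ensemble (Wigner–Dyson) law with its
characteristic level repulsion, whereas a matrix reduced to independent
modular blocks has superposed spectra whose spacings follow the Poisson law
$P(s) = e^{-s}$. `rmt_threshold()` scans candidate cutoffs (default grid
0.30–0.99, step 0.01), zeroing sub-threshold entries, and picks the smallest
cutoff at which the NNSD becomes consistent with Poisson and stays so for
two consecutive steps.

Numerical choices, each configurable:

* **Unfolding.** Spacings are meaningful only after normalizing the local
  eigenvalue density. We fit a monotone cubic spline (Hyman filtering) to
  the empirical spectral CDF on 15 knots and map eigenvalues through it,
  yielding unit mean spacing. Any smooth monotone unfolding is acceptable;
  the GOE/Poisson contrast tests (100 replicates each at $n=200$: GOE
  rejected, independent-block direct sums accepted) are the operational
  check that the smoother is adequate.
* **Duplicate eigenvalues.** Exact duplicates (e.g., the unit eigenvalues
  contributed by near-isolated rows) produce zero spacings that would
  swamp the fit; duplicates within $10^{-8}$ are merged before unfolding,
  and rows with no surviving off-diagonal entry are excluded from the
  eigendecomposition outright (each contributes only a trivial eigenvalue).
* **Goodness of fit.** Chi-square against Exponential(1) on
  equal-probability bins, bin count $\max(5, \lfloor n_{spacings}/10
  \rfloor)$. When fewer than 20 distinct spacings remain the test cannot
  reject and the threshold is flagged as untestable-but-consistent.
* **Sign handling.** Thresholding applies to $|\rho|$ and the sign is
  retained on edges, so co-exclusion (negative) links survive on equal
  terms with co-occurrence links.
* Scans whose thresholded matrix keeps fewer than 10 connected nodes stop
  with a diagnostic; a scan in which no candidate passes errors with advice
  to widen the range rather than silently picking an endpoint.

Constant OTU vectors (possible after aggressive filtering) have undefined
rank correlation; their entries are set to 0 with a warning instead of
dropping the OTU, keeping the matrix aligned with the node set.

Module detection runs fast-greedy modularity optimization on the unsigned
topology. Null models are degree-preserving double-edge-swap rewirings
(10 swaps per link, 100 nulls by default, seeded); they preserve node count,
link count and the exact degree sequence, and each topological index
(average degree, average local clustering with isolates as zero, average
path length on the largest component, modularity) is summarized as observed
value, null mean ± sd, and Z-score. Average path length is restricted to the
largest component because it is undefined across components.

## The synthetic generator

The generator exists so that every pipeline stage can be validated against
planted truth. What it emulates:

* **Skewed abundance structure.** Per-OTU log baselines are
  Normal($\mu=0$, $\sigma=2$) — a lognormal species-abundance distribution
  whose long tail produces rare-biosphere dominance at realistic richness
  (1,500 OTUs). Per-sample idiosyncratic noise (sd 0.6 on the log scale)
  creates occurrence variation; reads are one multinomial draw per sample at
  depth 50,000, large enough that sampling noise does not mask strong
  planted correlations at 60 samples.
* **Planted biosphere design.** OTUs whose *expected* relative abundance is
  at least twice the abundant cutoff in every sample, or below half the rare
  cutoff everywhere, are recorded as constructed-abundant /
  constructed-rare; classification of the realized counts must recover these
  labels exactly.
* **Signed associations.** A Gaussian copula on log expected abundances: the
  involved OTUs' noise vectors are replaced by multivariate-normal draws
  carrying the planted correlation matrix (rejected if not positive
  definite). Planted pairs are drawn from abundance ranks 11–pool so they
  survive the 30% occurrence filter without dominating the composition.
* **Trait–nutrient coupling.** A latent gradient $x_s$ tilts log expected
  abundances by $\tau\, \tilde n_i\, \eta_s$ with
  $\eta = c\,x + \sqrt{1-c^2}\,u$, so the realized correlation between the
  community-level rrn value and the first nutrient approaches the planted
  coupling $c$. The first nutrient column is the gradient itself; the others
  are noisy correlates including a deliberately collinear NH4-N/TN pair so
  control matrices in partial Mantel tests have structure to remove. The
  tilt strength is fixed at $\tau = 0.1$ by a design constraint: the tilt is
  a rank-1 common factor, and $\tau$ is capped so the factor-induced
  pairwise correlation $\tau^2 t_{max}^2/(\tau^2 t_{max}^2 + \sigma_s^2)$
  stays below the network scan floor (0.30) even for extreme-trait pairs
  ($t_{max} \approx 3$, $\sigma_s = 0.6$). This keeps the planted link list
  the sole source of super-threshold associations, at the cost of
  attenuating the realized trait–nutrient correlation below the planted
  value (observed ≈ 0.45–0.65 for $c = 0.7$) — the validation criterion is
  therefore sign and significance, not magnitude.
* **Taxonomy, tree and trait database.** A random seven-rank hierarchy with
  genus-conserved copy numbers (log-normal around 3, species jitter of ±1
  copy, floor 1), a coalescent tree over OTUs, and a database deliberately
  populated at mixed ranks so assignment must exercise the species-hit,
  sibling child-mean, genus-record, family-fallback and no-match paths.

The presets differ only in coupling and planted link mix — `"sediment"`
(coupling 0.7; 30 links, 40% negative) vs `"ocean"` (coupling 0.2; 15
links, none negative) — emulating the qualitative contrast between
nutrient-rich and nutrient-scarce systems.

**What the generator does not emulate**, and hence what passing tests do not
show about real data: compositional closure bias at low richness (no
SparCC-style correction is applied; the generator's planted correlations are
imposed before closure, and network inference on strongly compositional real
data inherits the usual caveats), temporal autocorrelation and succession,
sequencing error and chimeras, phylogenetic signal in the *abundances*
(the tree is independent of the SAD), copy-number correction of abundances
themselves, and any mechanistic consumer–resource dynamics. Recovery rates
on synthetic data are upper bounds on what identical settings would achieve
in the field.

## Determinism and problem sizes

Every stochastic function takes an explicit integer seed; `simulate_preset()`
and `run_all()` derive all stage seeds from one master seed by fixed small
offsets, so a dataset or a full report bundle is bit-identical under
regeneration. The validation suite runs the planted-recovery checks at the
generator's native scale (1,500 OTUs × 60 samples × 50,000 reads; 3 seeds
for link recovery, 20 seeds for coupling recovery, 10 paired seeds for the
preset contrast), the spectral checks at matrix size 200 with 100 replicates
per ensemble, and the Mantel calibration with 1,000 null replicates of 999
permutations at 20 samples — sizes chosen as the smallest at which the
corresponding statistics are stable.

## Known limitations

* The RMT scan needs on the order of 30+ retained OTUs for stable spacing
  statistics; it warns below that and refuses scans that isolate the matrix.
* The threshold grid step (0.01) bounds the resolution of the chosen cutoff.
* Partial Mantel uses raw-matrix permutation, which is approximate under
  strong three-way dependence; residual-permutation variants are not
  implemented.
* Trait assignment trusts the taxonomy: misannotated lineages propagate
  directly into $n_i$, and database coverage (the `coverage` attribute) is
  the only guard against unrepresentative exclusion.
* The pipeline treats every sequenced sample as one column; replicate
  pooling, if wanted, must happen upstream.
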