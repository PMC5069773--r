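---
title: "Methods behind the plastisphere pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the plastisphere pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastisphere)
```

This vignette explains the models and procedures the package implements,
the choices made where the underlying field methods leave details open, and
what the synthetic-data generators do and do not emulate. The pipeline has
four analysis stages — particle size spectra, bottle-incubation metabolism,
SSU rRNA taxonomic profiling, and KO differential abundance — plus the
generators that feed them during testing.

## Particle size spectra

Floating plastic fragments are counted by surface net tows and measured
individually. The distributional summary used throughout the marine-debris
literature is the *size spectrum*: diameters are placed in logarithmic bins
and the count in each bin is divided by the bin's **linear** width (mm),
giving the abundance density $A_n$ in particles mm$^{-1}$. For a
steady-state fragmentation cascade, $A_n \propto d^{-\xi}$ with $\xi = 3$;
observed spectra follow the power law only above roughly 3 mm, with a
deficit of smaller particles attributed to selective loss or under-sampling.

Choices a re-implementation has to make, and what this package does:

* **Bin anchoring.** Edges sit at $10^{k w}$ mm for integer $k$ and log
  width $w$ (default 0.1), so bins are data-independent and two surveys
  binned separately are comparable. A diameter $d$ belongs to the bin
  $(10^{(k-1)w}, 10^{kw}]$ — bins are labelled by their upper edge.
* **Fit abscissa.** The geometric bin midpoint
  $10^{(\log_{10}\text{lo} + \log_{10}\text{hi})/2}$, the standard
  x-coordinate for log-binned spectra. (A constant multiplicative shift of
  the abscissa — e.g. labelling by upper edge instead — leaves the slope
  unchanged.)
* **Estimator.** `fit_power_law()` defaults to a Poisson log-link
  regression of bin counts on $\log d$ with $\log(\text{bin width})$ as
  offset. The textbook alternative — unweighted OLS of $\log_{10} A_n$ on
  $\log_{10} d$ over occupied bins — is exactly right for noiseless
  spectra, and the package provides it (`method = "ols"`), but it degrades
  badly when the qualifying bins hold few particles: with 5,000 particles
  drawn at $\xi = 3$ over 0.3–30 mm, only ~60 fall above 3 mm, tail bins
  hold 0–2 particles each, zero bins must be dropped (log of zero), and the
  surviving singleton bins sit systematically above the true line. The OLS
  exponent is then biased low by about 0.3, and count-weighting does not
  repair it. The Poisson regression keeps zero bins, never takes the log of
  a small count, and recovers the generating exponent to within a few
  hundredths at the same sample size, so it is the default; the test suite
  pins both behaviours.
* **Fit range.** Bins whose upper edge exceeds `min_diameter` (default
  3 mm) enter the fit; for the OLS path only occupied ones can.
* **Concentrations.** Fragments/m³ is count over flowmeter volume;
  fragments/km² integrates that over the sampled surface layer (default
  0.15 m, the submerged height of a manta-trawl mouth):
  $\text{conc} \times 0.15 \times 10^6$. Particles are taken at face value
  from the input table; no re-classification of size classes is attempted.

## Bottle metabolism

Community metabolism is estimated from Winkler-type oxygen measurements in
light, dark and time-zero bottles:

$$\mathrm{NCP} = (\bar L - \bar{T_0})\,\frac{24}{\Delta t},\qquad
  \mathrm{R} = (\bar{T_0} - \bar D)\,\frac{24}{\Delta t},\qquad
  \mathrm{GPP} = \mathrm{NCP} + \mathrm{R},$$

in µmol O₂ per day, with $\Delta t$ the incubation duration in hours
(default 24). GPP is *computed as the sum*, so the identity holds
bit-exactly through every downstream transformation; standard errors
propagate from within-treatment variances.

Incubated plastic pieces displace water, so equal concentrations do not
mean equal oxygen amounts: `displacement_adjust()` converts concentrations
to amounts over the effective volume (bottle − particle). Rates can be
expressed per litre (natural for unamended seawater) or per bottle (the
basis for particle arithmetic). Because pieces are incubated one per
bottle, the per-particle rate is the amended bottle rate minus the mean
unamended rate (`background_subtract()`, `n_particles = 1` by default).
Negative rates are reported as-is, never clipped — a dark bottle can
genuinely out-gas a light one at low biomass, and clipping would bias
means.

Group comparisons use the tests standard for these small, tied-prone
samples: Kruskal–Wallis with Dunn's tie-corrected post hoc z-tests
(Benjamini–Hochberg adjusted, flagged at 0.05) across size classes, and a
two-sided Mann–Whitney U or one-way ANOVA between two rate groups. The
Mann–Whitney p-value is exact by enumeration when both groups have ≤ 8
untied values and otherwise uses the normal approximation with tie and
continuity corrections; all-tied degenerate input returns p = 1 with a
warning rather than NaN. Dunn's test is implemented in the package because
no installed package provides it; its z-statistics are unit-tested against
the closed-form rank expressions and its null flag rate against permutation.

Chlorophyll utilities: areal Chl *a* on a particle (mg m$^{-2}$) is mass
over surface area; the *seawater-equivalence volume* — how much water holds
the same pigment as one particle — is
$\text{Chl}_{areal} \cdot A / \text{Chl}_{water}$ converted to mL. For the
observed ranges (0.03–0.42 mg m$^{-2}$ on plastic, 0.04–0.1 mg m$^{-3}$ in
water) a 5-mm sphere is equivalent to tens to hundreds of mL of seawater.
Exact station pairings are a property of a given survey; the package
exposes the calculation, not a fixed pairing.

## SSU rRNA profiling by windowed LCA

Shotgun reads containing SSU rRNA are aligned to a reference database and
arrive here as tabular hits (query, subject, percent identity, alignment
length, bit score, optional subject coordinates). Assignment proceeds in
three steps:

1. **Screening.** Hits to blacklisted subjects (e.g. probable chimeras)
   are dropped, as are hits overlapping any masked subject interval
   (contaminant non-SSU tails). *Any* overlap removes the hit; coordinates
   are 1-based inclusive and reversed minus-strand coordinates are
   normalized before the check. Hit tables are assumed pre-filtered at the
   aligner's E-value cutoff.
2. **Retention.** Hits need alignment length ≥ 100 bp and bit score ≥ 50;
   among the qualifying hits of a read, those with
   $\text{bit} \ge (1 - 0.01)\cdot\text{best}$ are retained. The boundary
   is inclusive (ties at exactly 99% of the best are kept), the best is
   computed over floor-qualifying hits, and the operation is
   order-invariant and idempotent.
3. **LCA.** The read is assigned the longest common rank-prefix of the
   retained lineages: two hits in the same family but different genera give
   the family and no genus. Disjoint lineages (e.g. one bacterial, one
   eukaryotic hit) give the unclassified root. The top hit's percent
   identity is carried per read and averaged per clade for reporting.

Abundance tables fix a rank; reads assigned more shallowly are excluded.
Because different figures legitimately use different denominators, the
denominator is explicit per-table metadata: reads assigned at the rank
(default, within a domain when one is given), reads assigned at least to a
domain, or all reads including the unclassified root. Proportions are then
**rounded half away from zero** to a stated number of decimals (3 for
eukaryotic, 2 for bacterial tables by convention; the rule is recorded so
results are bit-reproducible). Rounding to $10^{-d}$ equalizes effective
resolution across libraries — the same goal as rarefying to $\sim 10^d$
reads — without injecting resampling noise; a clade's rounded value is
within half a resolution step of its true proportion whenever the library
is much deeper than $10^d$.

Ordination square-root transforms the (rounded) proportions, computes
Bray–Curtis dissimilarities and runs non-metric MDS in 2 dimensions via
`vegan::metaMDS` with multiple random restarts under a fixed, recorded
seed; stress is reported, and identical inputs with the same seed reproduce
identical coordinates. Family richness counts clades strictly above 1%
abundance per sample, compared between habitats with Welch's t test.
Per-clade differential abundance uses two-sided Mann–Whitney U tests on the
rounded proportions with BH adjustment across clades (flag at FDR < 0.005);
a clade constant across all samples has zero rank variance and is defined
to p = 1. The per-clade and per-KO loops use a vectorized Mann–Whitney
(normal approximation with tie and continuity corrections) verified to
machine precision against `stats::wilcox.test`.

Chloroplast reassignment against a second reference (PhytoREF-style) is the
same retention + LCA operation run with a second lineage map; no separate
code path exists or is needed.

## KO differential abundance

Reads are called bacterial when **all** their best-scoring protein hits
with ≥ 50 aa alignment are to bacterial subjects — a best-score tie with a
eukaryotic subject excludes the read. Each bacterial read takes the KO of
its single top hit; an unannotated top hit leaves the read unassigned even
if a runner-up is annotated. Top-score ties with conflicting KOs are broken
deterministically to the lowest KO id, with a warning (arbitrary, but
reproducible and logged). Each KO is tested once regardless of how many
functional categories it belongs to.

Counts become per-sample proportions of all KO-assigned reads, rounded to 5
decimals (the resolution of a ~100k–200k-read library), and each KO is
tested with the Mann–Whitney/BH machinery above. The fold change is
$\log_2\frac{\bar p_1 + c}{\bar p_2 + c}$ with a symmetric pseudocount $c$
defaulting to half the smallest nonzero proportion in the table — small
enough not to dampen real effects, large enough to keep absent KOs finite.
"Group 1" is the first level of the supplied group mapping (factor levels,
or order of first appearance), so the caller controls the sign convention;
reversing the mapping flips every fold change and leaves the calls
unchanged. A KO is flagged when adjusted p < 0.005 **and**
$|\log_2 FC| > 2$, and `enrichment_summary()` reports each direction as an
integer percentage of KOs tested. A negative-binomial count model is a
reasonable alternative test; `ko_diff_test(p_fun = ...)` accepts one as a
drop-in p-value engine while keeping the fold-change and flagging logic.

## What the generators emulate — and what they don't

Every generator is a pure function of its arguments once a seed is given,
and `sim_write_all()` writes the full fixture set with sub-seeds split from
one master seed, so adding a generator never perturbs another.

* `sim_particle_sizes()` inverts the bounded power-law CDF
  ($\xi \ne 1$: $d = (d_{min}^{1-\xi} + u\,(d_{max}^{1-\xi} -
  d_{min}^{1-\xi}))^{1/(1-\xi)}$; $\xi = 1$: log-uniform). Default
  conditions: $\xi = 3$ on 0.3–30 mm.
* `sim_bottles()` places treatment means exactly at the configured rates
  (so zero noise recovers them exactly) with Gaussian noise of sd
  0.5 µmol L$^{-1}$, typical replicate precision of automated Winkler
  titration, 8 bottles per treatment.
* `sim_hit_table()` draws reads from a small cross-domain community
  profile resembling plastic biofouling (bryozoans, diatoms,
  Rhodobacteraceae, Flavobacteriaceae, filamentous cyanobacteria). Bit
  scores are constructed, not random: the true subject always scores best;
  optional sister-lineage confounders land *inside* the 1% window (offset
  uniform on 0–0.9%) and decoys *outside* it (2–5% below), so the window
  logic is exercised by construction and the deepest recoverable rank per
  read is known exactly.
* `sim_ko_table()` draws negative-binomial counts (dispersion 0.3,
  variance $\mu + 0.3\mu^2$) around lognormal baseline abundances
  (sdlog 1), library sizes uniform on 216k–1M reads to emulate uneven
  depth, with a planted fraction (default 10%) of KOs whose group means
  differ by $2^{4}$, half in each direction, and truth flags returned.
  Defaults mirror the comparison design of 12 plastic vs 17 picoplankton
  libraries at 2,000 KOs — a desk-scale stand-in for the ~6,000 KOs of a
  full survey.

What passing tests on these generators shows: that binning, retention, LCA
truncation, rounding, rank tests and FDR control do what they claim under
data whose distributional assumptions hold and whose truth is known. What
they cannot show: robustness to real-world violations — chimeric reads,
database gaps and mislabeled lineages, non-NB overdispersion, tow-volume
errors, bottle effects — which enter real surveys upstream of this
package's inputs.

## Numerical choices and degenerate inputs

* Rounding is half away from zero, not banker's rounding.
* Bit-score window inclusive at the boundary; best hit computed over
  floor-qualifying hits.
* All-tied group tests return p = 1 with a warning; constant clades/KOs are
  never flagged.
* Zero-width bins, non-positive diameters/volumes, particle volume ≥
  bottle volume, missing treatment groups, zero-total samples, and unknown
  ranks raise immediate errors rather than propagating NaN.
* Negative simulated oxygen concentrations are clipped at zero with a
  warning (a physical bound, applied only in the generator).
* Tests and examples run at deliberate desk scale — 5,000 particles per
  survey (20 replicate surveys for the exponent study), ≤ 600 reads per
  hit-table scenario, 2,000 KOs × 29 samples × 50 replicate tables for the
  calibration study — sizes chosen so the statistical claims (CLT-level
  recovery, FDR control) are testable while the whole suite stays fast.

## Known limitations

* The aligner itself, read QC and rRNA sorting are out of scope: the
  pipeline starts at tabular hits and trusts their E-value filtering.
* The LCA is a strict rank-prefix operation; it does not use a tree
  topology beyond the lineage paths supplied.
* The Mann–Whitney path tests location shifts on rounded proportions; with
  very shallow libraries the rounding dominates and power drops — by
  design, mirroring what rarefying would do.
* Per-particle rates assume one particle per bottle and equal background
  activity in amended and unamended bottles; enhanced planktonic activity
  around a particle during incubation is attributed to the particle.
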