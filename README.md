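# plastisphere

Floating plastic debris in oligotrophic ocean gyres is colonized by dense,
metabolically active microbial biofilms — the "plastisphere" — that differ
sharply from the free-living picoplankton in the surrounding water column.
`plastisphere` is an R package for the quantitative side of surveying these
communities. It is written for microbial ecologists and oceanographers who
have (a) manta-trawl particle measurements, (b) light/dark bottle oxygen
incubations, (c) tabular alignment hits of shotgun SSU rRNA reads against a
reference database, and (d) KEGG-ortholog (KO) read counts from plastic and
planktonic metagenomes, and who want each stage reduced to a number they can
defend.

Everything operates on plain data frames and returns tibbles, so stages
chain with the pipe; each fitted object has `tidy()`/`glance()` and
`autoplot()` methods; and a synthetic-data module generates every input with
known truth, so the full pipeline runs and is validated without any
sequence downloads.

## What it computes

**Particle size spectra.** Diameters are binned into logarithmic size
classes (edges at `10^(k·w)` mm, default `w = 0.1`), counts are normalized
by linear bin width to the abundance density `A_n` (mm⁻¹), and the scaling
exponent ξ of `A_n ∝ d^(−ξ)` is fitted above a minimum diameter (default
3 mm). Steady-state fragmentation theory predicts ξ = 3. The default
estimator is a Poisson log-link regression of bin counts with a bin-width
offset (accurate when tail bins hold few particles); plain log–log OLS is
also available. Trawl counts convert to fragments/m³ and, integrated over
the sampled surface layer (0.15 m), to fragments/km².

**Bottle metabolism.** From light (`L`), dark (`D`) and time-zero (`T0`)
oxygen measurements:

    NCP = (mean L − mean T0) · 24/duration
    R   = (mean T0 − mean D) · 24/duration
    GPP = NCP + R

with oxygen amounts corrected for the water displaced by incubated plastic
pieces, background seawater rates subtracted to give per-particle rates, and
Kruskal–Wallis/Dunn and Mann–Whitney/ANOVA group tests. Chlorophyll
utilities express areal Chl *a* on particles as the equivalent volume of
seawater holding the same pigment.

**SSU rRNA taxonomic profiling.** Per read, hits with alignment length
≥ 100 bp and bit score ≥ 50 are kept if their bit score is within 1% of the
best qualifying hit; the read is assigned to the lowest common ancestor
(LCA) of the retained hits' lineages. Blacklisted subjects and hits
overlapping masked subject regions are removed first. Clade × sample tables
at any rank, with explicit proportion denominators, are rounded to a fixed
decimal resolution (a noise-free stand-in for rarefying), square-root
transformed and ordinated by Bray–Curtis NMDS; per-clade Mann–Whitney/BH
tests and >1%-presence richness comparisons round out the module.

**KO differential abundance.** Reads whose best-scoring protein hits
(≥ 50 aa) are all bacterial take the KO of their top hit; per-sample KO
proportions rounded to 5 decimals are compared between groups with
Mann–Whitney U tests, BH FDR control (< 0.005) and a |log2 fold change| > 2
rule, summarized as the percentage of KOs enriched in each habitat.

## Worked example

```r
library(plastisphere)

# --- particle size spectrum ------------------------------------------------
d <- sim_particle_sizes(5000, exponent = 3, d_min = 0.3, d_max = 30, seed = 1)
fit <- d |> assign_log_bins(log_width = 0.1) |>
  normalize_to_bin_width() |>
  fit_power_law(min_diameter = 3)
glance(fit)
#> # A tibble: 1 × 6
#>   exponent intercept r_squared fit_min_diameter method  n_bins
#> 1     3.16      3.07     0.970                3 poisson     10

# --- bottle metabolism -----------------------------------------------------
sim_bottles(ncp = 10, r = 5, noise_sd = 0.5, seed = 2) |> bottle_rates()
#>   experiment_id station   ncp     r   gpp se_ncp  se_r se_gpp ...
#> 1 exp1          S1       10.1  4.59  14.7  0.298 0.246  0.321

# --- SSU rRNA profiling ----------------------------------------------------
sim <- sim_hit_table(n_reads = 300,
                     samples = c("plastic_1", "plastic_2", "plastic_3"),
                     seed = 3)
asn <- assign_reads(sim$hits, sim$taxonomy)   # blacklist + window + LCA
clade_table(asn, rank = "family", domain = "Bacteria") |>
  round_normalize(decimals = 2) |> head(4)
#>   sample    clade             count proportion
#> 1 plastic_1 Flavobacteriaceae    63       0.37
#> 2 plastic_1 Microcoleaceae       38       0.22
#> 3 plastic_1 Rhodobacteraceae     62       0.36
#> 4 plastic_1 Rhodospirillaceae     8       0.05

# --- KO comparison ---------------------------------------------------------
ko <- sim_ko_table(seed = 4)   # 2000 KOs, 12 vs 17 samples, 10% planted
res <- ko_proportions(ko$counts) |> ko_diff_test(ko$groups)
enrichment_summary(res)
#>   n_tested n_up n_down pct_up pct_down group_up group_down
#> 1     2000  100    100      5        5 plastic  picoplankton
```

The fitted exponent 3.16 recovers the generating ξ = 3 from one survey of
5,000 particles; the bottle rates recover the configured NCP = 10 and R = 5
µmol O₂ L⁻¹ d⁻¹ within their standard errors, with GPP equal to NCP + R by
construction; the family table shows the rounded within-domain proportions;
and the KO test recovers all 200 planted effects (100 per direction, 5% of
KOs each way) with no false flags.

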