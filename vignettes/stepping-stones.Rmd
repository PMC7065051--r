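---
title: "Methods: particle transport, microsatellite F-statistics, and the asymmetric Mantel test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: particle transport, microsatellite F-statistics, and the asymmetric Mantel test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`stepstone` asks one question in two independent ways: do water currents
connect hard-substrate populations on offshore structures strongly enough
to leave a genetic imprint? This vignette documents the models behind each
track, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## 1. The particle transport model

Larvae are treated as passive, neutrally buoyant particles in a
depth-averaged 2-D velocity field. Positions live in an equirectangular
plane at 111.19 km per degree; velocities are metres per second; per time
step of length $dt$ a particle moves

$$\Delta x = u\,dt + \sqrt{2 D\,dt}\; z_1, \qquad
  \Delta y = v\,dt + \sqrt{2 D\,dt}\; z_2,$$

with independent standard normal draws — the Lagrangian equivalent of
advection plus Fickian horizontal diffusion with coefficient $D$. Velocity
is interpolated bilinearly in space and linearly in time, and never
extrapolated: queries outside the grid are an error, and particles are kept
inside the domain by the boundary policy (reflecting by default, which
conserves particle counts; absorbing optionally). Collapsing the vertical
dimension is a deliberate simplification: release is from the surface layer
and the larvae are passive, so depth-averaged transport retains the
horizontal connectivity structure while making the model desk-sized.

Release and tracking defaults follow the study design for spring-spawning
mussels: releases start on day-of-year 59 (1 March), each origin emits
1,489 particles every 30 minutes for 14 days (672 release events, hence
1,000,608 particles per origin by the schedule arithmetic — the package
always reports the schedule, via `release_schedule()`), and transport is
integrated with 30-minute steps for 70 days, bracketing the 16–70-day
pelagic larval duration.

Two choices the source methodology leaves open are made explicit here:

* **Arrival.** A particle "arrives" at a destination at its *first entry*
  into that site's capture radius (default 2 km), is counted at most once
  per destination, and keeps moving — it is not absorbed, so one particle
  can score at several sites, and the diagonal of the arrival matrix is
  local retention. First-entry counting makes arrival counts monotone in
  the capture radius, which the tests verify.
* **Dispersion.** $D = 10\ \mathrm{m^2/s}$ by default, a typical shelf-sea
  horizontal magnitude; it is a configuration knob, not an estimate.

Arrival matrices are always oriented rows = source, columns = destination,
and every file written carries that convention plus a configuration hash
and the seed in its `#` header, because asymmetric matrices make
orientation mistakes silent.

## 2. The synthetic flow field

`make_flow_field()` is a stand-in for hydrodynamic model output, not a
hydrodynamic model: a steady residual (uniform, user function, or a
solid-body anticlockwise gyre mimicking the residual circulation of a
semi-enclosed shelf sea) plus a sinusoidal tide
$A\cos(2\pi t/T + \phi)$ with default period $T = 12.42$ h (the M2
constituent). Fields can be declared time-periodic so a single tidal cycle
covers arbitrarily long simulations. What it deliberately lacks: wind
events, stratification, river plumes, irregular coastlines — so particle
tests validate the *transport numerics*, not North Sea realism.

## 3. The Wright–Fisher metapopulation simulator

`simulate_metapopulation()` is a forward, discrete-generation,
constant-size Wright–Fisher model. Migration is *backward*: an offspring
born in deme $j$ draws its parental deme $i$ with probability $m_{ij}$
(source rows × destination columns, columns normalised to 1) — the natural
counterpart of a row-normalised arrival matrix, and the standard
formulation for island-model theory. Gametes are drawn uniformly from the
source deme's allele pool per locus; loci are unlinked. Microsatellites
mutate under the strict one-step stepwise model at 0.001564 per gamete per
generation by default (a literature-standard microsatellite rate, also the
rate assumed in the study's coalescent analysis), reflecting at a
repeat-count floor of 1. The founder pool is 20 equifrequent alleles per
locus, so initial differentiation is essentially zero and anything the
analysis finds later was produced by drift and migration — which is what
the recovery tests need.

Two cross-checks anchor the simulator to theory (both run in the test
suite and the acceptance script): isolated demes show FST growing with
time, and an island model with one effective immigrant per deme
($N_e m = 1$) equilibrates at mean AMOVA FST near Wright's
$1/(1+4N_em) = 0.2$ (the 25-deme finite-island correction puts the exact
expectation at $\approx 0.187$; the acceptance band of $0.2 \pm 0.05$ spans
both). Problem sizes used: 25 demes of 50 diploids, 7 loci, 150
generations, 20 sampled individuals per deme, 20 replicates.

Hybrid introgression and genotyping artefacts are layered on top:
`make_parental_panels()` builds two per-locus allele-frequency tables with
a tunable shared fraction (0 = fully diagnostic, 1 = unidentifiable, which
downstream estimation refuses); `inject_hybrids()` draws each allele copy
independently from panel A with probability $h$; `apply_null_alleles()`
silences allele copies independently, scoring half-silenced genotypes as
homozygotes and fully-silenced ones as missing — the classic null-allele
artefact.

## 4. AMOVA and F-statistics

The three-stratum AMOVA (among samples / among individuals within samples /
within individuals) is computed on allele copies with the 0/1 mismatch
distance, per locus, summed over loci; missing genotypes are dropped per
locus (pairwise deletion, never imputation). Degrees of freedom follow the
sample structure ($P-1$, $N-P$, $N$), and variance components come from
the expected mean squares with the unequal-$n$ coefficient on allele
copies. The implementation is verified against an explicit enumeration
oracle (sum of pairwise copy distances divided by group size) on small
random datasets, where the two routes agree exactly.

$F_{ST} = V_a/(V_a+V_b+V_c)$, $F_{IS} = V_b/(V_b+V_c)$,
$F_{IT} = (V_a+V_b)/(V_a+V_b+V_c)$; on unclamped components
$(1-F_{IS})(1-F_{ST}) = 1-F_{IT}$ holds to machine precision and is
asserted at $10^{-12}$. Permutation p-values shuffle individuals among
samples (FST), allele copies among individuals within samples (FIS), and
allele copies globally (FIT), with the add-one rule
$(\text{count}+1)/(n+1)$. Pairwise FST is the two-sample AMOVA estimator —
matching the tool the study used, whose pairwise "Wright's FST" is
AMOVA-based — with negative estimates clamped to zero in reports (raw
values retained) and Bonferroni flags at $\alpha/\binom{n}{2}$.
Expected heterozygosity is Nei's $1-\sum p^2$. For null alleles both
Brookfield's first estimator $(H_E-H_O)/(1+H_E)$ and Chakraborty's
$(H_E-H_O)/(H_E+H_O)$ are offered; under the package's own silencing model
Chakraborty's is the calibrated one, and the recovery test uses it.

## 5. The hybrid index

For an individual with called genotypes, the log-likelihood of hybrid
index $h$ (proportion of ancestry from species A, $h=1$ pure A) is
$\sum \log[h\,p_A(a) + (1-h)\,p_B(a)]$ over allele copies. Alleles absent
from a finite reference panel get a floor frequency
$1/(2\cdot\text{panel size}+1)$ before renormalisation, so a single
unshared allele cannot drive the likelihood to $-\infty$. The
log-likelihood is concave, and the maximiser uses a 1e-3 coarse grid
refined by a 1e-6 fine grid — both constructed mirror-symmetrically and
evaluated with explicit weight pairs, with median tie-breaking, so
swapping the two panels maps every estimate to $1-\hat h$ to floating-point
precision (asserted at $10^{-12}$). Purity filtering implements the
"$h<1$ is a hybrid" rule with an explicit numerical tolerance (default
$10^{-6}$) because a finite optimiser rarely returns exactly 1.0.

## 6. Distances, migration conversion, and the Mantel test

Two distance metrics are offered. The default `degree_euclidean`
($111.19\,\text{km}/° \times \sqrt{\Delta\text{lat}^2+\Delta\text{lon}^2}$
on raw decimal degrees) is the metric that reproduces the study's printed
pairwise summaries, and is also the plane the particle model uses, keeping
the two tracks' geometry consistent; `haversine` is the geodetically
correct alternative (east–west distances shrink by the cosine of latitude,
so the two differ materially at 52–55°N). One wrinkle the package makes
explicit: the shipped site table contains two Wadden Sea mussel beds only
6 km apart, and the published distance summary (minimum 17 km) is
recovered exactly when those twin beds are collapsed to a single location —
the acceptance computation does so and labels it.

$F_{ST}$ converts to effective migrants by inverting Wright's island
approximation, $2N_em = (1-F_{ST})/(2F_{ST})$; non-positive $F_{ST}$
means unbounded migration and returns a flagged `NA` rather than a number.

The Mantel test correlates off-diagonal cells (the diagonal is structurally
zero for distance-like matrices and reported separately as retention for
arrival matrices) and permutes by a single random relabelling of sites
applied simultaneously to rows and columns of the second matrix. This is
the key point for directed exchange data: the joint permutation preserves
each permuted matrix's asymmetric structure, so the null distribution is
correct whether or not the inputs are symmetric. P-values count *strictly*
more extreme permuted correlations — the natural reading of "fraction of
permutations with a higher correlation" — which also makes the
self-correlation case exact ($p_{\text{greater}} = 1/(n+1)$ for $A$ vs
$A$). Because the sidedness used for the study's headline correlation is
ambiguous in the source, all three alternatives are always computed and
reported; Spearman is available alongside Pearson for the same reason
("Pearson's rank correlation" is a contradiction the caller must resolve).
Calibration is demonstrated, not assumed: on 200 independent null matrix
pairs the empirical type-I rate at $\alpha=0.05$ must fall inside the 95%
binomial interval, and on 3×3 inputs the Monte-Carlo p agrees with
exhaustive enumeration of all six relabellings.

Zero cells in arrival matrices are genuine zeros, not missing data, and
enter correlations as zeros — no-exchange pairs are the signal, not an
artefact.

## 7. The end-to-end experiment

`stepping_stone_experiment()` chains everything at desk scale: 10 sites in
two clusters of five (40-km spacing within clusters, a 120-km gap between
them) under a 0.1 m/s eastward residual with a 0.3 m/s M2 tide; 500
particles per site tracked 15 days with $D = 20\ \mathrm{m^2/s}$ and a
6-km capture radius; arrival proportions scaled into a backward migration
matrix (best-connected deme receives 30% immigrants); 200 Wright–Fisher
generations over demes of 50; pairwise FST; asymmetric Mantel of FST
against arrival counts. The geometry is chosen so the exchange matrix has
the study system's qualitative shape — mostly zeros (around 70% of cells),
strongly asymmetric, downstream neighbours linked, the far cluster
unreached — while differentiation has something to vary over. The expected
outcome, asserted over five replicate seeds in the acceptance suite, is a
negative FST-vs-arrivals correlation with $p_{\text{less}} \le 0.05$.

## 8. Reproducibility and limitations

One global seed drives everything; each stage derives its own stream
(`derive_seed(seed, stage)`, always below $2^{31}$), so stages can be
rerun independently and identical configurations are bit-identical.

What passing tests do *not* show: the flow fields are caricatures, so
nothing here validates any particular sea's circulation; the Wright–Fisher
demes are at equilibrium scales far below real mussel populations, so
absolute FST magnitudes are not comparable to field values; hybrid
injection draws allele copies independently given $h$ (no linkage, no
family structure), which is exactly the hybrid-index likelihood's model —
recovery tests therefore validate the estimator, not the biology; and the
coalescent migration machinery of the original study is out of scope —
migration matrices are consumed as inputs or produced as simulation ground
truth.
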