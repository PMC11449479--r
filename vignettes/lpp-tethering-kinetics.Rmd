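---
title: "Isotopologue masses and tethering kinetics of the Braun lipoprotein"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopologue masses and tethering kinetics of the Braun lipoprotein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lppkin)
```

## The experiment this package models

About a third of the ~10^6 copies of the Braun lipoprotein (Lpp) in an
*E. coli* cell are covalently tethered to the peptidoglycan (PG):
L,D-transpeptidases (ErfK, YbiS, YcfS) link the side chain of Lpp's
C-terminal Lys to the *meso*-diaminopimelate (DAP) of a stem peptide, and a
fourth enzyme of the family, YafK, hydrolyzes that bond. In a pulse-chase
design, cells grown on [^13^C]glucose and [^15^N]ammonium chloride (so every
pre-existing molecule is uniformly "heavy") are switched to light medium and
sampled over one generation (60 min). Digestion of the PG with proteases and
muramidase releases the diagnostic muropeptide **Tri→KR**: the
disaccharide-tripeptide GlcNAc-MurNAc^R^-L-Ala-D-iGlu-DAP cross-linked to
the Lys-Arg remnant that trypsin leaves of Lpp. Because the stem and the
Lys-Arg remnant are independently labelable, Tri→KR occurs as four
isotopologues — written stem-age→lpp-age: `nn` (new→new), `oo` (old→old),
`on` (old→new), `no` (new→old) — and their relative abundances over time
encode how fast Lpp is tethered, released, and re-tethered.

The package implements the whole desk side of that experiment: exact
isotopologue and MS² fragment masses, peak assignment and quantification, a
kinetic model of dilution + tethering + hydrolysis, parameter estimation
with bootstrap uncertainty, and a synthetic-data generator standing in for
the deposited raw spectra.

## Mass engine

Compositions are integer atom-count vectors; a muropeptide is an ordered
residue list with a condensation-bond count, a reduction flag (MurNAc is
borohydride-reduced to muramitol, +2 H, during work-up), and a moiety tag
per residue (`stem` or `lpp`). Assembly sums free-molecule residue formulas
and removes one water per condensation bond — peptide, isopeptide,
glycosidic and lactyl-amide bonds all lose exactly one water, which is why a
single bookkeeping rule reproduces the whole fragment ladder. Fragments are
treated as hydrolytic condensation products; no a/b/y-ion proton bookkeeping
is introduced, and masses are neutral monoisotopic values (charge is a
display transform).

Full isotopic enrichment is assumed: a heavy moiety replaces every C by
^13^C and every N by ^15^N, adding `nC·1.0033548 + nN·0.9970349` Da. Water
losses carry no C or N, so a moiety's shift depends only on its residues'
summed C/N counts — which makes the grid exactly additive:
`m(on) + m(no) = m(nn) + m(oo)` for every fragment. Displayed values are
rounded half-up to 2 decimals (base `round()` is half-to-even, which
disagrees on boundary values such as x.xx5), and comparisons use a
±0.01 Da window.

The four columns of the published isotopologue grid are mapped to label
states by mass arithmetic: the +18.02 Da step is the Lys-Arg moiety shift
(C12 N6) and the +40.10 Da step is the stem shift (C34 N6), giving the
column order (light,light), (heavy lpp), (heavy stem), (all heavy) =
`nn, no, on, oo`. The original figure encodes this by color, so the mapping
is an inference — flagged here because nothing else in the package pins it.

```{r masses}
theoretical_table(digits = 2)
```

## Assignment and quantification

Observed peak lists (deisotoped, neutral-mass) are matched to the grid by
nearest mass within 20 ppm at MS1 and 0.02 Da at MS2 (both configurable;
the reference data deviate by ≤0.01 Da). Exact ties resolve to the lower
theoretical mass and are flagged ambiguous — determinism over cleverness —
and coincident theoretical masses (the Lys-Arg fragment is identical in the
`nn` and `on` columns) are always flagged. The lpp label of a precursor can
be read directly from the Lys-Arg fragment (302.21 vs 320.23 Da) and the
stem label from the DAP→Lys-Arg increment (+9.02 Da); conflicting fragment
evidence is reported, never silently overridden.

Relative abundance is each isotopologue's intensity as a share of the
four-isotopologue sum, in percent. Ratios are computed **per replicate** and
averaged afterwards; the alternative (ratio of summed intensities) is not
what the reported averages describe, and per-replicate ratios are what the
replicate bootstrap needs. Moiety aggregates add the two isotopologues
sharing an age: old-Lpp = `oo + no`, old-stem = `oo + on`.

## Kinetic model

Nine pools: free Lpp by age (`F_o`, `F_n`), bound Tri→KR by stem→lpp age
(`B_oo`, `B_on`, `B_no`, `B_nn`), tetrapeptide donor stems by age
(`D_o`, `D_n`), and total tracked stems `S`. With growth rate
`mu = ln 2 / T`, donor-age fractions `p_o = D_o/(D_o+D_n)`, tethering rate
`k_t` (per free Lpp) and hydrolysis rate `k_h` (per bound Lpp):

```
F_o' = -k_t F_o + k_h (B_oo + B_no)
F_n' = mu L - k_t F_n + k_h (B_on + B_nn)
B_xy' = k_t F_y p_x - k_h B_xy
D_o' = -k_t (F_o + F_n) p_o
D_n' = mu delta L sigma - k_t (F_o + F_n) p_n
```

with `L` total Lpp, `delta` the donor-to-Lpp ratio and `sigma` an optional
septal-exclusion factor on new-donor supply (default 1 = off; no spatial
model beyond this knob). Hydrolyzed stems leave the donor pool permanently —
a tripeptide cannot re-donate — while the released Lpp re-enters the free
pool of its own age class undegraded. Two invariants follow exactly: old
Lpp (`F_o + B_oo + B_no`) is conserved, and total Lpp grows as
`L0 e^(mu t)`. At 10^6 copies per cell the mean-field ODE is the right
primary engine; an exact Gillespie simulation of the same network exists
purely as a test oracle and agrees with the ODE within Monte-Carlo error at
10^4 molecules.

**Parameters.** `T = 60` min (one generation), tethered fraction
`b0 = 1/3`, `L0 = 10^6`, `delta = 1` (the donor-pool size is not known; it
is exposed as a knob and replenished in proportion to cell mass). Neither
`k_t` nor `k_h` is known numerically — only the derived "at least 50 % per
generation" bound — so defaults are chosen to reproduce the observed laws:
`k_h = ln 2 / T` for the wild type (50 % bond survival per generation, the
value the 4-vs-2-fold observation implies), `k_h = 0` for the ΔyafK mutant,
and per genotype `k_t = (mu + k_h) b0 / (1 - b0)`, the unique rate that
holds the tethered fraction steady during balanced growth (the tethered
fraction is observed to be unchanged by the *yafK* deletion). Fitted values
on real data would be estimates, not ground truth.

**Initial conditions.** Two configurations are provided and the choice
matters:

* `scenario = "switch"` is the literal medium switch: every molecule heavy,
  `F_o = (1-b0) L0` free. Simulated forward, the large free-old-Lpp pool
  re-tethers to old donors and *regenerates* old→old bonds, so the old→old
  reduction over one generation is well short of 50 % — this scenario
  overstates exchange because most free Lpp sits surface-exposed in the
  outer membrane and is modeled here as one well-mixed pool. It is retained
  as the configuration in which the headline estimator's lower-bound
  property is exercised, since it maximizes the regeneration that causes
  the underestimate.
* `scenario = "cohort"` is the balanced-growth cohort configuration behind
  the dilution law: the bound pool (all old→old at the switch) is tracked
  together with only the old free Lpp actually exchanging with it at the
  tethering/hydrolysis equilibrium (`F_o = b0 L0 k_h / k_t`, zero for
  ΔyafK), no old tetrapeptide donors. With the steady tethering rate the
  bound pool grows exactly as `b0 L0 e^(mu t)` and bound old Lpp is exactly
  constant, so old→old relative abundance follows `2^(-t/T)`: a 50 %
  reduction per generation with hydrolysis off, `e^(-k_h t) 2^(-t/T)` for
  the old-stem aggregate with hydrolysis on (4-fold per generation at
  `k_h = ln 2/T`), and a 2-fold old-Lpp reduction in *both* genotypes.
  This is the default for the synthetic generator because it reproduces
  the observed curves' structure.

```{r dilution}
q <- trajectory_quant(simulate_pools(yafk_params(), scenario = "cohort"))
q[q$time_min %in% c(0, 30, 60), c("time_min", "oo", "old_lpp", "old_stem")]
```

**Numerics.** lsoda with rtol 1e-8 / atol 1e-10, output every minute over
[0, 60] by default. Fitting loops use a fixed-step RK4 (step 5 min, shrunk
automatically to 0.2 of the fastest rate's timescale) — the system is
smooth and non-stiff at biological rates, and the two integrators agree to
~1e-7 relative. Rate combinations that exhaust the donor pool (tethering
flux above donor supply) are outside the model's domain; the ODE signals
them as integration failures and the fitter treats them as a flat penalty
so multistart simply discards such starts.

## Estimation

The loss is the unweighted sum of squared residuals on the percent scale —
the scale the experiment reports — over time points, replicates and
isotopologues, minimized by Levenberg–Marquardt from a seeded
Latin-hypercube of starts (default 8; tethering rates sampled
log-uniformly, plus one domain-informed start at growth-rate-scale rates).
Ties resolve to the lowest `k_h`. A joint fit shares nothing but the data
structure: (`k_t_wt`, `k_t_mut`, `k_h`) with the mutant's hydrolysis fixed
at zero.

Uncertainty comes from resampling **biological replicates** (the
experiment's error unit) with replacement, independently per genotype, and
refitting from the point estimate; intervals are percentile. With 3–5
replicates the plain n-out-of-n resample understates the variance of a
replicate mean by (n−1)/n and plain percentiles behave like z-quantiles
although the interval width rests on ~n−1 degrees of freedom. Both standard
small-sample corrections are applied: the resample draws n−1 replicates
(making the resampled-mean variance unbiased) and the percentile levels are
expanded from α/2 to Φ(−t_{n−1, α/2}) (the expanded percentile interval).
Calibration is checked empirically in the test suite (95 % intervals over
100 synthetic datasets at 5 replicates and 10 % CV).

The **headline estimator** is model-free: fold decrease of the old-stem
aggregate over one generation in each genotype, then
`100 (1 - fold_mut / fold_wt)`. On cohort-law folds of 4 and 2 it returns
50 %. It is a *lower bound* on the true per-bond hydrolyzed fraction
`100 (1 - e^(-k_h T))`: whenever released old Lpp can re-tether to an old
tetrapeptide donor, old-stem isotopologues are regenerated and the excess
decay is partially masked — the switch-scenario sweep in the tests shows
the estimator undershooting at every `k_h`.

## Synthetic data

The generator simulates the cohort trajectory for a genotype, converts
abundances to intensities (`scale × abundance`), multiplies by log-normal
noise with mean 1 and a CV parameter (default 10 %; intensities are
positive and heteroscedastic, so multiplicative noise is the natural
choice — the real replicate-to-replicate variance is unknown at desk and
this default is a placeholder), and emits per-replicate quant tables plus
MS1/MS2 peak lists with Gaussian ppm mass error (default SD 5 ppm; at mass
1200 that is ±0.006 Da, comfortably inside the 20 ppm matching window).
Defaults: sampling at 0, 15, 30, 45, 60 min (the switch plus four chase
points — the actual chase times are not published), 4 replicates (within
the experimental 3–5), MS2 fragment intensities uniform (assignment uses
masses only). Everything regenerates bit-identically from the config's
mandatory seed.

What passing tests on these data do **not** show: robustness to
chromatographic artifacts, isotope-envelope overlap, fragmentation
efficiency, charge states, replicate-level growth-rate variation, or
incomplete isotopic enrichment — none of which the generator emulates.

## Problem sizes and study designs

The calibration studies shipped in the test suite use: 100 synthetic joint
datasets (5 replicates, 10 % CV, 5 time points) for the bias and coverage
checks, 100 bootstrap draws per dataset, 2 multistart points plus the
domain-informed start for study fits (the full default of 8 is used for
one-off fits), and 100 Gillespie runs at 10^4 molecules for the
stochastic-vs-deterministic comparison. These sizes give Monte-Carlo
standard errors small enough for the stated acceptance windows (binomial
SE ≈ 2 % on a 95 % coverage proportion at 100 datasets).

## Known limitations

* The cohort scenario labels the non-exchanging bulk of the free Lpp pool
  as "new" from the start; it is built for the aggregate dilution laws and
  for generating realistic curves, not for predicting the early new→old
  transient from first principles.
* One well-mixed free-Lpp pool: no surface-exposed vs periplasmic
  compartmentalization, no translocation kinetics.
* No spatial (septal vs lateral) PG model beyond the scalar septal factor;
  no 4→3/3→3 cross-link populations; no vesiculation.
* Isotopic enrichment is assumed complete; metabolite carry-over after the
  switch is assumed zero.
* The donor-pool ratio `delta` is a guess (1 donor per Lpp) exposed as a
  parameter; fits of `delta` are possible but not exercised.
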