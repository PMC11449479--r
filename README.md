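# lppkin

Turnover kinetics of the covalent bond between the Braun lipoprotein (Lpp)
and the peptidoglycan (PG) of *Escherichia coli*, analyzed through
heavy-isotope (¹³C/¹⁵N) pulse-chase labeling of the diagnostic **Tri→KR**
muropeptide — the disaccharide-tripeptide GlcNAc-MurNAc^R^-L-Ala-D-iGlu-DAP
cross-linked to the Lys-Arg remnant of trypsin-digested Lpp.

The package is for analysts of PG structure and protein–polymer attachment
who want to go from muropeptide peak lists to rates: it computes exact
neutral monoisotopic masses of the four Tri→KR isotopologues and their MS²
fragment ladder, assigns and quantifies peaks, models the pool kinetics, and
estimates how much of the tripeptide→Lpp bond population YafK hydrolyzes per
generation.

## The model in brief

Each Tri→KR isotopologue is written stem-age→lpp-age (`nn`, `oo`, `on`,
`no`; old = heavy). A heavy moiety adds `nC·Δ¹³C + nN·Δ¹⁵N` to the light
mass, so the 7-fragment × 4-isotopologue grid is fully determined by residue
formulas and condensation-water bookkeeping.

Pool dynamics (free Lpp `F`, bound Tri→KR `B`, tetrapeptide donors `D`, by
age class; growth rate μ = ln2/T):

    B'_xy = k_t F_y p_x − k_h B_xy,   p_x = D_x / (D_o + D_n)

with Lpp synthesis μL into `F_n`, donor supply μδL into `D_n`, released Lpp
returning to its age's free pool, and hydrolyzed stems leaving the donor
pool for good. Relative abundance of an isotopologue is its share (%) of the
summed four intensities. Two laws fall out in the balanced-growth (cohort)
configuration: any non-replenished species halves its relative abundance per
generation (pure dilution), and hydrolysis multiplies the old-stem decay by
`e^(k_h t)` — folds of 4 (wild type) versus 2 (ΔyafK) over 60 min give the
model-free lower bound `100(1 − 2/4) = 50 %` of bonds hydrolyzed per
generation.

## Worked example

```r
library(lppkin)

theoretical_table(digits = 2)[c(1, 6), ]
#>                                             nn      no      on      oo
#> GlcNAc-MurNAc(r)-Ala-iGlu-DAP->Lys-Arg 1154.57 1172.59 1194.66 1212.69
#> Lys-Arg                                 302.21  320.23  302.21  320.23

print(run_demo(seed = 1))
#> lppkin demo (seed 1)
#>   mass grid: 28/28 reference masses within +/-0.01 Da
#>   peaklist round trip: max |quant dev| = 0 %
#>   Delta-yafK old->old abundance at 60 min / 0 min = 0.5000
#>   joint fit: k_t_wt=0.01163, k_t_mut=0.00577, k_h=0.01171 (true k_h = 0.01155)
#>   headline estimate: 46.9 % of bonds hydrolyzed per generation (folds 3.88 vs 2.06)
```

Reading the demo: all 28 grid masses reproduce the reference table; a
zero-loss assign→quantify round trip on synthetic peak lists; the ΔyafK
(hydrolysis-off) simulation shows the pure dilution halving; the joint fit
recovers the generating hydrolysis rate (ln2/60 ≈ 0.01155 per min) from
noisy 4-replicate data; and the model-free estimator lands just under the
true 50 % — it is a lower bound, since re-tethering of released old Lpp to
old donors masks part of the hydrolysis.

## The analysis, step by step

Numbered scripts under `analysis/` run the full workflow and write tables
under `results/`:

1. `01_theoretical_masses.R` — the 7×4 mass grid, validated against the
   reference values.
2. `02_dilution_kinetics.R` — wild-type and ΔyafK trajectories, fold
   decreases, and the 50 % hydrolysis estimate.
3. `03_synthetic_experiment.R` — seeded synthetic intensity tables and
   MS1/MS2 peak lists for both genotypes.
4. `04_assignment_quantification.R` — peak assignment, per-replicate
   quantification, MS² label-state confirmation.
5. `05_fit_hydrolysis.R` — joint kinetic fit with bootstrap confidence
   intervals and the headline estimate.

The methods vignette (`vignettes/lpp-tethering-kinetics.Rmd`) documents the
model, its assumptions, parameter defaults, numerical choices and
limitations.

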