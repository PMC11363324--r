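# aquabridge

Analysis pipeline for structural and pharmacological characterization of
bitopic opioid-receptor ligands — compounds that reach from the
orthosteric pocket toward the sodium allosteric site around the
conserved aspartate D2.50 of a class A GPCR. The scientific question the
pipeline addresses: does a ligand's polar warhead engage the sodium-site
carboxylate directly or through bridging waters, how does that
engagement (and π–π stacking with the TM7 tyrosine) differ between
hydrogen-bond donor and acceptor analogs, where does the activated
receptor traffic, which proteins enter its proximal network, and what
are the compound's potency, efficacy, antinociceptive ED50 and brain
penetration?

It is aimed at structural pharmacologists who have simulation snapshots,
BRET concentration-response tables, APEX proximity-labeling intensity
matrices, or antinociception dose-response data — and at method
developers who want every stage exercisable on synthetic data with known
ground truth.

## What it computes

**Water-bridge classification.** Each frame is labeled by the exclusion
hierarchy over the hydrogen-bond graph (heavy-atom O···O window,
default 2.2–3.0 Å):

    direct   ligand-OH ··· Asp-Oδ
    water1   ligand-OH ··· W ··· Asp-Oδ        (no direct contact)
    water2   ligand-OH ··· W1 ··· W2 ··· Asp-Oδ (no direct, no one-water)
    none     anything else (≥3-water paths are not classified)

Class frequencies are fractions of frames per replicate, summarized as
mean ± SEM across replicates and compared between conditions with an
exact Mann–Whitney U test. π–π stacking uses centroid distance ≤ 5 Å,
interplanar angle ≤ 30°, lateral offset ≤ 2 Å.

**APEX proximity proteomics.** Receptor-sample indicator intensities `y`
are deconvolved against spatial reference profiles `X` (plasma membrane,
early endosome, lysosome) by nonnegative least squares,
`min ‖y − Xβ‖², β ≥ 0`, with β reported sum-normalized as location
fractions. Per-protein log2 time courses are fit with a degree-2
polynomial and F-tested against the flat model; hits satisfy
`max |log2FC| > 0.58` and `p < 0.001` (strict, no multiplicity
correction; the joint gate keeps the null hit rate below 1%).

**Pharmacology.** 4PL fits
`resp = Emax / (1 + 10^((log10 EC50 − log10 c)·h))` (baseline 0, Hill
slope free) reporting Emax (% of the reference agonist's maximum), pEC50
and EC50 in nM; two-parameter log-logistic ED50 fits for %MPE data
(floor 0, ceiling 100) with a delta-method 95% CI on log10(ED50); and
the brain:plasma concentration ratio.

**Synthetic data.** `gen_bridge_frames()`, `gen_dose_response()`,
`gen_apex_timecourse()` and `gen_mpe_doses()` generate every input above
with designed ground truth, explicit integer seeds and no global RNG
state.

## Worked example

```r
library(aquabridge)

# frames with designed topology: 40% one-water bridges
labs <- rep(c("water1", "none"), c(400, 600))
g <- gen_bridge_frames(frame_spec(labs, jitter_sd = 0.05, seed = 22))
cl <- classify_frames(g$frames)
mean(cl$label == "water1")
#> [1] 0.4

# concentration-response at pEC50 6.34, Emax 65%, 5% noise
d <- gen_dose_response(curve_truth(6.34, 65, noise_sd = 5, seed = 2))
fit_4pl(d)
#> 4PL fit (ok)
#>   Emax  67.84%   pEC50 6.325   EC50 473.3 nM   hill 0.88

# ED50 from %MPE data generated at 10.18 mg/kg
m <- gen_mpe_doses(mpe_truth(10.18, slope = 2, noise_sd = 10, seed = 3))
fit_ed50(m)$ed50
#> [1] 11.08525

# brain:plasma ratio from measured exposures
brain_plasma_ratio(2.8, 5.3)$ratio_1dp
#> [1] 0.5
```

The fitted Emax (67.8% vs the generating 65%), pEC50 (6.33 vs 6.34) and
ED50 (11.1 vs 10.18 mg/kg) show typical recovery at these designs; the
ratio 0.5 is the 1-decimal report of 2.8/5.3 = 0.528.

## Analysis workflow

The `analysis/` scripts run the full study on synthetic data and write
tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # generate all inputs (+ truth)
Rscript analysis/02_bridges.R      # classify frames, frequencies, U test
Rscript analysis/03_pharmacology.R # 4PL fits, ED50, brain:plasma
Rscript analysis/04_apex.R         # deconvolution, F-tests, hit calling
```

Stage 2, for example, reports per-class frequencies (mean ± SEM over 5
replicates) for a hydrogen-bond-donor versus -acceptor ligand condition
and the exact Mann–Whitney comparison of their one-water bridge
frequencies (U = 25.0, p = 0.0079 on the default conditions).

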