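---
title: "Methods: water-bridge classification, APEX deconvolution, and pharmacology fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water-bridge classification, APEX deconvolution, and pharmacology fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquabridge)
```

## Scope

`aquabridge` implements the computational stages of a bitopic
opioid-ligand characterization study as a reusable, tested pipeline:

1. **Water-bridge classification** — per-frame labeling of how a ligand
   hydroxyl engages the sodium-site aspartate (D2.50 in
   Ballesteros–Weinstein numbering) of a class A GPCR: directly, through
   one bridging water, through two consecutive waters, or not at all.
2. **Interaction-frequency scoring** — π–π stacking and hydrogen-bond
   frequencies across replicate trajectories, with Mann–Whitney U
   comparisons between ligand conditions.
3. **APEX proximity-proteomics** — spatial deconvolution of receptor-APEX
   samples against subcellular reference profiles, and polynomial
   time-course F-tests with joint effect-size/p-value hit calling.
4. **Pharmacology** — 4PL concentration-response fits (Emax, EC50/pEC50),
   reference-agonist normalization, log-logistic ED50 estimation for
   %MPE antinociception data, and the brain:plasma exposure ratio.

Every stage can be driven by the package's synthetic-data generators,
which plant a known ground truth; the `analysis/` scripts in the
repository run the stages in sequence on generated data.

## Water-bridge classification

### Model

A frame is an atom snapshot. Over the node set {ligand hydroxyl O, water
O's, carboxylate O's} we build a hydrogen-bond graph whose edges are
heavy-atom O···O distances inside a window, and classify with a strict
exclusion hierarchy:

* **direct** — the ligand O is H-bonded to either carboxylate oxygen;
* **water1** — otherwise, a ligand–water–carboxylate path exists
  (frames that *also* have a direct contact are counted as direct only);
* **water2** — otherwise, a path through two distinct consecutive waters
  exists;
* **none** — otherwise. Paths through three or more waters are not
  classified.

Because the hierarchy is exclusive and exhaustive, the four
per-replicate class fractions sum to exactly 1 — a property the test
suite asserts, along with equality between the graph search and a
brute-force enumeration of all simple paths of length ≤ 4.

### Numerical choices

* **H-bond window.** Default heavy-atom window **2.2–3.0 Å**. The upper
  bound matches the 2.5–3 Å range observed for the bridge bonds in this
  system; the lower bound guards against steric clashes rather than
  excluding real bonds. The same single window serves direct contacts and
  bridge links — one criterion, one configuration key.
* **Angle criterion.** A D–H···A angle ≥ 120° is applied only when
  explicit hydrogens are present (within 1.2 Å of the donor in the same
  residue). Simulation-derived snapshots are often stripped to heavy
  atoms, so the distance criterion must stand alone in that case.
* **Both carboxylate oxygens are equivalent endpoints**; the ligand
  hydroxyl O is the unique start atom.
* **Tie-breaking.** When several qualifying paths of the winning order
  exist, the minimum-total-length path is reported, making the output
  invariant under water reordering and atom renumbering (exact geometric
  ties excepted).
* **No periodic-boundary handling**: inputs are assumed pre-imaged
  snapshots, not raw trajectories.

### π–π stacking

Ring centroids are coordinate means; normals are the smallest-eigenvalue
eigenvectors of the ring-coordinate covariance (the best-fit plane),
sign-fixed (positive z, ties broken by x then y) so outputs are
deterministic. A face-to-face stack requires centroid distance ≤ 5.0 Å,
interplanar angle ≤ 30°, lateral offset ≤ 2.0 Å. The 5 Å bound encodes
the exclusion distance beyond which stacking is not considered robust;
the angle and offset gates follow common stacking conventions — the study
itself states no angle/offset criteria — and all three are configurable,
so reported frequencies should always quote the criteria used.

### Replicate statistics

Frequencies are computed per replicate; the summary reports the mean and
SEM (sample SD with denominator R−1, divided by √R), matching the
convention of drawing SEM bars over per-replicate points. Group
comparisons use the Mann–Whitney U test, two-sided: for ≤ 8 replicates
per group the p-value comes from full enumeration of all group
assignments of the pooled values (exact even under ties); larger groups
use the tie-corrected normal approximation. Replicate counts per
condition are explicit inputs — nothing assumes equal counts.

## Synthetic frame generation

Frames are built in a local axis system with the carboxylate at the
origin and the engagement path along +x; only atoms relevant to
classification plus decoy waters are emitted, since classification
depends only on relative geometry. Path distances are 2.7–2.8 Å; decoy
waters sit > 4.5 Å off-path; every frame carries exactly four waters so
that multi-model PDB output keeps a constant atom table. Direct frames
deliberately include a valid one-water path, so the exclusion hierarchy
is exercised, not just satisfied trivially.

Coordinate jitter is Gaussian; a jittered frame is **re-sampled** (never
clamped) if its realized class would differ from the designed label, so
truth labels remain valid by construction. Requests no jitter can
satisfy (e.g. SD comparable to the window width) fail explicitly after a
bounded number of attempts.

What the generator does *not* emulate: real solvation density (waters
appear only as designed bridges and sparse decoys), receptor flexibility
beyond isotropic jitter, correlated frame-to-frame dynamics, and
competing polar contacts. Passing tests therefore demonstrate
correctness of the classification machinery, not robustness to the full
complexity of simulation data.

The default conditions in the analysis scripts — 5 replicates × 200
frames per ligand — are conventions chosen at desk scale; the study this
emulates does not state frame strides or replicate counts, and the
replicate manifest keeps them explicit inputs.

## APEX stage

### Deconvolution

Each receptor sample's indicator-protein intensities `y` are modeled as
a linear mixture of spatial reference profiles `X` (columns = plasma
membrane, early endosome, lysosome; rows = indicator proteins; entries
averaged over reference replicates). Fractions of receptor at a location
cannot be negative, so the default solver is nonnegative least squares
(Lawson–Hanson); unconstrained least squares is available behind a flag.
Coefficients are reported sum-normalized for interpretation as
fractions; the residual norm is returned so exact mixtures are
verifiable (zero residual to 1e-9, a tested invariant). Each (time
point, replicate) column is solved independently — solving per column
keeps replicates independent for downstream error bars; a rank-deficient
reference matrix fails naming the collinear locations.

### Time-course statistics and hit calling

Intensities are log2-transformed with a pseudo-count of half the
matrix's minimum positive value (the preprocessing is otherwise
unstated upstream; the pseudo-count only matters if zeros occur). Each
protein's log2 time course is fit by ordinary least squares on raw
polynomial time terms, default **degree 2** over the 0–30 min course —
the degree is a logged configuration value, not a claim about the true
kinetics — and tested against the intercept-only model with an F-test on
(d, N−d−1) degrees of freedom. Zero-residual series are flagged and
reported at the machine floor rather than p = 0. Under the null the
p-values are uniform, verified by simulation (KS test) and against a
time-label permutation null.

Per-time log2 fold changes are formed per replicate against that
replicate's own baseline (t = 0) intensity and then averaged. A protein
is a hit iff max |log2FC| > 0.58 **and** p < 0.001, both strict, with no
multiple-testing correction — the joint gate is the multiplicity
control, and the null-generator hit rate stays below 1% (tested).

**Indicator proteins are excluded from the hit table by default.** Their
labeling tracks receptor trafficking between compartments — exactly the
signal the deconvolution consumes — so flagging them as
interaction-network changes would double-count a location shift as a
proximity change. The flag `exclude_indicators = FALSE` restores them.

### Generator conditions

Defaults: 500 proteins; three locations with 8 disjoint indicator
proteins each (32-fold enriched in their own reference, 8-fold depleted
in the others); time points 0/1/5/10/20/30 min × 3 biological
replicates; a mixing series moving from all-plasma-membrane at t = 0 to
(0.2, 0.5, 0.3) at 30 min (internalization); 3 planted changing proteins
following a rise-to-plateau profile with peak log2FC 1.0 sustained from
10 min; null deviations with SD 0.15 log2 units; reference replicate
noise SD 0.1. The effect profile was chosen smooth enough that a
degree-2 polynomial captures it with little lack-of-fit — with an
abruptly kinked profile the F-test's residual absorbs the
mis-specification and power drops, which is a real-data caveat worth
keeping in mind when choosing the degree.

## Pharmacology

### 4PL concentration-response

The model is
`resp = baseline + (emax − baseline) / (1 + 10^((log10 EC50 − log10 c)·h))`,
reported as Emax (% of the reference-agonist maximum), pEC50
(−log10 M), EC50 (nM, `10^(9−pEC50)`), and Hill slope. Defaults:
baseline fixed at 0 (agonist-mode data already normalized to a reference
maximum), Hill slope free in [0.3, 5]. Fits use Levenberg–Marquardt
least squares with a multi-start over a pEC50 grid spanning the observed
concentration range, guarding against local minima; standard errors come
from the covariance at the optimum and CIs are Wald intervals.
Zero-noise data are recovered to ~1e-6 across the constraint box
(property-tested), and the pEC50 recovery bias over 200 noisy
simulations at the 8-concentration × 4-replicate, 5%-noise design is
below 0.05.

Freeing the Hill slope costs EC50 precision: at that design the fitted
EC50's seed-to-seed SD is roughly 17% of its value, which is the
dominant contribution to recovery error at the published designs.

"No detectable activity" is an explicit output state — triggered when
the Emax CI includes 0 or the fitted span is under 3× the residual noise
estimate — rather than a silent near-zero fit; the upstream criterion
for "not measurable" efficacy is unstated, so the rule used here is
deliberately conservative and recorded in the result object.

### ED50

%MPE is bounded by definition, so the dose-response model is a
two-parameter log-logistic with floor 0 and ceiling 100:
`mpe = 100 / (1 + (ED50/dose)^slope)`. The fit estimates log10(ED50)
and slope; the 95% CI is a delta-method interval on log10(ED50)
back-transformed to mg/kg, and the method is recorded in the output
(the upstream estimation method is unstated). The estimate is
equivariant under dose rescaling (tested: mg/kg vs g/kg differ by
exactly 1000×). Data with all responses at the floor or ceiling fail
with "no intermediate response".

The %MPE generator adds subject-level Gaussian noise and clamps to
[0, 100]; clamping slightly biases low-dose means upward, which is a
property of bounded assay scales, not an artifact to correct.

## Problem sizes

Tests and the acceptance script run at desk scale by design:
concentration-response fits at 8 × 4 observations, ED50 at 3 doses × 8
subjects, APEX at 500 proteins × 21 samples, frame ensembles of ~10³
frames, and enumeration oracles at n ≤ 6 (Mann–Whitney) or ≤ 30 waters
(path search). These sizes were chosen as the smallest at which the
statistical behaviour under study (recovery bias, null uniformity, power
at the hit gate) is already visible.

## Known limitations

* Frames are heavy-atom-oriented; donor/acceptor directionality of
  hydrogen bonds is only resolved when explicit hydrogens are present.
* No cation–π or salt-bridge scoring, no solvent accessibility, no
  sodium-ion occupancy analysis.
* The deconvolution assumes reference profiles measured in the same
  intensity space as receptor samples; no cross-batch normalization is
  provided.
* 4PL CIs are Wald intervals; for concentration ranges that poorly
  bracket the EC50 they can be optimistic — the multi-start protects the
  point estimate, not the interval.
* The operational model of agonism (bias factors), Schild analysis and
  PK compartmental modelling are out of scope.
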