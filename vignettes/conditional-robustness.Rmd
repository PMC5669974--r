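---
title: "Conditional robustness analysis of patient-specific signaling models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional robustness analysis of patient-specific signaling models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwayCRA)
```

## The problem

Two tumors with the same histology can behave very differently under the same
chemotherapy. pathwayCRA implements a workflow for interrogating that
difference at the level of signal transduction: given a reverse phase protein
array (RPPA) panel measured in two patients — here a short-overall-survival
(s-OS) and a long-overall-survival (l-OS) lung adenocarcinoma — it builds a
personalized ordinary-differential-equation model of the
EGFR/IGF1R–MAPK–PI3K/mTOR network for each patient and asks which parts of the
network make each tumor's signaling state robust to perturbation.

Throughout, "ratio" means the s-OS intensity divided by the l-OS intensity of
one antibody endpoint, so a ratio above 1 marks a protein more
expressed/activated in the short-survival tumor.

## Endpoint selection

The panel shipped with the package has 51 endpoints. Ratios are recomputed
from the raw intensities; a printed-ratio column, when present, is
cross-checked to two decimals. Degenerate intensities are flagged instead of
imputed: a positive numerator over a zero denominator is "undefined-high", a
zero numerator is a true zero ratio, and 0/0 is uninformative. With the
default 2-fold rule (`ratio >= 2` or `<= 0.5`) the panel yields 20 divergent
endpoints, 4 up and 16 down in s-OS.

Calibration proteins are chosen among endpoints that map to model nodes (the
shipped antibody map drops total-protein antibodies, off-model proteins, and
the RAF isoform antibodies that do not correspond to the model's RAF node).
Nodes are ranked by their *most divergent endpoint* on the `|log2 ratio|`
scale, with flagged extremes ranked outermost on their side. We rank by the
extreme endpoint rather than by the per-node aggregate because a single
strongly divergent phosphosite is exactly the signal the calibration should
chase; aggregating first would let a flat second site mask it. Two nodes per
direction are taken: BAD and cKIT ("+", higher in s-OS), RAF and p70S6K
("−"). Only the *direction* of each calibration protein is consumed
downstream — the tail conditioning never uses the ratio magnitude — so a node
whose extreme endpoint has no finite ratio (BAD, whose S155 site has zero
l-OS intensity) is still selectable.

For validation, phosphosites of one node are aggregated by the geometric mean
of their finite ratios (the natural average for fold changes); the p70S6
T412 site is excluded from the p70S6K aggregate, which is defined by the
S371/T389 activation sites.

## The pathway model

The default network has 21 protein nodes and 30 signed interactions
(see `inst/extdata/model_21node.yaml`; the topology follows the canonical
MAPK and PI3K/AKT/mTOR cascades with receptor convergence on SOS and PI3K,
p90RSK negative feedback on SOS, p90RSK/AKT inhibition of BAD, AKT–RAF
crosstalk, the LKB1–AMPK–mTOR axis with ERK inhibition of LKB1, and p70S6K
feedback on PI3K). Each node carries a conserved total normalized to 1, so
its state is the active fraction `a ∈ [0, 1]` and the inactive fraction is
`1 − a` by construction — the conservation law is structural, never
integrated.

Construction rules:

* every enzymatic edge is Michaelis–Menten in its substrate: an activating
  edge contributes `k · a_src · (1 − a)/(K + 1 − a)`, an inhibiting edge
  removes `k · a_src · a/(K + a)`;
* basal deactivation is mass action, `k_dec · a`;
* receptors are driven by a constant extracellular stimulus level `S` acting
  mass-action on the inactive fraction, `S · (1 − a)` (ligand dynamics are
  out of scope, so saturation in the stimulus is not identifiable and a
  Michaelis constant there would be pure excess parameterization);
* the constitutive phosphatases RasGAP, RafPP and PP2A are clamped at a
  constant active fraction, itself a sampled parameter (`level_*`);
* LKB1 and BAD, which receive only inhibitory edges, carry a basal
  activation rate so they are not structurally dead at the all-inactive
  initial state;
* CASP stands for cleaved effector caspase; cleavage is irreversible, so it
  has no basal deactivation.

This yields exactly 86 named parameters: 30 edge rates `k`, 30 Michaelis
constants `K`, 17 basal deactivation rates, 4 receptor stimuli, 3 phosphatase
levels, and 2 basal activation rates. All are dimensionless except the rates
(1/time in the model's arbitrary time unit).

These functional forms keep every state inside `[0, 1]` for any positive
parameters: activation vanishes as `a → 1` and every removal term vanishes
as `a → 0`.

**Numerical choices.** The initial condition is all-inactive except a small
receptor seed (`1e-3`); the evaluation function is the area under the
transient response, so a quiescent start is what makes it informative. The
horizon is `T = 100` time units, long enough for nominal trajectories to
settle; integration uses `deSolve::lsoda` (stiff-capable — log-uniform
sampling over four decades produces stiff draws) at `rtol 1e-6` /
`atol 1e-9`, with the right-hand side compiled in C. A draw is *failed* when
the integrator stops early or a state leaves `[0, 1]` beyond `1e-6`; failed
draws are excluded from all statistics, counted, and a failure rate above 5%
aborts the run (typical rates at the default space are below 2%).

## Conditional robustness and the MIRI

Parameters are sampled by Latin hypercube, log-uniformly over
`nominal × [1e-2, 1e2]` (the standard ignorance interval for rate
constants; `level_*` parameters are capped at 1 because they are active
fractions). Each draw is simulated and scored by the evaluation function —
the trapezoidal AUC of a chosen node's active fraction.

The calibration conditions the sample jointly on the four calibration
proteins: the "s-OS-like" set is the intersection of each protein's
`alpha`-tail in its RPPA direction (upper for "+", lower for "−") and the
"l-OS-like" set is the opposite intersection. `alpha` defaults to 0.10. At
desk-scale sample sizes the four-way intersection is usually smaller than the
20 samples a density estimate needs, in which case the conditioning falls
back to ranking draws by the mean of direction-signed standardized AUCs and
taking the `alpha`-fraction extremes; the fallback is recorded in the result.

Each parameter is then scored by the **moment independent robustness
indicator**: the total-variation distance

$$\mathrm{MIRI}(\theta_j) = \tfrac12 \int \lvert f_L(\theta_j) -
f_U(\theta_j)\rvert \, d\theta_j \in [0, 1]$$

between the two tail-conditioned densities of that parameter, estimated with
Gaussian kernels, a common Silverman bandwidth computed on the pooled data,
and a shared 512-point grid. Densities are estimated on `log10(θ)` — on the
raw scale a log-uniform sample is dominated by its upper decade and the
estimator would be blind to structure in the lower decades. A 64-bin
histogram L1 estimator ships alongside as an independent cross-check; the two
agree within 0.05 in the test suite. A parameter that never reaches the
evaluation node scores statistically zero, which the tests verify on a model
with a deliberately disconnected node.

## Calibration, patients, validation

Parameters whose mean MIRI (over realizations) exceeds the upper boxplot
fence `Q3 + 1.5·IQR` are declared calibration-relevant — a box-plot-with-
threshold presentation makes the fence the natural rule when no numeric
cutoff is available; an explicit cutoff is also supported. The desk-scale
runs here select on the order of 10 parameters. Each selected parameter is
fixed to the *median* of its conditioned draws: the s-OS patient model takes
the s-OS-like tail median, the l-OS model the opposite tail, so the two
patients fix the same names to opposite-tail values and share the remaining
free space. The median is used because it is robust, invariant under the log
transform, and guaranteed to lie inside the induced tail; point fixing (not
sub-range resampling) keeps the two patients' free spaces identical.

Validation samples the shared free space (the same hypercube seeds for both
patients, a paired design that removes sampling noise from the patient
contrast), simulates both models, and compares per-node AUC distributions:
a node is "lower in s-OS" when its s-OS mean AUC is below its l-OS mean
(the mean is the primary location summary for stability; medians are also
reported). Directions are compared with the aggregated RPPA ratios for the
validation nodes — ERK, AMPK and mTOR, the measured nodes with the highest
closeness centrality then eccentricity on the undirected network skeleton —
and reported without an RPPA anchor for RAS, the KRAS readout. Each
patient's node-by-parameter MIRI matrix (every node as its own evaluation
function, both tails from its own distribution) summarizes robustness; the
clustered s-OS − l-OS difference map (Euclidean distance, average linkage,
dendrogram exported as Newick) localizes it, and the mean of all entries is
our operationalization of *overall robustness* — the published analysis
compares overall robustness qualitatively without stating its functional
form, so the mean is declared, not asserted, to match.

## The synthetic generator

`generate_rppa_table()` emulates the structure of the patient panel:
baseline intensities uniform on `1e3–7e4` arbitrary units (the scale of the
real table), multiplicative log-normal noise (RPPA variation is
multiplicative and intensities are positive), planted fold changes on named
proteins, and optional multiple phosphosite endpoints per protein. With
noise `σ = 0.2` and planted 4-fold changes, the 2-fold rule recovers planted
endpoints at ≥ 99% with ≤ 1% false positives — the margins follow directly
from `P(|N(0, 0.2)| > log 2) ≈ 5·10⁻⁴`. What the generator does *not*
emulate: spatial array artifacts, antibody cross-reactivity, or correlated
biological co-regulation between endpoints. Passing tests on synthetic
panels therefore demonstrate the selection machinery, not the biology of any
real panel.

## Problem sizes

The published analysis used 100000-sample hypercubes with 10 realizations
for calibration and 10000 × 100 for validation. The package's defaults are
desk-scale — calibration 5000 × 3, validation 2000 × 5, `alpha = 0.1` —
chosen so a full pipeline completes in about a minute on one CPU while
leaving the Monte-Carlo margins of the directional checks comfortable; the
`--scale paper` preset of the command-line wrapper restores the published
sizes. All stages derive their RNG streams from a single seed and reruns are
bit-identical.

## Known limitations

* The exact equations and parameter values of the original study are in
  supplementary material not available to this implementation; the topology
  and functional forms here are reconstructed from the stated construction
  rules. Robustness outputs are therefore validated by direction and
  ordering properties (planted-parameter recovery, 4/4 calibration-direction
  separation, analytic MIRI oracles), not by reproducing specific MIRI
  magnitudes. The patient-specific validation directions (ERK/mTOR lower,
  AMPK higher in s-OS, KRAS higher in l-OS) and the s-OS > l-OS overall-
  robustness ordering are reported and logged as soft expectations.
* Two patients cannot support statistical claims; the pipeline is a
  template for cohort-scale stratification, as the original discussion
  notes.
* The model omits receptor trafficking, explicit phosphatase dynamics
  beyond the clamped nodes, ligand dynamics, and drug treatment.
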