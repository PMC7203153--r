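---
title: "Discovering PSA-binding peptides: models, parameters and validation"
author: "psapep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering PSA-binding peptides: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psapep)
```

## The problem

Polysialic acid (PSA) is a long, highly anionic homopolymer of
N-acetylneuraminic acid (Neu5Ac). Its α-2,8-linked form decorates neural
cell-adhesion molecules on neural stem and progenitor cells and appears
on some tumours and bacterial capsules, which makes selective PSA
ligands attractive for targeting and detection. Peptides are a practical
ligand class — small, synthesizable, easy to array — but
carbohydrate–peptide interactions are weak (mid-to-high micromolar) and
dominated by electrostatics, so a discovery campaign needs careful
statistics to separate genuine, selective binders from generic
polycation–polyanion attraction.

`psapep` implements the analysis backbone of such a campaign: design a
peptide library from a PSA-binding lectin (a Siglec), screen it on
microarrays against the polymer, quantify affinity in solution by
fluorescence anisotropy, test which residues drive binding, and map
residue-level contacts from structural ensembles. Every assay has a
synthetic counterpart with known ground truth, so each analysis stage is
validated by parameter recovery rather than by eyeballing.

## Library design

Epitope tiling slides a `window`-residue frame along the parent protein
in steps of `step` residues. The defaults (window 15, step 2) give
13-residue overlap between neighbours — fine enough that any linear
epitope of the parent appears intact in at least one peptide. A parent
of length $L$ yields $\lfloor (L - \mathrm{window})/\mathrm{step}
\rfloor + 1$ peptides; trailing fragments shorter than the window are
dropped rather than padded, because a fixed-length library contains no
shorter peptides. Protein-derived peptides are flagged N-terminally
acetylated: on the array the synthetic fragment should carry the charge
of the corresponding internal protein segment, which has no free
α-amino group.

Mutants record their edit as `"<orig><pos><new>"` (e.g. `E6R`) and the
constructor refuses silent mutations. Scrambles resample a Fisher–Yates
permutation (seeded, hence reproducible) until the order differs from
the parent. Repeat peptides build the infinite repeat of a unit,
started at a phase offset and truncated — the lysine/glycine series
(`KG`, `KGGG` at phases 0 and 2) used as highly basic de novo controls
comes out of this constructor directly.

## Charge, pI and composition

Two charge models are deliberately kept apart:

* **Integer mode** counts Arg/Lys as +1 and Asp/Glu as −1, His and the
  termini as 0, at any pH. This is the right bookkeeping for
  library-level charge analysis of arrayed peptides: coarse, assumption-
  free, and it reproduces the +8 of the 8-lysine repeat peptide.
* **Titration mode** sums Henderson–Hasselbalch fractional charges
  $\sum_{\mathrm{basic}} \frac{1}{1+10^{\,\mathrm{pH}-\mathrm{p}K_a}} -
  \sum_{\mathrm{acidic}} \frac{1}{1+10^{\,\mathrm{p}K_a-\mathrm{pH}}}$
  over a user-overridable pKa table (defaults: N-term 8.6, C-term 3.6,
  K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1, matching the
  widely used EMBOSS `iep` defaults).

Termini are excluded by default because protein-derived arrayed peptides
are N-acetylated and surface-attached; both options are exposed since
free-peptide calculations may legitimately include them.

The titration charge is strictly decreasing in pH, so the isoelectric
point is found by bisection on [0, 14]. Bisection runs on the pH
interval (to < 1e-7) rather than stopping when the charge is small: for
an acid/base pair with well-separated pKa values the curve is nearly
flat around the pI, and a charge-only stopping rule would return a pH
tens of millipH units off while satisfying the charge tolerance.
Sequences still positive at pH 14 report `">14"` (e.g. polylysine with
no acidic group), still negative at pH 0 report `"<0"`, and sequences
with no titratable group report `"undefined"`.

The residue-class scheme used for composition analysis is
acidic = D,E; basic = R,K; polar = H,C,N,Q,S,T; aromatic = Y,F,W;
nonpolar = G,A,V,I,L,M,P. Threonine is assigned to the polar class (its
standard classification) so the scheme partitions all 20 canonical
residues; schemes are a parameter, not a constant.

## Microarray screen statistics

Spots are printed in intra-assay replicate (typically triplicate) and
each screen repeats as independent assays (typically three). Aggregation
averages replicates within an assay first, then averages assay means, so
unbalanced replicate counts cannot bias the grand mean toward any one
assay. The quality filter is the inter-assay coefficient of variation —
sd of assay means over the grand mean — with the conventional 25%
retention threshold; all-zero peptides get an undefined CV and a
`zero_mean` reason code instead of a division by zero.

Top binders are the `floor(fraction × N)` retained peptides of highest
grand mean; N counts the whole library, so 5% of 762 peptides is exactly
38. Ties break lexicographically by id to keep the selection
deterministic and row-order invariant.

Percent selectivity under a competing glycan is the retained-binding
ratio `100 × competed_mean / uncompeted_mean`. Values above 100 are
allowed (competition occasionally enhances signal), and peptides whose
uncompeted signal sits at background are marked not evaluable rather
than given a meaningless ratio — selectivity of a non-binder is not a
defined quantity. The standard competitor dose for comparison across a
library is 10% of the target concentration, since equimolar isomeric
competitor suppresses nearly everything.

The high-selectivity subset applies an affinity-then-selectivity chain:
peptides in the bottom 20% of the intensity range are background,
a further band up to 30% of the range removes very weak binders, and
survivors need percent selectivity above 65. All three numbers are
parameters of `build_selectivity_subset()`.

Mass-equivalent dosing converts a polymer concentration to the monomer
concentration of equal mass,
`polymer_conc × DP × residue_mass / monomer_mass`; for a DP-100 polymer
with ~300 Da per polymerized residue versus free Neu5Ac (309.3 Da),
10 μM polymer ≈ 970 μM monomer. Cell-screen comparisons subtract a
paired no-cell control (flooring at zero, since autofluorescence cannot
contribute negative binding) and rank descending with average ranks for
ties; rank vectors from different cell numbers are compared with
Spearman's ρ because background and dynamic range differ between
conditions.

## Residue enrichment

Composition tests pool residue counts over all positions of all
sequences and compare subset against library proportions with the pooled
two-proportion z-test; the two-tailed p comes from the normal tail (the
test is identical to the 2×2 χ² without continuity correction, a fact
the test suite exploits as an oracle). The p-value is computed as
`2·pnorm(-|z|)` — algebraically the textbook `2(1−Φ(|z|))` but without
catastrophic cancellation in the far tail.

Rows whose subset count fails the `np ≥ 5` / `n(1−p) ≥ 5` rule are
reported with `testable = FALSE` and no p-value: for residues nearly
absent from a 38-peptide subset the normal approximation is indefensible
and reporting a p would overstate certainty. The guard is evaluated on
the subset (smaller) sample, where the approximation breaks first.

No multiple-testing correction is applied by default — per-residue raw
p-values are the convention in this kind of composition figure — but
`adjust = "BH"` switches on Benjamini–Hochberg for users who prefer
controlled FDR. Positional analysis aligns N-terminally over positions
1–15 and drops position 16 of the occasional 16-mer, keeping column
sums interpretable.

## Fluorescence anisotropy binding

Anisotropy $r = (I_\parallel - gI_\perp)/(I_\parallel + 2gI_\perp)$ is
used instead of polarization because it is additive in total intensity;
the instrument G factor defaults to 1 and is exposed. At high polymer
concentrations solution viscosity scatters light unequally in the two
planes, so ligand-only blank intensities measured at the same
concentrations are subtracted channel-wise (floored at zero) before the
anisotropy is formed; a point whose corrected total vanishes is marked
invalid rather than propagating a 0/0.

Binding curves are fit to the four-parameter logistic

$$y(c) = y_0 + \frac{B_\max}{1 + (K_D/c)^h},$$

chosen so that $y(0) = y_0$ and the inflection parameter *is* the
half-saturation concentration: at $c = K_D$ the response is exactly
$y_0 + B_\max/2$ for any slope $h$. With $h \approx 1$ this is the 1:1
binding isotherm. Curves are baseline-transformed (minimum subtracted)
only for comparability on plots — with a free $y_0$ the fit is invariant
to the shift, which the tests verify.

Fitting is bounded Levenberg–Marquardt least squares with multi-start
initialization: $y_0 = \min r$, $B_\max = \mathrm{range}(r)$, $h = 1$,
and $K_D$ started at geometric quantiles of the positive concentration
range (4 starts by default, best SSR wins). The multi-start matters
because weak binders near the polymer solubility limit (~1.5 mM) produce
shallow likelihoods with local minima at millimolar $K_D$. Standard
errors are asymptotic, from the parameter covariance at the optimum;
$R^2 = 1 - SS_{res}/SS_{tot}$. Concentrations are handled in μM
internally and $K_D$ is reported in mM, the customary scale for these
affinities. An all-flat curve (singular Jacobian at every start) returns
a degenerate constant fit with $B_\max = 0$ and `reliable = FALSE`
instead of an error.

A fit is flagged unreliable when $SE(K_D) > K_D$ or
$SE(B_\max) > B_\max$, with the boundary case kept (strict
inequalities). The ranking quantity for candidate selection is the
binding potential $B_\max/K_D$, which for $h = 1$ equals the initial
slope of the binding curve — response per unit target at low
concentration.

## Contact maps

A residue pair is in contact in a frame when the minimum distance over
all atom pairs is at most the cutoff, 3.0 Å by default — the
conventional polar-contact distance. Contacts are counted per frame as
booleans (a pair contributes at most once per frame, never per atom
pair), which gives raw counts bounded by the number of frames and a
natural [0, 1] scale after normalization. Normalization divides by the
global maximum raw count, so the hottest pair defines 1.0, matching a
0-to-1 colour ramp; per-row normalization is available for maps whose
rows have very different overall contact levels. All atoms participate
by default (hydrogens included when present); `heavy_only` restricts to
heavy atoms. The maximum-interaction frame is the frame with the most
contacting pairs, earliest frame on ties.

## The synthetic generators

Each generator emits data in exactly the dialect its analysis stage
reads, alongside the ground truth used to produce it.

* **Microarray** (`gen_microarray`): log-mean intensity is a logistic
  function of integer net charge plus optional per-peptide effects;
  assays carry multiplicative scale factors (shared across conditions
  within an assay); replicate noise is lognormal, parameterized by CV,
  because spot intensities are positive and their error scales with
  signal. Competed conditions multiply each peptide's mean by its
  retention fraction, so at zero noise percent selectivity returns the
  planted retention exactly.
* **Titrations** (`gen_titration`): channels are emitted as
  $I_\parallel = T(1+2r)/3$ and $I_\perp = T(1-r)/3$ plus blanks, so
  the corrected total intensity is conserved at $T$ and blank correction
  followed by the anisotropy formula inverts the construction exactly at
  zero noise. Channel noise with sd $= \mathrm{noise\_sd} \cdot B_\max
  \cdot T/\sqrt{2}$ perturbs the recovered anisotropy by
  ≈ noise_sd·B_max to first order. Each concentration is measured in
  triplicate by default, matching the assay practice of screening every
  sample at least in triplicate within a titration; the optional
  viscosity artifact adds concentration-dependent, channel-asymmetric
  blank signal that biases uncorrected anisotropies but is removed
  exactly by blank correction.
* **Frames** (`gen_frames`): two residue groups sit on parallel lines
  8 Å apart, so unscripted pairs are never within 6 Å; scripted events
  place a pair at 2 Å in designated frames. Infeasible scripts (one
  residue simultaneously near two others) are rejected up front.
* **Cell screens** (`gen_cell_screen`): tiles overlapping designated
  parent regions get elevated means under both cell numbers; the control
  vector carries reduced background only.

What the generators deliberately do **not** emulate: scanner point
spread and spot morphology, chemiluminescence kinetics, plate-position
effects, fluorophore photophysics, and any sequence-structure
relationship beyond the planted effects. Passing recovery tests
therefore demonstrates that the analysis correctly inverts its own
stated statistical model — not that real screens satisfy that model.

## The demonstration workflow

`run_demo()` wires all stages on a synthetic campaign sized like a real
one: a 671-residue synthetic parent tiled into 329 peptides, a
172-peptide modified arm (86 Lys point mutants, 86 scrambles), 38
de novo and 223 external peptides — 762 in total, so the 5% top set has
38 members. The 41 highest-charge peptides are planted as strong binders
with high competitor retention (0.95 versus 0.30 elsewhere); the first
38 of them are the designated top set. Because the planted intensity
effect dominates the charge term, the zero-noise demo recovers the top
set exactly and the selectivity chain returns exactly the 41 planted
peptides, and these recoveries degrade gracefully as noise is turned
up. The demo also fits three titrations spanning strong to weak
affinity, maps a scripted 3-frame trajectory, and ranks a 59-tile cell
screen with two planted binding-site regions against two cell numbers.

Problem sizes used by the test suite were chosen to exercise each
statistic at realistic scale while keeping a full run near half a
minute: the 762-peptide demo library, 100-curve Monte-Carlo recovery
per affinity (plus a 200-curve sweep across K_D 100–1200 μM), 200
random 2×2 tables against the χ² oracle, and 50 random frames against
the brute-force contact oracle.

Configuration is a YAML document with a versioned schema
(`psapep-config/1`); unknown keys are an error so that a typo in a
threshold name cannot silently run with defaults.

## Numerical choices and degenerate inputs

* pI bisection converges on the pH interval (< 1e-7) and checks the
  residual charge afterwards; sentinels cover curves with no zero
  crossing.
* Top-fraction, top-residue and rank ties break by id/index order —
  every selection is deterministic and permutation-invariant.
* Zero grand means flag `zero_mean` (CV undefined); zero-variance
  vectors flag correlation as undefined rather than returning NaN.
* The z-test refuses pooled proportions of exactly 0 or 1
  (`degenerate = TRUE`).
* Blank correction floors at zero; a corrected total of zero invalidates
  the point.
* `fit_4pl` warns on under-determined designs (< 5 valid points or < 2
  decades of concentration) and degrades to a flagged constant fit when
  no start converges.
* All generator seeds are explicit; sub-seeds derived from a master seed
  stay below 2³¹.

## Known limitations

* The integer charge model ignores His; peptides whose binding is
  pH-sensitive through His protonation need titration-mode analysis at
  the relevant pH.
* Asymptotic standard errors understate uncertainty for weak binders
  whose $K_D$ approaches the highest measured concentration; the
  reliability flag catches the worst cases but profile-likelihood
  intervals would be more faithful there.
* Percent selectivity is a ratio of means; its error is not propagated,
  so downstream thresholds (65%, 80%) should be read as operational
  cuts, not significance statements.
* Contact maps treat frames as exchangeable snapshots; no
  autocorrelation correction is applied, so normalized frequencies from
  short, correlated trajectories overstate effective sampling.
* The enrichment module tests marginal residue proportions;
  position-position dependencies (motifs) are out of scope.
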