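---
title: "Modeling formamide denaturation of microarray probe/target duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling formamide denaturation of microarray probe/target duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formamelt)
```

## The problem

Diagnostic microarrays for microbial ecology carry thousands of short (18–26
nt) DNA probes against a phylogenetic marker, typically the 16S rRNA gene.
A probe is useful only if it captures its intended target efficiently
(sensitivity) while staying dim against closely related non-targets that
differ by one or a few mismatches (specificity). Stringency can be tuned
chemically by adding formamide to the hybridization buffer: as the
concentration rises, probe/target duplexes denature and the signal falls
sigmoidally, with mismatched duplexes melting earlier than perfect matches.
`formamelt` implements a predictive model of this melting behavior so that
probes and a single working formamide concentration can be chosen *in
silico* rather than by testing every probe experimentally.

## The model

Hybridization at a probe feature is treated as a two-state local equilibrium
P + T = PT with the target as the limiting species. The hybridization
efficiency — the fraction of locally available target bound by the probe —
is a logistic in the duplex free energy:

$$E([\mathrm{FA}]) = \frac{\{P\}_o K}{1 + \{P\}_o K},\qquad
K = \exp\!\left(-\frac{\Delta G^\circ + m\,[\mathrm{FA}]}{RT}\right)$$

where $\Delta G^\circ$ is the duplex standard free energy without formamide,
$m$ (kcal/mol per % v/v) is the linear free-energy cost of the denaturant,
$\{P\}_o$ is an effective probe concentration absorbing activity
coefficients, $R = 0.00199$ kcal/(mol·K), and $T = 315.15$ K (hybridization
at 42 °C). The melting point — the formamide concentration at which
efficiency falls to half its 0% value — has the closed form

$$[\mathrm{FA}]_{1/2} = \frac{RT}{m}\,
\ln\!\big(2 + \{P\}_o e^{-\Delta G^\circ / RT}\big),$$

which is strictly positive; the clamp at zero in `melting_point()` is
therefore never active but kept for safety. Because the initiation penalty
and the effective probe concentration enter only through the product
$e^{-\Delta G^\circ_{ini}/RT}\{P\}_o$, they are not separately identifiable;
the package fixes $\Delta G^\circ_{ini} = 1.96$ kcal/mol and back-computes
$\{P\}_o = 9.946\times 10^{-3}$ M from the calibrated product
$4.37\times10^{-4}$, so `log10({P}o)` is $-2.00$.

## Free-energy rules

Duplex free energies come from a microarray-specific nearest-neighbor rule
system:

* **Perfect matches** — sum of the $L-1$ stack free energies plus the
  initiation penalty (`dg_perfect()`). Sixteen probe-side dinucleotides
  collapse to 10 stack classes under strand reversal.
* **Single mismatches** — $\Delta\Delta G^\circ$ = loop term of the mismatch
  triplet (closing pair, mismatch, closing pair; 104 classes under strand
  reversal) minus the two replaced reference stacks (`ddg_single_mismatch()`,
  mode `M5_table`). A linear map from solution loop values
  ($\alpha = 0.354$, $\beta = 0.487$) is available as mode `M4_linear`.
* **Bulged mismatches** — the loop is the solution bulge-loop value scaled by
  the calibrated slope $\alpha = 0.238$; a deletion (target bulge) replaces
  two reference stacks, an insertion (probe bulge) one (`ddg_bulge()`).
* **Tandem mismatches** — the quadruplet is split into two halves, each
  scored by closing-pair class (AT/GC) and mismatch class (GG, GA, GT,
  other); the two of the eight rule scores add up to the loop, and three
  reference stacks are replaced (`ddg_tandem()`, mode `M9_rules`).
* **Two separated mismatches** — their $\Delta\Delta G^\circ$ values add.

The reference ("perfect") duplex for every loss term is the Watson–Crick
duplex of the *target site*; for substitution probes this is the unmodified
parent probe, and it makes deletions lose two stacks and insertions one, as
the accounting above requires. All loss terms are computed on the canonical
(lexicographically smaller) strand reading of the context, which makes every
$\Delta\Delta G^\circ$ exactly invariant under strand reversal — the same
symmetry that produces the 10/104 class counts.

### Relaxed ends

A mismatch near a probe terminus can cost more as an internal loop than the
few clamping terminal base pairs recover. `minimize_conformation()`
therefore enumerates, besides the imposed duplex, every relaxation that
unpairs all bases from a mismatch to either terminus (and the combinations
relaxing opposite ends for two-mismatch probes) and returns the most
negative state. This reproduces the characteristic flattening of mismatch
discrimination within roughly three positions of the ends. For a mismatch at
the outermost position no flanked triplet exists; the imposed conformation
is then scored by the extended rules below and flagged, and relaxation
normally prevails.

### Extended rules

Conformations not covered by the derived tables (three or more adjacent
mismatches, multi-base bulges, terminal mismatches in the imposed state)
receive the least-destabilizing covered analog sharing the closing pairs,
scaled by the number of non-Watson–Crick events, and the result carries an
`extended` flag. This is deliberately conservative for specificity claims:
it can only overestimate how well a non-target binds, never excuse it. A
side effect is that a flagged terminal mismatch may appear marginally
*stabilizing* when the most stable analog loop is negative; since such
states are flagged and relaxation usually wins, we accept this rather than
invent an uncalibrated penalty.

## Shipped parameter set

The global constants above are the published calibration of the model. The
per-context tables (10 stacks, 104 single-mismatch loops, 64 solution bulge
loops, 8 tandem scores) shipped in
`inst/extdata/ma_params_synthetic.txt` are **synthetic**: the original
per-context calibration values are not redistributable here, so the tables
are generated deterministically
(`synthetic_params()`) to sit on the reported scales — array stacks about
one third of the solution scale (≈1 kcal/mol weaker per stack in magnitude),
mismatch loops on the solution scale with GC closing pairs and G·G/G·A/G·T
mismatches more stable, solution bulge loops near +3 kcal/mol. Every
structural property (class counts, reversal symmetry, sign conventions) is
exact; individual numerical values are stand-ins, and analyses that depend
on a specific triplet's value should load a user-supplied parameter file via
`read_params()`. With the synthetic set, a typical 22-mer melts at 20–30%
formamide and single mismatches shift the melting point by roughly 2–10
points, matching the experimentally observed ranges.

The bulge table stores all 64 written forms (both strand readings, equal
values) rather than the 40 fully canonical classes, preserving the
conventional 4 × 16 count; the validator enforces the equality.

## Calibration machinery

Experimental profiles are preprocessed exactly as the study prescribes:

1. a replicate more than three standard deviations (of the remaining
   replicates) from their mean is eliminated (`outlier_filter()`);
2. the mean of the nonsense-control probes is subtracted as background, with
   standard deviations combined in quadrature (`preprocess_intensities()`);
3. probes with $I_{max} < 1000$ a.u. (perfect match) or $< 500$ a.u.
   (mismatched), and mismatched probes losing more than half their signal
   between 0% and 5% formamide, are discarded (`filter_probes()`);
4. points left of the profile maximum and below 80% of it are masked as
   kinetically limited (`trim_left_of_plateau()`).

Normalized profiles $I/I_{max}$ are matched to theoretical curves through a
per-probe proportionality factor $\gamma$ ($I/I_{max} = \gamma E$).
`bilevel_fit()` runs a derivative-free Nelder–Mead least squares over the
global parameters (start $m = 0.2$, $\log_{10}\{P\}_o = -2$, relative
tolerance $10^{-8}$, at most 500 iterations per parameter) while each
$\gamma$ is solved in closed form, $\gamma = \sum E y / \sum E^2$, at every
outer iterate — fast, exact, and deterministic. Alternative $\gamma$
policies ($\gamma \equiv 1$; $\gamma = 1/E(0)$) are available through
`gamma_factor()`; none of them moves the melting point, which is the
quantity the model is asked to predict. Goodness of fit is reported as the
coefficient of determination $R^2$, the per-point residual mean
$\sum r^2/n$, and the error-squares statistic $s^2 = \sum r^2/\nu$ with
$\nu = n - (\text{probes} + \text{globals})$, which penalizes the per-probe
$\gamma$ count. Prediction quality is summarized by
$\mathrm{err}[\mathrm{FA}]_{1/2}$, the signed distance between the
closed-form melting point and the experimental half-denaturation point
interpolated between the two bracketing profile points (`fa_half_exp()`).
An optional seeded random probe split reports validation-set prediction
error ($\epsilon^2_{val}$); the seed is recorded in the result.

## Synthetic data

`synth_generate()` emulates the experimental design so the whole pipeline is
testable offline: a random 1542-nt gene, 22-mer tiles between positions 50
and 1450, and per-probe profiles over the 8-point formamide series (0, 5,
10, 15, 20, 25, 32.5, 45% v/v) built as brightness × efficiency with

* per-probe brightness log-uniform between 500 and 40,000 a.u., modulated by
  a smooth positional field emulating amplification/labeling bias;
* homoscedastic Gaussian noise of SD 0.078 on the normalized scale (the
  pooled experimental variance of 0.0061);
* three replicates with a 1% chance of an injected outlier replicate;
* soft scanner saturation above 40,000 a.u. capped at the 65,536 pixel
  ceiling (a 10× `concentration_factor` reproduces the saturated
  concentrated-target regime);
* a constant 50 a.u. background with replicated nonsense-control rows.

The generator does **not** emulate the kinetic signal rise at low formamide
(which the preprocessing masks out on real data), sequence-dependent
labeling chemistry, fragment-length effects beyond the recorded 25–150 nt
(mean 65) distribution, or cross-hybridization between features. Passing the
recovery tests therefore demonstrates that the calibration machinery is
correct and well-conditioned under the stated noise model, not that the
synthetic tables equal the original calibration.

The recovery tests use 300 tiled probes (about 280 surviving the intensity
filters), which conditions the two global parameters well while keeping the
whole suite under a minute; with that design the bi-level fit recovers $m$
to within ±0.01 and $\log_{10}\{P\}_o$ to within ±0.1, and over 90% of
probes show $|\mathrm{err}[\mathrm{FA}]_{1/2}| < 5$% formamide against
their own noisy profiles.

## Probe design workflow

The design loop (`design_probes()`) follows the recommended practice:

1. tile candidates at every site and choose the length (18–26 nt) whose
   predicted melting point lands in a narrow window, by default 18–22%
   formamide (`select_by_melting_window()`);
2. hybridize about 5 points below the window (default working concentration
   15%);
3. score each candidate's specificity as the predicted efficiency against
   the best alignable site of every non-target
   (`conformation_from_pair()` + `specificity_score()`); probes with all
   non-target efficiencies below 0.05 are flagged specific;
4. call an OTU present only when nearly all of its panel probes are bright
   (default 9 of 10, `otu_call()`).

Mapping predicted efficiency to absolute fluorescence is probe-specific
(brightness varies ~100-fold at constant efficiency), so the 1750-unit
brightness threshold used in experimental simulations is exposed only
through the synthetic generator's brightness factors, not as a model output.

## Numerical choices and edge cases

* Efficiency is computed on the log scale (`plogis`) so very stable
  duplexes stay finite; values are strictly inside (0, 1).
* The alignment in `conformation_from_pair()` scores match +1, mismatch −1,
  gap −1.5/−1, and declares "no site" below half the probe length in score —
  at that depth of divergence the predicted efficiency is negligible anyway;
  a no-site result is treated as zero efficiency.
* Ties in conformation minimization resolve toward the imposed (least
  relaxed) state.
* Probe names use an ASCII hyphen; the parser also accepts the typographic
  en-dash.
* Deletion probes are 21-mers (the deleted probe base leaves the
  complementary target base bulged); the conventional set size bookkeeping
  (62 probes × 4 positions = 248) is unaffected.
* The probe subset used by the position/gap/insertion/two-mismatch/tandem
  constructors is configurable; by default an evenly spaced 62-probe sample
  is used, since only the subset's size, not its identity, is conventional.

## Limitations

The model is calibrated for one platform chemistry (42 °C, 1 M Na+,
fragmented DNA targets); the effective probe concentration, and possibly the
stack table, must be re-fitted for other configurations. Kinetic effects at
low formamide are masked, not modeled. Solution-parameter model variants
that require external dangling-end free energies are out of scope, as are
RNA/DNA duplexes and the recomputation of in-solution parameters.
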