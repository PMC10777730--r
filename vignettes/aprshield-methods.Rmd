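---
title: "Methods: APR shielding analysis for coarse-grained protein–excipient systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: APR shielding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aprshield)
```

# The problem

Therapeutic proteins aggregate, and aggregation typically nucleates at
aggregation-prone regions (APRs): short, contiguous, hydrophobic stretches
of sequence. Formulation excipients — polysorbates, fatty alcohol
ethoxylates, phospholipids, amino acids — can suppress aggregation by
adsorbing onto the protein surface and shielding those regions from
solvent. In a coarse-grained molecular dynamics screen this shielding is
quantified as the reduction of the solvent-accessible surface area (SASA)
of the APRs relative to an excipient-free control, and the per-excipient
shielding values can then be related to molecular structure through a
latent-variable regression on physicochemical descriptors.

`aprshield` implements the full post-simulation side of such a screen:

1. **APR detection** from sequence (`compute_profile()`, `detect_aprs()`);
2. **SASA** of coarse-grained bead configurations and trajectories,
   total and APR-restricted (`shrake_rupley()`, `trajectory_sasa()`),
   and the shielding statistic (`shielding()`);
3. **statistical comparison** of excipient systems against the control
   (`compare_all()`: Bartlett gate, Kruskal–Wallis or Welch omnibus,
   Dunn post-hoc);
4. **structure–property modelling** by PLS with leave-one-out component
   selection, repeated-split Q² validation and VIP scores
   (`fit_pls()`, `loo_select()`, `repeated_split()`, `vip()`);
5. a **synthetic-data module** standing in for the MD engine
   (`make_protein()`, `simulate_adsorption()`, `make_qspr()`).

Running the MD itself (force-field parametrization, solvation,
thermostats, production runs) is out of scope: trajectories are consumed,
never produced.

# APR detection

The detector is the classic sliding-window hot-spot rule. Every residue
gets a raw aggregation propensity from an experimentally derived
20-residue scale (shipped as an editable table,
`inst/extdata/a3v_scale.tsv`, and treated as data). The windowed profile
averages the raw values over a window centred on each position; a patch is
a maximal run of at least `min_patch_length = 5` positions whose windowed
value exceeds the hot-spot threshold `-0.02`, with proline positions
ineligible (prolines break runs). These defaults are the published rule of
the reference web method; all are overridable.

Choices worth knowing about:

* **Window size** follows the length-dependent schedule 5/7/9/11
  (≤ 75, ≤ 175, ≤ 300, > 300 residues) under `window = "auto"`.
  For a long sequence such as the 585-residue serum albumin this gives
  11, which is the default behaviour.
* **Edges**: positions without a full window have no profile value and can
  never start a patch. `truncated = TRUE` switches to clipped-window
  averaging when edge coverage matters.
* **Coordinates** are 1-based inclusive everywhere in reports; 0-based
  conversion happens only inside the bead-mapping helper.

# Coarse-grained SASA

`shrake_rupley()` is a dot-sampling implementation: each bead's sphere is
expanded by the probe radius (default 0.14 nm) and covered with a
deterministic golden-spiral lattice of `n_dots = 960` points; a dot is
exposed iff it lies strictly outside every other occluder's expanded
sphere (a dot exactly on a boundary counts as exposed — the documented
tie rule). The exposed area of bead *i* is
$A_i = 4\pi (r_i + r_p)^2 \, n_\mathrm{exposed} / n_\mathrm{dots}$.

* **Radii.** The default bead radius is 0.235 nm, half the standard
  0.47 nm coarse-grained bead diameter. The GROMACS `gmx sasa` radius
  table is *not* reproduced, so absolute areas are comparable across
  systems analysed with this package but need not match `gmx sasa`
  bit-for-bit. Per-residue-name overrides are available via a radii
  table in the readers.
* **Who is surface, who occludes.** Protein beads carry area. Excipient
  beads occlude but carry no area — that asymmetry is exactly what makes
  the control-minus-treated APR SASA difference a shielding measure.
  Solvent and ion beads are ignored on both sides (SASA is defined
  against the probe, not the explicit solvent); `include_solvent = TRUE`
  restores them as occluders, and `occluders = "protein"` gives the
  protein-only alternative.
* **Periodicity.** No periodic-boundary imaging is performed; frames are
  assumed whole. `check_whole_molecule()` flags the common symptom of an
  un-imaged trajectory (protein spanning the box).
* **Replicates.** `shielding()` aggregates by per-replicate trajectory
  means (five replicates per system in the emulated design), not pooled
  frames, to avoid frame-level pseudoreplication; `pooled = TRUE` exists
  for exploration.

Accuracy: at 960 dots the two-sphere configuration agrees with the
spherical-cap closed form to better than 0.1%; the dot lattice is
deterministic, so results are bit-reproducible.

# Statistical comparison

The gate-and-branch procedure is the standard one for this kind of screen:
Bartlett's test across all groups decides, at `alpha_gate = 0.05`, between
the Kruskal–Wallis rank ANOVA (homoscedastic branch) and Welch's
heteroscedastic ANOVA; Dunn's test on pooled midranks provides the
pairwise post-hoc in either branch (Dunn is used after both branches by
design; Games–Howell is not offered). Defaults report raw p values
(`adjust = "none"`), with any `p.adjust` method available; significance is
starred at 0.05 and 0.01.

Conventions for degenerate input: identical pooled values give H = 0,
p = 1 (documented convention); a zero-variance group is an error for
Bartlett and Welch, pointing at the issue rather than silently branching.
An exact permutation p for Kruskal–Wallis is available for total n ≤ 10
(complete enumeration of group assignments).

With five replicates per system these tests are weakly powered; the
package runs them on per-replicate means by design, and per-frame input
is possible but is pseudoreplication and flagged as such in the
documentation.

# PLS structure–property model

`fit_pls()` is single-response NIPALS: per component the weight vector is
the normalized covariance direction $w = X'y/\lVert X'y\rVert$, scores
$t = Xw$, followed by least-squares deflation of $X$ and $y$. Both $X$
and $y$ are autoscaled (centre, unit variance) — the standard choice for
heterogeneous physicochemical descriptors. Coefficients are back-transformed to the
original scale. For one response each component converges in a single
pass, so no iteration tolerance is ever active.

* **Component selection** (`loo_select()`): leave-one-out with a full
  refit (re-scaling included) inside every fold; RMSEP(k) is the root
  mean held-out squared error; the chosen k is the smallest within 2%
  relative RMSEP of the global minimum — the parsimony rule, made
  concrete.
* **MREP** is `mean(|ŷ − y| / y)` over LOO folds (zeros in y are an
  error); `mrep_mode = "ratio_of_means"` gives the alternative
  `mean(|ŷ − y|)/mean(y)`.
* **Robustness** (`repeated_split()`): 1000 random 0.8/0.2 partitions by
  default; LOO on each training set re-selects k; Q² on the test set uses
  the *training-set mean* in the denominator (stated convention; the
  trivial mean predictor scores exactly 0). Medians over repetitions are
  reported. Each repetition draws from a deterministic substream of the
  master seed, so results are bitwise reproducible; degenerate partitions
  (constant training response) are resampled and counted.
* **VIP**: $\mathrm{VIP}_j = \sqrt{p \sum_a SSY_a w_{ja}^2 / \sum_a
  SSY_a}$ with $SSY_a = q_a^2\, t_a't_a$; squared scores sum to p exactly.
* The descriptor keep-list is a user-supplied file (curating a
  descriptor set "by chemical intuition" is not an algorithm, so it is
  treated as data); constant columns are dropped before scaling.

Published screens of this kind sometimes report ambiguous component
counts (two vs four); any k up to the rank is runnable here
(`fit_pls(X, y, k)`), and the selection machinery always reports the full
RMSEP-by-k curve so such ambiguity is at least visible.

# The synthetic world

The generators replace microsecond MD with the cheapest objects that
still exercise every analysis contract.

**Trajectories.** `make_protein()` places beads on a jittered sphere
lattice sized so neighbouring beads touch, with consecutive residues
adjacent, so the evenly spaced contiguous APR patches are also spatial
patches. `simulate_adsorption()` draws every frame independently: each
excipient molecule comes from a mixture of a uniform bulk component and a
surface component with weight $s/(s+2)$ in the adsorption strength $s$;
surface molecules anchor on a protein bead chosen with weight $1 + s$ for
APR beads and lay their remaining beads along neighbouring lattice sites
(long chains wrap, short ones cluster — bead counts are the only polymer
physics). Protein beads receive a small per-frame thermal jitter
(0.01 nm), so SASA has realistic non-degenerate variance even in the
excipient-free control; the conformation itself never changes. Defaults:
60 one-bead residues, 25% APR coverage, 20 three-bead excipient molecules
in a 12 nm box, 20 frames, 5 replicates.

Because frames are independent equilibrium draws, temporal correlation,
diffusion, micellization and real binding thermodynamics are *not*
emulated: a green test establishes that the analysis pipeline measures
imposed shielding correctly and ranks known strengths, not that any
force field would produce such shielding. A calibration run (fixed before
the tests were written) established that strength 50 shields ≥ 20% of the
control APR SASA and that strengths {0, 5, 50} give strictly increasing
shielding.

**Descriptor tables.** `make_qspr()` builds $X = TP' + E$, $y =
\mathrm{offset} + Tc + e$ with orthonormal factor scores. The loading
structure is two-tier: factor 1 is a *bulk* factor carried by all 96
background descriptors (noise multiplier 0.35 of their signal sd) — the
analogue of molecular size, which most physicochemical descriptors track —
while the specific factor(s) are carried only by the 10 informative
descriptors (noise 0.1), the analogue of a feature like PEG content. The
response weights the specific factor more (`c = (2, 3)`).

This design was chosen deliberately over the naive "informative + pure
noise" background: PLS autoscales every column, so 96 pure-noise columns
would be inflated to unit variance and swamp the weight vectors at
n = 41 — the latent rank then cannot be recovered by any method at these
sizes. With the two-tier world, a single pre-registered 100-seed
validation run gave the chosen component count equal to the true rank in
88/100 runs (requirement ≥ 80) and all informative descriptors inside the
VIP top decile in 100/100 runs (requirement ≥ 95).

# Numerical conventions and edge cases

* SASA tie rule: boundary dots are exposed; occlusion uses strict
  inequality on squared distances.
* `detect_aprs()` uses strict `>` against the threshold.
* Kruskal–Wallis and Dunn use midranks with the standard tie corrections.
* Parsimony tolerance for component selection: 2% relative RMSEP.
* All generators are pure functions of their spec, including the seed;
  per-replicate and per-repetition seeds are derived substreams kept
  below 2³¹.
* JSON/CSV round-trips preserve patch coordinates, series metadata and
  model parameters; GRO output encodes molecule tags in residue names so
  a round trip preserves the classification.

# Known limitations

* Absolute SASA values depend on the bead-radius convention; only
  radius-consistent comparisons (e.g. shielding deltas) are meaningful
  across tools.
* No binary trajectory formats: multi-frame GRO (or lists of frames) is
  the trajectory interface. Convert upstream with standard tools.
* Headline numbers of published screens (absolute control APR SASA, a
  specific excipient's shielding delta, deposited-data QSPR statistics)
  derive from microsecond coarse-grained simulations and deposited
  tables; they are not recomputable at desk scale and are therefore not
  asserted by the test suite — the suite instead proves the machinery on
  closed forms, independent oracles and the synthetic world above.
* With n = 5 replicates per group, Bartlett and Dunn are weakly powered;
  published significance patterns at that design size are fragile by
  nature.
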