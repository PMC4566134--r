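---
title: "SIRAS phasing of serial-crystallography snapshots: models and design choices"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, what the synthetic data does and
does not emulate, and the places where the design was genuinely open and
a choice had to be made.

## 1. The measurement model

A serial femtosecond crystallography (SFX) experiment records one still
snapshot per crystal. After indexing, each snapshot contributes partial
intensities for a random subset of reflections. The generator
(`simulate_patterns`) models an observation of reflection $h$ on pattern
$j$ as

$$ I_{obs} = g_j \, p \, T_{e\!f\!f} \, |F(h)|^2 + \varepsilon, \qquad
   \varepsilon \sim N\!\big(0,\ \sqrt{\max(\text{signal},0) + b}\big) $$

* $g_j$ — per-pattern scale, log-normal with `scale_sdlog` (default 0.4,
  mean fixed at 1). Captures beam-intensity and crystal-size variation.
* $p$ — partiality, i.i.d. uniform on `[p_min, 1]` (default
  `p_min = 0.1`). This is deliberately *not* a geometric Ewald-offset
  model: the analysis treats partiality purely as multiplicative noise
  that Monte-Carlo averaging defeats as $1/\sqrt{N}$, and an i.i.d. law
  reproduces exactly that convergence. The law is pluggable; no
  partiality distribution for real crystals of this kind is available,
  so the default is a stand-in.
* $T_{e\!f\!f}$ — low-angle absorber transmittance (0.3636) applied to
  reflections with $d \ge 3.8$ Å when configured, mirroring an aluminium
  absorber protecting the detector from strong low-angle spots. The
  correction (`absorber_correct`) divides intensity and sigma by $T$
  with no angular dependence, and is not idempotent.
* $b$ — background variance floor (default 25), plus a counting term.
* a `weak_fraction` of snapshots is scaled down by `weak_scale` to give
  the intensity-based preselection (`preselect_patterns`, keep iff the
  low-resolution maximum *exceeds* the threshold) something to reject.

Which reflections appear on a pattern is a Bernoulli draw per reflection
(`observed_fraction`, default 0.3), with Friedel mates as distinct
observables. This preserves the multiplicity bookkeeping — the quantity
the experiments report — without simulating diffraction geometry.
Negative observed intensities are retained; their treatment (truncation
at the amplitude stage) is a merging decision, not a simulation one.

## 2. The toy crystal

`make_toy_structure` builds an orthorhombic P2~1~2~1~2~1~ cell
(30 × 40 × 50 Å, d~min~ 2.5 Å) containing 40 light point scatterers and
one Hg-like heavy site (f0 = 80 e, f′ = −10 e, f″ = 9.75 e, occupancy
0.7, the anomalous terms being the tabulated Hg values at 12.6 keV; f′
is not critical and −10 e is a nominal near-edge value). Scattering
factors are constant per atom — no Cromer–Mann s-dependence — with
isotropic B damping; at toy resolution the s-dependence is cosmetic and
a constant f0 keeps the brute-force oracle trivial and the f″/f0 ratio
explicit.

The light scatterers default to **f0 = 30 e, i.e. residue-scale lumped
clusters rather than single carbons**. This is the one genuinely
load-bearing generator choice: with 40 sites the heavy-to-protein
scattering ratio then matches that of a ~300-residue protein with one
Hg (|F_H| ≪ |F_P|, R_iso ≈ 0.15–0.2, Bijvoet ratio a few percent).
With carbon-scale scatterers the single Hg would rival the entire
"protein", mean-matching derivative scaling would be invalid, and the
iso ≫ ano signal hierarchy that the whole SIRAS-vs-SAD comparison rests
on would be destroyed. Atom placement uses uniform draws with a
minimum-separation rejection rule over all symmetry copies.

What the generator does **not** emulate — detector geometry, profile
integration, indexing ambiguity, non-isomorphism between native and
derivative crystals, radiation chemistry — bounds what passing tests
mean: they validate the statistical machinery of merging and phasing,
not the upstream data-reduction stack, and a real experiment's
non-isomorphism would push all pattern requirements upward.

## 3. Merging and quality metrics

Merging is a plain arithmetic mean per symmetry-reduced reflection and
Friedel branch — the Monte-Carlo approach; per-pattern scale or
partiality post-refinement is explicitly out of scope. The merged sigma
is the sample sd/√n (a lone observation keeps its own sigma). Random
halving for R_split/CC_1/2/CC_ano is by pattern, seeded, odd counts to
half A. Shells are equal-volume in 1/d³. Rates are rounded half away
from zero to integer percent.

`cc_anoref` correlates observed `I(+) − I(−)` against model-calculated
differences on the **intensity** scale (|F⁺|² − |F⁻|²). The
amplitude-scale alternative differs only by a smooth positive weight and
changes none of the qualitative behaviour; intensity scale avoids the
truncation noise of amplitude conversion at weak reflections. Because
`cc_anoref` does not halve the data it resolves weak anomalous signal at
far lower multiplicity than the half-set `cc_ano` — the package's
experiments reproduce that gap.

For the multiplicity bookkeeping both conventions are reported
(Friedel-separate and Friedel-merged), since published tables differ on
which one "SFX multiplicity" means.

## 4. Substructure location

The derivative is scaled to the native by a shell-wise straight-line fit
of log⟨|F_P|⟩/⟨|F_PH|⟩ against s², giving a global scale and relative B.
Amplitudes come from √max(I,0) with truncation counted — French–Wilson
would be better calibrated at weak intensities but at simulated
multiplicities truncation is rare, and the count makes the approximation
observable.

Difference Pattersons use ΔF_iso² (isomorphous) and an
intensity-normalized (ΔI_ano/⟨I⟩)² (anomalous) as coefficients. One
subtlety is worth recording: **the Patterson carries the symmetry of the
Laue group**, so coefficients are expanded over the rotation parts of
the operators only. Expanding with the screw translations' phase
factors — correct for densities — plants exact parity artifacts at
(½,½,0)-type special points that dwarf the genuine Harker peaks and
systematically promote the origin as a candidate site.

Sites are scored by the symmetry-minimum function: the minimum of the
interpolated (trilinear) Patterson value over all Harker self-vectors
and over all supplied maps. The minimum (not the sum) is robust to one
contaminated section; self-vectors falling within the origin-exclusion
radius (0.1 × the shortest cell edge) are masked so that special
positions cannot score on the origin peak. The coarse scan (step 1/48
over the [0,½)³ quotient left by the allowed origin shifts) is followed
by a local fine scan (step/5) around each clustered candidate, which
removes the ~half-Angstrom grid quantization. Every candidate is
reported with its enantiomorph mate; the hand is genuinely undecidable
from a Patterson.

## 5. Blow–Crick phasing

For each reflection the phase probability is evaluated on a uniform
5°-grid (centric reflections only at their two allowed phases, which for
this space group are multiples of 90°). The lack-of-closure widths
E_iso/E_ano are per-shell: initialized at the RMS isomorphous/Bijvoet
difference, then refined twice by phase-and-remeasure, floored at 5% of
the initial value. SAD uses the sine-rule parameterization
Δ_calc(φ_T) = −2|F_H″| sin(φ_T − φ_H) on the derivative total phase —
adequate for the qualitative SAD-vs-SIRAS comparison; a full amplitude
marginalization would be needed for quantitative SAD work.

**Hand discrimination** needs one precaution: when comparing the two
enantiomorphs, E_ano must *not* be refit from the residuals — a refitted
E_ano simply inflates to absorb the wrong hand's anomalous
inconsistency, and both hands then look equally good. Inside the
both-hands comparison E_ano therefore stays at its data-derived initial
value (hand-independent by construction), and the verdict is taken from
the solvent-flattening map contrast with mean FOM as tiebreaker. On the
default toy this separates the hands decisively (contrast ~11 vs ~3.5).

## 6. Density modification

Solvent flattening (default 20 cycles; the titration experiments use 10,
which is past the point of diminishing returns on this toy) iterates:
FOM-weighted synthesis → Gaussian smoothing (6 Å) → solvent mask as the
lowest `solvent_fraction` of grid points (default 0.44, the protein-like
solvent content carried by the toy's configuration) → flatten solvent to
its mean and **clamp protein-region density below the solvent level**
(positivity; point-atom toys are strictly nonnegative, and this clamp is
what breaks the SIR phase ambiguity) → back-transform → recombine with
the *cycle-0* Blow–Crick prior through a von-Mises likelihood centred on
the modified phase with concentration κ = 2|F_o||F_mod|/⟨(|F_o|−|F_mod|)²⟩
per shell, capped at 30. A divergence guard stops the loop and returns
the best state if the mean FOM drops by more than 0.2 in one cycle; that
outcome is flagged separately from failure-by-CC.

Maps are scored against the ground-truth F_c synthesis with the
correlation maximized over the 8 allowed origin shifts and both hands
(grid dimensions are forced even so half-cell shifts are exact index
rotations); the phase error is amplitude-weighted and computed under the
same optimal transform. Success is CC > 0.65 — the same rule the
experiments' titration grids use.

## 7. Experiment design and problem sizes

The titration subsamples *nested* pattern sets ("the first N
snapshots"), so larger grid points reuse all patterns of smaller ones —
a variance-reduction choice that makes the success boundary monotone in
expectation rather than seed-jittered. The default experiment scale —
1600 simulated patterns per crystal form, a 5×5 grid up to 400+400,
resolution cutoffs 2.5–6 Å, signal curves to 1600 patterns — keeps the
full workflow and the acceptance script each inside a few minutes on one
CPU while leaving the success boundary (SIRAS ≈ 100 total patterns)
well inside the grid. Titration cells phase with the true site by
default to isolate phasing behaviour from site-search behaviour; the
drivers run the located site where site quality is itself the question.

## 8. Known limitations

* Orthorhombic cells and two space groups only; the cell type carries
  angles so a general metric tensor is a non-breaking extension.
* Constant-f0 scattering, no bulk solvent, no Cromer–Mann curves.
* SAD mode's sine-rule approximation and the absence of phase-error
  weighting in the anomalous difference Fourier.
* No auto-tracing or refinement: production phasing programs interleave
  density modification with model tracing; here plain flattening cycles
  stand in, so iteration counts are not comparable with
  tracing-interleaved protocols.
* The toy's Bijvoet ratio (~a few percent of F) is still generous
  compared with large real proteins; absolute pattern counts should be
  read as relative between modes, not as beamtime predictions.
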