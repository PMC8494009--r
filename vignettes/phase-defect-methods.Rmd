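---
title: "Phase defects in cardiac excitation patterns: models, detectors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase defects in cardiac excitation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phasedefect)
```

## The problem

During tachycardia and fibrillation, electrical activation of the heart
organizes into rotating waves (rotors). The classical way to quantify such
patterns from voltage movies is *phase mapping*: assign every pixel an
angle describing where it sits in its excitation-recovery cycle, then find
*phase singularities* (PSs) — points around which the phase winds by
$\pm 2\pi$ — and call them rotor tips. This package implements the more
general *phase defect* view: in media whose rotors have linear (extended)
cores, the organizing structure is not a point but a *line* across which
the phase jumps quasi-discontinuously — a phase defect line (PDL), which
coincides with a line of conduction block (CBL), and which generalizes to
a phase defect surface (PDS) in 3D tissue. PSs detected by standard ring
methods then appear *on* these lines, flickering along them, which is
exactly what the package's statistics quantify.

## Phase constructions

Three phases are computed, all stored in $[-\pi, \pi)$ with all
comparisons made through the wrap operator
$U(x) = \mathrm{mod}(x+\pi, 2\pi) - \pi$ (so differences of $2\pi$ are
ignored; the boundary maps to $-\pi$).

* **Activation phase** `activation_phase()`: the polar angle of the state
  $(V, R)$ around a reference $(V_*, R_*)$ inside the cycle,
  $\phi_{act} = \mathrm{atan2}(R - R_*, V - V_*) + b$. The offset $b$ is
  free; choosing $b$ so that the resting state maps to 0 aligns it with
  the other phases.
* **Hilbert phase** `hilbert_phase()`: when only $V$ is observed (optical
  mapping), $R$ is replaced by the Hilbert transform of the mean-subtracted
  pixel trace; the phase is the angle of the analytic signal. The analytic
  signal is built directly via the FFT (zero negative frequencies, double
  positive ones).
* **Arrival-time phase** `arrival_phase()`: from the local activation time
  (LAT) map — the most recent upward crossing of $V_*$ — define
  $\phi_{arr} = 2\pi \tanh(3\, t_{elapsed} / \tau)$ with $t_{elapsed}$ the
  time since activation and $\tau$ a recovery timescale (the action
  potential duration, or the inverse dominant frequency). The saturating
  tanh makes long-recovered tissue phase-equivalent to rest, so wave
  fronts and wave backs produce *no* phase jumps; the only steep spatial
  transitions of $\phi_{arr}$ occur where LAT itself is discontinuous,
  i.e. at conduction block.

The LAT field uses 0 as the "never activated" sentinel; recordings start
at $t = 0$ and the first frame can assign no LAT, so every valid
activation time is positive.

## Detectors

* `detect_ps()` — ring methods on a phase frame. For each 2x2 plaquette the
  four *raw* cyclic differences are computed; a PS is flagged iff exactly
  one exceeds $\pi$ in magnitude (the combined `ring2x2_4x4` method also
  requires exactly one super-$\pi$ jump on the surrounding ring of 8
  pixels — the 4x4 perimeter without its corners). Raw differences matter:
  a plaquette straddling a defect line without winding has two large jumps
  and is rejected. Since the raw differences telescope to zero around the
  ring, the winding equals *minus* the sign of the single large jump; the
  reported chirality is the winding sign.
* `detect_cbl()` — edge midpoints where both endpoints have been activated
  (LAT > 0) and the LATs differ by more than $\Delta t_c \approx dx/c$.
* `detect_pdl()` / `detect_pds()` — edge midpoints where the *wrapped*
  phase difference exceeds $\Delta\phi_{crit}$; in 3D the same rule over
  all axis-aligned voxel edges, grouped by 26-connectivity.
* `detect_pdl_cos()` — the cosine variant: flag when
  $\cos(\phi_1 - \phi_2) < A$, exactly equivalent to `detect_pdl()` with
  $\Delta\phi_{crit} = \arccos A$. The comparison direction is deliberate:
  the cosine is near $+1$ in smooth tissue and near $-1$ across a defect,
  so the `<` inequality flags defects. (The opposite direction, which flags
  smooth tissue, is available behind `flag_smooth = TRUE`.)

Coordinates are 1-based with pixel centers at integers; cell corners and
edge midpoints live at half-integers. Defect components are connected sets
of midpoints at Chebyshev distance $\le 1$ (8-connectivity in 2D,
26-connectivity in 3D).

**PS-PDL association.** A detection rule of "within 0.5 px of the PDL"
cannot fire when PSs live at cell corners and PDL points at nodes and edge
midpoints: the minimum possible distance is exactly 0.5 (to a midpoint) or
$\sqrt2/2$ (to a node). `associate_ps_pdl()` therefore uses a default
radius of 0.75 px, which counts a PS as on-PDL precisely when its own
plaquette touches the defect — the intent of the original rule on a
common lattice.

## Tracking and statistics

PS detections are linked greedily between consecutive frames when they
move at most 1 pixel in any direction (Chebyshev) and keep their
chirality; competing pairings resolve by nearest distance, then lowest
(y, x). Defect components link across frames when any two points are
$\le 1$ px apart; families are connected components of that graph over the
recording, so lines may branch and merge. Lifespans are
$(\mathrm{last} - \mathrm{first} + 1)\,\Delta t$ frames for both tracks
and families (the inclusive convention makes a one-frame object live one
frame, and a stationary 10-frame line at 1 ms spacing live 10 ms).
`rotor_summary()` reports detection densities, co-location fractions,
birth rates, lifespans, and the dominant frequency of the spatially
averaged voltage trace (largest FFT peak excluding the zero bin).

## The built-in simulator

A monodomain reaction-diffusion model
$\partial_t \mathbf u = \Delta P \mathbf u + \mathbf F(\mathbf u)$ with
explicit Euler stepping, a 5-point (2D) / 7-point (3D) Neumann Laplacian
on the first (voltage) variable only, and mirrored ghost nodes — the
discrete operator conserves total voltage exactly when the reaction is
off, which the tests assert to machine precision. The stability bound
$dt < dx^2/(2 d\, P_{11})$ is enforced. Three published kinetics are
shipped with their standard parameter sets: Aliev-Panfilov (2 variables,
dimensionless), Fenton-Karma (3 variables; MLR-I and MBR sets) and the
Bueno-Orovio-Cherry-Fenton minimal ventricular model (4 variables; EPI
set). Stimuli clamp the voltage variable over a mask for a time window.
`default_config()` carries each model's reference grid spacing, time step,
LAT frame interval $\Delta t$, block threshold $\Delta t_c$, defect
thresholds and $\tau$.

### Fixture design, and what it does and does not emulate

The fixtures in `make_fixture()` are the package's study conditions; their
scales were chosen once from the models' measured conduction velocity (CV)
and action potential duration (APD) and are not tuned further:

* **AP S1-S2** (`s1s2_block`, `ap_circular_rotor`): 100x100 at $dx = 0.5$.
  Measured plane-wave CV $\approx 1.37$ units per time unit and APD
  $\approx 25$; an S2 quadrant clamp at $t = 45$ lands in the S1
  repolarization gradient, blocks eastward, and curls into a single
  sustained rotor (one PS per frame thereafter). The rotor fixture is the
  same run recorded from $t = 70$.
* **FK linear-core rotor** (`fk_linear_rotor`): the MLR-I wavelength at
  reference parameters is $\approx 125$ mm (CV 0.51 mm/ms x APD 244 ms),
  which no desk-scale domain can contain — S1-S2 at reduced scale produces
  a single sweep and dies. The fixture therefore uses the MBR set in 2D
  (wavelength $\approx 66$ mm, same linear-core class) on a 320x320 sheet
  (84 mm) and initiates by the standard broken-wavefront method: a 1D
  pulse profile is embedded in the top half of the domain and the free end
  curls into a spiral, giving sustained re-entry with an extended,
  drifting block-line core. The movie keeps $t \in [300, 900]$ ms (after
  LAT history is established).
* **BOCF S1-S2 block** (`bocf_linear_rotor`): the EPI wavelength
  ($\approx 172$ mm) again exceeds desk scale, so the fixture delivers the
  vulnerable-window scenario itself: the S2 wave is blocked along the
  refractory boundary and decays, leaving an extended conduction block
  line — the object the detectors target.
* **3D slab** (`fk_scroll_3d_small`): FK MBR in a 48x48x8 slab; S1-S2 at
  $t = 180$ ms leaves a transmural block surface whose bottom layer
  coincides exactly with the 2D defect line of the bottom surface.
* **`sinusoid_movie`**: analytic, for frequency and Hilbert-phase tests.

The simulated fixtures emulate rotor cores, conduction block and
single-observable movies. They do **not** emulate the photon noise, motion
artifacts, spatial background, optical blurring or bit-depth quantization
of real optical-mapping recordings, nor anisotropic fiber architecture
(the Laplacian is isotropic; the anisotropic monodomain operator needs
measured fiber fields and is out of scope). Passing tests therefore
demonstrate correctness of the *methods* on clean excitable-media data,
not robustness to experimental artifacts.

## Numerical choices and degenerate inputs

* Storage convention $[-\pi, \pi)$; $U(\pi) = -\pi$ is the tie rule.
* $dV/dt$ at frame $k$ is the backward difference — causal, and identical
  to the crossing rule used for LAT updates and wave fronts.
* Circular means for the upstroke/downstroke phase levels (arithmetic
  means break at the wrap); an empty crossing set is an error naming the
  missing level.
* A pixel exactly at $(V_*, R_*)$ has undefined activation phase (`NA`);
  undefined pixels poison every ring, edge and gradient they touch rather
  than being silently filled.
* `detect_pdl()` warns when $\Delta\phi_{crit} \ge \pi$ (wrapped
  differences can never exceed $\pi$).
* Thickness of the diffusive boundary layer around a defect:
  $d = \sqrt{D\tau}$ (in mm for $D$ in cm²/s and $\tau$ in ms), scaled by
  the conduction-velocity anisotropy ratio for a defect parallel to the
  fibers. With $D = 1.171$ cm²/s and $\tau = 269$ ms this gives 5.6 mm
  (14 mm at ratio 2.5). The product form $D\tau$ is dimensionally
  inconsistent with these worked values; the square root reproduces both
  and is what the package implements.
* The Hilbert phase applies a plain analytic signal to the mean-subtracted
  trace; the inverse dominant frequency is used only as the default
  $\tau$ for the arrival phase.

## Known limitations

* **Validity domain of the LAT block detector.** `detect_cbl()` keeps an
  edge flagged as long as the stored LATs differ, and its positivity
  conditions remove the wave front only while the tissue ahead has never
  been activated. On a *sustained* rotor, the re-entrant front constantly
  borders period-old tissue and every historical block edge stays flagged
  until both sides are re-swept, so the LAT rule flags far more edges than
  the arrival-phase rule, which forgets block on the tanh timescale
  $\tau$. The two detectors agree on first-passage episodes (the S1-S2
  fixtures) and disagree by construction on the sustained drifting rotor;
  the acceptance suite contains one deliberately strict frame-by-frame
  equivalence check that documents this mismatch quantitatively, and
  property tests assert the part of the claim that is mechanism-true:
  wave fronts and backs are invisible to $\phi_{arr}$ (per-edge jumps far
  below threshold) while block lines are not.
* **Boundary-layer smoothing of the activation phase.** At the reference
  resolutions the diffusive layer $\sqrt{D\tau}$ spans 10-15 px, so
  per-edge jumps of $\phi_{act}$ across a defect are often below the
  2.22 rad threshold except near the rotor tip; $\phi_{arr}$, being built
  from the discontinuous LAT, shows the full line. For the same reason the
  Hilbert-phase and activation-phase PS detections localize the tip only
  to within about one layer width of each other on a linear core (they
  agree much more tightly on circular cores).
* **LAT staircase.** LAT is quantized to the frame interval $\Delta t$,
  which imprints a staircase on $\phi_{arr}$ near the front (jumps up to
  $2\pi\tanh(3\Delta t/\tau)$); thresholds below that value will flag
  front bands. The AP reference threshold (0.7 rad with $\Delta t = 1$,
  $\tau = 20$, staircase 0.94 rad) sits in that regime, which is why the
  AP analyses here use the LAT-based detector instead.
* **Wave-speed discretization bias.** At the FK and BOCF reference
  space-time resolutions the explicit-Euler front is not grid-converged:
  the plane-wave speed rises by 13-16% under spatial refinement (and
  8-10% under time refinement alone), while the AP front at its reference
  spacing is within 1.5% of its refined value. This is a property of
  those discretizations, not of the implementation — an independently
  coded 1D cable at identical resolution reproduces the 2D stepper's
  speed to better than 1%. The speed validation therefore runs AP at its
  reference resolution and FK/BOCF one refinement level in (dx/2, dt/4),
  where successive refinement changes the speed by under 5%.
* PS localization is at plaquette resolution (no sub-pixel refinement);
  3D output is the defect surface point set, with no curve/filament
  extraction.
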