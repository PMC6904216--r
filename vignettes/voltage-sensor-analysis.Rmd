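---
title: "Analysing hyperpolarization-activated voltage sensors with voltsensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing hyperpolarization-activated voltage sensors with voltsensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltsensor)
```

## Scope and scientific background

Hyperpolarization-activated channels such as HCN1 open when the membrane
potential becomes more negative — the opposite polarity of most
voltage-gated channels. Their S4 helix carries the gating charges, and in
the activated (Down) state the lower half of S4 can break and lie almost
parallel to the membrane. `voltsensor` implements the quantitative
analyses used to characterise this kind of voltage-sensor motion:

* the **coupling-function decomposition of the gating charge** from
  electrostatic potential maps,
* **helix geometry**: backbone torsions, a per-residue helicity score,
  principal axes and bend angles, RMSD to reference states, contact
  persistence and hydration profiles,
* **probe-based solvent accessibility** (Shrake–Rupley at the MTSET probe
  radius) with state-dependent accessibility calls,
* **BAR free-energy estimation** and the alchemical thermodynamic cycle
  scoring a point mutation's state preference,
* **electrophysiology fits**: sum-of-two-Boltzmann relative-Po curves,
  the gating polarity index and its correlation with residue-property
  scales, and MTSET modification kinetics,
* **sequence-logo statistics** for aligned S4 segments.

Simulation trajectories and oocyte recordings are not distributed with
the package. Instead, a family of synthetic generators produces every
input class with *known ground truth*, so each analysis stage can be
validated as a closed loop: `analysis(generate(theta))` must recover
`theta`.

## Conventions

Coordinates are in Å, potentials and voltages in mV, energies in
kcal/mol, charges in elementary charges $e_0$, temperatures in K. The
membrane normal is the $z$ axis unless a `membrane_frame` states
otherwise; displacements are reported relative to the $z$ projection of a
named reference atom, conventionally the Cα of the charge-transfer-center
phenylalanine. Multi-model PDB is the trajectory interchange format
(MODEL/ENDMDL blocks are frames), and electrostatic maps enter as OpenDX
scalar grids tagged with the voltage under which they were computed — the
package never solves the Poisson problem itself.

## The gating-charge model

The fraction of the applied transmembrane voltage felt at a point
$\mathbf r$ is the *coupling function*

$$f(\mathbf r) \;=\; \frac{\partial \varphi(\mathbf r)}{\partial V_m}
\;\approx\; \frac{\varphi(\mathbf r, V_{m1}) - \varphi(\mathbf r, V_{m2})}
{V_{m1} - V_{m2}},$$

estimated per atom by trilinear interpolation of two (finite difference)
or more (least-squares slope) potential grids. The gating-charge
contribution of residue $j$ between the resting ($r$) and activated ($a$)
states is

$$Q_j \;=\; \sum_i q_{ij}\,\bigl[f_a(\mathbf r_{ij}) -
f_r(\mathbf r_{ij})\bigr],$$

with the sum over the residue's partial charges, and the net charge per
sensor is $Q = \sum_j Q_j$. Each state's coupling function is evaluated
at that state's own atom positions (a flag allows shared positions for
sensitivity checks): a charge moving through a static field contributes
through its displacement, while a *static* charge contributes whenever
the field itself rearranges between states — the mechanism by which
acidic countercharges that barely move still carry gating charge. On a
planar-capacitor fixture (potential linear across a slab) the
decomposition reduces to the analytic $q\,\Delta\bigl[(z - z_0)/L\bigr]$,
which the test suite checks to $10^{-6}$.

Partial charges are supplied externally (per atom id); force-field
parsing is out of scope. Averaging over several conformations per state
is done by `aggregate_charge`, which reports per-residue means, standard
errors across conformations, the cumulative charge in sequence order and
the per-channel total assuming four identical independent sensors.

## Helix geometry

Per-residue helicity uses the torsion-space score

$$h_p = \tfrac14\,\bigl(1 + \cos(\phi - \phi_\alpha)\bigr)
\bigl(1 + \cos(\psi - \psi_\alpha)\bigr),$$

which is 1 exactly at the reference α-helical torsions and 0 when both
torsions are 180° away. The reference values default to
$\phi_\alpha = -57°$, $\psi_\alpha = -47°$ (the textbook ideal α-helix;
configurable, since only "a perfect α-helix" is prescribed). Torsions at
chain termini are flagged undefined rather than dropped.

Helix axes are dominant eigenvectors of the Cα coordinate covariance,
signed toward the membrane normal. This matches the "principal axis"
language and remains robust down to 4-residue sub-helices, at the price
of a known small wobble: short segments of a real helix spiral around the
global axis, so even a perfectly straight helix splits into sub-segments
whose principal axes differ by a few degrees. The hinged-helix
closed-loop test therefore uses a ±3° tolerance, measured on the fixture
itself. Bend angles are between a sub-helix axis and a reference axis;
RMSD uses Kabsch superposition when requested.

Contact persistence calls a residue pair "in contact" when any heavy-atom
distance is ≤ 4.5 Å (default) and reports the fraction of frames in
contact; neither the cutoff nor a persistence threshold is prescribed
anywhere, so both are explicit parameters. Hydration profiles count
water oxygens in bins along the normal (default 3 Å) inside an optional
cylinder or box region — the counting volume is likewise an explicit
choice, defaulting to no lateral restriction so the caller decides what
"inside the sensor" means — and summarise the 10/25/50/75/90 percentiles
across frames.

## Solvent accessibility

`shrake_rupley` is a classic test-point SASA: each atom is expanded by
the probe radius, covered with a deterministic golden-spiral point set
(default 960 points), and points inside any neighbouring expanded sphere
are occluded. The probe radius defaults to 2.9 Å, the approximate radius
of the MTSET reagent, so "accessible" means MTSET-reachable rather than
water-reachable. Determinism was preferred over random test points so
results are bit-stable; the cost is that rotating a structure re-samples
the occlusion pattern, making SASA rotation-invariant only to the point
set's quantisation (≈0.3% at 960 points — the invariance test runs at
that tolerance; translations are exact). Accuracy against a seeded
Monte-Carlo rejection oracle is within 2% on overlapping-sphere
fixtures, and within 1% of the closed form for a lone atom.

`state_accessibility` thresholds per-residue SASA in two conformations
(default 5 Å², a deliberately permissive cut exposed as a parameter,
since no numeric criterion for "accessible" is prescribed) and classifies
residues as `gain`/`loss`/`unchanged`. Raw SASA does not know which side
of the membrane a crevice opens to; a crevice-connectivity (sidedness)
check is a noted extension, not implemented.

## Free energies

`bar_estimate` solves the Bennett acceptance ratio self-consistency
equation by bracketed root finding to $10^{-8}$ kcal/mol, with the
asymptotic maximum-likelihood variance for the standard error. When the
forward and reverse work distributions barely overlap — including the
degenerate zero-variance case — the variance estimate is not meaningful
and the result carries an `overlap_warning` instead of a number
pretending otherwise. β comes from $k_B = 0.0019872041$ kcal/(mol K),
T defaults to 300 K. Work samples are treated as independent;
decorrelation of time series is the caller's responsibility.

Multi-window paths are chained by summation with errors in quadrature
(`chain_windows`, e.g. the 21-λ-window protocol). The mutation cycle
(`thermodynamic_cycle`) combines per-conformation alchemical free
energies of the wild-type→mutant transformation computed in the activated
and resting states:
$\Delta\Delta G = \overline{\Delta G_a} - \overline{\Delta G_r}$ per
sensor, times the number of subunits per channel (default 4). The
synthetic generator draws Gaussian work samples with
$W_f \sim N(\Delta G + \beta\sigma^2/2, \sigma^2)$ and
$W_r \sim N(-\Delta G + \beta\sigma^2/2, \sigma^2)$ — the unique Gaussian
pair satisfying Crooks' theorem — so BAR is unbiased on them by
construction.

## Electrophysiology fits

Relative-Po curves are fitted to a sum of two Boltzmann components.
Two exact symmetries of this model matter for anyone comparing fitted
parameters:

1. **Offset gauge.** Shifting offset mass between the components
   ($O_1 \to O_1 - \delta$, $A_1 \to A_1 - \delta$,
   $O_2 \to O_2 + \delta$, $A_2 \to A_2 + \delta$) leaves the curve
   unchanged.
2. **Component reflection.** $(A, O, k) \to (O, A, -k)$ is the same
   sigmoid read from the other side.

Fits are therefore reported in a canonical form (both slope factors
positive, components ordered by half-point) together with the
`identifiable` combinations — amplitudes $A_i - O_i$, the depolarised
baseline $O_1 + O_2$, half-points and slopes — which are invariant under
both symmetries. Recovery tests assert on these and on the fitted curve,
never on raw $A$/$O$ values, which no fitting procedure could pin down.
The published model formula contains $(A_1 - O_2)$ in the first
component; the symmetric $(A_1 - O_1)$ form is the default here (the
printed variant makes $O_1$ a pure additive constant duplicating $O_2$)
and is available behind `strict_printed = TRUE`. Fitting is multi-start
nonlinear least squares (half-point grid × slope signs) with a
quasi-Newton/simplex polish.

The gating polarity index is $P_O(-150\,\mathrm{mV}) /
P_O(+50\,\mathrm{mV})$, evaluated from a fit or interpolated from data;
values above 1 mark inward rectification. Correlations with residue
properties are Pearson on $\log_{10}$ of the index (a ratio spanning
orders of magnitude; the transform is configurable). Three scales are
bundled: Kyte–Doolittle hydropathy, and Chou–Fasman helix and turn
propensities. The Chou–Fasman pair stands in for experimentally derived
transmembrane propensity scales whose numeric values are not reproduced
here; any named numeric vector can be passed instead.

MTSET modification kinetics fit peak current versus cumulative exposure
to $I(t) = I_\infty + (I_0 - I_\infty)e^{-t/\tau}$ and report the
apparent second-order rate $k = 1/(\tau\,C)$. Courses with no
resolvable amplitude change are flagged (`no_change`) rather than
yielding a spurious rate.

## Sequence logos

Column statistics exclude gaps from frequency normalisation by default
(configurable). Entropy is Shannon $H = -\sum p \log_2 p$ in bits. The
default stack height is the information content $\log_2 20 - H$ — the
standard logo convention — because a literal "inversely proportional to
entropy" height is undefined at perfectly conserved columns; that literal
mode is available as `height_mode = "inverse_entropy"` with a 0.1-bit
regulariser. Consensus ties break alphabetically and are flagged.

## The synthetic world, and what a green test establishes

The generators encode the stated experimental world, fixed once:

* **Helices**: NeRF-built backbones with standard bond geometry at the
  requested torsions; hinges rotate the C-terminal segment about an
  in-plane axis through the hinge Cα. The ~80° hinge fixture is the
  ground truth for bend recovery.
* **Potentials**: planar-capacitor profiles (0 → $V_m$ across a slab),
  optionally with additive Gaussian node noise. Test fixtures align slab
  boundaries with grid nodes so trilinear interpolation is exact there;
  with mid-cell kinks the interpolation error is O(spacing), which is a
  property of any gridded map, not of the estimator.
* **Work samples**: Crooks-consistent Gaussians (σ = 1 kcal/mol,
  n = 5000 per direction for the acceptance runs).
* **Po–V curves**: additive Gaussian noise on Po.
* **Modification courses**: 20 points spread over four time constants at
  1 mM reagent, 2% multiplicative noise on peak currents. A single
  simulated course recovers the rate with ≈6% scatter, so — as in the
  experiments, where published rates are means over several oocytes —
  recovery at the ±10% level is assessed on the mean of n = 5 simulated
  patches (SE ≈ 2.5%).
* **Alignments**: per-column consensus probability with uniform
  substitution among the other 19 residues.

None of the noise models is prescribed by the source experiments; they
are ordinary first choices (additive Gaussian on fields and Po,
multiplicative on peak currents) and are stated here once. A green
closed-loop test establishes that the estimator recovers the generator's
truth *under these models* — it says nothing about force-field accuracy,
sampling convergence of real trajectories, leak/rundown artefacts in
recordings, or alignment quality, none of which the synthetic world
contains.

## Numerical choices and degenerate inputs

* Trilinear interpolation; atoms outside a grid are an error, never an
  extrapolation.
* Principal axes error out when the two leading covariance eigenvalues
  tie (isotropic clouds) — exactly collinear points, by contrast, have a
  perfectly defined axis and are accepted.
* BAR root-finding brackets the work range and expands upward if needed;
  Fermi arguments are clamped at 700 to avoid overflow.
* The double-Boltzmann initialisation grid spans the voltage quartiles,
  both slope signs and two magnitudes (≤ 48 starts), then polishes.
* `nls` cannot iterate on exact zero-residual data, so oracles in the
  test suite use direct `optim` minimisation where fixtures are
  noiseless.
* Seeds: every generator takes an explicit seed and restores the
  caller's RNG state; identical spec + seed gives byte-identical output.

## Known limitations

* SASA has no sidedness/connectivity notion (a buried internal cavity
  counts as surface if the probe fits locally).
* Contact persistence is O(pairs × frames) pure R — fine for helix-scale
  selections, not for whole-protein contact maps.
* The per-channel scalings (×4) assume independent identical sensors.
* Potential maps are taken as given; no averaging protocol over
  simulation windows is imposed.
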