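---
title: "Tunneling-corrected barriers and active-site geometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tunneling-corrected barriers and active-site geometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtunnel)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, the numerical choices, and what the synthetic
fixtures do and do not establish about real data.

## The physical setting

Radical SAM lyases reductively cleave S-adenosyl-L-methionine to generate
the 5′-deoxyadenosyl radical (5′-dA•), which abstracts a hydrogen atom from
the amino group of a bound amino-acid substrate. The resulting aminyl
radical then breaks one specific carbon–carbon bond: Cα–Cβ in tyrosine
lyases (giving dehydroglycine and a p-cresyl radical), Cα–C in the
tryptophan lyase case (giving 3-methylindole-2-carboxylic acid). Two
quantitative questions sit on the desk after the expensive QM/MM work is
done:

1. The abstraction barriers are high (≈ 18–20 kcal/mol) yet the transition
   states carry very large imaginary frequencies (> 2000 cm⁻¹) and the
   hydrogen moves less than half an Ångström. How much does quantum
   tunneling lower the *effective* barrier, and are the printed barrier
   reductions consistent with the printed frequency bound?
2. Which C–C bond the aminyl radical can break is a stereoelectronic
   question: the singly-occupied nitrogen p orbital must overlap the
   breaking bond. Given the product dihedral Φ(Cβ–Cα–N–H), which bond is
   aligned?

Everything in the package consumes *tabulated* outputs (energies, frames,
curves, coordinates); it never performs electronic-structure, MD or
crystallographic calculations itself.

## Tunneling corrections

### Model

A one-dimensional barrier is specified by the forward barrier height
$\Delta E^\ddagger$ (kcal/mol), the reverse height, the imaginary-mode
wavenumber magnitude $\tilde\nu$ (cm⁻¹), the temperature, and the
transferring mass (default ¹H, 1.00783 u). The thermal transmission
coefficient is the Boltzmann-weighted average of the barrier transmission
probability relative to classical barrier crossing,

$$\kappa(T) = e^{\Delta E^\ddagger/k_BT}\,\frac{1}{k_BT}
  \int_0^\infty T(E)\, e^{-E/k_BT}\, dE,$$

and the effective barrier is $\Delta E^\ddagger - RT\ln\kappa$ — the
barrier a classical rate expression would need to reproduce the corrected
rate. Two transmission models are implemented side by side:

* **Eckart** (`kappa_eckart`): the exact $T(E)$ of the (a)symmetric Eckart
  potential in the Johnston–Heicklen dimensionless form with
  $\alpha_i = 2\pi V_i/(hc\tilde\nu)$, $\xi = E/V_1$:
  $$T(E) = 1 - \frac{\cosh 2\pi(a-b) + \cosh 2\pi d}
                   {\cosh 2\pi(a+b) + \cosh 2\pi d},$$
  $2\pi a = 2\sqrt{\alpha_1\xi}\,/(\alpha_1^{-1/2}+\alpha_2^{-1/2})$,
  $2\pi b = 2\sqrt{(\xi-1)\alpha_1+\alpha_2}\,/(\alpha_1^{-1/2}+\alpha_2^{-1/2})$,
  $2\pi d = 2\sqrt{\alpha_1\alpha_2 - \pi^2/4}$ (cos replaces cosh when the
  radicand is negative). Below the higher asymptote no channel is open and
  $T = 0$.
* **Bell** (`kappa_bell`): the analytic series for a parabolic barrier
  truncated at its base,
  $\kappa = \frac{u/2}{\sin(u/2)} + \sum_{n\ge1} (-1)^n
  \frac{u}{2n\pi-u} e^{\alpha(1-2n\pi/u)}$, $u = hc\tilde\nu/k_BT$,
  $\alpha = \Delta E^\ddagger/k_BT$, summed until terms drop below 1e-12.

Wigner's $1 + u^2/24$ is kept as the classical-limit comparator, and both
full models reduce to it for $u \le 0.5$ (property-tested at 2%).

The two models genuinely differ in the deep-tunneling regime ($u > 2\pi$):
the Eckart barrier is wider at its base than the truncated parabola, so at
$u \approx 12$ its $\kappa$ is two to three orders of magnitude smaller.
Published effective barriers computed one way will not be reproduced by the
other; `invert_frequency()` therefore exposes `model=` so a stated
(barrier, effective barrier) pair can be checked under either. Both answers
exceed the published 2000 cm⁻¹ bound for the study conditions shipped in
the acceptance script.

### Assumptions and limitations

* One-dimensional tunneling along the imaginary mode; no variational TST,
  no multidimensional (small/large-curvature) corrections, no fit to
  experimental kinetics.
* The transferring mass is the bare hydrogen by default; reduced-mass
  coupling to heavy-atom motion is not modeled. `kie()` scales
  $\tilde\nu_D = \tilde\nu_H\sqrt{m_H/m_D}$, i.e. a pure 1-D oscillator
  picture.
* Reverse barriers are rarely printed; the default is the symmetric barrier
  ($V_r = V_f$), the single-parameter choice, and conservative for the
  "is the implied frequency above 2000 cm⁻¹" consistency check (an
  asymmetric barrier of the same forward height tunnels no more at the
  energies that dominate the average). Asymmetric mode is available
  whenever the product-side energy is known.
* Temperatures follow the growth conditions of the two source organisms:
  60 °C = 333.15 K and 25 °C = 298.15 K.
* $u > 60$ is refused ("deep-tunneling regime outside validated domain"):
  beyond that the oracle cross-checks were not performed and double
  precision headroom shrinks.

### Numerical choices

* Physical constants are fixed to 7 significant digits
  ($R = 1.987204\times10^{-3}$ kcal mol⁻¹ K⁻¹, $hc/k_B = 1.438777$ cm K,
  1 kcal/mol = 349.755 cm⁻¹) so results reproduce bit-for-bit across
  platforms.
* $\cosh$ terms are evaluated in log space; the transmission never
  overflows to NaN however deep the tunneling.
* The Boltzmann integral runs in the reduced variable $\varepsilon = E/k_BT$
  after substituting $\varepsilon = t^2$, which removes the $\sqrt E$ edge
  of $T(E)$ at the origin; it uses an in-package composite-Simpson rule
  with interval doubling and Richardson error control at relative
  tolerance 1e-8, split at the barrier top where the integrand's rise is
  sharpest. The cutoff $\Delta E^\ddagger/k_BT + 40$ is a documented no-op:
  doubling it changes $\kappa$ by less than the quadrature tolerance.
* For $u < 0.02$ the transmission is a near-step of width $u/2\pi$ in
  $\varepsilon$ that quadrature cannot usefully resolve; there the thermal
  average equals the small-$u$ expansion $1 + u^2/24$ to double precision
  (next term $O(u^4)$) and is returned in closed form.
* Bell's series has poles at $u = 2n\pi$; within 0.1 of a pole the
  equivalent numerical Kemble-transmission integral is substituted and the
  substitution is flagged in the result.
* `invert_frequency` brackets on [50, 6000] cm⁻¹ and bisects to 1 cm⁻¹; a
  target equal to the forward barrier returns the lower edge annotated
  "no tunneling required" rather than hunting a root that is not there.

### Validation strategy

The analytic Eckart $T(E)$ is checked against an independent Numerov
integration of the 1-D Schrödinger equation for the same potential
(transmitted-wave boundary condition, incident/reflected decomposition on
the reactant side) at random (E, spec) points across $u \in [2, 20]$, at
1%. The thermal average is checked against a Numerov-plus-trapezoid
Boltzmann oracle at 2%, and Bell's series against direct numerical
integration of the Kemble transmission at 0.5% — the series and integral
agree to machine precision away from poles. The
invert–forward round trip closes to 1 cm⁻¹ over [500, 4000] cm⁻¹.

## Reaction profiles and scan curves

Stationary points are read directly off the tabulated energies: the
transition state is the interior global maximum (ties broken toward the
lower index and flagged), reactant and product are the branch minima, and
both barriers are reported. Energies are re-zeroed to the first frame on
ingest; all comparisons are on relative energies.

The operational **transfer distance** is the net Euclidean displacement of
the migrating hydrogen across the five-frame window centered on the
transition state — matching how a short IRC segment is reported in
practice — with donor–H and acceptor–H distances at every window frame
reported alongside so alternative definitions can be audited. The window is
index-based, not arc-length-based, since frame spacing conventions vary.

`fit_eckart` fits the asymmetric Eckart curve by Levenberg–Marquardt
(minpack.lm), with starting values from the discrete stationary points, and
reports the imaginary wavenumber implied by the fitted curvature,
$\tilde\nu = \frac{1}{2\pi c}\sqrt{|V''(s_0)|/\mu}$. Parameter recovery on
seeded synthetic profiles is median < 2% noiseless and < 6% at 0.05
kcal/mol Gaussian noise.

Scission scans are classified **complete** when the endpoint separation
exceeds 3.0 Å *and* the leaving fragment carries at least 95% of the
unpaired spin. The 3.0 Å threshold is the field's working definition of a
broken C–C bond in these systems; "exclusively located" spin has no printed
number, and 0.95 is this package's operationalization — both are arguments,
not constants. Minima are refined by three-point quadratic interpolation;
dihedral scans are treated as periodic at ±180° so a well straddling the
wrap is found once.

## Structure geometry

**Newman assessment.** With the remaining N–H at 0° in the projection along
the N–Cα axis, the radical p orbital lies on the ±90° axis (two-lobe
symmetry). The Cα–Cβ bond projects at Φ(Cβ–Cα–N–H) and the carboxylate
Cα–C at Φ + 120° (ideal sp³ offset; the sign is fixed by L-amino-acid
chirality). Each bond's misalignment ω is its angular distance to the
orbital axis folded to [0°, 90°]. The three zones — periplanar ≤ 30°,
intermediate 30–60°, clinal > 60° — are chosen so that the four qualitative
regiochemistry calls of the two enzymes ("maximized", "impeded", "allowed
although not optimal", "not possible") map onto periplanar / clinal /
intermediate / clinal; the boundaries are arguments. The printed product
dihedrals 174.5° and 39.6° then yield ω = 24.5° (Cα–C, periplanar) /
84.5° (Cα–Cβ, clinal) and ω = 50.4° (Cα–Cβ, intermediate) / 69.6°
(Cα–C, clinal).

**Contact census.** Nitrogen/oxygen partners within 3.5 Å of the target,
excluding its own residue; hydrogens are ignored (crystal structures).
Square-pyramidal typing requires four basal donors whose pairwise
target-centered angles split into four adjacent ones in [70°, 110°] and two
trans ones ≥ 140°, plus apical–basal angles in [70°, 110°] when a fifth
partner exists. These ±20° windows tolerate ~0.2 Å of coordinate noise on
2.8 Å contacts essentially always; at 0.3 Å (≈ 8.7° angular noise per
donor) the expected pass rate falls to ≈ 0.8, which the robustness test
asserts honestly rather than pretending the window is wider than it is.

**Superposition.** Kabsch SVD with the reflection degeneracy resolved to
det = +1. Optional trimming drops pairs deviating by more than twice the
current RMSD and refits, stopping when nothing changes or 70% retention is
reached — deposited-model comparisons that quote "N of M Cα atoms" imply
some trimming rule but never print one, so this package's rule is explicit
and the floor keeps it from chasing a minimal core. On rigid copies the
RMSD is numerically zero; on isotropic noise σ per coordinate it approaches
σ√3 (cross-checked against bio3d's fitter).

**χ1 deltas** fold |Δχ1| to [0°, 180°], with the γ atom chosen per residue
type (OG, OG1, SG, CG1, CG).

**Cavity mapping.** A voxel is probe-accessible when its center is at least
(Bondi vdW radius + probe) from every heavy-atom center. 26-connected
components of accessible space are labeled; those reachable from the box
boundary are surface-connected (bulk solvent and open channels) and are
reported separately from closed cavities rather than guessing which
convention a figure used. Defaults: probe 1.0 Å (the figure-caption
convention for these cavity maps), spacing 0.4 Å (refusing spacing > probe
as undersampling; halving spacing moves the shell-fixture volume by < 5%),
box = bounding box + probe + 2 Å. Ligands are excluded by residue name or
chain:resno before gridding, mirroring "substrate removed for the cavity
calculation". The same 26-connectivity serves the exterior fill and the
labeling, so channel-versus-cavity calls are consistent; total closed
volume varies < 3% over random rigid reorientations of the structure.

## Synthetic data: what it shows and what it cannot

Every generator is a pure function of its parameters and seed (the caller's
RNG state is restored), and each emits a ground-truth record consumed by
the tests. The defaults are the study conditions: barriers around 18–20
kcal/mol, a 0.45 Å hydrogen displacement across the TS window, a scan
minimum near 2.7 Å with residual spin 0.55 on the leaving fragment (the
incomplete-scission signature) versus a monotone decrease to 3.4 Å with
spin 1.0 (the completed one), 2.8 Å square-pyramidal donor shells, a
χ1 pair (−60°, +50°) giving the 110° rotation scenario, and dihedral wells
at −48°/+55°. Noise levels are test parameters, not claims about real
data — the profiles these stand in for carry no published noise model.

The generators are schematic by design: no force-field realism, idealized
donor geometry, a helical poly-alanine rather than a real fold, spherical
shells rather than a β-barrel. Passing tests therefore establish that the
*measurement machinery* is correct on known ground truth — not that real
structures will show the same numbers. The deposited-model comparisons
(chain RMSDs of 0.19–2.1 Å, the serine rotation, the phenolate census, the
gate-residue channel lining) require downloading the corresponding PDB
entries; the test suite emulates each of those measurements end-to-end on
synthetic twins built to the published ground truths instead, which is
exactly what an offline, text-only test bed can honestly do. Problem sizes
were likewise chosen at desk scale: 20–40-frame profiles, 50-seed recovery
panels, shells of radius 6–8 Å on 0.4 Å grids — enough for the stated
tolerances while the whole suite runs in well under a minute.

## Interfaces

Formats: PDB (ATOM/HETATM/MODEL/TER parsed via bio3d; first model; highest
occupancy altloc, ties to 'A'; residue numbering verbatim), multi-frame XYZ
with `E=` (and optional `s=`) comment tokens in kcal/mol, kJ/mol or hartree
(627.5095 kcal/mol), CSV scan curves with `spin_*` fragment columns, OpenDX
scalar fields and pseudo-atom PDB clouds for cavity visualization. Writers
are deterministic (energies `%.6f`, coordinates `%.3f`). The exported
functions are the interface; driving them from R scripts replaces a shell
entry point, and `scripts/acceptance.R` is the worked example of doing so.
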