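---
title: "Modelling the stability and rupture of lung parenchymal lesions"
author: "blebmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the stability and rupture of lung parenchymal lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blebmech)
```

## The problem

Spontaneous pneumothorax — sudden lung collapse — is triggered by the
rupture of quasi-spherical, thin-walled air blisters (blebs, or
parenchymal lesions) on the visceral pleural membrane. `blebmech`
implements a biomechanical toolchain for asking when such a lesion is
mechanically stable, how it fails, and how its material state can be
inferred from images of a deforming tissue boundary.

The package has four connected layers:

1. a forced, damped nonlinear oscillator for the lesion wall coupling
   breathing pressure, membrane elasticity and pleural-fluid loading;
2. closed-form equilibria of the autonomous system and Jacobian-based
   instability criteria over the material-parameter space;
3. two failure routes — a finite energy limiter that converts unbounded
   expansion into rupture at a definite stretch, and collagen–elastin
   remodelling kinetics that can carry a stable lesion into the unstable
   region;
4. an image-analysis pipeline (edge detection, sectorization, kinematics,
   nonlinear regression) that estimates wall parameters per angular sector
   of an observed boundary and classifies each sector as stable or
   unstable.

## The mechanical model

### Geometry and kinematics

The lesion is a spherical membrane of undeformed radius $R$ and thickness
$H \ll R$. The single kinematic degree of freedom is the stretch ratio
$\lambda(t) = r(t)/R$. Membrane incompressibility gives the deformed
thickness $h = H/\lambda^2$. The Green–Lagrange strain of the equibiaxial
deformation is $E_{11} = (\lambda^2 - 1)/2$.

### Wall constitutive model

The wall uses an isotropic collagen pseudostrain-energy of
logarithmic-plus-linear form, multiplied by the deformed thickness so all
energies are per unit *reference* area:

$$ w(\lambda) = \frac{H}{\lambda^2}\left( c_1 \log\!\left[1 -
\frac{e^{E_{11}} - 1}{c_2}\right] + c_3 E_{11} \right), $$

with $c_1 < 0$, $c_2 > 0$, $c_3 < 0$ for physically meaningful lung
tissue (defaults $c_1 = -22.5\times10^5$, $c_2 = 1.26$,
$c_3 = -7.8\times10^5$ N m$^{-2}$). The logarithm bounds validity to
$e^{E_{11}} - 1 < c_2$; `strain_energy_full()` reports states beyond it
as errors. For analysis and fitting the second-order Taylor expansion
about $E_{11}=0$ is used throughout
(`strain_energy_taylor()`), giving the elastic stress resultant

$$ T_{el}(\lambda) = a_1 + a_2(\lambda^2-1), \qquad
a_1 = -\tfrac{c_1 H}{c_2} + c_3 H,\quad
a_2 = -\tfrac{c_1 H}{2c_2^2} + \tfrac{3 c_1 H}{2 c_2} - 2 c_3 H, $$

plus a viscous term $2\mu_m H \dot\lambda/\lambda^3$. Note that the
default tissue is strain-*softening* in this expansion ($a_2 < 0$) while
the unstable reference point ($c_3 = -1.39\times10^6$) is
strain-*hardening*; several downstream behaviours (rupture, stability)
hinge on this sign.

### Breathing forcing

Tidal air flow is a seven-component Fourier cosine series (amplitudes in
L s$^{-1}$, frequencies 0.156–8.05 Hz, phases in radians — the values near
$\pi$ and $3\pi/2$ make degrees implausible). The inner pressure is
$P_\mathrm{inner} = 760 + R_b\,Q(t)$ mmHg with the bronchiole resistance
$R_b = 1$ mmHg s L$^{-1}$ kept explicit and testable rather than folded
into the amplitudes. All frequencies are integer multiples of
0.078125 Hz, so the series has a common period of 12.8 s over which the
pressure averages exactly to its 760 mmHg baseline.

### Momentum balance and nondimensionalization

Combining wall inertia, pleural-fluid pressure (from the spherically
symmetric Navier–Stokes solution), radial fluid stress, wall
viscoelasticity and the transmural pressure gives a second-order ODE in
$\lambda(t)$. It is nondimensionalized with

$$ \tau = \frac{t}{t_c},\quad t_c = R\sqrt{\rho_m/|c_1|}, \qquad
b = \frac{\rho_f R}{\rho_m H},\quad d = \frac{H}{R},\quad
m_f = \frac{\mu_f}{H\sqrt{\rho_m |c_1|}},\quad
m = \frac{\mu_m}{H\sqrt{\rho_m |c_1|}}, $$

$$ F(\tau) = \frac{(P_\mathrm{inner}(t) - p_\infty) R}{c_1 H}, \qquad
f(y_0) = \frac{T_{el}(y_0)}{c_1 H}, $$

yielding the first-order system ($y_0 = \lambda$, $y_1 = dy_0/d\tau$):

$$ \frac{dy_1}{d\tau} = \frac{F(\tau) - \tfrac{3}{2} b y_1^2
- 4 m_f y_1/y_0 - 2 f(y_0)/y_0 - 4 m d\, y_1/y_0^4}
{b y_0 + y_0^{-2}}. $$

Two conventions deserve emphasis (this section doubles as the package's
derivation note):

* **The scalings above are reconstructions.** They are fixed uniquely by
  requiring that the dimensional momentum balance map *exactly* onto the
  nondimensional system: the time scale makes the inertial factor
  $b y_0 + y_0^{-2}$, and the viscosity numbers make the damping terms
  $4 m_f y_1/y_0$ and $4 m d\, y_1 / y_0^4$. The radial fluid-stress term
  is taken in rate-over-stretch form ($4\mu_f \dot\lambda/\lambda$
  dimensionally), the standard form for radial fluid stress on a sphere
  and the only one consistent with the $4 m_f y_1/y_0$ term.
* **Signs follow from dividing by $c_1 H/R$ with $c_1 < 0$.** Both $F$
  and $f$ are negative for physical inputs; in this convention the
  *stress* term $-2f/y_0 > 0$ drives expansion and the *pressure* term
  $F < 0$ opposes it. The convention is internally consistent: from the
  undeformed rest state the system expands to a stable equilibrium at
  $\lambda \approx 1.34$ for default parameters, and
  `simulate_lesion_si()` integrates the dimensional form and reproduces
  the nondimensional trajectories to $10^{-13}$ relative, which is the
  test that certifies the reconstruction.

With default parameters $b = 9.336$, $d = 0.1$,
$m_f = 3.04\times10^{-5}$, $m = 1.44\times10^{-3}$,
$\bar F = -0.4503$ and $t_c = 2.16\times10^{-4}$ s. Because $t_c$ is
sub-millisecond, the membrane's natural oscillation (period
$\approx 22\,\tau \approx 4.8$ ms) is orders of magnitude faster than
breathing; over a typical simulation window the forcing is nearly
constant, and the oscillations seen in trajectories are the natural
membrane mode about the equilibrium, lightly damped ($|J_{22}|\sim
2\times10^{-5}$ per $\tau$, so orbits persist essentially undamped over
any practical window).

### Integration

The integrator is a classical fixed-step fourth-order Runge–Kutta
scheme, `integrate_rk4()` (verified at empirical order 4 and against
`deSolve`'s RK4) — the standard explicit choice for this non-stiff
oscillator, and a deliberate one: fixed steps keep sweeps and
dimensional/nondimensional comparisons exactly reproducible.
Defaults: step $10^{-3}$ in $\tau$; parameter sweeps coarsen to
$5\times10^{-3}$, which a convergence check shows changes sweep metrics
at below measurement resolution. Initial conditions are not part of the
model statement; the package default is the undeformed rest state
$(1, 0)$, configurable everywhere.

## Equilibria and stability

With constant forcing $\bar F$ (the autonomous approximation — justified
above by the timescale separation), equilibria satisfy
$\bar F - 2 f(\lambda)/\lambda = 0$, which with the Taylor stress is the
quadratic $\gamma \lambda^2 + \alpha\lambda + \beta = 0$ where

$$ \alpha = c_1 c_2^2 \bar F,\qquad
\beta = -c_1 + 5 c_1 c_2 - 6 c_2^2 c_3,\qquad
\gamma = c_1 - 3 c_1 c_2 + 4 c_2^2 c_3 . $$

$\alpha > 0$ always for physical inputs, and $\beta, \gamma$ cannot both
be positive (this is a short contradiction argument from the sign
constraints, property-tested over $10^4$ random draws). For the default
tissue the positive root is $\lambda_{eq}^+ = 1.3404$.

The $2\times2$ Jacobian at an equilibrium has first row $(0, 1)$ and

$$ J_{21} = \frac{\bar F\, Q'(\lambda)}{\alpha\,\lambda\, D},\qquad
J_{22} = -\frac{4 m_f/\lambda + 4 m d/\lambda^4}{D},\qquad
D = b\lambda + \lambda^{-2}, $$

with $Q$ the equilibrium quadratic. Instability holds when
$\det J < 0$ or $\operatorname{tr} J > 0$, and both conditions reduce to
closed-form inequalities in $(\alpha, \beta, \gamma, b, d, m, m_f)$:

* **Determinant criterion** (`unstable_by_determinant()`):
  $\gamma < 0$, $\beta > 0$ and
  $\gamma < b^{1/3}\alpha - b^{2/3}\beta$.
* **Trace criterion** (`unstable_by_trace()`): $\gamma < 0$, $\beta > 0$,
  $\gamma > b^{1/3}\alpha - b^{2/3}\beta$, and with
  $k = (d m / m_f)^{1/3}$, $\beta < \alpha k - \gamma k^2$.

One subtlety: the closed-form criteria are formulated about the "+"
branch $(-\alpha + \sqrt{\alpha^2-4\beta\gamma})/(2\gamma)$ of the
quadratic. In the $\gamma<0,\ \beta>0$ regime where the criteria can
fire, that branch is *negative* while the physically meaningful positive
equilibrium is the other root. `jacobian_at_equilibrium()` therefore
defaults to the analysis branch (where the criteria are exactly
equivalent to the Jacobian sign conditions — we verified the algebra
step by step and property-test it on $10^3$ random draws), and
`classify_lesion()` reports the positive root as `lambda_eq` alongside
numerically recomputed signs of $\det J$ and $\operatorname{tr} J$ as a
cross-check.

A second subtlety concerns the trace criterion's dissipation inequality.
Carrying the sign analysis of the $J_{22}$ numerator through from
$2 m_f (\alpha + \sqrt{\alpha^2-4\beta\gamma})/\beta
- 64\gamma^4 d m / (-\alpha+\sqrt{\alpha^2-4\beta\gamma})^4 < 0$
gives, after using
$(\alpha+\sqrt{\cdot})(-\alpha+\sqrt{\cdot}) = -4\beta\gamma$ and taking
a cube root, exactly $\beta < \alpha k - \gamma k^2$. A typeset variant
of this inequality with a $\gamma^2$ factor circulates; it is
dimensionally inhomogeneous, provably inequivalent to the trace sign,
and for realistic magnitudes essentially never satisfiable. The package
defaults to the derived form; the variant is available as
`form = "printed"` and `trace_criterion_forms_agree()` reports any
disagreement together with the numeric trace, so the discrepancy is
surfaced rather than silently resolved.

`region_scan()` maps either criterion over any two of
$(c_1, c_2, c_3)$; cells whose quadratic has no positive root are
reported as an explicit no-equilibrium state, never silently as stable.

## Rupture: the finite energy limiter

Hyperelastic walls can expand without bound; real tissue cannot. The
limited energy

$$ \Psi = H\Phi\left(1 - e^{-w/(H\Phi)}\right) $$

caps storable energy at $H\Phi$ ($\Phi$ in J m$^{-3}$), and the
corresponding stress is the elastic stress attenuated by
$e^{-w/(H\Phi)}$. For strain-hardening parameter sets this creates an
interior stress maximum: the softening-onset stretch
(`rupture_stretch()`), beyond which the wall sheds load as it expands.
`simulate_lesion(stress = "limited")` declares rupture at the first
crossing of that stretch while expanding; an alternative rule (stored
energy at 99% of the cap) is available via `rupture_rule = "energy"`.
For the default strain-softening tissue the elastic stress has no
interior maximum above $\lambda = 1$ and the softening detector is
inert — correctly so, since that tissue oscillates stably.

No measured value of $\Phi$ exists for lung tissue; any rupture study
must choose it. The packaged default (`default_energy_limit()`) sets
$H\Phi$ to three times the Taylor strain energy at $\lambda = 2$ for the
material at hand, which places the softening onset mid-expansion
(at $\lambda^\ast = 1.61$ for the unstable reference point) rather than
immediately or never. $\Phi$ is a required, explicit knob in any
configuration that exercises rupture.

Two behaviours of this system are worth recording:

* From the rest state $(1,0)$ the unstable reference point
  ($c_3 = -1.39\times10^6$) *collapses inward*: its positive equilibrium
  $\lambda = 1.093$ is a saddle sitting above the rest state. The
  expansion-to-rupture scenario is reached from beyond the saddle, and
  the package's rupture demonstrations initialize at the normal-tissue
  equilibrium $1.3405$ — the natural state of a lesion whose wall has
  degraded (e.g. by remodelling) from the stable into the unstable
  parameter region. From there the hyperelastic wall expands without
  bound while the limited wall ruptures at finite time
  ($\tau \approx 7.4$ with the default cap).
* Rupture time is *not* globally monotone in $\Phi$: shrinking the cap
  lowers the softening stretch (monotonically), but once the onset drops
  below the starting stretch the detector must wait for an expanding
  excursion, which the weakened wall reaches later. The tests assert the
  monotonicity that actually holds.

## Collagen–elastin remodelling

The wall's energy is generalized to a protein-weighted mixture:
$A_c(\tau)$ times the collagen energy plus $A_e(\tau)$ times an
elastin-only term $(b_e H/\lambda^2)(\lambda - \log\lambda - 1)$, where
the elastin stiffness $b_e$ (N m$^{-2}$) is distinct from the inertia
ratio $b$ despite the shared symbol in the underlying theory. No
literature value for $b_e$ is asserted; the package default
($7.8\times10^5$ N m$^{-2}$, the magnitude of $|c_3|$) is an
order-of-magnitude choice, exposed in the configuration. The quadratic
form of the mixture (elastin enters at second order in $E_{11}$) is used
in the dynamics for robustness: trajectories legitimately visit
stretches beyond the logarithmic form's validity.

Remodelling is driven by the gap between the unlimited and limited
mixture energies, $s = |w' - \Psi'|$: second-order small far from the
energy cap and large near it, which encodes the histochemical
observation that collagen is deposited and elastin degraded near
failure. The kinetics are

$$ \frac{dA_c}{dt} = k_1 A_c \left(\frac{s}{H\Phi'}\right)^n, \qquad
\frac{dA_e}{dt} = -k_2 A_e \left(\frac{s}{H\Phi'}\right)^n, $$

so $A_c$ never decreases and $A_e$ never increases (asserted along every
accepted trajectory). The signal is normalized by the energy cap so that
$k_1, k_2$ carry units of s$^{-1}$ regardless of $n$; this is the
package's choice, stated because the reference calibration
($A_c = 100$, $A_e = 50$, $k_1 = 10^7$, $k_2 = 10^3$, $n = 1$) comes
with no units and no $\Phi$. Consequently only the *qualitative*
contrast is reproducible: with the reference kinetics and a finite cap
the trajectory leaves its stable orbit in finite time, with
$k_1 = k_2 = 0$ it never does. The escape time itself depends entirely
on the unspecified $\Phi$ and rate units, and with the default cap the
reference kinetics are violently fast (escape within a fraction of a
characteristic time).

The changing protein mass adds a momentum-flux correction
$-m_p y_1/y_0^2$ to the momentum balance, with
$m_p = (t_c/\rho_m)\, d(\rho_c A_c + \rho_e A_e)/dt$ — the unique
dimensionless form under the core time scale; it cancels exactly when
collagen deposition mass-balances elastin loss. Protein densities
default to $\rho_c = \rho_e = 5.10$ kg m$^{-3}$.

**Escape detection.** A remodelling run "escapes" when its stretch
leaves the envelope of the frozen-kinetics base orbit by a 50% margin
for at least one characteristic time, *or* when it terminates in
rupture, collapse or runaway expansion that the base run does not
exhibit. The departure can be inward: in this sign convention the
attenuated stress removes the expansive force, so a fully degraded wall
falls inward rather than flying apart. Detection on one side only would
miss real failures.

## Boundary imaging and parameter estimation

### What the synthetic fixtures emulate

`generate_fixture_frames()` renders grayscale stacks of a bright lesion
interior against a dark background, the boundary radius following
$R\,\lambda(t)$ from the forward model, with optional per-angular-range
material overrides (to build mixed stable/unstable phantoms) and
Gaussian pixel noise in 8-bit gray levels. A fixed seed makes stacks
bit-reproducible. The fixtures emulate the *geometry and contrast* of
transient CT boundary data — a quasi-circular bright/dark interface of
realistic pixel scale (0.1 mm/px, ~2 cm lesion) — and deliberately not
its acquisition physics: no beam hardening, no motion artifacts, no
partial-volume texture. Passing the round-trip tests therefore
demonstrates that the *pipeline* is correct and noise-tolerant, not that
clinical CT will behave as benignly.

The default frame interval is $2\times10^{-5}$ s with 64 frames. This is
the package's choice, made so the window resolves the membrane's natural
oscillation (period ≈ 4.8 ms) that the forward model actually produces:
the regression differentiates the boundary radius twice, which requires
sampling well inside the signal's timescale. (Breathing-rate sampling,
natural as it sounds for CT, would alias the model's millisecond
dynamics into garbage derivatives.) Within this window the stable
default tissue sweeps $\lambda: 1 \to 1.45$ and the unstable point
collapses to $\lambda \approx 0.7$ — both informative, resolvable arcs.

### Pipeline

1. **Preprocess** (`preprocess_frame()`): grayscale, contrast compressed
   50% towards mid-gray (halving the intensity range), Gaussian
   softening with $\sigma = 1$ px.
2. **Edges** (`sobel_edges()`): the 3×3 Sobel pair at interior pixels,
   magnitude $|G_x| + |G_y|$, threshold at a fraction (default 0.25) of
   the per-frame maximum; coordinates centered at the image center,
   y up. The detected band is a few pixels wide (its width tracks edge
   softness plus blur); the *gradient-weighted* mean radius localizes
   the boundary to ~0.02 px on clean frames, and that weighted mean is
   what the kinematics use.
3. **Sectors** (`sectorize()`): equal half-open angular bins
   $[\theta_{lo}, \theta_{hi})$ partitioning $[0, 2\pi)$; default 36
   (10° bins — a count that keeps tens of edge pixels per sector at the
   default geometry); empty sectors are flagged, and sectorization
   commutes with quarter-turn rotations exactly.
4. **Kinematics** (`sector_kinematics()`): per-sector mean radius,
   stretch (radius over first-frame radius — the first frame is the
   reference configuration), centered-difference radial velocity, and
   kinetic energy per area $\tfrac12 \rho_m v^2 H$. Sectors empty in any
   frame are excluded from fitting with a flag, never silently.
5. **Fit** (`fit_material_parameters()`): Levenberg–Marquardt
   (`minpack.lm`) on the momentum-balance residual: the membrane-stress
   side $2T_{el}(\lambda)/(\lambda R)$ minus the data side (inertia,
   damping and transmural pressure evaluated from the observed
   kinematics, with $\dot\lambda,\ \ddot\lambda$ from Savitzky–Golay
   filters, order 3, window 11, filter-edge samples dropped). Sign
   constraints enter through a log parameterization; $R^2$ is reported
   against the observed force signal. Fits start from the configured
   center (defaults) and the 8 corners of a ×1.5 log-cube around it;
   lowest residual wins, ties resolved towards the center.
6. **Classify** (`classify_sectors()`): each successful fit goes through
   `classify_lesion()`; failed, degenerate (no strain variation) or
   incomplete sectors are labelled indeterminate, and
   `render_overlay()` recolors edge pixels green/red/yellow for
   stable/unstable/indeterminate.

### Identifiability

The Taylor stress exposes only the two coefficients $(a_1, a_2)$, so a
single trajectory determines $(c_1, c_2, c_3)$ only up to a
one-parameter ridge; the multi-start policy resolves the ridge towards
the configured center, which is what "recovering $c_2$" means here.
This is not a defect of the optimizer but of the observation model, and
it is harmless for the scientific output: writing the equilibrium
coefficients in terms of $(a_1, a_2)$ gives
$\alpha = c_2^2\,PR/H$, $\beta = 2c_2^2(a_2^{\,*} - a_1^{\,*})$,
$\gamma = -2 c_2^2 a_2^{\,*}$ (starred quantities per unit thickness),
so $c_2^2$ is a common positive factor that cancels from every
instability inequality and from the equilibrium roots: **the stability
verdict is identifiable even though $c_2$ alone is not.** The round-trip
tests exercise both facts: median recovered $c_2$ lands within a few
percent of truth (ridge resolved at the center), and verdicts are exact
on clean stacks, ≥ 90% on mixed noisy ones (the misclassified sectors
are the two straddling a material boundary, whose pixels genuinely mix
two walls).

## Numerical choices, sizes, and degenerate inputs

* Fixed-step RK4 everywhere; $\Delta\tau = 10^{-3}$ (sweeps
  $5\times10^{-3}$ after a convergence check). Integration halts with
  explicit flags on rupture, collapse ($y_0 < 0.05$), runaway expansion
  or non-finite states.
* Oscillation metrics discard the leading 20% of a record; frequency is
  the largest spectral peak of the mean-removed, Hann-windowed stretch
  series with parabolic interpolation, ties to the lowest frequency.
* `limited_energy()` uses `expm1` so the remodelling signal survives
  $w \ll H\Phi$ without catastrophic cancellation.
* The common breathing period is found by continued-fraction
  rationalization of frequency ratios (denominators up to $10^6$);
  incommensurate inputs raise an error rather than returning a
  pseudo-period.
* Test and sweep problem sizes: stiffness sweeps integrate 56 runs to
  $\tau = 500$; criterion/numeric-sign consistency draws $10^3$ random
  parameter sets ($10^4$ for the sign-exclusion property); imaging round
  trips use
  64-frame, 384² stacks at 36 sectors. These sizes were chosen so each
  check resolves what it measures (several natural periods, both
  criteria firing non-vacuously, tens of pixels per sector).

## Known limitations

* Isotropic, spherical, axisymmetric: no anisotropy, nonspherical
  geometry or gravity; valid for small boundary patches.
* The stability theory addresses the autonomous approximation; no
  Floquet analysis of the periodically forced system is attempted (the
  forcing modulation is ~0.3% of the mean here).
* Erratic (non-sinusoidal) breathing is out of scope.
* The energy limit $\Phi$, the elastin stiffness $b_e$ and the
  remodelling rate units are not experimentally constrained; results
  that depend on them (rupture time, escape time) are qualitative.
* The imaging fixtures do not model CT acquisition physics, and the
  fitted $c_2$ is a ridge-resolved representative, not an independent
  measurement (the verdict is the identifiable quantity).
* No DICOM ingestion; frames enter as PNG stacks with a JSON sidecar.
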