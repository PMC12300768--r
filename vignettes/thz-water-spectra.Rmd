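---
title: "Computing THz absorption spectra of water models from collective dipole dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing THz absorption spectra of water models from collective dipole dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzwater)
```

## The observable and the two routes to it

The far-infrared/THz absorption of a polar liquid is governed by the
fluctuations of the collective rotational dipole moment
$\vec M_D(t) = \sum_i \vec\mu_i(t)$, the vector sum of all molecular dipoles
in the simulation box.  The quantity experiments report, the product of the
absorption coefficient and the real refractive index, follows from the
one-sided (Laplace) cosine transform of either the moment autocorrelation
$\Phi_D(t) = \langle \vec M_D(0)\cdot\vec M_D(t)\rangle$ or the
autocorrelation of the rotational current
$\vec J_D(t) = d\vec M_D/dt$:

$$\alpha(\omega)\,n'(\omega)
  = \frac{\omega^2}{3 V k_B T c\,\epsilon_0}\int_0^\infty \Phi_D(t)\cos(\omega t)\,dt
  = \frac{1}{3 V k_B T c\,\epsilon_0}\int_0^\infty
    \langle \vec J_D(0)\cdot\vec J_D(t)\rangle\cos(\omega t)\,dt .$$

`spectrum_from_moment()` implements the first form and
`spectrum_from_current()` the second.  The $\omega^2$ factor of the moment
route amplifies any baseline error parabolically, which is why the current
route is the package default throughout (`run_pipeline()` uses it).  The two
only coincide when $\Phi_D$ is a legitimate autocorrelation of a
differentiable process — in particular $\dot\Phi_D(0)=0$; for a bare damped
cosine (which has a kink at $t=0$) they differ by a constant baseline
$\dot\Phi_D(0)$ times the prefactor, and the test suite asserts equivalence
on the physical underdamped family
$e^{-\gamma t}\left(\cos\omega_1 t + \tfrac{\gamma}{\omega_1}\sin\omega_1 t\right)$.
Choosing the Laplace convention means no factor of two is applied; that
factor (which enters when the transform is written over the whole real line)
is owned by the spectra module and documented here so decompositions remain
comparable.

`permittivity()` evaluates
$\hat\epsilon(\omega)-\epsilon_\infty =
\left[\langle M_D^2\rangle + i\omega\int_0^\infty\Phi_D e^{i\omega t}dt\right]
/(3Vk_BT\epsilon_0)$, with the static value taken from the
$\langle M_D^2\rangle$ term alone.  $\epsilon_\infty$ is an *input* (default
1.0); nothing in the method fixes it.  Internal consistency,
$\alpha n' = (\omega/c)\,\epsilon''$, is asserted to $10^{-9}$ relative in
the tests.

**Numerical choices.**  The transform is a direct trapezoid cosine
quadrature over the retained lag window with an Euler–Maclaurin end
correction (the end slopes estimated by one-sided $O(\Delta t^2)$
differences).  There is no zero padding of the correlation tail and no taper
by default, consistent with the baseline-free rationale for the current
route; with the correction the Lorentzian closed form is reproduced to
better than 0.1% at $\Delta t = \tau/100$ for $\omega\tau \le 10$.  Units
are Å, ps, e and Debye internally, with 1 e·Å = 4.80321 D, spectra in
cm$^{-1}$, and $\bar\nu = \omega/(2\pi c)$.

## Decompositions

Two orthogonal splits of the current correlation are provided:

* **self/cross** (`self_cross_split()`):
  $C_{self}$ sums each molecule's own current autocorrelation (molecules are
  statistically equivalent, so per-molecule correlations are averaged and
  summed); $C_{cross} = C_{total} - C_{self}$.  Subtraction avoids the noisy
  $O(N^2)$ pair double sum, which is retained in the test suite as the
  oracle that the subtraction is exact.
* **permanent/induced** (`perm_ind_split()`): the *total* current is
  correlated against its permanent and induced parts, so only two
  contributions arise and $C_{perm}+C_{ind}=C_{total}$ holds exactly by
  linearity of the estimator.

Correlation estimates use FFTs with unbiased per-lag normalization and a
default maximum lag of half the series (cross terms grow noisy at long lag).
Currents are formed by central differences of the stored dipole series —
not charge-weighted atomic velocities, since trajectories may not carry
velocities — with one-sided endpoint values excluded from estimation.

## Electrostatic models

The bundled parameter files (`inst/extdata/water_models/`) mirror the
published electrostatics of SPC/E, SWM4-NDP, IPOL-0.13, OPC3-pol and
AMOEBA14 field for field, plus the CHELPG charge set of a water dimer.
Bond lengths that the charge tables do not determine are shipped as named
constants from the cited model definitions (SPC/E 1.0 Å, SWM4-NDP
0.9572 Å, OPC3 0.97888 Å, AMOEBA14 equilibrium 0.9565 Å); IPOL-0.13's bond
length is not published alongside its charges, and 1.0 Å is adopted as the
value consistent with its reported 1.86 D permanent dipole (tests on this
model are tolerance-based, ±0.02 D).

Local atomic frames for distributed multipoles follow the AMOEBA
conventions: oxygen $z$ along the H–O–H bisector with $x$ in-plane;
hydrogen $z$ pointing from H to O with $x$ in-plane pointing inward; $y$
completes right-handed frames ("up" for O and H1, "down" for H2).  These
sign conventions are *uniquely* fixed by reconstructing the 1.71 D AMOEBA14
monomer dipole from charges plus rotated atomic dipoles: flipping the O
dipole gives 1.39 D and flipping the hydrogen $x$ components gives 2.54 D,
and the test suite enumerates all alternatives by brute force.  Atomic
quadrupoles are stored as printed and divided by three
(`quadrupole_scale_convention: one_third`) when lab-frame tensors are built,
matching the convention of the simulation engines that consume them; the
trace (zero by definition, up to the 0.001 D·Å rounding of the printed
values) is preserved under rotation.

Two tabulated values do **not** reconstruct from their printed charges and
are deliberately not asserted: the OPC3-pol "permanent" dipole of 2.05 D
(the printed charges give 1.66 D at the OPC3 geometry — the
permanent/induced partition of this model is ambiguous, and this package
treats the printed site charges as the permanent set, with the partition
exposed through `set_site_polarizability()`); and the dimer monomer dipoles
of 2.37/2.35 D (the optimized dimer geometry is unpublished and the
monomers carry ±0.043 e of transferred charge, so their dipoles are
origin-dependent — the tests assert a plausible 2.0–2.4 D band about each
monomer's center of mass).  Similarly, the SPC/E charge set yields 2.3517 D
with this package's conversion constant, matching the tabulated 2.35 D;
the occasionally quoted 2.36 D is attributed to rounding under a slightly
different constant.

## Induced dipoles

Drude models carry a *physical* induced dipole $\mu = q_D \vec d$ read
directly from the Drude pair displacement (`drude_induced()`).  Multipole
models and post-hoc polarization use *mathematical* point dipoles solved
self-consistently:
$\mu_i = \alpha_i\big(E^0_i + \sum_{j\neq i} T_{ij}\,\mu_j\big)$ with the
dipole–dipole tensor $T(r) = (3\hat r\hat r^T - I)/r^3$.

Design decisions a user should know:

* **Intramolecular exclusions.**  The self-consistent field excludes all
  same-molecule permanent sources and (by default) same-molecule mutual
  induction — the only choice under which an isolated rigid molecule is
  field-free.  A flag re-enables intramolecular induction for multi-site
  polarizable models.
* **Field sources.**  $E^0$ defaults to permanent *charges* only; atomic
  dipole and quadrupole sources can be switched on
  (`polar_options(field_sources=)`).  Charges-only is the documented
  default because that is the minimal reading of the field definition;
  the dipole/quadrupole field terms are validated against a numerical
  gradient of the multipole potential.
* **Interaction damping.**  The bare tensor diverges when
  $2\alpha/r^3 \ge 1$; the solver detects divergence (growing residuals or
  a singular system) and raises a "polarization catastrophe" error naming
  the closest polarizable pair.  Thole exponential damping
  ($\lambda_3 = 1-e^{-au^3}$, $\lambda_5 = 1-(1+au^3)e^{-au^3}$,
  $u = r/(\alpha_i\alpha_j)^{1/6}$, default $a=0.39$) is available and
  recommended for dense-liquid post-trajectory polarization; the bare
  tensor remains the default because it is the form the method defines.
* **Solvers.**  Damped fixed-point iteration (mixing 0.7, tolerance
  $10^{-6}$ D, cap 200 iterations, warm-started across frames) and a direct
  $(I-\alpha T)$ solve; the two agree to $10\times$ the tolerance on
  hundreds of random clusters in the tests, and the fixed point converges
  in well under 15 iterations on liquid-like configurations.
* **Boundaries.**  Open cluster, or cubic minimum image with a real-space
  cutoff (default 9 Å) and a smooth $\cos^2$ switching band; Ewald-type
  dipolar sums are out of scope.  A minimum-image run whose configuration
  fits inside the cutoff reproduces the open cluster exactly.

`post_trajectory_polarization()` applies the solver frame by frame to a
trajectory from a non-polarizable model (e.g. SPC/E with an elevated oxygen
polarizability of 1.14 Å$^3$ attached via `set_site_polarizability()`), so
the induced channel and its spectral contribution can be studied even when
no polarization existed during trajectory production.  Polarizability
scaling experiments (e.g. $0.98\ \text{Å}^3 \times 1.2 = 1.176$) go through
`scale_polarizability()`, which rescales the stored effective
$\alpha = q_D^2/k_D$ for Drude models.

## The synthetic librator

Real multi-nanosecond MD of liquid water is out of reach for a test suite,
so the generator provides a *dipole-fluctuation model* with exactly known
statistics.  Each molecular dipole component is an independent stationary
Gaussian process: a superposition of exactly discretized damped oscillators
(complex Ornstein–Uhlenbeck processes, which have autocorrelation
$e^{-\gamma t}\cos\omega t$ with no integrator drift at any admissible
$\Delta t$) plus an exponential orientational-diffusion mode.  The
collective autocorrelation is therefore *exactly*

$$\Phi_D(t) = N\mu_0^2\Big[\sum_k a_k e^{-\gamma_k t}\cos(\omega_k t)
  + a_0 e^{-t/\tau_r}\Big]$$

at the sample times, and `librator_phi()` / `librator_cjj()` expose the
closed forms (the latter as the second central difference of $\Phi_D$,
i.e. the exact expectation of the package's own derivative estimator).

Defaults were chosen once, as a caricature of the liquid-water THz
landscape: modes at 200 cm$^{-1}$ ($a=0.65$) and 650 cm$^{-1}$ ($a=0.10$)
with damping 10 ps$^{-1}$ (half-widths ≈ 53 cm$^{-1}$, typical THz line
widths), a diffusive remainder $a_0 = 0.25$ with $\tau_r = 8$ ps,
$\mu_0 = 2.35$ D, 64 molecules in a 12.42 Å box, $\Delta t = 1$ fs (the
generator refuses time steps with $\omega_k\Delta t > 0.5$).  The amplitude
asymmetry compensates the $\sim\omega^2$ weighting of the current route so
the two spectral peaks appear at the experimentally observed ≈ 0.65 height
ratio.  Molecules are dynamically independent by design — cross
correlations vanish in expectation, giving a sharp statistical test of the
self/cross split — and `shared_mode_amplitude` adds one mode driven
identically in all molecules to produce a nonzero cross term of known
magnitude $N(N-1)\,a_s\mu_0^2$.

What the generator does *not* emulate: liquid structure (no packing
correlations, no hydrogen-bond network), anharmonicity, and any coupling
between orientation and the polarization solver.  Passing the recovery
tests therefore demonstrates correctness of the analysis chain, not
realism of any water model.  Coordinates emitted by
`librator_trajectory()` orient a rigid reference molecule along each
instantaneous dipole direction; since a rigid molecule has fixed dipole
magnitude, the coordinate route carries the direction but not the magnitude
fluctuations and is used for I/O tests, while statistical tests consume the
dipole series directly.

The end-to-end recovery check runs 8 molecules for $2^{20}$ frames (~1 ns)
at 1 fs, correlates over a 1 ps window, and evaluates the spectrum on a
0–1200 cm$^{-1}$ grid with 10 cm$^{-1}$ steps — sizes picked so both modes
are resolved with comfortable statistics.  Recovered peak positions match
the closed-form oracle (pushed through the identical truncation, transform
and smoothing) to one grid step, peak-height ratios to 5%, and
`classify_200cm_peak()` reports a genuine maximum.

## Spectral presentation conventions

`smooth_and_scale()` applies Savitzky–Golay smoothing (window 21 points,
order 3 by default — the filter reproduces polynomials up to its order
exactly and preserves peak shapes) and optional scaling by the channel
maximum, recording both in the spectrum's metadata.
`classify_200cm_peak()` operationalizes the yes/shoulder/no taxonomy of the
low-frequency feature: a strict local maximum in 150–300 cm$^{-1}$ is a
peak; failing that, a strict local minimum of the first derivative there
(an inflection plateau on the rising librational flank) is a shoulder;
otherwise the feature is absent.  Band edges are arguments, not constants.

## Scope and limitations

The package analyses trajectories; it does not produce them (no MD engine,
no Drude thermostating, no forces or virials).  Multi-model PDB is the
native text round-trip format; DCD is read against a PDB topology; XTC/TRR
are rejected with a clear error since no reader is available.  Molecules
must be whole across periodic boundaries — a bonded O–H distance above
1.5 Å aborts dipole extraction.  Flexible-geometry electrostatics are
evaluated at the frame coordinates, but AMOEBA14 is represented by its
equilibrium monomer geometry in the bundled file; intramolecular
flexibility of the real model is not reproduced.  The interface of this
package is its functions and `run_pipeline()`; pipeline runs write every
intermediate (correlation functions, spectra, provenance log) as plain
text, and identical configurations with identical seeds produce
byte-identical outputs.
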