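---
title: "Methods: transport, diffusion, and Monte Carlo models for layered turbid media"
author: "layerlux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transport, diffusion, and Monte Carlo models for layered turbid media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The physical problem

`layerlux` computes how light injected by a collimated beam propagates
through a plane-parallel stack of scattering, absorbing, and possibly
fluorescent layers — the standard forward model for diffuse optics of
skin, subcutaneous fat, muscle, and similar layered tissues. The governing
equation is the radiative transport equation (RTE) for the radiance
$I(\mathbf r,\hat s)$,

$$\hat s\cdot\nabla I + \mu_t I
  = \mu_s \int I(\mathbf r, \hat s')\, f(\hat s\cdot\hat s')\, d^2 s'
  + S(\rho)\,\delta(z)\,\delta(\hat s - \hat z),$$

with total attenuation $\mu_t=\mu_a+\mu_s$ and a rotationally symmetric
single-scattering phase function $f$. Units are fixed package-wide to
millimetres and picoseconds, with $c = 0.299792458$ mm/ps.

Each layer carries its own $\mu_a$, $\mu_s$, phase function, refractive
index, and thickness; only the last layer may be semi-infinite. At the
illuminated surface the upward radiance is partially reflected back
according to the unpolarized Fresnel probability $R(\mu)$; at internal
index steps the radiance satisfies the bidirectional Fresnel conditions
with Snell-refracted direction cosines and the $n^2$ radiance scaling. The
incident beam is perpendicular and axisymmetric; the default is Gaussian,
$S(\rho) = \tfrac{2}{\pi\rho_w^2} e^{-2\rho^2/\rho_w^2}$, whose transverse
spectrum is $\tilde S(q) = e^{-q^2 \rho_w^2/8}$.

# The spherical-harmonics (PN) solution

## Spectral structure

After a 2-D Fourier transform in the lateral coordinates (reducing, for
axisymmetric problems, to a Hankel transform of order zero) and a Laplace
transform in time (entering only through the substitution
$\mu_a \to \mu_a + s\,n/c$ per layer), the PN-truncated transport operator
admits plane-wave solutions $V(\hat s)\,e^{i q x + \kappa_z z}$. Writing
$\nu^2 = \kappa_z^2 - q^2$ and rotating the angular frame onto the complex
propagation vector, the eigenproblem separates into one symmetric
tridiagonal pencil per azimuthal family $m$,

$$\nu\,(T^{(m)} u)_\ell + \sigma_\ell u_\ell = 0,\qquad
  \sigma_\ell = \mu_a + \mu_s (1 - f_\ell),$$

with the standard normalized associated-Legendre coupling coefficients on
the off-diagonals and the Legendre moments $f_\ell$ of the phase function
($f_0 = 1$, $f_1 = g$). The crucial property is that the eigenvalues
$\nu_j$ do not depend on the transverse frequency: the decomposition is
performed once per layer (and per Laplace node), and the vertical decay
constants follow analytically as $\lambda_j(q) = \sqrt{\nu_j^2 + q^2}$.
For odd order $N$ the decaying modes number exactly $(N+1)^2/4$.

Mode shapes are evaluated in the laboratory frame by analytic continuation
of the associated Legendre functions to the complex rotation; because all
angular factors reduce to polynomials in the direction cosines, no Wigner
rotation recursions (with their well-known large-degree instabilities) are
needed. A property test verifies that every constructed mode annihilates
the PN-projected transport operator on a dense spherical quadrature.

## Boundary conditions

The surface, interface, and bottom conditions are imposed in Marshak form:
each condition is projected onto the half-range test set
$\{P_\ell^m(\mu)\cos m\varphi : \ell \le N,\ m \le \ell,\ \ell - m\
\text{odd}\}$, whose size equals the number of unknown mode amplitudes —
the closure is exactly square for every layer count. Half-range Fresnel
integrals are computed by Gauss–Legendre rules split at the critical
cosine (64 points by default; results change by less than $10^{-5}$
relative against 128). The first-scatter source of the attenuated
collimated beam enters as a particular solution; it is solved in the
laboratory spherical-harmonic basis, where the operator
$iqB_x - \gamma A_z + \mathrm{diag}(\sigma_\ell)$ stays bounded for every
$(q,\gamma)$ — the rotated-frame construction degenerates removably at
$q \to \mu_t$. True resonances (a source exponent coinciding with a mode
eigenvalue) are handled by a relative $10^{-5}$ detuning of the source
exponent, which reproduces the limiting solution to the same order.

Reflectance is the net upward flux of the diffuse field at $z=0$ (the
specularly reflected fraction of the beam is reported separately and
excluded); with the Fresnel surface condition enforced, the net-flux and
Fresnel-weighted exit-radiance definitions coincide for the diffuse part.

## Precision

At large transverse frequency the decaying modes of one azimuthal family
become nearly collinear and the boundary system loses rank in double
precision — high approximation orders and weakly scattering layers
(relative to $1/\rho_w$) make this worse. The `precision = "extended"`
configuration runs the whole per-frequency pipeline (mode evaluation,
Marshak projection, elimination, functionals) in 80-bit extended
arithmetic, which defers the breakdown far beyond the frequencies that
contribute to the Gaussian-beam fixtures. Double precision is the default
and is sufficient for every computation in the test suite; the extended
path is cross-checked against it in the healthy regime.

# Transform inversions

*Spatial domain.* $R_s(r)$ is the order-zero inverse Hankel transform of
$\tilde R(q)$, computed with panel Gauss–Legendre quadrature whose panel
widths resolve both the Bessel oscillation at the largest radius and the
intrinsic $q$-variation of layered reflectance amplitudes; slowly decaying
spectra are finished with a Longman-type accelerated alternating series
over half-period tail panels. The three closed-form oracle pairs (Gaussian,
modified-Bessel, Gaussian beam profile) are reproduced to better than
$10^{-8}$.

*Time domain.* $R_t(r,t)$ is obtained by numerical Laplace inversion with
one time-independent node set per window (windows are capped at a 12:1
dynamic range). The `hyperbolic` contour preset (family
$s(u) = s_0 + a(1-\cosh u) + i b \sinh u$, wide opening, trapezoidal
summation with conjugate symmetry) is used for the diffusion equation,
whose singularities hug the negative real axis, and was calibrated once
against elementary transform pairs ($1/(s+a)$ to $10^{-8}$,
$e^{-a\sqrt s}$ to $10^{-6}$) and frozen. The transport dispersion,
however, carries branch-type structure *off* the real axis: mapping the
minimal mode margin $\min_j |\mathrm{Re}\,\lambda_j|/|\lambda_j|$ over
the complex $s$-plane shows cut-like bands throughout
$\mathrm{Re}\,s \lesssim -\mu_a c/n$, reaching large
$\mathrm{Im}\,s$. Transport time curves therefore use a two-part scheme
(`type = "auto"`): early windows ($t <$ 1 ns), where the signal is
broadband, are inverted on a plain vertical Bromwich line (analyticity is
guaranteed right of the axis) with the frequency truncation adapted to the
spectrum's own diffusive decay and a cosine taper against onset ringing;
later windows use the flattened `two_part` contour with nearly vertical
arms (slope 0.3), whose leftward reach $\sim 30/t_{\min}$ then stays
inside the cut-free gap next to the imaginary axis. The hybrid was
verified against a dense (about 1000-node) vertical-line reference
inversion to $10^{-4}$ relative.

Two self-checks guard every time-domain computation: negative undershoot
beyond $10^{-4}$ of the curve peak aborts the run (values are reported,
never clipped), and the steady-state identity
$\int_0^\infty R_t(r,t)\,dt = \tilde R(r, s{=}0)$ is enforced in the test
suite to 0.5%. At the 0.5 mm-beam study conditions this closure holds to
0.1–0.3% at source-detector separations of a few millimetres; at 10 mm a
residual near 2% remains that is invariant under every inversion control
(contour family, damping, node density, taper, window sizes, quadrature
orders, time-grid refinement) and therefore reflects the accuracy floor of
the inverted time curves for far detectors at desk scale, not a property
of the frequency-domain solution.

# The layered diffusion comparator

The diffusion solver works in the same $(q,s)$ domain with per-layer
$\alpha_k^2 = \mu_{a,\mathrm{eff}}/D_k + q^2$ and hyperbolic fundamental
solutions (scaled exponentials; layer merging holds to $10^{-10}$). The
beam is represented by an isotropic point source at
$z_0 = 1/(\mu_a + \mu_s')$. Because the underlying reference formulations
differ in several small conventions, these are explicit options
(`de_options()`), with defaults:

- $D = 1/(3(\mu_a + \mu_s'))$ (option: $1/(3\mu_s')$);
- extrapolated-boundary condition, $\Phi = 0$ at $-z_b = -2AD$ with $A$
  from the Fresnel reflection moments (option: Robin partial-current);
- reflectance from the Fresnel-weighted hemispheric exit radiance,
  $R = \tfrac{C_\Phi}{4}\Phi(0) + \tfrac{C_j}{2} D\,\partial_z\Phi(0)$
  (option: net flux $D\,\partial_z\Phi$; the two coincide exactly under
  the Robin condition).

The defaults were fixed by requiring the classic qualitative behaviours of
diffusion theory against transport on the tissue fixtures: failure at
early times and short distances, validity at late times, blindness to the
phase function at fixed $\mu_s'$, collapse when a layer is thinner than
its transport length, and the characteristic large-distance crossover
between the layered DE and transport curves (at 21.5 mm for the
three-layer model, with the exact transport decay constant
$\nu_{\min} = 0.17511\,\mathrm{mm}^{-1}$ of the bottom layer bracketed by
the two $D$ conventions). Under the Robin/flux/$1/(3\mu_s')$ choices no
crossover occurs out to 30 mm — this sensitivity is a genuine property of
the comparison, not of the transport solver, and is why the conventions
are documented options rather than hard-coded. The sensitivity also shows
up in the time domain: with the default conventions the DE runs 6–8% above
$P_3$ at $r = 2$ mm for $t \gtrsim 0.5$ ns (other conventions reduce this
to 1–4% but lose the crossover), so the classic "diffusion is valid at
late times" statement holds at the five-to-ten-percent level, with the
exact figure depending on the DE variant, not on the transport solution.

When the top-layer transport length exceeds its thickness the source depth
is clamped to the layer with a warning; diffusion results are meaningless
in that regime regardless.

# Fluorescence

The coupled problem is solved in two stages: the excitation field at
wavelength $x$, then an emission solve at wavelength $m$ driven by the
isotropic source $\Phi_e\,\mu_{ax}\,\Phi_x(q,z)/4\pi$ per layer. Because
the excitation fluence is an exact sum of exponentials in depth (including
the unscattered beam, which is deliberately part of $\Phi_x$), each term
yields one lab-frame particular solution of the emission system; the same
Marshak machinery closes the emission boundary problem. Emission output is
exactly linear in each layer's quantum yield. Re-absorption cascades
(emission light re-exciting fluorophores) are not modelled, and the index
is wavelength independent. The diffusion backend mirrors this two-stage
structure on the DE sublayer decomposition.

Because the emission sources are isotropic and distributed, the
approximation order needed for a given accuracy is much lower than for the
collimated elastic problem — the suite verifies that the $P_3$-to-$P_9$
change of the emission curve is smaller than the elastic counterpart, and
that even $P_1$ emission lies closer to high-order transport than the
diffusion backend.

# Analog Monte Carlo

The MC module is the package's internal oracle: unweighted photon-by-photon
transport with exponential free paths (residual optical depth carried
across layer crossings), analog absorption/scattering decisions, exact
Fresnel reflection/refraction at every boundary, and tallies of escape
radius and optical path time $\sum n_k \ell_k/c$. Henyey–Greenstein and
Reynolds–McCormick deflections use closed-form inverse CDFs; Rayleigh and
tabulated kernels use a monotone-cubic inverse-CDF table of $2^{14}$
points. Fluorescence is simulated directly: at each absorption event in a
fluorescent layer an emission photon is launched isotropically from the
site with the layer's yield and transported with the emission properties —
no convolution step. The RNG is a counter-based splitmix64 keyed by (seed,
photon index), so every run is exactly reproducible. Photon accounting is
an integer identity (specular + reflected + transmitted + absorbed + guard
= launched) asserted on every run; a track-length estimator provides
fluence maps whose absorption integral closes the energy balance to better
than 0.2%.

Analytic curves are always compared to MC tallies bin-averaged with the
annular area weight, never at bin midpoints.

# Problem sizes and what the tests show

The suite runs desk-scale versions of the reference computations: MC runs
of $10^6$–$10^7$ photons (the reference curves used $10^{11}$), time-domain
fixtures with 40-node contour windows and a $q$-grid truncated where the
beam spectrum falls below $10^{-6}$, and order-convergence checks at
$N = 9/19/29$ on a reduced radius set. Statistical tolerances carry the
corresponding allowances (e.g. the $P_3$-vs-MC time-domain check requires
the median relative deviation over bins with standard error below 0.5% to
stay around the percent level). These comparisons validate the numerical
chain end to end on generic layered tissue models; they do not, of course,
certify any particular biological tissue parameterization.

# Known limitations

- Perpendicular incidence and axisymmetric beams only; oblique incidence
  would require the full transverse-Fourier treatment of all azimuthal
  source orders.
- Unpolarized transport throughout; no polarization-resolved Fresnel
  coefficients.
- Secondary ballistic reflections at index-mismatched internal interfaces
  are neglected (exactly zero for the index-matched internal interfaces of
  the bundled models).
- Angular-resolved exit radiance is not an output; reflectance is the net
  diffuse flux.
- Double precision degrades at high order combined with weak scattering or
  very large transverse frequencies; the extended path extends, but does
  not eliminate, that limit.
- The fluorescence model is single-step (no re-absorption cascade, no
  finite lifetime kinetics).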