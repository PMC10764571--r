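---
title: "Turing instabilities in coupled bilayer reaction-cross-diffusion systems: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turing instabilities in coupled bilayer reaction-cross-diffusion systems: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayerTuring)
```

## The model

Developing skin is a layered tissue: a thin epidermis sits on a deeper
dermis, and the periodic structures that appear there (hair follicle and
feather primordia) emerge at the interface between the two. This package
analyses the canonical mathematical abstraction of that situation: two
active reaction-cross-diffusion systems, a 1D *surface* with $n$ species
$u_S$ and a *bulk* with $m \ge n$ species $u_B$, which exchange their
first $n$ species linearly across the interface with strength
$\eta \ge 0$,

$$\partial_t u_S = f_S(u_S) + \eta A(\tilde u_B - u_S)
  + \nabla\cdot(D_S \nabla u_S),$$

with the analogous equation (exchange matrix $\tilde B$, the zero-padded
$n \times n$ matrix $B$) for the bulk. Two geometries are covered: a
thin-bulk limit in which both layers are 1D intervals of length $L$
("1d1d"), and a bulk rectangle $[0,L]\times[0,H]$ whose top edge carries
the surface line, with the transport law
$D_B \partial_y u_B = \eta \tilde B(\tilde u_S - u_B)$ at the interface
("1d2d"). Chemotaxis is included as a state-dependent lower-triangular
block of the bulk diffusion matrix: cells $c$ drift up gradients of a
chemoattractant with flux $-\nabla\cdot(h(c)\nabla k(u))$, $h(c)=\chi c$,
$k(u)=u_1$.

The package answers one question in several asymptotic regimes: *when
does coupling two layers create or destroy a Turing (diffusion-driven)
instability that neither, or one, of them has on its own?*

## Linear stability machinery

Perturbing a homogeneous equilibrium with cosine modes
$\cos(k_q x)e^{\lambda t}$, $\xi = k_q^2$, gives a block dispersion
matrix. In the 1d1d geometry its determinant is a polynomial of degree
$n+m$ in $\lambda$; `char_poly_1d1d()` recovers its coefficients by
evaluating the determinant at $n+m+1$ Chebyshev-spaced samples and
interpolating, which avoids both symbolic algebra and any reliance on an
eigenvalue solver (eigen-decompositions serve as the *independent oracle*
in the test-suite instead). Mode stability is decided by the
Routh-Hurwitz criterion on those coefficients (`routh_hurwitz_stable()`);
marginal cases — any Hurwitz minor within `1e-10` of zero after
normalising the coefficients by their largest magnitude — are reported
*unstable*, so instability regions are closed sets.

In the 1d2d geometry the bulk factor is transcendental. All of it can be
written in terms of three entire functions of the matrix
$R_0 = D_B^{-1}(\xi D_B - J_B)$:

$$F_1(H,R) = \sum_{k\ge1}\frac{H^{2k-1}}{(2k-1)!}R^k,\qquad
  F_2(H,R) = \sum_{k\ge0}\frac{H^{2k}}{(2k)!}R^k,$$

(the analytic continuations of $\sqrt R\sinh(H\sqrt R)$ and
$\cosh(H\sqrt R)$), plus a third series $\tilde F_2$ appearing in
parameter derivatives. These are functions of $R$ itself, so no matrix
square root is ever formed — which matters because at a two-species
critical point $R_0$ is *nilpotent* ($R_0^2 = 0$) and has no square root
at all. `matrix_entire_functions()` sums the series directly when
$H^2\|R\|_F \le 25$ or when $R$ is numerically nilpotent, and otherwise
scales $H$ down and applies the doubling identities
$F_2(2H) = 2F_2(H)^2 - I$, $F_1(2H) = 2F_1(H)F_2(H)$, which remain valid
for defective matrices; $\tilde F_2$ has no doubling identity and falls
back to a spectral evaluation, returning `NA` for near-defective
large-argument cases (it is not needed on any critical path). Because no
standard analogue of Routh-Hurwitz exists for transcendental dispersion
relations, 1d2d stability claims are limited to marginal ($\lambda = 0$)
curves plus simulator verification; full root-finding in $\lambda$ is not
attempted.

## Equilibria

In the 1d1d geometry the two layers may sit at *different* homogeneous
equilibria, which then depend on $\eta$. `coupled_equilibrium()` tracks
the branch continued from the uncoupled ($\eta = 0$) equilibria by Newton
continuation with an adaptive step (initial step $10^{-3}$, halved on
failure, capped at 1 and at the remaining distance); only this branch is
tracked, since neither existence nor uniqueness of other branches is
guaranteed in general. The derivative of the branch at $\eta = 0$,
$u_S^{*\prime}(0) = J_S^{-1}A(u_S^* - \tilde u_B^*)$, feeds the
asymmetric-equilibria term of the weak-coupling slope. In the 1d2d
geometry the interface forces a shared equilibrium, so the solver instead
verifies that both reaction terms vanish at the same point (tolerance
$10^{-10}$) and refuses otherwise.

## Bifurcation analysis

A Turing bifurcation of the coupled system solves
$a_0(\xi_c,\delta_c) = 0$, $\partial_\xi a_0 = 0$, where
$a_0(\xi) = \det M(\lambda{=}0,\xi)$ and $\delta$ is any scalar
bifurcation parameter (a diffusion coefficient or $\chi$, selected
through the override hook `set_param()`). `critical_point()` solves this
2-by-2 system by Newton iteration with finite-difference derivatives
($\partial_\xi$ step $10^{-6}(1+\xi)$), warm-started from the classical
uncoupled value; additional $\xi$-minima are enumerated by sign changes
of $\partial_\xi a_0$ on a 64-point log-spaced grid over
$[10^{-4}, 10^2]$ and the branch with the smallest $\delta_c$ is
reported as the global onset. `continue_critical_curve()` continues the
solution in $\eta$ with warm starts and adaptive sub-stepping on
failure. Natural continuation (rather than pseudo-arclength) proved
sufficient for every system studied here because $\delta_c(\eta)$ is
single-valued in $\eta$ even where it is non-monotone; a fold in $\eta$
would require re-parametrising, which the interface deliberately leaves
open.

The classical single-layer critical diffusion uses the closed form
$\delta_c = d_u\big((\sqrt{f_ug_v - f_vg_u} + \sqrt{-f_vg_u})/f_u\big)^2$
for two-species reaction-diffusion layers, and otherwise (three or more
species, chemotaxis) locates the smallest $\delta$ at which
$\min_{\xi>0}\det(\xi D - J)$ reaches zero: the determinant is a
degree-$m$ polynomial in $\xi$ (recovered by interpolation), its
stationary points are roots of the derivative polynomial, and the onset
is bracketed on a geometric $\delta$ grid and bisected to relative
tolerance $10^{-6}$. One deliberate looseness: the closed form is
returned *with a warning* when the kinetics are unstable at $\xi = 0$
(positive trace), because reference parameter sets in this literature
occasionally violate the precondition while still quoting the closed-form
value; the warning keeps the check visible without making those systems
unusable.

Weak coupling: the slope of the marginal curve at zero coupling is
evaluated from the first-order formulas
$$\delta_c'(0) = -\frac{\mathrm{co}(P_0)\cdot A +
  u_S^{*\prime}(0)\cdot\nabla_{u^*}|P_0|}{\partial_\delta|P_0|}$$
(surface-driven 1d1d; the bulk-driven and 1d2d variants swap the blocks
and add the interface factor $F_2(H,R_0)$). The cofactor matrix enters
through Jacobi's formula and is computed from signed minors so that it
remains valid at the exactly singular $P_0$ of a critical point. For two
identical layers with diagonal exchange $\mathrm{diag}(\alpha,\beta)$
this reduces to
$\delta_c'(0) = \frac{\alpha\delta_c}{\xi_c}(1 - \frac{\beta/\alpha}{\delta_c})$:
equal exchange rates always *oppose* patterning, while a sufficiently
large inhibitor exchange rate $\beta$ flips the sign and lets two
independently non-patterning layers pattern.

Strong coupling: for $\eta \to \infty$ the layers lock together and obey
$(A^{-1}+B^{-1})\partial_t u = A^{-1}f_S + B^{-1}f_B + \dots$; for equal
two-species layers with $A = B$,
$\delta_c(\infty) = 2\delta_c[(f_S+f_B)/2] - d_{v_B}$. Whether strong
coupling can stabilise two patterning layers or destabilise two
non-patterning ones reduces to the midpoint convexity of
$\delta_c[\cdot]$ over kinetics (`midpoint_convexity_verdict()`, equality
tolerance $10^{-9}$): Schnakenberg pairs are always on the "can pattern"
side, while the linear $J_p$ family ($\delta_c = 1 + p + 2\sqrt p$,
concave in $p$) is on the "can stabilise" side. Finally, intermediate
coupling can destabilise the *homogeneous* mode: for identical layers
with $A = B = \mathrm{diag}(\alpha, \beta)$ the $\xi = 0$ mode is
unstable exactly between the roots of
$4\alpha\beta\eta^2 - 2(\alpha g_v + \beta f_u)\eta + |J|$
(`homogeneous_mode_band()`), a non-Turing route to instability that the
raster scans of `instability_region()` pick up as well.

## Simulator

`simulate_1d1d()` and `simulate_1d2d()` integrate the full nonlinear
systems with a first-order IMEX scheme: diagonal diffusion implicit
(Thomas solves; dimensional splitting in 2D), reactions, exchange and
chemotaxis explicit. The default `dt = 0.01` is halved (up to four
times, restarting from the initial data) when any field exceeds $10^8$
times the equilibrium scale. The interfacial Robin flux enters the top
bulk cell through its ghost-point value with the exchange term lagged
explicitly. The chemotactic drift uses donor-cell upwind fluxes on faces
(the advected density is taken from the side the drift comes from): a
centred face average of $h(c)$ is marginally more accurate near
equilibrium but generates negative cell densities once aggregation
spikes sharpen, after which bulk-driven chemotaxis runs blow up at any
time step, while the upwind flux keeps the density nonnegative by
construction, as is standard for Keller-Segel-type solvers. No
positivity clamp is applied to any species — positivity of the chemical
fields must emerge from the clipped kinetics, which makes it a
meaningful test rather than an enforced constraint. Initial data are
the homogeneous equilibrium
perturbed multiplicatively by uniform noise in $[-1,1]\times$
`init_noise` (default $10^{-2}$), drawn from a user seed so runs are
bit-reproducible. Integration stops early when the maximum relative
field change per unit time drops below $10^{-6}$.

The stored 1d2d arrays put the interface at the *last* y index (top of
the domain); the analytic formulas internally use the flipped coordinate
with the interface at the origin, which is the convention in which the
$\cosh((H-y)\sqrt{R_0})$ bulk eigenfunctions are written.

## Validation strategy and problem sizes

The test-suite checks every structural identity against an independent
oracle: dispersion-polynomial coefficients against dense eigensolves
(500 random systems), Routh-Hurwitz verdicts against polynomial root
finding (200 random quartics/quintics), the comatrix against
finite-difference determinant derivatives, continued equilibria against
the asymmetric-Schnakenberg closed forms, and the simulator against the
mode-scan verdicts on points straddling the marginal curve.

Simulations in the suite run on deliberately reduced problems so the
whole suite stays interactive: 1D domains of length 50-100 with 48-256
cells (rather than the reference $L = 1000$ with 1500 modes), 2D grids
up to 64 x 24 (rather than 128 x 128 or 512 x 512), `dt = 0.05` for
Schnakenberg kinetics, and horizons of a few hundred to a few thousand
time units. These sizes resolve the selected wavelength by a comfortable
margin (the critical mode at $\xi_c \approx 0.24$ has wavelength
$\approx 12.8$, about 16 cells at the default resolution); the
grid-refinement test checks that halving the spacing moves the dominant
mode index by at most one. The amplitude-transfer check ($\eta = 0.005$
vs $0.01$) uses $L = 100$, 128 cells, and the ratio of bulk pattern
amplitudes, which carries a visible second-order contribution from the
coupling's feedback on the surface pattern; the $\pm 20\%$ band around
the linear-response value $0.5$ absorbs it.

What the synthetic studies do *not* emulate: real skin geometry
(curvature, growing domains), mechanochemical feedback, gene-expression
noise, or heterogeneous bulk equilibria. Passing tests show that the
implementation agrees with the linearised theory and its asymptotics,
not that any particular biological tissue is described quantitatively.

## Parameter choices worth knowing about

* **Clip cap `M`** in the pseudo-linear kinetics defaults to ten times
  the largest production-branch value at equilibrium, so the kinetics are
  exactly linear in the neighbourhood explored by the linear analysis;
  it is configurable per preset. Jacobians requested on a clipped branch
  warn rather than silently returning the linear-branch matrix.
* **Chemotaxis sensitivity** is bound as $h(c) = \chi c$ with
  $k(u) = u_1$ ($k_u = 1$): the strength parameter multiplies the cell
  density, which is where it appears in the reference parameter sets.
* **Reference parameter sets** (`figure_preset()`): the `fig4*`/`fig5`
  sets specify different surface and bulk equilibria, which the 1d2d
  interface condition cannot support, and their surface kinetics have
  $f_u = 0$, so no classical surface-driven critical diffusion exists;
  the printed surface thresholds for those sets are therefore not
  reproducible from the printed parameters. `adjust_shared = TRUE`
  substitutes surface production offsets $a_0 = 1.5$, $b_0 = 0.25$
  (a synthetic variant, labelled as such) so that both layers share the
  bulk equilibrium $(0.5, 0.75)$ and the simulations run. The bulk-side
  threshold *is* reproducible (the numeric branch gives
  $d_{v_B}^c \approx 8.4$ for the `fig4` coefficients and
  $\approx 37.4$ for the `fig5` overrides).
* **1d2d domain**: the reference grids are square, but only the depth
  $H = 50$ is quoted; the presets use $L = 100$, $H = 50$, and the
  scaled-down tests shrink both while keeping several pattern
  wavelengths in the domain.
* **Default surface inhibitor diffusion** in the 1d1d presets is 20
  (above the uncoupled threshold $\delta_c(0) \approx 17.3$), so the
  surface starts in its patterning regime; override with `set_param()`.

## A worked example

```{r, eval = FALSE}
pr <- figure_preset("fig2a")
bil <- pr$bilayer

# uncoupled threshold and critical wavenumber
layer_critical_diffusion(bil$surface, "d_v")
#> delta_c = 17.2797, xi_c = 0.2406

# coupling two identical layers raises the threshold...
weak_coupling_slope(bil, "surface_1d1d", "d_v")
#> 67.67
# ...up to the strong-coupling asymptote 2 * 17.28 - 15 = 19.56
continue_critical_curve(bil, c(0.1, 1, 10, 100, 1000), "d_vS")
```

## Known limitations

* Hopf and wave bifurcations ($\lambda = i\rho$) are out of scope; the
  analysis finds marginal $\lambda = 0$ points only.
* 1d2d stability away from the marginal curve is verified by simulation,
  not proved: the transcendental dispersion relation has no
  Routh-Hurwitz analogue.
* The IMEX scheme is first order in time; it is meant for verifying
  linear predictions and reproducing pattern morphology, not for
  high-accuracy quantitative PDE solutions.
* Only the equilibrium branch continued from $\eta = 0$ is tracked; no
  global enumeration of coupled equilibria is attempted.
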