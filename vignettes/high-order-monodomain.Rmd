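---
title: "High-order hierarchical finite elements for the cardiac monodomain equation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-order hierarchical finite elements for the cardiac monodomain equation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Cardiac tissue propagates action potentials through an electrically
coupled syncytium of myocytes. After homogenisation, the transmembrane
potential $u(x,t)$ (mV) obeys the monodomain reaction–diffusion equation

$$C_m \frac{\partial u}{\partial t}
  - \frac{1}{\beta}\,\nabla\!\cdot(\sigma \nabla u)
  - I_{ionic}(u, w) = I_{stim}(x, t),$$

with zero-flux boundary conditions, coupled at every point to the ordinary
differential equations $\partial w/\partial t = g(u, w)$ of an ionic cell
model. Here $C_m$ is the membrane capacitance (µF/cm²), $\beta$ the
surface-to-volume ratio (1/cm), $\sigma(x)$ the conductivity tensor
(S/m), and $I_{ionic}$, $I_{stim}$ current densities (µA/cm²,
depolarising-positive). Internally the package works in cm/ms/mV units; a
conductivity given in S/m enters the discrete operators with a factor 10
so that all terms are µA/cm².

The cell model is Luo–Rudy 1991 (`lr91_standard()`): six Hodgkin–Huxley
gates ($m,h,j,d,f,X$) and intracellular calcium, with the published
current formulation. Its $h$- and $j$-gate rate functions switch analytic
branch at $-40$ mV and are discontinuous there, which matters for
high-order methods (below). `fitzhugh_nagumo()` provides an infinitely
smooth two-variable caricature for diagnostics.

## Discretisation

**Space.** The weak form is discretised with continuous piecewise
polynomials of degree $p \le 4$ on intervals or triangles, built
*hierarchically*: vertex hat functions, one edge mode per degree
$\ge 2$ per edge, and interior bubbles ($\lambda_1\lambda_2\lambda_3$
times a monomial basis). The degree-$p$ basis is a prefix of the
degree-$(p+1)$ basis, so spaces nest and the vertex (linear) block is a
leading principal submatrix of every operator. Odd-degree edge kernels
change sign under edge reversal; all modes are evaluated in a global
low-to-high vertex orientation, which guarantees inter-element
continuity. The semidiscrete system is
$M u_t + \frac{1}{\beta C_m} A u = \frac{1}{C_m} I$ with mass and
stiffness matrices $M_{ji} = (\phi_i, \phi_j)$,
$A_{ji} = (\sigma\nabla\phi_i, \nabla\phi_j)$; $\sigma$ is read at every
Gauss point, so smoothly varying fibre fields are integrated without
element averaging.

**The cell state.** The $m$ state variables do not diffuse, so they are
carried at *nodal* points: the Gauss–Lobatto points of degree
$\tilde p$ on each element (on triangles, a warp-and-blend lattice whose
edge traces are exactly the 1D Gauss–Lobatto points). Each point hosts an
independent ODE system. A piecewise-linear representation of $w$
($\tilde p = 1$) caps the whole scheme at second order however large $p$
is; taking $\tilde p \ge p$ (default $\tilde p = 4$) restores the full
rate, and the suite measures both behaviours.

**The right-hand side.** The ionic current is evaluated at the nodal
points, interpolated (the degree-$\tilde p$ interpolant $\iota I$), and
converted from nodal values to hierarchical coefficients by a per-element
inverse generalised Vandermonde — exact for polynomials of degree
$\le \tilde p$. The load vector is then a single sparse product
$\tilde M c$ with the nested rectangular mass matrix $\tilde M$ (the rows
of the degree-$\tilde p$ mass matrix belonging to modes shared with
degree $p$). A direct Gauss-quadrature assembler of $(\iota I, \phi_j)$
is kept as an independent oracle; the two agree to $10^{-11}$ relative on
random polynomial currents, which is the central correctness test of the
matrix-based shortcut.

**Time.** Semi-implicit backward Euler: diffusion implicit, reaction
explicit. Per step the loop (1) evaluates $u_n$ at the nodal points,
(2) advances $w$ pointwise (forward Euler by default; Rush–Larsen
exponential updates keep gates in $[0,1]$ for any `dt`), (3) forms
$I_{total} = I_{ionic}(u_n, w_{n+1}) + I_{stim}$, (4) changes basis,
(5) forms $M u_n + \frac{\Delta t}{C_m} \tilde M c$, and (6) solves
$K u_{n+1} = \text{rhs}$ with
$K = M + \frac{\Delta t}{\beta C_m} A$. Evaluating $I_{ionic}$ at
$(u_n, w_{n+1})$ is our reading of the one-line scheme statement common
in this field; a switch (`ionic_state = "previous"`) selects $w_n$
instead. The forward-Euler cell update is stable at the production
`dt = 0.01` ms (the fastest gate has $\tau_m \approx 6\,\mu$s at rest,
within the stability bound) but not at 0.02 ms. The bound also interacts
with spatial resolution: $\beta_m$ grows exponentially with
hyperpolarisation, so on coarse meshes whose fronts undershoot below
about $-90$ mV the $m$-gate leaves the forward-Euler stability region
and $i_{Na} \propto m^3$ blows up. The qualitative coarse-mesh fibre
drivers therefore use the Rush–Larsen update, which is unconditionally
stable for the gates; quantitative runs keep forward Euler.

**Linear solver.** Conjugate gradients preconditioned by an ILU(0)
factorisation of the linear (vertex-mode) block, with the remaining
higher-order modes preconditioned by their diagonal; the factorisation is
built once per (mesh, $p$, `dt`) and reused every step. For $p = 1$ this
is ILU of the whole matrix. Warm-started in-loop counts are modest
(≈ 70 iterations per step at $p=4$ on 5×10⁴ DOFs); cold-started counts
grow markedly with $p$ because the diagonal completion is weak — a sparse
Cholesky alternative (`solver = "cholesky"`) factors once and is both
exact and faster for long runs. Convergence studies use it: iterating to
a $10^{-8}$ residual each of 20 000 steps leaves an accumulated drift
around $3\times10^{-3}$ mV, which would floor the fine-ladder errors.

## Rate-function repair

The LR91 $h/j$ rate discontinuities at $-40$ mV degrade spatial
convergence: every mesh point crossing $-40$ mV injects an $O(1)$ kink
into $\iota I$. `scan_rate_discontinuities()` finds such switches by
flagging adjacent-grid jumps 100× above the local slope estimate and
bisecting to $10^{-9}$ mV. `lr91_noble_form()` repairs them by blending
the two analytic branches with a logistic switch
$s(V) = (1 + e^{-(V+40)/k})^{-1}$, $k = $ `blend_width`/4 (default
width 1 mV): continuous by construction, equal to the published branches
to $10^{-6}$ relative beyond ten blend widths, and a documented,
pluggable stand-in for the continuous forms cited in the literature. The
blended rates are continuous but steep at the switch: their slope is the
branch gap divided by $4k$, so a finite-straddle difference is
proportional to the straddle width rather than arbitrarily small. The
single-cell action potential changes by well under 1% of the AP
amplitude.

## Fibre architecture

Conductivity tensors are
$\sigma = \sigma_t I + (\sigma_l - \sigma_t) f f^T$ with unit fibre
direction $f(x)$, so the eigenvalues are exactly
$\{\sigma_l, \sigma_t\}$ everywhere (default anisotropy 1 : 0.2 S/m).
Three fibre constructions: fixed axis; a bivariate-cubic angle field
(default $\theta = \frac{\pi}{2}(2y-1)^3 + \frac{\pi}{4}(2x-1)$, sweeping
about 270° across the unit square — the published cubic's coefficients
are not available, so exact reproduction of that study's activation
times is out of reach by design); and a Laplace–Dirichlet rule: solve
$\Delta\varphi = 0$ with $\varphi = \pm 1$ on two opposite outer edges
and natural conditions elsewhere, and take $f = \nabla\varphi/\lVert
\nabla\varphi\rVert$. Zero-Neumann hole boundaries make $f$ tangent to
holes, emulating fibres negotiating around blood vessels; we use the
gradient itself (not its rotation) because that choice realises the
tangency. At the two stagnation points of each hole the exact direction
field is singular (the gradient vanishes; its limit direction depends on
the approach path), so points whose gradient falls below 0.2× the median
inherit the nearest well-defined direction, and `hole_tangency()`
measures $\max |f\cdot\hat n| $ at Gauss points on the hole-boundary
edges outside those neighbourhoods (gradient ≥ 0.3× the ring median;
about 13% of the ring is excluded). Hole boundary rings are graded to a
chord half-angle ≤ 1/28 so the polygonal geometry does not dominate the
measurement; typical values are ≈ 0.01 against the 0.05 contract.

## Meshes

`build_interval_mesh()` gives uniform segments. `build_square_mesh()`
lays a jittered hexagonal lattice plus uniform boundary points and
triangulates with a built-in Bowyer–Watson Delaunay kernel, rescaling the
lattice internally until the mean element circumdiameter lands within 2%
of the target (mean circumdiameter is the "mean element diameter"
reported by the 2D studies; `mesh_quality()` uses the longest edge and
the inradius for the quasiuniformity and shape constants).
Generation is deterministic per seed. `build_square_with_holes_mesh()`
additionally cuts circular holes: point rings lie exactly on each circle
(to $10^{-8}$ cm), outer rings grade geometrically up to the background
spacing, and triangles whose centroid falls inside a hole are removed,
giving Euler characteristic $1 - \#\text{holes}$.

## The stimulus and convergence studies

The stimulus is a linear temporal ramp (default 2 ms to 80 µA/cm²) in a
spatial region (1D end segment of 0.05 cm; 2D bottom strip or corner
disc). A jump-edged region is represented differently by each mesh's
nodal interpolation — an $O(h)$ current leak into the edge element —
which shifts activation by $O(h)$ and caps observed convergence orders
near 1 regardless of $p$. Regions therefore accept a linear spatial
`taper`; the convergence drivers use width 0.05 cm with a 0.02 cm
shoulder and ladder spacings $h \in \{0.01, 0.005, 0.0025\}$ cm chosen so
both profile kinks (0.03 and 0.05 cm) sit on element boundaries of every
mesh, including the reference. With that protocol the piecewise-linear
profile is interpolated exactly on every mesh and the measured orders are
the discretisation's own.

The 1D convergence study runs 2 cm for 20 ms at `dt = 0.001` ms and
0.5 S/m with Noble-form LR91, against a quartic reference at
$h = 5\times10^{-4}$ cm (a desk-scale choice: the ladders stay ≥ 5×
coarser than the reference and the whole study runs in minutes).
Errors are evaluated at the reference mesh's quadrature points;
$L^\infty(L^2)$ is the max-in-time spatial $L^2$ error over snapshots
every 0.5 ms, $L^2(H^1)$ the trapezoid-in-time $L^2$ norm of the Sobolev
error. Observed $L^\infty(L^2)$ slopes approach $p + 1$ for
$\tilde p = 4$ and collapse to ≈ 2 for $\tilde p = 1$; with the standard
(discontinuous) LR91 the $p = 3$ slope drops well below its Noble-form
value. One caveat we document rather than hide: at $p = 1$ the
$L^2(H^1)$ error decays *faster* than the theoretical first order over
any practical ladder (≈ 1.4–1.6), because on these front-propagation
solutions the $H^1$ error mixes the $O(h)$ interpolation term with an
$O(h^2)$ front-position term that has a comparable constant; the two
cross over only below $h \sim 4\times10^{-4}$ cm.

## Conduction-velocity protocols and calibration

The monodomain equation maps onto itself under a rescaling of space, so
the conduction velocity scales exactly as $\sqrt{\sigma/(\beta C_m)}$ at
fixed cell model and time step. Absolute velocities therefore hinge on
$\beta$, which the sources for this class of simulation rarely print. We
default to $C_m = 1$ µF/cm², $\beta = 1400$ 1/cm, and, where absolute
velocities matter, calibrate the single scalar $\beta$ once so that the
mesh-converged 1D velocity at 1 S/m ($h = 0.01$ cm, $p = 4$,
`dt = 0.01` ms, nodes at 2 and 4 cm of a 6 cm fibre) equals a reference
value — `calibrate_beta()` does this in two or three runs using the exact
$\sqrt{1/\beta}$ scaling. Every downstream velocity (the slow-direction
1D run, the 2D planar wave) then follows without further tuning. 2D
velocities average $|\Delta y|/\Delta t$ over seeded random vertex pairs
with at least 0.2 cm separation and 0.5 ms delay.

## What the generators emulate — and what they do not

The built-in meshes, stimuli and fibre rules reproduce the *structure*
of the published test problems: unit squares, two-vessel geometries,
planar and corner activation, rapidly rotating fibres. They do not
reproduce unpublished specifics — the exact unstructured meshes, the
cubic fibre polynomial, the hole positions/radii (ours: 0.08 cm at
(0.32, 0.60) and 0.10 cm at (0.68, 0.34)), or the stimulus
parameterisation — so activation *times* in the fibre-field and hole
studies are checked structurally (ordering, $p$-convergence), not
numerically. Passing tests demonstrate correctness of the discretisation
and its implementation on these synthetic conditions; they do not
validate the LR91 model against tissue data, nor the monodomain
approximation itself (typically a ~2% CV difference from the bidomain).

## Known limitations

- 2D only; no bidomain; no adaptivity (the hierarchical basis is chosen
  to enable it later).
- $p \le 4$ for the potential; nodal degree $\tilde p \le 6$. The
  hierarchical constructors accept degree up to 6 because the
  matrix-based right-hand side needs the trial space at degree
  $\tilde p$.
- Forward-Euler cell updates limit `dt`; Rush–Larsen relaxes this but
  changes the temporal error constant.
- Error norms are implemented for 1D studies (the 2D studies are
  assessed through conduction velocities and activation maps).
- The $p = 3$/$p = 4$ error crossing reported for this class of schemes
  at the finest resolutions is recorded but not asserted by the suite.
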