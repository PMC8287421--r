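---
title: "Methods: delay-coupled Wilson-Cowan networks and the delay Master Stability Function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delay-coupled Wilson-Cowan networks and the delay Master Stability Function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Each node of the network is a Wilson-Cowan neural mass: an excitatory
activity $E_k$, an inhibitory activity $I_k$, and a homeostatic
inhibitory weight $W^{EI}_k$ that slowly adjusts to hold the excitatory
population at a target activity $p$:

$$
\tau_1 \dot E_k = -E_k + \phi\Big(\sum_j W^{EE}_{kj} E_j(t-\epsilon_{kj})
  - W^{EI}_k I_k\Big), \qquad
\dot I_k = -I_k + \phi(W^{IE} E_k), \qquad
\tau_2 \dot W^{EI}_k = I_k (E_k - p),
$$

with the logistic transfer $\phi(x) = 1/(1+e^{-ax})$. Excitatory
connections carry conduction delays $\epsilon_{kj}$; time is measured in
units of the inhibitory time constant, so physically plausible cortical
delays of 1–14 ms against $\tau_I = 20$ ms correspond to dimensionless
delays 0.05–0.7 (`scale_delay()`).

Two structural constraints make the synchronization analysis tractable:
every row of $W^{EE}$ sums to the same global coupling $W^E$, and (in
the baseline case) all delays are equal. Under these constraints the
all-nodes-identical state is invariant, and the synchronous trajectory
obeys a *single node coupled to itself* with weight $W^E$ and delay
$\epsilon$. That node has the closed-form equilibrium
$(p,\ \phi(W^{IE}p),\ (W^E p - \phi^{-1}(p))/\phi(W^{IE}p))$
(`equilibrium()`): the homeostatic weight settles exactly where
inhibition cancels the recurrent drive down to the input that sustains
activity $p$. The homeostatic weight is deliberately not clamped at
zero — the model definition has no clamp, and transiently negative
values are possible and permitted.

Baseline constants, used everywhere unless overridden:
$p = 0.2$, $a = 5$, $\tau_1 = 1$, $\tau_2 = 5$, $W^{IE} = 1$
(`node_params()`). All analysis functions accept an explicit bundle, so
nothing is hard-wired to the defaults.

## Integrating the delayed system

No installed R integrator provides constant-lag DDE solving with the
dense, renormalization-friendly history access that the variational
machinery below needs, so the package carries its own scheme: classical
fixed-step RK4 with cubic Hermite dense output. States and derivatives
are stored at every grid point; a delayed value at a stage time is read
from the completed part of the solution by local cubic interpolation,
which is valid because the step never exceeds the smallest positive lag
(default step: $\min(0.01, \epsilon_{\min}/4)$). The step is snapped so
the smallest lag is an integer number of steps — the method-of-steps
alignment that keeps propagated derivative discontinuities on grid
points. Heterogeneous lags are honored exactly through the dense
output; nothing is rounded to the grid.

`integrate_dde()` is the reference pure-R implementation of this scheme
for arbitrary systems; `integrate_network()` and
`integrate_single_node()` run the identical scheme in compiled code for
the Wilson-Cowan right-hand sides. The test suite pins the two against
each other pointwise to $10^{-10}$, verifies 4th-order convergence
against closed-form method-of-steps solutions of $x'(t) = -x(t-1)$, and
cross-checks the zero-lag case against `deSolve`. Adaptive stepping,
stiff methods, and state-dependent delays are out of scope; the model's
timescales (1–5 time units against steps of 0.01) do not need them.

## Linear stability of the single node

Linearizing the self-coupled node about its equilibrium gives a 3-d
linear DDE whose characteristic determinant `char_fn()` uses the gains
$M_1 = \phi'(\phi^{-1}(p)) = a\,p(1-p)$ and
$M_2 = W^{IE}\phi'(W^{IE}p)$, with the delayed term entering as
$W^E e^{-\lambda\epsilon}$. The Hopf boundary in $(W^{IE}, W^E)$ is
computed by solving $\mathrm{char}(i\omega) = 0$ with a damped Newton
step, continued in the delay from the exact no-delay anchor (a cubic
eigenvalue problem bracketed by bisection). The search is restricted to
$\omega \in (0, 20]$: every oscillation this model produces has a
period of a few time units, so higher frequencies are not physical
here. Each returned point is validated by checking that the rightmost
characteristic root (Newton from a seeded grid over
$\mathrm{Re}\,\lambda \in [-3, 1.5]$) crosses the imaginary axis across
the reported coupling. The delay raises the Hopf threshold
monotonically — delayed self-excitation needs stronger coupling to
destabilize the equilibrium.

Beyond the Hopf point the node is explored by simulation:
`orbit_diagram()` records the local maxima of $E(t)$ after a transient
and clusters them within a tolerance (default $10^{-3}$ in $E$ units;
transient 500 and recording window 1500 time units, long against
$\tau_2 = 5$). One cluster is a simple cycle; doubling cluster counts
(`detect_period_doubling()`) trace the period-doubling cascade, which
is present at small delays and absent at larger ones, where only the
single-peak oscillation survives. Period-doubling is detected from
orbit diagrams only; continuation of periodic orbits and Floquet
analysis are out of scope.

## The delay Master Stability Function

Perturbations transverse to the synchronous manifold decompose along
eigenvectors of $W^{EE}$; the perturbation at eigenvalue $\hat r$ obeys
the variational system

$$
\tau_1 \dot\eta_x = -\eta_x + M_1^s(t)\big(\hat r\,\eta_x(t-\epsilon)
  - I_s\eta_z - W^{EI}_s\eta_y\big),\quad
\dot\eta_y = -\eta_y + M_2^s(t)\eta_x,\quad
\tau_2 \dot\eta_z = (E_s - p)\eta_y + I_s\eta_x,
$$

with coefficients evaluated along the synchronous trajectory. The
Master Stability Function $\lambda(r)$ is the maximal Lyapunov exponent
of this system as a function of the *scaled* eigenvalue
$r = \hat r / W^E$, which puts the spectrum of any nonnegative
row-normalized matrix on or inside the unit disk.

To compute $\lambda$, the delayed term is replaced by an $m$-cell
delay-line: the live variable $\eta_x$ is advected through
$x_2, \dots, x_m$ with interior cells
$\dot x_n = (x_{n-1} - x_{n+1})\,m/(2\epsilon)$ and the outflow closure
$\dot x_m = (x_{m-1} - x_m)\,m/\epsilon$, so $x_m$ approximates
$\eta_x(t-\epsilon)$ and the linear DDE becomes a small ODE system.
The sign convention matters: the interior difference must advect *from*
the live end *toward* the delayed end; the opposite orientation, though
sometimes written, is anti-causal and dynamically unstable. The default
$m = 10$ is validated in the suite by doubling $m$ on a 20-point sample
of the unit disk (exponent shifts below $10^{-2}$) and by the spectral
response of the driven chain to a sinusoid.

The exponent itself comes from Benettin renormalization: the nonlinear
synchronous node (a true DDE, integrated with dense history) is
co-integrated with the chain-discretized variational block; the
variational norm is renormalized every 1 time unit and the average log
growth accumulated. Defaults: transient 500 (attractor settling),
variational alignment 50 (excluded from the average), averaging 2000
time units, all configurable in `lyap_config()`. A running-mean
diagnostic declares convergence when the estimate moves less than
$10^{-3}$ over the second half of the window; unconverged estimates are
recomputed with doubled averaging up to 8000 time units, and
$|\lambda| < 10^{-3}$ is reported as *marginal* rather than forced into
a sign. Complex eigenvalues are handled by integrating the complexified
variational state; $\lambda(\bar r) = \lambda(r)$ is exact by
construction and asserted in the tests.

Two independent cross-checks guard the pipeline. Whenever the
synchronous solution is the equilibrium (coupling below Hopf) the
variational system has constant coefficients, and $\lambda(r)$ must
equal the real part of the rightmost characteristic root with $\hat r$
in the delayed slot; the suite holds the two routes to $10^{-2}$.
Independently, `direct_dde_growth()` integrates the variational system
as a true linear DDE — no chain — renormalizing state and history
together (exact for a linear system), and its sign classification must
agree with the chain exponent off a $\pm 10^{-3}$ marginal band.

`predict_synchronization()` evaluates $\lambda$ at every eigenvalue of
a weight matrix and calls the synchronous state stable when all
*transverse* exponents are negative. The Perron eigenvalue (scaled
value 1, eigenvector all-ones) is excluded from the verdict and
reported separately: a perturbation along it moves the network within
the synchronous manifold, so its exponent is the attractor's own
leading exponent — about zero on a limit cycle, positive for chaos —
not a desynchronizing direction. This exclusion is our design choice,
stated prominently because the verdict at couplings past the Hopf point
would otherwise always be "unstable" for trivial reasons.

## Synthetic networks: what is emulated and what is not

`ring_unidirectional()`, `ring_lattice()` and
`random_row_normalized()` generate the three topology families the
analyses use; all are exactly row-normalized (a single rescale per
row) and pure functions of their arguments and seed. Design choices the
problem leaves open, fixed once here: random networks have a zero
diagonal (no self-coupling) and uniform(0,1) pre-normalization weights;
"lattice" means the 1-d periodic nearest-neighbour ring with weight
$W^E/2$ per neighbour. Heterogeneous delays are drawn per edge from a
Beta distribution on $(0, 2\bar\epsilon)$ — shapes default to
$\alpha = \beta = 2$, symmetric about the target and strictly positive
— then rescaled by one constant so the sample mean over edges equals
$\bar\epsilon$ exactly.

These generators emulate idealized topologies, not measured
connectomes: no distance-dependent weights, no hemispheric structure,
no sparsity thresholding, and delays independent of weights. Passing
tests therefore show that the *method* behaves correctly on matrices
with known spectra, and that its qualitative predictions (which
spectra synchronize under delay) are internally consistent — not that
any particular measured brain network synchronizes.

## Study conditions and problem sizes

The packaged studies (`run_experiment()`, the acceptance script, and
the test suite) use: couplings $W^E \in \{2.05, 2.115, 2.25\}$ spanning
the just-past-Hopf regime at delay 0.1; ring scans over $N = 2..10$;
orbit diagrams over $W^E \in [2, 3]$ with grid step 0.02; lattice scans
from $N = 12$ upward at zero delay and $W^E = 2.115$; heterogeneous
rings $N \in \{6, 7, 8\}$ at mean delay 0.1 across 5 seeds. Network
simulations run 2000 time units from the equilibrium plus a seeded
uniform perturbation of scale $10^{-2}$ per state component — a local
kick, matching the local claim the Master Stability Function makes —
and synchrony is judged by the time-averaged maximal pairwise spread of
$E$ over the final 20% of the run against a threshold of $10^{-3}$.
With unequal delays exact coincidence is impossible, so the
heterogeneous study instead requires the run to land on the
homogeneous attractor (Hausdorff distance in $(E, I)$ below 0.05) with
pairwise phase lags bounded by five times the largest sampled delay —
lags on the scale of the delays themselves are the expected residue of
delay heterogeneity.

## Degenerate inputs and tie-breaks

Spectra are ordered by descending real part, ties by descending
modulus, making conjugate pairs and reports deterministic. Conjugate
eigenvalues share one exponent computation. A delay of exactly zero
switches every code path to the undelayed system explicitly (no chain,
no history) rather than taking a singular limit. Divergent simulations
inside scans and studies are flagged in the returned tables, not
raised; the low-level integrators do raise, naming the failure time.
A degenerate all-zero delay sample (impossible for a continuous Beta,
but guarded) is resampled with an incremented, logged seed.

## Known limitations

The transverse exponents of a *chaotic* synchronous state converge
slowly (ergodic averages), and near the stability boundary the verdict
can hinge on which attractor window the coupling lands in: at zero
delay the single node passes through interleaved periodic and chaotic
windows a few thousandths of a coupling unit wide near
$W^E \approx 2.115$, and the transverse stability landscape moves with
them. Threshold sizes computed in that regime (the zero-delay lattice
scan) are therefore sensitive to integrator details in a way the
delayed ring scan — whose synchronous state is a robust limit cycle —
is not. Relatedly, simulations can desynchronize slightly before the
mean transverse exponent crosses zero (attractor bubbling), which is
why scans record both verdicts and flag disagreements instead of
averaging them away.

The Master Stability formalism itself requires identical delays; with
heterogeneous delays the package deliberately falls back to direct
simulation. Finally, the delay enters excitatory coupling only — no
delayed inhibition, no delay distributions within a single connection,
and no spiking dynamics beneath the rate description.
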