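---
title: "Methods: single-chain mean-field micelles and the modified Eyring model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-chain mean-field micelles and the modified Eyring model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`micellex` implements a coarse-grained single-chain mean-field (SCMF)
description of poloxamer (PEO--PPO--PEO) micelles and the kinetic analysis of
single-chain exchange between micelle and bulk.  It covers four layers:

1. a Kuhn-rod chain model of the L44 triblock EO10--PO23--EO10 with exact
   intramolecular energetics;
2. an equilibrium SCMF solver on spherical shells, from which
   chemical-potential curves, the preferred aggregation number N* and the CMC
   follow;
3. dynamic Monte Carlo exchange simulations yielding the tagged-chain
   correlation function F(t) and radial conformational diagnostics of the
   exit pathway;
4. a three-parameter modified Eyring kinetic model with a closed-form
   solution, asymptotic regime analysis, nonlinear fitting, and a universal
   master-curve scaling of relaxation data.

## The chain model

Each EO and PO monomer is one bead of diameter $\sigma$ (physically about
0.2 nm); consecutive beads are bonded at distance exactly $\sigma$.
Stiffness enters through Kuhn segments: `kuhn_EO` (`kuhn_PO`) consecutive
monomers of a block form a straight rigid rod, with full rotational freedom
at the joints between consecutive rods and at every EO/PO chemical boundary.
The partition uses ceiling arithmetic, so a terminal segment may be shorter
than the Kuhn length (23 is not a multiple of 4 or 20; the semiflexible and
rigid PO blocks still count 6 and 2 segments).  A straight rod is the
minimal shape consistent with "rigid segment of bonded beads at spacing
$\sigma$"; no torsional potential is imposed.

The three stiffness presets are flexible (Kuhn lengths 2/2), semiflexible
(3/4; the realistic L44) and rigid (10/20).

Non-bonded beads interact through square wells of inner radius $\sigma$
(hard core) and outer radius $1.62\sigma$.  Well depths are quoted per
coordination contact: a neighbour whose centre falls inside the well
contributes $\epsilon_{xy}/z$ $k_BT$ with $z = 26$ a fixed constant, and
$\epsilon_{\mathrm{EO,PO}} = 0.006$, $\epsilon_{\mathrm{EO,s}} = 0.5$,
$\epsilon_{\mathrm{PO,s}} = 2.1$ (implicit water, valid at 37 °C only).
The convention is self-consistent with the default molecular volumes: with
$v_p = v_s = (\pi/6)\sigma^3$, a fully solvated isolated bead holds exactly
$v_{\mathrm{well}}/v_s = 26 = z$ solvent molecules in its well, so its total
solvation energy is $\epsilon_{xy}$.  Positive $\epsilon$ values act as
contact penalties; their ordering (PO--water ≫ EO--water ≫ EO--PO) encodes
the hydrophobicity that drives micellization.  No same-species intra-chain
well depths are defined by the parameter set, so same-species intra-chain
pairs carry zero energy (a flagged convention, not inferred physics).

Intramolecular energetics are exact: a pairwise sum over non-bonded beads,
infinite on hard-core overlap.

### Intra-chain screening of the interaction wells

Solvent and neighbouring molecules cannot occupy space already filled by the
chain's own beads.  A bead inside a connected chain therefore exposes only
part of its interaction well: the bonded neighbours alone block roughly a
third of it.  The projection of a conformation onto the radial lattice
multiplies every bead's well volume by its accessible fraction
$s_i = \exp(-\sum_j v_{ij}/v_{\mathrm{well}})$, where $v_{ij}$ is the
overlap of bead $j$'s exclusion sphere with bead $i$'s well shell — an
independent-overlap closure for the union of the exclusion spheres, exact to
first order in the blocked fraction and within a few percent of direct
Monte-Carlo integration of the exact union for all three chain stiffnesses
(the plain pairwise sum overcounts blocking by ~35 %).  This is part
of the exact single-chain treatment; without it the solvation free energy of
a connected chain is overcounted by ~40 %, which inflates the
micellization driving force, deepens $\Delta\mu_N$ several-fold, and pushes
the preferred aggregation numbers far beyond the physical range.  The
correction can be disabled (`screen_intra = FALSE`) to recover the bare
geometric well volumes, which is also how the well-volume conservation
identity is tested.

## The SCMF free-energy functional

The mean fields live on concentric spherical shells (default width
$1\sigma$) around the cell centre.  For a conformation ensemble
$\{\alpha\}$ with weights $P[\alpha]$ and $N$ chains per cell, the
functional (in $k_BT$) is

$$
F = N\sum_\alpha P[\alpha]\, U_{\mathrm{intra}}(\alpha)
  + E_{\mathrm{EO-PO}} + E_{\mathrm{chain-solvent}}
  + N\sum_\alpha P[\alpha]\ln P[\alpha] + \ln N!
  + \sum_r V_r\, c_s(r)\left[\ln(c_s(r) v_s) - 1\right],
$$

where the interchain EO--PO energy couples the ensemble-averaged available
interaction volumes $\langle\Phi_X(r)\rangle$ to the averaged concentrations
$\langle c_Y(r)\rangle$ (each pair counted once; a factor $(N-1)/N$ removes
the mean-field self-pair at small $N$), and the chain--solvent energy is
$\sum_r [\epsilon_{\mathrm{EO,s}}\langle\Phi_{EO}\rangle +
\epsilon_{\mathrm{PO,s}}\langle\Phi_{PO}\rangle]\, c_s(r)$ per the same
contact convention.  The $\ln N!$ term is the chain indistinguishability
factor; the solvent term carries its own Stirling factor through
$c_s(\ln c_s v_s - 1)$.  Leaving the chain factorial out injects a spurious
$-\ln N$ per chain into $\Delta\mu_N$ and suppresses the interior minimum
entirely — one of the quietly decisive details of the implementation.

Minimizing $F$ subject to per-shell incompressibility
$\phi_{\mathrm{chains}}(r) + c_s(r) v_s = 1$ (Lagrange field $\pi(r)$)
yields the fixed-point structure the solver iterates:

* $P[\alpha] \propto e^{-H[\alpha]}$ with $H[\alpha]$ the single-chain
  Hamiltonian — intramolecular energy, mean-field EO--PO and solvent
  couplings, and $\sum_r \pi(r)\,v_p\,n(\alpha,r)$;
* $c_s(r)$ directly from the incompressibility constraint;
* $\pi(r)$ from the solvent stationarity condition (gauge $\pi = 0$ at the
  cell boundary).

Because $H$ is the exact functional derivative of $F$ (with $c_s$
eliminated), the Picard fixed point coincides with the direct minimizer of
$F$; the test suite verifies this on an enumerable toy system (six
conformations, three shells) against an independent BFGS minimization over
softmax weights, to $10^{-6}$ in free energy.  Incompressibility is
satisfied identically by construction (the residual only reflects the
numerical solvent floor).

### Numerical scheme

Damped Picard mixing (default 0.1) with an automatic back-off: when the
residual history shows a limit cycle the mixing halves, down to 0.005.
Conformations are importance sampled: shapes are free-chain samples, and
placements of the PO-block centre of mass are drawn uniformly in radius
(centre-weighted in volume) with an exact conditional-density correction,
so free energies are placement-unbiased.  Two refinements keep the
effective sample size usable in strongly localized micelle states:

* macro-iterations re-draw the placements from the current weighted radial
  density of the micelle (mixed with 30 % of the flat proposal);
* the internal PO→EO axis is importance-biased toward the outward radial
  direction (density-corrected), which is the orientation the corona
  selects.

The default reduced-sampling configuration (ensemble 2000–5000 per solve,
three macro-iterations, 28–30 shells of width $1\sigma$) keeps a full
three-stiffness scan in minutes; these sizes are the package's default
study conditions and are recorded with every scan.

### Chemical potentials and the CMC

$\Delta\mu_N^0 = [F_{\mathrm{cell}}(N) - F_{\mathrm{cell}}(0)]/N - \mu_1^0$,
with $F_{\mathrm{cell}}(0) = -V/v_s$ the pure-solvent cell and $\mu_1^0$
from a single-chain solve whose PO centre is pinned at the origin.  Chain
placement entropy is measured per solvent site ($v_s$ inside the entropy
measure), making the standard state one chain per solvent site — a
mole-fraction convention — so
$\mathrm{CMC} = e^{\min_N \Delta\mu_N^0} \times 55.5\ \mathrm{mol/L}$.
Before the minimum is taken, each solve is classified as micelle-branch
(dense hydrophobic core) or dispersed: small aggregation numbers melt back
to dispersed chains whose translational free energy depends on the cell
volume and is not a standard chemical potential, so the argmin runs over
the micelle branch only.  $N^*$ is the branch minimum (smallest $N$ within
0.01 $k_BT$); a minimum sitting at the edge of the scanned branch is
flagged, and a scan in which no aggregation number holds a micelle reports
"no micellization".

The absolute scale of $\Delta\mu_N$ is sensitive to quantities the model
only fixes by convention (molecular volumes, shell width, the well-screening
treatment); the solver's value lies in the relative structure — the
existence and location of the minimum and its dependence on chain stiffness.

## Dynamic SCMF Monte Carlo

The dynamics evolves $N$ explicit chains.  Per cycle every chain receives
one symmetric local move — with equal probability a pivot of one side of
the chain about a random inter-segment joint (rotation up to the amplitude,
radians) or a rigid translation (step up to the amplitude, $\sigma$) — and
is accepted with $\min(1, e^{-\Delta H})$, where $H$ is evaluated in the
cycle-start fields with the chain's own field contribution removed.  After
all chains have moved, concentrations, solvent and $\pi$ are re-solved from
the instantaneous ensemble (one field update per cycle).  Acceptance for the L44 chains plateaus near 60–75 % over a wide amplitude
range (pivots of short sub-chains remain cheap whatever the cap), so the
40–50 % tuning target is not reachable with this move set; the default
amplitude 1.2 sits at the onset of the plateau and is logged with each run.  Detailed balance in frozen fields is verified against a
direct-sampling Boltzmann oracle on a three-bead toy.

Exchange runs tag the chains inside the micelle after burn-in; membership
is decided by the PO-block centre of mass relative to the corona/bulk
interface radius (detected from the burn-in averaged fields), with a
$1\sigma$ hysteresis band against boundary flicker.  The correlation
function is normalized as $F(t) = (f(t) - f_{eq})/(f(0) - f_{eq})$ with
$f_{eq} = f(0)\,\times$ (tagged/total chains), the mixing-equilibrium
expectation, computed rather than measured because runs are far shorter
than full remixing.

Physical time: the free-chain diffusion constant $D_{\mathrm{SCMF}}$
($\sigma^2$/cycle, from the centre-of-mass MSD slope over six) is matched
to the Stokes–Einstein value $D = k_BT/(6\pi\eta a)$ with
$\eta = 6.91\times10^{-4}$ kg/m/s (water, 37 °C), giving
$t_{\mathrm{cycle}} = D_{\mathrm{SCMF}} l^2/D$ with $l = 0.2$ nm.  The
hydrodynamic radius $a$ has no closed expression in the model and is an
explicit input (a measured free-chain radius of gyration is the documented
default choice); cycle times are therefore move-set-dependent and
order-of-magnitude in nature.

## The modified Eyring model

The tagged-fraction relaxation obeys

$$
\frac{dF}{dt} = -k_1 e^{F/\epsilon} + k_1 e^{-F/\epsilon} - k_2 .
$$

The first two terms are the forward/backward activated (Eyring) pair whose
crossover scale is $\epsilon$; the third, with constant $k_2$, supplies the
final exponential regime.  In $y \equiv e^{F/\epsilon}$ this is a
constant-coefficient Riccati equation
$\epsilon\,\dot y = -k_1 y^2 - k_2 y + k_1$, solved in closed form.  The
package evaluates the solution in the bounded variable $w = e^{-F/\epsilon}$
with every term positive (no cancellation, no overflow for
$\epsilon \sim 10^{-2}$ where $e^{1/\epsilon}$ exceeds $10^{21}$), and the
test suite checks it against adaptive numerical integration of the ODE to
$10^{-8}$ across $\epsilon \in [0.01, 0.1]$,
$\gamma = k_1/k_2 \in [10^{-14}, 10^3]$.

Regimes, with $\tau_1 = (\epsilon/k_1)e^{-1/\epsilon}$ and
$\gamma = k_1/k_2$:

* initial fast decay for $t \lesssim \tau_1$;
* logarithmic decay $F \simeq 1 - \epsilon\ln(t/\tau_1)$ for
  $t \gg \tau_1$ (slope $-\epsilon$ per $e$-fold);
* for $\gamma > 1$ (type a) a direct crossover to terminal exponential
  relaxation with $\tau_2 = \epsilon/(2k_1)$;
* for $\gamma < 1$ (type b) a universal second intermediate exponential
  regime with rate $k_2/\epsilon$, the terminal regime proper being pushed
  beyond observation when $\gamma$ is tiny.

The generic derived quantity reported as $\tau_2$ is
$\epsilon/(k_2\sqrt{1+4\gamma^2})$, the exact linearization rate at the
stable stationary point; it reduces to the two limits above.

Scaling $t = a t^*$, $\tilde y = b y^*$ with $a = \epsilon/k_2$,
$b = e^{-1/\epsilon}/\gamma$ (equivalently $y^* = \gamma e^{F/\epsilon}$)
reduces the dynamics to the parameter-free master equation
$dy^*/dt^* = -y^{*2} - y^*$ (plus a $\gamma^2$ correction relevant only near
the stationary state).  All curves with a developed logarithmic regime
($\gamma e^{1/\epsilon} \gg 1$) collapse: log–log slope $-1$ in the
intermediate window and a common crossover at $t^* \sim 1$.  The initial
fast regime is not universal — each curve carries its own offset
$e^{-1/\epsilon}/\gamma$ — so collapse comparisons start beyond it.

### Fitting

Nonlinear least squares of the closed form against F(t), with residuals in
F on points resampled uniformly in log time (information is spread per
decade; the $y$ variable would amplify noise by $e^{F/\epsilon}$).
Positivity is enforced by fitting $(\log\epsilon, \log k_1, \log k_2)$;
initialization is deterministic ($\epsilon_0$ from the straightest lin–log
window, $k_1$ from the plateau-departure time via the $\tau_1$ identity,
$k_2$ from the data span) with eight jittered multi-starts under a fixed
seed.  The reported accuracy proxy is $R^2$ on the resampled points.  A
fitted $k_2$ is flagged unreliable when the data never leave the
logarithmic window ($t^*_{\max} < 0.1$), in which case only
$\epsilon, k_1$ are meaningful.  Noiseless synthetic curves are recovered
to machine precision; with 1 % additive noise, identifiability of $k_1$ is
limited by the exponential $e^{-1/\epsilon}$ amplification of the
$\epsilon$ uncertainty, so recovery to ~10 % requires curves that resolve
both the plateau departure and the crossover.

## The synthetic-data generator

`synth_curves()` wraps the closed-form solution: log-uniform time grids
spanning $\tau_1/10$ to $10\,\epsilon/k_2$ by default, additive Gaussian
noise of stated amplitude, ground truth and seed recorded in a manifest.
It emulates the shape, sampling and noise character of exchange-relaxation
data (simulation or TR-SANS-style); it does not emulate instrument-specific
error correlation, polydispersity mixtures, or baseline drifts, so fitter
tests certify parameter recovery under the model's own assumptions, not
robustness to systematically mis-specified data.

## Design choices on genuinely open points

* **Membership rule** — a chain is "in the micelle" if its PO centre is
  inside the corona/bulk interface, with $1\sigma$ hysteresis: the interface
  is where exchange becomes bulk-like, and hysteresis suppresses counting
  noise from boundary flicker.
* **Micelle centre** — dynamics profiles use the instantaneous PO-density
  centre; equilibrium solves are pinned to the lattice origin by
  construction.  Both are supported for radial measurement.
* **Same-species intra wells** — set to zero (no parameters exist);
  flagged rather than guessed.
* **$\gamma = 1$** — labelled "boundary" and excluded from class-conditional
  analyses (a measure-zero case).
* **Aggregation numbers for dynamics** — the preferred sizes for flexible
  and semiflexible chains and 150 for the rigid chain, which keeps the
  rigid run tractable without affecting single-chain exchange.

## Known limitations

* Interchain correlations beyond the mean field (entanglements,
  hydrodynamics, fusion/fission) are outside SCMF by construction.
* The implicit-solvent parameters are valid at 37 °C only.
* Absolute $\Delta\mu_N$ and CMC values inherit the convention choices for
  $v_p$, $v_s$ and well screening; stiffness orderings and regime structure
  are the robust outputs.
* The cycle-time calibration depends on the move set and amplitude; only
  its order of magnitude is meaningful.
* Reduced-sampling scans (ensembles of a few thousand conformations) carry
  stochastic errors of a few tenths of $k_BT$ in $\Delta\mu_N$; scan
  minima flatter than that are reported but not resolved.
* In this realization the flexible-chain micelle is only numerically stable
  for aggregation numbers around and above the semiflexible optimum; at
  smaller sizes the solver's effective sample size collapses and the state
  melts to the dispersed branch.  The stiffness ordering of the CMC
  (flexible > semiflexible > rigid) is robust; the ordering of the
  preferred sizes is resolved between the semiflexible and rigid chains
  but not reliably for the flexible chain at reduced sampling.
* Chain generation is plain rejection sampling of freely-jointed rigid
  rods; the fully flexible (Kuhn length 1) 43-mer is essentially
  unsamplable this way and fails with an explicit attempt-budget error —
  the study's flexible case (Kuhn length 2) is unaffected.
* The observable contrast of an exchange run is the gap between the tagged
  count and its mixing equilibrium, which is set by the number of untagged
  bulk chains the cell holds at coexistence.  Because the semiflexible and
  rigid CMCs are low, their coexistence bulk populations in desk-scale
  cells are small (tens and units of chains), so their reduced-scale F(t)
  curves are noisy (semiflexible) or pinned near one (rigid); the flexible
  chain, with its much higher CMC, shows the full relaxation.  Multi-decade
  quantitative F(t) curves for the stiffer chains require cells and cycle
  counts beyond the test-suite scale.
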