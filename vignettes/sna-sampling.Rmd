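---
title: "Deciding mirror-symmetry breaking by stoichiometric network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding mirror-symmetry breaking by stoichiometric network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralnet)
```

## The problem

Biological homochirality — life's exclusive use of one enantiomer of its
chiral building blocks — is commonly explained by *absolute asymmetric
synthesis*: chemical mechanisms that, in an achiral environment, amplify a
vanishingly small imbalance between the L- and D-forms of a molecule into a
persistent, macroscopic enantiomeric excess.  Candidate mechanisms are
written as mass-action reaction networks, and the claim "this mechanism can
break mirror symmetry" is a statement about the stability of the network's
*racemic* steady states: states with every pair balanced, $L_i = D_i$.

`chiralnet` answers two questions for such a network:

1. Does the network admit *symmetry-breaking states* — racemic steady
   states whose instability is directed along an enantiomer-distinguishing
   mode — at all?
2. If so, what are concrete parameter values (concentrations and rate
   constants) at such a state, so that the homochiral dynamics can be
   simulated?

## The model

A network over species $X_1,\dots,X_n$ is a finite set of reactions
$c_1X_1+\dots+c_nX_n \to d_1X_1+\dots+d_nX_n$ with nonnegative integer
coefficients and a mass-action rate constant $k_j$ per reaction.  The
concentration dynamics are

$$\frac{dX_i}{dt} \;=\; \sum_{j=1}^{r} k_j\,(d_{ij}-c_{ij})\,
  \prod_m X_m^{c_{mj}} \;=\; (S\,v(X))_i,$$

where $S = (d_{ij}-c_{ij})$ is the stoichiometric matrix and
$v_j = k_j \prod_m X_m^{c_{mj}}$ the velocity of reaction $j$.  A *state*
bundles all concentrations and all rate constants; it is *steady* when
$S\,v = 0$.  Reversible reactions are split at parse time into two
irreversible ones, because the kinetic formalism above is stated for
irreversible steps.  Pool chemicals (declared `constant`) keep their
concentrations as factors of the rate laws but contribute no differential
equation, no row of $S$ and no Jacobian column — the standard open-system
idealization of a sustained feed.  All quantities are treated as
dimensionless; rescaling concentrations and rate constants reintroduces
units without changing any stability conclusion.

## Pseudochirality

A network modelling an achiral environment must be *pseudochiral*: swapping
every L-species with its D-partner maps each reaction onto a *dual*
reaction present in the network, and dual reactions carry equal rate
constants (enantiomers are indistinguishable to achiral chemistry).
`check_pseudochiral()` verifies this, producing the involution, the dual
map on reactions, and the partition of rate labels into equal-value
classes.  The number $k$ of dynamic enantiomeric pairs is the network's
*order*.  Pairing is declared explicitly in the input (`pair L:D`) rather
than inferred from species names, which follow no reliable convention in
the literature.

The *enantiomeric gap* of a state is $\sum_{i\le k}\lvert L_i - D_i\rvert$;
a state is racemic exactly when its gap is zero.  The absolute values
matter: a bare sum would declare the fully crossed state $L=(0,1)$,
$D=(1,0)$ racemic, contradicting the componentwise racemic condition, so
the gap is implemented with $\lvert\cdot\rvert$.

## The MM-condition

Order the species $L_1..L_k, D_1..D_k$, achiral rest (the *canonical
order*).  At a racemic state, after identifying $D_i$ with $L_i$ and dual
rate labels with one another, the Jacobian of the ODE takes a
block-symmetric form; let $A$ be its $k\times k$ block coupling the L-side
to itself and $B$ the block coupling the L-side to the D-side.  A racemic
steady state is symmetry-breaking **iff** the characteristic polynomial of
$A - B$ has a root with positive real part.  This reduces an $n\times n$
eigenproblem to a $k\times k$ one ($n \ge 2k$) and, crucially, isolates
exactly the instabilities whose eigenvectors distinguish the two sides —
an unstable but mirror-symmetric mode does not break symmetry.

The package implements both sides of this equivalence: `mm_matrix()` /
`char_poly()` / `is_unstable_polynomial()` for the reduced test, and a
full-Jacobian eigen-decomposition that searches for an unstable eigenvalue
whose eigenvector has $v_i \ne v_{i+k}$.  `is_symmetry_breaking_state()`
runs both and the test suite checks their agreement on randomly generated
networks.

### Numerical tolerances

* Instability band: a root counts as unstable when
  $\mathrm{Re}\,\lambda > 10^{-9}$; verdicts with
  $\lvert\mathrm{Re}\,\lambda\rvert \le 10^{-9}$ are *marginal* and are
  excluded from confirmed samples (the mathematical criterion is strict;
  floating point needs a band).
* Eigenvector asymmetry: $\lvert v_i - v_{i+k}\rvert >
  10^{-7}\lVert v\rVert$.
* Steady-state / racemic precondition: residuals up to $10^{-8}$ relative
  to the velocity scale.

`is_unstable_polynomial()` computes roots numerically (`polyroot`) and
independently runs a Routh–Hurwitz table; degenerate tables (zero pivots)
are flagged rather than silently resolved.

## Degree reduction by stoichiometric network analysis

The instability conditions above are polynomial inequalities of high
degree in concentrations and rate constants.  Clarke's change of variables
removes most of that nonlinearity.  The steady states map onto the
polyhedral cone $C = \{v \ge 0 : S\,v = 0\}$ of steady reaction currents.
A minimal generating set of *extreme currents* $v_1,\dots,v_s$ yields
convex coordinates $j \ge 0$ with steady velocity $\sum_l j_l v_l$, and the
Jacobian factorizes as $J = S\,E\,R\,\Delta$ with
$E = \mathrm{diag}(\sum_l v_{li} j_l)$, $R$ the kinetic-order matrix and
$\Delta = \mathrm{diag}(1/X_i)$.  The analysis then concentrates on
$V = S\,E\,R$, whose entries are *linear* in $j$.

### Exact enumeration

`extreme_currents()` enumerates the extreme rays by the double-description
method in exact integer arithmetic: starting from the coordinate rays,
each equality is intersected in turn, combining positive- and
negative-side rays with integer multipliers and keeping support-minimal
vectors (for cones of the form $\{v\ge 0, Mv=0\}$ the extreme rays are
exactly the support-minimal nonzero solutions, unique up to scale).  Rays
are normalized to integer entries with gcd 1 and sorted lexicographically,
so results are reproducible bit for bit; every returned ray is re-verified
against the constraints exactly before the cone is accepted.  Floating
point ray enumeration was rejected outright: the downstream certificates
reason about exact signs of polynomial coefficients.

### The extended matrix

Working in the cone does not yet know that dual reactions must carry equal
rate constants.  The stoichiometric matrix is therefore *extended* with
rows $e_p - e_q$ forcing equal steady currents through the reactions of
each dual pair — the construction used by the reference implementations
of this analysis, which it reproduces.  `chiralnet` generalizes this to
every *rate-label equal-value class*: a class of $m$ reactions contributes
$m-1$ chained difference rows.  For ordinary dual pairs this is exactly
the published construction; for deliberately merged classes (the APED
model with all stereoselectivity factors equal to 1, or the Iwamoto model
with its stereoselective/stereospecific rate equalities imposed) it is
what expresses those equalities inside the cone.  The soundness argument
is specific to the sampler's back-mapping (below): at unit concentrations
every rate monomial is 1, so equal currents are literally equal rate
constants.  Two modes are provided: `all` (default) constrains every
class; `paper` additionally drops dual pairs whose two reactions directly
interconvert the enantiomers (racemization steps $L\to D$ / $D\to L$,
recognized as "the dual is the mirror-reverse"), reproducing the variant
of the Calvin analysis that leaves racemization currents unconstrained
(the choice is conventionally made without a stated criterion, so both
modes are provided rather than guessing intent).  Since at racemic states *every* dual pair carries equal
currents, `all` is sound and prunes the cone harder.

## The sampling algorithm

Write $p(\lambda) = \lambda^k - \Omega_1\lambda^{k-1} + \dots +
(-1)^k\Omega_k$ for the characteristic polynomial of
$AV - BV$, the L/L-minus-L/D block difference of $V$ in canonical order;
$\Omega_i$ is the sum of the $i\times i$ principal minors, a polynomial of
total degree $\le i$ in $j$.  The heuristic searches the sets
$\{j \ge 0 : (-1)^i\,\Omega_i < 0\}$ for $i = 1,\dots,\min(k,5)$:

* For $i = k$, a point of the set gives $p(0) < 0$ and hence a positive
  real root — a *sufficient* condition for instability.
* For $i < k$, a negative coefficient is only *necessary* for positive
  real roots, so every sampled point is post-verified on the eigenvalues
  before being reported as confirmed.

The cap at $i \le 5$ avoids symbolic determinants of unbounded size; the
instabilities of chemically realistic networks are typically carried by
small subnetworks, whose influence appears in the leading coefficients.

**Emptiness certificate.**  If every monomial coefficient of
$(-1)^i\Omega_i$ is nonnegative, the polynomial is nonnegative on the
orthant and the region is empty — a sound certificate, and for degree-1
polynomials (always the case at $i=1$, and all $i$ when $k=1$) a complete
decision: a linear form with some negative coefficient takes negative
values on $j \ge 0$.  The pipeline therefore *rejects* a network only on
certificates (or the exact linear decision), never on failed sampling;
exhausted rejection sampling for $i \ge 2$ yields `inconclusive`.  For
order-1 networks accept/reject is always decided exactly.

**Sampling.**  Points are drawn uniformly from $[0, 2]^s$, $10^4$ draws
per coefficient index by default; the interval $[0,2]$ matches the
dimensionless working range used throughout the benchmark analyses, and
$10^4$ keeps even the order-4 APED run in seconds while resolving
acceptance fractions down to $\sim 10^{-3}$.  A feasible linear region
missed by rejection (possible when it is a thin slab) is sampled by a
deterministic descent construction instead.  All sampling is a pure
function of the seed, which is mandatory.

**Back-mapping.**  A sampled $j$ is realized as an explicit state by
setting *every* concentration to 1 and $k_q = w_q$ with
$w = \sum_l j_l v_l$ (all rate monomials evaluate to 1).  Among the
infinitely many preimages of $w$ this choice has three virtues: the state
is racemic by construction; the extended-cone constraints turn into the
dual rate-constant equalities exactly; and $\Delta = I$, so $V$ evaluated
at $j$ *is* the Jacobian at the state — the SNA verdict is exact there,
not an approximation.  Points where some reaction carries zero current are
rejected (that reaction's rate constant would have to vanish), naming the
dead reaction.

**Confirmation.**  Each back-mapped state must pass
`is_symmetry_breaking_state()` on both the reduced and the full-Jacobian
path, outside the marginal band.  Sampled points that fail are counted and
reported as candidates, never as confirmed.  The overall verdict is
`accept` on the first confirmed state, `reject` on certificates only, and
`inconclusive` otherwise.

## Dynamic confirmation

`detect_smsb()` perturbs the first pair of a racemic steady state by a
relative $\varepsilon$ (default $10^{-10}$) in both directions, integrates
the stiff mass-action ODE (`deSolve::lsoda`) in expanding chunks, and
declares SMSB when both runs saturate at a final enantiomeric excess
$\lvert ee\rvert > 0.1$ with mirror-image signs.  The default threshold is
deliberately far from both 0 and 1: confirmed instabilities in these
models run to $\lvert ee\rvert \approx 1$, while stable states relax to
$ee \approx 0$, so any threshold in between is uncritical.  The horizon is
adaptive: integration stops early only when the flow is at rest *and* the
gap has relaxed back to its initial size for three consecutive checks —
and, importantly, never when the initial gap sits below the double-precision
round-off floor ($\sim 10^{-12}$ relative).  At unit concentrations a
relative seed of $10^{-16}$ is below half an ulp: whether and when a
particular integration path amplifies it is decided by rounding noise — the
same regime in which reference simulations of these models are routinely
run, with exactly racemic initial data broken by numerical error alone.
The package therefore treats sub-ulp seeds as a magnitude
experiment — does $\lvert ee\rvert$ amplify by orders of magnitude? — and
reserves the mirror-sign requirement for resolvable perturbations.

`bifurcation_scan()` moves one rate constant (with its whole equal-value
class, keeping the network pseudochiral) along a grid, re-equilibrates the
racemic steady state by continuation — integrating the symmetric
subsystem from the previous point and re-symmetrizing against round-off —
and records the final excess at each point.  Continuation was chosen over
root-finding from scratch for robustness near folds, where Newton solvers
jump branches.

## Fixtures and the random-network generator

The package ships the classical benchmark set as plain-text fixtures:
the achiral toy network used to illustrate convex coordinates, Frank's
minimal autocatalytic model (order 1, feed held constant), Calvin's
model (order 2; the classical negative control, provably without
symmetry-breaking states), the Hochberg–Ribo replicator (order 2, with
feed inflow/outflow and replicator decay), APED (order 4, with
stereoselectivity factors $\alpha,\beta,\gamma$ as label-class structure),
and the Iwamoto model under perfect and imperfect conditions (order 2,
with only $A, L, D, E_L, E_D$ dynamic, as in the original analysis).
Typesetting-hostile names are mapped to identifiers (`^1R_L` → `R1L`,
`L*` → `Lx`); each fixture documents its choices inline.

`random_pseudochiral()` generates property-test inputs: random mass-action
reactions (coefficients $\le 2$, at most two species per side) over $k$
pairs plus achiral species, closed under the involution with shared rate
labels; every pair anchors at least one reaction.  It emulates the
*structure* of pseudochiral chemistry — involution closure, shared dual
constants, small stoichiometries — and nothing else: no thermodynamic
consistency, no mass conservation beyond what closure implies, no
realistic rate-constant magnitudes.  Green property tests on these inputs
therefore certify the algebra (Jacobian symmetry, criterion equivalences,
cone exactness) on a broad family of networks; they are not evidence about
any particular laboratory mechanism.

## Verification sizes

The oracle suites run at the following sizes, chosen so the full test
suite stays interactive while leaving the estimates nowhere near their
statistical floor: 500 random integer matrices up to $6\times 6$ for the
principal-minor characteristic coefficients against interpolated
determinant expansion; 1000 random polynomials for the Routh–Hurwitz table
against companion-matrix eigenvalues; 100 random order-1/2 networks with
back-mapped racemic steady states for the reduced-vs-full criterion
equivalence; support-subset brute force against double description for
$r \le 8$; and 100 random positive steady states for the factorization
identity $J = S\,E\,R\,\Delta$.  The benchmark pipelines run at $10^4$
samples per coefficient index.

## Known limitations

* Completeness holds only for order 1.  For $k \ge 2$ the coefficient
  regions are a heuristic superset probe: `reject` is still rigorous
  (certificates), but `inconclusive` proves nothing, and for $k > 5$ the
  truncation at $i \le 5$ additionally approximates the target set.
* Emptiness for $i \ge 2$ is only ever certified through coefficient
  signs; a region that is empty for subtler reasons stays `inconclusive`.
* The uniqueness of convex coordinates fails when $s$ exceeds the cone
  dimension; `convex_coordinates()` then returns a minimum-norm
  nonnegative solution and flags it, rather than pretending uniqueness.
* Sub-ulp perturbation experiments are round-off-seeded by construction;
  see the dynamics section.
* Thermodynamic feasibility of sampled rate constants is out of scope, as
  are stochastic kinetics and large (non-infinitesimal) perturbations of
  racemic states.

## A worked session

```{r worked, eval = FALSE}
fx <- fixture("frank")
rep <- sna_sampling(fx$network, fx$chiral, seed = 42, n_samples = 1000)
rep$verdict                      # "accept"
st <- rep$confirmed[[1]]$state   # a unit-concentration racemic steady state
detect_smsb(fx$network, fx$chiral, st)   # TRUE, final ee -> +/-1

ca <- fixture("calvin")
sna_sampling(ca$network, ca$chiral, seed = 42)$verdict   # "reject"
```
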