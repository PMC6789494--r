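# chiralnet

Stability analysis of pseudochiral mass-action reaction networks: does a
proposed mechanism of absolute asymmetric synthesis admit **spontaneous
mirror-symmetry breaking (SMSB)**, and at which parameter values?

Models of biological homochirality (Frank's autocatalytic scheme and its
many successors) explain the emergence of single-handed chemistry through
dynamic instability: a racemic steady state — one with every enantiomeric
pair balanced, `L_i = D_i` — that amplifies an infinitesimal imbalance
instead of damping it. Showing that a network has such *symmetry-breaking
states*, and exhibiting concentrations and rate constants at one, is the
central step in vetting any such model. `chiralnet` automates it.

## Method

For a pseudochiral network of order *k* (*k* enantiomeric pairs, dual
reactions sharing rate constants), the racemic Jacobian is block
symmetric; let `A` be its L-side/L-side block and `B` the L-side/D-side
block. A racemic steady state is symmetry-breaking **iff** the
characteristic polynomial of `A − B` is unstable (has a root with
`Re λ > 0`) — equivalently, iff the full Jacobian has an unstable
eigenvector that distinguishes some pair (`v_i ≠ v_{i+k}`). Both tests are
implemented and cross-checked.

Searching for such states directly means sampling a high-degree
semialgebraic set. The package instead works in Clarke's stoichiometric
network analysis coordinates: the steady states map onto the current cone
`{v ≥ 0 : S v = 0}`, enumerated exactly (integer double description) by
its extreme currents `v_1 … v_s`, and the Jacobian factorizes as
`J = S·E(j)·R·Δ` with `E = diag(Σ_l v_li j_l)` linear in the convex
coordinates `j ≥ 0`. The stoichiometric matrix is extended with rows
forcing equal currents through reactions that share a rate-constant class,
so the racemic rate equalities live inside the cone. The sampler then:

1. forms `Ω_i`, the i-th characteristic coefficient (principal-minor sums)
   of the reduced matrix `AV − BV` of `V = S·E·R`, for `i = 1 … min(k, 5)`;
2. certifies `{j ≥ 0 : (−1)^i Ω_i < 0}` empty when all monomial
   coefficients are nonnegative (an exact decision for order-1 networks),
   or samples it (uniform on `[0, 2]^s`, seeded);
3. back-maps each sampled `j` to the state with all concentrations 1 and
   `k_q = w_q`, `w = Σ_l j_l v_l` — racemic by construction, steady, and
   with `Δ = I`, so the SNA verdict is exact there;
4. confirms every state on the eigenvalues (both criteria, outside a
   `1e-9` marginal band) and, optionally, by stiff ODE integration of the
   perturbed state (`detect_smsb`, enantiomeric excess
   `ee = (L − D)/(L + D)`).

Verdicts: `accept` (confirmed state found), `reject` (certified — for
order 1, exact), `inconclusive`.

## Worked example

```r
library(chiralnet)
fx  <- fixture("frank")                # Frank's model: L + A -> 2L, etc.
rep <- sna_sampling(fx$network, fx$chiral, seed = 42, n_samples = 1000)
print(rep)
#> SNA-sampling report (order 1, 1 extreme currents)
#>   verdict: accept
#>   i=1  (-1)^i Omega_i = -j1
#>         status: found  (1000 sample points)
#>   confirmed symmetry-breaking states: 25

rep$confirmed[[1]]$state
#> network_state
#>   concentrations: A=1, P=1, L=1, D=1
#>   rate constants: k1=1.82961, k2=1.82961, k3=1.82961

sm <- detect_smsb(fx$network, fx$chiral, rep$confirmed[[1]]$state)
#> SMSB: TRUE   final ee (+): 1   (-): -1
```

Reading: Frank's order-1 network has a one-ray current cone, the single
signed coefficient `−j1` is negative on the whole open cone, so *every*
positive racemic steady state is symmetry-breaking; the sampled state
(unit concentrations, equal autocatalysis/sink constants `≈ 1.83`) is
confirmed, and a `1e-10` relative perturbation integrated forward runs to
complete homochirality (`ee → ±1`, mirror-image outcomes for the two
perturbation signs). The Calvin model, by contrast, is rejected with
coefficient certificates (`sna_sampling(...)$verdict == "reject"`): it has
no symmetry-breaking states.

Fixtures: `theta0`, `frank`, `calvin`, `aped` (and `aped_variant(alpha,
beta, gamma)`), `replicator`, `iwamoto_perfect`, `iwamoto_imperfect`,
`iwamoto_imperfect_equal`. A shell front end with `check`, `analyze`,
`simulate`, `bifurcate` and `fixtures` subcommands ships at
`inst/scripts/chiralnet.R`.

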