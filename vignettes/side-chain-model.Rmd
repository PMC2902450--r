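---
title: "A continuous probabilistic model of side-chain conformations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A continuous probabilistic model of side-chain conformations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidechainr)
```

This vignette is the package's account of its statistical model, its
numerical choices, and the design decisions that were genuinely open. The
README shows the user-facing workflow; here we explain *why* things are the
way they are.

## The model

A residue of amino-acid type $a$ with $n_\chi$ side-chain dihedrals is
modelled by a dynamic Bayesian network of $T = 2 + n_\chi$ slices, ordered
$\phi, \psi, \chi_1, \dots, \chi_{n_\chi}$. Slice $t$ has a discrete
*input index* $\iota_t$ (a bookkeeping label identifying the amino-acid
type and angle label), a discrete *hidden node* $h_t \in \{1,\dots,H\}$,
and a continuous angular output $x_t$ with a von Mises emission

$$ f(x \mid h) = \frac{\exp\{\kappa_h \cos(x - \mu_h)\}}{2\pi I_0(\kappa_h)} ,$$

the circular analogue of the Gaussian. The joint density of angles and
hidden states is

$$ p(\mathbf{x}, \mathbf{h} \mid \boldsymbol\iota)
   = P(h_1 \mid \iota_1)\, f(x_1 \mid h_1)
     \prod_{t=2}^{T} P(h_t \mid h_{t-1}, \iota_t)\, f(x_t \mid h_t). $$

Three structural features matter:

* **One model for all amino acids.** The initial and transition
  distributions are indexed by $\iota_t$, but the von Mises emission table
  $\{(\mu_h, \kappa_h)\}_{h=1}^H$ is shared by *every* slice of *every*
  amino acid. This multitask parameterization keeps the parameter count low
  and lets rare amino acids borrow statistical strength from common ones
  with similar dihedral preferences.
* **Hidden nodes couple all angles.** Because the hidden chain runs through
  every slice, the model induces dependence between all angles of the
  residue, not merely adjacent ones — in particular between the backbone
  $(\phi,\psi)$ and every $\chi$.
* **Variable slice count.** Amino acids with more $\chi$ angles simply get
  more slices; no per-amino-acid architecture is needed.

All inference reduces to the forward algorithm over the hidden chain.
Unobserved slices contribute an emission factor of 1 (they are integrated
out), which yields both backbone-dependent quantities (condition on
$\phi,\psi$: `loglik_chi(..., "conditional")`, `sample_conditional()`) and
backbone-independent ones (mask $\phi,\psi$ unobserved:
`loglik_chi(..., "marginal")`, `sample_ancestral()`). Likelihoods are
reported as per-radian log *densities* in nats; they are not directly
comparable with the discrete per-rotamer *probabilities* printed by rotamer
libraries, only with other densities.

## Scope of the amino-acid menu

Eighteen amino acids carry at least one rotatable side-chain dihedral and
are modelled; alanine and glycine have none and pass through untouched
everywhere. Proline is included with two $\chi$ angles: its ring makes them
strongly constrained rather than free, but they are still well-defined
dihedrals, and modelling them keeps the menu uniform. The chi-count table
is `chi_counts()`; the deterministic input-index scheme (amino acids in
alphabetical 3-letter order, angles in the order $\phi,\psi,\chi_1..$) is
`build_index_map()`. Whether backbone indices should be shared across amino
acids was an open choice; we assign each amino acid its own $\phi$ and
$\psi$ indices, because the index is defined as identifying *both* the
amino-acid type and the angle label, and per-type backbone indices let the
model express type-specific Ramachandran preferences at no structural cost.

Backbone-independent use keeps the $\phi/\psi$ slices in the chain and
merely marks them unobserved; the alternative — building a shorter chain —
would need a second parameterization. With evidence masks one parameter set
serves both modes.

## Training

`chi_dbn()` fits by expectation-maximization:

* **exact** (default): the E-step computes per-slice hidden posteriors and
  pairwise transition expectations by forward–backward; the M-step
  re-estimates every CPD row from expected counts plus a pseudocount, and
  the shared emissions by weighted von Mises maximum likelihood. The
  per-datum log-likelihood is non-decreasing up to the convergence
  tolerance, which the test suite asserts on every fit.
* **stochastic**: the E-step instead draws hidden-state sequences from
  their *exact* posterior (forward pass, then backward sampling) and uses
  hard counts. This variant trades the monotonicity guarantee for cheaper
  steps and some ability to escape shallow local optima. Its M-step,
  initialization and stopping rule are identical to the exact variant; the
  number of posterior draws per datum is 1 per iteration. These schedule
  choices are our defaults, documented here rather than derived from
  anywhere.

Tunable parameters, with defaults and rationale:

| parameter | default | units | why |
|---|---|---|---|
| `hidden` (H) | 15 | states | chosen by `select_hidden()` in practice; 15 is a sensible floor for real data |
| `tol` | 1e-6 | nats/residue | improvement below this is invisible at test-set scale |
| `max_iter` | 300 | iterations | EM on these models converges in tens of iterations; 300 is a safety bound |
| `restarts` | 1 | — | recovery studies here use 2–5; EM is multimodal, restarts are the standard remedy |
| `pseudocount` | 1e-3 | counts/cell | prevents structurally absorbing zero rows; small enough not to bias well-visited rows |

With `pseudocount = 0`, a CPD row that receives no (expected) counts is
left at its previous value rather than renormalized garbage — the M-step
only updates rows with positive mass.

Model selection uses AIC $= 2k - 2\log L$ with $k$ the *dense*
free-parameter count: $K(H-1)$ initial, $KH(H-1)$ transition and $2H$
emission parameters, $K$ being the number of input indices. A trained model
usually has many near-zero probabilities; `count_parameters(nonzero_only =
TRUE)` reports the strictly-positive count (threshold $10^{-8}$) for users
who prefer that convention. We default to the dense count because it is
what the AIC penalty formally assumes; the choice rarely changes the
selected $H$ since both counts grow the same way.

## Numerical choices

* **Scaled forward recursions.** Forward vectors are renormalized per slice
  and the log scaling factors accumulate the log-likelihood. This is robust
  for concentrations up to the cap below, unlike naive probability-space
  recursions.
* **Concentration cap.** $\kappa$ is capped at 700, the largest value for
  which $I_0$ and the density remain finite in double precision; the
  density uses `besselI(..., expon.scaled = TRUE)` throughout, so
  $\log I_0$ is computed stably at any admissible $\kappa$.
* **Maximum-likelihood $\kappa$.** The weighted MLE solves
  $A(\kappa) = I_1(\kappa)/I_0(\kappa) = \bar R$ via Fisher's closed-form
  three-regime approximation followed by Newton refinement to
  $|A(\kappa) - \bar R| < 10^{-10}$ (at most 50 steps, in practice 2–4).
* **Sampling.** Von Mises draws use Best–Fisher rejection sampling with a
  wrapped-Cauchy envelope (acceptance ≥ ~65% at any $\kappa$), vectorized
  in batches; $\kappa = 0$ falls back to the circular uniform.
* **Angles.** Radians in every API; degrees only in files (angle TSV,
  rotamer libraries, CLI flags). Dihedrals live in the half-open interval
  $[-\pi, \pi)$, so an exactly trans arrangement reports $-\pi$.
* **Reproducibility.** Every stochastic entry point takes a `seed`
  argument, evaluated under a local RNG state that is restored afterwards;
  master seeds derive per-restart/per-iteration sub-seeds.
* **Model files.** JSON with 17 significant digits — enough to round-trip
  IEEE doubles bit-exactly, which the tests assert.

## Rotamer-library densities and model comparison

A backbone-independent rotamer library defines the mixture density
$q_R(\boldsymbol\chi) = \sum_r P(r) \prod_j N(\chi_j; \mu_{rj},
\sigma_{rj})$. We evaluate each Gaussian on the *wrapped* difference
`angle_diff(chi, mu)` folded to $(-\pi,\pi]$: libraries contain rotamers
with means near $\pm180°$, and unwrapped evaluation would split their mass
across the seam. For the standard deviations found in libraries
($\lesssim 30°$) the wrap leakage is negligible and the density still
integrates to 1 within $10^{-3}$ (asserted by quadrature in the tests).

Two models are compared through the relative Kullback–Leibler divergence
$D(p\|q_r) - D(p\|q_b)$, estimated as the empirical mean of
$\log q_b(x_i) - \log q_r(x_i)$ over test observations drawn from $p$ —
the unknown normalizer of $p$ cancels. Positive values mean model $b$ fits
better. Values are reported in nats and labelled as such in every output;
divide by $\log 2$ for bits.

## Geometry

Side chains are built from the backbone (N, CA, C) by sequential
internal-to-Cartesian (NeRF) placement with ideal bond lengths and angles
(Engh–Huber-type values, shipped as a table in `sidechain_topology()`), the
$\chi$ dihedrals being the only degrees of freedom. The C$\beta$ improper
dihedral (N–C–CA–CB $= +122.6°$) was calibrated against high-resolution
crystal-structure geometry so the build has the correct L-chirality. The
canonical $\chi$ quadruples used for extraction are *derived from the same
topology table*, which guarantees the build→extract round trip to
$10^{-6}$ rad by construction — asserted across all 18 amino acids anyway,
since a transcription error in the table would break it.

PDB reading and writing delegate to `bio3d`; hydrogens are always dropped
(the energy model is heavy-atom only), alternate locations resolve to the
highest-occupancy copy, and chain breaks (CA–CA > 4.5 Å) and incomplete
backbones are flagged. Ring closure bonds that the sequential construction
does not traverse (e.g. in histidine or tryptophan) are declared explicitly
so the nonbonded exclusion lists are right.

## Packing

`pack_side_chains()` places side chains on a fixed backbone by
Metropolis–Hastings. Each iteration jointly resamples
`residues_per_move = 3` randomly chosen residues from the model and accepts
or rejects the joint move — joint, with one accept/reject, because that is
what lets two side chains swap positions in a packed core; sequential
single-residue acceptance could not cross such barriers. (Whether to accept
the three moves jointly or one at a time was an open choice; we use one
joint decision.)

The energy is an unmodified Lennard-Jones 6-12 potential,
$4\varepsilon[(\sigma/d)^{12} - (\sigma/d)^6]$, over all non-excluded
heavy-atom pairs: 1-2 and 1-3 bonded pairs excluded, 1-4 included at full
weight. Parameters follow the OPLS convention — $\sigma$ is the
*zero-crossing* of the pair potential (the minimum sits at $2^{1/6}\sigma$)
and pair parameters combine by geometric means. Users coming from
conventions where "$\sigma$" denotes the optimal distance should note this
explicitly: with our form the well depth is exactly $-\varepsilon$ at
$2^{1/6}\sigma$, which the tests assert analytically. A small packaged
atom-class table maps residue/atom names to $(\varepsilon, \sigma)$; there
is no softening or tweaking of the potential, only a numerical cap at
$10^6$ kcal/mol per pair to avoid overflow.

Energies become probabilities via Boltzmann's law at $T = 298.15$ K:
$RT \approx 0.5925$ kcal/mol, computed from the gas constant rather than
hard-coded. Three acceptance modes:

* `proposal_only`: the target is the pure Boltzmann distribution; the model
  enters only as the proposal, and the Hastings correction
  $q(x)/q(x')$ makes the sampling of the physical distribution unbiased.
* `pseudo_energy`: the model density multiplies the target as well; since
  it is also the proposal, the four-term Metropolis–Hastings ratio
  algebraically reduces to the plain energy ratio. `mh_accept(reduced =
  FALSE)` evaluates the unreduced expression; the tests check the two agree
  to $10^{-12}$.
* `pseudo_energy_bbdep`: as above with conditional (backbone-dependent)
  model densities and forward-backtrack proposals.

The returned prediction is the visited state minimizing the mode's score
(energy, or energy $- RT\log q$). Accuracy against a reference uses the
field's $\pm20°$ criterion per $\chi$, with the conditional
$\chi_2|\chi_1$ column counting $\chi_2$ only among residues whose $\chi_1$
is already correct. Folding of the two-fold terminal symmetries (Phe/Tyr
$\chi_2$, Asp $\chi_2$, Glu $\chi_3$) is available but off by default, so
default numbers are conservative. Burial can be supplied as a mask or
approximated by the built-in Shrake–Rupley-style surface routine.

## What the synthetic data do and do not emulate

`make_ground_truth()` provides data-generating models with known
parameters: a `"random"` style (Dirichlet CPDs, spread emissions,
$\kappa \in [2, 20]$, with a quadrature check that the backbone actually
informs $\chi_1$ — total variation above 0.05 at some backbone
conformation, so conditioning tests cannot pass vacuously) and a
`"rotameric"` style (three hidden states at the staggered positions
$-60°/60°/180°$, $\kappa = 30$, i.e. an angular spread of about $10°$,
with hand-set couplings in which the backbone flips the preferred
$\chi_1$ rotamer). `sample_dataset()` draws i.i.d. residues;
`make_toy_protein()` builds small ideal-geometry structures with recorded
native side chains, including the `helix_clash` layout in which the two
leucines' individually most probable rotamers collide sterically
(closest approach ~1.0 Å) while the native combination is clash-free.

These fixtures emulate the *structure* of real training data — amino-acid
mixtures, missing backbone observations at chain termini, rotamer-like
multimodality, backbone–side-chain coupling — but not its messiness:
no experimental coordinate error, no alternate conformations, no
non-rotameric states, no crystal contacts, and far fewer residue types per
dataset. A passing suite therefore demonstrates that the *machinery* is
correct (likelihoods exact, samplers exact, EM recovers truth, the MH
sampler targets its stationary distribution, the geometry round-trips),
not that a model trained on the toys describes real proteins.

## Problem sizes

The verification suite runs at sizes chosen to make each statistical check
well-powered while keeping a full run comfortable on a laptop: $2\times
10^5$ draws for sampler-vs-density histograms, $10^5$ for estimator
calibration, $2\times 10^4$ residues for EM recovery (held-out gap below
0.05 nats/residue), five seeded repetitions of the AIC scan over
$H \in \{2,3,5\}$ at $4\times 10^3$ residues each, $2\times 10^5$
Metropolis–Hastings iterations for the stationary-distribution check, and
five seeded 3000-iteration packing runs for the end-to-end pipeline. The
packing default of 500{,}000 iterations reflects production use on real
proteins, not the toys.

## Known limitations

* Ideal covalent geometry: small real variations in bond angles (notably
  $\tau$(N–CA–C)) are ignored; rebuilt side chains can deviate slightly
  from crystal coordinates even at the correct $\chi$.
* Heavy atoms only; no hydrogens, hydrogen bonds, electrostatics or
  solvation in the packing energy. Packing accuracy on exposed residues is
  accordingly not meaningful; evaluate buried residues.
* The rotamer-library reader handles mean/SD-style backbone-independent
  libraries; purely discrete conformer lists have no density and cannot be
  compared by KL divergence. Backbone-dependent libraries are out of scope
  (they provide no joint density over backbone and side chain).
* Proline's ring constraint is not enforced during building: the two
  $\chi$ values are taken at face value, and the ring-closure bond is used
  only for exclusion bookkeeping.
* mmCIF, multi-model and multi-chain files beyond simple cases are not
  supported.
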