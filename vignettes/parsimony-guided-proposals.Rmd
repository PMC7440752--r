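---
title: "Parsimony-guided tree proposals: model, mechanics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony-guided tree proposals: model, mechanics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgmcmc)
```

## The problem

Bayesian phylogenetic inference samples unrooted binary trees (topology plus
branch lengths) in proportion to their posterior probability with Markov
chain Monte Carlo. The hard part is the topology move: uniform-at-random
SPR or TBR rearrangements mostly propose terrible trees and are rejected,
while the standard remedies (stochastic NNI, the "extending" eSPR/eTBR
moves that random-walk the regraft point away from the pruning point) still
leave chains stuck on local peaks of rugged tree spaces.

`pgmcmc` implements a family of *parsimony-guided* proposals, pSPR and pTBR,
alongside the standard sNNI/eSPR/eTBR reference moves. The guided moves
score every candidate regraft (or reconnection) point by the Fitch
parsimony score of the resulting tree — a few orders of magnitude cheaper
than the likelihood — and propose candidates with probability proportional
to a score-derived weight. Because the proposal distribution is known
exactly, the asymmetry it introduces is removed exactly by the
Metropolis–Hastings proposal ratio, so the sampled posterior is untouched:
parsimony is only used to *propose* well, never to *weigh* trees.

## The guided weights

After pruning a subtree A at branch $a$ (the pendant branch $q$ travels with
it; the branch left behind, $b$, bridges the gap in the remainder), every
branch $i$ of the remainder is a regraft candidate with weight

$$\omega_i = \rho_i^{\,\epsilon S_i},$$

where $S_i$ is the parsimony score of the tree regrafted at $i$ minus the
scores of the two detached subtrees, $\epsilon$ is the *warp factor*
controlling how strongly parsimony biases the choice, and $\rho_i$ is the
*base factor*:

* **scheme 1 (pSPR1/pTBR1)** — $\rho_i = e^{-1}$, so
  $\omega_i = e^{-\epsilon_1 S_i}$ (default $\epsilon_1 = 0.5$);
* **scheme 2 (pSPR2/pTBR2)** — $\rho_i$ is the JC69 probability of ending
  in one specific different state over the quick branch-length estimate
  $\hat v_i = S_i/N + \eta$:
  $\rho_i = \tfrac14\!\left(1 - e^{-4\hat v_i/3}\right)$ with
  $\epsilon_2 = 0.1$, $\eta = 10^{-4}$ and $N$ the number of sites used for
  guidance. High scores on what is probably just a long branch are thereby
  discounted.

Two conventions of the scheme-2 base factor circulate: the total
change probability $\tfrac34(1 - e^{-4\hat v/3})$ and the per-state
$\tfrac14(1 - e^{-4\hat v/3})$. Only the $\tfrac14$ variant reproduces the
reference example weight tables that fix this move family's tuning (the
package's acceptance tests pin all 28 table cells to three decimals), so it
is the default; `move_tuning(rho_scheme = "threequarter")` selects the
other. Both are valid proposal distributions — the choice affects sampling
efficiency only, never correctness, because the Hastings ratio adapts.

The move is *Metropolized*: the current attachment $b$ is excluded from the
candidate set, so the topology always changes. With old attachment $b$ and
proposed attachment $r$, the proposal ratio is

$$\frac{\omega_b \big/ \sum_{i \in \mathcal B \setminus r} \omega_i}
       {\omega_r \big/ \sum_{j \in \mathcal B \setminus b} \omega_j},$$

evaluated in log space after shifting all log weights so the minimum-score
candidate sits at zero — this bounds the exponent range and keeps the ratio
finite even when guidance data are long and scores span hundreds of steps.

pTBR applies the same weighting jointly to reconnection *pairs* $(i, j)$
within $\delta$ nodes of the bisected branch on either side
($S_{ij}$ per pair, identity pair excluded, default $\delta = 5$, up to
roughly $2^6 \cdot 2^6 = 4096$ candidates). Because the reverse
neighbourhood is centred on the landing branches, the reverse-move sums run
over the reverse candidate sets; the implementation computes both sides
exactly.

## Fast candidate scoring

Scoring ~$2n$ SPR candidates (or thousands of TBR pairs) per proposal with
full-tree Fitch passes would be wasteful. The package computes, for every
branch of the pruned remainder, a direction-aware pair of Fitch state sets
(one per side of the branch) in two passes, and combines them into a
per-branch "root set" $X_i$. The candidate score then reduces to

$$S_i \;=\; \sum_{\text{patterns } p} w_p\,
            \big[\, X_{i,p} \cap A_p = \emptyset \,\big],$$

where $A_p$ is the Fitch set at the root of the moving subtree — one subset
intersection per pattern per candidate. The test suite asserts *exact*
equality between these incremental scores and brute-force rescoring
(regraft, full Fitch pass) on hundreds of random instances; the same holds
for the TBR pair scores. Ambiguity codes participate as their state
subsets, and gaps/`?`/`N` are treated as fully missing — the common
convention for both parsimony and likelihood.

## The reference moves and their proposal ratios

* **sNNI** picks an interior branch and swaps one of the two subtree pairs
  across it with equal probability; the proposal ratio is 1 and branch
  lengths map across unchanged.
* **eSPR/eTBR** move the regraft point with an extension walk: one
  mandatory step away from the pruning point, direction chosen uniformly
  among the interior endpoints of the bridge, then repeated extension with
  probability $p_e$ (default 0.5) and a fresh binary direction choice at
  each interior node; the walk stops when it lands on a terminal branch.
  The Hastings ratio is computed as the exact ratio of forward and backward
  path probabilities of this walk,
  $(I_b/I_r)\cdot(\tau_{\text{rev}}/\tau_{\text{fwd}})$, where $I_x$ counts
  the interior endpoints of the start/end branch and $\tau$ is the stop
  factor ($1-p_e$ for a free stop, 1 for a tip-forced stop). This
  reproduces the familiar constants — 1 when unconstrained or constrained
  in both directions, $1/(2(1-p_e))$ when only the backward walk is
  tip-constrained, $2(1-p_e)$ when only the forward walk is — which the
  tests assert verbatim. eTBR forces one uniformly chosen movable end of
  the bisected branch to walk and lets the other walk at all with
  probability 1/2.

With $p_e = 0.5$, eSPR proposes an NNI-equivalent rearrangement half the
time and eTBR a quarter of the time — *exactly* so only when no tip
truncates the walk, and more often otherwise. On any finite tree tips do
interfere, so the package's mechanism tests measure the fractions among
proposals whose first extension edge is interior (and, for eTBR, whose
optional end was free to move), for which the design values $1-p_e$ and
$(1-p_e)/2$ hold exactly on any tree; NNI-equivalence of the flagged
proposals is independently verified topologically.

After every SPR-family topology change, the three branch lengths the move
handled — the picked branch $v_a$, the pendant moved with it $v_q$, and the
branch left behind $v_b$ (for TBR: the bisected branch and the two
pendants, one per moved side) — are each rescaled by an independent
multiplier $m = e^{\lambda(u - 1/2)}$, $u \sim U(0,1)$, adding $\log m$ per
branch to the log proposal ratio. The default $\lambda = 2\ln 1.05$ bounds
each change at 5% up or down.

## Likelihood, priors, chain mechanics

The likelihood is the pruning algorithm over compressed site patterns under
JC69, K80 or GTR, optionally with discrete-gamma rate variation
(equal-probability categories, *mean* category rates — the dominant
convention in Bayesian phylogenetics software). Every internal node
rescales its partial likelihoods per pattern and category, so long trees
and many taxa do not underflow; the result is invariant to where the
traversal is rooted (asserted to $10^{-9}$) and matches an independent
pruning implementation (phangorn) to $10^{-6}$ on random instances. GTR
transition probabilities come from the spectral decomposition of the
symmetrised rate matrix; the engine's fixed-size Jacobi solver is checked
against base R's `eigen`.

Priors: uniform over unrooted topologies; branch lengths either i.i.d.
exponential or the compound gamma-Dirichlet — tree length
$T \sim \mathrm{Gamma}(a_T, b_T)$ ($b_T$ a *rate*; the default
gamma-Dirichlet(1, 0.1, 1, 1) gives mean tree length 10) with branch
proportions Dirichlet($a_c$, internal concentration $a_c c$) and the
$(v) \to (T, \text{proportions})$ Jacobian included. The density is
verified by numerical quadrature (it integrates to 1 over the three-branch
simplex slice) and by prior-only MCMC recovering the Gamma tree-length
marginal. The gamma shape takes an Exponential(1) prior; when $\kappa$ is
sampled it takes an Exponential(0.1) prior (mean 10, weakly informative —
the move family itself never requires sampling $\kappa$); GTR
exchangeabilities take a flat Dirichlet with stationary frequencies fixed
at their empirical values.

One move per generation is drawn from a weighted schedule
(`schedule_preset` reproduces the standard mixes: the 5:1
tree/branch-length prior-recovery protocol; the reference mix 1 sNNI :
2 eSPR : 1 eTBR : 2 pSPR2 : 1 pTBR2 at 46.67/50/3.33% category masses; the
evaluation mixes at 36/60/4%). Within the branch-length mass a single
branch scaler and a tree-length multiplier split 4:1 — the reference protocols
do not fix this split, so it is a package choice, logged with every run.
Optional Metropolis coupling runs $k$ chains at
$\beta_i = 1/(1 + \lambda_h i)$ (default $\lambda_h = 0.1$) with one
random-pair swap attempt per generation; only the cold chain is sampled.
Acceptance uses
$\min\!\big(1, e^{\beta \Delta\log L + \Delta\log\pi + \log H}\big)$ and
runs are bit-reproducible given a seed (the engine carries its own
generator; R's RNG only seeds it and builds starting trees).

## What the simulator emulates — and what it does not

`simulate_dna` evolves sites independently down the tree from stationary
root states, with per-site rates drawn from a continuous Gamma when the
model carries rate variation. `lba_fixture` builds the classic
five-taxon long-branch-attraction geometry — two long terminal branches
(0.8 expected substitutions/site) separated by short interior branches
(0.05), values chosen once as a reconstruction of the usual Felsenstein-
zone setup — simulates K80 ($\kappa = 4$) sequences, and *verifies* by
exhaustive Fitch scoring of all 15 topologies that parsimony is misled into
joining the long branches while the likelihood prefers the truth.

The generator produces i.i.d. sites without indels, codon structure,
partitions or alignment error. Passing the validation suite therefore
demonstrates the *correctness of the samplers* (exact Hastings ratios,
detailed balance, convergence diagnostics), not robustness to real-data
violations of the substitution model.

## The validation experiments

The acceptance tests rerun, at desk scale, the experiments that validate a
guided-proposal implementation:

1. **Example weight tables** — both weighting schemes at scores 10–16,
   reproduced to three printed decimals.
2. **Uniform-prior recovery** — with the likelihood held constant, a
   correct sampler must recover the uniform topology prior
   (1/15 ≈ 0.0667 per five-taxon topology). Each of the seven move families
   runs a single 10-million-generation chain (sampled every 100, 25%
   burn-in; the per-topology Monte Carlo s.e. is then ≈ 0.0009, so the
   ±0.005 pass band sits at >5 s.e.) — a scale the compiled engine covers
   in seconds per million generations.
3. **Misleading-guidance test** — guide weights computed from the first
   100 or 1000 sites of the long-branch alignment while the likelihood
   stays constant: uniform recovery must survive, and the
   parsimony-attracted topology must not be oversampled relative to the
   generating one (one-sided two-proportion test at $\alpha = 0.01$). This
   is the decisive check that the proposal ratio, not the guidance, owns
   the stationary distribution.
4. **Mechanism fractions** — the NNI-equivalence rates of eSPR/eTBR above.
5. **Cross-sampler agreement** — four single chains (sNNI; eSPR+eTBR;
   pSPR1+pTBR1; pSPR2+pTBR2) on an 8-taxon, 500-site K80 simulation with
   deliberately short interior branches (several splits stay genuinely
   contentious) must agree pairwise to ASDSF ≤ 0.01 after 1 million
   generations each.

The signal strength of experiment 5 is deliberate: on weaker data the
posterior can fragment into tree islands that single extending chains
cross only rarely — the very pathology guided proposals exist to fix — and
cross-run disagreement would then measure per-sampler mixing ability
rather than correctness. The fixture therefore keeps enough signal that
every move family mixes, while its short interior branches keep several
splits genuinely uncertain so the comparison is informative.

## Numerical and edge-case choices

* Candidate weights and Hastings sums use shifted log-sum-exp throughout.
* Zero-length branches are legal for the topology code and parsimony
  (the length prior may veto them); the branch scaler refuses length 0.
* Degenerate picks (an SPR whose remainder would keep only two tips; a TBR
  end flanked by a two-tip side) are rejected and redrawn symmetrically, so
  no Hastings correction is needed for them.
* Proposal candidate sets work at branch granularity of the pruned
  remainder — the two half-segments of a previously split branch are not
  distinguished, matching the branch-set sums of the proposal-ratio
  formula.
* ASDSF uses the sample standard deviation (denominator $n-1$) across runs
  and the conventional 0.10 inclusion threshold; both are configurable and
  recorded, since reported analyses rarely print them.
* Split identifiers orient each bipartition to the side not containing the
  alphabetically first taxon; topology keys are the sorted split sets, so
  they are stable across node orderings, rotations and runs.

## Known limitations

Single partition, nucleotide data only; no invariant-sites mixture; no
clock or rooted trees; no checkpointing; chains execute sequentially. The
pTBR neighbourhood is truncated at $\delta$ nodes by design, so it is not
irreducible on its own for very large trees — schedules should (and the
presets do) mix move families.
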