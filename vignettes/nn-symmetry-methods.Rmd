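---
title: "Methods: testing spatial symmetry in nearest-neighbor structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing spatial symmetry in nearest-neighbor structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnsymmetry)
```

## The two symmetry hypotheses

For a completely mapped pattern of $n$ labeled points in the plane, every
point has a unique nearest neighbor (NN), giving a digraph with exactly one
outgoing arc per point. Two summaries of this digraph carry the symmetry
structure:

* the **NNCT** $N_{ij}$, counting base points of class $i$ with a class-$j$
  NN. *Mixed-structure symmetry* is $\mathrm{E}[N_{ij}] =
  \mathrm{E}[N_{ji}]$ for all $i \neq j$.
* the **Q-symmetry table** $Q_{im}$, counting class-$i$ points that serve as
  a NN to exactly $m$ others. *Shared-structure symmetry* says the rows have
  a common distribution.

Both hypotheses are implied by two reference nulls: *CSR independence*
(each class an independent binomial process on the window) and *random
labeling* (RL; labels permuted over fixed locations). The tests differ in
which null they are calibrated against, and this calibration — not the
hypothesis — decides which test may be used on completely mapped data.

## Test statistics and their calibration

**Type I (McNemar / Bowker / exact binomial).** These treat the $n_t =
N_{12} + N_{21}$ mixed base–NN pairs as independent trials, which holds only
under sparse sampling of base–NN pairs. On completely mapped data the pairs
are strongly dependent (reflexivity alone creates dependence), the binomial
variance badly overstates the true variance of $N_{12} - N_{21}$, and the
tests become extremely conservative — our CSR study (10&nbsp;000 replicates,
two classes of 50) measures empirical size below $10^{-3}$ at nominal .05
for both corrections. Every result object of these tests carries a standing
warning, and `randomization_test()` provides the label-permutation version
whose size is correct by construction.

**Dixon's test.** Under RL the moments of NNCT cells are exact
finite-sample quantities. We compute every cell covariance by an *arc-pair
decomposition*: writing $N_{ij}$ as a sum of label indicators over arcs,
the $n^2$ ordered arc pairs fall into five coincidence classes — same arc,
reflexive pair, shared target, head-of-one-equals-tail-of-other (twice) —
with counts $(n, R, Q, n-R, n-R)$ and remainder $n^2 - 3n - Q + R$, where
$Q = \sum_j j(j-1)Q_j$ and $R$ is twice the number of reflexive pairs. Each
class contributes a falling-factorial probability that an ordered tuple of
distinct points carries the required labels. This reproduces the familiar
closed forms for $\mathrm{Var}[N_{ij}]$ and
$\mathrm{Cov}[N_{12}, N_{21}]$, extends them to all six index cases needed
for the multi-class covariance matrix $\Sigma_{\mathrm{sym}}$ of
$T_S = (N_{ij} - N_{ji})_{i<j}$, and is verified in the test suite against
exhaustive enumeration of all labelings for patterns with $n \le 8$
(agreement to $10^{-12}$). Two consequences worth noting:

* the exact RL expectation is $\mathrm{E}[N_{ij}] = n_i n_j/(n-1)$; the
  often-quoted $n_i n_j / n$ is its large-$n$ form. We use the exact form
  throughout, which is also what the enumeration oracle yields.
* when all four classes in $\mathrm{Cov}[N_{ij} - N_{ji}, N_{kl} - N_{lk}]$
  are distinct, the four cell covariances are equal (though individually
  nonzero) and the contrast covariance vanishes — exactly, even in floating
  point, because identical terms cancel.

The overall statistic is $T_S' \Sigma_{\mathrm{sym}}^- T_S$ with a
Moore–Penrose inverse (relative eigenvalue tolerance $10^{-10}$) and df
equal to the numerical rank; for two classes this is $Z_D^2$. Under CSR the
observed $Q$ and $R$ are plugged in, making the reference distribution
conditional on the realized geometry.

**Type II (Pearson on the Q-symmetry table).** Expected counts are
$n_i Q_m / n$ (row sum × column sum / total); df is
$(k-1)(\#\text{columns}-1)$. Although the row-wise independence assumptions
fail for mapped data, the reduced table (columns $m \ge 2$ merged, df
$2(k-1)$) holds its level empirically — our CSR study measures .0497 at
nominal .05 — so this is the default reduction. An adaptive
expected-count-based merging rule is available but never merges below two
columns.

**Exact tests on the Q-symmetry table.** Conditional on all margins, table
probabilities are multivariate hypergeometric; we enumerate all tables with
the observed margins (vectorized for two rows; depth-first with pruning and
a $10^7$-table cap otherwise) and report five two-sided p-value variants.
Probability ties are compared with relative tolerance $10^{-12}$ so
equally-likely tables enter the rejection set together. The
twice-table-inclusive value is capped at 1 to keep probability semantics.
The Tocher rule is randomized only in the boundary case
$p_{\mathrm{exc}} < \alpha < p_{\mathrm{inc}}$; the realized uniform draw
and seed are always reported, never applied silently. For more than two
rows full enumeration is rarely feasible and `exact_symmetry_mc()` samples
fixed-margin tables by Patefield's algorithm — an extension beyond the
two-row setting, flagged as such. The table-exclusive variant is the one
whose empirical size sits inside the acceptance band in our CSR study; the
others are mildly conservative.

## Nearest-neighbor computation

Distances are Euclidean in double precision, or taken from a user-supplied
dissimilarity matrix (symmetric, finite off-diagonal, minimal diagonal);
nothing in the test machinery assumes planarity except the serving-count
cap, for which the general statistic $\tilde Q = 2\sum_j \binom{j}{2} Q_j$
is kept alongside the capped planar form ($Q = \tilde Q$ whenever no point
serves more than six times, which is always the case for planar Euclidean
data). Tied minimal distances are resolved to the lowest point index by
default — deterministic and reproducible on grid-recorded coordinates — with
seeded random tie-breaking available; tie-broken assignments are flagged.
Duplicate points are legal (a NN at distance 0) and produce a warning. No
edge correction of any kind is applied; near the window boundary the tests
are accordingly slightly conservative or liberal.

## The pattern generators

The simulation families define the conditions under which the tests' size
and power are studied; all live on the unit square with classes 1 (X) and
2 (Y).

* **csr** / **rl-uniform**: both classes iid uniform; the size benchmark.
* **rl-matern**: Matérn cluster background (Poisson($\kappa$) parents,
  Poisson($\mu$) offspring uniform in a disc of radius $r$), labels split
  $\lfloor n/2 \rfloor$ / rest. Realizations with $n < 4$ (possible under
  the Poisson counts) are redrawn, as the RL moments need four points.
* **caseI**: Y bivariate normal around the centre, sd $\sigma$ — central
  clustering of one class.
* **caseII**: each Y is attached, with probability $p$, to a randomly
  picked X (with replacement) with polar jitter of radius uniform on
  $(0, d)$, $d$ = that X's NN distance among the X's; otherwise uniform.
  The attachment radius is read per-point rather than as the global minimum
  inter-X spacing: the global reading glues every attached pair into a
  mutual-NN couple and the family degenerates to near-perfect pairing.
* **caseIII**: X on $(0, 1-s)^2$, Y on $(s, 1)^2$ — segregation with
  overlap $(1-2s)^2$ for $s < 1/2$.
* **caseIV**: half of each class iid on its (possibly shifted) support, the
  other half displaced from its partner by a fixed radius $r$ at a uniform
  angle — abundant self-reflexive pairs. Displaced points may leave the
  window; they are deliberately not clipped, since the tests use no window
  information.
* **caseV**: $Y_j = X_j + r(\cos T_j, \sin T_j)$ — fully paired
  association.
* **caseVI**: the three-stage asymmetric-association construction with
  $n_1 = n_2 = m_1 + 2m_2$. Stage 1: $m_1 + m_2$ uniform X's; a Y is glued
  to each of the first $m_1$ at radius $U(0, \rho d^x_i)$, inside that X's
  NN ball. Stage 2: an extra X is glued the same way to each of the last
  $m_2$ X's. Stage 3: $m_2$ further Y's are uniform, and $m_2$ more are
  attached around randomly picked stage-1 X's with the caseII attachment
  radius. The recipe for the third stage is the one genuinely open design
  point in this family: gluing the last Y's tightly to the uniform Y's
  (the most literal alternative) collapses the family's signature — the
  off-diagonal NNCT means become nearly equal, and sporadically the digraph
  becomes perfectly reflexive ($Q = 0$, $R = n$), where
  $\mathrm{Var}[N_{12} - N_{21}] = 0$ and $Z_D$ is undefined. The adopted
  attachment reproduces the family's intended one-directional asymmetry
  (class-1 points all acquire very close NNs; many class-2 points have
  class-1 NNs without reciprocation) with moment behavior consistent
  across the whole $\rho$ range.

All generators consume the current RNG state (or an explicit seed):
identical specification and seed give identical patterns.

What the generators deliberately do **not** emulate: inhomogeneous
intensity, interaction (Gibbs) structure, measurement-grid coordinate
rounding (hence ties), and observation windows with edges that matter.
Passing the simulation-based tests therefore says nothing about edge
effects or tied distances in field data; the deterministic tie rule and the
duplicate-point path are exercised by separate unit tests.

## Monte Carlo harness and study sizes

`empirical_rejection_rate()` follows the standard estimator: a replicate
rejects when its statistic exceeds the asymptotic critical value (or its
exact p-value falls below $\alpha$). With 10&nbsp;000 replicates at
$\alpha = .05$, estimates outside $(.0464, .0536)$ are conservative/liberal
at the binomial 95% band. `rl_rejection_rate()` implements the RL protocol
(fresh backgrounds, many relabelings each, digraph computed once per
background). The packaged test suite uses 10&nbsp;000 replicates for the
CSR size study, 2&nbsp;000 for each power study and the moment summaries,
and 60 patterns of 1&nbsp;000 points for the large-$n$ shared/reflexive
rates $\mathrm{E}[Q/n] \approx .63$, $\mathrm{E}[R/n] \approx .62$; the
acceptance script uses 10&nbsp;000 replicates throughout.

## Post hoc analysis

After a significant overall test, `pairwise_symmetry_tests()` (unrestricted:
sub-tables extracted from the full pattern, full-pattern $Q$, $R$, $n$ in
the variance; restricted: everything rebuilt from the two classes alone) and
`one_vs_rest_symmetry_tests()` (labels pooled, geometry untouched) localize
the asymmetry. The two pairwise modes answer different questions and can
disagree; the unrestricted mode is the natural companion of a significant
overall test, while one-versus-rest aggregates the same table the overall
shared-structure test used. No multiplicity adjustment is applied by
default (matching how such post hoc batteries are usually reported); Holm
adjustment is available by flag. Significance of the overall test is
narrative guidance, never enforced programmatically.

## Asymptotic utilities

`local_power(lambda, nu, alpha)` gives the first-order expansion of the
power of a $\chi^2_\nu$ test in the noncentrality $\lambda$,
$\beta \approx \alpha + \lambda(-\alpha/2 + [1 - F_{\nu+2}(q_{\nu,1-\alpha})]/2)$,
with $F_{\nu+2}$ the *central* cdf with two extra df evaluated at the
central critical value — the reading under which $\beta(0) = \alpha$ exactly
and the slope matches the noncentral tail numerically. `pae_dixon(nu1, p_q)
= 1/(\nu_1(1-\nu_1)p_q)$ and `pae_pielou() = 4` give the Pitman
efficiencies under their respective parameterizations; because the
underlying nulls and alternatives differ, the two are exposed separately
and no ratio is formed.

## Degenerate inputs and edge cases

* $n < 2$: no NN relation — error. $n < 4$: no RL quartet moments — error.
* A perfectly reflexive digraph ($Q = 0$, $R = n$) makes
  $N_{12} \equiv N_{21}$ under every labeling; the zero variance is
  reported as an error with a diagnostic rather than a spurious $Z_D$.
* Off-diagonal NNCT pairs with $N_{ij} + N_{ji} = 0$ are structural zeros:
  dropped from Bowker's sum and df. All pairs empty — error.
* Zero columns of the Q-symmetry table are dropped with a warning and the
  df reduced.
* The exact binomial two-sided p-value is the minimum-likelihood sum
  (all outcomes no more probable than the observed one, with a $10^{-7}$
  relative tie guard); the doubled-one-tail convention is available by
  flag.

## Known limitations

* The caseII family, at the settings studied, produces strong association
  but only weak *shared-structure* asymmetry: attached pairs are mutual
  NNs, so both classes' serving-count distributions shift together. Its
  role as a shared-structure alternative is therefore limited; the caseVI
  family is the sharper shared-structure alternative in this collection.
* Exact enumeration for Q-symmetry tables with more than two rows grows
  quickly; the Monte Carlo mode is an estimate with a reported standard
  error, not an exact computation.
* No edge correction; tests on patterns whose window boundary carries real
  structure inherit a small size distortion.
* The shipped tree-census tables support table-level analyses only; the
  raw coordinates behind them are not distributed, so digraph-level
  statistics (e.g. $Z_D$) cannot be recomputed for that data set, and one
  of the published one-versus-rest tables is internally inconsistent as
  printed (a corrected variant, restoring its margins by a single-entry
  change, is shipped alongside and clearly labeled).
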