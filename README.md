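# nnsymmetry

Tests of **spatial symmetry in nearest-neighbor (NN) structure** for
multi-class planar point patterns — for ecologists, epidemiologists and
spatial statisticians asking whether two (or more) classes of points relate
to each other *symmetrically*, rather than whether they are segregated or
associated.

Two distinct symmetry notions are covered:

- **Mixed NN structure.** Record, for every point (the *base*), the class of
  its NN. The k×k nearest-neighbor contingency table (NNCT) has entries
  `N_ij` = number of class-*i* base points whose NN is class *j*. Symmetry
  means `E[N_ij] = E[N_ji]` for all `i ≠ j`: class *i* serves as NN to class
  *j* as often as the reverse.
- **Shared NN structure.** Record, for every point, the number of times *m*
  it serves as a NN (in the plane, `m ≤ 6`, and `m ≤ 5` almost surely for
  continuous data). The k×(m+1) *Q-symmetry table* has entries `Q_im` =
  number of class-*i* points serving as NN exactly *m* times. Symmetry means
  all classes share the same serving-count distribution.

## The tests

**Pielou's first type** (mixed structure): McNemar's statistic
`χ²_I = (|N12 − N21| − 1)² / (N12 + N21)` (Yates-corrected; an uncorrected
version, an exact `BIN(nt, ½)` binomial version, and Bowker's k-class
extension `Σ_{i<j}(|N_ij − N_ji| − 1)²/(N_ij + N_ji)` are included). These
are valid only for *sparsely sampled* base–NN pairs: for completely mapped
data they are **extremely conservative** (empirical size ≈ .0007 at nominal
.05), and the package both warns about this and provides the Monte Carlo
randomization version that should be used instead.

**Dixon's symmetry test** (mixed structure, completely mapped data): under
random labeling (RL) of the fixed locations,

    Z_D = (N12 − N21) / √(Var N12 + Var N21 − 2 Cov(N12, N21))

with *exact* finite-sample moments driven by the digraph statistics `Q`
(ordered point pairs sharing a NN, `Q = Σ_j j(j−1)Q_j`) and `R` (twice the
number of reflexive pairs), e.g.
`Var[N_ij] = n p_ij + Q p_iij + (n² − 3n − Q + R) p_iijj − (n p_ij)²` with
falling-factorial label probabilities `p_..`. For k classes the contrasts
`T_S = (N_ij − N_ji)_{i<j}` are combined into the quadratic form
`χ²_D = T_S' Σ_sym⁻ T_S` (Moore–Penrose inverse, df = rank). All cell
covariances are computed exactly by an arc-pair decomposition of the NN
digraph and are validated against an exhaustive labeling-enumeration oracle.

**Pielou's second type** (shared structure): Pearson's chi-square on the
Q-symmetry table (columns `m ≥ 2` merged by default, df `2(k−1)`), which
holds its nominal level even for completely mapped data; plus **five exact
conditional test variants** on the table (table-inclusive, table-exclusive,
mid-p, twice-table-inclusive, Tocher-randomized) — the table-exclusive
variant is the one that attains the nominal level.

Also included: restricted/unrestricted **pairwise** and **one-versus-rest**
post hoc tests, Pitman asymptotic efficiencies and a local-power
approximation, NN relations from arbitrary **dissimilarity matrices** (with
the generalized statistic `Q̃ = 2 Σ_j C(j,2) Q_j` for non-planar data), and
seed-deterministic **pattern generators** (CSR, RL over uniform and
Matérn-cluster backgrounds, and six alternative families) with a Monte Carlo
harness for size/power studies.

## Worked example

An asymmetric-association pattern (40 + 40 points; class 2 points crowd
class 1 points one-directionally):

```r
library(nnsymmetry)
pat <- generate_pattern(pattern_spec("caseVI", m1 = 20, m2 = 10, rho = 1/3),
                        seed = 42)
symmetry_analysis(pat, B = 999, seed = 42)
```

```
Nearest-neighbor contingency table (base class x NN class)
    nn
base  1  2
   1 20 20
   2 33  7
Q = 36  R = 62

Q-symmetry contingency table (class x times serving as NN) [reduced]
   0  1 2+
1  0 28 12
2 17 19  4

Overall symmetry tests:
  dixon     Z_D = -4.306, p = 1.661e-05
  pielou1   X-squared = 2.717, p = 0.09929
  pielou1u  X-squared = 3.189, p = 0.07415
  binom     N12 = 20, p = 0.09837
  pielou2   X-squared = 22.72, p = 1.163e-05
  fisher    p_exc = 1.404e-06 (exact, enumerated)
Randomization p-values (B = 999):
  dixon     p = 0.001
  pielou1   p = 0.001
  pielou1u  p = 0.001
  pielou2   p = 0.001
```

Reading the output: class 2 points take class 1 points as NNs far more often
than the reverse (`N21 = 33` vs `N12 = 20`), so Dixon's exact-moment test
rejects mixed-structure symmetry decisively (`Z_D = −4.3`). Every class-1
point serves as a NN at least once while 17 of 40 class-2 points never do,
so the shared-structure tests (`χ²_II = 22.7` and the exact table-exclusive
p-value) also reject. The asymptotic type I (McNemar/binomial) p-values are
non-significant — the conservativeness the package warns about — while their
randomization versions (p = .001) agree with the calibrated tests.

Classic tree-census tables (black oaks / maples / white oaks from the
Lansing Woods data) ship under `inst/extdata/` for table-level analyses;
e.g. `pielou_q_symmetry(as_qsymtab(read_count_table(...)))` on the full
reduced table gives `χ²_II = 16.595` (df 4, p = .002): the species differ
significantly in shared NN structure.

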