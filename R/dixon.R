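## Dixon's symmetry test under random labeling (RL).
##
## Under RL, class labels are a random permutation of a fixed label multiset
## over a fixed NN digraph, so NNCT cell moments are exact finite-sample
## quantities driven by the digraph's arc structure through Q (ordered pairs
## sharing a NN) and R (twice the reflexive pairs). Cell covariances are
## computed by the arc-pair decomposition: N_ij is a sum over arcs of label
## indicators, and the n^2 ordered arc pairs fall into five coincidence
## classes with counts (n, R, Q, n - R, n - R) and remainder
## n^2 - 3n - Q + R; each class contributes a falling-factorial tuple
## probability. This reproduces the printed variance and reflexive-pair
## covariance formulas exactly and extends them to every cell pair in the
## multi-class table.

falling <- function(x, k) {
  if (k == 0L) return(1)
  prod(x - seq_len(k) + 1)
}

## probability that an ordered tuple of distinct points carries the given
## classes (indices into n_i) under RL
tuple_prob <- function(n_i, classes) {
  n <- sum(n_i)
  cnt <- tabulate(classes, nbins = length(n_i))
  num <- 1
  for (cl in which(cnt > 0L)) num <- num * falling(n_i[cl], cnt[cl])
  num / falling(n, length(classes))
}

#' Exact random-labeling moments for NNCT cells
#'
#' Packages the class sizes and the digraph summaries Q and R needed for the
#' exact first and second moments of NNCT cells under random labeling. For
#' patterns generated under CSR the observed Q and R are plugged in (the
#' moments are then conditional on the realized geometry).
#'
#' @param n_i integer vector of class sizes (or an `"nnct"`, from which the
#'   sizes, Q and R are taken).
#' @param Q,R digraph summaries from [graph_summaries()]; ignored when
#'   `n_i` is an `"nnct"`.
#' @return An object of class `"rl_moments"`: list with `n_i`, `n`, `k`,
#'   `Q`, `R`.
#' @seealso [nnct_cell_cov()], [dixon_z()], [dixon_overall()]
#' @export
rl_moments <- function(n_i, Q, R) {
  if (inherits(n_i, "nnct")) {
    Q <- attr(n_i, "Q"); R <- attr(n_i, "R")
    n_i <- attr(n_i, "n_i")
  }
  n_i <- as.numeric(n_i)
  n <- sum(n_i)
  if (n < 4)
    stop("too few points for RL moments (need n >= 4 for quartet probabilities)")
  if (any(n_i < 1))
    stop("every class must have at least one point")
  structure(list(n_i = n_i, n = n, k = length(n_i), Q = Q, R = R),
            class = "rl_moments")
}

#' Expected NNCT under random labeling
#'
#' `E[N_ij] = n p_ij = n_i n_j / (n - 1)` for i != j and
#' `n p_ii = n_i (n_i - 1) / (n - 1)` on the diagonal (for large n these
#' approach `n_i n_j / n` and `n_i^2 / n`).
#'
#' @param m an [rl_moments()] object.
#' @return A k x k matrix of expected counts.
#' @export
expected_nnct <- function(m) {
  stopifnot(inherits(m, "rl_moments"))
  k <- m$k
  E <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    E[i, j] <- m$n * tuple_prob(m$n_i, c(i, j))
  E
}

#' Exact covariance of two NNCT cells under random labeling
#'
#' `Cov[N_ij, N_kl]` for off-diagonal cells (i != j, k != l), computed by
#' the arc-pair decomposition described in the package vignette. The result
#' specializes to the printed variance formula when (k, l) = (i, j) and to
#' the reflexive-pair covariance when (k, l) = (j, i); for four distinct
#' classes the cell covariance is generally nonzero, but the four-term
#' combination in [ts_cov()] cancels exactly.
#'
#' @param m an [rl_moments()] object.
#' @param i,j,k,l class indices with `i != j` and `k != l`.
#' @return The covariance (a scalar).
#' @export
nnct_cell_cov <- function(m, i, j, k, l) {
  stopifnot(inherits(m, "rl_moments"))
  idx <- c(i, j, k, l)
  if (any(idx < 1L) || any(idx > m$k))
    stop("invalid class index")
  if (i == j || k == l)
    stop("cell covariances are defined for off-diagonal cells (i != j, k != l)")
  n <- m$n; Q <- m$Q; R <- m$R; n_i <- m$n_i
  rest <- n^2 - 3 * n - Q + R
  cross <- rest * tuple_prob(n_i, c(i, j, k, l))
  if (i == k && j == l) cross <- cross + n * tuple_prob(n_i, c(i, j))
  if (i == l && j == k) cross <- cross + R * tuple_prob(n_i, c(i, j))
  if (j == l) cross <- cross + Q * tuple_prob(n_i, c(i, k, j))
  if (i == l) cross <- cross + (n - R) * tuple_prob(n_i, c(i, j, k))
  if (j == k) cross <- cross + (n - R) * tuple_prob(n_i, c(i, j, l))
  cross - n^2 * tuple_prob(n_i, c(i, j)) * tuple_prob(n_i, c(k, l))
}

#' Covariance of two symmetry contrasts
#'
#' `Cov[N_ij - N_ji, N_kl - N_lk]`, the building block of the covariance
#' matrix of the symmetry vector T_S. When all four classes are distinct the
#' four cell covariances are equal and the result is exactly zero.
#'
#' @inheritParams nnct_cell_cov
#' @export
ts_cov <- function(m, i, j, k, l) {
  nnct_cell_cov(m, i, j, k, l) - nnct_cell_cov(m, i, j, l, k) -
    nnct_cell_cov(m, j, i, k, l) + nnct_cell_cov(m, j, i, l, k)
}

## index pairs (i < j) in the lexicographic order of T_S
ts_pairs <- function(k) {
  out <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    out <- rbind(out, c(i, j))
  out
}

#' Symmetry vector and its covariance matrix
#'
#' Builds `T_S = (N_ij - N_ji)` over pairs i < j in lexicographic order,
#' together with its exact RL covariance matrix Sigma_sym.
#'
#' @param t a k x k NNCT.
#' @param m an [rl_moments()] object (defaults to `rl_moments(t)`).
#' @return List with `ts` (length k(k-1)/2), `sigma` (its covariance
#'   matrix), and `pairs` (the index pairs, one row per entry).
#' @export
symmetry_vector <- function(t, m = rl_moments(t)) {
  x <- as.matrix(t)
  k <- nrow(x)
  pairs <- ts_pairs(k)
  ks <- nrow(pairs)
  ts <- numeric(ks)
  sigma <- matrix(0, ks, ks)
  for (a in seq_len(ks)) {
    ts[a] <- x[pairs[a, 1L], pairs[a, 2L]] - x[pairs[a, 2L], pairs[a, 1L]]
    for (b in a:ks) {
      sigma[a, b] <- sigma[b, a] <-
        ts_cov(m, pairs[a, 1L], pairs[a, 2L], pairs[b, 1L], pairs[b, 2L])
    }
  }
  list(ts = ts, sigma = sigma, pairs = pairs)
}

#' Dixon's symmetry test for two classes
#'
#' `Z_D = (N12 - N21) / sqrt(Var[N12] + Var[N21] - 2 Cov[N12, N21])` with
#' the exact RL variance and covariance, referred to the standard normal.
#' Appropriate for completely mapped data; under CSR the observed Q and R
#' are used, making the reference distribution conditional on the geometry.
#'
#' @param t a 2 x 2 NNCT.
#' @param m an [rl_moments()] object (defaults to `rl_moments(t)`).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return An `"htest"` with statistic `Z_D`.
#' @export
dixon_z <- function(t, m = rl_moments(t),
                    alternative = c("two.sided", "greater", "less")) {
  x <- as.matrix(t)
  if (nrow(x) != 2L || ncol(x) != 2L)
    stop("dixon_z needs a 2 x 2 NNCT; use dixon_z_pairwise or dixon_overall for k > 2")
  dixon_z_pairwise(x, m, 1L, 2L, alternative = match.arg(alternative))
}

#' Pairwise Dixon symmetry score in the multi-class table
#'
#' `Z_D^{ij} = (N_ij - N_ji) / sqrt(Var[N_ij - N_ji])` with the unrestricted
#' variance: all classes are kept in Q, R and n.
#'
#' @param t a k x k NNCT.
#' @param m an [rl_moments()] object.
#' @param i,j class indices, `i < j`.
#' @inheritParams dixon_z
#' @return An `"htest"` with statistic `Z_D` and extra element `var_diff`.
#' @export
dixon_z_pairwise <- function(t, m = rl_moments(t), i, j,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.matrix(t)
  v <- ts_cov(m, i, j, i, j)
  if (v <= 0)
    stop("zero variance for the symmetry contrast (degenerate configuration: ",
         "Var[N_ij - N_ji] = ", format(v), ")")
  z <- (x[i, j] - x[j, i]) / sqrt(v)
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z))
  make_htest(statistic = c(Z_D = z), p.value = p,
             method = sprintf("Dixon symmetry test (classes %s vs %s)", i, j),
             data.name = sprintf("N%d%d = %d, N%d%d = %d; Q = %d, R = %d",
                                 i, j, x[i, j], j, i, x[j, i], m$Q, m$R),
             alternative = alternative, var_diff = v)
}

#' Dixon's overall symmetry test for k classes
#'
#' Quadratic form `X^2_D = T_S' Sigma_sym^- T_S` with a Moore-Penrose
#' generalized inverse; df is the numerical rank of Sigma_sym (equal to
#' k(k-1)/2 in non-degenerate cases), and the p-value is the upper
#' chi-square tail.
#'
#' @param t a k x k NNCT.
#' @param m an [rl_moments()] object.
#' @param tol relative eigenvalue tolerance for the generalized inverse and
#'   the rank.
#' @return An `"htest"` with extra elements `ts` and `sigma`.
#' @export
dixon_overall <- function(t, m = rl_moments(t), tol = 1e-10) {
  sv <- symmetry_vector(t, m)
  ev <- eigen(sv$sigma, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) <= 0)
    stop("Sigma_sym is numerically zero")
  rank <- sum(ev > tol * max(ev))
  ginv <- MASS::ginv(sv$sigma, tol = tol)
  stat <- drop(sv$ts %*% ginv %*% sv$ts)
  make_htest(statistic = c("X-squared" = stat), parameter = c(df = rank),
             p.value = stats::pchisq(stat, rank, lower.tail = FALSE),
             method = "Dixon overall symmetry test",
             data.name = deparse1(substitute(t)),
             alternative = "two.sided",
             ts = sv$ts, sigma = sv$sigma)
}

## all distinct permutations of the label multiset given by class sizes
multiset_permutations <- function(n_i) {
  n <- sum(n_i)
  if (n == 0L) return(matrix(integer(), 1L, 0L))
  out <- NULL
  for (cl in seq_along(n_i)) {
    if (n_i[cl] == 0L) next
    rest <- n_i
    rest[cl] <- rest[cl] - 1L
    sub <- multiset_permutations(rest)
    out <- rbind(out, cbind(cl, sub))
  }
  out
}

#' Exhaustive random-labeling oracle for NNCT moments
#'
#' Enumerates every labeling of a fixed NN digraph with the given class
#' sizes and returns the exact mean and covariance of all NNCT cells. Used
#' as an independent check of the closed-form moments; infeasible beyond
#' small n.
#'
#' @param g an `"nndigraph"` (or a [point_pattern()], whose digraph is
#'   computed first).
#' @param n_i class sizes (must sum to the number of points).
#' @param cap maximum number of labelings to enumerate.
#' @return List with `E` (k x k expected NNCT), `cov` (k x k x k x k array
#'   of cell covariances), and `n_labelings`.
#' @export
rl_enumeration_oracle <- function(g, n_i, cap = 1e6) {
  if (inherits(g, "ppattern"))
    g <- nearest_neighbors(g)
  stopifnot(inherits(g, "nndigraph"))
  n_i <- as.integer(n_i)
  n <- g$n
  if (sum(n_i) != n)
    stop("class sizes must sum to the number of points")
  n_lab <- exp(lfactorial(n) - sum(lfactorial(n_i)))
  if (n_lab > cap)
    stop("enumeration cap exceeded (", format(n_lab, digits = 3),
         " labelings); use the analytic moments instead")
  labelings <- multiset_permutations(n_i)
  k <- length(n_i)
  nn <- g$nn_index
  m1 <- matrix(0, k, k)
  m2 <- array(0, c(k, k, k, k))
  for (r in seq_len(nrow(labelings))) {
    lab <- labelings[r, ]
    counts <- matrix(0, k, k)
    for (t in seq_len(n))
      counts[lab[t], lab[nn[t]]] <- counts[lab[t], lab[nn[t]]] + 1
    m1 <- m1 + counts
    m2 <- m2 + outer(counts, counts)
  }
  nl <- nrow(labelings)
  m1 <- m1 / nl
  m2 <- m2 / nl
  list(E = m1, cov = m2 - outer(m1, m1), n_labelings = nl)
}
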