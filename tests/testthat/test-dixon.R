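test_that("tuple probabilities follow the falling-factorial form", {
  m <- rl_moments(c(2, 2), Q = 4, R = 2)
  expect_equal(nnsymmetry:::tuple_prob(c(2, 2), c(1, 2)), 1 / 3)  # p12 = 4/12
  expect_equal(expected_nnct(m)[1, 2], 4 / 3)                     # n p12
  # a singleton class cannot supply a same-class pair
  expect_equal(nnsymmetry:::tuple_prob(c(1, 3), c(1, 1)), 0)
  # quartet probability p_iijj
  expect_equal(nnsymmetry:::tuple_prob(c(3, 3), c(1, 1, 2, 2)),
               3 * 2 * 3 * 2 / (6 * 5 * 4 * 3))
})

test_that("analytic moments equal exhaustive enumeration on the unit-square corners", {
  g <- nearest_neighbors(corner_pattern())
  or <- rl_enumeration_oracle(g, c(2, 2))
  m <- rl_moments(c(2, 2), g$Q, g$R)
  expect_equal(or$n_labelings, 6)
  expect_equal(or$E[1, 2], expected_nnct(m)[1, 2], tolerance = 1e-12)
  expect_equal(or$cov[1, 2, 1, 2], nnct_cell_cov(m, 1, 2, 1, 2),
               tolerance = 1e-12)
  expect_equal(or$cov[1, 2, 2, 1], nnct_cell_cov(m, 1, 2, 2, 1),
               tolerance = 1e-12)
})

test_that("arc-pair coincidence classes count (n, R, Q, n-R, n-R) with the stated remainder", {
  for (seed in 1:10) {
    g <- nearest_neighbors(random_pattern(sample(8:40, 1), seed = seed))
    n <- g$n; nn <- g$nn_index
    counts <- c(same = 0, refl = 0, shared = 0, head_t = 0, head_s = 0,
                disjoint = 0)
    for (t in 1:n) for (s in 1:n) {
      if (t == s) counts["same"] <- counts["same"] + 1
      else if (nn[t] == s && nn[s] == t) counts["refl"] <- counts["refl"] + 1
      else if (nn[t] == nn[s]) counts["shared"] <- counts["shared"] + 1
      else if (nn[s] == t) counts["head_t"] <- counts["head_t"] + 1
      else if (nn[t] == s) counts["head_s"] <- counts["head_s"] + 1
      else counts["disjoint"] <- counts["disjoint"] + 1
    }
    expect_equal(unname(counts),
                 c(n, g$R, g$Q, n - g$R, n - g$R, n^2 - 3 * n - g$Q + g$R))
  }
})

test_that("all six covariance cases match the enumeration oracle to 1e-12", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(6:8, 1)
    k <- sample(2:4, 1)
    sizes <- as.vector(rmultinom(1, n - k, rep(1, k))) + 1L
    pat <- random_pattern(n, k)
    g <- nearest_neighbors(pat)
    or <- rl_enumeration_oracle(g, sizes)
    m <- rl_moments(sizes, g$Q, g$R)
    expect_equal(expected_nnct(m), or$E, tolerance = 1e-12)
    for (i in 1:k) for (j in 1:k) for (a in 1:k) for (b in 1:k) {
      if (i == j || a == b) next
      expect_equal(nnct_cell_cov(m, i, j, a, b), or$cov[i, j, a, b],
                   tolerance = 1e-12)
    }
  }
})

test_that("case-6 contrast covariance is exactly zero; specializations recover the variance forms", {
  g <- nearest_neighbors(random_pattern(30, k = 4, seed = 31))
  sizes <- as.vector(table(nearest_neighbors(random_pattern(30, k = 4, seed = 31))$labels))
  m <- rl_moments(sizes, g$Q, g$R)
  expect_identical(ts_cov(m, 1, 2, 3, 4), 0)

  # case 1 equals the printed variance expression on random (n, Q, R)
  set.seed(32)
  for (rep in 1:20) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1); n <- n1 + n2
    Q <- 2 * sample(0:(n / 2), 1); R <- 2 * sample(1:(n / 2), 1)
    m2 <- rl_moments(c(n1, n2), Q, R)
    p12 <- n1 * n2 / (n * (n - 1))
    p112 <- n1 * (n1 - 1) * n2 / (n * (n - 1) * (n - 2))
    p122 <- n1 * n2 * (n2 - 1) / (n * (n - 1) * (n - 2))
    p1122 <- n1 * (n1 - 1) * n2 * (n2 - 1) / (n * (n - 1) * (n - 2) * (n - 3))
    rest <- n^2 - 3 * n - Q + R
    v12 <- n * p12 + Q * p112 + rest * p1122 - (n * p12)^2
    cov1221 <- R * p12 + (n - R) * (p112 + p122) + rest * p1122 -
      n^2 * p12 * p12
    expect_equal(nnct_cell_cov(m2, 1, 2, 1, 2), v12, tolerance = 1e-12)
    expect_equal(nnct_cell_cov(m2, 1, 2, 2, 1), cov1221, tolerance = 1e-12)
  }
})

test_that("Sigma_sym is positive semidefinite across classes and patterns", {
  set.seed(41)
  for (rep in 1:30) {
    k <- sample(2:4, 1)
    pat <- random_pattern(sample((4 * k):60, 1), k)
    ct <- build_nnct(pat)
    sv <- symmetry_vector(ct)
    ev <- eigen(sv$sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(abs(ev)))
  }
})

test_that("two-class Z and the overall quadratic form are consistent", {
  pat <- random_pattern(60, seed = 51)
  ct <- build_nnct(pat)
  m <- rl_moments(ct)
  z <- dixon_z(ct, m)
  ov <- dixon_overall(ct, m)
  expect_equal(unname(ov$statistic), unname(z$statistic)^2, tolerance = 1e-10)
  expect_equal(unname(ov$parameter), 1)
  expect_equal(sign(unname(z$statistic)), sign(ct[1, 2] - ct[2, 1]))
  # pairwise form with k = 2 is the same test
  expect_equal(unname(dixon_z_pairwise(ct, m, 1, 2)$statistic),
               unname(z$statistic))
  # symmetric table: statistic zero, p = 1
  sym <- ct; sym[1, 2] <- sym[2, 1] <- 10
  class(sym) <- class(ct)
  zs <- dixon_z(sym, m)
  expect_equal(unname(zs$statistic), 0)
  expect_equal(zs$p.value, 1)
})

test_that("enumeration oracle enforces its cap and the n >= 4 moment guard", {
  g <- nearest_neighbors(random_pattern(12, seed = 61))
  expect_error(rl_enumeration_oracle(g, c(6, 6), cap = 100), "cap exceeded")
  expect_error(rl_moments(c(1, 2), Q = 0, R = 2), "n >= 4")
})
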