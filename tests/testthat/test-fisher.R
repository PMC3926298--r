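test_that("table probability matches hand-enumerated small cases", {
  expect_equal(table_probability(diag(2)), 1 / 2)
  expect_equal(table_probability(rbind(c(1, 1, 0), c(0, 0, 1))), 1 / 3)
  expect_error(table_probability(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("enumerated fixed-margin probabilities sum to one", {
  set.seed(1)
  for (rep in 1:20) {
    m <- matrix(rpois(6, 6), 2)
    logp <- nnsymmetry:::enum_tables_logprob(rowSums(m), colSums(m))
    expect_equal(sum(exp(logp)), 1, tolerance = 1e-10)
  }
  # and for a 3-row table via the DFS path
  m3 <- matrix(rpois(9, 4), 3)
  expect_equal(sum(exp(nnsymmetry:::enum_tables_logprob(rowSums(m3),
                                                        colSums(m3)))), 1,
               tolerance = 1e-10)
})

test_that("enumeration count equals the bounded-composition count", {
  count_comp <- function(left, caps) {
    if (length(caps) == 1L) return(as.integer(left <= caps))
    sum(vapply(0:min(left, caps[1]),
               function(v) count_comp(left - v, caps[-1]), integer(1)))
  }
  set.seed(2)
  for (rep in 1:15) {
    m <- matrix(rpois(8, 5), 2)
    logp <- nnsymmetry:::enum_tables_logprob(rowSums(m), colSums(m))
    expect_equal(length(logp), count_comp(sum(m[1, ]), colSums(m)))
  }
})

test_that("exact p-value variants on the 2x2 permutation example", {
  r <- exact_symmetry_test(as_qsymtab(diag(2)), seed = 1)
  expect_equal(r$p_t, 0.5)
  expect_equal(r$p_inc, 1)
  expect_equal(r$p_exc, 0.5)
  expect_equal(r$p_mid, 0.75)
  expect_equal(r$p_t_inc, 1)
})

test_that("the ordering chain and mid-p identity hold on random tables", {
  set.seed(3)
  for (rep in 1:40) {
    m <- matrix(rpois(2 * sample(2:4, 1), sample(3:12, 1)), 2)
    m[1, 1] <- m[1, 1] + 1  # positive margins
    r <- exact_symmetry_test(as_qsymtab(m), seed = rep)
    expect_lte(r$p_exc, r$p_toc + 1e-12)
    expect_lte(r$p_toc, r$p_inc + 1e-12)
    expect_lte(r$p_inc, r$p_t_inc + 1e-12)
    expect_equal(r$p_mid, r$p_exc + r$p_t / 2)
    expect_equal(r$p_mid, (r$p_inc + r$p_exc) / 2)
    expect_true(all(unlist(r[c("p_t", "p_inc", "p_exc", "p_mid",
                               "p_t_inc", "p_toc")]) >= 0))
    expect_true(all(unlist(r[c("p_inc", "p_exc", "p_mid",
                               "p_t_inc", "p_toc")]) <= 1))
  }
})

test_that("table-inclusive p-value agrees with the reference exact test", {
  set.seed(4)
  for (rep in 1:25) {
    m <- matrix(rpois(6, 8) + 1, 2)
    ours <- exact_symmetry_test(as_qsymtab(m), seed = rep)
    ref <- fisher.test(m)
    expect_equal(ours$p_inc, ref$p.value, tolerance = 1e-8)
  }
})

test_that("Tocher randomization follows the boundary rule and is seed-stable", {
  # craft a case with p_exc < alpha < p_inc by using alpha between them
  m <- as_qsymtab(rbind(c(9, 1, 2), c(2, 8, 3)))
  r0 <- exact_symmetry_test(m, seed = 11)
  alpha <- (r0$p_exc + r0$p_inc) / 2
  r <- exact_symmetry_test(m, alpha = alpha, seed = 11)
  expected <- if (r$tocher_u >= (alpha - r$p_exc) / r$p_t) r$p_inc else r$p_exc
  expect_equal(r$p_toc, expected)
  expect_equal(exact_symmetry_test(m, alpha = alpha, seed = 11)$p_toc, r$p_toc)
})

test_that("Monte Carlo mode tracks full enumeration within sampling error", {
  m <- as_qsymtab(rbind(c(12, 20, 9), c(16, 14, 11)))
  exact <- exact_symmetry_test(m, seed = 5)
  mc <- exact_symmetry_mc(m, B = 4000, seed = 5)
  expect_lt(abs(mc$p_inc - exact$p_inc), 3 * mc$se + 1e-9)
  expect_identical(exact_symmetry_mc(m, B = 2000, seed = 9)$p_inc,
                   exact_symmetry_mc(m, B = 2000, seed = 9)$p_inc)
  # degenerate single-column table admits only itself
  one <- as_qsymtab(cbind(c(5, 7)))
  expect_equal(exact_symmetry_mc(one, B = 1000, seed = 1)$p_inc, 1)
})
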