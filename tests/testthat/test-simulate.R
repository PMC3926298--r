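test_that("generators are seed-deterministic and family-faithful", {
  for (spec in list(pattern_spec("csr", n1 = 15, n2 = 25),
                    pattern_spec("caseI", n1 = 10, n2 = 10, sigma = 1 / 10),
                    pattern_spec("caseII", n1 = 12, n2 = 12, p = .5),
                    pattern_spec("caseIII", n1 = 10, n2 = 10, s = 1 / 3),
                    pattern_spec("caseIV", n1 = 12, n2 = 12, r = 1 / 8),
                    pattern_spec("caseV", n1 = 12, r = 1 / 7),
                    pattern_spec("caseVI", m1 = 8, m2 = 4, rho = 1 / 3),
                    pattern_spec("rl-matern", kappa = 4, mu = 10,
                                 r_cluster = .1))) {
    a <- generate_pattern(spec, seed = 77)
    b <- generate_pattern(spec, seed = 77)
    expect_identical(a$coords, b$coords)
    expect_identical(a$labels, b$labels)
  }
})

test_that("class sizes come out as specified", {
  p <- generate_pattern(pattern_spec("csr", n1 = 13, n2 = 29), seed = 1)
  expect_equal(as.vector(table(p$labels)), c(13, 29))
  p6 <- generate_pattern(pattern_spec("caseVI", m1 = 20, m2 = 10, rho = 1 / 3),
                         seed = 2)
  expect_equal(as.vector(table(p6$labels)), c(40, 40))  # n_i = m1 + 2 m2
  pm <- generate_pattern(pattern_spec("rl-matern", kappa = 4, mu = 10,
                                      r_cluster = .1), seed = 3)
  expect_gte(pm$n, 4)
  expect_lte(abs(diff(table(pm$labels))), 1)  # floor(n/2) split
})

test_that("caseIII supports and caseI dispersion match their definitions", {
  s <- 1 / 3
  p <- generate_pattern(pattern_spec("caseIII", n1 = 300, n2 = 300, s = s),
                        seed = 4)
  x <- p$coords[p$labels == "1", ]; y <- p$coords[p$labels == "2", ]
  expect_true(all(x >= 0 & x <= 1 - s))
  expect_true(all(y >= s & y <= 1))

  p1 <- generate_pattern(pattern_spec("caseI", n1 = 10, n2 = 2000,
                                      sigma = 1 / 10), seed = 5)
  yc <- p1$coords[p1$labels == "2", ]
  expect_equal(colMeans(yc), c(.5, .5), tolerance = .02)
  expect_equal(apply(yc, 2, sd), c(.1, .1), tolerance = .01)
  expect_lt(abs(cor(yc[, 1], yc[, 2])), .1)
})

test_that("invalid specifications are rejected", {
  expect_error(pattern_spec("caseIII", n1 = 10, n2 = 10, s = 1.2))
  expect_error(pattern_spec("caseII", n1 = 10, n2 = 10, p = -0.1))
  expect_error(pattern_spec("caseII", n1 = 10, n2 = 10), "needs parameter")
  expect_error(pattern_spec("nope"))
})

test_that("randomization p-values respect rank bounds and determinism", {
  pat <- random_pattern(40, seed = 6)
  r <- randomization_test(pat, "pielou1", B = 199, seed = 42)
  expect_gte(r$p.value, 1 / 200)
  expect_lte(r$p.value, 1)
  r2 <- randomization_test(pat, "pielou1", B = 199, seed = 42)
  expect_identical(r$p.value, r2$p.value)

  # constant statistic -> p = 1
  const <- randomization_test(pat, function(ct, qs, m) 1, B = 99, seed = 1)
  expect_equal(const$p.value, 1)
})

test_that("randomization and analytic inference agree for Dixon's test", {
  # the randomization reference distribution IS random labeling, so the
  # rank p-value and the normal p-value should reach the same conclusion
  # on a strongly asymmetric pattern and on a null pattern
  alt <- generate_pattern(pattern_spec("caseVI", m1 = 20, m2 = 10,
                                       rho = 1 / 3), seed = 10)
  z_alt <- dixon_z(build_nnct(alt))
  r_alt <- randomization_test(alt, "dixon", B = 999, seed = 10)
  expect_lt(z_alt$p.value, 0.01)
  expect_lte(r_alt$p.value, 0.02)

  null <- generate_pattern(pattern_spec("csr", n1 = 30, n2 = 30), seed = 7)
  z_null <- dixon_z(build_nnct(null))
  r_null <- randomization_test(null, "dixon", B = 999, seed = 7)
  expect_gt(z_null$p.value, 0.05)
  expect_gt(r_null$p.value, 0.05)
  # and the two p-values track each other to Monte Carlo accuracy
  expect_lt(abs(r_null$p.value - z_null$p.value), 0.2)
})

test_that("rejection-rate harness reports rates, SEs and moment summaries", {
  spec <- pattern_spec("csr", n1 = 15, n2 = 15)
  out <- empirical_rejection_rate(spec, c("dixon", "pielou2"),
                                  n_sim = 150, seed = 8)
  expect_named(out$rates, c("dixon", "pielou2"))
  expect_true(all(out$rates >= 0 & out$rates <= 1))
  expect_equal(out$mc_se, sqrt(out$rates * (1 - out$rates) / 150))
  expect_equal(out$summaries$diff[["mean"]],
               out$summaries$N12[["mean"]] - out$summaries$N21[["mean"]])
  # alpha = 1 rejects everything for p-value based tests
  one <- empirical_rejection_rate(spec, "fisher_exc", n_sim = 100,
                                  alpha = .9999, seed = 9)
  expect_gte(one$rates[["fisher_exc"]], .99)
  # determinism
  out2 <- empirical_rejection_rate(spec, c("dixon", "pielou2"),
                                   n_sim = 150, seed = 8)
  expect_identical(out$rates, out2$rates)
})

test_that("RL relabeling harness holds its level on a fixed uniform background", {
  out <- rl_rejection_rate(pattern_spec("rl-uniform", n1 = 30, n2 = 30),
                           tests = c("dixon", "pielou2"),
                           backgrounds = 8, relabels = 250, seed = 10)
  expect_lt(abs(out$rates[["dixon"]] - 0.05), 0.03)
  expect_lt(abs(out$rates[["pielou2"]] - 0.05), 0.03)
})
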