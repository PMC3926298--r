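test_that("hand-checked NN assignments, including lowest-index tie-breaking", {
  g2 <- nearest_neighbors(point_pattern(cbind(c(0, 1), 0), c("A", "B")))
  expect_equal(g2$nn_index, c(2L, 1L))
  expect_equal(g2$R, 2)

  g3 <- nearest_neighbors(collinear_pattern())
  expect_equal(g3$nn_index, c(2L, 1L, 2L))
  expect_true(g3$tie_flags[2])  # middle point equidistant to both ends
  expect_false(any(g3$tie_flags[c(1, 3)]))

  g4 <- nearest_neighbors(corner_pattern())
  expect_equal(g4$nn_index, c(2L, 1L, 1L, 2L))
})

test_that("graph summaries match hand computation on the tiny geometries", {
  g2 <- nearest_neighbors(point_pattern(cbind(c(0, 1), 0), c("A", "B")))
  expect_equal(unname(g2$Qj), c(0, 2))
  expect_equal(g2$Q, 0)

  g3 <- nearest_neighbors(collinear_pattern())
  expect_equal(unname(g3$Qj), c(1, 1, 1))  # in-degrees 1, 2, 0
  expect_equal(g3$Q, 2)
  expect_equal(g3$R, 2)

  g4 <- nearest_neighbors(corner_pattern())
  expect_equal(g4$Q, 4)
  expect_equal(g4$R, 2)
  expect_equal(unname(g4$Qj), c(2, 0, 2))
})

test_that("digraph identities hold on random patterns", {
  for (seed in 1:25) {
    n <- sample(5:50, 1)
    g <- nearest_neighbors(random_pattern(n, k = sample(2:4, 1), seed = seed))
    j <- as.integer(names(g$Qj))
    expect_equal(sum(g$Qj), n)
    expect_equal(sum(j * g$Qj), n)              # each point has exactly one NN
    expect_equal(g$Q, sum(j * (j - 1) * g$Qj))
    expect_equal(g$Q, g$Qtilde)                 # planar: serving counts <= 6
    expect_equal(g$R %% 2, 0)
    expect_gte(g$R, 2)                          # closest pair is mutual
    # Q equals the brute-force count of ordered arc pairs with common target
    brute <- sum(outer(g$nn_index, g$nn_index, "==") &
                   !diag(TRUE, n))
    expect_equal(g$Q, brute)
  }
})

test_that("tie rule is irrelevant when all pairwise distances are distinct", {
  pat <- jittered_grid_pattern(30)
  g1 <- nearest_neighbors(pat, tie_rule = "lowest-index")
  g2 <- nearest_neighbors(pat, tie_rule = "random", seed = 99)
  expect_false(any(g1$tie_flags))
  expect_identical(g1$nn_index, g2$nn_index)
})

test_that("dissimilarity input reproduces Euclidean results and allows j > 6", {
  pat <- random_pattern(20, seed = 4)
  d <- as.matrix(dist(pat$coords))
  pat_d <- point_pattern(dissim = d, labels = pat$labels)
  g <- nearest_neighbors(pat)
  gd <- nearest_neighbors(pat_d)
  expect_identical(g$nn_index, gd$nn_index)
  expect_equal(g$Q, gd$Q)

  # star dissimilarity: one hub is everyone's NN, serving n - 1 > 6 times
  n <- 9
  d <- matrix(2, n, n); d[1, ] <- d[, 1] <- 1; diag(d) <- 0
  hub <- nearest_neighbors(point_pattern(dissim = d,
                                         labels = rep(c("A", "B"), c(4, 5))))
  expect_equal(unname(hub$Qj[as.character(n - 1)]), 1)
  expect_equal(hub$Qtilde, (n - 1) * (n - 2))
  expect_gt(hub$Qtilde, hub$Q)   # capped form differs beyond 6
})

test_that("degenerate and malformed inputs error", {
  expect_error(point_pattern(cbind(1, 1), "A"), "degenerate")
  expect_error(point_pattern(cbind(c(0, NA), c(0, 1)), c("A", "B")),
               "non-finite")
  expect_error(point_pattern(cbind(0:1, 0:1), c("A", NA)), "missing")
  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(point_pattern(dissim = asym, labels = c("A", "B")),
               "symmetric")
})

test_that("duplicate points warn but are assigned a zero-distance NN", {
  pat <- point_pattern(rbind(c(0, 0), c(0, 0), c(1, 1)), c("A", "B", "A"))
  expect_warning(g <- nearest_neighbors(pat), "duplicate")
  expect_equal(g$nn_dist[1], 0)
  expect_equal(g$nn_index[1], 2L)
})

test_that("point-pattern reader round-trips and rejects empty files", {
  pat <- random_pattern(15, seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = pat$coords[, 1], y = pat$coords[, 2],
                       label = pat$labels), f, row.names = FALSE)
  back <- read_point_pattern(f)
  expect_equal(back$coords, pat$coords, ignore_attr = TRUE)
  expect_equal(as.character(back$labels), as.character(pat$labels))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y,label", f2)
  expect_error(read_point_pattern(f2), "0 rows")
})
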