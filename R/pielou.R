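## Pielou's two types of symmetry tests.
##
## Type I targets symmetry in the mixed NN structure (off-diagonal NNCT
## entries); it is McNemar's test for two classes and Bowker's test for k > 2.
## Both are valid for sparsely sampled base-NN pairs only: for completely
## mapped data they are extremely conservative and the Monte Carlo
## randomization version (see randomization_test()) should be preferred.
## Type II targets symmetry in the shared NN structure via Pearson's
## chi-square on the Q-symmetry table.

SPARSE_WARNING <- paste(
  "valid for sparsely sampled base-NN pairs only; for completely mapped",
  "data this test is extremely conservative -- prefer the Monte Carlo",
  "randomization version")

make_htest <- function(statistic, parameter = NULL, p.value, method,
                       data.name, alternative = NULL, ...) {
  out <- list(statistic = statistic, parameter = parameter,
              p.value = p.value, method = method, data.name = data.name,
              alternative = alternative, ...)
  out <- out[!vapply(out, is.null, logical(1))]
  class(out) <- "htest"
  out
}

off_diagonal_pair <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == 2L))
    stop("expected a 2 x 2 NNCT")
  c(n12 = x[1L, 2L], n21 = x[2L, 1L])
}

#' Pielou's first type of symmetry test (McNemar form)
#'
#' Tests equality of the expected off-diagonal NNCT entries in the two-class
#' case with the chi-square statistic `(|N12 - N21| - c)^2 / (N12 + N21)`
#' (`c = 1` with Yates' continuity correction, 0 without), referred to the
#' chi-square distribution with 1 df.
#'
#' The result carries a standing warning: for completely mapped spatial data
#' the test is extremely conservative, and the Monte Carlo randomization
#' version should be used instead (see [randomization_test()]).
#'
#' @param n12,n21 off-diagonal NNCT counts; alternatively pass a 2 x 2 NNCT
#'   as `n12` and leave `n21` missing.
#' @param correction apply Yates' continuity correction? Default `TRUE`.
#' @return An object of class `"htest"` with an extra `warnings` element.
#' @examples
#' mcnemar_symmetry(35, 28)           # statistic 36/63
#' @export
mcnemar_symmetry <- function(n12, n21, correction = TRUE) {
  if (missing(n21)) {
    p <- off_diagonal_pair(n12)
    n12 <- p[["n12"]]; n21 <- p[["n21"]]
  }
  nt <- n12 + n21
  if (nt < 1)
    stop("no mixed NN pairs (N12 + N21 = 0)")
  stat <- if (correction) (abs(n12 - n21) - 1)^2 / nt else (n12 - n21)^2 / nt
  make_htest(statistic = c("X-squared" = stat), parameter = c(df = 1),
             p.value = stats::pchisq(stat, 1, lower.tail = FALSE),
             method = paste0("Pielou symmetry test, type I (McNemar",
                             if (correction) ", continuity-corrected", ")"),
             data.name = sprintf("N12 = %d, N21 = %d", n12, n21),
             alternative = "two.sided",
             nt = nt, warnings = SPARSE_WARNING)
}

#' Exact binomial version of Pielou's first symmetry test
#'
#' Conditional on `nt = N12 + N21`, under symmetry `N12 ~ BIN(nt, 1/2)`. The
#' default two-sided p-value sums the probabilities of all outcomes no more
#' likely than the observed one; the doubled-one-tail alternative is
#' available with `two_sided = "double"`. The normal-approximation score
#' `Z_I = (N12 - N21) / sqrt(N12 + N21)` and its p-value are reported in the
#' `Z` and `p.normal` elements.
#'
#' @inheritParams mcnemar_symmetry
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (in terms of
#'   N12 against N21).
#' @param two_sided method for the two-sided exact p-value: `"minlike"`
#'   (sum of outcome probabilities at most the observed probability) or
#'   `"double"` (twice the smaller tail, capped at 1).
#' @return An `"htest"` with extra elements `nt`, `Z`, `p.normal`,
#'   `warnings`.
#' @examples
#' binomial_symmetry(3, 0)$p.value    # 0.25
#' @export
binomial_symmetry <- function(n12, n21,
                              alternative = c("two.sided", "greater", "less"),
                              two_sided = c("minlike", "double")) {
  if (missing(n21)) {
    p <- off_diagonal_pair(n12)
    n12 <- p[["n12"]]; n21 <- p[["n21"]]
  }
  alternative <- match.arg(alternative)
  two_sided <- match.arg(two_sided)
  nt <- n12 + n21
  if (nt < 1)
    stop("no mixed NN pairs (N12 + N21 = 0)")
  dens <- stats::dbinom(0:nt, nt, 0.5)
  p <- switch(alternative,
    greater = stats::pbinom(n12 - 1, nt, 0.5, lower.tail = FALSE),
    less = stats::pbinom(n12, nt, 0.5),
    two.sided = if (two_sided == "minlike") {
      sum(dens[dens <= dens[n12 + 1L] * (1 + 1e-7)])
    } else {
      min(1, 2 * min(stats::pbinom(n12, nt, 0.5),
                     stats::pbinom(n12 - 1, nt, 0.5, lower.tail = FALSE)))
    })
  z <- (n12 - n21) / sqrt(nt)
  pz <- switch(alternative,
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  make_htest(statistic = c(N12 = n12), p.value = min(1, p),
             method = "Pielou symmetry test, type I (exact binomial)",
             data.name = sprintf("N12 = %d, N21 = %d (nt = %d)", n12, n21, nt),
             alternative = alternative,
             nt = nt, Z = z, p.normal = pz, warnings = SPARSE_WARNING)
}

#' Bowker's symmetry test on a k x k NNCT
#'
#' Multi-class extension of Pielou's first symmetry test:
#' `sum_{i<j} (|Nij - Nji| - c)^2 / (Nij + Nji)` with df equal to the number
#' of contributing pairs (pairs with `Nij + Nji = 0` are structural zeros
#' and are dropped from both the sum and the df). For k = 2 this is
#' [mcnemar_symmetry()].
#'
#' @param t a k x k NNCT (matrix).
#' @param correction apply the continuity correction in each pair?
#' @return An `"htest"` with extra elements `pairs` (per-pair components)
#'   and `warnings`.
#' @export
bowker_symmetry <- function(t, correction = FALSE) {
  m <- as.matrix(t)
  k <- nrow(m)
  if (k < 2L || ncol(m) != k)
    stop("expected a square k x k NNCT with k >= 2")
  cc <- if (correction) 1 else 0
  comps <- data.frame(i = integer(), j = integer(), term = numeric())
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    s <- m[i, j] + m[j, i]
    if (s > 0)
      comps <- rbind(comps, data.frame(
        i = i, j = j, term = (abs(m[i, j] - m[j, i]) - cc)^2 / s))
  }
  if (nrow(comps) == 0L)
    stop("all off-diagonal pairs are empty")
  stat <- sum(comps$term)
  df <- nrow(comps)
  make_htest(statistic = c("X-squared" = stat), parameter = c(df = df),
             p.value = stats::pchisq(stat, df, lower.tail = FALSE),
             method = paste0("Pielou symmetry test, type I (Bowker",
                             if (correction) ", continuity-corrected", ")"),
             data.name = deparse1(substitute(t)),
             alternative = "two.sided",
             pairs = comps, warnings = SPARSE_WARNING)
}

#' Pielou's second type of symmetry test
#'
#' Pearson's chi-square test of identical row distributions in the
#' Q-symmetry contingency table, i.e. of symmetry in the shared NN
#' structure. Expected counts are `E[Q_im] = n_i Q_m / n` (row sum times
#' column sum over the grand total); df is `(k - 1)(c - 1)` where c is the
#' number of (nonzero) columns. Columns with zero total are dropped with a
#' warning, reducing the df accordingly.
#'
#' Unlike the type I tests, extensive simulation shows this test holds its
#' nominal level for completely mapped data when used on the reduced table.
#'
#' @param t a `"qsymtab"` (or plain count matrix), usually reduced via
#'   [reduce_qsym()].
#' @return An `"htest"` with an `expected` element.
#' @examples
#' q <- as_qsymtab(rbind(c(37, 67, 31), c(113, 259, 142), c(143, 220, 85)))
#' pielou_q_symmetry(q)    # X-squared = 16.595, df = 4
#' @export
pielou_q_symmetry <- function(t) {
  m <- as.matrix(t)
  if (nrow(m) < 2L)
    stop("need at least 2 classes (k >= 2)")
  zero <- colSums(m) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero column(s) from the Q-symmetry table")
    m <- m[, !zero, drop = FALSE]
  }
  if (ncol(m) < 2L)
    stop("fewer than 2 nonzero columns")
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  make_htest(statistic = c("X-squared" = stat), parameter = c(df = df),
             p.value = stats::pchisq(stat, df, lower.tail = FALSE),
             method = "Pielou symmetry test, type II (Q-symmetry table)",
             data.name = deparse1(substitute(t)),
             alternative = "two.sided",
             expected = E)
}
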