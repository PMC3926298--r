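#' Full symmetry analysis of a labeled point pattern
#'
#' Convenience wrapper running the overall symmetry battery: the NNCT and
#' (reduced) Q-symmetry table, Dixon's test (Z_D for two classes, the
#' quadratic-form test for k > 2), Pielou's first test (with and without
#' continuity correction, plus the exact binomial version for two classes),
#' Pielou's second test, the exact test on the Q-symmetry table, and --
#' optionally -- Monte Carlo randomization p-values.
#'
#' @param pattern a [point_pattern()].
#' @param alpha level (Tocher rule and report annotations).
#' @param B number of randomization replicates; 0 skips randomization.
#' @param seed optional seed (randomization and Tocher draw).
#' @param tie_rule passed to [nearest_neighbors()].
#' @return An object of class `"symmetry_analysis"`: list with `nnct`,
#'   `qsym`, `digraph`, `tests` (named `"htest"` / `"exact_symmetry"`
#'   results), `randomization` (named randomization results, if any), and
#'   the call parameters.
#' @examples
#' pat <- point_pattern(cbind(runif(60), runif(60)), rep(c("A", "B"), 30))
#' symmetry_analysis(pat, B = 0)
#' @export
symmetry_analysis <- function(pattern, alpha = 0.05, B = 0, seed = NULL,
                              tie_rule = "lowest-index") {
  stopifnot(inherits(pattern, "ppattern"))
  if (!is.null(seed)) set.seed(seed)
  g <- nearest_neighbors(pattern, tie_rule = tie_rule)
  ct <- build_nnct(pattern, g)
  qs <- reduce_qsym(build_qsym(pattern, g))
  m <- rl_moments(ct)
  k <- nlevels(pattern$labels)
  tests <- list()
  tests$dixon <- if (k == 2L) dixon_z(ct, m) else dixon_overall(ct, m)
  tests$pielou1 <- if (k == 2L) mcnemar_symmetry(ct) else bowker_symmetry(ct, correction = TRUE)
  tests$pielou1u <- if (k == 2L) mcnemar_symmetry(ct, correction = FALSE) else bowker_symmetry(ct)
  if (k == 2L)
    tests$binom <- binomial_symmetry(ct)
  tests$pielou2 <- pielou_q_symmetry(qs)
  tests$fisher <- if (k == 2L) {
    exact_symmetry_test(qs, alpha = alpha)
  } else {
    exact_symmetry_mc(qs, alpha = alpha)
  }
  randomization <- NULL
  if (B > 0) {
    randomization <- list(
      dixon = randomization_test(pattern, "dixon", B = B, g = g),
      pielou1 = randomization_test(pattern, "pielou1", B = B, g = g),
      pielou1u = randomization_test(pattern, "pielou1u", B = B, g = g),
      pielou2 = randomization_test(pattern, "pielou2", B = B, g = g))
  }
  structure(list(nnct = ct, qsym = qs, digraph = g, tests = tests,
                 randomization = randomization,
                 alpha = alpha, B = B, seed = seed, tie_rule = tie_rule),
            class = "symmetry_analysis")
}

#' @export
print.symmetry_analysis <- function(x, ...) {
  print(x$nnct); cat("\n")
  print(x$qsym); cat("\n")
  cat("Overall symmetry tests:\n")
  for (nm in names(x$tests)) {
    r <- x$tests[[nm]]
    if (inherits(r, "exact_symmetry")) {
      cat(sprintf("  %-9s p_exc = %.4g (exact, %s)\n", nm, r$p_exc,
                  if (grepl("Monte", r$method)) "Monte Carlo" else "enumerated"))
    } else {
      cat(sprintf("  %-9s %s = %.4g, p = %.4g\n", nm,
                  names(r$statistic)[1], r$statistic[1], r$p.value))
    }
  }
  if (!is.null(x$randomization)) {
    cat("Randomization p-values (B = ", x$B, "):\n", sep = "")
    for (nm in names(x$randomization))
      cat(sprintf("  %-9s p = %.4g\n", nm, x$randomization[[nm]]$p.value))
  }
  cat("note: the type I (McNemar/Bowker/binomial) asymptotic p-values are\n",
      "extremely conservative for completely mapped data; prefer the\n",
      "randomization p-values for those tests.\n", sep = "")
  invisible(x)
}

strip_for_json <- function(r) {
  if (inherits(r, "exact_symmetry"))
    return(unclass(r)[c("p_t", "p_inc", "p_exc", "p_mid", "p_t_inc",
                        "p_toc", "tocher_u", "alpha", "n_tables", "method")])
  out <- unclass(r)
  out$expected <- NULL
  out$sigma <- NULL
  out
}

#' Serialize analysis results to JSON
#'
#' Writes every statistic, df and p-value of a [symmetry_analysis()] (or a
#' single test result) together with the tables and reproducibility
#' information (seed, B, tie rule) as JSON.
#'
#' @param x a `"symmetry_analysis"`, `"htest"`, `"exact_symmetry"`, or
#'   `"rejection_rates"` object.
#' @param file optional output path; when `NULL` the JSON string is
#'   returned.
#' @export
results_to_json <- function(x, file = NULL) {
  obj <- if (inherits(x, "symmetry_analysis")) {
    list(nnct = unclass(as.matrix(x$nnct)),
         qsym = unclass(as.matrix(x$qsym)),
         Q = attr(x$nnct, "Q"), R = attr(x$nnct, "R"),
         tie_rule = x$tie_rule, alpha = x$alpha, B = x$B, seed = x$seed,
         tests = lapply(x$tests, strip_for_json),
         randomization = lapply(x$randomization, strip_for_json))
  } else if (inherits(x, "rejection_rates")) {
    list(rates = as.list(x$rates), mc_se = as.list(x$mc_se),
         summaries = x$summaries, n_sim = x$n_sim, alpha = x$alpha,
         seed = x$seed, family = x$spec$family, parameters = x$spec$par)
  } else {
    strip_for_json(x)
  }
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
  if (is.null(file)) return(json)
  writeLines(json, file)
  invisible(file)
}
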