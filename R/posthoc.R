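## Post hoc symmetry analysis for k > 2 classes: after a significant overall
## test, pairwise (restricted or unrestricted) and one-versus-rest tests
## locate the classes driving the asymmetry. The significance gate is
## narrative guidance only; the functions always run.

two_class_battery <- function(nnct2, qsym2, m, tests, alpha, mc_cap = 1e5) {
  out <- list()
  if ("dixon" %in% tests)
    out$dixon <- dixon_z(nnct2, m)
  if ("pielou1" %in% tests) {
    out$pielou1 <- mcnemar_symmetry(nnct2[1, 2], nnct2[2, 1])
    out$pielou1u <- mcnemar_symmetry(nnct2[1, 2], nnct2[2, 1],
                                     correction = FALSE)
  }
  if ("pielou2" %in% tests)
    out$pielou2 <- pielou_q_symmetry(qsym2)
  if ("fisher" %in% tests)
    out$fisher <- exact_symmetry_test(qsym2, alpha = alpha)
  out
}

#' Pairwise post hoc symmetry tests
#'
#' For every pair of classes, runs the two-class symmetry tests in one of
#' two modes. Unrestricted: the pair's off-diagonal entries are extracted
#' from the full k x k NNCT, the variance of their difference uses Q, R and
#' n of the full pattern, and the pair's rows are extracted from the full
#' Q-symmetry table. Restricted: the pattern is subset to the two classes
#' and the NN digraph and both tables are rebuilt from that subset alone.
#' The two modes answer different questions and can disagree.
#'
#' @param pattern a [point_pattern()] with k >= 3 classes (for k = 2 the
#'   two-class tests are returned directly).
#' @param mode `"unrestricted"` (recommended after a significant overall
#'   test) or `"restricted"`.
#' @param tests subset of `"dixon"`, `"pielou1"`, `"pielou2"`, `"fisher"`.
#' @param alpha level (used by the exact test's Tocher rule).
#' @param adjust p-value adjustment across comparisons: `"none"` (default,
#'   matching the reference analyses) or any [stats::p.adjust()] method.
#' @return An object of class `"posthoc_report"`: list of comparisons, each
#'   holding the sub-tables used and the test results, plus adjusted
#'   p-values when requested.
#' @export
pairwise_symmetry_tests <- function(pattern,
                                    mode = c("unrestricted", "restricted"),
                                    tests = c("dixon", "pielou1", "pielou2",
                                              "fisher"),
                                    alpha = 0.05, adjust = "none") {
  stopifnot(inherits(pattern, "ppattern"))
  mode <- match.arg(mode)
  tests <- match.arg(tests, c("dixon", "pielou1", "pielou2", "fisher"),
                     several.ok = TRUE)
  k <- nlevels(pattern$labels)
  lev <- levels(pattern$labels)
  g <- nearest_neighbors(pattern)
  comparisons <- list()
  if (mode == "unrestricted") {
    ct <- build_nnct(pattern, g)
    qs <- reduce_qsym(build_qsym(pattern, g))
    m <- rl_moments(ct)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (attr(ct, "n_i")[i] == 0L || attr(ct, "n_i")[j] == 0L)
        stop("pair with an empty class")
      sub_ct <- structure(ct[c(i, j), c(i, j)], class = c("nnct", "matrix"))
      sub_qs <- as_qsymtab(unclass(qs)[c(i, j), , drop = FALSE])
      res <- list()
      if ("dixon" %in% tests)
        res$dixon <- dixon_z_pairwise(ct, m, i, j)
      if ("pielou1" %in% tests) {
        res$pielou1 <- mcnemar_symmetry(ct[i, j], ct[j, i])
        res$pielou1u <- mcnemar_symmetry(ct[i, j], ct[j, i],
                                         correction = FALSE)
      }
      if ("pielou2" %in% tests)
        res$pielou2 <- pielou_q_symmetry(sub_qs)
      if ("fisher" %in% tests)
        res$fisher <- exact_symmetry_test(sub_qs, alpha = alpha)
      comparisons[[paste(lev[i], "vs", lev[j])]] <-
        list(classes = lev[c(i, j)], nnct = sub_ct, qsym = sub_qs,
             results = res)
    }
  } else {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      sub <- pattern[pattern$labels %in% lev[c(i, j)]]
      gsub <- nearest_neighbors(sub)
      ct2 <- build_nnct(sub, gsub)
      qs2 <- reduce_qsym(build_qsym(sub, gsub))
      m2 <- rl_moments(ct2)
      comparisons[[paste(lev[i], "vs", lev[j])]] <-
        list(classes = lev[c(i, j)], nnct = ct2, qsym = qs2,
             results = two_class_battery(ct2, qs2, m2, tests, alpha))
    }
  }
  finish_report(comparisons, mode = paste("pairwise", mode), adjust = adjust)
}

#' One-versus-rest post hoc symmetry tests
#'
#' For each class, pools all other classes into a single "rest" class and
#' runs the two-class symmetry tests on the full geometry. Pooling only
#' relabels points: the NN digraph, Q and R are unchanged. Recommended for
#' locating shared-NN asymmetry, as it aggregates the same table the overall
#' test used.
#'
#' @inheritParams pairwise_symmetry_tests
#' @return A `"posthoc_report"`.
#' @export
one_vs_rest_symmetry_tests <- function(pattern,
                                       tests = c("dixon", "pielou1",
                                                 "pielou2", "fisher"),
                                       alpha = 0.05, adjust = "none") {
  stopifnot(inherits(pattern, "ppattern"))
  tests <- match.arg(tests, c("dixon", "pielou1", "pielou2", "fisher"),
                     several.ok = TRUE)
  lev <- levels(pattern$labels)
  if (length(lev) < 3L)
    stop("one-versus-rest tests need k >= 3 classes")
  g <- nearest_neighbors(pattern)
  comparisons <- list()
  for (i in seq_along(lev)) {
    pooled <- pattern
    pooled$labels <- factor(ifelse(pattern$labels == lev[i], lev[i], "rest"),
                            levels = c(lev[i], "rest"))
    gp <- g
    gp$labels <- pooled$labels
    ct2 <- build_nnct(pooled, gp)
    qs2 <- reduce_qsym(build_qsym(pooled, gp))
    m2 <- rl_moments(ct2)
    comparisons[[paste(lev[i], "vs rest")]] <-
      list(classes = c(lev[i], "rest"), nnct = ct2, qsym = qs2,
           results = two_class_battery(ct2, qs2, m2, tests, alpha))
  }
  finish_report(comparisons, mode = "one-vs-rest", adjust = adjust)
}

finish_report <- function(comparisons, mode, adjust) {
  report <- list(comparisons = comparisons, mode = mode, adjustment = adjust)
  if (adjust != "none") {
    for (tn in names(comparisons[[1L]]$results)) {
      p <- vapply(comparisons, function(cm) {
        r <- cm$results[[tn]]
        if (inherits(r, "exact_symmetry")) r$p_exc else r$p.value
      }, numeric(1))
      report$adjusted_p[[tn]] <- stats::p.adjust(p, method = adjust)
    }
  }
  class(report) <- "posthoc_report"
  report
}

#' @export
print.posthoc_report <- function(x, ...) {
  cat("Post hoc symmetry analysis (", x$mode, ")\n", sep = "")
  cat("Run after a significant overall test; raw p-values",
      if (x$adjustment != "none") paste0(" (", x$adjustment, "-adjusted also shown)"),
      "\n\n", sep = "")
  for (nm in names(x$comparisons)) {
    cm <- x$comparisons[[nm]]
    cat("--", nm, "--\n")
    for (tn in names(cm$results)) {
      r <- cm$results[[tn]]
      if (inherits(r, "exact_symmetry")) {
        cat(sprintf("  %-9s p_exc = %.4g (p_inc = %.4g)\n", tn,
                    r$p_exc, r$p_inc))
      } else {
        cat(sprintf("  %-9s %s = %.4g, p = %.4g\n", tn,
                    names(r$statistic), r$statistic, r$p.value))
      }
    }
  }
  invisible(x)
}
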