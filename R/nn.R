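#' Nearest-neighbor digraph of a labeled point pattern
#'
#' Assigns to every point its nearest neighbor (NN), i.e. the point with
#' minimal Euclidean distance (or minimal dissimilarity, for
#' dissimilarity-based patterns), producing the directed graph point -> NN
#' with exactly one outgoing arc per point. Ties in the minimal distance are
#' resolved by `tie_rule` and flagged. No edge correction of any kind is
#' applied.
#'
#' @param pattern a [point_pattern()].
#' @param tie_rule `"lowest-index"` (default, deterministic) or `"random"`.
#'   The default is reproducible on grid-recorded data; random tie-breaking
#'   uses `seed` when supplied.
#' @param seed optional integer seed used only when `tie_rule = "random"`.
#' @return An object of class `"nndigraph"`: list with `nn_index` (length-n
#'   NN assignment), `nn_dist`, `tie_flags` (was the NN tie-broken?),
#'   `in_degree` (times each point serves as NN), `labels`, `n`, and the
#'   summaries of [graph_summaries()] as attributes-free named elements
#'   `Qj`, `Q`, `Qtilde`, `R`.
#' @examples
#' pat <- point_pattern(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)),
#'                      c("A", "A", "B", "B"))
#' g <- nearest_neighbors(pat)
#' g$nn_index   # 2 1 1 2 under lowest-index tie-breaking
#' g$Q          # 4 ordered pairs share a NN
#' @export
nearest_neighbors <- function(pattern, tie_rule = c("lowest-index", "random"),
                              seed = NULL) {
  stopifnot(inherits(pattern, "ppattern"))
  tie_rule <- match.arg(tie_rule)
  n <- pattern$n
  if (n < 2L)
    stop("degenerate pattern: need at least 2 points")
  D <- if (is.null(pattern$dissim)) {
    as.matrix(stats::dist(pattern$coords))
  } else {
    pattern$dissim
  }
  diag(D) <- Inf
  mins <- D[cbind(seq_len(n), max.col(-D, ties.method = "first"))]
  ties <- rowSums(D == mins) > 1L
  if (tie_rule == "random" && !is.null(seed))
    set.seed(seed)
  nn <- max.col(-D, ties.method = if (tie_rule == "random") "random" else "first")
  nn_dist <- D[cbind(seq_len(n), nn)]
  if (any(nn_dist == 0))
    warning("duplicate points: some nearest-neighbor distances are zero")
  g <- structure(list(nn_index = nn, nn_dist = nn_dist, tie_flags = ties,
                      in_degree = tabulate(nn, nbins = n),
                      labels = pattern$labels, n = n,
                      tie_rule = tie_rule),
                 class = "nndigraph")
  c2 <- graph_summaries(g)
  g[names(c2)] <- c2
  g
}

#' Combinatorial summaries of a NN digraph
#'
#' Computes the shared-NN counts `Qj` (number of points serving as NN to
#' exactly j other points, j = 0, 1, ...), the shared-NN statistics `Q` and
#' its general form `Qtilde`, and `R`, twice the number of reflexive
#' (mutually nearest) pairs.
#'
#' `Q = 2(Q2 + 3 Q3 + 6 Q4 + 10 Q5 + 15 Q6)` counts ordered pairs of distinct
#' points that share a NN, using serving counts up to six -- the geometric
#' maximum for planar Euclidean data. `Qtilde = 2 * sum(choose(j, 2) * Qj)`
#' extends the count to arbitrary serving counts, as needed for
#' dissimilarity-based patterns where a point may serve as NN more than six
#' times; the two coincide whenever the maximal serving count is at most 6.
#'
#' @param g an `"nndigraph"`.
#' @return List with `Qj` (named vector, serving counts `0:max`), `Q`,
#'   `Qtilde`, and `R`.
#' @export
graph_summaries <- function(g) {
  stopifnot(inherits(g, "nndigraph"))
  indeg <- g$in_degree
  jmax <- max(indeg)
  Qj <- tabulate(factor(indeg, levels = 0:jmax))
  names(Qj) <- 0:jmax
  j <- 0:jmax
  Qtilde <- 2 * sum(choose(j, 2) * Qj)
  jcap <- pmin(j, 6L)
  Q <- 2 * sum(choose(jcap, 2) * Qj)
  R <- sum(g$nn_index[g$nn_index] == seq_len(g$n))
  list(Qj = Qj, Q = Q, Qtilde = Qtilde, R = R)
}

#' @export
print.nndigraph <- function(x, ...) {
  cat("NN digraph on ", x$n, " points (tie rule: ", x$tie_rule, ")\n",
      sep = "")
  cat("serving counts Qj:\n")
  print(x$Qj)
  cat("Q = ", x$Q, ", Qtilde = ", x$Qtilde, ", R = ", x$R,
      " (", x$R / 2, " reflexive pairs)\n", sep = "")
  if (any(x$tie_flags))
    cat(sum(x$tie_flags), "NN assignment(s) were tie-broken\n")
  invisible(x)
}
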