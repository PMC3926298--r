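#' Nearest-neighbor contingency table (NNCT)
#'
#' Cross-tabulates the class of each base point against the class of its NN:
#' entry (i, j) counts base points of class i whose NN is of class j. Row
#' sums equal the class sizes.
#'
#' @param pattern a [point_pattern()] with at least two classes.
#' @param g optional precomputed [nearest_neighbors()] digraph for `pattern`.
#' @return A k x k integer matrix of class `"nnct"` with class-name dimnames
#'   and attributes `n_i` (class sizes), `Q`, `Qtilde`, `R` (carried from the
#'   digraph, as needed by the random-labeling moments).
#' @examples
#' pat <- point_pattern(cbind(runif(40), runif(40)),
#'                      rep(c("A", "B"), 20))
#' build_nnct(pat)
#' @export
build_nnct <- function(pattern, g = NULL) {
  stopifnot(inherits(pattern, "ppattern"))
  if (nlevels(pattern$labels) < 2L)
    stop("need at least 2 classes (k >= 2)")
  if (is.null(g))
    g <- nearest_neighbors(pattern)
  if (g$n != pattern$n)
    stop("digraph and pattern sizes differ")
  lab <- pattern$labels
  tab <- table(base = lab, nn = lab[g$nn_index])
  m <- matrix(as.integer(tab), nrow = nlevels(lab),
              dimnames = list(base = levels(lab), nn = levels(lab)))
  structure(m, class = c("nnct", "matrix"),
            n_i = as.integer(table(lab)),
            Q = g$Q, Qtilde = g$Qtilde, R = g$R)
}

#' @export
print.nnct <- function(x, ...) {
  cat("Nearest-neighbor contingency table (base class x NN class)\n")
  print(unclass(x)[, , drop = FALSE])
  cat("Q =", attr(x, "Q"), " R =", attr(x, "R"), "\n")
  invisible(x)
}

#' Q-symmetry contingency table
#'
#' Tabulates, per class, the number of points serving as NN to exactly m
#' other points (m = 0, 1, ..., `m_max`, with serving counts above `m_max`
#' pooled into the last column). Under symmetry in the shared NN structure,
#' all rows have the same distribution.
#'
#' @param pattern a [point_pattern()].
#' @param g optional precomputed digraph.
#' @param m_max highest serving count kept as its own column; defaults to 5,
#'   the almost-sure planar maximum (counts of 6 are pooled with 5).
#' @return A k x (m_max + 1) integer matrix of class `"qsymtab"` with
#'   attributes `reduced` (FALSE) and `merge_boundary` (NA).
#' @export
build_qsym <- function(pattern, g = NULL, m_max = 5L) {
  stopifnot(inherits(pattern, "ppattern"))
  if (nlevels(pattern$labels) < 2L)
    stop("need at least 2 classes (k >= 2)")
  if (is.null(g))
    g <- nearest_neighbors(pattern)
  m_max <- as.integer(m_max)
  if (m_max < 1L)
    stop("'m_max' must be at least 1")
  serve <- pmin(g$in_degree, m_max)
  tab <- table(class = pattern$labels,
               m = factor(serve, levels = 0:m_max))
  m <- matrix(as.integer(tab), nrow = nlevels(pattern$labels),
              dimnames = list(class = levels(pattern$labels), m = 0:m_max))
  structure(m, class = c("qsymtab", "matrix"),
            reduced = FALSE, merge_boundary = NA_integer_)
}

#' Reduce a Q-symmetry table by merging sparse high-count columns
#'
#' The default rule merges all columns with serving count m >= 2 into one,
#' giving a k x 3 table (the reduction used throughout the reference
#' analyses, with chi-square df 2(k - 1)). The `"expected-count"` rule
#' instead merges the highest remaining column into its left neighbor until
#' the usual cell-count criterion holds (no expected count below 1 and at
#' most 20% of cells below 5) or only two columns remain.
#'
#' @param t an unreduced `"qsymtab"`.
#' @param rule `"merge-2plus"` or `"expected-count"`.
#' @return A reduced `"qsymtab"` with `merge_boundary` recording the first
#'   merged column (serving count).
#' @export
reduce_qsym <- function(t, rule = c("merge-2plus", "expected-count")) {
  stopifnot(inherits(t, "qsymtab"))
  rule <- match.arg(rule)
  if (isTRUE(attr(t, "reduced")))
    stop("table is already reduced")
  m <- unclass(t)
  if (rule == "merge-2plus") {
    if (ncol(m) > 3L) {
      merged <- cbind(m[, 1:2, drop = FALSE],
                      rowSums(m[, -(1:2), drop = FALSE]))
      colnames(merged) <- c(colnames(m)[1:2],
                            paste0(colnames(m)[3], "+"))
      m <- merged
    }
    boundary <- 2L
  } else {
    crit_ok <- function(x) {
      E <- outer(rowSums(x), colSums(x)) / sum(x)
      all(E >= 1) && mean(E < 5) <= 0.2
    }
    while (ncol(m) > 2L && !crit_ok(m)) {
      nc <- ncol(m)
      m[, nc - 1L] <- m[, nc - 1L] + m[, nc]
      colnames(m)[nc - 1L] <- paste0(colnames(m)[nc - 1L], "+")
      m <- m[, -nc, drop = FALSE]
    }
    boundary <- ncol(m) - 1L
  }
  structure(m, class = c("qsymtab", "matrix"),
            reduced = TRUE, merge_boundary = boundary)
}

#' @export
print.qsymtab <- function(x, ...) {
  cat("Q-symmetry contingency table (class x times serving as NN)",
      if (isTRUE(attr(x, "reduced"))) " [reduced]", "\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Read a contingency table from delimited text
#'
#' Expects a header row of column labels; the first column holds row (class)
#' labels. Comma- or tab-delimited, autodetected. Works for both NNCTs and
#' Q-symmetry tables; the returned matrix carries no table-type class, so
#' wrap it with [as_qsymtab()] when exact or Pearson tests on the Q-symmetry
#' table are intended.
#'
#' @param file path to the file.
#' @return An integer matrix with dimnames.
#' @export
read_count_table <- function(file) {
  first <- readLines(file, n = 1L)
  if (length(first) == 0L)
    stop("empty table file: ", file)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (any(m < 0) || any(m != round(m)))
    stop("table entries must be nonnegative integers")
  storage.mode(m) <- "integer"
  m
}

#' Write a contingency table as delimited text
#'
#' @param x a count matrix (NNCT or Q-symmetry table).
#' @param file output path.
#' @export
write_count_table <- function(x, file) {
  df <- data.frame(class = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Mark a count matrix as a (reduced) Q-symmetry table
#'
#' @param x count matrix, rows = classes, columns = serving-count categories.
#' @param reduced is the table already column-merged?
#' @param merge_boundary first merged serving count (default 2 when reduced).
#' @return A `"qsymtab"`.
#' @export
as_qsymtab <- function(x, reduced = TRUE,
                       merge_boundary = if (reduced) 2L else NA_integer_) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- as.character(seq_len(ncol(x)) - 1L)
  if (is.null(rownames(x)))
    rownames(x) <- as.character(seq_len(nrow(x)))
  structure(x, class = c("qsymtab", "matrix"),
            reduced = reduced, merge_boundary = as.integer(merge_boundary))
}

#' Serialize a contingency table (with provenance) to JSON
#'
#' @param x a count matrix; `"nnct"` and `"qsymtab"` attributes are included.
#' @param file optional output path; when `NULL` the JSON string is returned.
#' @export
table_to_json <- function(x, file = NULL) {
  obj <- list(type = if (inherits(x, "nnct")) "nnct"
              else if (inherits(x, "qsymtab")) "qsymtab" else "table",
              counts = unclass(as.matrix(x)),
              row_labels = rownames(x), col_labels = colnames(x))
  if (inherits(x, "nnct"))
    obj <- c(obj, list(Q = attr(x, "Q"), R = attr(x, "R")))
  if (inherits(x, "qsymtab"))
    obj <- c(obj, list(reduced = attr(x, "reduced"),
                       merge_boundary = attr(x, "merge_boundary")))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(json)
  writeLines(json, file)
  invisible(file)
}
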