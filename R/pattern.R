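#' Labeled planar point pattern
#'
#' Construct a labeled point pattern from planar coordinates or from a
#' precomputed dissimilarity matrix. The pattern is the raw input for all
#' nearest-neighbor (NN) symmetry analyses: every point carries a class label,
#' and NN relations are computed either from Euclidean distance between
#' coordinates or directly from the supplied dissimilarities.
#'
#' A dissimilarity matrix must be symmetric with finite off-diagonal entries,
#' and its diagonal must be minimal in each row (an object is at least as
#' close to itself as to anything else). Class labels are kept in
#' first-appearance order unless `labels` is already a factor.
#'
#' @param coords numeric matrix or data frame with two columns (x, y), or
#'   `NULL` when `dissim` is supplied.
#' @param labels vector of class labels, one per point.
#' @param dissim optional square dissimilarity matrix, used instead of
#'   coordinates.
#' @param window optional axis-aligned rectangle `c(xmin, xmax, ymin, ymax)`,
#'   recorded for provenance only (no edge correction is performed).
#' @return An object of class `"ppattern"`: a list with elements `coords`
#'   (or `NULL`), `dissim` (or `NULL`), `labels` (factor), `n`, and `window`.
#' @examples
#' pat <- point_pattern(cbind(runif(20), runif(20)),
#'                      rep(c("A", "B"), each = 10))
#' pat
#' @seealso [nearest_neighbors()], [read_point_pattern()]
#' @export
point_pattern <- function(coords = NULL, labels, dissim = NULL, window = NULL) {
  if (is.null(coords) && is.null(dissim))
    stop("supply either 'coords' or 'dissim'")
  if (!is.null(coords) && !is.null(dissim))
    stop("supply only one of 'coords' and 'dissim'")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (ncol(coords) != 2L)
      stop("'coords' must have exactly two columns (x, y)")
    storage.mode(coords) <- "double"
    if (!all(is.finite(coords)))
      stop("non-finite coordinates")
    n <- nrow(coords)
  } else {
    dissim <- as.matrix(dissim)
    storage.mode(dissim) <- "double"
    n <- nrow(dissim)
    if (ncol(dissim) != n)
      stop("'dissim' must be square")
    if (!all(is.finite(dissim[row(dissim) != col(dissim)])))
      stop("non-finite dissimilarities")
    if (!isTRUE(all.equal(dissim, t(dissim), tolerance = 1e-8)))
      stop("'dissim' must be symmetric")
    off_min <- apply(`diag<-`(dissim, Inf), 1L, min)
    if (any(diag(dissim) > off_min))
      stop("diagonal of 'dissim' must be minimal (rho(x,x) <= rho(x,y))")
  }
  if (n < 2L)
    stop("degenerate pattern: need at least 2 points")
  if (length(labels) != n)
    stop("'labels' must have one entry per point")
  if (anyNA(labels))
    stop("missing class labels")
  if (!is.factor(labels))
    labels <- factor(labels, levels = unique(as.character(labels)))
  labels <- droplevels(labels)
  if (!is.null(window)) {
    window <- as.numeric(window)
    if (length(window) != 4L || window[1] >= window[2] || window[3] >= window[4])
      stop("'window' must be c(xmin, xmax, ymin, ymax) with positive extent")
  }
  structure(list(coords = coords, dissim = dissim, labels = labels,
                 n = n, window = window),
            class = "ppattern")
}

#' @export
print.ppattern <- function(x, ...) {
  kind <- if (is.null(x$dissim)) "planar" else "dissimilarity-based"
  cat("Labeled ", kind, " point pattern: ", x$n, " points, ",
      nlevels(x$labels), " classes\n", sep = "")
  print(table(class = x$labels))
  if (!is.null(x$window))
    cat("window: [", x$window[1], ", ", x$window[2], "] x [",
        x$window[3], ", ", x$window[4], "]\n", sep = "")
  invisible(x)
}

#' Subset a point pattern
#'
#' @param x a `"ppattern"`.
#' @param i index vector of points to keep.
#' @param ... ignored.
#' @return A `"ppattern"` restricted to the selected points; unused class
#'   levels are dropped.
#' @export
`[.ppattern` <- function(x, i, ...) {
  point_pattern(coords = if (is.null(x$coords)) NULL else x$coords[i, , drop = FALSE],
                labels = factor(x$labels[i]),
                dissim = if (is.null(x$dissim)) NULL else x$dissim[i, i, drop = FALSE],
                window = x$window)
}

#' Read a labeled point pattern from a delimited text file
#'
#' Expects a header row and columns named `x`, `y` and `label` (comma- or
#' tab-delimited, autodetected).
#'
#' @param file path to the file.
#' @param window optional window passed to [point_pattern()].
#' @return A `"ppattern"`.
#' @export
read_point_pattern <- function(file, window = NULL) {
  first <- readLines(file, n = 1L)
  if (length(first) == 0L)
    stop("empty point-pattern file: ", file)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("point-pattern file has 0 rows: ", file)
  need <- c("x", "y", "label")
  if (!all(need %in% names(df)))
    stop("point-pattern file must have columns x, y, label")
  point_pattern(cbind(df$x, df$y), df$label, window = window)
}

#' Read a dissimilarity-based pattern from a matrix file plus a label file
#'
#' The matrix file holds the square dissimilarity matrix (delimited text, no
#' header); the label file holds one class label per line.
#'
#' @param matrix_file path to the square dissimilarity matrix.
#' @param label_file path to the label file.
#' @return A `"ppattern"` with a `dissim` component.
#' @export
read_dissim_pattern <- function(matrix_file, label_file) {
  first <- readLines(matrix_file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- as.matrix(utils::read.table(matrix_file, header = FALSE, sep = sep))
  dimnames(d) <- NULL
  labs <- readLines(label_file)
  labs <- labs[nzchar(labs)]
  point_pattern(dissim = d, labels = labs)
}
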