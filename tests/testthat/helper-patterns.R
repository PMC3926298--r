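# fixtures built in code: random labeled patterns and tiny named geometries

random_pattern <- function(n, k = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # guarantee every class occurs
  labs <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  point_pattern(cbind(runif(n), runif(n)), factor(labs, levels = seq_len(k)))
}

# pattern with all pairwise distances distinct (no ties)
jittered_grid_pattern <- function(n, k = 2, seed = 1) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(ceiling(sqrt(n))), y = seq_len(ceiling(sqrt(n))))
  xy <- as.matrix(g[seq_len(n), ]) + matrix(runif(2 * n, 0, 0.2), n)
  labs <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  point_pattern(xy, factor(labs, levels = seq_len(k)))
}

corner_pattern <- function(labels = c("A", "A", "B", "B")) {
  point_pattern(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), labels)
}

collinear_pattern <- function(labels = c("A", "B", "A")) {
  point_pattern(cbind(0:2, 0), labels)
}

lansing_file <- function(name) {
  system.file("extdata", name, package = "nnsymmetry")
}
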