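#' Isolation Forest
#'
#' Ensemble of random partition trees for unsupervised anomaly
#' scoring. Each tree is grown on a random subsample: at every node a
#' feature with non-zero range is drawn at random and a split value is
#' drawn uniformly within its range; growth stops at singleton nodes or
#' at the depth cap `ceiling(log2(subsample size))`. A point's path
#' length, averaged over trees and normalised by the expected
#' unsuccessful-search depth `c(n)` of a binary search tree, gives the
#' anomaly score `s = 2^(-E[h] / c(psi))`: scores near 1 mean the point
#' isolates quickly (anomalous), scores well below 0.5 mean it is
#' buried in the bulk of the data.
#'
#' @param x numeric matrix or data frame of features (rows = points).
#' @param n_trees number of trees (default 100).
#' @param sample_size subsample size per tree (default 256, capped at
#'   the number of rows).
#' @param seed integer seed making subsampling and splits reproducible.
#' @return An object of class `iso_forest`.
#' @seealso [predict.iso_forest()]
#' @export
iso_forest <- function(x, n_trees = 100, sample_size = 256, seed = 42) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stopf("'x' must be numeric without NA")
  n <- nrow(x)
  if (n < 2) stopf("need at least 2 rows to fit an isolation forest")
  check_number(n_trees, "n_trees")
  if (n_trees < 1) stopf("'n_trees' must be >= 1")
  psi <- min(sample_size, n)
  hlim <- ceiling(log2(psi))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(i) {
    idx <- sample.int(n, psi)
    grow_itree(x[idx, , drop = FALSE], 0L, hlim)
  }))
  structure(list(trees = trees, psi = psi, n_trees = n_trees,
                 p = ncol(x), seed = seed),
            class = "iso_forest")
}

grow_itree <- function(x, depth, hlim) {
  n <- nrow(x)
  if (n <= 1L || depth >= hlim) return(list(leaf = TRUE, size = n))
  rng <- apply(x, 2, range)
  usable <- which(rng[2, ] > rng[1, ])
  if (!length(usable)) return(list(leaf = TRUE, size = n))
  a <- if (length(usable) == 1L) usable else sample(usable, 1L)
  v <- runif(1, rng[1, a], rng[2, a])
  left <- x[, a] < v
  list(leaf = FALSE, attr = a, val = v,
       l = grow_itree(x[left, , drop = FALSE], depth + 1L, hlim),
       r = grow_itree(x[!left, , drop = FALSE], depth + 1L, hlim))
}

# expected path length of an unsuccessful BST search over n points
avg_path_length <- function(n) {
  if (n <= 1) return(0)
  if (n == 2) return(1)
  2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
}

itree_path <- function(node, row, depth = 0) {
  while (!node$leaf) {
    node <- if (row[node$attr] < node$val) node$l else node$r
    depth <- depth + 1
  }
  depth + avg_path_length(node$size)
}

#' Anomaly scores from an isolation forest
#'
#' @param object an [iso_forest()] fit.
#' @param newdata matrix or data frame with the same number of feature
#'   columns the forest was grown on.
#' @param ... unused.
#' @return Numeric vector of anomaly scores in (0, 1).
#' @export
predict.iso_forest <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$p)
    stopf("newdata has %d columns; forest was grown on %d", ncol(x), object$p)
  cn <- avg_path_length(object$psi)
  apply(x, 1, function(row) {
    h <- mean(vapply(object$trees, itree_path, numeric(1), row = row))
    2^(-h / cn)
  })
}
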