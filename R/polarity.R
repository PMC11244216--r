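#' K-means clustering of sample amplitudes
#'
#' Clusters the individual samples of a signal by amplitude (1-D
#' feature space) with Lloyd's algorithm and k-means++ seeding.
#' Amplitudes are min-max scaled to \[-1, 1\] before clustering and the
#' centroids are mapped back to the original units afterwards, so the
#' reported centroids are directly comparable to the signal.
#'
#' @param signal an [ecg_signal()].
#' @param k number of clusters (default 5); `k >= 2` and at most the
#'   number of distinct amplitudes.
#' @param seed integer seed controlling the k-means++ initialisation;
#'   the same seed always yields the same labels.
#' @param max_iter Lloyd iteration cap (default 300).
#' @return An object of class `ecg_clusters`: list with `k`, `labels`
#'   (one per sample, in `1..k`), `centroids` (original amplitude
#'   units), `sizes`, and `tot_withinss` (within-cluster sum of squares
#'   in the scaled space).
#' @export
cluster_amplitudes <- function(signal, k = 5, seed = 42, max_iter = 300) {
  stopifnot(inherits(signal, "ecg_signal"))
  check_number(k, "k")
  if (k < 2 || k != floor(k)) stopf("'k' must be an integer >= 2")
  x <- as.numeric(signal)
  if (length(x) < k) stopf("signal length (%d) below k (%d)", length(x), k)
  rng <- range(x)
  n_distinct <- length(unique(x))
  if (n_distinct < k)
    stopf("degenerate input: only %d distinct amplitude(s) for k = %d",
          n_distinct, k)
  xs <- 2 * (x - rng[1]) / (rng[2] - rng[1]) - 1

  centers <- with_seed(seed, kmeanspp_centers(xs, k))
  fit <- suppressWarnings(
    kmeans(xs, centers = matrix(centers, ncol = 1), iter.max = max_iter,
           algorithm = "Lloyd"))
  cent <- (as.numeric(fit$centers) + 1) / 2 * (rng[2] - rng[1]) + rng[1]
  structure(list(k = as.integer(k), labels = fit$cluster, centroids = cent,
                 sizes = as.integer(fit$size),
                 tot_withinss = fit$tot.withinss, seed = seed),
            class = "ecg_clusters")
}

# k-means++ seeding on a 1-D sample; ties broken by lowest index
kmeanspp_centers <- function(xs, k) {
  n <- length(xs)
  centers <- numeric(k)
  centers[1] <- xs[sample.int(n, 1)]
  d2 <- (xs - centers[1])^2
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[(j + 1):k] <- xs[1]
      break
    }
    pick <- sample.int(n, 1, prob = d2 / sum(d2))
    centers[j + 1] <- xs[pick]
    d2 <- pmin(d2, (xs - centers[j + 1])^2)
  }
  # Lloyd in stats::kmeans requires distinct centers
  if (anyDuplicated(centers)) {
    ux <- unique(xs)
    extra <- setdiff(ux, centers)
    dup <- which(duplicated(centers))
    centers[dup] <- extra[seq_along(dup)]
  }
  centers
}

#' @export
print.ecg_clusters <- function(x, ...) {
  cat(sprintf("<ecg_clusters> k = %d over %d samples\n", x$k, length(x$labels)))
  ord <- order(x$centroids)
  df <- data.frame(cluster = ord, centroid = signif(x$centroids[ord], 5),
                   size = x$sizes[ord])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Assess signal polarity from amplitude clusters
#'
#' In a correctly oriented single-lead recording the dominant deflection
#' (the R peak) is positive, so the largest-magnitude positive centroid
#' outweighs the largest-magnitude negative one. The verdict is
#' `"inverted"` when the most negative centroid exceeds the most
#' positive one in absolute value; the evidence ratio is that quotient
#' `|c_min| / |c_max|` (values > 1 indicate inversion). The rule is
#' antisymmetric: negating the signal (and its fitted centroids) flips
#' the verdict and takes the ratio to its reciprocal.
#'
#' @param signal the [ecg_signal()] the model was fitted on.
#' @param model an `ecg_clusters` fit from [cluster_amplitudes()].
#' @return An object of class `polarity_verdict`: list with `verdict`
#'   (`"normal"` or `"inverted"`) and `ratio`.
#' @export
assess_polarity <- function(signal, model) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(model, "ecg_clusters"))
  if (length(model$labels) != length(signal))
    stopf("model was not fitted on this signal (length mismatch)")
  if (diff(range(as.numeric(signal))) == 0)
    stopf("degenerate input: constant signal has no polarity")
  c_min <- min(model$centroids)
  c_max <- max(model$centroids)
  if (c_max <= 0) {
    verdict <- "inverted"; ratio <- Inf
  } else if (c_min >= 0) {
    verdict <- "normal"; ratio <- 0
  } else {
    ratio <- abs(c_min) / abs(c_max)
    verdict <- if (ratio > 1) "inverted" else "normal"
  }
  structure(list(verdict = verdict, ratio = ratio), class = "polarity_verdict")
}

#' @export
print.polarity_verdict <- function(x, ...) {
  cat(sprintf("<polarity_verdict> %s (evidence ratio %.4g)\n", x$verdict, x$ratio))
  invisible(x)
}

#' Correct an inverted recording
#'
#' When the verdict is `"inverted"`, every sample is multiplied by -1,
#' restoring the expected orientation; otherwise the signal is returned
#' unchanged. Applying the correction twice with inverted verdicts is
#' the identity.
#'
#' @param signal an [ecg_signal()].
#' @param verdict a `polarity_verdict` from [assess_polarity()].
#' @return The (possibly negated) [ecg_signal()].
#' @export
correct_polarity <- function(signal, verdict) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(verdict, "polarity_verdict"))
  if (identical(verdict$verdict, "inverted")) reclass_signal(-as.numeric(signal), signal)
  else signal
}

#' Cluster, assess and correct in one step
#'
#' Convenience wrapper: fits [cluster_amplitudes()], assesses polarity
#' and applies [correct_polarity()].
#'
#' @inheritParams cluster_amplitudes
#' @return List with `signal` (corrected), `verdict` and `model`.
#' @export
fix_polarity <- function(signal, k = 5, seed = 42) {
  model <- cluster_amplitudes(signal, k = k, seed = seed)
  verdict <- assess_polarity(signal, model)
  list(signal = correct_polarity(signal, verdict), verdict = verdict,
       model = model)
}
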