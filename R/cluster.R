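## Ward hierarchical clustering of scaled temporal profiles with
## elbow-based selection of the cluster count.

wss_for_assignment <- function(x, cl) {
  sum(vapply(split(seq_len(nrow(x)), cl), function(i) {
    xi <- x[i, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
}

#' Ward clustering of temporal profiles
#'
#' Agglomerative clustering with `hclust(method = "ward.D2")` on the
#' Euclidean distances of the (scaled) profiles, cut with `cutree`. When
#' `k` is not given it is chosen by a deterministic elbow rule on the
#' within-group sum-of-squares curve: the k in `2..(kmax - 1)` maximizing
#' the second forward difference `wss(k-1) - 2 wss(k) + wss(k+1)`. The
#' published analyses chose k by eye from the same curve, so `k` is
#' always overridable.
#'
#' @param x Numeric matrix of profiles (features x timepoints), finite.
#' @param k Number of clusters; `NULL` to select by the elbow rule.
#' @param kmax Largest candidate k for the WSS curve (default 15).
#' @return An object of class `"ward_cluster"`: `assignment` (named
#'   integer vector), `k`, `tree` (the `hclust` object), `wss_curve`
#'   (data.frame k, wss), `heights`.
#' @export
ward_cluster <- function(x, k = NULL, kmax = 15L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop2("profiles must be finite")
  n <- nrow(x)
  if (n < 2L) stop2("at least two profiles required")
  if (!is.null(k) && (k < 1L || k > n)) stop2("k must be in 1..n")
  h <- stats::hclust(stats::dist(x), method = "ward.D2")
  kmax <- min(kmax, n)
  ks <- seq_len(kmax)
  cuts <- stats::cutree(h, k = ks)
  if (kmax == 1L) cuts <- matrix(cuts, ncol = 1L)
  wss <- vapply(ks, function(kk) wss_for_assignment(x, cuts[, kk]),
                numeric(1))
  if (is.null(k)) {
    if (kmax < 3L) stop2("kmax too small for elbow selection")
    cand <- 2:(kmax - 1L)
    d2 <- wss[cand - 1L] - 2 * wss[cand] + wss[cand + 1L]
    k <- cand[which.max(d2)]
  }
  assignment <- stats::cutree(h, k = k)
  names(assignment) <- rownames(x)
  structure(list(assignment = assignment, k = as.integer(k), tree = h,
                 wss_curve = data.frame(k = ks, wss = wss),
                 heights = h$height),
            class = "ward_cluster")
}

#' @export
print.ward_cluster <- function(x, ...) {
  cat("<ward_cluster> ", length(x$assignment), " features in ", x$k,
      " clusters\n", sep = "")
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Per-cluster median and quartile profiles
#'
#' @param x Profile matrix used for clustering (features x timepoints).
#' @param clusters A `ward_cluster` object (or an assignment vector).
#' @return A data.frame with one row per (cluster, timepoint):
#'   `cluster`, `timepoint`, `median`, `q25`, `q75`, `n`.
#' @export
cluster_summary <- function(x, clusters) {
  cl <- if (inherits(clusters, "ward_cluster")) clusters$assignment else
    clusters
  if (length(cl) != nrow(x)) stop2("assignment does not cover all features")
  if (any(table(cl) == 0L)) stop2("empty cluster")
  tp <- colnames(x) %||% as.character(seq_len(ncol(x)))
  out <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    xi <- x[cl == k, , drop = FALSE]
    data.frame(cluster = k,
               timepoint = tp,
               median = apply(xi, 2, stats::median),
               q25 = apply(xi, 2, stats::quantile, probs = 0.25,
                           names = FALSE),
               q75 = apply(xi, 2, stats::quantile, probs = 0.75,
                           names = FALSE),
               n = nrow(xi),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
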