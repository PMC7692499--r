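#' Density-based spatial clustering (DBSCAN) on a point set
#'
#' Classic DBSCAN with Euclidean distances, used on the 2-D UMAP embeddings
#' produced inside the consensus-clustering iterations. A point is a core
#' point if at least `min_points` points (itself included) lie within `eps`;
#' clusters grow from core points, border points join the first cluster that
#' reaches them, and everything else is noise (label 0). Implemented in the
#' package because no DBSCAN implementation is available among the installed
#' dependencies; the O(n^2) distance matrix is fine at cohort scale.
#'
#' @param x Numeric matrix of coordinates (rows = points).
#' @param eps Neighborhood radius.
#' @param min_points Minimum neighborhood size for a core point.
#' @return Integer vector of cluster labels, 0 = noise; clusters are
#'   numbered 1, 2, ... in order of discovery (deterministic in row order).
#' @export
dbscan_points <- function(x, eps, min_points) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 1, eps > 0, min_points >= 2)
  d <- as.matrix(stats::dist(x))
  within <- d <= eps
  nbr <- lapply(seq_len(n), function(i) which(within[i, ]))
  core <- lengths(nbr) >= min_points
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      for (q in nbr[[p]]) {
        if (labels[q] == 0L) labels[q] <- cl
        if (core[q] && !visited[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Choose a DBSCAN eps from the knee of the k-nearest-neighbor distance curve
#'
#' Computes each point's distance to its k-th nearest neighbor, sorts the
#' distances, and returns the distance at the point of maximum discrete
#' curvature of the (normalized) sorted curve — the "elbow" that separates
#' within-cluster from between-cluster distance regimes. A light moving
#' average stabilizes the second differences.
#'
#' @param embedding Numeric matrix of coordinates (rows = points).
#' @param k Neighbor rank (typically the DBSCAN `min_points`).
#' @return Positive scalar eps.
#' @export
select_eps_knee <- function(embedding, k) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < k + 1L) stop("need at least k + 1 points to compute k-NN distances")
  d <- as.matrix(stats::dist(embedding))
  kdist <- apply(d, 1L, function(row) sort(row)[k + 1L])  # row[1] is self (0)
  y <- sort(kdist)
  if (max(y) - min(y) < .Machine$double.eps^0.5) return(max(max(y), .Machine$double.eps))
  # normalize both axes to [0, 1] so curvature is scale-free
  yn <- (y - min(y)) / (max(y) - min(y))
  w <- max(3L, round(n / 50) * 2L + 1L)
  ys <- stats::filter(yn, rep(1 / w, w), sides = 2)
  ys[is.na(ys)] <- yn[is.na(ys)]
  h <- 1 / (n - 1)
  i <- 2:(n - 1L)
  d1 <- (ys[i + 1L] - ys[i - 1L]) / (2 * h)
  d2 <- (ys[i + 1L] - 2 * ys[i] + ys[i - 1L]) / h^2
  curv <- abs(d2) / (1 + d1^2)^1.5
  knee <- i[which.max(curv)]
  max(y[knee], .Machine$double.eps)
}
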