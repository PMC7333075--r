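# Independent oracles used to pin down expected values. These deliberately
# avoid the code paths they check: exhaustive enumeration instead of dynamic
# programming, brute-force subset search instead of alternating updates.

# Exhaustive DTW: enumerate every monotone warping path (unit steps right/
# down/diagonal), take the minimal aggregate Euclidean cost, and among
# minimal-cost paths the minimal path length.
oracle_dtw <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A); m <- nrow(B)
  d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  best_cost <- Inf; best_len <- Inf
  walk <- function(i, j, cost, len) {
    cost <- cost + d(i, j); len <- len + 1
    if (i == n && j == m) {
      if (cost < best_cost - 1e-12 ||
          (abs(cost - best_cost) <= 1e-12 && len < best_len)) {
        best_cost <<- cost; best_len <<- len
      }
      return(invisible())
    }
    if (i < n) walk(i + 1, j, cost, len)
    if (j < m) walk(i, j + 1, cost, len)
    if (i < n && j < m) walk(i + 1, j + 1, cost, len)
  }
  walk(1, 1, 0, 0)
  list(raw = best_cost, normalized = best_cost / best_len)
}

# Brute-force k-medoids: enumerate all k-subsets of candidate medoids with
# nearest-medoid assignment; returns the global-minimum inertia (sum of
# squared dissimilarities) and, for a fixed medoid set, the best-assignment
# inertia.
oracle_inertia_for_medoids <- function(D, medoids) {
  sum(apply(D[, medoids, drop = FALSE], 1, min)^2)
}
oracle_kmedoids_global <- function(D, k) {
  subsets <- utils::combn(nrow(D), k)
  min(apply(subsets, 2, function(med) oracle_inertia_for_medoids(D, med)))
}

# Brute-force nearest point on a polyline: dense sampling along every
# segment.
oracle_route_progress <- function(verts, px, py, step = 0.01) {
  seg <- sqrt(rowSums(diff(verts)^2))
  cum <- c(0, cumsum(seg))
  svals <- seq(0, cum[length(cum)], by = step)
  idx <- findInterval(svals, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(verts) - 1)
  f <- (svals - cum[idx]) / pmax(seg[idx], 1e-12)
  qx <- verts[idx, 1] + f * (verts[idx + 1, 1] - verts[idx, 1])
  qy <- verts[idx, 2] + f * (verts[idx + 1, 2] - verts[idx, 2])
  vapply(seq_along(px), function(i) {
    svals[which.min((qx - px[i])^2 + (qy - py[i])^2)]
  }, 0)
}

# Trapezoid integral by independent means (stats::approxfun + integrate on
# the piecewise-linear interpolant).
oracle_trapezoid <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  x <- fpr[ord]; y <- tpr[ord]
  f <- approxfun(x, y, ties = "ordered")
  # integrate each linear piece separately so quadrature never straddles a kink
  sum(vapply(seq_len(length(x) - 1), function(i) {
    if (x[i + 1] <= x[i]) return(0)
    integrate(f, x[i], x[i + 1], rel.tol = 1e-12)$value
  }, 0))
}
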