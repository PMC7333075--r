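#' Dynamic time warping dissimilarity between two subintervals
#'
#' Aligns the time steps of the two channel matrices to minimize the
#' aggregate per-step Euclidean difference across channels (classic DP over
#' monotone warping paths with unit steps, no window). The default
#' `"normalized"` mode divides the minimal aggregate cost by the warping
#' path length (among minimal-cost paths, the shortest), so zone-transit
#' duration does not dominate the dissimilarity; `"raw"` returns the
#' aggregate cost itself. Symmetric; zero iff the sequences are identical.
#'
#' DTW is not a metric: the triangle inequality is not guaranteed and is not
#' relied on anywhere in the package.
#'
#' @param a,b `subinterval` objects or plain channel matrices (frames x
#'   channels) with the same channel count. Channels should be standardized
#'   beforehand (see [standardize_zone()]) so meters and pedal fractions are
#'   commensurate.
#' @param normalization `"normalized"` (default) or `"raw"`.
#' @return non-negative scalar dissimilarity.
#' @export
#' @examples
#' dtw(matrix(c(0, 0, 0)), matrix(c(1, 1)))  # 1 under path-length normalization
dtw <- function(a, b, normalization = c("normalized", "raw")) {
  normalization <- match.arg(normalization)
  ma <- if (inherits(a, "subinterval")) a$channels else as.matrix(a)
  mb <- if (inherits(b, "subinterval")) b$channels else as.matrix(b)
  if (nrow(ma) < 1 || nrow(mb) < 1) stop("sequences must be non-empty")
  if (ncol(ma) != ncol(mb))
    stop("channel count mismatch: ", ncol(ma), " vs ", ncol(mb))
  .dtw_dist_cpp(ma, mb, normalization == "normalized")
}

#' Standardize one zone's subintervals for clustering
#'
#' Each of the four channels is z-scored with the pooled mean/SD over the
#' given subinterval set (the clustering scope), so lane offset (meters)
#' does not dominate the unit-interval pedal channels in the DTW cost. The
#' pooled SD is floored at 5% of the channel's physical range (3.6 m lane
#' offset, unit pedals, 2 for signed steering): a channel that is nearly
#' constant in a zone is informative *because* it is constant, and
#' inflating its residual noise to unit variance would drown the channels
#' that actually vary there. A channel with zero pooled variance is
#' centered only.
#'
#' @param subs list of `subinterval`s from one zone.
#' @param center,scale optionally reuse precomputed per-channel statistics
#'   (e.g. a training fold's).
#' @return list with `subs` (standardized copies), `center`, `scale`.
#' @export
standardize_zone <- function(subs, center = NULL, scale = NULL) {
  pooled <- do.call(rbind, lapply(subs, `[[`, "channels"))
  if (is.null(center)) center <- colMeans(pooled)
  if (is.null(scale)) {
    scale <- apply(pooled, 2, sd)
    ranges <- c(lane_offset = 3.6, throttle = 1, brake = 1, steering = 2)
    floors <- rep(1e-12, ncol(pooled))
    hit <- match(colnames(pooled), names(ranges))
    floors[!is.na(hit)] <- 0.05 * ranges[hit[!is.na(hit)]]
    scale[!is.finite(scale)] <- 1
    scale <- pmax(scale, floors)
    scale[scale < 1e-12] <- 1
  }
  out <- lapply(subs, function(su) {
    su$channels <- sweep(sweep(su$channels, 2, center), 2, scale, "/")
    su
  })
  list(subs = out, center = center, scale = scale)
}

#' Pairwise DTW dissimilarity matrix for one zone
#'
#' Computes every pair once (the matrix is symmetric by construction with a
#' zero diagonal). All subintervals must come from the same zone and share
#' the 4-channel layout.
#'
#' @param subs list of >= 2 `subinterval`s (or channel matrices).
#' @param normalization passed to [dtw()].
#' @return `dissimilarity_matrix`: an n x n symmetric matrix with `ids`
#'   (drive ids) attached as dimnames.
#' @export
dissimilarity_matrix <- function(subs, normalization = c("normalized", "raw")) {
  normalization <- match.arg(normalization)
  if (length(subs) < 2) stop("need at least 2 subintervals")
  mats <- lapply(subs, function(su)
    if (inherits(su, "subinterval")) su$channels else as.matrix(su))
  nc <- vapply(mats, ncol, 0L)
  if (length(unique(nc)) != 1L) stop("channel count mismatch across subintervals")
  D <- .dtw_matrix_cpp(mats, normalization == "normalized")
  ids <- vapply(seq_along(subs), function(i) {
    su <- subs[[i]]
    if (inherits(su, "subinterval")) su$drive_id else as.character(i)
  }, "")
  dimnames(D) <- list(ids, ids)
  class(D) <- c("dissimilarity_matrix", class(D))
  D
}
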