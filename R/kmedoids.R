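#' k-medoids clustering on a precomputed dissimilarity matrix
#'
#' Partitioning around medoids in the alternating form: (i) assign each
#' subinterval to its nearest medoid (ties broken by the lowest medoid
#' index); (ii) within each cluster elect as new medoid the member
#' minimizing the aggregate dissimilarity to all other members (ties broken
#' by the lowest subinterval index). After each round the inertia — the sum
#' of *squared* dissimilarities from subintervals to their assigned medoids —
#' is computed; iteration stops as soon as a round fails to decrease it (the
#' previous round's model is kept) or after `max_iter` rounds.
#'
#' @param D dissimilarity matrix (from [dissimilarity_matrix()] or any
#'   symmetric non-negative matrix with zero diagonal).
#' @param k number of clusters (default 8).
#' @param max_iter round cap (default 100).
#' @param seed integer seed for the initial uniform k-subset draw.
#' @param init optionally, explicit initial medoid indices (overrides `seed`).
#' @return a `cluster_model`: list with `k`, `medoid_ids` (row indices into
#'   `D`), `assignment` (1..k per subinterval), `inertia`, `inertia_trace`
#'   (per accepted round), `n_members`.
#' @export
k_medoids <- function(D, k = 8L, max_iter = 100L, seed = 1L, init = NULL) {
  D <- unclass(D)
  n <- nrow(D)
  if (is.null(n) || n != ncol(D)) stop("D must be a square matrix")
  if (n < k) stop("need at least k subintervals (n = ", n, ", k = ", k, ")")
  if (is.null(init)) {
    set.seed(seed)
    medoids <- sort(sample.int(n, k))
  } else {
    medoids <- sort(as.integer(init))
    if (length(medoids) != k || anyDuplicated(medoids))
      stop("init must be k distinct indices")
  }
  assign_to <- function(medoids) {
    # nearest medoid, ties -> lowest medoid index (max.col ties.method first
    # on the negated distances)
    sub <- D[, medoids, drop = FALSE]
    max.col(-sub, ties.method = "first")
  }
  inertia_of <- function(medoids, assignment) {
    sum(D[cbind(seq_len(n), medoids[assignment])]^2)
  }
  assignment <- assign_to(medoids)
  best <- list(medoids = medoids, assignment = assignment,
               inertia = inertia_of(medoids, assignment))
  trace <- best$inertia
  for (r in seq_len(max_iter)) {
    new_medoids <- integer(k)
    for (c in seq_len(k)) {
      members <- which(best$assignment == c)
      if (!length(members)) { new_medoids[c] <- best$medoids[c]; next }
      agg <- colSums(D[members, members, drop = FALSE])
      new_medoids[c] <- members[which.min(agg)]
    }
    new_assignment <- assign_to(new_medoids)
    new_inertia <- inertia_of(new_medoids, new_assignment)
    if (new_inertia < best$inertia) {
      best <- list(medoids = new_medoids, assignment = new_assignment,
                   inertia = new_inertia)
      trace <- c(trace, new_inertia)
    } else break
  }
  structure(list(k = k,
                 medoid_ids = best$medoids,
                 assignment = best$assignment,
                 inertia = best$inertia,
                 inertia_trace = trace,
                 n_members = tabulate(best$assignment, nbins = k)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d  n=%d  inertia=%.4g\n",
              x$k, length(x$assignment), x$inertia))
  cat("  members per cluster:", paste(x$n_members, collapse = " "), "\n")
  invisible(x)
}

#' Best-of-restarts k-medoids
#'
#' Runs [k_medoids()] from `restarts` independent uniform initial medoid
#' draws (seeded substreams of `seed`) and returns the minimal-inertia model
#' (first winner on exact ties). Deterministic given `seed`.
#'
#' @inheritParams k_medoids
#' @param restarts number of initializations (default 20).
#' @param zone_id optional zone id stored on the model.
#' @return the best `cluster_model`, with `restart_inertias` attached.
#' @export
best_clustering <- function(D, k = 8L, restarts = 20L, max_iter = 100L,
                            seed = 1L, zone_id = NULL) {
  best <- NULL
  inertias <- numeric(restarts)
  for (r in seq_len(restarts)) {
    m <- k_medoids(D, k = k, max_iter = max_iter, seed = derive_seed(seed, r))
    inertias[r] <- m$inertia
    if (is.null(best) || m$inertia < best$inertia) best <- m
  }
  best$restart_inertias <- inertias
  best$zone_id <- zone_id
  best
}

#' Per-cluster outcome summaries
#'
#' Summaries shown next to each prototypical behavior: member count, the
#' fraction of member subintervals with a collision flagged in the zone, and
#' the mean/SD of members' on-road-exam scores.
#'
#' @param model a `cluster_model`.
#' @param collision logical per subinterval (in `D` row order).
#' @param ore_score numeric per subinterval.
#' @return data.frame with one row per cluster.
#' @export
cluster_summaries <- function(model, collision = NULL, ore_score = NULL) {
  k <- model$k
  out <- data.frame(cluster = seq_len(k),
                    medoid = model$medoid_ids,
                    n_members = model$n_members,
                    collision_rate = NA_real_,
                    ore_score_mean = NA_real_,
                    ore_score_sd = NA_real_)
  for (c in seq_len(k)) {
    members <- which(model$assignment == c)
    if (!length(members)) next
    if (!is.null(collision))
      out$collision_rate[c] <- mean(collision[members])
    if (!is.null(ore_score)) {
      out$ore_score_mean[c] <- mean(ore_score[members])
      out$ore_score_sd[c] <- sd(ore_score[members])
    }
  }
  out
}

#' Soft-clustering membership features
#'
#' Arranges, per drive, the dissimilarities from its zone-z subinterval to
#' each of zone z's k medoids as a feature block; blocks are concatenated in
#' ascending zone id order, giving k x n_zones columns (1328 for k = 8 over
#' 166 zones). A drive that never encounters a zone gets k missing entries
#' (`NA`) for that zone; a drive whose subinterval *is* a medoid has a zero
#' in that medoid's column. Drives visiting no zone at all are dropped with
#' a warning.
#'
#' @param drive_ids character vector of all drives to featurize (row order).
#' @param zone_features named list (by `"z<zone_id>"`) of lists with
#'   `drive_ids` (zone row order) and `diss` (n_zone x k matrix of member ->
#'   medoid dissimilarities), as produced by [zone_membership_block()].
#' @return numeric matrix, rows = drives with >= 1 visited zone, columns
#'   named `z<zone>_m<j>`.
#' @export
membership_features <- function(drive_ids, zone_features) {
  zids <- as.integer(sub("^z", "", names(zone_features)))
  ord <- order(zids)
  zone_features <- zone_features[ord]
  zids <- zids[ord]
  blocks <- lapply(seq_along(zone_features), function(i) {
    zf <- zone_features[[i]]
    k <- ncol(zf$diss)
    blk <- matrix(NA_real_, length(drive_ids), k,
                  dimnames = list(drive_ids,
                                  paste0("z", zids[i], "_m", seq_len(k))))
    hit <- match(zf$drive_ids, drive_ids)
    ok <- !is.na(hit)
    blk[hit[ok], ] <- zf$diss[ok, , drop = FALSE]
    blk
  })
  X <- do.call(cbind, blocks)
  visited <- rowSums(!is.na(X)) > 0
  if (any(!visited)) {
    warning(sum(!visited), " drive(s) visited no zone; excluded")
    X <- X[visited, , drop = FALSE]
  }
  X
}

#' One zone's member-to-medoid dissimilarity block
#'
#' @param D the zone's dissimilarity matrix (rows/cols in zone order).
#' @param model the zone's `cluster_model` (medoid indices into `D`), or a
#'   vector of medoid indices.
#' @param drive_ids drive ids in `D` row order (default from dimnames).
#' @param rows optionally restrict to these `D` rows (e.g. test-fold drives).
#' @return list with `drive_ids` and `diss` (rows x k).
#' @export
zone_membership_block <- function(D, model, drive_ids = rownames(D),
                                  rows = seq_len(nrow(D))) {
  medoids <- if (inherits(model, "cluster_model")) model$medoid_ids else
    as.integer(model)
  list(drive_ids = drive_ids[rows],
       diss = unclass(D)[rows, medoids, drop = FALSE])
}
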