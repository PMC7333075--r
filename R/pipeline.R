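#' Build a pipeline run configuration
#'
#' Flat key/value configuration for [run_pipeline()]; every run writes the
#' fully resolved configuration back to its output directory as YAML.
#'
#' @param seed master seed (all stage substreams derive from it).
#' @param n_drivers cohort size.
#' @param n_env,total_zones,route_length,base_limit environment-bank shape
#'   (see [generate_environment_bank()]).
#' @param k,restarts,max_iter clustering controls (see [best_clustering()]).
#' @param cluster_scope `"trainfold"` (default; medoids elected per training
#'   fold) or `"all"` (cluster once on the full set).
#' @param dtw_normalization `"normalized"` or `"raw"` (see [dtw()]).
#' @param classifier `"logistic"` or `"svm"`.
#' @param folds CV folds.
#' @param a,b,sigma_e,noise_sd simulator parameters.
#' @param out output directory.
#' @param write_artifacts write every intermediate artifact (default TRUE).
#' @return named list of class `run_config`.
#' @export
run_config <- function(seed = 7L, n_drivers = 200L, n_env = 10L,
                       total_zones = 166L, route_length = 5500,
                       base_limit = 13.4, k = 8L, restarts = 20L,
                       max_iter = 100L,
                       cluster_scope = c("trainfold", "all"),
                       dtw_normalization = c("normalized", "raw"),
                       classifier = c("logistic", "svm"), folds = 10L,
                       a = 34, b = 0.05, sigma_e = 8, noise_sd = 0.05,
                       out = tempfile("zonescreen_run_"),
                       write_artifacts = TRUE) {
  cfg <- list(seed = as.integer(seed), n_drivers = as.integer(n_drivers),
              n_env = as.integer(n_env), total_zones = as.integer(total_zones),
              route_length = route_length, base_limit = base_limit,
              k = as.integer(k), restarts = as.integer(restarts),
              max_iter = as.integer(max_iter),
              cluster_scope = match.arg(cluster_scope),
              dtw_normalization = match.arg(dtw_normalization),
              classifier = match.arg(classifier), folds = as.integer(folds),
              a = a, b = b, sigma_e = sigma_e, noise_sd = noise_sd,
              out = out, write_artifacts = isTRUE(write_artifacts))
  stopifnot(cfg$n_drivers > 0, cfg$n_env > 0, cfg$total_zones >= cfg$n_env,
            cfg$k > 0, cfg$restarts > 0, cfg$folds > 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

#' Cluster every zone of a cohort
#'
#' Standardizes each zone's subintervals (pooled channel z-scores), computes
#' the DTW dissimilarity matrix, and elects the best-of-restarts k-medoids
#' model. Zones visited by fewer than `max(k, 2)` drives are skipped.
#'
#' @param sub_lists per-drive [extract_subintervals()] results.
#' @param zone_ids integer zone ids to cluster.
#' @param k,restarts,max_iter see [best_clustering()].
#' @param seed master seed (fans out per zone).
#' @param normalization see [dtw()].
#' @return named list (`"z<zone_id>"`) of zone objects: `D`, `model`,
#'   `drive_ids`, `collision`.
#' @export
cluster_zones <- function(sub_lists, zone_ids, k = 8L, restarts = 20L,
                          max_iter = 100L, seed = 1L,
                          normalization = "normalized") {
  out <- list()
  for (z in zone_ids) {
    subs <- collect_zone(sub_lists, z)
    if (length(subs) < max(k, 2)) next
    std <- standardize_zone(subs)
    D <- dissimilarity_matrix(std$subs, normalization = normalization)
    model <- best_clustering(D, k = k, restarts = restarts,
                             max_iter = max_iter,
                             seed = derive_seed(seed, z), zone_id = z)
    out[[paste0("z", z)]] <- list(
      D = D, model = model,
      drive_ids = vapply(subs, `[[`, "", "drive_id"),
      collision = vapply(subs, `[[`, TRUE, "collision"))
  }
  out
}

# Membership feature matrix when clustering on the full set ("all" scope).
membership_from_zone_objs <- function(zone_objs, drive_ids) {
  blocks <- lapply(zone_objs, function(zo)
    zone_membership_block(zo$D, zo$model, zo$drive_ids))
  membership_features(drive_ids, blocks)
}

# Per-fold membership features for the "trainfold" scope: within each fold,
# medoids are elected on training-set rows only (the precomputed DTW matrix
# is reused), then train/test dissimilarity blocks are read off it.
membership_fold_features <- function(zone_objs, drive_ids, fold_id, k = 8L,
                                     restarts = 20L, max_iter = 100L,
                                     seed = 1L) {
  lapply(sort(unique(fold_id)), function(f) {
    te_drives <- drive_ids[fold_id == f]
    blocks <- list()
    for (nm in names(zone_objs)) {
      zo <- zone_objs[[nm]]
      tr_rows <- which(!(zo$drive_ids %in% te_drives))
      if (length(tr_rows) < max(k, 2)) next
      Dtr <- unclass(zo$D)[tr_rows, tr_rows, drop = FALSE]
      model <- best_clustering(Dtr, k = k, restarts = restarts,
                               max_iter = max_iter,
                               seed = derive_seed(seed, zo$model$zone_id, f))
      medoid_rows <- tr_rows[model$medoid_ids]
      blocks[[nm]] <- zone_membership_block(zo$D, medoid_rows, zo$drive_ids)
    }
    suppressWarnings({
      X <- membership_features(drive_ids, blocks)
      X <- X[match(drive_ids, rownames(X)), , drop = FALSE]
    })
    rownames(X) <- drive_ids
    te <- fold_id == f
    list(train = X[!te, , drop = FALSE], test = X[te, , drop = FALSE])
  })
}

#' Run the full screening pipeline
#'
#' simulate -> extract -> cluster -> featurize -> evaluate, as one
#' reproducible run: identical configuration and seed give identical
#' artifacts. Stage timings and seeds are logged to stderr and `run.log`;
#' every intermediate artifact is written under `config$out` when
#' `write_artifacts` is set.
#'
#' @param config a [run_config()].
#' @return run report: list with `config`, `bank`, `cohort`, `features`
#'   (membership matrix, `"all"` scope), `variables`, `sweep` (or `grid`),
#'   `timings`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out, "run.log")
  cat("", file = logf)
  t0_all <- proc.time()[3]
  timings <- c()
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    say("[%s] start (seed %d)", name, config$seed)
    val <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (artifacts under ", config$out, ")", call. = FALSE))
    el <- proc.time()[3] - t0
    timings[name] <<- el
    say("[%s] done in %.1f s", name, el)
    val
  }
  yaml::write_yaml(unclass(config), file.path(config$out, "config.yaml"))

  bank <- stage("simulate-bank", {
    b <- generate_environment_bank(config$n_env, config$total_zones,
                                   seed = derive_seed(config$seed, 10),
                                   route_length = config$route_length,
                                   base_limit = config$base_limit)
    if (config$write_artifacts)
      write_environments(b, file.path(config$out, "environments.json"))
    b
  })

  sim <- stage("simulate-cohort", {
    cs <- generate_cohort(config$n_drivers, bank,
                          seed = derive_seed(config$seed, 20),
                          a = config$a, b = config$b,
                          sigma_e = config$sigma_e,
                          noise_sd = config$noise_sd)
    if (config$write_artifacts) {
      rd <- file.path(config$out, "replays")
      dir.create(rd, showWarnings = FALSE)
      for (rec in cs$recordings) {
        write_replay(rec, file.path(rd, paste0(rec$drive_id, ".jsonl")))
        if (!is.null(rec$events) && nrow(rec$events))
          write.csv(rec$events,
                    file.path(rd, paste0(rec$drive_id, ".events.csv")),
                    row.names = FALSE)
      }
      write_cohort(cs$cohort, file.path(config$out, "cohort.csv"))
    }
    cs
  })

  recs <- lapply(sim$recordings, function(r) {
    r <- truncate_at_motion(r)
    r
  })
  drive_ids <- vapply(recs, `[[`, "", "drive_id")

  sub_lists <- stage("extract", {
    sl <- lapply(recs, function(r)
      extract_subintervals(r, bank[[r$environment_id]]))
    if (config$write_artifacts) {
      sd_ <- file.path(config$out, "subintervals")
      dir.create(sd_, showWarnings = FALSE)
      all_zones <- unique(unlist(lapply(sl, names)))
      for (zn in all_zones) {
        rows <- do.call(rbind, lapply(sl, function(x) {
          su <- x[[zn]]
          if (is.null(su)) return(NULL)
          data.frame(drive_id = su$drive_id,
                     frame_idx = seq_len(nrow(su$channels)) - 1L,
                     su$channels, t = su$timestamps)
        }))
        write.csv(rows, file.path(sd_, paste0(zn, ".csv")), row.names = FALSE)
      }
    }
    sl
  })

  all_zone_ids <- sort(unlist(lapply(bank, function(e) e$zones$zone_id)))
  zone_objs <- stage("cluster", {
    zo <- cluster_zones(sub_lists, all_zone_ids, k = config$k,
                        restarts = config$restarts,
                        max_iter = config$max_iter,
                        seed = derive_seed(config$seed, 30),
                        normalization = config$dtw_normalization)
    if (config$write_artifacts) {
      models <- lapply(zo, function(z) list(
        zone_id = z$model$zone_id, k = z$model$k,
        medoid_drive_ids = z$drive_ids[z$model$medoid_ids],
        assignment = z$model$assignment, inertia = z$model$inertia,
        summaries = cluster_summaries(z$model, collision = z$collision)))
      jsonlite::write_json(models, file.path(config$out, "models.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    zo
  })

  features <- stage("featurize", {
    X <- membership_from_zone_objs(zone_objs, drive_ids)
    V <- build_variables_cohort(recs, bank)
    if (config$write_artifacts) {
      write.csv(data.frame(drive_id = rownames(X), X, check.names = FALSE),
                file.path(config$out, "features.csv"), row.names = FALSE)
      write.csv(data.frame(drive_id = rownames(V), V, check.names = FALSE),
                file.path(config$out, "variables.csv"), row.names = FALSE)
    }
    list(membership = X, variables = V)
  })

  report <- stage("evaluate", {
    lab <- label_outcome(sim$cohort$ore_score)
    actual_fail <- lab$label == "fail"
    names(actual_fail) <- sim$cohort$drive_id
    af <- actual_fail[rownames(features$membership)]
    ev_seed <- derive_seed(config$seed, 40)
    if (config$classifier == "logistic") {
      if (config$cluster_scope == "trainfold") {
        fold_id <- stratified_folds(af, config$folds, ev_seed)
        ff <- membership_fold_features(zone_objs,
                                       rownames(features$membership), fold_id,
                                       k = config$k, restarts = config$restarts,
                                       max_iter = config$max_iter,
                                       seed = derive_seed(config$seed, 31))
        sweep <- logistic_sweep(features$membership, af, folds = config$folds,
                                seed = ev_seed, fold_features = ff)
      } else {
        sweep <- logistic_sweep(features$membership, af, folds = config$folds,
                                seed = ev_seed)
      }
      if (config$write_artifacts) {
        write.csv(sweep$metrics, file.path(config$out, "metrics.csv"),
                  row.names = FALSE)
        write.csv(sweep$roc, file.path(config$out, "roc.csv"),
                  row.names = FALSE)
        best <- sweep$metrics[which.max(sweep$metrics$accuracy), ]
        jsonlite::write_json(list(auc = sweep$auc, best = as.list(best)),
                             file.path(config$out, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      sweep
    } else {
      grid <- svm_grid(features$membership, af, folds = config$folds,
                       seed = ev_seed)
      if (config$write_artifacts)
        write.csv(grid, file.path(config$out, "metrics.csv"),
                  row.names = FALSE)
      grid
    }
  })

  say("pipeline complete in %.1f s", proc.time()[3] - t0_all)
  list(config = config, bank = bank, cohort = sim$cohort,
       features = features$membership, variables = features$variables,
       zone_objs = zone_objs, result = report, timings = timings)
}
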