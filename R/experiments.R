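# Orchestration of the three evaluation protocols:
#   (a) training benchmark across resolutions and methods,
#   (b) cross-dataset generalization with dive-map evaluation,
#   (c) fine-tuning versus from-scratch over a ladder of training-set sizes.

#' Simulate and preprocess a labelled trip set
#'
#' Convenience wrapper: simulates a multi-trip deployment dataset for a
#' species preset and assembles 1-s labelled trips.
#'
#' @param species_tag Species preset tag (see [preset_config()]).
#' @param n_trips Number of trips.
#' @param seed Master seed.
#' @param duration Optional fixed trip duration (s); default draws from the
#'   species trip-duration distribution.
#' @param with_gaps Apply the species gap fraction (default `TRUE`).
#' @return List of 1-s `dive_trip` objects, with the `sim_config` attached
#'   as attribute `config`.
#' @export
simulate_trips <- function(species_tag, n_trips, seed = 1L, duration = NULL,
                           with_gaps = TRUE) {
  cfg <- preset_config(species_tag, seed)
  deps <- simulate_dataset(cfg, n_trips, seed = seed, with_gaps = with_gaps,
                           duration = duration)
  trips <- lapply(deps, process_deployment)
  attr(trips, "config") <- cfg
  trips
}

# Downsample a whole trip list, dropping trips too short for the window.
downsample_all <- function(trips, dt, min_len = 20) {
  out <- lapply(trips, function(tr) {
    if (nrow(tr) %/% dt < max(2, min_len)) return(NULL)
    downsample(tr, dt)
  })
  out[!vapply(out, is.null, TRUE)]
}

trips_by_id <- function(trips, ids) {
  all_ids <- vapply(trips, trip_id, "")
  trips[match(ids, all_ids)]
}

#' Training benchmark: all methods on one dataset at several resolutions
#'
#' For each resolution: downsample, split trips 50/30/20, fit networks on the
#' training/validation splits and evaluate everything on the held-out test
#' trips. FPT needs no training; the HMM is fitted unsupervised on the
#' training trips with supervised dive-state selection.
#'
#' @param trips List of 1-s `dive_trip`s (e.g. [simulate_trips()]).
#' @param dataset Dataset label for the output table.
#' @param resolutions Subset of `c(5, 15, 30)` seconds.
#' @param models Subset of `c("FPT", "HMM", "FCNET", "CNNET", "UNET")`.
#' @param class_weight Dive-class weight for the network loss (30 for
#'   booby-like, 5 for cormorant-like data).
#' @param n_states HMM state count (3 booby-like, 4 cormorant-like).
#' @param split_seed,model_seed Seeds for the split and the network
#'   initialization/shuffling.
#' @param train_cfg Optional [train_config()] overrides (list).
#' @return List with `table` (one row per resolution and model: AUC, BCE,
#'   F-score, train/validation loss, reference name) and `models` (the
#'   trained bundles, named by reference).
#' @export
run_training_benchmark <- function(trips, dataset = "sim",
                                   resolutions = c(5, 15, 30),
                                   models = c("FPT", "HMM", "FCNET",
                                              "CNNET", "UNET"),
                                   class_weight = 30, n_states = 3,
                                   split_seed = 1L, model_seed = 1L,
                                   train_cfg = list()) {
  models <- toupper(models)
  rows <- list()
  bundles <- list()
  for (dt in resolutions) {
    ds <- downsample_all(trips, dt)
    split <- split_dataset(ds, seed = split_seed)
    tr_trips <- trips_by_id(ds, split$train)
    va_trips <- trips_by_id(ds, split$validation)
    te_trips <- trips_by_id(ds, split$test)
    norm <- fit_norm_stats(tr_trips, fitted_on = dataset)
    tr_ws <- make_windows(tr_trips, norm)
    va_ws <- make_windows(va_trips, norm)
    for (model in models) {
      ref <- sprintf("%s_%s_%ss", dataset, model, dt)
      if (model == "FPT") {
        preds <- lapply(te_trips, fpt_predict_trip)
        met <- pooled_metrics(preds, te_trips)
        rows[[ref]] <- data.frame(dataset = dataset, resolution = dt,
                                  model = model, auc = met$auc,
                                  bce = met$bce, f_score = met$f_score,
                                  train_loss = NA, validation_loss = NA,
                                  reference = ref)
      } else if (model == "HMM") {
        hmm <- hmm_fit(tr_trips, n_states = n_states, seed = model_seed)
        hmm <- hmm_select_dive_state(hmm, tr_trips)
        preds <- lapply(te_trips, function(tr) hmm_dive_probability(hmm, tr))
        met <- pooled_metrics(preds, te_trips)
        rows[[ref]] <- data.frame(dataset = dataset, resolution = dt,
                                  model = model, auc = met$auc,
                                  bce = met$bce, f_score = met$f_score,
                                  train_loss = NA, validation_loss = NA,
                                  reference = ref)
        bundles[[ref]] <- hmm
      } else {
        cfg <- do.call(train_config,
                       utils::modifyList(list(class_weight = class_weight,
                                              seed = model_seed), train_cfg))
        net <- build_network(model, seed = model_seed)
        fit <- train_network(net, tr_ws, va_ws, cfg)
        fit$model$meta$dt <- dt
        preds <- lapply(te_trips, function(tr) predict_trip(fit$model, tr))
        met <- pooled_metrics(preds, te_trips)
        be <- attr(fit$history, "best_epoch")
        rows[[ref]] <- data.frame(dataset = dataset, resolution = dt,
                                  model = model, auc = met$auc,
                                  bce = met$bce, f_score = met$f_score,
                                  train_loss = fit$history$train_loss[be],
                                  validation_loss =
                                    fit$history$validation_loss[be],
                                  reference = ref)
        bundles[[ref]] <- fit$model
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "split_seed") <- split_seed
  attr(tab, "model_seed") <- model_seed
  list(table = tab, models = bundles)
}

#' Cross-dataset generalization of trained models
#'
#' Applies trained bundles to a new dataset without any weight update; the
#' source normalization statistics are reused unchanged. Reports AUC, BCE,
#' F-score and the mean squared error between the dive-distribution map
#' estimated from the predictions and the map of true dive locations.
#'
#' @param models Named list of trained `dive_model` bundles (each with
#'   `meta$dt` set) and/or `dive_hmm` fits.
#' @param target_trips List of 1-s labelled `dive_trip`s of the target
#'   dataset.
#' @param grid_step,bandwidth KDE grid parameters (degrees).
#' @return data.frame with one row per model: metrics plus `map_mse`.
#' @export
run_generalization <- function(models, target_trips, grid_step = 0.01,
                               bandwidth = 0.25) {
  rows <- list()
  for (ref in names(models)) {
    mdl <- models[[ref]]
    dt <- if (inherits(mdl, "dive_model")) mdl$meta$dt else mdl$dt
    if (is.null(dt)) stop("model '", ref, "' carries no resolution (dt)")
    ds <- downsample_all(target_trips, dt)
    if (!length(ds)) stop("no target trip is long enough at dt = ", dt)
    preds <- if (inherits(mdl, "dive_model")) {
      lapply(ds, function(tr) predict_trip(mdl, tr))
    } else {
      lapply(ds, function(tr) hmm_dive_probability(mdl, tr))
    }
    met <- pooled_metrics(preds, ds)
    lon <- unlist(lapply(ds, function(tr) tr$lon))
    lat <- unlist(lapply(ds, function(tr) tr$lat))
    pw <- unlist(lapply(preds, function(d) d$p_dive))
    yw <- unlist(lapply(ds, function(tr) as.numeric(tr$dive)))
    grid <- make_grid_spec(range(lon), range(lat), grid_step, bandwidth)
    ref_map <- kde_map(lon, lat, yw, grid = grid)
    est_map <- kde_map(lon, lat, pw, grid = grid)
    rows[[ref]] <- data.frame(model = ref, resolution = dt, auc = met$auc,
                              bce = met$bce, f_score = met$f_score,
                              map_mse = map_mse(est_map, ref_map))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Fine-tuning ladder: pretrained initialization versus from scratch
#'
#' For each training-set size in `ladder` and each replicate seed, trains the
#' pretrained model's architecture both from scratch and initialized from
#' the pretrained weights on the same trip subset (subsets are nested across
#' ladder sizes within a seed), then evaluates on a fixed held-out test set.
#'
#' @param pretrained A trained `dive_model` (source dataset).
#' @param target_trips List of 1-s labelled target `dive_trip`s.
#' @param dt Analysis resolution (s).
#' @param ladder Training-set sizes in trips (default `c(1, 5, 15, 30)`).
#' @param seeds Replicate seeds (default `1:5`).
#' @param class_weight Dive-class weight for the target dataset.
#' @param split_seed Seed fixing the validation/test trips.
#' @param train_cfg Optional [train_config()] overrides.
#' @return data.frame with one row per (init, n_trips, seed): AUC, stopping
#'   and best epoch.
#' @export
run_finetuning_ladder <- function(pretrained, target_trips, dt = 15,
                                  ladder = c(1, 5, 15, 30), seeds = 1:5,
                                  class_weight = 30, split_seed = 99L,
                                  train_cfg = list()) {
  stopifnot(inherits(pretrained, "dive_model"))
  ds <- downsample_all(target_trips, dt)
  n_val <- max(2L, round(0.15 * length(ds)))
  n_test <- max(2L, round(0.25 * length(ds)))
  need <- max(ladder) + n_val + n_test
  if (length(ds) < need) {
    stop("need at least ", need, " usable trips (", max(ladder),
         " train + ", n_val, " validation + ", n_test, " test); have ",
         length(ds))
  }
  ids <- vapply(ds, trip_id, "")
  fixed <- with_seed(split_seed, sample(ids))
  test_ids <- fixed[seq_len(n_test)]
  val_ids <- fixed[n_test + seq_len(n_val)]
  pool_ids <- setdiff(ids, c(test_ids, val_ids))
  te_trips <- trips_by_id(ds, test_ids)
  va_trips_all <- trips_by_id(ds, val_ids)
  rows <- list()
  for (seed in seeds) {
    pool <- with_seed(seed, sample(pool_ids))
    for (n_tr in sort(ladder)) {
      tr_trips <- trips_by_id(ds, pool[seq_len(n_tr)])
      norm <- fit_norm_stats(tr_trips, fitted_on = "finetune_target")
      tr_ws <- make_windows(tr_trips, norm)
      va_ws <- make_windows(va_trips_all, norm)
      if (n_windows(tr_ws) == 0) next
      cfg <- do.call(train_config,
                     utils::modifyList(list(class_weight = class_weight,
                                            seed = seed), train_cfg))
      for (init in c("scratch", "finetune")) {
        fit <- if (init == "scratch") {
          train_network(build_network(pretrained$spec$kind, seed = seed),
                        tr_ws, va_ws, cfg)
        } else {
          fine_tune(pretrained, tr_ws, va_ws, cfg)
        }
        fit$model$meta$dt <- dt
        preds <- lapply(te_trips, function(tr) predict_trip(fit$model, tr))
        met <- pooled_metrics(preds, te_trips)
        rows[[length(rows) + 1L]] <-
          data.frame(init = init, n_trips = n_tr, seed = seed,
                     auc = met$auc,
                     stopped_epoch = attr(fit$history, "stopped_epoch"),
                     best_epoch = attr(fit$history, "best_epoch"))
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "split_seed") <- split_seed
  tab
}
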