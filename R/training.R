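# Supervised training with weighted binary cross-entropy, Adam, and early
# stopping on the validation loss; fine-tuning from a pretrained bundle; and
# stride-1 window-mean prediction of whole trips.

#' Training configuration
#'
#' @param class_weight Weight `w` on the dive class in the loss. The study
#'   defaults are 30 for booby-like and 5 for cormorant-like datasets.
#' @param learning_rate Fixed Adam learning rate (default 0.001).
#' @param batch_size Windows per optimization step (default 64).
#' @param max_epochs Maximum epochs (default 100).
#' @param patience Epochs without validation improvement before stopping
#'   (default 1: stop as soon as the validation loss starts increasing).
#' @param seed Seed for shuffling (weight init is seeded in
#'   [build_network()]).
#' @return A `train_config` list.
#' @export
train_config <- function(class_weight = 30, learning_rate = 0.001,
                         batch_size = 64, max_epochs = 100, patience = 1,
                         seed = 1L) {
  stopifnot(class_weight > 0, learning_rate > 0, patience >= 1 || max_epochs == 0)
  structure(list(class_weight = class_weight, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Weighted binary cross-entropy
#'
#' Mean over elements of `-(w * y * log(p) + (1 - y) * log(1 - p))`, with
#' probabilities clipped to `[1e-7, 1 - 1e-7]`. `w = 1` reduces to the
#' unweighted binary cross-entropy.
#'
#' @param p Predicted probabilities.
#' @param y Labels in `{0, 1}` (same shape as `p`).
#' @param w Positive weight on the positive (dive) class.
#' @return Scalar loss.
#' @examples
#' weighted_bce(0.5, 1, 30)  # 30 * log(2)
#' @export
weighted_bce <- function(p, y, w = 1) {
  if (length(p) != length(y)) stop("p and y must have the same shape")
  stopifnot(w > 0)
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(-(w * y * log(p) + (1 - y) * log(1 - p)))
}

# Gradient of the weighted BCE at the pre-sigmoid logits:
# dL/dz = ((1 - y) * p - w * y * (1 - p)) / n_elements.
wbce_logit_grad <- function(p, y, w) {
  ((1 - y) * p - w * y * (1 - p)) / length(p)
}

# Full-set loss evaluated in bounded chunks.
eval_loss <- function(bundle, ws, w, chunk = 1024L) {
  N <- n_windows(ws)
  tot <- 0
  for (i0 in seq(1L, N, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, N)
    p <- net_forward(bundle$spec, bundle$params,
                     ws$x[, , idx, drop = FALSE])$p
    tot <- tot + weighted_bce(p, ws$y[, idx, drop = FALSE], w) * length(idx)
  }
  tot / N
}

#' Train a network on labelled windows
#'
#' Minimizes the weighted binary cross-entropy with Adam (beta1 = 0.9,
#' beta2 = 0.999, eps = 1e-8) at a fixed learning rate. Train and validation
#' losses are recorded after every epoch; training stops once the validation
#' loss has not improved for `patience` epochs, and the weights of the best
#' epoch are returned. Identical seeds and data give identical histories.
#'
#' @param bundle An untrained (or pretrained) `dive_model`.
#' @param train_ws,val_ws `dive_windows` sets (both non-empty).
#' @param cfg A [train_config()].
#' @return List with `model` (best-epoch `dive_model`) and `history`
#'   (data.frame `epoch, train_loss, validation_loss`, plus `stopped_epoch`
#'   and `best_epoch` attributes).
#' @export
train_network <- function(bundle, train_ws, val_ws, cfg = train_config()) {
  stopifnot(inherits(bundle, "dive_model"), inherits(cfg, "train_config"))
  if (n_windows(train_ws) == 0 || n_windows(val_ws) == 0) {
    stop("training and validation window sets must be non-empty")
  }
  bundle$norm_stats <- train_ws$norm_stats
  bundle$meta$class_weight <- cfg$class_weight
  if (cfg$max_epochs == 0L) {
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       validation_loss = numeric(0))
    attr(hist, "stopped_epoch") <- 0L
    attr(hist, "best_epoch") <- 0L
    return(list(model = bundle, history = hist))
  }
  w <- cfg$class_weight
  N <- n_windows(train_ws)
  state <- adam_init(bundle$params)
  best <- list(params = bundle$params, loss = Inf, epoch = 0L)
  tl <- vl <- numeric(0)
  step <- 0L
  wait <- 0L
  stopped <- cfg$max_epochs
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(N)
      for (i0 in seq(1L, N, by = cfg$batch_size)) {
        idx <- perm[i0:min(i0 + cfg$batch_size - 1L, N)]
        xb <- train_ws$x[, , idx, drop = FALSE]
        yb <- train_ws$y[, idx, drop = FALSE]
        fw <- net_forward(bundle$spec, bundle$params, xb)
        if (!all(is.finite(fw$p))) {
          stop("non-finite network output at epoch ", epoch,
               "; training aborted")
        }
        dz <- wbce_logit_grad(fw$p, yb, w)
        grads <- net_backward(bundle$spec, bundle$params, xb, fw$cache, dz)
        step <- step + 1L
        upd <- adam_step(bundle$params, grads, state, cfg$learning_rate, step)
        bundle$params <- upd$params
        state <- upd$state
      }
      tl[epoch] <- eval_loss(bundle, train_ws, w)
      vl[epoch] <- eval_loss(bundle, val_ws, w)
      if (!is.finite(tl[epoch]) || !is.finite(vl[epoch])) {
        stop("non-finite loss at epoch ", epoch, "; training aborted")
      }
      if (vl[epoch] < best$loss) {
        best <- list(params = bundle$params, loss = vl[epoch], epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) {
          stopped <- epoch
          break
        }
      }
      stopped <- epoch
    }
  })
  bundle$params <- best$params
  bundle$meta$epochs_trained <- best$epoch
  bundle$meta$train_seed <- cfg$seed
  hist <- data.frame(epoch = seq_along(tl), train_loss = tl,
                     validation_loss = vl)
  attr(hist, "stopped_epoch") <- as.integer(stopped)
  attr(hist, "best_epoch") <- as.integer(best$epoch)
  list(model = bundle, history = hist)
}

#' Fine-tune a pretrained model on a new dataset
#'
#' Identical to [train_network()] but the weights are initialized from the
#' pretrained bundle (all layers unfrozen) and the normalization statistics
#' are the ones refitted on the new training windows.
#'
#' @param pretrained A trained `dive_model`.
#' @param train_ws,val_ws `dive_windows` of the new dataset (built with norm
#'   stats fitted on its training split).
#' @param cfg A [train_config()]; `max_epochs = 0` returns the pretrained
#'   weights unchanged.
#' @return Same shape as [train_network()].
#' @export
fine_tune <- function(pretrained, train_ws, val_ws, cfg = train_config()) {
  stopifnot(inherits(pretrained, "dive_model"))
  if (train_ws$L != pretrained$spec$L) {
    stop("window length ", train_ws$L, " does not match the pretrained spec (",
         pretrained$spec$L, ")")
  }
  bundle <- pretrained
  bundle$meta$finetuned_from <- pretrained$meta$seed
  out <- train_network(bundle, train_ws, val_ws, cfg)
  out$model$meta$finetuned <- TRUE
  out
}

#' Predict per-position dive probabilities for a whole trip
#'
#' Runs the network on every stride-1 window of the trip and averages, for
#' each position, the probabilities of all windows containing it.
#'
#' @param bundle A trained `dive_model` (with normalization statistics).
#' @param tr A `dive_trip` of length at least the window length.
#' @return A `dive_probs` data.frame `t, lon, lat, p_dive` with attributes
#'   `trip_id` and `dt`.
#' @export
predict_trip <- function(bundle, tr) {
  stopifnot(inherits(bundle, "dive_model"), inherits(tr, "dive_trip"))
  if (is.null(bundle$norm_stats)) stop("model has no normalization statistics")
  L <- bundle$spec$L
  n <- nrow(tr)
  if (n < L) stop("trip of length ", n, " is shorter than the window (", L, ")")
  ws <- make_windows(tr, bundle$norm_stats, L = L, stride = 1)
  N <- n_windows(ws)
  sums <- numeric(n)
  cnts <- numeric(n)
  chunk <- 512L
  for (i0 in seq(1L, N, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, N)
    p <- net_forward(bundle$spec, bundle$params,
                     ws$x[, , idx, drop = FALSE])$p
    pos <- rep(ws$start[idx], each = L) + seq_len(L) - 1L
    sums <- sums + tabulate_sum(as.vector(p), pos, n)
    cnts <- cnts + tabulate(pos, nbins = n)
  }
  out <- data.frame(t = tr$t, lon = tr$lon, lat = tr$lat,
                    p_dive = sums / cnts)
  attr(out, "trip_id") <- trip_id(tr)
  attr(out, "dt") <- trip_dt(tr)
  class(out) <- c("dive_probs", "data.frame")
  out
}

# Sum of values grouped by integer position 1..n.
tabulate_sum <- function(v, pos, n) {
  out <- numeric(n)
  agg <- rowsum(v, pos)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
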