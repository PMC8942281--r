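# The three window-based segmentation architectures, mapping a 3 x 20 input
# window (speed, turning angle, coverage) to 20 per-position dive
# probabilities:
#
#   FCNET  flatten(60) -> 100 -> 500 -> 500 -> 500 -> 20, ReLU hidden layers,
#          per-position sigmoid head (~570k parameters)
#   CNNET  1-D convolutions 3->16->32->32 (k=3, 'same') -> 1 (k=1), sigmoid
#          head (4,865 parameters, the "5k" budget)
#   UNET   two-scale encoder/decoder with skip concatenation: 3->24->24,
#          maxpool (20->10), 24->48->48, transposed-conv upsample 48->24
#          (10->20), concat (48), 48->24->24, head 24->1 (20,041 parameters,
#          the "20k" budget)

NETWORK_KINDS <- c("FCNET", "CNNET", "UNET")

#' Architecture specification (layer table)
#'
#' Returns the fixed layer table of one of the three architectures. The table
#' fully determines the trainable-parameter count.
#'
#' @param kind One of `"FCNET"`, `"CNNET"`, `"UNET"`.
#' @param L Window length in positions (fixed at 20).
#' @return An object of class `arch_spec` with the layer table.
#' @export
architecture_spec <- function(kind, L = 20) {
  kind <- toupper(kind)
  if (!kind %in% NETWORK_KINDS) {
    stop("unknown architecture '", kind, "'; valid kinds: ",
         paste(NETWORK_KINDS, collapse = ", "))
  }
  layers <- switch(kind,
    FCNET = data.frame(
      name = c("fc1", "fc2", "fc3", "fc4", "fc5"),
      op = "dense",
      fan_in = c(3 * L, 100, 500, 500, 500),
      fan_out = c(100, 500, 500, 500, L),
      kernel = 1,
      activation = c("relu", "relu", "relu", "relu", "sigmoid")
    ),
    CNNET = data.frame(
      name = c("c1", "c2", "c3", "head"),
      op = "conv",
      fan_in = c(3, 16, 32, 32),
      fan_out = c(16, 32, 32, 1),
      kernel = c(3, 3, 3, 1),
      activation = c("relu", "relu", "relu", "sigmoid")
    ),
    UNET = data.frame(
      name = c("enc1", "enc2", "bot1", "bot2", "up", "dec1", "dec2", "head"),
      op = c("conv", "conv", "conv", "conv", "upconv", "conv", "conv", "conv"),
      fan_in = c(3, 24, 24, 48, 48, 48, 24, 24),
      fan_out = c(24, 24, 48, 48, 24, 24, 24, 1),
      kernel = c(3, 3, 3, 3, 2, 3, 3, 1),
      activation = c("relu", "relu", "relu", "relu", "linear", "relu",
                     "relu", "sigmoid")
    )
  )
  structure(list(kind = kind, input_channels = 3L, L = as.integer(L),
                 layers = layers),
            class = "arch_spec")
}

#' Count trainable parameters of an architecture
#'
#' Sums, over the layer table, `fan_in * fan_out * kernel + fan_out` for
#' convolutions and transposed convolutions, and `fan_in * fan_out + fan_out`
#' for dense layers.
#'
#' @param spec An `arch_spec` (or a kind name).
#' @return Integer parameter count.
#' @examples
#' count_parameters("CNNET")  # 4865, i.e. the 5k budget
#' count_parameters("UNET")   # 20041, i.e. the 20k budget
#' @export
count_parameters <- function(spec) {
  if (is.character(spec)) spec <- architecture_spec(spec)
  stopifnot(inherits(spec, "arch_spec"))
  ly <- spec$layers
  sum(ly$fan_in * ly$fan_out * ifelse(ly$op == "dense", 1, ly$kernel) +
        ly$fan_out)
}

#' Build an untrained model bundle
#'
#' Allocates seeded initial weights (uniform fan-in scaling) for the given
#' architecture. The bundle carries the architecture spec, the parameter
#' store, normalization statistics (attached at training time) and metadata.
#'
#' @param kind One of `"FCNET"`, `"CNNET"`, `"UNET"`.
#' @param seed Integer seed for the weight initialization.
#' @param L Window length (fixed default 20).
#' @return An object of class `dive_model`.
#' @export
build_network <- function(kind, seed = 1L, L = 20) {
  spec <- architecture_spec(kind, L)
  params <- with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(spec$layers))) {
      ly <- spec$layers[i, ]
      fan <- if (ly$op == "dense") ly$fan_in else ly$fan_in * ly$kernel
      s <- 1 / sqrt(fan)
      W <- switch(ly$op,
        dense = matrix(stats::runif(ly$fan_out * ly$fan_in, -s, s),
                       ly$fan_out, ly$fan_in),
        conv = array(stats::runif(ly$fan_out * ly$fan_in * ly$kernel, -s, s),
                     c(ly$fan_out, ly$fan_in, ly$kernel)),
        upconv = array(stats::runif(ly$fan_in * ly$fan_out * ly$kernel, -s, s),
                       c(ly$fan_in, ly$fan_out, ly$kernel))
      )
      out[[ly$name]] <- list(W = W, b = stats::runif(ly$fan_out, -s, s))
    }
    out
  })
  bundle <- structure(list(spec = spec, params = params, norm_stats = NULL,
                           meta = list(seed = as.integer(seed),
                                       epochs_trained = 0L)),
                      class = "dive_model")
  stopifnot(n_model_parameters(bundle) == count_parameters(spec))
  bundle
}

# Actual number of scalars held in a bundle's parameter store.
n_model_parameters <- function(bundle) {
  sum(vapply(bundle$params,
             function(p) length(p$W) + length(p$b), 0))
}

#' Forward pass of a model on a batch of windows
#'
#' @param bundle A `dive_model`.
#' @param x A single `3 x L` matrix or a `3 x L x N` array of windows.
#' @return A `L x N` matrix of probabilities in `(0, 1)` (a length-L vector
#'   for a single window).
#' @export
forward <- function(bundle, x) {
  stopifnot(inherits(bundle, "dive_model"))
  single <- length(dim(x)) == 2
  if (single) x <- array(x, c(dim(x), 1))
  d <- dim(x)
  if (d[1] != bundle$spec$input_channels || d[2] != bundle$spec$L) {
    stop("input must be ", bundle$spec$input_channels, " x ", bundle$spec$L)
  }
  if (!all(is.finite(x))) stop("input must be finite")
  p <- net_forward(bundle$spec, bundle$params, x)$p
  if (single) p[, 1] else p
}

# Forward pass returning the cache needed for backprop. Output p: (L, N).
net_forward <- function(spec, params, x) {
  switch(spec$kind,
    FCNET = {
      N <- dim(x)[3]
      xm <- matrix(x, 3 * spec$L, N)
      f1 <- dense_forward(xm, params$fc1$W, params$fc1$b)
      r1 <- relu_forward(f1$out)
      f2 <- dense_forward(r1$out, params$fc2$W, params$fc2$b)
      r2 <- relu_forward(f2$out)
      f3 <- dense_forward(r2$out, params$fc3$W, params$fc3$b)
      r3 <- relu_forward(f3$out)
      f4 <- dense_forward(r3$out, params$fc4$W, params$fc4$b)
      r4 <- relu_forward(f4$out)
      f5 <- dense_forward(r4$out, params$fc5$W, params$fc5$b)
      p <- sigmoid(f5$out)
      list(p = p, cache = list(f1 = f1, r1 = r1, f2 = f2, r2 = r2, f3 = f3,
                               r3 = r3, f4 = f4, r4 = r4, f5 = f5, p = p))
    },
    CNNET = {
      c1 <- conv1d_forward(x, params$c1$W, params$c1$b)
      r1 <- relu_forward(c1$out)
      c2 <- conv1d_forward(r1$out, params$c2$W, params$c2$b)
      r2 <- relu_forward(c2$out)
      c3 <- conv1d_forward(r2$out, params$c3$W, params$c3$b)
      r3 <- relu_forward(c3$out)
      h <- conv1d_forward(r3$out, params$head$W, params$head$b)
      p <- sigmoid(matrix(h$out, spec$L, dim(x)[3]))
      list(p = p, cache = list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, c3 = c3,
                               r3 = r3, h = h, p = p))
    },
    UNET = {
      e1 <- conv1d_forward(x, params$enc1$W, params$enc1$b)
      re1 <- relu_forward(e1$out)
      e2 <- conv1d_forward(re1$out, params$enc2$W, params$enc2$b)
      re2 <- relu_forward(e2$out)
      pool <- maxpool2_forward(re2$out)                     # 24 x 10 x N
      b1 <- conv1d_forward(pool$out, params$bot1$W, params$bot1$b)
      rb1 <- relu_forward(b1$out)
      b2 <- conv1d_forward(rb1$out, params$bot2$W, params$bot2$b)
      rb2 <- relu_forward(b2$out)
      up <- upconv2_forward(rb2$out, params$up$W, params$up$b)  # 24 x 20 x N
      N <- dim(x)[3]
      cat_ <- array(0, c(48, spec$L, N))                    # skip concat
      cat_[1:24, , ] <- re2$out
      cat_[25:48, , ] <- up$out
      d1 <- conv1d_forward(cat_, params$dec1$W, params$dec1$b)
      rd1 <- relu_forward(d1$out)
      d2 <- conv1d_forward(rd1$out, params$dec2$W, params$dec2$b)
      rd2 <- relu_forward(d2$out)
      h <- conv1d_forward(rd2$out, params$head$W, params$head$b)
      p <- sigmoid(matrix(h$out, spec$L, N))
      list(p = p,
           cache = list(e1 = e1, re1 = re1, e2 = e2, re2 = re2, pool = pool,
                        b1 = b1, rb1 = rb1, b2 = b2, rb2 = rb2, up = up,
                        d1 = d1, rd1 = rd1, d2 = d2, rd2 = rd2, h = h, p = p))
    }
  )
}

# Backward pass from dL/dz (gradient at the pre-sigmoid logits, shape L x N).
net_backward <- function(spec, params, x, cache, dz) {
  grads <- list()
  switch(spec$kind,
    FCNET = {
      g5 <- dense_backward(dz, params$fc5$W, cache$f5$cache)
      d4 <- relu_backward(g5$dx, cache$r4$cache)
      g4 <- dense_backward(d4, params$fc4$W, cache$f4$cache)
      d3 <- relu_backward(g4$dx, cache$r3$cache)
      g3 <- dense_backward(d3, params$fc3$W, cache$f3$cache)
      d2 <- relu_backward(g3$dx, cache$r2$cache)
      g2 <- dense_backward(d2, params$fc2$W, cache$f2$cache)
      d1 <- relu_backward(g2$dx, cache$r1$cache)
      g1 <- dense_backward(d1, params$fc1$W, cache$f1$cache)
      grads <- list(fc1 = g1, fc2 = g2, fc3 = g3, fc4 = g4, fc5 = g5)
    },
    CNNET = {
      N <- ncol(dz)
      gh <- conv1d_backward(array(dz, c(1, spec$L, N)), params$head$W,
                            cache$h$cache)
      d3 <- relu_backward(gh$dx, cache$r3$cache)
      g3 <- conv1d_backward(d3, params$c3$W, cache$c3$cache)
      d2 <- relu_backward(g3$dx, cache$r2$cache)
      g2 <- conv1d_backward(d2, params$c2$W, cache$c2$cache)
      d1 <- relu_backward(g2$dx, cache$r1$cache)
      g1 <- conv1d_backward(d1, params$c1$W, cache$c1$cache)
      grads <- list(c1 = g1, c2 = g2, c3 = g3, head = gh)
    },
    UNET = {
      N <- ncol(dz)
      gh <- conv1d_backward(array(dz, c(1, spec$L, N)), params$head$W,
                            cache$h$cache)
      dd2 <- relu_backward(gh$dx, cache$rd2$cache)
      gd2 <- conv1d_backward(dd2, params$dec2$W, cache$d2$cache)
      dd1 <- relu_backward(gd2$dx, cache$rd1$cache)
      gd1 <- conv1d_backward(dd1, params$dec1$W, cache$d1$cache)
      dcat <- gd1$dx
      dskip <- dcat[1:24, , , drop = FALSE]
      dup <- dcat[25:48, , , drop = FALSE]
      gup <- upconv2_backward(dup, params$up$W, cache$up$cache)
      db2 <- relu_backward(gup$dx, cache$rb2$cache)
      gb2 <- conv1d_backward(db2, params$bot2$W, cache$b2$cache)
      db1 <- relu_backward(gb2$dx, cache$rb1$cache)
      gb1 <- conv1d_backward(db1, params$bot1$W, cache$b1$cache)
      dpool <- maxpool2_backward(gb1$dx, cache$pool$cache)
      de2 <- relu_backward(dpool + dskip, cache$re2$cache)
      ge2 <- conv1d_backward(de2, params$enc2$W, cache$e2$cache)
      de1 <- relu_backward(ge2$dx, cache$re1$cache)
      ge1 <- conv1d_backward(de1, params$enc1$W, cache$e1$cache)
      grads <- list(enc1 = ge1, enc2 = ge2, bot1 = gb1, bot2 = gb2, up = gup,
                    dec1 = gd1, dec2 = gd2, head = gh)
    }
  )
  grads
}

#' Save / load a model bundle
#'
#' The bundle round-trips bit-exactly through serialization; loading
#' validates the parameter-count invariant against the architecture spec.
#'
#' @param bundle A `dive_model`.
#' @param file Path to the checkpoint file.
#' @return `load_model` returns the `dive_model`.
#' @export
save_model <- function(bundle, file) {
  stopifnot(inherits(bundle, "dive_model"))
  saveRDS(bundle, file)
  invisible(file)
}

#' @rdname save_model
#' @export
load_model <- function(file) {
  bundle <- readRDS(file)
  stopifnot(inherits(bundle, "dive_model"))
  if (n_model_parameters(bundle) != count_parameters(bundle$spec)) {
    stop("checkpoint is inconsistent with its architecture spec")
  }
  bundle
}

#' @export
print.dive_model <- function(x, ...) {
  cat("<dive_model>", x$spec$kind, "-", count_parameters(x$spec),
      "parameters\n")
  if (!is.null(x$meta$dt)) cat("  dt:", x$meta$dt, "s\n")
  cat("  epochs trained:", x$meta$epochs_trained %||% 0L, "\n")
  invisible(x)
}
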