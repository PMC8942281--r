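# Low-level network primitives operating on batched 1-D signals stored as
# arrays of dimension (channels, length, batch). Each forward returns the
# output plus the cache needed for the matching backward; backwards return
# the input gradient and parameter gradients. All ops are plain matrix
# algebra so gradients can be verified against finite differences.

# im2col for a k-tap 'same'-padded 1-D convolution: returns a (C*k) x (L*N)
# matrix whose column (n-1)*L + l stacks the receptive field of output l.
im2col <- function(x, k, pad) {
  d <- dim(x)
  C <- d[1]; L <- d[2]; N <- d[3]
  xp <- array(0, c(C, L + 2 * pad, N))
  xp[, pad + seq_len(L), ] <- x
  K <- matrix(0, C * k, L * N)
  for (t in seq_len(k)) {
    K[(t - 1) * C + seq_len(C), ] <- matrix(xp[, t:(t + L - 1), ], C, L * N)
  }
  K
}

col2im <- function(dK, C, L, N, k, pad) {
  dxp <- array(0, c(C, L + 2 * pad, N))
  for (t in seq_len(k)) {
    block <- array(dK[(t - 1) * C + seq_len(C), ], c(C, L, N))
    dxp[, t:(t + L - 1), ] <- dxp[, t:(t + L - 1), ] + block
  }
  dxp[, pad + seq_len(L), , drop = FALSE]
}

# 'same'-padded 1-D convolution. W: (C_out, C_in, k); b: C_out.
conv1d_forward <- function(x, W, b) {
  d <- dim(x); dW <- dim(W)
  k <- dW[3]; pad <- (k - 1) %/% 2
  K <- im2col(x, k, pad)
  Wm <- matrix(W, nrow = dW[1])
  out <- Wm %*% K + b
  list(out = array(out, c(dW[1], d[2], d[3])),
       cache = list(K = K, dims = d, k = k, pad = pad))
}

conv1d_backward <- function(dOut, W, cache) {
  d <- cache$dims; dW <- dim(W)
  dm <- matrix(dOut, dW[1])
  gW <- array(dm %*% t(cache$K), dW)
  gb <- rowSums(dm)
  dK <- t(matrix(W, nrow = dW[1])) %*% dm
  dx <- col2im(dK, d[1], d[2], d[3], cache$k, cache$pad)
  list(dx = dx, gW = gW, gb = gb)
}

# Max pooling, width 2, stride 2 (ties keep the first element).
maxpool2_forward <- function(x) {
  d <- dim(x)
  xo <- x[, seq(1, d[2], by = 2), , drop = FALSE]
  xe <- x[, seq(2, d[2], by = 2), , drop = FALSE]
  mask <- xo >= xe
  list(out = pmax(xo, xe), cache = list(mask = mask, dims = d))
}

maxpool2_backward <- function(dOut, cache) {
  d <- cache$dims
  dx <- array(0, d)
  dx[, seq(1, d[2], by = 2), ] <- dOut * cache$mask
  dx[, seq(2, d[2], by = 2), ] <- dOut * !cache$mask
  dx
}

# Transposed 1-D convolution, kernel 2, stride 2 (doubles the length).
# W: (C_in, C_out, 2); b: C_out. out[2(l-1)+t] = t(W[,,t]) %*% x[,l] + b.
upconv2_forward <- function(x, W, b) {
  d <- dim(x)
  Cin <- d[1]; L <- d[2]; N <- d[3]; Cout <- dim(W)[2]
  xm <- matrix(x, Cin)
  o1 <- t(W[, , 1]) %*% xm + b
  o2 <- t(W[, , 2]) %*% xm + b
  out <- array(0, c(Cout, 2 * L, N))
  out[, seq(1, 2 * L, by = 2), ] <- o1
  out[, seq(2, 2 * L, by = 2), ] <- o2
  list(out = out, cache = list(xm = xm, dims = d))
}

upconv2_backward <- function(dOut, W, cache) {
  d <- cache$dims
  Cin <- d[1]; L <- d[2]; N <- d[3]
  d1 <- matrix(dOut[, seq(1, 2 * L, by = 2), ], ncol = L * N)
  d2 <- matrix(dOut[, seq(2, 2 * L, by = 2), ], ncol = L * N)
  gW <- array(0, dim(W))
  gW[, , 1] <- cache$xm %*% t(d1)
  gW[, , 2] <- cache$xm %*% t(d2)
  gb <- rowSums(d1) + rowSums(d2)
  dx <- array(W[, , 1] %*% d1 + W[, , 2] %*% d2, d)
  list(dx = dx, gW = gW, gb = gb)
}

# Dense layer on flattened input. W: (n_out, n_in); b: n_out.
dense_forward <- function(x, W, b) {
  list(out = W %*% x + b, cache = list(x = x))
}

dense_backward <- function(dOut, W, cache) {
  list(dx = t(W) %*% dOut, gW = dOut %*% t(cache$x), gb = rowSums(dOut))
}

relu_forward <- function(x) list(out = x * (x > 0), cache = x > 0)
relu_backward <- function(dOut, cache) dOut * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

## --- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(mW = array(0, dim(p$W) %||% length(p$W)),
                                  vW = array(0, dim(p$W) %||% length(p$W)),
                                  mb = numeric(length(p$b)),
                                  vb = numeric(length(p$b))))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$gW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$gb
    s$vb <- beta2 * s$vb + (1 - beta2) * g$gb^2
    mW_hat <- s$mW / (1 - beta1^t)
    vW_hat <- s$vW / (1 - beta2^t)
    mb_hat <- s$mb / (1 - beta1^t)
    vb_hat <- s$vb / (1 - beta2^t)
    params[[nm]]$W <- params[[nm]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}
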