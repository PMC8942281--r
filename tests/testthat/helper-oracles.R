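# Independent oracles used by both the unit and the acceptance suites.

# Brute-force pairwise concordance (Mann-Whitney with tie correction).
auc_concordance <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# O(n^2) FPT oracle: full distance matrix and a step-by-step circle-exit
# scan with linear interpolation of the crossing time.
fpt_oracle <- function(tr, radius) {
  n <- nrow(tr)
  D <- outer(seq_len(n), seq_len(n), function(i, j) {
    geosphere::distHaversine(cbind(tr$lon[i], tr$lat[i]),
                             cbind(tr$lon[j], tr$lat[j]), r = 6371000)
  })
  out <- numeric(n)
  for (i in seq_len(n)) {
    cross <- function(idx) {
      d <- D[i, idx]
      j <- NA
      for (k in seq_along(d)) if (d[k] >= radius - 1e-9) { j <- k; break }
      if (is.na(j)) return(tr$t[idx[length(idx)]])
      frac <- (radius - d[j - 1]) / (d[j] - d[j - 1])
      tr$t[idx[j - 1]] + frac * (tr$t[idx[j]] - tr$t[idx[j - 1]])
    }
    out[i] <- cross(i:n) - cross(i:1)
  }
  out
}

# Exhaustive-enumeration posterior for a small HMM observation sequence.
hmm_posterior_oracle <- function(obs, spec) {
  K <- spec$n_states
  T_ <- length(obs$step)
  le <- divetrace:::hmm_log_emissions(obs, spec)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  jp <- apply(seqs, 1, function(s) {
    lp <- log(spec$delta[s[1]]) + le[1, s[1]]
    for (t in 2:T_) lp <- lp + log(spec$tpm[s[t - 1], s[t]]) + le[t, s[t]]
    exp(lp)
  })
  post <- matrix(0, T_, K)
  for (t in seq_len(T_)) {
    for (k in seq_len(K)) post[t, k] <- sum(jp[seqs[, t] == k])
  }
  post / rowSums(post)
}
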