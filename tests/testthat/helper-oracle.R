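# Independent oracles used across tests.

# Data-augmented CJS likelihood of one capture history by exhaustive
# enumeration over all latent alive/dead state sequences. The individual is
# alive at its first capture; a dead individual stays dead; detection
# requires being alive. This is the brute-force counterpart of the
# marginalized chi-recursion likelihood and must agree with it exactly.
oracle_history_likelihood <- function(history, phi, p) {
  T <- length(history)
  f <- which(history == 1L)[1]
  if (f == T) return(1)
  n_free <- T - f
  total <- 0
  for (code in 0:(2^n_free - 1)) {
    z <- c(rep(NA, f - 1), 1L,
           as.integer(intToBits(code))[seq_len(n_free)])
    pr <- 1
    for (t in f:(T - 1)) {
      pr <- pr * if (z[t] == 1L) {
        if (z[t + 1] == 1L) phi[t] else (1 - phi[t])
      } else {
        if (z[t + 1] == 1L) 0 else 1   # dead stays dead
      }
      # observation at occasion t + 1 (p indexed occasions 2..T)
      pr <- pr * if (z[t + 1] == 1L) {
        if (history[t + 1] == 1L) p[t] else (1 - p[t])
      } else {
        if (history[t + 1] == 1L) 0 else 1
      }
      if (pr == 0) break
    }
    total <- total + pr
  }
  total
}

# All 2^(T-f) possible post-first-capture histories for completeness checks.
all_histories_from <- function(T, f) {
  n_free <- T - f
  out <- list()
  for (code in 0:(2^n_free - 1)) {
    h <- integer(T)
    h[f] <- 1L
    if (n_free > 0)
      h[(f + 1):T] <- as.integer(intToBits(code))[seq_len(n_free)]
    out[[code + 1]] <- h
  }
  out
}

# Pearson p-value by permutation: fraction of |r| under random permutation
# of one series at least as large as observed.
oracle_permutation_p <- function(a, b, n_perm = 10000) {
  r_obs <- abs(cor(a, b))
  hits <- 0
  for (k in seq_len(n_perm))
    if (abs(cor(a, sample(b))) >= r_obs) hits <- hits + 1
  hits / n_perm
}
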