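# Independent oracles used across the suite. These deliberately avoid the
# package's estimator code paths: entropies come from table()-based
# histograms and closed forms.

# Shannon entropy (bits) of a sample by direct histogram summation.
hist_entropy <- function(samples) {
  p <- as.numeric(table(samples)) / length(samples)
  -sum(p * log2(p))
}

# Conditional mutual information I(X; Y | V) in bits by exhaustive histogram
# over the observed (x, y, v) triples.
brute_cmi <- function(x, y, v) {
  key_v <- as.character(v)
  total <- length(x)
  out <- 0
  for (vv in unique(key_v)) {
    idx <- key_v == vv
    pv <- sum(idx) / total
    xj <- x[idx]; yj <- y[idx]
    tab <- table(xj, yj) / sum(idx)
    px <- rowSums(tab); py <- colSums(tab)
    for (a in rownames(tab)) for (b in colnames(tab)) {
      pxy <- tab[a, b]
      if (pxy > 0) out <- out + pv * pxy * log2(pxy / (px[[a]] * py[[b]]))
    }
  }
  out
}

bernoulli_entropy <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

# A deterministic lagged-copy pair: x[n] = y[n - lag], y i.i.d. fair bits.
copy_pair <- function(n, lag, seed = 1) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.5)
    x <- c(rep(0L, lag), y[seq_len(n - lag)])
    list(x = as.integer(x), y = as.integer(y))
  })
}
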