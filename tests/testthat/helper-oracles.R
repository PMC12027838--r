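# Independent brute-force oracles used to validate the vectorized
# implementations.  These deliberately use explicit loops and no shared code
# with the package internals.

# InfoNCE by explicit enumeration of the denominator
clp_oracle <- function(anchor, positive, negatives, tau) {
  cosv <- function(a, b) {
    s <- 0; na <- 0; nb <- 0
    for (i in seq_along(a)) {
      s <- s + a[i] * b[i]; na <- na + a[i]^2; nb <- nb + b[i]^2
    }
    s / (sqrt(na) * sqrt(nb))
  }
  num <- exp(cosv(anchor, positive) / tau)
  den <- num
  for (z in negatives) den <- den + exp(cosv(anchor, z) / tau)
  -log(num / den)
}

# naive cross-entropy by summation over the one-hot indicator
ce_oracle <- function(probs, label) {
  y <- rep(0, length(probs))
  y[label + 1] <- 1
  s <- 0
  for (i in seq_along(probs)) if (y[i] > 0) s <- s - y[i] * log(probs[i])
  s
}

# SSIM by explicit sliding windows with Gaussian weights
ssim_oracle <- function(a, b, size = 11, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  C1 <- 0.01^2; C2 <- 0.03^2
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (i in 1:(H - size + 1))
    for (j in 1:(W - size + 1)) {
      wa <- a[i:(i + size - 1), j:(j + size - 1)]
      wb <- b[i:(i + size - 1), j:(j + size - 1)]
      mua <- sum(w * wa); mub <- sum(w * wb)
      va <- sum(w * wa^2) - mua^2
      vb <- sum(w * wb^2) - mub^2
      vab <- sum(w * wa * wb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + C1) * (2 * vab + C2)) /
                  ((mua^2 + mub^2 + C1) * (va + vb + C2)))
    }
  mean(vals)
}

# group separation by explicit double loops
latent_distance_oracle <- function(groups) {
  cents <- lapply(groups, function(g) colMeans(g))
  between <- c()
  for (i in seq_along(groups))
    for (j in seq_along(groups))
      if (j > i) between <- c(between,
                              sqrt(sum((cents[[i]] - cents[[j]])^2)))
  within <- c()
  for (i in seq_along(groups)) {
    d <- 0
    for (r in seq_len(nrow(groups[[i]])))
      d <- d + sqrt(sum((groups[[i]][r, ] - cents[[i]])^2))
    within <- c(within, d / nrow(groups[[i]]))
  }
  list(between = mean(between), within = mean(within))
}

# energy fraction in the lowest 1/8 of spatial frequencies
lowfreq_fraction <- function(delta) {
  n <- nrow(delta)
  S <- Mod(stats::fft(delta))^2
  sh <- c((n / 2 + 1):n, 1:(n / 2))
  Sc <- S[sh, sh]
  cy <- n / 2 + 1
  d <- sqrt(outer((1:n - cy)^2, (1:n - cy)^2, "+"))
  sum(Sc[d <= n / 8]) / sum(Sc)
}
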