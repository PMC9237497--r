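# Independent numeric oracles used across the suite.

# Studentized range CDF by direct numerical integration:
# P(Q <= q) = int_0^inf f_S(s) * k * int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds
# where S = sqrt(chi2_df / df). Entirely independent of stats::ptukey.
ptukey_num <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z) k * dnorm(z) * (pnorm(z) - pnorm(z - q * s))^(k - 1)
    integrate(f, -8, 8, rel.tol = 1e-10)$value
  }
  ln_c <- (df / 2) * log(df) - (df / 2 - 1) * log(2) - lgamma(df / 2)
  f_s <- function(s) exp(ln_c + (df - 1) * log(s) - df * s^2 / 2)
  integrate(function(s) vapply(s, function(si) f_s(si) * inner(si), 0),
            1e-6, 10, rel.tol = 1e-9)$value
}

qtukey_num <- function(p, k, df) {
  uniroot(function(q) ptukey_num(q, k, df) - p,
          interval = c(0.01, 50), tol = 1e-8)$root
}

# Brute-force Duncan letter-sharing relation: two sorted positions share
# iff SOME contiguous span containing both has range <= LSR(span width).
duncan_sharing_oracle <- function(means, lsr) {
  ord <- order(-means, names(means))
  ms <- means[ord]
  m <- length(ms)
  share <- matrix(FALSE, m, m, dimnames = list(names(ms), names(ms)))
  diag(share) <- TRUE
  if (m >= 2) {
    for (a in seq_len(m - 1)) {
      for (b in seq((a + 1), m)) {
        width <- b - a + 1
        if (ms[a] - ms[b] <= lsr[width - 1]) share[a:b, a:b] <- TRUE
      }
    }
  }
  share
}

# Power iteration with deflation: independent eigensolver for symmetric
# positive semi-definite matrices.
power_eigen <- function(s, tol = 1e-12, max_iter = 10000) {
  p <- ncol(s)
  vals <- numeric(p)
  vecs <- matrix(0, p, p)
  a <- s
  for (j in seq_len(p)) {
    v <- rep(1 / sqrt(p), p)
    lam <- 0
    for (i in seq_len(max_iter)) {
      w <- a %*% v
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      v_new <- as.vector(w / nw)
      if (sum(abs(v_new - v)) < tol || sum(abs(v_new + v)) < tol) {
        v <- v_new
        break
      }
      v <- v_new
    }
    lam <- as.numeric(t(v) %*% a %*% v)
    vals[j] <- lam
    vecs[, j] <- v
    a <- a - lam * tcrossprod(v)
  }
  list(values = vals, vectors = vecs)
}
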