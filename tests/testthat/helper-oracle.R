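# Shared test utilities: small parameter sets and independent oracles.

# A small, fast, well-behaved parameter set (f = 0.1, eta = 10, adder).
small_params <- function(N = 30, N0 = round(0.4 * N), beta = 0, kappa = 2,
                         d = 1, alpha0 = 1, alpha1 = 1, rho = 10, B = 1,
                         mean_volume = 1, mean_number = 100) {
  model_params(g = log(2) * 0.1, rho = rho, kappa = kappa, B = B,
               beta = beta, d = d, N = N, N0 = N0,
               alpha0 = alpha0, alpha1 = alpha1, a = 1,
               mean_volume = mean_volume, mean_number = mean_number)
}

# Direct stationary solve of the truncated reduced-model master equation:
# states (k, n) with n <= nmax; returns the N x (nmax+1) probability matrix.
# Independent of the moment recursion (dense linear solve on the generator).
me_stationary <- function(prof, d, nmax) {
  N <- length(prof$v)
  S <- N * (nmax + 1)
  id <- function(k, n) (k - 1) * (nmax + 1) + n + 1
  A <- matrix(0, S, S) # generator transpose: A[to, from]
  for (k in 1:N) {
    Bk <- prof$Bk[k]
    for (n in 0:nmax) {
      i <- id(k, n)
      if (n < nmax) {
        ms <- 1:(nmax - n)
        rates <- prof$rhok[k] * (Bk / (Bk + 1))^ms * (1 / (Bk + 1))
        A[id(k, n + ms), i] <- A[id(k, n + ms), i] + rates
        A[i, i] <- A[i, i] - sum(rates)
      }
      if (n > 0) {
        A[id(k, n - 1), i] <- A[id(k, n - 1), i] + n * d
        A[i, i] <- A[i, i] - n * d
      }
      if (k < N) {
        A[id(k + 1, n), i] <- A[id(k + 1, n), i] + prof$q[k]
      } else {
        A[id(1, 0:n), i] <- A[id(1, 0:n), i] + prof$q[N] * dbinom(0:n, n, 0.5)
      }
      if (k == N) A[i, i] <- A[i, i] - prof$q[N]
      else if (k < N) A[i, i] <- A[i, i] - prof$q[k]
    }
  }
  A[S, ] <- 1
  p <- solve(A, c(rep(0, S - 1), 1))
  matrix(p, nrow = N, byrow = TRUE)
}

# Standard error of the mean for (possibly autocorrelated) samples via
# block means.
block_sem <- function(x, nblocks = 20) {
  n <- length(x)
  b <- floor(n / nblocks)
  means <- vapply(seq_len(nblocks), function(i) mean(x[((i - 1) * b + 1):(i * b)]), 0)
  sd(means) / sqrt(nblocks)
}
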