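# Analytic autocorrelation and power spectrum of concentration
# fluctuations along a lineage, and the oscillation-onset prefactor.

# Eigen-expansion of the autocorrelation:
#   R(t) = (m1+m2) V^-1 e^{W11 t} V^-1 1 - (m1 V^-1 1)^2
#          + int_0^t m1 V^-1 e^{W00 s} S Tmat e^{W11 (t-s)} V^-1 1 ds.
# With W11 = P diag(lambda) P^-1 and W00 = Q diag(nu) Q^-1 every term is a
# combination of e^{lambda t}, e^{nu t} and (for confluent eigenvalue
# pairs) t e^{lambda t}, so both R(t) and its Fourier transform have exact
# closed forms (a weighted sum of Lorentzians).
spectral_terms <- function(moments, profile, d = moments$d) {
  m0 <- moments$m[[1]]; m1 <- moments$m[[2]]; m2 <- moments$m[[3]]
  q <- profile$q
  N <- length(q)
  W11 <- moment_matrix(1, q, d)
  W00 <- moment_matrix(0, q, d)
  vin <- 1 / profile$v
  K <- profile$rhok * profile$Bk             # diagonal of S Tmat

  eA <- eigen(W11); lam <- eA$values; P <- eA$vectors; Pinv <- solve(P)
  eQ <- eigen(W00); nu <- eQ$values; Q <- eQ$vectors; Qinv <- solve(Q)

  u <- (m1 + m2) * vin
  h <- vin
  mu_c <- sum(m1 * vin)

  cA <- as.vector(u %*% P) * as.vector(Pinv %*% h)   # coeff of e^{lambda_i t}
  aj <- as.vector((m1 * vin) %*% Q)
  bi <- as.vector(Pinv %*% h)
  M <- Qinv %*% (K * P)                               # rows: j, cols: i
  D <- (aj * M) * rep(bi, each = N)                   # D[j, i]

  scale <- max(abs(lam))
  conf_lambda <- complex(0); conf_coef <- complex(0)
  coefA <- cA
  coefQ <- rep(0 + 0i, N)
  for (j in seq_len(N)) {
    for (i in seq_len(N)) {
      dji <- D[j, i]
      if (dji == 0) next
      del <- nu[j] - lam[i]
      if (abs(del) < 1e-9 * scale) {
        conf_lambda <- c(conf_lambda, lam[i])
        conf_coef <- c(conf_coef, dji)
      } else {
        coefQ[j] <- coefQ[j] + dji / del
        coefA[i] <- coefA[i] - dji / del
      }
    }
  }
  # W00's stationary zero mode contributes a constant, which must cancel
  # the squared mean; fold both into c0 and keep only decaying terms.
  zero <- abs(nu) < 1e-9 * scale
  c0 <- sum(coefQ[zero]) - mu_c^2
  lambdas <- c(lam, nu[!zero])
  coefs <- c(coefA, coefQ[!zero])
  keep <- coefs != 0
  list(lambda = lambdas[keep], coef = coefs[keep],
       conf_lambda = conf_lambda, conf_coef = conf_coef,
       c0 = c0, mu = mu_c,
       R0 = Re(sum(coefs[keep]) + c0))
}

#' Analytic autocorrelation of concentration fluctuations
#'
#' Evaluates the stationary autocovariance `R(t)` of the concentration
#' along a lineage of the reduced model, via the eigen-expansion of the
#' moment-recursion matrices.  `R(0)` equals the stationary concentration
#' variance; `R(t) -> 0` as `t -> Inf`.
#'
#' @param moments an `"scc_moments"` object with `lmax >= 2`.
#' @param profile the matching `"scc_profile"`.
#' @param tgrid times at which to evaluate (non-negative).
#' @param d degradation rate (defaults to the one used for the moments).
#' @return Numeric vector `R(tgrid)`.
#' @export
autocorrelation <- function(moments, profile = moments$profile,
                            tgrid, d = moments$d) {
  st <- spectral_terms(moments, profile, d)
  vapply(tgrid, function(t) {
    val <- sum(st$coef * exp(st$lambda * t)) +
      sum(st$conf_coef * t * exp(st$conf_lambda * t)) + st$c0
    Re(val)
  }, 0)
}

#' Analytic power spectrum of concentration fluctuations
#'
#' Fourier transform `G(xi) = int R(|t|) e^{-2 pi i xi t} dt` of the
#' analytic autocorrelation, computed term by term from the eigen-expansion
#' (a weighted sum of Lorentzians), and normalized so that `G(0) = 1`.
#'
#' @param moments an `"scc_moments"` object with `lmax >= 2`.
#' @param profile the matching `"scc_profile"`.
#' @param freq frequency grid; defaults to 2048 points on `[0, 4f]` where
#'   `f` is the cell cycle frequency.
#' @param d degradation rate.
#' @param normalize if `TRUE` (default) divide by the zero-frequency power.
#' @return An `"scc_spectrum"` list with `freq`, `G`, the unnormalized
#'   zero-frequency power `G0`, the stationary variance `R0`, the peak
#'   height `H` and `peak_freq` (see [peak_height()]).
#' @export
power_spectrum <- function(moments, profile = moments$profile,
                           freq = NULL, d = moments$d, normalize = TRUE) {
  p <- profile$params
  f <- p$g / log(2)
  if (is.null(freq)) freq <- seq(0, 4 * f, length.out = 2048)
  st <- spectral_terms(moments, profile, d)
  G <- vapply(freq, function(xi) {
    iw <- 2i * pi * xi
    val <- sum(st$coef * (-1 / (st$lambda - iw)))
    if (length(st$conf_coef))
      val <- val + sum(st$conf_coef / (st$conf_lambda - iw)^2)
    2 * Re(val)
  }, 0)
  G0 <- 2 * Re(sum(st$coef * (-1 / st$lambda)))
  if (normalize) G <- G / G0
  spec <- structure(list(freq = freq, G = G, G0 = G0, R0 = st$R0, f = f),
                    class = "scc_spectrum")
  pk <- peak_height(spec, f)
  spec$H <- pk$H
  spec$peak_freq <- pk$peak_freq
  spec
}

#' @export
print.scc_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum on [%.4g, %.4g]; G(0) power %.6g\n",
              min(x$freq), max(x$freq), x$G0))
  if (!is.null(x$H))
    cat(sprintf("  off-zero peak height H = %.4g%s\n", x$H,
                if (x$H > 0) sprintf(" at xi = %.4g (f = %.4g)",
                                     x$peak_freq, x$f) else ""))
  invisible(x)
}

#' Off-zero peak height of a normalized spectrum
#'
#' `H` is the excess of the normalized spectrum above the zero-frequency
#' power within the fundamental band around the cell cycle frequency
#' (default `[0.3 f, 1.7 f]`), floored at zero.  A monotonically decreasing
#' spectrum has `H = 0`; a large `H` indicates regular division-induced
#' concentration oscillations.  The first-harmonic band `[1.7f, 2.7f]` is
#' reported separately as `H2`.
#'
#' @param spec an `"scc_spectrum"` (normalized), or a list with `freq` and
#'   `G`.
#' @param f cell cycle frequency.
#' @param band fundamental search band as multiples of `f`.
#' @return List with `H`, `peak_freq` (NA when `H = 0`), and `H2`.
#' @export
peak_height <- function(spec, f = spec$f, band = c(0.3, 1.7)) {
  sel <- spec$freq >= band[1] * f & spec$freq <= band[2] * f
  H <- 0; peak_freq <- NA_real_
  if (any(sel)) {
    i <- which.max(spec$G[sel])
    H <- max(spec$G[sel][i] - 1, 0)
    if (H > 0) peak_freq <- spec$freq[sel][i]
  }
  sel2 <- spec$freq >= 1.7 * f & spec$freq <= 2.7 * f
  H2 <- if (any(sel2)) max(max(spec$G[sel2]) - 1, 0) else 0
  list(H = H, peak_freq = peak_freq, H2 = H2)
}

#' Oscillation-regularity prefactor C(beta, kappa, w)
#'
#' The height of the off-zero spectral peak is proportional to `N^2` and to
#' \deqn{C(\beta,\kappa,w) = |1 - \kappa 2^{\beta-1}
#'   + (\kappa - 1) 2^{(\beta-1)w} e^{2\pi w i}|^2.}
#' `C = 0` is necessary for the spectrum to lack an off-zero peak (strong
#' homeostasis): it holds for `beta = kappa = 1` at any `w`, and for
#' `kappa = 2^((1-beta)/2)` with `w = 0.5` when biosynthesis is not
#' balanced.
#'
#' @param beta degree of balanced biosynthesis.
#' @param kappa dosage-compensation factor.
#' @param w replication fraction in (0, 1).
#' @return `C` (non-negative; vectorized over the arguments).
#' @export
oscillation_condition <- function(beta, kappa, w) {
  z <- 1 - kappa * 2^(beta - 1) +
    (kappa - 1) * 2^((beta - 1) * w) * exp(2i * pi * w)
  Mod(z)^2
}
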