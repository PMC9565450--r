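# Factorial-moment recursion of the reduced model and the mixture
# approximations of the stationary lineage/population distributions.

#' Moment-recursion matrix W_ll
#'
#' The stationary factorial moments of the reduced model satisfy
#' `m_l W_ll + sum_{j<l} m_j W_jl = 0`, where `W_ll` has diagonal
#' `-q_k - l*d`, superdiagonal entries `q_k` at `(k, k+1)` and the corner
#' entry `q_N / 2^l` at `(N, 1)` — the factor `1/2^l` encodes binomial
#' partitioning at division.  The cross terms `W_jl = (l!/j!) S Tmat^(l-j)`
#' are diagonal, with `S = diag(rho_k)` and `Tmat = diag(B_k)`.
#'
#' @param l moment order (non-negative integer).
#' @param q vector of stage-exit rates.
#' @param d degradation rate.
#' @return Dense `N x N` matrix `W_ll`.
#' @export
moment_matrix <- function(l, q, d) {
  N <- length(q)
  W <- matrix(0, N, N)
  diag(W) <- -q - l * d
  if (N > 1) W[cbind(seq_len(N - 1), seq_len(N - 1) + 1)] <- q[-N]
  W[N, 1] <- W[N, 1] + q[N] / 2^l
  W
}

#' Stage-occupancy distribution
#'
#' The stationary probability of finding the (lineage-tracked) cell in
#' stage `k` is `m0k = (1/q_k) / sum_i (1/q_i)`: occupancy is proportional
#' to the typical stage duration.
#'
#' @param profile an `"scc_profile"` object (or a plain vector of rates).
#' @return Vector of `N` probabilities summing to one.
#' @export
stage_occupancy <- function(profile) {
  q <- if (inherits(profile, "scc_profile")) profile$q else profile
  w <- 1 / q
  w / sum(w)
}

#' Unnormalized factorial moments of the reduced model
#'
#' Solves the stationary moment recursion
#' `m_l = -(sum_{j<l} m_j W_jl) W_ll^{-1}` for `l = 1, ..., lmax`, starting
#' from the closed-form occupancy `m_0`.  Each step is one linear solve
#' (never an explicit inverse); `W_ll` is nonsingular for all `d >= 0`
#' because the corner factor `1/2^l` breaks the zero row-sum structure for
#' `l >= 1`.
#'
#' @param profile an `"scc_profile"` object.
#' @param d degradation rate; defaults to the profile's.
#' @param lmax highest moment order (>= 1; 2 is enough for means,
#'   variances, spectra).
#' @return An `"scc_moments"` list whose element `m` holds the row vectors
#'   `m_0 ... m_lmax` (as `m[[l+1]]`), plus the residual of each stationary
#'   equation.
#' @export
factorial_moments <- function(profile, d = profile$params$d, lmax = 2) {
  stopifnot(lmax >= 1)
  q <- profile$q
  N <- length(q)
  S <- profile$rhok
  Bk <- profile$Bk
  m <- vector("list", lmax + 1)
  m[[1]] <- stage_occupancy(profile)
  for (l in seq_len(lmax)) {
    rhs <- numeric(N)
    for (j in 0:(l - 1)) {
      # W_jl = (l!/j!) S Tmat^(l-j), diagonal
      rhs <- rhs + m[[j + 1]] * (factorial(l) / factorial(j)) * S * Bk^(l - j)
    }
    Wll <- moment_matrix(l, q, d)
    m[[l + 1]] <- as.vector(solve(t(Wll), -rhs))
  }
  resid <- vapply(seq_len(lmax), function(l) {
    rhs <- numeric(N)
    for (j in 0:(l - 1))
      rhs <- rhs + m[[j + 1]] * (factorial(l) / factorial(j)) * S * Bk^(l - j)
    max(abs(m[[l + 1]] %*% moment_matrix(l, q, d) + rhs))
  }, 0)
  structure(list(m = m, lmax = lmax, d = d, residual = resid,
                 profile = profile),
            class = "scc_moments")
}

#' Per-stage concentration and copy-number statistics
#'
#' From the factorial moments, the conditional copy-number mean and
#' variance at stage `k` are `mu_n_k = m1k/m0k` and
#' `sigma2_n_k = (m1k + m2k)/m0k - mu_n_k^2`; dividing by the typical stage
#' volume gives the concentration statistics `mu_k = m1k/(m0k v_k)` and
#' `sigma2_k = (m1k + m2k)/(m0k v_k^2) - mu_k^2`.
#'
#' @param moments an `"scc_moments"` object with `lmax >= 2`.
#' @param profile the profile the moments were computed from (defaults to
#'   the one stored in `moments`).
#' @return An `"scc_stats"` list with `mu`, `sigma2` (concentration),
#'   `mu_n`, `sigma2_n` (copy number) and `occupancy`.
#' @export
stage_stats <- function(moments, profile = moments$profile) {
  stopifnot(moments$lmax >= 2)
  m0 <- moments$m[[1]]; m1 <- moments$m[[2]]; m2 <- moments$m[[3]]
  v <- profile$v
  mu_n <- m1 / m0
  sigma2_n <- (m1 + m2) / m0 - mu_n^2
  mu <- mu_n / v
  sigma2 <- (m1 + m2) / (m0 * v^2) - mu^2
  tol <- -1e-8 * max(sigma2_n, 1)
  if (any(sigma2_n < tol) || any(sigma2 < -1e-8 * max(sigma2, 1)))
    stop("negative stage variance beyond round-off; moment recursion inconsistent")
  structure(list(mu = mu, sigma2 = pmax(sigma2, 0),
                 mu_n = mu_n, sigma2_n = pmax(sigma2_n, 0),
                 occupancy = m0, v = v),
            class = "scc_stats")
}

# ---- mixture distributions -----------------------------------------------

new_mixture <- function(kind, weights, par1, par2, component_kind = NULL) {
  stopifnot(length(weights) == length(par1), length(par1) == length(par2))
  w <- weights / sum(weights)
  if (is.null(component_kind)) component_kind <- rep(kind, length(w))
  structure(list(kind = kind, weights = w, par1 = par1, par2 = par2,
                 component_kind = component_kind),
            class = "scc_mixture")
}

#' @export
print.scc_mixture <- function(x, ...) {
  cat(sprintf("%s mixture with %d components\n", x$kind, length(x$weights)))
  invisible(x)
}

#' Approximate lineage concentration distribution (gamma mixture)
#'
#' At each stage the concentration is approximated by a gamma distribution
#' matched to the stage mean and variance (shape `mu_k^2/sigma2_k`, rate
#' `mu_k/sigma2_k`); the lineage distribution is the occupancy-weighted
#' mixture.  A component with vanishing variance degenerates to a point
#' mass at `mu_k`, represented by a very narrow gamma so densities remain
#' defined on a grid.
#'
#' @param stats an `"scc_stats"` object.
#' @param weights mixture weights; defaults to the stage occupancies
#'   (lineage statistics).  Pass population proportions `pi_k` from
#'   [population_weights()] for population snapshots.
#' @return An `"scc_mixture"` of kind `"gamma"` (fields `par1` = shape,
#'   `par2` = rate).
#' @export
lineage_concentration_distribution <- function(stats,
                                               weights = stats$occupancy) {
  mu <- stats$mu; s2 <- stats$sigma2
  degen <- s2 <= 0 | (s2 / pmax(mu^2, .Machine$double.xmin)) < 1e-14
  s2[degen] <- (1e-6 * mu[degen])^2
  new_mixture("gamma", weights, shape <- mu^2 / s2, rate <- mu / s2)
}

#' Approximate lineage copy-number distribution (negative-binomial mixture)
#'
#' At each stage the copy number is approximated by a negative binomial
#' with `size = mu_n^2/(sigma2_n - mu_n)` and success probability
#' `mu_n/sigma2_n`; components at the Poisson boundary
#' (`sigma2_n <= mu_n`) are replaced by Poisson(`mu_n`), the limiting case.
#' Strict underdispersion beyond round-off is an error: the bursty model
#' cannot produce it.
#'
#' @inheritParams lineage_concentration_distribution
#' @return An `"scc_mixture"` of kind `"nbinom"` (fields `par1` = size,
#'   `par2` = prob; Poisson components carry the mean in `par1`).
#' @export
lineage_number_distribution <- function(stats, weights = stats$occupancy) {
  mu <- stats$mu_n; s2 <- stats$sigma2_n
  under <- s2 < mu * (1 - 1e-9)
  if (any(under))
    stop("underdispersed copy-number component (sigma2 < mu) at stage ",
         which(under)[1], "; numerical failure upstream")
  pois <- s2 <= mu * (1 + 1e-9)
  size <- ifelse(pois, mu, mu^2 / (s2 - mu))
  prob <- ifelse(pois, NA_real_, mu / s2)
  kindv <- ifelse(pois, "poisson", "nbinom")
  new_mixture("nbinom", weights, size, prob, component_kind = kindv)
}

#' Mixture density / probability mass
#'
#' @param mix an `"scc_mixture"`.
#' @param x evaluation points (concentrations, or non-negative integers for
#'   copy-number mixtures).
#' @return Vector of densities (gamma mixtures) or probabilities (count
#'   mixtures).
#' @export
dmixture <- function(mix, x) {
  out <- numeric(length(x))
  for (i in seq_along(mix$weights)) {
    out <- out + mix$weights[i] * switch(
      mix$component_kind[i],
      gamma   = dgamma(x, shape = mix$par1[i], rate = mix$par2[i]),
      nbinom  = dnbinom(x, size = mix$par1[i], prob = mix$par2[i]),
      poisson = dpois(x, lambda = mix$par1[i]))
  }
  out
}

#' Mixture cumulative distribution function
#' @inheritParams dmixture
#' @export
pmixture <- function(mix, x) {
  out <- numeric(length(x))
  for (i in seq_along(mix$weights)) {
    out <- out + mix$weights[i] * switch(
      mix$component_kind[i],
      gamma   = pgamma(x, shape = mix$par1[i], rate = mix$par2[i]),
      nbinom  = pnbinom(x, size = mix$par1[i], prob = mix$par2[i]),
      poisson = ppois(x, lambda = mix$par1[i]))
  }
  out
}

#' Sample from a mixture
#' @param mix an `"scc_mixture"`.
#' @param n number of draws.
#' @export
rmixture <- function(mix, n) {
  comp <- sample.int(length(mix$weights), n, replace = TRUE,
                     prob = mix$weights)
  out <- numeric(n)
  for (i in unique(comp)) {
    idx <- comp == i
    out[idx] <- switch(
      mix$component_kind[i],
      gamma   = rgamma(sum(idx), shape = mix$par1[i], rate = mix$par2[i]),
      nbinom  = rnbinom(sum(idx), size = mix$par1[i], prob = mix$par2[i]),
      poisson = rpois(sum(idx), lambda = mix$par1[i]))
  }
  out
}

#' Default evaluation grid for a mixture
#'
#' Concentration mixtures are evaluated on `[0, mean + 10 sd]` with
#' `npts` points; count mixtures on `0:nmax` where `nmax` covers the
#' `1 - 1e-10` quantile.
#'
#' @param mix an `"scc_mixture"`.
#' @param npts grid size for continuous mixtures.
#' @return Numeric vector of evaluation points.
#' @export
mixture_grid <- function(mix, npts = 2048) {
  if (mix$kind == "gamma") {
    m1 <- sum(mix$weights * mix$par1 / mix$par2)
    m2 <- sum(mix$weights * (mix$par1 * (mix$par1 + 1) / mix$par2^2))
    s <- sqrt(max(m2 - m1^2, 0))
    seq(0, m1 + 10 * s, length.out = npts)
  } else {
    nmax <- max(vapply(seq_along(mix$weights), function(i) {
      switch(mix$component_kind[i],
             nbinom  = qnbinom(1 - 1e-10, size = mix$par1[i], prob = mix$par2[i]),
             poisson = qpois(1 - 1e-10, lambda = mix$par1[i]))
    }, 0))
    0:nmax
  }
}

# ---- population statistics -----------------------------------------------

#' Population growth exponent and stage proportions
#'
#' In an exponentially growing population the number of cells grows like
#' `e^(J t)`, where `J` is the unique positive root of
#' `(q_1 + J)(q_2 + J)...(q_N + J) = 2 q_1 q_2 ... q_N`, and the proportion
#' of cells in stage `k` is
#' `pi_k \propto (q_(k+1) + J)...(q_N + J) / (q_k ... q_(N-1))` —
#' young stages are overrepresented relative to lineage occupancies.
#'
#' @param profile an `"scc_profile"` (or vector of stage-exit rates).
#' @return An `"scc_popweights"` list with `J` and `pi`.
#' @export
population_weights <- function(profile) {
  q <- if (inherits(profile, "scc_profile")) profile$q else profile
  N <- length(q)
  gfun <- function(J) sum(log1p(J / q)) - log(2)
  if (N == 1) {
    J <- q[1]
  } else {
    hi <- (2^(1 / N) - 1) * max(q)
    J <- uniroot(gfun, c(0, hi * (1 + 1e-12)), tol = 1e-15 * hi)$root
  }
  # log pi_k (unnormalized): sum_{i>k} log(q_i + J) - sum_{i=k}^{N-1} log q_i
  lq <- log(q); lqJ <- log(q + J)
  logpi <- numeric(N)
  for (k in seq_len(N)) {
    tail_qJ <- if (k < N) sum(lqJ[(k + 1):N]) else 0
    tail_q <- if (k <= N - 1) sum(lq[k:(N - 1)]) else 0
    logpi[k] <- tail_qJ - tail_q
  }
  pi <- exp(logpi - max(logpi))
  structure(list(J = J, pi = pi / sum(pi)), class = "scc_popweights")
}

#' Population copy-number and concentration distributions
#'
#' Same mixture components as the lineage approximations, but weighted by
#' the population stage proportions `pi_k` instead of the lineage
#' occupancies.
#'
#' @param stats an `"scc_stats"` object.
#' @param weights an `"scc_popweights"` object from [population_weights()].
#' @return List with elements `concentration` and `number`
#'   (`"scc_mixture"` objects).
#' @export
population_distributions <- function(stats, weights) {
  list(concentration = lineage_concentration_distribution(stats, weights$pi),
       number = lineage_number_distribution(stats, weights$pi))
}
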