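# Concentration-homeostasis metrics: noise decomposition, the
# dosage-compensation balance condition, gamma approximation of the
# concentration distribution, Hellinger distances, and modality counting.

#' Decompose concentration noise into cell-cycle and intrinsic parts
#'
#' The overall lineage mean and variance of concentration are
#' `<c> = sum_k mu_k m0k` and
#' `sigma^2 = sum_k (sigma2_k + mu_k^2) m0k - <c>^2`.  The total noise
#' `phi = sigma^2/<c>^2` decomposes exactly as `phi = phi_ext + phi_int`,
#' where `phi_ext` is the CV^2 of the stage means `mu_k` under the
#' occupancy weights (fluctuations between cell cycle positions) and
#' `phi_int` is the occupancy-weighted mean of `sigma2_k` over `<c>^2`
#' (bursty synthesis and degradation within a stage).  The accuracy of
#' homeostasis is `gamma = phi_ext / phi`: zero for perfect homeostasis,
#' close to one when cell cycle effects dominate.
#'
#' @param stats an `"scc_stats"` object (or any list with `mu`, `sigma2`,
#'   `occupancy`).
#' @return An `"scc_homeostasis"` list with `mean_c`, `var_c`, `phi`,
#'   `phi_ext`, `phi_int`, `gamma`.
#' @export
noise_decomposition <- function(stats) {
  m0 <- stats$occupancy; mu <- stats$mu; s2 <- stats$sigma2
  mean_c <- sum(mu * m0)
  if (mean_c <= 0) stop("mean concentration is zero; noise metrics undefined")
  var_c <- sum((s2 + mu^2) * m0) - mean_c^2
  phi_ext <- (sum(mu^2 * m0) - mean_c^2) / mean_c^2
  phi_int <- sum(s2 * m0) / mean_c^2
  phi <- phi_ext + phi_int
  structure(list(mean_c = mean_c, var_c = var_c, phi = phi,
                 phi_ext = phi_ext, phi_int = phi_int,
                 gamma = if (phi > 0) phi_ext / phi else 0),
            class = "scc_homeostasis")
}

#' @export
print.scc_homeostasis <- function(x, ...) {
  cat(sprintf("Concentration noise: <c> = %.6g, phi = %.4g\n",
              x$mean_c, x$phi))
  cat(sprintf("  phi_ext = %.4g  phi_int = %.4g  gamma = %.4g\n",
              x$phi_ext, x$phi_int, x$gamma))
  if (!is.null(x$D)) cat(sprintf("  Hellinger distance to gamma D = %.4g\n", x$D))
  if (!is.null(x$H)) cat(sprintf("  spectral peak height H = %.4g\n", x$H))
  invisible(x)
}

#' Dosage compensation balancing the mean concentration across replication
#'
#' Requiring the time-averaged mean concentration before and after
#' replication to coincide gives the optimal compensation strength
#' \deqn{\kappa^*(\beta, w) = \frac{(1-w)\,(2^{(\beta-1)w} - 1)}
#'   {w\,(2^{\beta-1} - 2^{(\beta-1)w})},}
#' with the limit `kappa* = 1` at `beta = 1`.  At `beta = 0, w = 0.5` this
#' equals `sqrt(2) ~ 1.414`, and for `w = 0.5` generally
#' `kappa* = 2^((1-beta)/2)` — the same curve along which the oscillation
#' prefactor [oscillation_condition()] vanishes.
#'
#' @param beta degree of balanced biosynthesis in `[0, 1]`.
#' @param w replication fraction in (0, 1).
#' @return `kappa*` (vectorized).
#' @export
optimal_kappa <- function(beta, w) {
  if (any(w <= 0 | w >= 1)) stop("w must lie strictly inside (0, 1)")
  k <- (1 - w) * (2^((beta - 1) * w) - 1) /
    (w * (2^(beta - 1) - 2^((beta - 1) * w)))
  k[abs(beta - 1) < 1e-9] <- 1
  k
}

#' Moment-matched gamma approximation
#'
#' Gamma distribution with the same mean and variance as the concentration
#' distribution: `shape = mean^2/var`, `rate = mean/var`.  Under perfect
#' homeostasis this is the exact stationary law (shape `rho/d_eff`, scale
#' `B`).
#'
#' @param mean_c,var_c mean and variance (e.g. from
#'   [noise_decomposition()]); alternatively pass an `"scc_homeostasis"`
#'   object as `mean_c`.
#' @return List with `shape` and `rate`.
#' @export
gamma_approximation <- function(mean_c, var_c = NULL) {
  if (inherits(mean_c, "scc_homeostasis")) {
    var_c <- mean_c$var_c; mean_c <- mean_c$mean_c
  }
  stopifnot(mean_c > 0, var_c > 0)
  list(shape = mean_c^2 / var_c, rate = mean_c / var_c)
}

#' Hellinger distance between two distributions on a common grid
#'
#' `D = sqrt(1 - sum sqrt(p q) dx)`, clipped to `[0, 1]`.  For discrete
#' distributions (probability vectors) use `dx = 1`.  Inputs must be
#' normalized to within `1e-3`.
#'
#' @param p,q nonnegative densities on a uniform grid (or probability
#'   vectors).
#' @param dx grid spacing (1 for discrete distributions).
#' @return `D` in `[0, 1]`.
#' @export
hellinger <- function(p, q, dx = 1) {
  if (abs(sum(p) * dx - 1) > 1e-3 || abs(sum(q) * dx - 1) > 1e-3)
    stop("hellinger(): inputs are not normalized on the supplied grid")
  aff <- sum(sqrt(p * q)) * dx
  sqrt(max(0, min(1, 1 - aff)))
}

#' Count the modes of a density sampled on a uniform grid
#'
#' Applies a light moving-average smoothing (window about 1% of the grid,
#' to suppress quadrature ripple) and counts strict local maxima; plateau
#' runs count once.
#'
#' @param dens density (or probability) values on a uniform grid.
#' @param smooth logical; set `FALSE` to count raw maxima.
#' @return Integer number of modes.
#' @export
count_modes <- function(dens, smooth = TRUE) {
  y <- as.numeric(dens)
  # densities can be infinite at a support boundary (gamma with shape < 1)
  if (any(!is.finite(y))) {
    cap <- 2 * max(y[is.finite(y)], 0)
    y[!is.finite(y)] <- cap
  }
  n <- length(y)
  if (smooth && n >= 20) {
    k <- max(3L, as.integer(round(0.01 * n)))
    if (k %% 2 == 0) k <- k + 1L
    kern <- rep(1 / k, k)
    pad <- (k - 1) / 2
    ypad <- c(rep(y[1], pad), y, rep(y[n], pad))
    y <- as.numeric(stats::filter(ypad, kern, sides = 2))[(pad + 1):(pad + n)]
  }
  # collapse plateaus, then count sign changes of the slope from + to -
  d <- diff(y)
  d <- d[d != 0]
  if (!length(d)) return(if (all(y == 0)) 0L else 1L)
  s <- sign(d)
  modes <- sum(s[-length(s)] > 0 & s[-1] < 0)
  if (s[1] < 0) modes <- modes + 1L          # mode at the left edge
  if (s[length(s)] > 0) modes <- modes + 1L  # mode at the right edge
  as.integer(modes)
}

#' Effective whole-cycle size-control strength
#'
#' The birth and division volumes satisfy (to first order in the size
#' fluctuations) `Vd = 2^(1 - alpha) Vb + noise` with
#' `alpha = w*alpha0 + (1-w)*alpha1`; `alpha -> 0, 1, Inf` is an overall
#' timer, adder, sizer.
#'
#' @param params an `"scc_params"`.
#' @param profile optional precomputed profile.
#' @return List with `alpha` and the implied birth-division regression
#'   `slope = 2^(1 - alpha)`.
#' @export
effective_alpha <- function(params, profile = meanfield_profile(params)) {
  w <- profile$w
  alpha <- w * params$alpha0 + (1 - w) * params$alpha1
  list(alpha = alpha, slope = 2^(1 - alpha))
}

#' Full homeostasis report for a parameter set
#'
#' Runs the analytic pipeline (profile, moments, stage statistics) and
#' returns the noise decomposition augmented with the Hellinger distance
#' `D` of the mixture concentration distribution from its moment-matched
#' gamma approximation and the spectral peak height `H`.
#'
#' @param params an `"scc_params"`.
#' @param lmax moment order (>= 2).
#' @param npts density grid size for `D`.
#' @param spectrum logical; compute `H` (skipping it saves the eigenwork).
#' @return An `"scc_homeostasis"` object with additional fields `D`, `H`
#'   and `stats`.
#' @export
homeostasis_report <- function(params, lmax = 2, npts = 2048,
                               spectrum = TRUE) {
  prof <- meanfield_profile(params)
  mom <- factorial_moments(prof, lmax = max(2, lmax))
  stats <- stage_stats(mom, prof)
  rep <- noise_decomposition(stats)
  mix <- lineage_concentration_distribution(stats)
  x <- mixture_grid(mix, npts)
  dx <- x[2] - x[1]
  pm <- dmixture(mix, x)
  ga <- gamma_approximation(rep)
  pg <- dgamma(x, shape = ga$shape, rate = ga$rate)
  # renormalize on the truncated grid before comparing
  rep$D <- hellinger(pm / (sum(pm) * dx), pg / (sum(pg) * dx), dx)
  if (spectrum) {
    spec <- power_spectrum(mom, prof)
    rep$H <- spec$H
  }
  rep$stats <- stats
  rep
}

#' Metric sweep over a parameter grid
#'
#' Evaluates homeostasis metrics over a grid of parameter values, one row
#' per grid point (tidy layout for heat maps).  Grid columns named after
#' model parameters replace those entries; a column `w` retunes the
#' replication fraction via [tune_replication_fraction()]; targets stored
#' in the parameter set are re-calibrated at every point.
#'
#' @param params base `"scc_params"`.
#' @param grid data frame of parameter combinations.
#' @param metrics character vector among `"gamma"`, `"phi"`, `"phi_ext"`,
#'   `"phi_int"`, `"H"`, `"D"`, `"mean_c"`.
#' @return `grid` with the metric columns appended.
#' @export
sweep_metrics <- function(params, grid,
                          metrics = c("gamma", "phi", "H")) {
  need_spec <- "H" %in% metrics
  out <- grid
  for (m in metrics) out[[m]] <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- params
    for (nm in names(grid)) {
      if (nm == "w") p <- tune_replication_fraction(p, grid$w[i])
      else if (nm == "eta") p$d <- grid$eta[i] * p$g / log(2)
      else p[[nm]] <- grid[[nm]][i]
    }
    p <- calibrate(p)
    rep <- homeostasis_report(p, spectrum = need_spec)
    for (m in metrics) out[[m]][i] <- rep[[m]] %||% NA_real_
  }
  out
}
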