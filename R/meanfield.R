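# Mean-field (reduced model) profile: typical stage volumes, transition
# rates and burst parameters obtained by replacing the stochastic volume at
# each stage with its typical value while keeping stage durations random.

#' Typical birth volume of the mean-field model
#'
#' When the number of stages is large the generalized added volumes before
#' and after replication concentrate at their means `M0` and `M1`, division
#' doubles the birth volume, and the typical birth volume `Vb` solves the
#' implicit equation
#' \deqn{(V_b^{\alpha_0} + M_0)^{\alpha_1/\alpha_0} + M_1 = (2 V_b)^{\alpha_1}.}
#' For `alpha0 == alpha1 == alpha` this has the closed form
#' `Vb = ((M0 + M1) / (2^alpha - 1))^(1/alpha)`.
#'
#' @param params an `"scc_params"` object.
#' @return The positive root (a scalar volume).
#' @export
birth_volume <- function(params) {
  p <- params
  a0 <- p$alpha0; a1 <- p$alpha1
  M0 <- p$N0 * a0 * p$g / p$a^a0
  M1 <- (p$N - p$N0) * a1 * p$g / p$a^a1
  if (isTRUE(all.equal(a0, a1))) {
    return(((M0 + M1) / (2^a0 - 1))^(1 / a0))
  }
  # exponent arithmetic in log space to survive large alpha
  h <- function(Vb) {
    lhs <- exp((a1 / a0) * log(Vb^a0 + M0)) + M1
    lhs - (2 * Vb)^a1
  }
  # h(0+) > 0 and h -> -Inf; bracket by doubling from the equal-alpha guesses
  guess <- ((M0 + M1) / (2^min(a0, a1) - 1))^(1 / min(a0, a1)) +
    ((M0 + M1) / (2^max(a0, a1) - 1))^(1 / max(a0, a1))
  lo <- guess * 1e-8
  hi <- guess
  it <- 0
  while (h(hi) > 0 && it < 200) { hi <- hi * 2; it <- it + 1 }
  if (h(hi) > 0)
    stop("birth-volume root finding failed: no sign change up to Vb = ", hi,
         " (M0 = ", M0, ", M1 = ", M1, ")", call. = FALSE)
  r <- uniroot(h, c(lo, hi), tol = .Machine$double.eps * guess)
  r$root
}

#' Mean-field profile of the reduced model
#'
#' Fills the per-stage typical volumes
#' \deqn{v_k = [v_1^{\alpha_0} + (k-1) M_0/N_0]^{1/\alpha_0}, k \le N_0}
#' \deqn{v_k = [(v_1^{\alpha_0} + M_0)^{\alpha_1/\alpha_0} + (k-N_0-1) M_1/N_1]^{1/\alpha_1}, k > N_0}
#' together with the stage-exit rates `q_k = (a*v_k)^alpha`, the mean burst
#' sizes `B_k = B * v_k^beta`, the burst frequencies `rho_k` (`rho` before
#' replication, `kappa*rho` after) and the replication fraction
#' `w = log2(v_(N0+1) / v_1)`.
#'
#' @param params an `"scc_params"` object.
#' @return An `"scc_profile"` list with fields `v`, `q`, `Bk`, `rhok`,
#'   `Vb`, `Vr`, `w`, `M0`, `M1` and the originating `params`.
#' @export
meanfield_profile <- function(params) {
  p <- params
  a0 <- p$alpha0; a1 <- p$alpha1
  N <- p$N; N0 <- p$N0; N1 <- N - N0
  M0 <- N0 * a0 * p$g / p$a^a0
  M1 <- N1 * a1 * p$g / p$a^a1
  Vb <- birth_volume(p)
  k <- seq_len(N)
  v <- numeric(N)
  pre <- k <= N0
  v[pre] <- (Vb^a0 + (k[pre] - 1) * M0 / N0)^(1 / a0)
  vr_gen <- exp((a1 / a0) * log(Vb^a0 + M0))  # (Vb^a0 + M0)^(a1/a0)
  v[!pre] <- (vr_gen + (k[!pre] - N0 - 1) * M1 / N1)^(1 / a1)
  q <- ifelse(pre, (p$a * v)^a0, (p$a * v)^a1)
  Bk <- p$B * v^p$beta
  rhok <- ifelse(pre, p$rho, p$kappa * p$rho)
  Vr <- vr_gen^(1 / a1)
  w <- log2(Vr / Vb)
  if (w <= 1e-10 || w >= 1 - 1e-10)
    warning("degenerate replication placement: w = ", signif(w, 4),
            call. = FALSE)
  structure(list(v = v, q = q, Bk = Bk, rhok = rhok,
                 Vb = Vb, Vr = Vr, w = w, M0 = M0, M1 = M1, params = p),
            class = "scc_profile")
}

#' @export
print.scc_profile <- function(x, ...) {
  N <- length(x$v)
  cat("Mean-field profile:", N, "stages, replication after stage",
      x$params$N0, "\n")
  cat(sprintf("  Vb = %.6g  Vr = %.6g  Vd = %.6g  w = %.4f\n",
              x$Vb, x$Vr, 2 * x$Vb, x$w))
  cat(sprintf("  M0 = %.6g  M1 = %.6g\n", x$M0, x$M1))
  invisible(x)
}

#' Replication fraction of a profile
#'
#' The proportion of the cell cycle spent before replication,
#' `w = log2(v_(N0+1) / v_1)`.  Note this differs from `N0/N` because
#' stage-exit rates grow with volume, so earlier stages last longer.
#'
#' @param profile an `"scc_profile"` object.
#' @return `w` in `(0, 1)` (degenerate values are flagged when the profile
#'   is built).
#' @export
replication_fraction <- function(profile) log2(profile$Vr / profile$Vb)

#' Calibrate `a` and `rho` to target lineage means
#'
#' Adjusts the transition-rate constant `a` so the lineage mean cell volume
#' `sum(m0k * v_k)` matches `mean_volume`, and then rescales the burst
#' frequency `rho` so the lineage mean copy number `sum(m1k)` matches
#' `mean_number`.  The model has an exact scale symmetry (rescaling `a` by
#' `c` rescales all stage volumes by `1/c` while leaving `a*v_k`, hence all
#' `q_k` and occupancies, unchanged), so the volume step is a single exact
#' rescale; the first moment is exactly linear in `rho`, so the copy-number
#' step is a single multiplicative rescale.
#'
#' @param params an `"scc_params"` object.
#' @param mean_volume,mean_number targets; default to the ones stored in
#'   `params`.  `NULL` skips that step.
#' @return A recalibrated `"scc_params"` object.
#' @export
calibrate <- function(params, mean_volume = params$mean_volume,
                      mean_number = params$mean_number) {
  p <- params
  if (!is.null(mean_volume)) {
    if (mean_volume <= 0) stop("mean_volume target must be positive")
    prof <- meanfield_profile(p)
    meanV <- sum(stage_occupancy(prof) * prof$v)
    p$a <- p$a * meanV / mean_volume
    p$mean_volume <- mean_volume
  }
  if (!is.null(mean_number)) {
    if (mean_number <= 0) stop("mean_number target must be positive")
    prof <- meanfield_profile(p)
    m <- factorial_moments(prof, d = p$d, lmax = 1)
    p$rho <- p$rho * mean_number / sum(m$m[[2]])
    p$mean_number <- mean_number
  }
  p
}

#' Choose N0 and the size-control strength to achieve a target replication
#' fraction
#'
#' For studies that scan the replication timing `w`, this helper picks
#' `N0 = floor(N * (2^w - 1))` (the adder solution) and then solves for a
#' common size-control strength `alpha0 = alpha1 = alpha` such that the
#' profile's replication fraction equals `w` exactly.  For equal strengths
#' `w = log2(1 + (N0/N) * (2^alpha - 1)) / alpha`, which increases
#' monotonically from `N0/N` (timer limit) to 1, so a root always exists
#' when `N0/N < w`.
#'
#' @param params base `"scc_params"`.
#' @param w target replication fraction in (0, 1).
#' @return `"scc_params"` with adjusted `N0`, `alpha0`, `alpha1`.
#' @export
tune_replication_fraction <- function(params, w) {
  stopifnot(w > 0, w < 1)
  p <- params
  N <- p$N
  N0 <- max(1L, min(N - 1L, as.integer(floor(N * (2^w - 1)))))
  # ensure N0/N strictly below w (2^w - 1 < w on (0,1) guarantees it)
  p$N0 <- N0
  frac <- N0 / N
  wfun <- function(al) log2(1 + frac * (2^al - 1)) / al - w
  r <- uniroot(wfun, c(1e-3, 60), tol = 1e-13)
  p$alpha0 <- p$alpha1 <- r$root
  p
}
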