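# Named parameter sets for the standard study conditions used throughout
# the documentation and tests.

fixture_table <- function() {
  f <- 0.1
  g <- log(2) * f
  base3 <- function(N, a0, a1) {
    model_params(g = g, rho = 10, kappa = 2, B = 1, beta = 0,
                 d = 1, N = N, N0 = max(1L, round(0.4 * N)),
                 alpha0 = a0, alpha1 = a1, a = 1,
                 mean_volume = 1, mean_number = 100)
  }
  fx <- list()
  for (N in c(10, 20, 30)) {
    fx[[paste0("fig3_adder_N", N)]] <- list(
      params = base3(N, 1, 1),
      note = "model comparison set, adder control (eta = 10, beta = 0, kappa = 2)")
    fx[[paste0("fig3_sizer_timer_N", N)]] <- list(
      params = base3(N, 2, 0.5),
      note = "model comparison set, sizer-like then timer-like control")
    fx[[paste0("fig3_timer_sizer_N", N)]] <- list(
      params = base3(N, 0.5, 2),
      note = "model comparison set, timer-like then sizer-like control")
  }
  fx$fig4_perfect <- list(
    params = model_params(g = g, rho = 10, kappa = 1, B = 1, beta = 1,
                          d = 0.1, N = 50, N0 = 21, alpha0 = 1, alpha1 = 1,
                          a = 1, mean_volume = 1, mean_number = 100),
    note = "perfect homeostasis regime (beta = kappa = 1); regime-matched, not value-matched")
  fx$fig4_quasi <- list(
    params = suppressWarnings(tune_replication_fraction(
      model_params(g = g, rho = 10, kappa = sqrt(2), B = 1, beta = 0,
                   d = 0.1, N = 50, N0 = 20, alpha0 = 1, alpha1 = 1,
                   a = 1, mean_volume = 1, mean_number = 100), 0.5)),
    note = "quasi-perfect homeostasis (beta = 0, kappa = sqrt(2), w = 0.5); regime-matched, not value-matched")
  fx$fig4_weak <- list(
    params = model_params(g = g, rho = 10, kappa = 2, B = 1, beta = 1,
                          d = 1, N = 50, N0 = 21, alpha0 = 1, alpha1 = 1,
                          a = 1, mean_volume = 1, mean_number = 100),
    note = "weak homeostasis (balanced synthesis, no compensation, unstable product); regime-matched, not value-matched")
  fx$fig5_base <- list(
    params = model_params(g = g, rho = 4.7, kappa = 2, B = 1, beta = 1,
                          d = 0.4, N = 50, N0 = 21, alpha0 = 1, alpha1 = 1,
                          a = 1, mean_volume = 1),
    note = "size-control study set (N = 50, N0 = 21, rho = 4.7, kappa = 2, d = 0.4, eta = 4)")
  fx$s4_timer <- list(
    params = model_params(g = g, rho = 10, kappa = 2, B = 1, beta = 0,
                          d = 0.5, N = 20, N0 = 10, alpha0 = 0.01,
                          alpha1 = 0.01, a = 1,
                          mean_volume = 1, mean_number = 100),
    note = "near-timer control (alpha0 = alpha1 = 0.01, eta = 5)")
  fx
}

#' Standard parameter sets
#'
#' Returns the named study conditions used across the package: the
#' model-comparison sets (adder, sizer-timer and timer-sizer control at
#' several stage counts, all with `f = 0.1`, `eta = 10`, `beta = 0`,
#' `kappa = 2` and calibration targets `<V> = 1`, `<n> = 100`), the
#' perfect / quasi-perfect / weak homeostasis regimes, the size-control
#' study set and a near-timer set.  Each entry holds `params`
#' (an `"scc_params"`, uncalibrated — pass through [calibrate()]) and a
#' provenance `note`.
#'
#' @param name optional fixture name; omit to get the full list.
#' @return A single fixture (list with `params`, `note`) or the named list
#'   of all of them.
#' @export
fixtures <- function(name = NULL) {
  fx <- suppressWarnings(fixture_table())
  for (nm in names(fx)) fx[[nm]]$name <- nm
  if (is.null(name)) return(fx)
  if (!name %in% names(fx))
    stop("unknown fixture '", name, "'; see names(fixtures())")
  fx[[name]]
}
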