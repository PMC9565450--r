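# The user-facing model object: parameters, mean-field profile and moment
# statistics bundled together, with the usual modelling-object methods.

#' Build a cell-size-coupled gene expression model
#'
#' Constructs the model object from the eleven parameters (see
#' [model_params()]), optionally calibrating `a` and `rho` to the targets
#' stored in the parameter set, and precomputes the mean-field profile,
#' factorial moments and per-stage statistics on which all analytic
#' results are based.
#'
#' @param params an `"scc_params"` object, or arguments passed on to
#'   [model_params()] via `...`.
#' @param calibrate logical; apply [calibrate()] when targets are present.
#' @param lmax moment order to precompute (2 suffices for all summaries).
#' @param ... parameters forwarded to [model_params()] when `params` is
#'   missing.
#' @return An object of class `"scc_model"` with elements `params`,
#'   `derived`, `profile`, `moments`, `stats`.
#' @export
#' @examples
#' m <- scc_model(g = log(2) / 10, rho = 10, kappa = 2, B = 1, beta = 0,
#'                d = 1, N = 30, N0 = 12, mean_volume = 1, mean_number = 100)
#' summary(m)
scc_model <- function(params = NULL, calibrate = TRUE, lmax = 2, ...) {
  if (is.null(params)) params <- model_params(...)
  if (calibrate &&
      (!is.null(params$mean_volume) || !is.null(params$mean_number)))
    params <- calibrate(params)
  profile <- meanfield_profile(params)
  moments <- factorial_moments(profile, lmax = max(2, lmax))
  stats <- stage_stats(moments, profile)
  structure(list(params = params,
                 derived = derived_params(params, profile),
                 profile = profile, moments = moments, stats = stats),
            class = "scc_model")
}

#' @export
print.scc_model <- function(x, ...) {
  cat("Coupled gene-expression / cell-size model\n")
  print(x$params)
  d <- x$derived
  cat(sprintf("  T = %.4g, f = %.4g, d_eff = %.4g, eta = %.4g, w = %.4g\n",
              d$T, d$f, d$d_eff, d$eta, d$w))
  invisible(x)
}

#' @export
coef.scc_model <- function(object, ...) {
  p <- object$params
  unlist(p[c("g", "rho", "kappa", "B", "beta", "d", "N", "N0",
             "alpha0", "alpha1", "a")])
}

#' @export
summary.scc_model <- function(object, ...) {
  rep <- homeostasis_report(object$params)
  ea <- effective_alpha(object$params, object$profile)
  out <- structure(list(model = object, report = rep, alpha = ea$alpha,
                        slope = ea$slope),
                   class = "summary.scc_model")
  out
}

#' @export
print.summary.scc_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  effective size control alpha = %.4g (Vd~Vb slope %.4g)\n",
              x$alpha, x$slope))
  print(x$report)
  invisible(x)
}

#' Simulate lineages from a model
#'
#' `simulate()` method dispatching to [simulate_lineage()].
#'
#' @param object an `"scc_model"`.
#' @param nsim number of independent lineages.
#' @param seed optional seed.
#' @param t_max,sample_dt,model,burnin passed to [simulate_lineage()].
#' @param ... ignored.
#' @return A single `"scc_trajectory"` (`nsim = 1`) or a list of them.
#' @export
simulate.scc_model <- function(object, nsim = 1, seed = NULL,
                               t_max = 1e4, sample_dt = 0.1,
                               model = "full", burnin = 10, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i)
    simulate_lineage(object$params, t_max = t_max, sample_dt = sample_dt,
                     model = model, burnin = burnin))
  if (nsim == 1) out[[1]] else out
}

#' Plot a model's concentration distribution and power spectrum
#'
#' Left panel: the gamma-mixture lineage concentration density and its
#' moment-matched gamma approximation.  Right panel: the normalized power
#' spectrum with the cell cycle frequency and its first harmonic marked.
#'
#' @param x an `"scc_model"`.
#' @param ... ignored.
#' @export
plot.scc_model <- function(x, ...) {
  mix <- lineage_concentration_distribution(x$stats)
  xs <- mixture_grid(mix, 512)
  rep <- noise_decomposition(x$stats)
  ga <- gamma_approximation(rep)
  spec <- power_spectrum(x$moments, x$profile)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(xs, dmixture(mix, xs), type = "l", xlab = "concentration",
                 ylab = "density", main = "lineage distribution")
  graphics::lines(xs, dgamma(xs, ga$shape, ga$rate), lty = 2, col = 2)
  graphics::legend("topright", c("mixture", "matched gamma"),
                   lty = c(1, 2), col = c(1, 2), bty = "n")
  graphics::plot(spec$freq, spec$G, type = "l", xlab = "frequency",
                 ylab = "G", main = "power spectrum")
  graphics::abline(v = c(1, 2) * x$derived$f, lty = 3)
  invisible(x)
}
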