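# Model parameters: the eleven rate/structure constants of the coupled
# gene-expression / cell-size model, plus optional calibration targets.

#' Construct a model parameter set
#'
#' The model is specified by eleven parameters: the exponential volume
#' growth rate `g`, the burst frequency `rho` before replication, the
#' dosage-compensation factor `kappa` (burst frequency after replication is
#' `kappa * rho`; `kappa = 1` is perfect compensation, `kappa = 2` none),
#' the burst-size constant `B` and scaling exponent `beta` (mean burst size
#' is `B * V^beta`; `beta = 1` is balanced biosynthesis), the degradation
#' rate `d`, the number of effective cell cycle stages `N` of which `N0`
#' precede gene replication, the size-control strengths `alpha0` (before)
#' and `alpha1` (after) replication, and the transition-rate constant `a`
#' (rate from stage k is `(a*V)^alpha`).
#'
#' Units of time and volume are the user's; all formulas are
#' unit-consistent by construction.
#'
#' @param g volume growth rate (1/time); the mean cycle duration is
#'   `log(2)/g`.
#' @param rho burst frequency before replication (bursts/time).
#' @param kappa post-replication burst-frequency multiplier.  Values
#'   outside `[1, 2]` trigger a warning.
#' @param B proportionality constant of the mean burst size.
#' @param beta degree of balanced biosynthesis, in `[0, 1]`.
#' @param d gene-product degradation rate (1/time); may be zero (stable
#'   product).
#' @param N total number of effective cell cycle stages.
#' @param N0 number of stages before replication, `1 <= N0 < N`.
#' @param alpha0,alpha1 size-control strengths before/after replication
#'   (`alpha -> 0` timer, `alpha = 1` adder, `alpha -> Inf` sizer).  Must
#'   be strictly positive; a timer is represented by a small value such as
#'   0.01.
#' @param a proportionality constant of the stage-transition rate
#'   (1/volume).
#' @param mean_volume,mean_number optional calibration targets for the
#'   lineage mean cell volume and mean copy number (see [calibrate()]).
#' @return An object of class `"scc_params"`.
#' @seealso [validate_params()], [derived_params()], [meanfield_profile()]
#' @export
#' @examples
#' p <- model_params(g = log(2) / 10, rho = 10, kappa = 2, B = 1, beta = 0,
#'                   d = 1, N = 50, N0 = 20, alpha0 = 1, alpha1 = 1, a = 1)
#' derived_params(p)$T  # mean cycle duration = 10
model_params <- function(g, rho, kappa = 2, B = 1, beta = 0, d = 0,
                         N = 50, N0 = 20, alpha0 = 1, alpha1 = 1, a = 1,
                         mean_volume = NULL, mean_number = NULL) {
  p <- structure(
    list(g = as.numeric(g), rho = as.numeric(rho), kappa = as.numeric(kappa),
         B = as.numeric(B), beta = as.numeric(beta), d = as.numeric(d),
         N = as.integer(N), N0 = as.integer(N0),
         alpha0 = as.numeric(alpha0), alpha1 = as.numeric(alpha1),
         a = as.numeric(a),
         mean_volume = if (is.null(mean_volume)) NULL else as.numeric(mean_volume),
         mean_number = if (is.null(mean_number)) NULL else as.numeric(mean_number)),
    class = "scc_params")
  w <- validate_params(p)
  for (msg in w) warning(msg, call. = FALSE)
  p
}

#' Validate a parameter set
#'
#' Hard errors are raised for structurally invalid parameters (non-positive
#' rates, `N0 >= N`, ...); soft issues (e.g. `kappa` outside `[1, 2]`, the
#' near-timer limit `alpha < 0.01`) are returned as a character vector of
#' warnings.
#'
#' @param params an `"scc_params"` object (or plain named list).
#' @return Character vector of warning messages (empty for a clean set).
#' @export
validate_params <- function(params) {
  p <- params
  need_pos <- c("g", "rho", "B", "a", "alpha0", "alpha1")
  for (f in need_pos) {
    v <- p[[f]]
    if (is.null(v) || !is.finite(v) || v <= 0)
      stop("parameter '", f, "' must be a strictly positive number", call. = FALSE)
  }
  if (is.null(p$d) || !is.finite(p$d) || p$d < 0)
    stop("parameter 'd' must be a non-negative number", call. = FALSE)
  if (is.null(p$N) || p$N < 1) stop("parameter 'N' must be >= 1", call. = FALSE)
  if (is.null(p$N0) || p$N0 < 1 || p$N0 >= p$N)
    stop("parameter 'N0' must satisfy 1 <= N0 < N", call. = FALSE)
  for (f in c("mean_volume", "mean_number"))
    if (!is.null(p[[f]]) && (!is.finite(p[[f]]) || p[[f]] <= 0))
      stop("calibration target '", f, "' must be positive", call. = FALSE)

  warns <- character(0)
  if (p$kappa < 1 || p$kappa > 2)
    warns <- c(warns, sprintf(
      "kappa = %g is outside [1, 2]; dosage compensation is normally between perfect (1) and absent (2)",
      p$kappa))
  if (p$beta < 0 || p$beta > 1)
    warns <- c(warns, sprintf("beta = %g is outside [0, 1]", p$beta))
  if (min(p$alpha0, p$alpha1) < 0.01)
    warns <- c(warns, "very small size-control strength (timer limit); stage volumes may be poorly determined")
  warns
}

#' Derived model quantities
#'
#' Computes the quantities implied by a parameter set: the mean cycle
#' duration `T = log(2)/g`, cycle frequency `f = 1/T`, effective decay rate
#' `d_eff = d + log(2) * f` (degradation plus dilution), the stability
#' ratio `eta = d/f`, the mean generalized added volumes
#' `M0 = N0 * alpha0 * g / a^alpha0` and `M1 = (N - N0) * alpha1 * g /
#' a^alpha1`, and the replication fraction `w` (proportion of the cycle
#' before replication, taken from the mean-field profile).
#'
#' @param params an `"scc_params"` object.
#' @param profile optionally, a precomputed [meanfield_profile()] (avoids
#'   re-solving for the birth volume).
#' @return Named list with elements `T`, `f`, `d_eff`, `eta`, `M0`, `M1`,
#'   `w`.
#' @export
derived_params <- function(params, profile = NULL) {
  p <- params
  Tc <- log(2) / p$g
  f <- 1 / Tc
  if (is.null(profile)) profile <- meanfield_profile(p)
  list(T = Tc, f = f,
       d_eff = p$d + log(2) * f,
       eta = p$d / f,
       M0 = p$N0 * p$alpha0 * p$g / p$a^p$alpha0,
       M1 = (p$N - p$N0) * p$alpha1 * p$g / p$a^p$alpha1,
       w = profile$w)
}

#' @export
print.scc_params <- function(x, ...) {
  cat("Model parameters (coupled gene expression / cell size model)\n")
  flds <- c("g", "rho", "kappa", "B", "beta", "d", "N", "N0",
            "alpha0", "alpha1", "a")
  vals <- vapply(flds, function(f) format(x[[f]], digits = 6), "")
  cat(paste0("  ", format(flds, width = 7), " = ", vals, collapse = "\n"), "\n")
  if (!is.null(x$mean_volume) || !is.null(x$mean_number))
    cat("  calibration targets: <V> =", x$mean_volume %||% NA,
        ", <n> =", x$mean_number %||% NA, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- configuration files --------------------------------------------------

.scc_config_keys <- c("g", "rho", "kappa", "B", "beta", "d", "N", "N0",
                      "alpha0", "alpha1", "a", "mean_volume", "mean_number")

#' Read a model configuration file
#'
#' Configurations are flat YAML (or JSON, which YAML subsumes) mappings
#' with keys named exactly as the fields of [model_params()] plus the
#' optional calibration targets `mean_volume` and `mean_number`.  Unknown
#' keys raise an error, so typos do not pass silently.
#'
#' @param path path to the YAML file.
#' @param overrides optional named list (or `"key=value"` strings) applied
#'   on top of the file.
#' @return An `"scc_params"` object.
#' @export
read_config <- function(path, overrides = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(overrides)) {
    if (is.character(overrides)) {
      kv <- strsplit(overrides, "=", fixed = TRUE)
      overrides <- setNames(
        lapply(kv, function(x) as.numeric(x[2])),
        vapply(kv, `[`, "", 1))
    }
    cfg[names(overrides)] <- overrides
  }
  unknown <- setdiff(names(cfg), .scc_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(c("g", "rho"), names(cfg))
  if (length(missing))
    stop("configuration is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(model_params, cfg)
}

#' Write a model configuration file
#'
#' @param params an `"scc_params"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  cfg <- params[.scc_config_keys]
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
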