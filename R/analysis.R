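# Estimators for single-cell lineage time series (simulated or measured):
# empirical power spectra, cell-cycle binning, noise decomposition,
# number-volume scatter and size-control regression.

series_of <- function(x) {
  if (inherits(x, "scc_trajectory")) x$series else as.data.frame(x)
}

division_times_of <- function(x, division_times = NULL) {
  if (!is.null(division_times)) return(division_times)
  if (inherits(x, "scc_trajectory")) return(x$division_times)
  stop("division times must be supplied for plain data-frame input")
}

#' Empirical power spectrum of a lineage (Wiener-Khinchin estimate)
#'
#' Splits the uniformly sampled concentration series into consecutive
#' segments (20 cell cycles each by default), computes the mean-subtracted
#' truncated-Fourier-transform periodogram `|c_T(xi)|^2 / T` of each
#' segment, and averages.  The estimate is normalized to 1 at the
#' low-frequency plateau (mean of the 3 lowest positive-frequency
#' ordinates; the raw zero ordinate is removed with the mean), matching
#' the `G(0) = 1` convention of the analytic spectrum.
#'
#' @param x an `"scc_trajectory"` or data frame with columns `time` and
#'   `concentration` (uniform sampling).
#' @param f cell cycle frequency (used to size segments); defaults to the
#'   trajectory's.
#' @param cycles_per_segment segment length in cell cycles.
#' @param value column to analyse (`"concentration"` or `"number"`).
#' @return List with `freq`, `G` (normalized), `se` (standard error of the
#'   normalized mean across segments) and `n_segments`.
#' @export
empirical_spectrum <- function(x, f = NULL, cycles_per_segment = 20,
                               value = "concentration") {
  ser <- series_of(x)
  if (is.null(f)) {
    if (inherits(x, "scc_trajectory")) f <- x$params$g / log(2)
    else stop("supply the cell cycle frequency f for data-frame input")
  }
  dt <- diff(ser$time[1:2])
  cvals <- ser[[value]]
  L <- floor(cycles_per_segment / f / dt)
  nseg <- floor(length(cvals) / L)
  if (nseg < 1) stop("series shorter than one segment")
  if (length(cvals) < 5 / f / dt)
    warning("series covers fewer than 5 cell cycles", call. = FALSE)
  nfreq <- floor(L / 2)
  P <- matrix(0, nseg, nfreq)
  for (s in seq_len(nseg)) {
    seg <- cvals[((s - 1) * L + 1):(s * L)]
    seg <- seg - mean(seg)
    ft <- fft(seg) * dt
    P[s, ] <- (Mod(ft)^2 / (L * dt))[2:(nfreq + 1)]
  }
  freq <- (1:nfreq) / (L * dt)
  Gbar <- colMeans(P)
  se <- apply(P, 2, sd) / sqrt(nseg)
  plateau <- mean(Gbar[1:min(3, nfreq)])
  list(freq = freq, G = Gbar / plateau, se = se / plateau,
       n_segments = nseg, f = f)
}

#' Bin samples by cell-cycle fraction
#'
#' Each sample is assigned the within-cycle fraction
#' `(t - t_birth)/(t_div - t_birth)` of its own generation and pooled into
#' `n_bins` equal-width bins across all cycles; per-bin means and standard
#' deviations of the concentration are returned.  Cycles with fewer
#' samples than bins simply contribute to the bins they hit.
#'
#' @param x trajectory or data frame with `time` and `concentration`.
#' @param division_times increasing division times (taken from the
#'   trajectory when available); consecutive pairs delimit cycles.
#' @param n_bins number of cycle pieces (default 50).
#' @param value column to bin.
#' @return An `"scc_binned"` list with `bin_centers`, `bin_means`,
#'   `bin_sds`, `bin_counts` and the pooled sample vector `values`.
#' @export
bin_by_cycle <- function(x, division_times = NULL, n_bins = 50,
                         value = "concentration") {
  ser <- series_of(x)
  dv <- sort(division_times_of(x, division_times))
  if (length(dv) < 2) stop("need at least two division times")
  idx <- findInterval(ser$time, dv)
  inside <- idx >= 1 & idx < length(dv)
  tt <- ser$time[inside]
  vv <- ser[[value]][inside]
  tb <- dv[idx[inside]]
  td <- dv[idx[inside] + 1]
  frac <- (tt - tb) / (td - tb)
  bin <- pmin(n_bins, floor(frac * n_bins) + 1L)
  means <- tapply(vv, bin, mean)
  sds <- tapply(vv, bin, sd)
  counts <- tapply(vv, bin, length)
  full <- as.character(seq_len(n_bins))
  structure(list(bin_centers = (seq_len(n_bins) - 0.5) / n_bins,
                 bin_means = as.numeric(means[full]),
                 bin_sds = as.numeric(sds[full]),
                 bin_counts = as.integer(ifelse(is.na(counts[full]), 0L,
                                                counts[full])),
                 values = vv, n_bins = n_bins),
            class = "scc_binned")
}

#' Estimate the noise decomposition from a lineage series
#'
#' The total noise `phi` is estimated as the CV^2 of all concentration
#' samples; the extrinsic (cell-cycle) part `phi_ext` as the CV^2 of the
#' cycle-piece means from [bin_by_cycle()]; `gamma = phi_ext/phi`.  All
#' three are invariant under rescaling the concentration by a constant.
#'
#' @inheritParams bin_by_cycle
#' @return List with `phi`, `phi_ext`, `gamma`, `mean_c` and the binned
#'   object.
#' @export
estimate_gamma <- function(x, division_times = NULL, n_bins = 50,
                           value = "concentration") {
  b <- bin_by_cycle(x, division_times, n_bins, value)
  m <- mean(b$values)
  if (m == 0) stop("zero mean concentration")
  phi <- var(b$values) / m^2
  bm <- b$bin_means[!is.na(b$bin_means)]
  phi_ext <- var(bm) / mean(bm)^2
  gamma <- if (phi > 0) phi_ext / phi else 0
  list(phi = phi, phi_ext = phi_ext, gamma = gamma, mean_c = m, binned = b)
}

#' Copy number versus cell volume scatter statistics
#'
#' Sorts samples into `n_bins` equal-occupancy volume bins, reports the
#' per-bin mean and variance of the molecule number, and fits an ordinary
#' least-squares line through the raw scatter.  Under accurate
#' concentration homeostasis the bin means are collinear with volume and
#' `R^2` is high; inaccurate homeostasis shows up as curvature and a lower
#' `R^2`.
#'
#' @param x trajectory or data frame with `volume` and `number` columns.
#' @param n_bins number of volume bins (default 8).
#' @return List with the bin table (`volume`, `mean_n`, `var_n`, `count`),
#'   `slope`, `intercept`, `r_squared`.
#' @export
number_volume_scatter <- function(x, n_bins = 8) {
  ser <- series_of(x)
  V <- ser$volume; n <- ser$number
  if (diff(range(V)) <= 0) stop("degenerate volume range")
  br <- quantile(V, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- br[1] - 1e-9; br[n_bins + 1] <- br[n_bins + 1] + 1e-9
  bin <- cut(V, br, labels = FALSE)
  tab <- data.frame(
    volume = as.numeric(tapply(V, bin, mean)),
    mean_n = as.numeric(tapply(n, bin, mean)),
    var_n = as.numeric(tapply(n, bin, var)),
    count = as.integer(tapply(n, bin, length)))
  fit <- lm(n ~ V)
  list(bins = tab, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Size-control regression from generation records
#'
#' Least-squares slope of the division volume on the birth volume; under
#' the model `Vd = 2^(1-alpha) Vb + noise` with effective strength
#' `alpha = w alpha0 + (1-w) alpha1`, so `alpha_hat = 1 - log2(slope)`.
#' Per-phase fits are returned as well: `Vr` on `Vb` (slope
#' `2^(w(1-alpha0))`) and `Vd` on `Vr` (slope `2^((1-w)(1-alpha1))`).
#'
#' @param gens data frame of generation records (`Vb`, `Vr`, `Vd`), or an
#'   `"scc_trajectory"` from the full model.
#' @return List with `slope`, `alpha_hat`, `slope_rep` (Vr on Vb),
#'   `slope_div` (Vd on Vr) and the number of generations used.
#' @export
size_control_fit <- function(gens) {
  if (inherits(gens, "scc_trajectory")) gens <- gens$generations
  if (is.null(gens) || nrow(gens) < 100)
    stop("need at least 100 generation records")
  s <- unname(coef(lm(Vd ~ Vb, data = gens))[2])
  list(slope = s,
       alpha_hat = 1 - log2(s),
       slope_rep = unname(coef(lm(Vr ~ Vb, data = gens))[2]),
       slope_div = unname(coef(lm(Vd ~ Vr, data = gens))[2]),
       n = nrow(gens))
}

#' Moment-matched gamma fit and Hellinger distance for a sample
#'
#' Fits a gamma distribution to the concentration sample by moment
#' matching and reports the Hellinger distance between the histogram of
#' the sample and the fitted gamma, both discretized on the same bins.
#'
#' @param x trajectory, data frame with a `concentration` column, or a
#'   plain numeric sample.
#' @param breaks number of histogram bins.
#' @return List with `shape`, `rate`, `D` and the sample size.
#' @export
fit_gamma_and_distance <- function(x, breaks = 64) {
  v <- if (is.numeric(x)) x else series_of(x)$concentration
  if (length(v) < 1000) stop("need at least 1000 samples")
  if (any(v < 0)) stop("negative concentration values")
  m <- mean(v); s2 <- var(v)
  shape <- m^2 / s2; rate <- m / s2
  br <- seq(0, max(v) * (1 + 1e-9), length.out = breaks + 1)
  ph <- as.numeric(table(cut(v, br, labels = FALSE, include.lowest = TRUE),
                         deparse.level = 0)[as.character(seq_len(breaks))])
  ph[is.na(ph)] <- 0
  ph <- ph / sum(ph)
  pg <- diff(pgamma(br, shape = shape, rate = rate))
  pg <- pg / sum(pg)
  list(shape = shape, rate = rate, D = hellinger(ph, pg), n = length(v))
}

#' Hellinger distance between two samples via common histograms
#'
#' Utility for comparing simulated distributions (e.g. full vs reduced
#' model): bins both samples on a shared grid and computes the discrete
#' Hellinger distance of the bin proportions.
#'
#' @param x,y numeric samples.
#' @param breaks number of shared bins.
#' @return `D` in `[0, 1]`.
#' @export
hellinger_hist <- function(x, y, breaks = 60) {
  rng <- range(c(x, y))
  br <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = breaks + 1)
  px <- tabulate(cut(x, br, labels = FALSE, include.lowest = TRUE), breaks)
  py <- tabulate(cut(y, br, labels = FALSE, include.lowest = TRUE), breaks)
  hellinger(px / sum(px), py / sum(py))
}
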