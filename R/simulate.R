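# R interface to the event-driven simulators.

#' Simulate a single-cell lineage
#'
#' Runs the exact event-driven simulation of either the full model
#' (stochastic volume, time-inhomogeneous stage hazards sampled by exact
#' inverse transform) or the mean-field reduced model (typical stage
#' volumes, constant per-stage rates).  At division the volume halves
#' exactly, each molecule is kept with probability 1/2 (binomial
#' partitioning), and one daughter is followed.  The trajectory is
#' returned sampled on a uniform time grid, together with per-generation
#' birth/replication/division records (full model only).
#'
#' @param params an `"scc_params"` object.
#' @param t_max total simulated time per lineage.
#' @param sample_dt uniform sampling interval for the output series.
#' @param model `"full"` or `"reduced"`.
#' @param seed optional integer seed (`set.seed` is called when supplied;
#'   identical seeds give identical event sequences).
#' @param burnin number of initial cell cycles discarded from the returned
#'   series and generation records (stationarity of the stage process is
#'   reached geometrically fast; 10 cycles is conservative).
#' @param n_init initial copy number; defaults to the analytic stage-1
#'   mean so that burn-in is short.
#' @return An `"scc_trajectory"` list: `series` (data frame with `time`,
#'   `stage`, `volume`, `number`, `concentration`, `generation`),
#'   `generations` (full model: data frame with `Vb`, `Vr`, `Vd`, `Trep`,
#'   `Tdiv`, `n_birth`, `n_div`), `division_times`, the `model` label and
#'   the profile used.
#' @export
simulate_lineage <- function(params, t_max = 1e4, sample_dt = 0.1,
                             model = c("full", "reduced"), seed = NULL,
                             burnin = 10, n_init = NULL) {
  model <- match.arg(model)
  p <- params
  if (!is.null(seed)) set.seed(seed)
  prof <- meanfield_profile(p)
  Tcycle <- log(2) / p$g
  if (t_max < (burnin + 5) * Tcycle)
    warning("t_max covers fewer than 5 cycles beyond burn-in", call. = FALSE)
  if (is.null(n_init)) {
    m <- factorial_moments(prof, lmax = 1)
    n_init <- max(0L, as.integer(round(m$m[[2]][1] / m$m[[1]][1])))
  }
  if (model == "full") {
    raw <- sim_full_cpp(p$g, p$rho, p$kappa, p$B, p$beta, p$d,
                        p$N, p$N0, p$alpha0, p$alpha1, p$a,
                        t_max, sample_dt, prof$Vb, n_init)
    ns <- raw$n_samples
    series <- data.frame(time = raw$time[seq_len(ns)],
                         stage = raw$stage[seq_len(ns)],
                         volume = raw$volume[seq_len(ns)],
                         number = raw$number[seq_len(ns)],
                         generation = raw$generation[seq_len(ns)])
    series$concentration <- series$number / series$volume
    gens <- data.frame(Vb = raw$gen_Vb, Vr = raw$gen_Vr, Vd = raw$gen_Vd,
                       t_birth = raw$gen_tb, Trep = raw$gen_Trep,
                       Tdiv = raw$gen_Tdiv, n_birth = raw$gen_nb,
                       n_div = raw$gen_nd)
    div_times <- raw$gen_tb + raw$gen_Tdiv
  } else {
    raw <- sim_reduced_cpp(prof$v, prof$q, prof$Bk, prof$rhok, p$d,
                           t_max, sample_dt, n_init)
    ns <- raw$n_samples
    series <- data.frame(time = raw$time[seq_len(ns)],
                         stage = raw$stage[seq_len(ns)],
                         volume = raw$volume[seq_len(ns)],
                         number = raw$number[seq_len(ns)],
                         generation = raw$generation[seq_len(ns)])
    series$concentration <- series$number / series$volume
    gens <- NULL
    # division times: generation counter increments
    inc <- which(diff(series$generation) > 0)
    div_times <- series$time[inc + 1]
  }
  burn_t <- burnin * Tcycle
  keep <- series$time >= burn_t
  series <- series[keep, , drop = FALSE]
  if (!is.null(gens)) gens <- gens[gens$t_birth >= burn_t, , drop = FALSE]
  div_times <- div_times[div_times >= burn_t]
  structure(list(series = series, generations = gens,
                 division_times = div_times, model = model,
                 profile = prof, params = p, sample_dt = sample_dt,
                 burnin = burnin, t_max = t_max),
            class = "scc_trajectory")
}

#' @export
print.scc_trajectory <- function(x, ...) {
  cat(sprintf("%s-model lineage: %d samples (dt = %g), %s generations\n",
              x$model, nrow(x$series), x$sample_dt,
              if (is.null(x$generations)) length(x$division_times)
              else nrow(x$generations)))
  invisible(x)
}

#' Exact stage waiting time sample
#'
#' Draws the time to the next stage transition for a cell of volume `V0`
#' growing exponentially at rate `g` under the hazard `(a V(t))^alpha`,
#' by inverse transform: `tau = log(1 + alpha*g*E/(a*V0)^alpha)/(alpha*g)`
#' with `E` standard exponential.  The implied generalized added size
#' `V0^alpha (e^(alpha g tau) - 1)` is exponential with mean
#' `alpha*g/a^alpha`.
#'
#' @param n number of draws.
#' @param V0 volume at stage entry.
#' @param alpha size-control strength.
#' @param a transition-rate constant.
#' @param g growth rate; `g = 0` gives the fixed-volume exponential clock.
#' @return Vector of waiting times.
#' @export
sample_stage_waiting_time <- function(n, V0, alpha, a, g) {
  E <- rexp(n)
  if (g == 0) return(E / (a * V0)^alpha)
  log1p(alpha * g * E / (a * V0)^alpha) / (alpha * g)
}

#' Binomial partitioning at division
#'
#' Each molecule is allocated to the followed daughter with probability
#' 1/2.
#'
#' @param n copy number(s) at division.
#' @return Daughter copy number(s), `Binomial(n, 1/2)`.
#' @export
partition_at_division <- function(n) rbinom(length(n), n, 0.5)

#' Parameters of the three-stage (telegraph + translation) model
#'
#' Gene switching between inactive and active states (`rho_act`
#' activation, `r` inactivation), transcription at rate `s * V^beta` per
#' active copy, translation at rate `u` per mRNA, and first-order decay of
#' mRNA (`v`) and protein (`d`).  Dosage compensation acts as a drop of
#' the per-copy activation rate from `rho_act` to `kappa*rho_act/2` at
#' replication.  In the bursty timescale regimes (`r >> rho_act` for mRNA,
#' `v >> d` for protein) this model reduces to the bursty model with burst
#' frequency `rho_act` and mean burst sizes `(s/r) V^beta` (mRNA) and
#' `(s u / (r v)) V^beta` (protein).
#'
#' @param cell an `"scc_params"` carrying the cell-size parameters
#'   (`g`, `N`, `N0`, `alpha0`, `alpha1`, `a`) and `kappa`, `beta`.
#' @param rho_act,r,s,u,v,d kinetic rates (all positive; `u`, `d` may be 0
#'   if the protein layer is not needed).
#' @return An `"scc_params3"` list.
#' @export
three_stage_params <- function(cell, rho_act, r, s, u = 0, v, d = 0) {
  stopifnot(rho_act > 0, r > 0, s > 0, v > 0, u >= 0, d >= 0)
  structure(list(cell = cell, rho_act = rho_act, r = r, s = s,
                 u = u, v = v, d = d),
            class = "scc_params3")
}

#' Simulate the three-stage model
#'
#' @param params3 an `"scc_params3"` from [three_stage_params()].
#' @param t_max,sample_dt,seed,burnin as in [simulate_lineage()].
#' @return An `"scc_trajectory"`-like list whose `series` has `mrna` and
#'   `protein` columns (plus their concentrations).
#' @export
simulate_three_stage <- function(params3, t_max = 1e4, sample_dt = 0.1,
                                 seed = NULL, burnin = 10) {
  if (!is.null(seed)) set.seed(seed)
  p <- params3$cell
  prof <- meanfield_profile(p)
  raw <- sim3_cpp(p$g, params3$rho_act, params3$r, params3$s, params3$u,
                  params3$v, params3$d, p$kappa, p$beta,
                  p$N, p$N0, p$alpha0, p$alpha1, p$a,
                  t_max, sample_dt, prof$Vb)
  ns <- raw$n_samples
  series <- data.frame(time = raw$time[seq_len(ns)],
                       stage = raw$stage[seq_len(ns)],
                       volume = raw$volume[seq_len(ns)],
                       mrna = raw$mrna[seq_len(ns)],
                       protein = raw$protein[seq_len(ns)],
                       generation = raw$generation[seq_len(ns)])
  series$mrna_conc <- series$mrna / series$volume
  series$protein_conc <- series$protein / series$volume
  burn_t <- burnin * log(2) / p$g
  series <- series[series$time >= burn_t, , drop = FALSE]
  structure(list(series = series, model = "three_stage", profile = prof,
                 params = params3, sample_dt = sample_dt),
            class = "scc_trajectory")
}
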