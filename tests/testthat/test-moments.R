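test_that("moment matrices have the documented structure", {
  # N = 2, equal rates: W_00 is the plain cyclic generator
  W0 <- moment_matrix(0, c(1, 1), d = 0.7)
  expect_equal(W0, matrix(c(-1, 1, 1, -1), 2, 2, byrow = TRUE))
  # l = 1, d = 0: corner halves, row sums (0, -1/2)
  W1 <- moment_matrix(1, c(1, 1), d = 0)
  expect_equal(W1[2, 1], 1 / 2)
  expect_equal(rowSums(W1), c(0, -1 / 2))
  # diagonal carries l*d
  W2 <- moment_matrix(2, c(3, 5), d = 0.25)
  expect_equal(diag(W2), c(-3.5, -5.5))
  expect_equal(W2[2, 1], 5 / 4)
})

test_that("stage occupancy matches the null-space of W_00", {
  expect_equal(stage_occupancy(rep(2.3, 7)), rep(1 / 7, 7))
  expect_equal(stage_occupancy(c(1, 2)), c(2 / 3, 1 / 3))
  set.seed(7)
  for (i in 1:5) {
    q <- runif(12, 0.5, 5)
    m0 <- stage_occupancy(q)
    # independent solve: null space of t(W00) with normalization
    W <- moment_matrix(0, q, d = 0)
    A <- t(W); A[12, ] <- 1
    m0_solve <- solve(A, c(rep(0, 11), 1))
    expect_equal(m0, m0_solve, tolerance = 1e-12)
    expect_lt(max(abs(m0 %*% W)), 1e-12)
  }
})

test_that("factorial moments recover known limits", {
  # balanced synthesis + perfect compensation: <c> = rho*B/d_eff within 1%
  p <- calibrate(small_params(N = 50, N0 = 21, beta = 1, kappa = 1, d = 1,
                              mean_number = 1000))
  prof <- meanfield_profile(p)
  st <- stage_stats(factorial_moments(prof, lmax = 2), prof)
  de <- derived_params(p, prof)
  meanc <- sum(st$mu * st$occupancy)
  expect_lt(abs(meanc - p$rho * p$B / de$d_eff) / meanc, 0.01)
  # stage variances approach the continuum value rho*B^2/d_eff in the
  # large-burst limit (the discreteness correction is of relative size 1/B_k)
  pv <- calibrate(small_params(N = 50, N0 = 21, beta = 1, kappa = 1, d = 1,
                               B = 100, mean_number = 4000))
  profv <- meanfield_profile(pv)
  stv <- stage_stats(factorial_moments(profv, lmax = 2), profv)
  dev_ <- derived_params(pv, profv)
  expect_lt(max(abs(stv$sigma2 - pv$rho * pv$B^2 / dev_$d_eff)) /
              (pv$rho * pv$B^2 / dev_$d_eff), 0.05)

  # fast degradation: per-stage quasi-steady state m1k/m0k -> rho_k B_k / d,
  # approached monotonically as eta = d/f grows
  errs <- vapply(c(10, 100, 1000), function(d) {
    p2 <- small_params(N = 10, N0 = 4, d = d, mean_volume = NULL,
                       mean_number = NULL)
    prof2 <- meanfield_profile(p2)
    st2 <- stage_stats(factorial_moments(prof2, lmax = 2), prof2)
    max(abs(st2$mu_n / (prof2$rhok * prof2$Bk / d) - 1))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)

  # rho -> 0: all moments with l >= 1 vanish (linearity in rho)
  p3 <- small_params(N = 20, N0 = 8, mean_volume = NULL, mean_number = NULL)
  p3$rho <- 1e-12
  m3 <- factorial_moments(meanfield_profile(p3), lmax = 2)
  expect_lt(sum(m3$m[[2]]), 1e-9)

  # copy-number Fano factor >= 1 (bursty production is overdispersed)
  for (pp in list(p, pv, small_params(N = 15, beta = 0.5, kappa = 1.4))) {
    prf <- meanfield_profile(pp)
    s <- stage_stats(factorial_moments(prf, lmax = 2), prf)
    expect_true(all(s$sigma2_n / s$mu_n >= 1 - 1e-8))
  }
})

test_that("time-averaged SSA moments match the recursion", {
  p <- calibrate(small_params(N = 20))
  prof <- meanfield_profile(p)
  m <- factorial_moments(prof, lmax = 1)
  tr <- simulate_lineage(p, t_max = 2e4, sample_dt = 0.2, model = "reduced",
                         seed = 99)
  n <- tr$series$number
  expect_lt(abs(mean(n) - sum(m$m[[2]])), 3 * block_sem(n))
  occ <- tabulate(tr$series$stage, p$N) / nrow(tr$series)
  expect_lt(max(abs(occ - m$m[[1]])), 0.005)
})

test_that("mixture distributions are normalized and hit easy limits", {
  p <- calibrate(small_params(N = 30))
  prof <- meanfield_profile(p)
  st <- stage_stats(factorial_moments(prof, lmax = 2), prof)
  mix <- lineage_concentration_distribution(st)
  x <- mixture_grid(mix)
  dx <- x[2] - x[1]
  expect_lt(abs(sum(dmixture(mix, x)) * dx - 1), 1e-4)

  nmix <- lineage_number_distribution(st)
  ns <- 0:(20 * sum(st$mu_n * st$occupancy))
  expect_lt(abs(sum(dmixture(nmix, ns)) - 1), 1e-8)

  # single-stage profile gives a plain negative binomial
  st1 <- list(mu_n = 10, sigma2_n = 30, occupancy = 1,
              mu = 10, sigma2 = 30)
  m1 <- lineage_number_distribution(st1)
  expect_equal(dmixture(m1, 0:50),
               dnbinom(0:50, size = 100 / 20, prob = 10 / 30))

  # sampling agrees with the analytic CDF
  set.seed(1)
  xs <- rmixture(mix, 2e4)
  expect_lt(max(abs(ecdf(xs)(x) - pmixture(mix, x))), 0.02)
})

test_that("perfect homeostasis collapses the mixture to a single gamma", {
  # large mean and large burst size: the classical gamma law with
  # shape rho/d_eff and scale B
  p <- calibrate(small_params(N = 50, N0 = 21, beta = 1, kappa = 1, d = 1,
                              B = 100, mean_number = 4000))
  prof <- meanfield_profile(p)
  st <- stage_stats(factorial_moments(prof, lmax = 2), prof)
  mix <- lineage_concentration_distribution(st)
  de <- derived_params(p, prof)
  shape <- p$rho / de$d_eff
  x <- mixture_grid(mix)
  dx <- x[2] - x[1]
  pm <- dmixture(mix, x); pm <- pm / (sum(pm) * dx)
  pg <- dgamma(x, shape = shape, rate = shape / (p$rho * p$B / de$d_eff))
  pg <- pg / (sum(pg) * dx)
  expect_lt(hellinger(pm, pg, dx), 0.01)
})

test_that("population weights solve the growth-rate condition", {
  # uniform rates: J = q (2^(1/N) - 1) in closed form
  for (N in c(1, 4, 9)) {
    pw <- population_weights(rep(3, N))
    expect_equal(pw$J, 3 * (2^(1 / N) - 1), tolerance = 1e-10)
    expect_equal(sum(pw$pi), 1)
  }
  expect_equal(population_weights(5)$pi, 1)

  set.seed(11)
  q <- runif(8, 0.5, 4)
  pw <- population_weights(q)
  # defining product equation
  expect_lt(abs(prod(q + pw$J) - 2 * prod(q)), 1e-8 * prod(q))
  # chained ratios: q_k pi_k - q_{k+1} pi_{k+1} = J pi_{k+1}; and the
  # division boundary 2 q_N pi_N - q_1 pi_1 = J pi_1
  expect_equal(q[-8] * pw$pi[-8] - q[-1] * pw$pi[-1], pw$J * pw$pi[-1],
               tolerance = 1e-10)
  expect_equal(2 * q[8] * pw$pi[8] - q[1] * pw$pi[1], pw$J * pw$pi[1],
               tolerance = 1e-10)

  # constant rates: younger stages are overrepresented (pi decreasing)
  pwc <- population_weights(rep(2, 10))
  expect_true(all(diff(pwc$pi) < 0))
})

test_that("population mixtures are normalized and reweighted versions", {
  p <- calibrate(small_params(N = 20))
  prof <- meanfield_profile(p)
  st <- stage_stats(factorial_moments(prof, lmax = 2), prof)
  pw <- population_weights(prof)
  pd <- population_distributions(st, pw)
  x <- mixture_grid(pd$concentration)
  dx <- x[2] - x[1]
  expect_lt(abs(sum(dmixture(pd$concentration, x)) * dx - 1), 1e-4)
  expect_equal(pd$concentration$weights, pw$pi)
  # population mean concentration differs from lineage (generically)
  lin <- lineage_concentration_distribution(st)
  expect_false(isTRUE(all.equal(pd$concentration$weights, lin$weights)))
})

test_that("truncated master equation confirms the moment pipeline", {
  p <- model_params(g = log(2) * 0.5, rho = 4, kappa = 2, B = 2, beta = 0.5,
                    d = 2, N = 4, N0 = 2, alpha0 = 1, alpha1 = 1, a = 1)
  prof <- meanfield_profile(p)
  pkn <- me_stationary(prof, p$d, 120)
  expect_lt(sum(pkn[, 121]), 1e-10)
  m0 <- rowSums(pkn)
  ns <- 0:120
  mu_me <- as.vector(pkn %*% ns) / m0
  v_me <- as.vector(pkn %*% ns^2) / m0 - mu_me^2
  mom <- factorial_moments(prof, lmax = 2)
  st <- stage_stats(mom, prof)
  expect_lt(max(abs(m0 / mom$m[[1]] - 1)), 0.005)
  expect_lt(max(abs(mu_me / st$mu_n - 1)), 0.005)
  expect_lt(max(abs(v_me / st$sigma2_n - 1)), 0.005)
  # mixture approximation close to the exact stationary pmf
  mix <- lineage_number_distribution(st)
  pn <- colSums(pkn)
  expect_lt(hellinger(pn / sum(pn), dmixture(mix, ns) / sum(dmixture(mix, ns))),
            0.05)
})
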