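test_that("stage waiting times have the exact generalized-added-size law", {
  set.seed(17)
  V0 <- 0.8; alpha <- 1.3; a <- 1.2; g <- 0.07
  tau <- sample_stage_waiting_time(1e5, V0, alpha, a, g)
  # generalized added size is exponential with mean alpha*g/a^alpha
  add <- V0^alpha * (exp(alpha * g * tau) - 1)
  m <- alpha * g / a^alpha
  expect_lt(abs(mean(add) - m), 3 * sd(add) / sqrt(length(add)))
  ks <- suppressWarnings(ks.test(add[1:1e4], pexp, rate = 1 / m))
  expect_gt(ks$p.value, 0.01)
  # g -> 0: plain exponential clock with rate (a V0)^alpha
  tau0 <- sample_stage_waiting_time(1e5, V0, alpha, a, 0)
  r <- (a * V0)^alpha
  expect_lt(abs(mean(tau0) - 1 / r), 3 * sd(tau0) / sqrt(length(tau0)))
})

test_that("binomial partitioning has the right moments", {
  expect_equal(partition_at_division(0), 0)
  set.seed(2)
  x <- partition_at_division(rep(100, 1e5))
  expect_lt(abs(mean(x) - 50), 3 * sd(x) / sqrt(1e5))
  expect_lt(abs(var(x) - 25), 1)
})

test_that("full-model generalized added volumes are Erlang distributed", {
  # gene expression switched nearly off so generations are cheap
  p <- small_params(N = 50, N0 = 20, rho = 0.01, d = 0,
                    mean_volume = NULL, mean_number = NULL)
  tr <- simulate_lineage(p, t_max = 5e4, sample_dt = 5, model = "full",
                         seed = 7)
  gens <- tr$generations
  expect_gt(nrow(gens), 4000)
  de <- derived_params(p, tr$profile)
  d0 <- gens$Vr^p$alpha0 - gens$Vb^p$alpha0
  expect_lt(abs(mean(d0) - de$M0), 3 * sd(d0) / sqrt(nrow(gens)))
  cv2 <- var(d0) / mean(d0)^2
  cv2_blocks <- vapply(split(d0, rep(1:20, length.out = length(d0))),
                       function(z) var(z) / mean(z)^2, 0)
  expect_lt(abs(cv2 - 1 / p$N0), 3 * sd(cv2_blocks) / sqrt(20))
  # post-replication phase likewise
  d1 <- gens$Vd^p$alpha1 - gens$Vr^p$alpha1
  expect_lt(abs(mean(d1) - de$M1), 3 * sd(d1) / sqrt(nrow(gens)))
  expect_lt(abs(var(d1) / mean(d1)^2 - 1 / (p$N - p$N0)), 0.2 / (p$N - p$N0))
  # volume records are ordered within each generation
  expect_true(all(gens$Vb < gens$Vr & gens$Vr < gens$Vd))
  expect_true(all(gens$Trep > 0 & gens$Tdiv > gens$Trep))
})

test_that("size-control regression recovers the effective strength", {
  for (al in list(c(1, 1), c(2, 0.5))) {
    p <- small_params(N = 50, N0 = 20, rho = 0.01, d = 0,
                      alpha0 = al[1], alpha1 = al[2],
                      mean_volume = NULL, mean_number = NULL)
    tr <- simulate_lineage(p, t_max = 3e4, sample_dt = 5, model = "full",
                           seed = 100 + al[1])
    fit <- size_control_fit(tr)
    ea <- effective_alpha(p, tr$profile)
    expect_lt(abs(fit$slope - ea$slope), 0.05)
  }
})

test_that("constitutive limit matches the analytic first moment", {
  # rho large, B small with rho*B fixed: constitutive expression
  p <- small_params(N = 20, N0 = 8, rho = 500, B = 0.02, d = 0,
                    mean_volume = NULL, mean_number = NULL)
  tr <- simulate_lineage(p, t_max = 5e3, sample_dt = 0.2, model = "full",
                         seed = 55)
  m <- factorial_moments(meanfield_profile(p), lmax = 1)
  n <- tr$series$number
  expect_lt(abs(mean(n) - sum(m$m[[2]])), 4 * block_sem(n))
})

test_that("identical seeds reproduce identical event sequences", {
  p <- calibrate(small_params(N = 15))
  a <- simulate_lineage(p, t_max = 500, sample_dt = 0.5, model = "full",
                        seed = 12)
  b <- simulate_lineage(p, t_max = 500, sample_dt = 0.5, model = "full",
                        seed = 12)
  expect_identical(a$series, b$series)
  expect_identical(a$generations, b$generations)
  c2 <- simulate_lineage(p, t_max = 500, sample_dt = 0.5, model = "full",
                         seed = 13)
  expect_false(identical(a$series$number, c2$series$number))
})

test_that("volume halves exactly at division and grows in between", {
  p <- calibrate(small_params(N = 15))
  tr <- simulate_lineage(p, t_max = 1000, sample_dt = 0.1, model = "full",
                         seed = 3, burnin = 0)
  s <- tr$series
  # within a generation volume is increasing; across the boundary it halves
  same <- diff(s$generation) == 0
  expect_true(all(diff(s$volume)[same] > 0))
  gens <- tr$generations
  expect_equal(gens$Vb[-1], gens$Vd[-nrow(gens)] / 2, tolerance = 1e-12)
})

test_that("reduced and full models converge as stages increase", {
  Ds <- vapply(c(10, 30), function(N) {
    p <- calibrate(small_params(N = N, N0 = round(0.4 * N)))
    trf <- simulate_lineage(p, t_max = 2e4, sample_dt = 0.2, model = "full",
                            seed = 200 + N)
    trr <- simulate_lineage(p, t_max = 2e4, sample_dt = 0.2,
                            model = "reduced", seed = 300 + N)
    hellinger_hist(trf$series$concentration, trr$series$concentration, 50)
  }, 0)
  expect_lt(Ds[2], Ds[1])
  # copy-number distributions agree closely already at moderate N
  p <- calibrate(small_params(N = 30))
  trf <- simulate_lineage(p, t_max = 2e4, sample_dt = 0.2, model = "full",
                          seed = 41)
  trr <- simulate_lineage(p, t_max = 2e4, sample_dt = 0.2, model = "reduced",
                          seed = 42)
  expect_lt(hellinger_hist(trf$series$number, trr$series$number, 50), 0.03)
})

test_that("three-stage model reduces to the bursty model in fast-switching limits", {
  # transcriptional bursting: r >> rho_act with s/r fixed (mRNA layer)
  cell <- model_params(g = log(2), rho = 20, kappa = 2, B = 0.2, beta = 1,
                       d = 10, N = 10, N0 = 2, alpha0 = 1, alpha1 = 1, a = 1)
  trb <- simulate_lineage(cell, t_max = 3000, sample_dt = 0.05,
                          model = "full", seed = 11)
  p3 <- three_stage_params(cell, rho_act = 20, r = 1000, s = 200, u = 0,
                           v = 10, d = 0)
  tr3 <- simulate_three_stage(p3, t_max = 3000, sample_dt = 0.05, seed = 12)
  nmax <- max(trb$series$number, tr3$series$mrna)
  pb <- tabulate(trb$series$number + 1, nmax + 1)
  pm <- tabulate(tr3$series$mrna + 1, nmax + 1)
  expect_lt(hellinger(pb / sum(pb), pm / sum(pm)), 0.05)

  # translational bursting: v >> d with u/v fixed (protein layer)
  cellp <- model_params(g = log(2), rho = 20, kappa = 2, B = 0.2, beta = 1,
                        d = 0.5, N = 10, N0 = 2, alpha0 = 1, alpha1 = 1,
                        a = 1)
  trbp <- simulate_lineage(cellp, t_max = 3000, sample_dt = 0.05,
                           model = "full", seed = 13)
  p3p <- three_stage_params(cellp, rho_act = 20, r = 1000, s = 200, u = 50,
                            v = 50, d = 0.5)
  tr3p <- simulate_three_stage(p3p, t_max = 3000, sample_dt = 0.05,
                               seed = 14)
  expect_lt(hellinger_hist(trbp$series$number, tr3p$series$protein, 40),
            0.05)

  # always-active gene: mRNA mean approaches the constitutive prediction
  p3c <- three_stage_params(cell, rho_act = 5000, r = 1, s = 20, u = 0,
                            v = 10, d = 0)
  tr3c <- simulate_three_stage(p3c, t_max = 2000, sample_dt = 0.05,
                               seed = 15)
  pc <- cell; pc$rho <- 2000; pc$B <- 20 / 2000; pc$d <- 10; pc$kappa <- 2
  mc <- factorial_moments(meanfield_profile(pc), lmax = 1)
  m3 <- tr3c$series$mrna
  expect_lt(abs(mean(m3) - sum(mc$m[[2]])),
            max(4 * block_sem(m3), 0.05 * sum(mc$m[[2]])))
})
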