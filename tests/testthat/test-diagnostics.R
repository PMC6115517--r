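# Simulation-based diagnostics: ensembles, NPDE, pcVPC, bootstrap, tables.

test_that("ensembles are seed-reproducible and validate K", {
  st <- simulate_study(small_design(), seed = 6)
  pars <- truth_params()
  e1 <- simulate_ensemble(pars, st, K = 20, seed = 3)
  e2 <- simulate_ensemble(pars, st, K = 20, seed = 3)
  expect_identical(e1$sim, e2$sim)
  e3 <- simulate_ensemble(pars, st, K = 20, seed = 4)
  expect_false(identical(e1$sim, e3$sim))
  expect_error(simulate_ensemble(pars, st, K = 1, seed = 1), "K")
})

test_that("degenerate variances collapse every replicate onto the population prediction", {
  st <- simulate_study(small_design(), seed = 6)
  degen <- pk_parameters(omega = c(0, 0, 0), sigma = 1e-12)
  en <- simulate_ensemble(degen, st, K = 5, seed = 1)
  for (k in 1:5) {
    expect_equal(unname(en$sim[k, ]), en$obs$PRED, tolerance = 1e-9)
  }
})

test_that("simulated log-concentration variance matches the delta-method decomposition", {
  st <- simulate_study(small_design(), seed = 6)
  pars <- truth_params()
  en <- simulate_ensemble(pars, st, K = 1000, seed = 2)
  # pick the observation with the largest prediction (rich signal)
  j <- which.max(en$obs$PRED)
  id <- en$obs$ID[j]
  ev <- st$events
  d <- ev[ev$ID == id & ev$EVID == 1, ]
  gr <- baclopk:::.cpp_logpred_grad(d$TIME, d$AMT, rep(1L, nrow(d)),
                                    en$obs$TIME[j], 11.6, 72.8, 1.64,
                                    c(0, 0, 0))
  expected <- sum(gr$J[1, ]^2 * pars$omega^2) + pars$sigma^2
  observed <- var(log(en$sim[, j]))
  expect_equal(observed, expected, tolerance = 0.15)
})

test_that("npde equals the brute-force marginal rank construction for independent rows", {
  # hand-built ensemble: 3 subjects x 1 observation each -> decorrelation
  # reduces to the marginal probability integral transform
  set.seed(9)
  K <- 40
  sim <- matrix(rlnorm(K * 3, log(100), 0.4), K, 3)
  obs <- data.frame(ID = 1:3, TIME = c(1, 2, 3),
                    DV = c(80, 120, 100), PRED = c(100, 100, 100),
                    TAD = c(1, 2, 3))
  en <- structure(list(sim = sim, obs = obs, K = K, seed = 9,
                       params = truth_params()), class = "pk_ensemble")
  nd <- npde(NULL, en)
  for (j in 1:3) {
    mu <- mean(sim[, j]); sdv <- sd(sim[, j])
    zs <- (sim[, j] - mu) / sdv
    zo <- (obs$DV[j] - mu) / sdv
    pd_manual <- min(max((sum(zs < zo) + 0.5 * sum(zs == zo)) / K,
                         1 / (2 * K)), 1 - 1 / (2 * K))
    expect_equal(nd$pd[j], pd_manual)
    expect_equal(nd$npde[j], qnorm(pd_manual))
  }
})

test_that("npde on self-simulated data is approximately standard normal", {
  st <- simulate_study(seed = 13)
  en <- simulate_ensemble(truth_params(), st, K = 300, seed = 13)
  nd <- npde(st, en)
  expect_lt(abs(mean(nd$npde)), 0.15)
  expect_lt(abs(var(nd$npde) - 1), 0.25)
  # an observation sitting at its simulated median has NPDE near 0
  j <- which.min(abs(nd$pd - 0.5))
  expect_lt(abs(nd$npde[j]), 0.05)
})

test_that("pcVPC percentiles are ordered and the correction is the identity under constant PRED", {
  st <- simulate_study(small_design(), seed = 7)
  en <- simulate_ensemble(truth_params(), st, K = 60, seed = 7)
  vp <- pc_vpc(st, en)
  expect_true(all(vp$obs_p5 <= vp$obs_p50 & vp$obs_p50 <= vp$obs_p95))
  expect_true(all(vp$p5_lo <= vp$p5_hi & vp$p50_lo <= vp$p50_hi &
                    vp$p95_lo <= vp$p95_hi))
  expect_true(all(vp$n >= 5))
  # constant PRED within bins -> correction factor 1 -> same as plain VPC
  en2 <- en
  en2$obs$PRED <- 100
  expect_equal(as.data.frame(pc_vpc(st, en2)),
               as.data.frame(pc_vpc(st, en2, correct = FALSE)))
})

test_that("bootstrap of a cloned-subject dataset has (near) zero CI width", {
  st <- simulate_study(small_design(), seed = 8)
  ev1 <- st$events[st$events$ID == 1, ]
  cov1 <- st$covariates[1, ]
  evs <- do.call(rbind, lapply(1:20, function(j) transform(ev1, ID = j)))
  covs <- do.call(rbind, lapply(1:20, function(j) transform(cov1, ID = j)))
  covs$GRP <- 1
  clone <- pk_study(evs, covs)
  fit <- pk_fit(clone, settings = pk_settings(compute_se = FALSE))
  bt <- bootstrap_ci(clone, fit, B = 50, seed = 2)
  expect_lt(bt$ci["tvcl", "hi"] - bt$ci["tvcl", "lo"], 1e-4)
})

test_that("bootstrap resamples are seed-deterministic and stratified", {
  st <- simulate_study(small_design(), seed = 9)
  fit <- pk_fit(st, settings = pk_settings(compute_se = FALSE))
  b1 <- bootstrap_ci(st, fit, B = 50, seed = 5)
  b2 <- bootstrap_ci(st, fit, B = 50, seed = 5)
  expect_identical(b1$estimates, b2$estimates)
  expect_identical(b1$ci, b2$ci)
  expect_error(bootstrap_ci(st, fit, B = 10, seed = 1), "B must")
})

test_that("prediction tables: CPRED = IPRED without BSV, and conditioning helps", {
  st <- simulate_study(small_design(), seed = 10)
  # no BSV: individual and population predictions coincide
  gen0 <- pk_parameters(omega = c(0, 0, 0), sigma = 0.24)
  st0 <- simulate_study(small_design(), gen0, seed = 10)
  fit0 <- pk_fit(st0, init = pk_parameters(tvcl = 10, tvv = 60, tvka = 1.2,
                                           omega = c(0, 0, 0), sigma = 0.3),
                 settings = pk_settings(compute_se = FALSE))
  pt0 <- prediction_tables(fit0, st0)
  expect_equal(pt0$CPRED, pt0$IPRED, tolerance = 1e-10)
  # with BSV, individual predictions absorb subject effects
  fit <- pk_fit(st, settings = pk_settings(compute_se = FALSE))
  pt <- prediction_tables(fit, st)
  r_ipred <- log(pt$DV) - log(pt$IPRED)
  r_cpred <- log(pt$DV) - log(pt$CPRED)
  expect_lt(var(r_ipred), var(r_cpred))
  # calibration: regression of log DV on log IPRED has slope near 1
  slope <- coef(lm(log(pt$DV) ~ log(pt$IPRED)))[2]
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})
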