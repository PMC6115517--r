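# FOCE-I engine: Gaussian oracles, engine equivalence, recovery, contracts.

test_that("reference objective equals the exact Gaussian marginal for an eta-linear model", {
  set.seed(7)
  omega2 <- 0.25
  sigma2 <- 0.09
  subjects <- lapply(1:8, function(i) {
    n <- sample(3:6, 1)
    y <- rnorm(n, 1.5, 0.7)
    list(y = y, f = function(eta) rep(1.5 + eta, n))
  })
  ref <- foce_ofv_reference(subjects, omega2, sigma2)
  exact <- sum(vapply(subjects, function(s) {
    n <- length(s$y)
    exact_gaussian_m2ll(s$y, matrix(1, n, 1), rep(1.5, n), omega2, sigma2)
  }, 1))
  expect_lt(abs(ref$ofv - exact) / abs(exact), 1e-6)
})

test_that("conditional modes match the ridge/posterior closed form on a linear model", {
  set.seed(8)
  omega2 <- 0.16
  sigma2 <- 0.04
  y <- rnorm(5, 0.8, 0.5)
  res <- foce_ofv_reference(list(list(y = y, f = function(e) rep(e, 5))),
                            omega2, sigma2)
  closed <- sum(y) / sigma2 / (5 / sigma2 + 1 / omega2)
  expect_equal(res$eta[1, 1], closed, tolerance = 1e-6)
})

test_that("the C++ engine agrees with the model-agnostic reference on study data", {
  st <- fixture_study(3)
  pars <- truth_params()
  ofv_engine <- pk_ofv(st, pars)
  ev <- st$events
  subjects <- lapply(unique(ev$ID), function(id) {
    d <- ev[ev$ID == id & ev$EVID == 1, ]
    o <- ev[ev$ID == id & ev$EVID == 0 & ev$MDV == 0, ]
    reg <- data.frame(time = d$TIME, amt = d$AMT)
    ot <- o$TIME
    list(y = log(o$DV / 1000),
         f = function(e) {
           log(pmax(conc_profile(reg, ot, 11.6 * exp(e[1]),
                                 72.8 * exp(e[2]),
                                 1.64 * exp(e[3])) / 1000, 1e-12))
         })
  })
  ref <- foce_ofv_reference(subjects, pars$omega^2, pars$sigma^2)
  expect_lt(abs(ofv_engine - ref$ofv) / abs(ref$ofv), 1e-6)
})

test_that("OFV is additive over subjects", {
  st <- fixture_study(2)
  pars <- truth_params()
  one <- pk_ofv(st, pars)
  ev2 <- st$events
  ev2$ID <- ev2$ID + 1000
  cov2 <- st$covariates
  cov2$ID <- cov2$ID + 1000
  doubled <- pk_study(rbind(st$events, ev2), rbind(st$covariates, cov2))
  expect_equal(pk_ofv(doubled, pars), 2 * one, tolerance = 1e-10)
})

test_that("analytic outer gradient matches finite differences", {
  st <- fixture_study(2)
  ef <- list(covariate_effect("cl", "WT", "power",
                              ref = median(st$covariates$WT)))
  fd <- baclopk:::build_fit_data(st, ef)
  init <- pk_parameters(tvcl = 10, tvv = 60, tvka = 1.3,
                        omega = c(0.25, 0.3, 0.35), sigma = 0.27,
                        cov_coeffs = c(0.4))
  ps <- baclopk:::make_parspec(init, ef, pk_settings())
  obj <- baclopk:::make_objective(fd, ef, ps)
  gr <- baclopk:::make_gradient(fd, ef, ps)
  par0 <- ps$start
  ga <- gr(par0)
  h <- 1e-6
  gn <- vapply(seq_along(par0), function(j) {
    ep <- em <- par0
    ep[j] <- ep[j] + h
    em[j] <- em[j] - h
    (obj(ep) - obj(em)) / (2 * h)
  }, 1)
  expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1)), 1e-4)
})

test_that("vanishing omega forces the conditional modes to zero", {
  st <- fixture_study(2)
  tiny <- pk_parameters(omega = c(1e-6, 1e-6, 1e-6))
  eta <- map_etas(st, tiny)
  expect_lt(max(abs(eta)), 1e-6)
})

test_that("theta is recovered to < 0.1% from near-noise-free data with variances fixed", {
  design <- small_design()
  gen <- pk_parameters(omega = c(0, 0, 0), sigma = 1e-6)
  st <- simulate_study(design, gen, seed = 11)
  init <- pk_parameters(tvcl = 9, tvv = 55, tvka = 1.1, omega = c(0, 0, 0),
                        sigma = 1e-6)
  fit <- pk_fit(st, init = init,
                settings = pk_settings(compute_se = FALSE,
                                       fix_sigma = TRUE))
  expect_lt(abs(fit$params$theta["tvcl"] - 11.6) / 11.6, 1e-3)
  expect_lt(abs(fit$params$theta["tvv"] - 72.8) / 72.8, 1e-3)
  expect_lt(abs(fit$params$theta["tvka"] - 1.64) / 1.64, 1e-3)
})

test_that("fitting is deterministic and invariant to subject relabeling", {
  st <- fixture_study(4)
  f1 <- pk_fit(st, settings = pk_settings(compute_se = FALSE))
  f2 <- pk_fit(st, settings = pk_settings(compute_se = FALSE))
  expect_identical(f1$ofv, f2$ofv)
  expect_identical(coef(f1), coef(f2))
  # relabel subjects (reversed IDs, reordered rows)
  ev <- st$events
  cov <- st$covariates
  remap <- setNames(rev(sort(unique(ev$ID))), sort(unique(ev$ID)))
  ev$ID <- unname(remap[as.character(ev$ID)])
  cov$ID <- unname(remap[as.character(cov$ID)])
  ev <- ev[order(ev$ID, ev$TIME, -ev$EVID), ]
  cov <- cov[order(cov$ID), ]
  f3 <- pk_fit(pk_study(ev, cov), settings = pk_settings(compute_se = FALSE))
  expect_equal(coef(f3), coef(f1), tolerance = 1e-5)
})

test_that("eta shrinkage: formula variants, bounds, and sparse > rich", {
  fit <- fixture_fit(1)
  sh_sd <- eta_shrinkage(fit, "sd")
  sh_var <- eta_shrinkage(fit, "var")
  expect_true(all(sh_sd >= 0 & sh_sd <= 1))
  # variance form shrinks harder than SD form when shrinkage is nonzero
  expect_true(all(sh_var >= sh_sd - 1e-12))
  # rich sampling recovers etas better than the sparse design: compare the
  # spread of conditional modes on the same subjects and generating etas
  st <- fixture_study(1)
  pars <- truth_params()
  eta_sparse <- map_etas(st, pars)
  rich_times <- seq(72.25, 95.75, by = 0.8)  # ~30 samples after run-in
  ev <- st$events
  rich_rows <- lapply(unique(ev$ID), function(id) {
    d <- ev[ev$ID == id & ev$EVID == 1, ]
    tr <- st$truth
    i <- match(id, st$covariates$ID)
    f <- conc_profile(data.frame(time = d$TIME, amt = d$AMT), rich_times,
                      11.6 * exp(tr$eta[i, 1]), 72.8 * exp(tr$eta[i, 2]),
                      1.64 * exp(tr$eta[i, 3]))
    set.seed(1000 + id)
    y <- f * exp(rnorm(length(f)) * pars$sigma)
    rbind(d[, c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "BLQ")],
          data.frame(ID = id, TIME = rich_times, AMT = NA, DV = round(y, 2),
                     EVID = 0L, MDV = 0L, BLQ = 0L))
  })
  rich_ev <- do.call(rbind, rich_rows)
  rich_ev <- rich_ev[order(rich_ev$ID, rich_ev$TIME, -rich_ev$EVID), ]
  rich <- pk_study(rich_ev, st$covariates)
  eta_rich <- map_etas(rich, pars)
  truth_eta <- st$truth$eta
  for (k in 1:3) {
    shr_sparse <- 1 - sd(eta_sparse[, k]) / pars$omega[k]
    shr_rich <- 1 - sd(eta_rich[, k]) / pars$omega[k]
    if (shr_sparse > 0.2) {
      # strictly less shrinkage under rich sampling where the sparse design
      # shrinks materially (V, Ka); for a parameter the sparse design
      # already determines well (CL), the SD ratio is dominated by
      # estimation noise, which inflates SD(eta-hat) and masks shrinkage,
      # so the paired comparison is made on recovery error instead
      expect_lt(shr_rich, shr_sparse)
    }
    rmse_sparse <- sqrt(mean((eta_sparse[, k] - truth_eta[, k])^2))
    rmse_rich <- sqrt(mean((eta_rich[, k] - truth_eta[, k])^2))
    expect_lt(rmse_rich, rmse_sparse * 1.05)
  }
})

test_that("standard errors: scale-free RSE and informative failure diagnostics", {
  fit <- pk_fit(fixture_study(1))
  expect_true(fit$se_ok)
  rse <- fit$rse
  expect_true(all(rse[c("tvcl", "tvv", "tvka")] > 0))
  # sparse design: CL best determined, Ka worst (matches the study's 3/5/10)
  expect_lt(rse["tvcl"], rse["tvka"])
})
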