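# Clinical covariate formulas, LRT thresholds, pooling, stepwise search.

test_that("Cockcroft-Gault reproduces hand arithmetic and the sex multiplier", {
  expect_equal(cockcroft_gault(40, 72, 1.0, "male"), 100)
  expect_equal(cockcroft_gault(55, 80, 1.2, "female"),
               0.85 * cockcroft_gault(55, 80, 1.2, "male"))
  expect_equal(cockcroft_gault(140, 72, 1.0, 0), 0)
  expect_error(cockcroft_gault(40, 72, 0, 0), "creatinine")
})

test_that("BMI and James lean body mass behave physiologically", {
  dc <- derived_covariates(80, 2.0, "male")
  expect_equal(dc$bmi, 20)
  expect_identical(attr(dc, "lbm_formula"), "James")
  # LBM bounded by weight over a physiologic grid, both sexes
  grid <- expand.grid(wt = seq(40, 150, by = 10), ht = seq(1.4, 2.1, by = 0.1),
                      sex = c(0, 1))
  dcg <- derived_covariates(grid$wt, grid$ht, grid$sex)
  expect_true(all(dcg$lbm <= grid$wt))
  # BMI dimensional identity
  expect_equal(derived_covariates(80 * 1.21, 2.0 * 1.1, 0)$bmi, 20)
})

test_that("LRT thresholds reproduce 3.84 / 10.8 / 16.3 and the chi-square quantile", {
  expect_equal(lrt_threshold(1, 0.05), 3.84)
  expect_equal(lrt_threshold(1, 0.001), 10.8)
  expect_equal(lrt_threshold(3, 0.001), 16.3)
  for (df in 1:4) {
    for (a in c(0.05, 0.01, 0.001)) {
      expect_equal(lrt_threshold(df, a, rounded = FALSE), qchisq(1 - a, df),
                   tolerance = 1e-4)
    }
  }
  expect_error(lrt_threshold(0, 0.05), "df")
  expect_error(lrt_threshold(1, 1.5), "alpha")
})

test_that("rare categorical levels are pooled to >= 10% or the covariate dropped", {
  x <- c(rep(1, 40), rep(2, 40), rep(3, 3))
  pool <- pool_rare_levels(x)
  expect_false(pool$dropped)
  merged <- unname(pool$map[as.character(x)])
  expect_true(all(table(merged) / length(x) >= 0.10))
  # a two-level covariate with one rare level collapses entirely
  y <- c(rep(0, 95), rep(1, 5))
  expect_true(pool_rare_levels(y)$dropped)
  # property over random draws
  set.seed(5)
  for (i in 1:20) {
    z <- sample(1:5, 200, replace = TRUE, prob = runif(5)^2)
    pz <- pool_rare_levels(z)
    if (!pz$dropped) {
      mz <- unname(pz$map[as.character(z)])
      expect_true(all(table(mz) / length(z) >= 0.10))
    }
  }
})

test_that("covariate effect degrees of freedom follow the form", {
  expect_equal(covariate_effect("cl", "WT", "power", ref = 75)$df, 1L)
  expect_equal(covariate_effect("cl", "SEX", "categorical", ref = 0)$df, 1L)
  expect_equal(covariate_effect("cl", "GRP", "multilevel",
                                levels = 1:4, ref = 3)$df, 3L)
  expect_error(covariate_effect("cl", "WT", "power"), "reference")
})

test_that("the default candidate set spans the declared search space", {
  st <- fixture_study(1)
  cands <- default_candidates(st)
  labs <- vapply(cands, function(e) paste0(e$param, "~", e$covariate), "")
  expect_true(all(c("cl~WT", "cl~AGE", "cl~CRCL", "cl~DOSE", "cl~GRP",
                    "cl~SEX", "v~WT", "v~SEX", "ka~DOSE", "ka~NINT")
                  %in% labs))
  grp <- cands[[which(labs == "cl~GRP")]]
  expect_equal(grp$df, 3L)
  # reference = modal level, lowest on ties: groups 3 and 4 both have 16
  expect_equal(grp$ref, 3)
})

test_that("forward step with no candidates returns the base model unchanged", {
  fit <- fixture_fit(1)
  fw <- forward_step(fixture_study(1), fit, list())
  expect_identical(fw$fit$ofv, fit$ofv)
  expect_length(fw$effects, 0)
})

test_that("a strong generated weight effect on CL is found by forward selection", {
  ef <- list(covariate_effect("cl", "WT", "power", ref = 75))
  gen <- pk_parameters(cov_coeffs = c(0.75))
  st <- simulate_study(params = gen, effects = ef, seed = 21)
  base <- pk_fit(st, settings = pk_settings(compute_se = FALSE))
  cands <- list(covariate_effect("cl", "WT", "power",
                                 ref = median(st$covariates$WT)),
                covariate_effect("cl", "SEX", "categorical", ref = 0))
  fw <- forward_step(st, base, cands)
  labs <- vapply(fw$effects, function(e) paste0(e$param, "~", e$covariate), "")
  expect_true("cl~WT" %in% labs)
  est <- fw$fit$params$cov_coeffs["cl~WT"]
  expect_equal(unname(est), 0.75, tolerance = 0.35)
  # and survives the stricter backward threshold
  bw <- backward_step(st, fw$fit)
  labs2 <- vapply(bw$effects, function(e) paste0(e$param, "~", e$covariate), "")
  expect_true("cl~WT" %in% labs2)
})

test_that("backward elimination drops a null covariate and keeps a bare model intact", {
  st <- fixture_study(1)
  base <- fixture_fit(1)
  # identity on a model with no covariates
  bw0 <- backward_step(st, base)
  expect_identical(bw0$fit$ofv, base$ofv)
  # a covariate fitted on null data carries ~0 OFV and is eliminated
  ef <- list(covariate_effect("cl", "AGE", "power",
                              ref = median(st$covariates$AGE)))
  full <- pk_fit(st, init = baclopk:::extend_init(base, ef), effects = ef,
                 settings = pk_settings(compute_se = FALSE))
  bw <- backward_step(st, full)
  expect_length(bw$effects, 0)
  expect_match(bw$log[1], "removed cl~AGE")
})
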