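# Virtual-study generator: design fidelity, determinism, distributions.

test_that("generated subjects respect the demographic design", {
  covtab <- generate_subjects(seed = 17)
  expect_equal(nrow(covtab), 57)
  expect_equal(as.vector(table(covtab$GRP)), c(10, 15, 16, 16))
  # group 1 ages within the observed range
  g1 <- covtab[covtab$GRP == 1, ]
  expect_true(all(g1$AGE >= 42.2 & g1$AGE <= 75.0))
  # renal exclusion respected
  expect_true(all(covtab$CRCL > 30))
  # derived covariates are consistent with the recorded ones
  dc <- derived_covariates(covtab$WT, covtab$HT / 100, covtab$SEX)
  expect_equal(covtab$BMI, round(dc$bmi, 2), tolerance = 0.02)
  # determinism
  expect_identical(covtab, generate_subjects(seed = 17))
})

test_that("the female fraction matches the study's 33.3% over many subjects", {
  big <- study_design(group_n = c(10, 15, 16, 16) * 9)  # 513 subjects
  covtab <- generate_subjects(big, seed = 23)
  expect_equal(mean(covtab$SEX), 19 / 57, tolerance = 0.05)
})

test_that("regimens respect dose ranges, conservation and the 4 h gap", {
  set.seed(NULL)
  for (s in 1:50) {
    g <- 1 + (s %% 4)
    reg <- generate_regimen(group = g, seed = s)
    daily <- attr(reg, "daily_dose")
    rng <- list(c(30, 50), c(60, 120), c(130, 180), c(190, 300))[[g]]
    expect_gte(daily, rng[1])
    expect_lte(daily, rng[2])
    # per-day amounts sum exactly to the daily dose
    day1 <- reg[reg$time < 24, ]
    expect_equal(sum(day1$amt), daily)
    # minimum inter-dose gap >= 4 h including the overnight wrap
    gaps <- diff(reg$time)
    expect_true(all(gaps >= 4 - 1e-9))
    expect_true(all(reg$amt > 0))
  }
})

test_that("sampling schedules give 9-10 windowed samples per subject", {
  for (s in 1:30) {
    reg <- generate_regimen(group = 1 + (s %% 4), seed = s)
    st <- sampling_times(reg, seed = 100 + s)
    expect_true(nrow(st) %in% c(9, 10))
    tN <- attr(reg, "t_N")
    gap <- attr(reg, "gap")
    tags <- split(st$time, st$tag)
    expect_true(all(tags[["preN"]] < tN & tags[["preN"]] > tN - 0.5))
    expect_true(all(tags[["N+0-1"]] - tN > 0 & tags[["N+0-1"]] - tN < 1))
    expect_true(all(tags[["N+1-2"]] - tN > 1 & tags[["N+1-2"]] - tN < 2))
    expect_true(all(tags[["N+2-3"]] - tN > 2 & tags[["N+2-3"]] - tN < 3))
    expect_true(all(tags[["N+3+"]] - tN > 3 & tags[["N+3+"]] - tN < gap))
    expect_true(all(abs(tags[["D2-trough"]] - (tN + 24)) < 0.5))
    # two late samples only when the interval leaves >= 2 h past the 3 h mark
    expect_equal(length(tags[["N+3+"]]), if (gap - 3 >= 2) 2L else 1L)
  }
})

test_that("a 57-subject study brackets the published observation count", {
  for (s in c(31, 32, 33)) {
    st <- simulate_study(seed = s)
    nobs <- sum(st$events$EVID == 0)
    expect_gte(nobs, 513)
    expect_lte(nobs, 570)
    persub <- table(st$events$ID[st$events$EVID == 0])
    expect_true(all(persub %in% 9:10))
  }
})

test_that("noise-free simulation reproduces the population prediction exactly", {
  gen <- pk_parameters(omega = c(0, 0, 0), sigma = 1e-12)
  st <- simulate_study(small_design(), gen, seed = 3)
  ev <- st$events
  for (id in unique(ev$ID)) {
    d <- ev[ev$ID == id & ev$EVID == 1, ]
    o <- ev[ev$ID == id & ev$EVID == 0 & ev$MDV == 0, ]
    f <- conc_profile(data.frame(time = d$TIME, amt = d$AMT), o$TIME,
                      11.6, 72.8, 1.64)
    expect_equal(o$DV, round(f, 2), tolerance = 1e-8)
  }
})

test_that("BLQ censoring is rare at the generating parameters and is flagged coherently", {
  st <- simulate_study(seed = 37)
  ev <- st$events[st$events$EVID == 0, ]
  expect_lt(mean(ev$BLQ), 0.10)
  expect_true(all(is.na(ev$DV[ev$BLQ == 1])))
  expect_true(all(ev$MDV[ev$BLQ == 1] == 1))
  expect_true(all(ev$DV[ev$BLQ == 0] >= 5))
})

test_that("between-subject clearance variability reproduces the ~21% CV", {
  big <- study_design(group_n = c(10, 15, 16, 16) * 9)
  st <- simulate_study(big, seed = 41)
  cl_i <- 11.6 * exp(st$truth$eta[, "cl"])
  expect_equal(100 * sd(cl_i) / mean(cl_i), 21, tolerance = 2)
})

test_that("the truth record regenerates every noise-free concentration", {
  st <- simulate_study(small_design(), seed = 5)
  tr <- st$truth
  ev <- st$events
  ids <- st$covariates$ID
  for (i in seq_along(ids)) {
    d <- ev[ev$ID == ids[i] & ev$EVID == 1, ]
    o <- ev[ev$ID == ids[i] & ev$EVID == 0, ]
    f <- conc_profile(data.frame(time = d$TIME, amt = d$AMT), o$TIME,
                      11.6 * exp(tr$eta[i, 1]), 72.8 * exp(tr$eta[i, 2]),
                      1.64 * exp(tr$eta[i, 3]))
    expect_equal(f, tr$pred[[i]], tolerance = 1e-12)
    y <- tr$pred[[i]] * exp(tr$eps[[i]])
    quant <- o$BLQ == 0
    expect_equal(o$DV[quant], round(y[quant], 2), tolerance = 1e-9)
  }
})

test_that("whole-study simulation is reproducible from the master seed", {
  s1 <- simulate_study(seed = 99)
  s2 <- simulate_study(seed = 99)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$covariates, s2$covariates)
  expect_identical(s1$truth$eta, s2$truth$eta)
})
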