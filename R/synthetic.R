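#' Sparse-sampling steady-state study design
#'
#' Describes the four-dose-group trial the generator emulates: 57 completers
#' (10/15/16/16 by dose range <60 / 60-120 / >120-180 / >180 mg/day), usual
#' regimens of 2-8 daily intakes continued unchanged through a 72 h run-in
#' (steady state: > 16 half-lives), then 9-10 samples per subject drawn in
#' fixed windows around two consecutive intakes on the sampling day plus a
#' next-morning trough, with a 5 ng/mL lower limit of quantification.
#'
#' Group-level dose, intake, age and sex distributions are the observed
#' study demographics; weight, height, serum creatinine and the liver-panel
#' covariates, which the source tables do not characterise, use documented
#' adult defaults (see the package vignette) and are configurable here.
#' Intakes per day are capped at 6 because a repeating daily schedule cannot
#' keep 4 h between consecutive intakes beyond that.
#'
#' @param group_n subjects per dose group
#' @param dose,intakes,age per-group `list(mean, sd, min, max)` truncated
#'   normal specifications
#' @param female_frac per-group probability a subject is female
#' @param wt,ht,crea,pt,bili,ast,alt `list(mean, sd, min, max, male_shift)`
#'   covariate distributions (male_shift added to the mean for males)
#' @param lloq lower limit of quantification (ng/mL)
#' @param run_in pre-observation dosing history (h)
#' @param missing_rate per-sample probability a scheduled draw is missed
#' @return object of class `pk_design`
#' @export
study_design <- function(
    group_n = c(10, 15, 16, 16),
    dose = list(c(37.00, 9.49, 30, 50), c(93.33, 21.93, 60, 120),
                c(163.13, 17.78, 130, 180), c(250.63, 39.41, 190, 300)),
    intakes = list(c(2.80, 0.63, 2, 4), c(3.40, 0.74, 2, 5),
                   c(3.44, 1.15, 2, 7), c(3.94, 1.48, 2, 8)),
    age = list(c(56.75, 9.83, 42.2, 75.0), c(44.80, 13.21, 23.4, 66.1),
               c(45.16, 11.29, 25.6, 68.7), c(43.97, 9.16, 33.8, 59.4)),
    female_frac = c(0.500, 0.200, 0.3125, 0.375),
    wt = list(75, 15, 45, 130, 5), ht = list(170, 10, 150, 200, 8),
    crea = list(0.9, 0.2, 0.5, 1.6, 0.1),
    pt = list(95, 10, 60, 120, 0), bili = list(0.7, 0.3, 0.2, 2.0, 0),
    ast = list(40, 20, 10, 150, 0), alt = list(35, 20, 8, 150, 0),
    lloq = 5, run_in = 72, missing_rate = 0) {
  stopifnot(length(group_n) == length(dose), length(dose) == length(intakes),
            length(intakes) == length(age),
            length(age) == length(female_frac))
  structure(list(group_n = group_n, dose = dose, intakes = intakes,
                 age = age, female_frac = female_frac,
                 wt = wt, ht = ht, crea = crea, pt = pt, bili = bili,
                 ast = ast, alt = alt, lloq = lloq, run_in = run_in,
                 missing_rate = missing_rate),
            class = "pk_design")
}

#' @export
print.pk_design <- function(x, ...) {
  cat("Sparse-sampling steady-state PK study design\n")
  cat("  groups:", paste(x$group_n, collapse = "/"),
      "subjects; LLOQ", x$lloq, "ng/mL; run-in", x$run_in, "h\n")
  invisible(x)
}

#' @noRd
draw_trunc <- function(spec, male) {
  m <- spec[[1]] + if (male) (spec[[5]] %||% 0) else 0
  rtruncnorm(1, m, spec[[2]], spec[[3]], spec[[4]])
}

#' Generate the per-subject covariate table
#'
#' Draws age (truncated normal, per-group demographics), sex (per-group
#' female fraction), weight/height/serum creatinine and liver-panel values
#' (documented defaults), derives BMI and lean body mass, and computes
#' Cockcroft-Gault creatinine clearance, resampling serum creatinine if a
#' draw lands at or below 30 mL/min (the trial's renal exclusion
#' criterion). Daily dose and intakes/day are drawn through the same
#' per-subject regimen substream used by [simulate_study()], so the table
#' and the dosing events always agree.
#'
#' All randomness derives from `seed` via per-subject substreams, so the
#' table for subject i is invariant to the other subjects.
#'
#' @param design a [study_design()]
#' @param seed master seed (integer)
#' @return data.frame with one row per subject: ID, GRP, DOSE, NINT, SEX
#'   (0 male / 1 female), WT, HT (cm), AGE, BMI, LBM, CRCL, CREA, PT, BILI,
#'   AST, ALT
#' @export
generate_subjects <- function(design = study_design(), seed = 1) {
  n <- sum(design$group_n)
  grp <- rep(seq_along(design$group_n), design$group_n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- grp[i]
    set.seed(substream_seed(seed, i * 7L + 1L))
    age <- rtruncnorm(1, design$age[[g]][1], design$age[[g]][2],
                      design$age[[g]][3], design$age[[g]][4])
    female <- runif(1) < design$female_frac[g]
    male <- !female
    wtv <- draw_trunc(design$wt, male)
    htv <- draw_trunc(design$ht, male)
    creav <- draw_trunc(design$crea, male)
    ptv <- draw_trunc(design$pt, male)
    biliv <- draw_trunc(design$bili, male)
    astv <- draw_trunc(design$ast, male)
    altv <- draw_trunc(design$alt, male)
    crcl <- cockcroft_gault(age, wtv, creav, as.numeric(female))
    tries <- 0
    while (crcl <= 30 && tries < 100) {
      creav <- draw_trunc(design$crea, male)
      crcl <- cockcroft_gault(age, wtv, creav, as.numeric(female))
      tries <- tries + 1
    }
    if (crcl <= 30) stop_bad("could not satisfy CRCL > 30 for subject ", i)
    reg <- generate_regimen(design, g, substream_seed(seed, i * 7L + 2L))
    dc <- derived_covariates(wtv, htv / 100, as.numeric(female))
    rows[[i]] <- data.frame(
      ID = i, GRP = g, DOSE = attr(reg, "daily_dose"),
      NINT = attr(reg, "n_intakes"), SEX = as.numeric(female),
      WT = round(wtv, 1), HT = round(htv, 1), AGE = round(age, 1),
      BMI = round(dc$bmi, 2), LBM = round(dc$lbm, 2),
      CRCL = round(crcl, 1), CREA = round(creav, 2), PT = round(ptv, 1),
      BILI = round(biliv, 2), AST = round(astv, 1), ALT = round(altv, 1))
  }
  do.call(rbind, rows)
}

#' Generate one subject's dosing history
#'
#' Draws the total daily dose (truncated normal per dose group, rounded to
#' 10 mg) and the number of daily intakes (truncated discrete normal, capped
#' at 6 so consecutive intakes stay >= 4 h apart on a repeating schedule,
#' and at one intake per 10 mg so unit doses exist). The daily dose is split
#' equally across intakes in 10-mg units with the remainder on the first
#' intake, intakes are spread evenly over the 24 h cycle (identical schedule
#' each day), and the history covers the 72 h run-in, the sampling day, and
#' the next-morning dose.
#'
#' @param design a [study_design()]
#' @param group dose group (1-4)
#' @param seed integer seed
#' @return data.frame with columns `time` (h since first dose) and `amt`
#'   (mg); attributes `daily_dose`, `n_intakes`, `gap` (h), `t_N`, `t_n`
#'   (times of the two sampling-day reference doses)
#' @export
generate_regimen <- function(design = study_design(), group = 1, seed = 1) {
  stopifnot(group %in% seq_along(design$group_n))
  set.seed(seed)
  d <- design$dose[[group]]
  daily <- 10 * round(rtruncnorm(1, d[1], d[2], d[3], d[4]) / 10)
  daily <- min(max(daily, 10 * ceiling(d[3] / 10)), 10 * floor(d[4] / 10))
  it <- design$intakes[[group]]
  m <- round(rtruncnorm(1, it[1], it[2], it[3] - 0.49, it[4] + 0.49))
  m <- max(2L, min(m, 6L, as.integer(daily / 10)))
  gap <- 24 / m
  base <- 10 * (daily %/% 10 %/% m)
  amt <- rep(base, m)
  amt[1] <- amt[1] + daily - base * m
  n_days <- design$run_in / 24 + 1
  times <- as.vector(outer((seq_len(m) - 1) * gap, (0:n_days) * 24, `+`))
  times <- times[times <= design$run_in + 24]
  amts <- rep(amt, length.out = length(times))
  reg <- data.frame(time = times, amt = amts)
  reg <- reg[order(reg$time), ]
  rownames(reg) <- NULL
  attr(reg, "daily_dose") <- daily
  attr(reg, "n_intakes") <- m
  attr(reg, "gap") <- gap
  attr(reg, "t_N") <- design$run_in
  attr(reg, "t_n") <- design$run_in + gap
  reg
}

#' Draw the scheduled sampling times for one subject
#'
#' Implements the windowed sparse design around two consecutive sampling-day
#' intakes N and n: a pre-dose sample before each, post-N samples in the
#' 0-1, 1-2 and 2-3 h windows, one late sample between 3 h and the next
#' dose (two when the interval leaves at least 2 h past the 3 h mark),
#' post-n samples in the 0-1 and 1-2 h windows, and a next-morning trough —
#' 9 or 10 samples per subject. Times are uniform within each window and
#' recorded to 0.01 h.
#'
#' @param regimen output of [generate_regimen()]
#' @param seed integer seed
#' @return data.frame with `time` (h) and `tag` (window label)
#' @export
sampling_times <- function(regimen, seed = 1) {
  gap <- attr(regimen, "gap")
  tN <- attr(regimen, "t_N")
  tn <- attr(regimen, "t_n")
  if (is.null(gap) || gap < 4) stop_bad("regimen must have >= 4 h between intakes")
  set.seed(seed)
  times <- c(tN - runif(1, 0.05, 0.5),
             tN + runif(1, 0.05, 0.95),
             tN + runif(1, 1.05, 1.95),
             tN + runif(1, 2.05, 2.95))
  tags <- c("preN", "N+0-1", "N+1-2", "N+2-3")
  if (gap - 3 >= 2) {
    mid <- 3 + (gap - 3) / 2
    times <- c(times, tN + runif(1, 3.05, mid), tN + runif(1, mid, gap - 0.05))
    tags <- c(tags, "N+3+", "N+3+")
  } else {
    times <- c(times, tN + runif(1, 3.05, gap - 0.05))
    tags <- c(tags, "N+3+")
  }
  times <- c(times,
             tn - runif(1, 0.02, 0.04),  # pre-n draw right before the dose
             tn + runif(1, 0.05, 0.95),
             tn + runif(1, 1.05, 1.95),
             tN + 24 - runif(1, 0.05, 0.5))
  tags <- c(tags, "pren", "n+0-1", "n+1-2", "D2-trough")
  out <- data.frame(time = round(times, 2), tag = tags)
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  out
}

#' Simulate a complete virtual study
#'
#' Composes [generate_subjects()], [generate_regimen()], [sampling_times()]
#' and the structural model: individual parameters are
#' \eqn{\theta \cdot e^{\eta}} with \eqn{\eta \sim N(0, \Omega)} (optionally
#' times covariate factors from `effects`), concentrations follow the
#' multiple-dose profile with exponential residual error
#' \eqn{y = f e^{\varepsilon}}, and values below the LLOQ are flagged BLQ
#' with the measurement withheld. A truth record (generating parameters,
#' per-subject eta, per-observation noise-free predictions and residuals) is
#' attached for recovery scoring.
#'
#' @param design a [study_design()]
#' @param params generating [pk_parameters()]
#' @param effects optional list of [covariate_effect()] whose coefficients
#'   (in `params$cov_coeffs`) act on the simulated subjects
#' @param seed master seed; every random draw derives from it through
#'   per-subject substreams
#' @return a `pk_study`: `events` (dose + observation rows), `covariates`,
#'   `schedule` (window tags), `lloq` and `truth`
#' @examples
#' study <- simulate_study(seed = 42)
#' study
#' @export
simulate_study <- function(design = study_design(), params = pk_parameters(),
                           effects = list(), seed = 1) {
  covtab <- generate_subjects(design, seed)
  n <- nrow(covtab)
  fac <- covariate_factor_table(effects, params$cov_coeffs, covtab)
  ev <- vector("list", n)
  sched <- vector("list", n)
  etas <- matrix(0, n, 3, dimnames = list(covtab$ID, c("cl", "v", "ka")))
  fpred <- vector("list", n)
  epss <- vector("list", n)
  for (i in seq_len(n)) {
    reg <- generate_regimen(design, covtab$GRP[i],
                            substream_seed(seed, i * 7L + 2L))
    st <- sampling_times(reg, substream_seed(seed, i * 7L + 3L))
    set.seed(substream_seed(seed, i * 7L + 4L))
    eta <- rnorm(3) * params$omega
    eps <- rnorm(nrow(st)) * params$sigma
    keep <- rep(TRUE, nrow(st))
    if (design$missing_rate > 0) keep <- runif(nrow(st)) >= design$missing_rate
    st <- st[keep, , drop = FALSE]
    eps <- eps[keep]
    cl <- params$theta["tvcl"] * fac[i, "cl"] * exp(eta[1])
    v <- params$theta["tvv"] * fac[i, "v"] * exp(eta[2])
    ka <- params$theta["tvka"] * fac[i, "ka"] * exp(eta[3])
    f <- conc_profile(reg, st$time, cl, v, ka)  # ng/mL
    y <- f * exp(eps)
    blq <- y < design$lloq
    obs <- data.frame(ID = covtab$ID[i], TIME = st$time,
                      AMT = NA_real_, DV = ifelse(blq, NA, round(y, 2)),
                      EVID = 0L, MDV = as.integer(blq),
                      BLQ = as.integer(blq))
    dose <- data.frame(ID = covtab$ID[i], TIME = reg$time, AMT = reg$amt,
                       DV = NA_real_, EVID = 1L, MDV = 1L, BLQ = 0L)
    both <- rbind(dose, obs)
    both <- both[order(both$TIME, -both$EVID), ]
    ev[[i]] <- both
    sched[[i]] <- data.frame(ID = covtab$ID[i], st)
    etas[i, ] <- eta
    fpred[[i]] <- f
    epss[[i]] <- eps
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  structure(list(
    events = events, covariates = covtab,
    schedule = do.call(rbind, sched), lloq = design$lloq,
    truth = list(params = params, effects = effects, eta = etas,
                 pred = fpred, eps = epss, seed = seed)
  ), class = "pk_study")
}
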