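#' Estimation settings for [pk_fit()]
#'
#' @param rel_tol relative tolerance on the outer objective (nlminb)
#' @param max_iter maximum outer iterations
#' @param compute_se compute a finite-difference Hessian at the optimum and
#'   report relative standard errors (skipped for throwaway refits such as
#'   bootstrap replicates)
#' @param fix_omega keep the between-subject SDs at their initial values
#' @param fix_sigma keep the residual SD at its initial value
#' @return list of settings
#' @export
pk_settings <- function(rel_tol = 1e-9, max_iter = 500, compute_se = TRUE,
                        fix_omega = FALSE, fix_sigma = FALSE) {
  list(rel_tol = rel_tol, max_iter = max_iter, compute_se = compute_se,
       fix_omega = fix_omega, fix_sigma = fix_sigma)
}

#' Generic starting values for [pk_fit()]
#'
#' Deliberately away from the adult baclofen typical values so that fits do
#' not start at the answer.
#' @return a [pk_parameters()] object
#' @export
pk_init <- function() {
  pk_parameters(tvcl = 10, tvv = 50, tvka = 1,
                omega = c(0.3, 0.3, 0.3), sigma = 0.3)
}

# Collapse a subject's dose events into dose groups: a first dose at t0 of
# amount a repeated every 24 h. The engine accumulates the repeats by
# geometric recursion, which is exactly the naive superposition; events that
# do not repeat become groups of one.
#' @noRd
group_doses <- function(time, amt) {
  ord <- order(time)
  time <- time[ord]
  amt <- amt[ord]
  used <- rep(FALSE, length(time))
  t0 <- a <- numeric(0)
  nrep <- integer(0)
  for (i in seq_along(time)) {
    if (used[i]) next
    used[i] <- TRUE
    n <- 1L
    repeat {
      nxt <- which(!used & abs(time - (time[i] + 24 * n)) < 1e-9 &
                     amt == amt[i])
      if (!length(nxt)) break
      used[nxt[1]] <- TRUE
      n <- n + 1L
    }
    t0 <- c(t0, time[i])
    a <- c(a, amt[i])
    nrep <- c(nrep, n)
  }
  list(t0 = t0, amt = a, nrep = nrep)
}

# Flatten a pk_study into per-subject 0-based offset arrays for the C++
# objective. Observation rows with MDV = 1 (incl. BLQ) are excluded from the
# likelihood (M1 handling); subjects left with no usable observation are
# dropped with a warning.
#' @noRd
build_fit_data <- function(study, effects = list()) {
  study <- as_pk_study(study)
  ev <- study$events
  covtab <- study$covariates
  obs <- ev[ev$EVID == 0 & ev$MDV == 0, ]
  dos <- ev[ev$EVID == 1, ]
  ids <- covtab$ID
  usable <- ids[ids %in% obs$ID]
  dropped <- setdiff(ids, usable)
  if (length(dropped)) {
    warning("excluding ", length(dropped),
            " subject(s) with no quantifiable observation: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(usable)) stop_bad("no usable observations in dataset")
  covtab <- covtab[match(usable, covtab$ID), , drop = FALSE]
  sp_obs <- lapply(usable, function(id) obs[obs$ID == id, ])
  sp_dos <- lapply(usable, function(id) {
    d <- dos[dos$ID == id, ]
    if (nrow(d) == 0) stop_bad("subject ", id, " has no dose records")
    group_doses(d$TIME, d$AMT)
  })
  n_obs <- vapply(sp_obs, nrow, 1L)
  n_grp <- vapply(sp_dos, function(d) length(d$t0), 1L)
  list(
    ids = usable,
    covtab = covtab,
    dose_t0 = unlist(lapply(sp_dos, function(d) d$t0)),
    dose_amt = unlist(lapply(sp_dos, function(d) d$amt)),
    dose_nrep = as.integer(unlist(lapply(sp_dos, function(d) d$nrep))),
    dose_ptr = as.integer(c(0, cumsum(n_grp))),
    obs_time = unlist(lapply(sp_obs, function(d) d$TIME)),
    logy = log(unlist(lapply(sp_obs, function(d) d$DV)) / ng_per_mg_L),
    obs_ptr = as.integer(c(0, cumsum(n_obs))),
    n_obs = sum(n_obs),
    n_blq = sum(ev$BLQ == 1)
  )
}

# Parameter packing: log(theta) (3), covariate coefficients (raw exponents
# for power effects, log-multipliers otherwise), log(omega^2) for active
# non-fixed effects, log(sigma^2) unless fixed. Returns the packed start,
# bounds, and unpack().
#' @noRd
make_parspec <- function(init, effects, settings) {
  cn <- effect_coef_names(effects)
  ncov <- length(cn)
  coef_init <- rep(NA_real_, ncov)
  if (length(init$cov_coeffs) == ncov && ncov > 0) {
    coef_init <- as.numeric(init$cov_coeffs)
  }
  is_mult <- unlist(lapply(effects, function(ef) {
    rep(ef$form != "power", ef$df)
  })) %||% logical()
  coef_init[is.na(coef_init)] <- ifelse(is_mult[is.na(coef_init)], 1, 0)

  active <- init$omega > 0
  est_om <- active & !settings$fix_omega
  est_sg <- !settings$fix_sigma

  start <- c(log(init$theta),
             ifelse(is_mult, log(pmax(coef_init, 1e-6)), coef_init),
             log(init$omega[est_om]^2),
             if (est_sg) log(init$sigma^2))
  lower <- c(rep(log(1e-3), 3), ifelse(is_mult, -10, -20),
             rep(log(1e-6), sum(est_om)), if (est_sg) log(1e-8))
  upper <- c(rep(log(1e4), 3), ifelse(is_mult, 10, 20),
             rep(log(25), sum(est_om)), if (est_sg) log(25))

  i_th <- 1:3
  i_cv <- if (ncov) 3 + seq_len(ncov) else integer()
  i_om <- 3 + ncov + seq_len(sum(est_om))
  i_sg <- if (est_sg) 3 + ncov + sum(est_om) + 1L else integer()

  unpack <- function(par) {
    theta <- exp(par[i_th])
    names(theta) <- c("tvcl", "tvv", "tvka")
    coeffs <- if (ncov) {
      out <- par[i_cv]
      out[is_mult] <- exp(out[is_mult])
      names(out) <- cn
      out
    } else numeric()
    omega2 <- setNames(numeric(3), c("cl", "v", "ka"))
    omega2[active] <- init$omega[active]^2
    omega2[est_om] <- exp(par[i_om])
    sigma2 <- if (est_sg) exp(par[i_sg]) else init$sigma^2
    list(theta = theta, coeffs = coeffs, omega2 = omega2, sigma2 = sigma2)
  }
  list(start = start, lower = lower, upper = upper, unpack = unpack,
       idx = list(theta = i_th, cov = i_cv, omega = i_om, sigma = i_sg),
       is_mult = is_mult, est_om = est_om, est_sg = est_sg,
       coef_names = cn)
}

# The inner solver starts from a FIXED point (eta = 0, or a caller-supplied
# per-subject matrix such as a parent fit's EBEs), so the objective is a
# pure function of its arguments (required by the outer finite-difference
# quasi-Newton steps and by the determinism contract on the EBEs).
#' @noRd
make_objective <- function(fd, effects, parspec, eta_init = NULL) {
  force(fd); force(effects); force(parspec); force(eta_init)
  if (!is.null(eta_init) && nrow(eta_init) != length(fd$ids)) {
    eta_init <- NULL
  }
  function(par, want_eta = FALSE) {
    p <- parspec$unpack(par)
    fac <- covariate_factor_table(effects, p$coeffs, fd$covtab)
    res <- .cpp_foce_ofv(fd$dose_t0, fd$dose_amt, fd$dose_nrep, fd$dose_ptr,
                         fd$obs_time, fd$logy, fd$obs_ptr,
                         p$theta["tvcl"] * fac[, "cl"],
                         p$theta["tvv"] * fac[, "v"],
                         p$theta["tvka"] * fac[, "ka"],
                         unname(p$omega2), p$sigma2, want_eta,
                         eta_init = eta_init)
    if (want_eta) return(res)
    if (!is.finite(res$ofv)) return(1e10)
    res$ofv
  }
}

# Per-coefficient design vectors for the covariate chain rule:
# d a_{i,param} / d par_c (log(x/ref) for power exponents, level indicators
# for the log-multiplier parameters). Constant in par, computed once.
#' @noRd
effect_design <- function(effects, covtab) {
  cols <- integer(0)
  vecs <- list()
  for (ef in effects) {
    x <- covtab[[ef$covariate]]
    if (!is.null(ef$map)) x <- unname(ef$map[as.character(x)])
    pcol <- match(ef$param, c("cl", "v", "ka"))
    if (ef$form == "power") {
      vecs[[length(vecs) + 1L]] <- log(x / ef$ref)
      cols <- c(cols, pcol)
    } else if (ef$form == "categorical") {
      vecs[[length(vecs) + 1L]] <- as.numeric(x != ef$ref)
      cols <- c(cols, pcol)
    } else {
      for (lv in setdiff(ef$levels, ef$ref)) {
        vecs[[length(vecs) + 1L]] <- as.numeric(x == lv)
        cols <- c(cols, pcol)
      }
    }
  }
  list(cols = cols, vecs = vecs)
}

# Analytic gradient of the packed-parameter objective, assembled from the
# per-subject gradients with respect to the log individual typical values.
#' @noRd
make_gradient <- function(fd, effects, parspec, eta_init = NULL) {
  force(fd); force(effects); force(parspec); force(eta_init)
  if (!is.null(eta_init) && nrow(eta_init) != length(fd$ids)) {
    eta_init <- NULL
  }
  des <- effect_design(effects, fd$covtab)
  function(par) {
    p <- parspec$unpack(par)
    fac <- covariate_factor_table(effects, p$coeffs, fd$covtab)
    res <- .cpp_foce_grad(fd$dose_t0, fd$dose_amt, fd$dose_nrep,
                          fd$dose_ptr, fd$obs_time, fd$logy, fd$obs_ptr,
                          p$theta["tvcl"] * fac[, "cl"],
                          p$theta["tvv"] * fac[, "v"],
                          p$theta["tvka"] * fac[, "ka"],
                          unname(p$omega2), p$sigma2,
                          eta_init = eta_init)
    ga <- res$grad_a
    g <- numeric(length(par))
    g[parspec$idx$theta] <- colSums(ga)
    if (length(parspec$idx$cov)) {
      g[parspec$idx$cov] <- vapply(seq_along(des$cols), function(c2) {
        sum(ga[, des$cols[c2]] * des$vecs[[c2]])
      }, 1)
    }
    if (length(parspec$idx$omega)) {
      g[parspec$idx$omega] <- res$grad_lw2[parspec$est_om]
    }
    if (length(parspec$idx$sigma)) g[parspec$idx$sigma] <- res$grad_ls2
    if (any(!is.finite(g))) g[!is.finite(g)] <- 0
    g
  }
}

#' FOCE-I objective function value
#'
#' The approximate \eqn{-2 \log} marginal likelihood of the dataset under a
#' one-compartment oral model with log-normal between-subject variability
#' and exponential residual error, summed over subjects. The residual model
#' is handled exactly on the log-concentration scale (where it is additive
#' Gaussian with variance independent of \eqn{\eta}), and the marginal
#' integral is approximated by a Laplace/FOCE expansion around each
#' subject's conditional mode. The additive constant convention includes
#' the \eqn{n \log 2\pi} term of the log-scale data density, so absolute
#' values differ from other implementations by a dataset constant; only OFV
#' differences are used for model selection.
#'
#' @param data a `pk_study` or event data.frame (see [read_pk_dataset()])
#' @param params a [pk_parameters()] object
#' @param effects list of [covariate_effect()] objects (coefficients taken
#'   from `params$cov_coeffs`)
#' @return the scalar OFV
#' @export
pk_ofv <- function(data, params, effects = list()) {
  fd <- build_fit_data(data, effects)
  fac <- covariate_factor_table(effects, params$cov_coeffs, fd$covtab)
  res <- .cpp_foce_ofv(fd$dose_t0, fd$dose_amt, fd$dose_nrep, fd$dose_ptr,
                       fd$obs_time, fd$logy, fd$obs_ptr,
                       params$theta["tvcl"] * fac[, "cl"],
                       params$theta["tvv"] * fac[, "v"],
                       params$theta["tvka"] * fac[, "ka"],
                       unname(params$omega^2), params$sigma^2, FALSE)
  res$ofv
}

#' Empirical Bayes (conditional mode) random-effect estimates
#'
#' Per-subject MAP estimates \eqn{\hat\eta_i}: the minimizer of the
#' penalized log-scale residual objective
#' \eqn{\sum_j (\log y_{ij} - \log f_{ij}(\eta))^2/\sigma^2 +
#' \eta'\Omega^{-1}\eta}, found by damped Gauss-Newton started from
#' \eqn{\eta = 0} (deterministic given inputs).
#'
#' @inheritParams pk_ofv
#' @return matrix of \eqn{\hat\eta} (one row per subject, columns cl/v/ka;
#'   zero columns for inactive effects), with attribute `converged`
#' @export
map_etas <- function(data, params, effects = list()) {
  fd <- build_fit_data(data, effects)
  fac <- covariate_factor_table(effects, params$cov_coeffs, fd$covtab)
  res <- .cpp_foce_ofv(fd$dose_t0, fd$dose_amt, fd$dose_nrep, fd$dose_ptr,
                       fd$obs_time, fd$logy, fd$obs_ptr,
                       params$theta["tvcl"] * fac[, "cl"],
                       params$theta["tvv"] * fac[, "v"],
                       params$theta["tvka"] * fac[, "ka"],
                       unname(params$omega^2), params$sigma^2, TRUE)
  eta <- res$eta
  dimnames(eta) <- list(fd$ids, c("cl", "v", "ka"))
  if (!all(res$subject_ok)) {
    warning("inner estimation flagged subject(s): ",
            paste(fd$ids[!res$subject_ok], collapse = ", "))
  }
  attr(eta, "converged") <- as.logical(res$subject_ok)
  eta
}

#' Fit the population model by FOCE-I
#'
#' Maximizes the approximate marginal likelihood (see [pk_ofv()]) over
#' log-transformed fixed effects, covariate coefficients, between-subject
#' variances and residual variance with a quasi-Newton outer optimizer
#' (PORT/nlminb). Positivity is enforced through the log parameterization.
#' The fit is deterministic given the dataset, starting values and settings.
#'
#' @inheritParams pk_ofv
#' @param init starting [pk_parameters()]; defaults to [pk_init()]
#' @param effects covariate effects to estimate alongside the base model
#' @param settings see [pk_settings()]
#' @param eta_init optional fixed per-subject starting matrix for the inner
#'   conditional-mode search (columns cl/v/ka, rows in covariate-table
#'   order), e.g. a parent fit's EBEs when refitting resampled data; the
#'   reported EBEs are always recomputed from the standard \eqn{\eta = 0}
#'   start
#' @return object of class `pk_fit`: estimated `params`, `ofv`, `rse`
#'   (relative standard errors, %), `ebes`, `shrinkage`, `converged`,
#'   counts and optimizer trace
#' @examples
#' \donttest{
#' study <- simulate_study(seed = 1)
#' fit <- pk_fit(study)
#' fit
#' }
#' @export
pk_fit <- function(data, init = pk_init(), effects = list(),
                   settings = pk_settings(), eta_init = NULL) {
  study <- as_pk_study(data)
  fd <- build_fit_data(study, effects)
  parspec <- make_parspec(init, effects, settings)
  obj <- make_objective(fd, effects, parspec, eta_init = eta_init)
  gr <- make_gradient(fd, effects, parspec, eta_init = eta_init)

  opt <- nlminb(parspec$start, obj, gradient = gr,
                lower = parspec$lower, upper = parspec$upper,
                control = list(rel.tol = settings$rel_tol,
                               iter.max = settings$max_iter,
                               eval.max = settings$max_iter * 4))
  p <- parspec$unpack(opt$par)
  # reported OFV/EBEs from the canonical eta = 0 inner start
  final <- make_objective(fd, effects, parspec)(opt$par, want_eta = TRUE)
  eta <- final$eta
  dimnames(eta) <- list(fd$ids, c("cl", "v", "ka"))

  omega <- sqrt(p$omega2)
  params <- pk_parameters(p$theta["tvcl"], p$theta["tvv"], p$theta["tvka"],
                          omega = omega, sigma = sqrt(p$sigma2),
                          cov_coeffs = p$coeffs)
  fit <- structure(list(
    params = params, effects = effects, ofv = final$ofv,
    ebes = eta,
    shrinkage = shrinkage_from(eta, omega, type = "sd"),
    converged = opt$convergence == 0 && all(final$subject_ok),
    message = opt$message, iterations = opt$iterations,
    evaluations = opt$evaluations,
    n_obs = fd$n_obs, n_subjects = length(fd$ids), n_blq = fd$n_blq,
    par = opt$par, parspec = parspec, settings = settings,
    rse = NULL, se_ok = NA
  ), class = "pk_fit")

  if (settings$compute_se) {
    se <- tryCatch(standard_errors(fit, study), error = function(e) {
      warning("standard errors unavailable: ", conditionMessage(e))
      NULL
    })
    if (!is.null(se)) {
      fit$rse <- se$rse
      fit$se_ok <- se$ok
      fit$se_diag <- se$diagnostics
    }
  }
  fit
}

#' @noRd
shrinkage_from <- function(eta, omega, type = c("sd", "var")) {
  type <- match.arg(type)
  out <- setNames(rep(NA_real_, 3), c("cl", "v", "ka"))
  for (k in seq_len(3)) {
    if (omega[k] > 0) {
      s <- if (type == "sd") 1 - sd(eta[, k]) / omega[k]
           else 1 - var(eta[, k]) / omega[k]^2
      out[k] <- min(max(s, 0), 1)
    }
  }
  out
}

#' Random-effect (eta) shrinkage
#'
#' \eqn{1 - SD(\hat\eta)/\omega} per random effect (the SD form; set
#' `type = "var"` for the variance-ratio form \eqn{1 - var(\hat\eta)/
#' \omega^2}), clipped to \[0, 1\]. Values near 1 mean the sparse data carry
#' little subject-level information about that effect; undefined (NA) when
#' \eqn{\omega = 0}.
#'
#' @param fit a `pk_fit`
#' @param type `"sd"` (default) or `"var"`
#' @return named vector (cl, v, ka)
#' @export
eta_shrinkage <- function(fit, type = c("sd", "var")) {
  stopifnot(inherits(fit, "pk_fit"))
  shrinkage_from(fit$ebes, fit$params$omega, match.arg(type))
}

#' Relative standard errors from a finite-difference Hessian
#'
#' Inverts the finite-difference Hessian of OFV/2 at the optimum (the
#' asymptotic information matrix in the log parameterization). Because the
#' internal parameters are logs of the reported quantities, the standard
#' error of a log-parameter is directly the relative standard error of the
#' natural parameter: RSE% = 100 x SE(log p); for the SDs
#' (\eqn{\omega,\sigma}), whose internal parameter is \eqn{\log \omega^2},
#' RSE% = 100 x SE/2.
#'
#' @param fit a converged `pk_fit`
#' @param data the dataset the fit was produced from
#' @return list with `rse` (named, %), `ok` (Hessian positive definite) and
#'   `diagnostics` (eigenvalues) — when the Hessian is not positive definite
#'   the per-parameter RSEs are NA and the eigen-spectrum is reported
#'   instead of silent output
#' @export
standard_errors <- function(fit, data) {
  stopifnot(inherits(fit, "pk_fit"))
  fd <- build_fit_data(data, fit$effects)
  parspec <- fit$parspec
  obj <- make_objective(fd, fit$effects, parspec)
  H <- optimHess(fit$par, obj, make_gradient(fd, fit$effects, parspec))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  nm <- c("tvcl", "tvv", "tvka", parspec$coef_names,
          paste0("omega_", c("cl", "v", "ka")[parspec$est_om]),
          if (parspec$est_sg) "sigma")
  rse <- setNames(rep(NA_real_, length(fit$par)), nm)
  ok <- all(ev > 0)
  if (ok) {
    se_log <- sqrt(diag(2 * solve(H)))  # cov = (H/2)^{-1}
    rse[parspec$idx$theta] <- 100 * se_log[parspec$idx$theta]
    if (length(parspec$idx$cov)) {
      cv <- parspec$idx$cov
      est <- fit$par[cv]
      r <- 100 * se_log[cv]               # log-multiplier scale
      raw <- !parspec$is_mult
      r[raw] <- 100 * se_log[cv][raw] / pmax(abs(est[raw]), 1e-12)
      rse[cv] <- r
    }
    rse[parspec$idx$omega] <- 100 * se_log[parspec$idx$omega] / 2
    if (length(parspec$idx$sigma)) {
      rse[parspec$idx$sigma] <- 100 * se_log[parspec$idx$sigma] / 2
    }
  }
  list(rse = rse, ok = ok, diagnostics = ev)
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("FOCE-I population PK fit\n")
  cat(sprintf("  %d subjects, %d observations (%d BLQ excluded); OFV %.3f; %s\n",
              x$n_subjects, x$n_obs, x$n_blq, x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  th <- x$params$theta
  om <- x$params$omega
  rse <- x$rse
  fmt <- function(name, val) {
    r <- if (!is.null(rse) && name %in% names(rse) && is.finite(rse[name])) {
      sprintf(" (RSE %.0f%%)", rse[name])
    } else ""
    paste0(signif(val, 3), r)
  }
  cat("  CL/F ", fmt("tvcl", th["tvcl"]), " L/h;  Vd/F ",
      fmt("tvv", th["tvv"]), " L;  Ka ", fmt("tvka", th["tvka"]), " 1/h\n",
      sep = "")
  cat("  omega: CL ", fmt("omega_cl", om["cl"]), ", V ",
      fmt("omega_v", om["v"]), ", Ka ", fmt("omega_ka", om["ka"]),
      ";  sigma ", fmt("sigma", x$params$sigma), "\n", sep = "")
  if (length(x$params$cov_coeffs)) {
    cat("  covariates:",
        paste(names(x$params$cov_coeffs),
              signif(x$params$cov_coeffs, 3), collapse = ", "), "\n")
  }
  sh <- x$shrinkage
  cat(sprintf("  eta-shrinkage: CL %.2f, V %.2f, Ka %.2f\n",
              sh["cl"], sh["v"], sh["ka"]))
  invisible(x)
}

#' @export
logLik.pk_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$par), class = "logLik")
}

#' @export
coef.pk_fit <- function(object, ...) {
  c(object$params$theta, object$params$cov_coeffs,
    omega_cl = unname(object$params$omega["cl"]),
    omega_v = unname(object$params$omega["v"]),
    omega_ka = unname(object$params$omega["ka"]),
    sigma = object$params$sigma)
}

# ---------------------------------------------------------------------------
# Reference (pure-R, model-agnostic) FOCE/Laplace objective. Each subject is
# a list(y = data vector, f = function(eta) mean vector, q = eta dimension).
# Used as the slow cross-check path for the C++ engine and as the vehicle
# for closed-form Gaussian oracles on eta-linear models.
# ---------------------------------------------------------------------------

#' Reference FOCE/Laplace objective for arbitrary mean functions
#'
#' Model-agnostic, pure-R evaluation of the same approximate -2 log marginal
#' likelihood as [pk_ofv()]: data \eqn{y_i = f_i(\eta_i) + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}, \eqn{\eta_i \sim N(0, \Omega)}
#' (diagonal). For mean functions linear in \eqn{\eta} the Laplace
#' approximation is exact, which provides the closed-form Gaussian oracle
#' used in the test suite.
#'
#' @param subjects list; each element `list(y = , f = function(eta) ...)`
#' @param omega2 vector of random-effect variances (diagonal of Omega)
#' @param sigma2 residual variance
#' @return list with `ofv` and matrix `eta` of conditional modes
#' @export
foce_ofv_reference <- function(subjects, omega2, sigma2) {
  q <- length(omega2)
  if (any(omega2 <= 0)) stop_bad("omega2 must be positive; drop the degenerate effect")
  total <- 0
  etas <- matrix(0, length(subjects), q)
  for (i in seq_along(subjects)) {
    y <- subjects[[i]]$y
    f <- subjects[[i]]$f
    n <- length(y)
    g <- function(eta) {
      r <- y - f(eta)
      sum(r^2) / sigma2 + sum(eta^2 / omega2)
    }
    opt <- nlminb(rep(0, q), g, control = list(rel.tol = 1e-14))
    eta <- opt$par
    h <- 1e-5
    J <- matrix(0, n, q)
    for (k in seq_len(q)) {
      ep <- em <- eta
      ep[k] <- ep[k] + h
      em[k] <- em[k] - h
      J[, k] <- (f(ep) - f(em)) / (2 * h)
    }
    H <- crossprod(J) / sigma2 + diag(1 / omega2, q)
    total <- total + opt$objective + n * log(2 * pi * sigma2) +
      sum(log(omega2)) + determinant(H, logarithm = TRUE)$modulus[1]
    etas[i, ] <- eta
  }
  list(ofv = total, eta = etas)
}
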