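# Simulation-based model qualification: replicate simulation under the
# original design, NPDE, prediction-corrected VPC, nonparametric bootstrap,
# and CPRED/IPRED prediction tables.

#' @noRd
fit_params <- function(fit) if (inherits(fit, "pk_fit")) fit$params else fit

#' @noRd
fit_effects <- function(fit, effects) {
  if (inherits(fit, "pk_fit")) fit$effects else effects
}

# Per-subject design extraction shared by the diagnostics: dose history,
# quantified-observation rows, covariate factors.
#' @noRd
diag_context <- function(data, params, effects) {
  study <- as_pk_study(data)
  fd <- build_fit_data(study, effects)
  fac <- covariate_factor_table(effects, params$cov_coeffs, fd$covtab)
  ns <- length(fd$ids)
  subjects <- lapply(seq_len(ns), function(i) {
    di <- (fd$dose_ptr[i] + 1):fd$dose_ptr[i + 1]
    oi <- (fd$obs_ptr[i] + 1):fd$obs_ptr[i + 1]
    # expand dose groups back to individual dose events
    dt <- unlist(lapply(di, function(d) {
      fd$dose_t0[d] + 24 * (seq_len(fd$dose_nrep[d]) - 1)
    }))
    da <- rep(fd$dose_amt[di], fd$dose_nrep[di])
    ord <- order(dt)
    list(id = fd$ids[i],
         dose_time = dt[ord], dose_amt = da[ord],
         obs_time = fd$obs_time[oi], dv = exp(fd$logy[oi]) * ng_per_mg_L,
         tcl = params$theta["tvcl"] * fac[i, "cl"],
         tv = params$theta["tvv"] * fac[i, "v"],
         tka = params$theta["tvka"] * fac[i, "ka"])
  })
  list(study = study, subjects = subjects, fd = fd)
}

#' Simulate a replicate ensemble under the original design
#'
#' Draws `K` replicate datasets from the fitted model keeping every design
#' element of the source data fixed (same subjects, dose histories,
#' sampling times, covariates): per replicate and subject,
#' \eqn{\eta \sim N(0, \hat\Omega)}, \eqn{\varepsilon \sim N(0,
#' \hat\sigma^2)} on the log scale, \eqn{y = f(\eta) e^{\varepsilon}}.
#' Reproducible bit-for-bit under a fixed seed.
#'
#' @param fit a `pk_fit` (or a [pk_parameters()] object)
#' @param data the source `pk_study`
#' @param K number of replicates (>= 2)
#' @param seed integer seed
#' @param effects covariate effects when `fit` is a bare parameter set
#' @return a `pk_ensemble`: `sim` (K x n matrix of simulated ng/mL), `obs`
#'   (per-row ID, TIME, DV, PRED, TAD), `K`, `seed`
#' @export
simulate_ensemble <- function(fit, data, K = 500, seed = 1,
                              effects = list()) {
  if (K < 2) stop_bad("K must be >= 2 (predictive diagnostics undefined)")
  params <- fit_params(fit)
  effects <- fit_effects(fit, effects)
  ctx <- diag_context(data, params, effects)
  omega <- params$omega
  sigma <- params$sigma
  nvec <- vapply(ctx$subjects, function(s) length(s$obs_time), 1L)
  total <- sum(nvec)
  sim <- matrix(NA_real_, K, total)
  pred <- numeric(total)
  tad <- numeric(total)
  set.seed(seed)
  off <- 0L
  for (s in ctx$subjects) {
    n_i <- length(s$obs_time)
    cols <- off + seq_len(n_i)
    pred[cols] <- ng_per_mg_L *
      .cpp_profile(s$dose_time, s$dose_amt, s$obs_time, s$tcl, s$tv, s$tka)
    tad[cols] <- vapply(s$obs_time, function(t) {
      t - max(s$dose_time[s$dose_time < t])
    }, 1)
    eta <- matrix(rnorm(3 * K), K, 3) %*% diag(omega)
    eps <- matrix(rnorm(K * n_i), K, n_i) * sigma
    for (k in seq_len(K)) {
      f <- .cpp_profile(s$dose_time, s$dose_amt, s$obs_time,
                        s$tcl * exp(eta[k, 1]), s$tv * exp(eta[k, 2]),
                        s$tka * exp(eta[k, 3]))
      sim[k, cols] <- ng_per_mg_L * f * exp(eps[k, ])
    }
    off <- off + n_i
  }
  obs <- data.frame(
    ID = rep(vapply(ctx$subjects, function(s) s$id, 1), nvec),
    TIME = unlist(lapply(ctx$subjects, function(s) s$obs_time)),
    DV = unlist(lapply(ctx$subjects, function(s) s$dv)),
    PRED = pred, TAD = tad)
  structure(list(sim = sim, obs = obs, K = K, seed = seed, params = params),
            class = "pk_ensemble")
}

#' @export
print.pk_ensemble <- function(x, ...) {
  cat(sprintf("simulation ensemble: %d replicates x %d observations (seed %d)\n",
              x$K, ncol(x$sim), x$seed))
  invisible(x)
}

#' Normalized prediction distribution errors
#'
#' Per subject, the observed vector and each simulated replicate are
#' decorrelated with the inverse Cholesky factor of the empirical
#' simulation covariance; each decorrelated observation's rank among its
#' decorrelated simulations (mid-rank for ties) gives
#' \eqn{pd \in (0, 1)}, clipped to \eqn{[1/2K, 1 - 1/2K]}, and
#' NPDE = \eqn{\Phi^{-1}(pd)}. Under the true model NPDE is approximately
#' standard normal. A singular simulation covariance triggers a marginal
#' (uncorrelated) fallback, flagged in the result.
#'
#' @param data the observed `pk_study`
#' @param ensemble a [simulate_ensemble()] result aligned to `data`
#' @return a `pk_npde`: data.frame (ID, TIME, DV, pd, npde) with attribute
#'   `decorrelated` (FALSE for subjects that used the marginal fallback)
#' @export
npde <- function(data, ensemble) {
  stopifnot(inherits(ensemble, "pk_ensemble"))
  obs <- ensemble$obs
  K <- ensemble$K
  ids <- unique(obs$ID)
  pd <- numeric(nrow(obs))
  decorr <- setNames(rep(TRUE, length(ids)), ids)
  for (id in ids) {
    cols <- which(obs$ID == id)
    y <- obs$DV[cols]
    S <- ensemble$sim[, cols, drop = FALSE]
    mu <- colMeans(S)
    V <- stats::cov(S)
    L <- tryCatch(t(chol(V)), error = function(e) NULL)
    if (is.null(L)) {
      decorr[as.character(id)] <- FALSE
      ys <- (y - mu) / sqrt(pmax(diag(V), 1e-300))
      Ss <- sweep(sweep(S, 2, mu), 2, sqrt(pmax(diag(V), 1e-300)), "/")
    } else {
      ys <- forwardsolve(L, y - mu)
      Ss <- t(forwardsolve(L, t(sweep(S, 2, mu))))
    }
    for (j in seq_along(cols)) {
      r <- (sum(Ss[, j] < ys[j]) + 0.5 * sum(Ss[, j] == ys[j])) / K
      pd[cols[j]] <- min(max(r, 1 / (2 * K)), 1 - 1 / (2 * K))
    }
  }
  if (!all(decorr)) {
    warning("singular simulation covariance for subject(s) ",
            paste(names(decorr)[!decorr], collapse = ", "),
            "; marginal pd used")
  }
  out <- data.frame(obs[, c("ID", "TIME", "DV")], pd = pd, npde = qnorm(pd))
  structure(out, decorrelated = decorr, class = c("pk_npde", "data.frame"))
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulations are rescaled by the ratio of the bin-median
#' population prediction to the row's own population prediction
#' (\eqn{pcY_{ij} = Y_{ij} \cdot \tilde{PRED}_{bin} / PRED_{ij}}), removing
#' regimen and covariate heterogeneity within a bin; the observed 5/50/95th
#' percentiles per time-after-dose bin are then compared with the 95%
#' simulation band of the same percentiles.
#'
#' @inheritParams npde
#' @param bins time-after-dose bin edges (h); bins holding fewer than
#'   `min_bin` observations are merged into their left neighbour and logged
#' @param correct set `FALSE` for a plain (uncorrected) VPC
#' @param min_bin minimum observations per bin
#' @return a `pk_vpc` data.frame: per bin, observation count, the observed
#'   percentiles (`obs_p5/50/95`) and the simulation 95% CI of each
#'   percentile (`p5_lo` ... `p95_hi`); merge decisions in attribute `log`
#' @export
pc_vpc <- function(data, ensemble, bins = c(0, 1, 2, 3, 4, 6, 8, 12, 24),
                   correct = TRUE, min_bin = 5) {
  stopifnot(inherits(ensemble, "pk_ensemble"))
  obs <- ensemble$obs
  edges <- sort(unique(bins))
  if (max(obs$TAD) > max(edges)) edges <- c(edges, max(obs$TAD) + 1e-9)
  idx <- cut(obs$TAD, edges, include.lowest = TRUE, labels = FALSE)
  log <- character()
  repeat {
    counts <- tabulate(idx, nbins = length(edges) - 1)
    small <- which(counts > 0 & counts < min_bin)
    if (!length(small)) break
    b <- small[1]
    target <- if (b > 1) b - 1L else b + 1L
    log <- c(log, sprintf("merged bin %d (n=%d) into bin %d", b, counts[b],
                          target))
    edges <- edges[-max(b, target)]
    idx <- cut(obs$TAD, edges, include.lowest = TRUE, labels = FALSE)
  }
  used <- sort(unique(idx))
  probs <- c(0.05, 0.5, 0.95)
  rows <- lapply(used, function(b) {
    cols <- which(idx == b)
    corr <- if (correct) {
      median(obs$PRED[cols]) / obs$PRED[cols]
    } else rep(1, length(cols))
    pcy <- obs$DV[cols] * corr
    op <- quantile(pcy, probs, names = FALSE)
    simq <- t(apply(ensemble$sim[, cols, drop = FALSE], 1, function(s) {
      quantile(s * corr, probs, names = FALSE)
    }))
    band <- apply(simq, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    data.frame(tad_lo = edges[b], tad_hi = edges[b + 1], n = length(cols),
               obs_p5 = op[1], obs_p50 = op[2], obs_p95 = op[3],
               p5_lo = band[1, 1], p5_hi = band[2, 1],
               p50_lo = band[1, 2], p50_hi = band[2, 2],
               p95_lo = band[1, 3], p95_hi = band[2, 3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, log = log, class = c("pk_vpc", "data.frame"))
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples subjects with replacement, stratified by dose group to
#' preserve the study's group sizes, refits the model on each replicate
#' (warm-started from the original estimates), and reports percentile
#' 2.5/97.5% intervals computed from the converged replicates only. A
#' non-convergence rate above 20% flags the result unreliable.
#'
#' @param data a `pk_study`
#' @param fit the original `pk_fit` (supplies the model and warm start)
#' @param B number of bootstrap replicates (>= 50; 200 recommended)
#' @param seed integer seed (drives the resample indices; fixed seed gives
#'   identical resamples)
#' @param stratify covariate column defining the strata (`NULL` for
#'   unstratified resampling)
#' @param settings estimation settings for the replicate fits
#' @return a `pk_bootstrap`: `estimates` (B x p matrix, NA rows for
#'   non-converged replicates), `ci` (percentile bounds), `n_converged`,
#'   `unreliable`
#' @export
bootstrap_ci <- function(data, fit, B = 200, seed = 1, stratify = "GRP",
                         settings = scm_settings()) {
  if (B < 50) stop_bad("B must be >= 50")
  study <- as_pk_study(data)
  cov <- study$covariates
  ids <- cov$ID
  strata <- if (!is.null(stratify) && stratify %in% names(cov)) {
    cov[[stratify]]
  } else rep(1, length(ids))
  init <- fit_params(fit)
  effects <- fit_effects(fit, list())
  set.seed(substream_seed(seed, 0L))
  draws <- lapply(seq_len(B), function(b) {
    unlist(lapply(unique(strata), function(g) {
      pool <- ids[strata == g]
      pool[sample.int(length(pool), length(pool), replace = TRUE)]
    }))
  })
  # resample at the flattened-array level: a resample of a valid study is
  # valid, so each replicate skips the event-table rebuild and revalidation
  fd <- build_fit_data(study, effects)
  settings <- utils::modifyList(settings, list(compute_se = FALSE))
  parspec <- make_parspec(init, effects, settings)
  ebes <- if (inherits(fit, "pk_fit")) fit$ebes
  d_idx <- lapply(seq_along(fd$ids), function(i) {
    (fd$dose_ptr[i] + 1):fd$dose_ptr[i + 1]
  })
  o_idx <- lapply(seq_along(fd$ids), function(i) {
    (fd$obs_ptr[i] + 1):fd$obs_ptr[i + 1]
  })
  pos <- match(fd$ids, fd$ids)  # identity; guards renumbered inputs
  names(pos) <- fd$ids
  cn <- c("tvcl", "tvv", "tvka", parspec$coef_names,
          "omega_cl", "omega_v", "omega_ka", "sigma")
  est <- matrix(NA_real_, B, length(cn), dimnames = list(NULL, cn))
  conv <- logical(B)
  for (b in seq_len(B)) {
    take <- pos[as.character(draws[[b]])]
    di <- unlist(d_idx[take])
    oi <- unlist(o_idx[take])
    fd_b <- list(
      ids = seq_along(take),
      covtab = fd$covtab[take, , drop = FALSE],
      dose_t0 = fd$dose_t0[di], dose_amt = fd$dose_amt[di],
      dose_nrep = fd$dose_nrep[di],
      dose_ptr = as.integer(c(0, cumsum(lengths(d_idx[take])))),
      obs_time = fd$obs_time[oi], logy = fd$logy[oi],
      obs_ptr = as.integer(c(0, cumsum(lengths(o_idx[take])))))
    ei <- if (!is.null(ebes)) ebes[take, , drop = FALSE]
    obj <- make_objective(fd_b, effects, parspec, eta_init = ei)
    gr_b <- make_gradient(fd_b, effects, parspec, eta_init = ei)
    opt <- tryCatch(
      nlminb(parspec$start, obj, gradient = gr_b, lower = parspec$lower,
             upper = parspec$upper,
             control = list(rel.tol = settings$rel_tol,
                            iter.max = settings$max_iter,
                            eval.max = settings$max_iter * 4)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$convergence == 0) {
      conv[b] <- TRUE
      p <- parspec$unpack(opt$par)
      est[b, ] <- c(p$theta, p$coeffs, sqrt(p$omega2), sqrt(p$sigma2))
    }
  }
  ok <- est[conv, , drop = FALSE]
  ci <- t(apply(ok, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  ci <- data.frame(lo = ci[, 1], hi = ci[, 2], row.names = colnames(est))
  structure(list(estimates = est, ci = ci, n_converged = sum(conv), B = B,
                 seed = seed, unreliable = mean(!conv) > 0.2),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("nonparametric bootstrap: %d/%d replicates converged%s\n",
              x$n_converged, x$B,
              if (x$unreliable) " [UNRELIABLE: > 20% non-convergence]" else ""))
  print(round(x$ci, 4))
  invisible(x)
}

#' Population and individual prediction tables
#'
#' CPRED is the model prediction with the subject's covariates and
#' \eqn{\eta = 0}; IPRED uses the empirical Bayes estimates
#' \eqn{\hat\eta_i}. One row per quantified observation.
#'
#' @param fit a converged `pk_fit`
#' @param data the fitted `pk_study`
#' @return data.frame with ID, TIME, DV, CPRED, IPRED (ng/mL)
#' @export
prediction_tables <- function(fit, data) {
  stopifnot(inherits(fit, "pk_fit"))
  params <- fit$params
  ctx <- diag_context(data, params, fit$effects)
  eta <- fit$ebes
  rows <- lapply(seq_along(ctx$subjects), function(i) {
    s <- ctx$subjects[[i]]
    e <- eta[match(as.character(s$id), rownames(eta)), ]
    cpred <- .cpp_profile(s$dose_time, s$dose_amt, s$obs_time,
                          s$tcl, s$tv, s$tka)
    ipred <- .cpp_profile(s$dose_time, s$dose_amt, s$obs_time,
                          s$tcl * exp(e[1]), s$tv * exp(e[2]),
                          s$tka * exp(e[3]))
    data.frame(ID = s$id, TIME = s$obs_time, DV = s$dv,
               CPRED = ng_per_mg_L * cpred, IPRED = ng_per_mg_L * ipred)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
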