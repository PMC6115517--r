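# Stepwise covariate modelling on likelihood-ratio OFV thresholds:
# greedy best-first forward inclusion at P = 0.05, then backward elimination
# at P = 0.001, each threshold at the candidate's own degrees of freedom.

#' @noRd
neutral_coeffs <- function(ef) {
  if (ef$form == "power") 0 else rep(1, ef$df)
}

# Warm starting values for a model extending `fit` by `new_effects`.
#' @noRd
extend_init <- function(fit, new_effects = list()) {
  p <- fit$params
  extra <- unlist(lapply(new_effects, neutral_coeffs)) %||% numeric()
  pk_parameters(p$theta["tvcl"], p$theta["tvv"], p$theta["tvka"],
                omega = p$omega, sigma = p$sigma,
                cov_coeffs = c(p$cov_coeffs, extra))
}

# Starting values for a model dropping effect `j` from `fit`.
#' @noRd
reduce_init <- function(fit, j) {
  p <- fit$params
  dfs <- vapply(fit$effects, function(e) e$df, 1L)
  off <- cumsum(c(0L, dfs))
  keep <- setdiff(seq_along(p$cov_coeffs), off[j] + seq_len(dfs[j]))
  pk_parameters(p$theta["tvcl"], p$theta["tvv"], p$theta["tvka"],
                omega = p$omega, sigma = p$sigma,
                cov_coeffs = p$cov_coeffs[keep])
}

#' @noRd
scm_settings <- function() pk_settings(rel_tol = 1e-6, compute_se = FALSE)

#' Forward covariate inclusion
#'
#' Tests each candidate effect one at a time against the current model and
#' greedily adds the candidate with the largest significant OFV drop
#' (\eqn{\Delta OFV \ge \chi^2_{df}(1-\alpha)}, i.e. 3.84 for 1 df at
#' P = 0.05), repeating until no candidate passes. Candidate fits that fail
#' to converge are skipped with a log entry. Categorical candidates should
#' already be pooled (see [default_candidates()]).
#'
#' @param data a `pk_study`
#' @param base_fit the starting [pk_fit()] (normally the base model)
#' @param candidates list of [covariate_effect()] objects
#' @param alpha forward inclusion significance level
#' @param settings estimation settings for the candidate fits
#' @return list with `fit` (the full model), `effects` (included), and
#'   `log` (per-step records)
#' @export
forward_step <- function(data, base_fit, candidates, alpha = 0.05,
                         settings = scm_settings()) {
  study <- as_pk_study(data)
  current <- base_fit
  remaining <- candidates
  log <- attr(candidates, "log") %||% character()
  repeat {
    if (!length(remaining)) break
    delta <- rep(NA_real_, length(remaining))
    thr <- vapply(remaining, function(ef) {
      lrt_threshold(ef$df, alpha, rounded = FALSE)
    }, 1)
    fits <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      effects_j <- c(current$effects, list(remaining[[j]]))
      fit_j <- tryCatch(
        pk_fit(study, extend_init(current, remaining[j]), effects_j,
               settings, eta_init = current$ebes),
        error = function(e) NULL)
      if (is.null(fit_j) || !fit_j$converged) {
        log <- c(log, paste0("skipped ", effect_label(remaining[[j]]),
                             ": candidate fit did not converge"))
        next
      }
      fits[[j]] <- fit_j
      delta[j] <- current$ofv - fit_j$ofv
    }
    pass <- which(!is.na(delta) & delta >= thr)
    if (!length(pass)) break
    best <- pass[which.max(delta[pass])]
    log <- c(log, sprintf("added %s (dOFV %.2f >= %.2f)",
                          effect_label(remaining[[best]]), delta[best],
                          thr[best]))
    current <- fits[[best]]
    remaining <- remaining[-best]
  }
  list(fit = current, effects = current$effects, log = log)
}

#' Backward covariate elimination
#'
#' Removes each included effect in turn from the full model; an effect is
#' retained only if its removal increases the OFV by more than the
#' stricter threshold (\eqn{\chi^2_{df}} at P = 0.001: 10.8 for 1 df,
#' 16.3 for 3 df). The weakest removable effect is dropped and the
#' procedure iterates until the model is stable.
#'
#' @param data a `pk_study`
#' @param full_fit the [pk_fit()] produced by [forward_step()]
#' @param alpha backward retention significance level
#' @param settings estimation settings for the reduced fits
#' @return list with `fit` (final model), `effects`, `log`
#' @export
backward_step <- function(data, full_fit, alpha = 0.001,
                          settings = scm_settings()) {
  study <- as_pk_study(data)
  current <- full_fit
  log <- character()
  repeat {
    effects <- current$effects
    if (!length(effects)) break
    delta <- rep(NA_real_, length(effects))
    fits <- vector("list", length(effects))
    thr <- vapply(effects, function(ef) {
      lrt_threshold(ef$df, alpha, rounded = FALSE)
    }, 1)
    for (j in seq_along(effects)) {
      fit_j <- tryCatch(
        pk_fit(study, reduce_init(current, j), effects[-j], settings,
               eta_init = current$ebes),
        error = function(e) NULL)
      if (is.null(fit_j) || !fit_j$converged) {
        log <- c(log, paste0("kept ", effect_label(effects[[j]]),
                             ": reduced fit did not converge"))
        delta[j] <- Inf
        next
      }
      fits[[j]] <- fit_j
      delta[j] <- fit_j$ofv - current$ofv
    }
    removable <- which(delta <= thr)
    if (!length(removable)) break
    worst <- removable[which.min(delta[removable])]
    log <- c(log, sprintf("removed %s (dOFV %.2f <= %.2f)",
                          effect_label(effects[[worst]]), delta[worst],
                          thr[worst]))
    current <- fits[[worst]]
  }
  list(fit = current, effects = current$effects, log = log)
}

#' Full stepwise covariate search
#'
#' [forward_step()] at P = 0.05 followed by [backward_step()] at
#' P = 0.001, starting from the base (no-covariate) model.
#'
#' @param data a `pk_study`
#' @param base_fit base-model fit; fitted here when `NULL`
#' @param candidates candidate set; [default_candidates()] when `NULL`
#' @param settings estimation settings for search fits
#' @return list with `fit` (final model), `effects`, `forward_log`,
#'   `backward_log`
#' @export
covariate_search <- function(data, base_fit = NULL, candidates = NULL,
                             settings = scm_settings()) {
  study <- as_pk_study(data)
  if (is.null(base_fit)) base_fit <- pk_fit(study, settings = settings)
  if (is.null(candidates)) candidates <- default_candidates(study)
  fw <- forward_step(study, base_fit, candidates, settings = settings)
  bw <- backward_step(study, fw$fit, settings = settings)
  list(fit = bw$fit, effects = bw$effects,
       forward_log = fw$log, backward_log = bw$log)
}
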