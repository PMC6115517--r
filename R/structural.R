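#' Population parameter set for the one-compartment oral model
#'
#' Bundles the typical (population) values of apparent clearance CL/F,
#' apparent volume Vd/F and absorption rate constant Ka together with the
#' between-subject standard deviations (log scale) and the residual standard
#' deviation of the exponential error model. Defaults are the base-model
#' estimates for racemic baclofen in adults treated for alcohol use disorder
#' at 30-300 mg/day.
#'
#' @param tvcl typical apparent clearance CL/F (L/h)
#' @param tvv typical apparent volume of distribution Vd/F (L)
#' @param tvka typical absorption rate constant Ka (1/h)
#' @param omega between-subject SDs (log scale) for CL, V, Ka, in that order;
#'   an entry of 0 removes the corresponding random effect
#' @param sigma residual SD on the log-concentration scale (the "exponential"
#'   residual model \eqn{y = f e^\varepsilon})
#' @param cov_coeffs named numeric vector of covariate coefficients, one per
#'   active [covariate_effect()] parameter (exponents for power effects,
#'   log-multipliers are *not* used here: multipliers are stored natively)
#' @return an object of class `pk_parameters`
#' @examples
#' pk_parameters()  # published adult baclofen values
#' @export
pk_parameters <- function(tvcl = 11.6, tvv = 72.8, tvka = 1.64,
                          omega = c(cl = 0.21, v = 0.22, ka = 0.44),
                          sigma = 0.24, cov_coeffs = numeric()) {
  check_positive(tvcl, "tvcl")
  check_positive(tvv, "tvv")
  check_positive(tvka, "tvka")
  if (length(omega) != 3 || any(!is.finite(omega)) || any(omega < 0)) {
    stop_bad("omega must be three finite non-negative SDs (CL, V, Ka)")
  }
  check_positive(sigma, "sigma")
  structure(list(
    theta = c(tvcl = unname(tvcl), tvv = unname(tvv), tvka = unname(tvka)),
    omega = setNames(as.numeric(omega), c("cl", "v", "ka")),
    sigma = as.numeric(sigma),
    cov_coeffs = cov_coeffs
  ), class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("One-compartment oral PK parameters\n")
  cat(sprintf("  CL/F %.3g L/h   Vd/F %.3g L   Ka %.3g 1/h   (t1/2 %.2f h)\n",
              x$theta["tvcl"], x$theta["tvv"], x$theta["tvka"],
              half_life(x$theta["tvcl"], x$theta["tvv"])))
  cat(sprintf("  omega (log-SD): CL %.3g  V %.3g  Ka %.3g;  sigma %.3g\n",
              x$omega["cl"], x$omega["v"], x$omega["ka"], x$sigma))
  if (length(x$cov_coeffs)) {
    cat("  covariate coefficients:",
        paste(names(x$cov_coeffs), signif(x$cov_coeffs, 3), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Single-dose one-compartment concentration
#'
#' Closed-form plasma concentration after one oral dose under first-order
#' absorption and elimination:
#' \deqn{C(t) = \frac{D\,K_a}{V (K_a - k)} (e^{-k t} - e^{-K_a t}),\quad
#'       k = CL/V,}
#' evaluated with the limiting form \eqn{(D k t / V) e^{-k t}} when
#' \eqn{K_a} and \eqn{k} coincide to within a relative 1e-8 band, so the
#' function is continuous through the removable singularity. Doses are mg,
#' times hours, parameters L/h and L; the result is in ng/mL (1 mg/L =
#' 1000 ng/mL).
#'
#' @param dose oral dose (mg)
#' @param t time after the dose (h); vectorized
#' @param cl apparent clearance CL/F (L/h)
#' @param v apparent volume Vd/F (L)
#' @param ka absorption rate constant (1/h)
#' @return concentrations in ng/mL, 0 at `t = 0`
#' @examples
#' conc_single_dose(50, 0:12, cl = 11.6, v = 72.8, ka = 1.64)
#' @export
conc_single_dose <- function(dose, t, cl, v, ka) {
  check_positive(dose, "dose")
  check_positive(cl, "cl")
  check_positive(v, "v")
  check_positive(ka, "ka")
  if (any(t < 0)) stop_bad("t must be >= 0")
  ng_per_mg_L * .cpp_profile(0, dose, as.numeric(t), cl, v, ka)
}

#' Concentration profile under a multiple-dose history
#'
#' Superposition of [conc_single_dose()] over a dosing history: the
#' concentration at each requested time is the sum of the single-dose curves
#' of all doses given strictly before that time. Linearity of the
#' one-compartment model makes this exact.
#'
#' @param doses data.frame with columns `time` (h) and `amt` (mg), sorted by
#'   time
#' @param times evaluation times (h)
#' @inheritParams conc_single_dose
#' @return concentrations in ng/mL at `times`
#' @examples
#' reg <- data.frame(time = seq(0, 72, by = 8), amt = 50)
#' conc_profile(reg, c(73, 74, 76), cl = 11.6, v = 72.8, ka = 1.64)
#' @export
conc_profile <- function(doses, times, cl, v, ka) {
  if (is.null(doses) || nrow(doses) == 0) {
    warning("empty dose history: returning an all-zero profile")
    return(rep(0, length(times)))
  }
  if (is.unsorted(doses$time)) stop_bad("doses must be sorted by time")
  check_positive(doses$amt, "dose amounts")
  check_positive(cl, "cl")
  check_positive(v, "v")
  check_positive(ka, "ka")
  ng_per_mg_L * .cpp_profile(as.numeric(doses$time), as.numeric(doses$amt),
                             as.numeric(times), cl, v, ka)
}

#' Individual parameters from typical values, covariates and random effects
#'
#' Applies the multiplicative covariate model and the exponential
#' between-subject model: for clearance, e.g.
#' \eqn{CL_i = TVCL \prod_c g_c(x_{ic}) \, e^{\eta_{CL,i}}}, where each
#' \eqn{g_c} is a power term \eqn{(x/\mathrm{ref})^{\theta_c}} for a
#' continuous covariate or a category multiplier for a categorical one.
#'
#' @param params a [pk_parameters()] object (its `cov_coeffs` supply the
#'   coefficient of each effect in `effects`)
#' @param covariates one-row data.frame (or named list) holding every
#'   covariate named by `effects`
#' @param eta named numeric vector of random effects `c(cl=, v=, ka=)`
#'   (log scale); defaults to zeros
#' @param effects list of [covariate_effect()] objects
#' @return list with elements `cl`, `v`, `ka` (individual values) and `eta`
#' @examples
#' individual_from_typical(pk_parameters(), covariates = list(),
#'                         eta = c(cl = 0.1, v = 0, ka = 0))
#' @export
individual_from_typical <- function(params, covariates = list(),
                                    eta = c(cl = 0, v = 0, ka = 0),
                                    effects = list()) {
  stopifnot(inherits(params, "pk_parameters"))
  eta <- eta[c("cl", "v", "ka")]
  eta[is.na(eta)] <- 0
  fac <- covariate_factors(effects, params$cov_coeffs, covariates)
  list(
    cl = unname(params$theta["tvcl"] * fac["cl"] * exp(eta["cl"])),
    v  = unname(params$theta["tvv"]  * fac["v"]  * exp(eta["v"])),
    ka = unname(params$theta["tvka"] * fac["ka"] * exp(eta["ka"])),
    eta = eta
  )
}

#' Elimination half-life
#'
#' \eqn{t_{1/2} = \ln(2) \, V / CL}. With the adult baclofen typical values
#' (CL/F 11.6 L/h, Vd/F 72.8 L) this is 4.4 h.
#'
#' @inheritParams conc_single_dose
#' @return half-life in hours
#' @examples
#' half_life(11.6, 72.8)
#' @export
half_life <- function(cl, v) {
  check_positive(cl, "cl")
  check_positive(v, "v")
  log(2) * v / cl
}
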