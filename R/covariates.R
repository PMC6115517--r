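#' Declare a covariate effect on a structural parameter
#'
#' A covariate effect links one covariate to one PK parameter
#' multiplicatively:
#' * `power` (continuous): factor \eqn{(x/\mathrm{ref})^{\theta}}, `ref`
#'   normally the analysis-dataset median; 1 added parameter.
#' * `categorical` (two levels): factor \eqn{\theta^{I(x \ne \mathrm{ref})}},
#'   i.e. multiplier 1 for the reference level; 1 added parameter.
#' * `multilevel`: one multiplier per non-reference level; `levels - 1`
#'   added parameters.
#'
#' @param param target parameter, one of `"cl"`, `"v"`, `"ka"`
#' @param covariate column name in the covariate table
#' @param form `"power"`, `"categorical"` or `"multilevel"`
#' @param ref reference value: the centring value for `power` (required),
#'   the reference level otherwise
#' @param levels for `multilevel`: the full set of (possibly pooled) levels
#' @param map optional named vector mapping raw levels to pooled levels
#'   (applied before the multipliers); see [pool_rare_levels()]
#' @return a `covariate_effect` object (fields include `df`, the number of
#'   parameters the effect adds)
#' @examples
#' covariate_effect("cl", "WT", "power", ref = 75)
#' covariate_effect("cl", "SEX", "categorical", ref = 0)
#' @export
covariate_effect <- function(param = c("cl", "v", "ka"), covariate,
                             form = c("power", "categorical", "multilevel"),
                             ref = NULL, levels = NULL, map = NULL) {
  param <- match.arg(param)
  form <- match.arg(form)
  if (form == "power") {
    check_positive(ref, paste0("reference value for ", covariate))
    df <- 1L
  } else if (form == "categorical") {
    if (is.null(ref)) stop_bad("categorical effect needs a reference level")
    df <- 1L
  } else {
    if (is.null(levels) || length(levels) < 2) {
      stop_bad("multilevel effect needs >= 2 levels")
    }
    if (is.null(ref)) ref <- levels[1]
    if (!ref %in% levels) stop_bad("reference level not among levels")
    df <- length(levels) - 1L
  }
  structure(list(param = param, covariate = covariate, form = form,
                 ref = ref, levels = levels, map = map, df = df),
            class = "covariate_effect")
}

#' @export
print.covariate_effect <- function(x, ...) {
  cat(sprintf("covariate effect: %s ~ %s (%s, %d df, ref %s)\n",
              toupper(x$param), x$covariate, x$form, x$df,
              paste(format(x$ref), collapse = "/")))
  invisible(x)
}

#' @noRd
effect_label <- function(ef) paste0(ef$param, "~", ef$covariate)

# Coefficient names, one per added parameter, in packing order.
#' @noRd
effect_coef_names <- function(effects) {
  unlist(lapply(effects, function(ef) {
    if (ef$form == "multilevel") {
      paste0(effect_label(ef), "[", setdiff(ef$levels, ef$ref), "]")
    } else {
      effect_label(ef)
    }
  }), use.names = FALSE) %||% character()
}

# Multiplicative covariate factors for every row of a covariate table.
# coeffs are on the natural scale (exponents, multipliers), packed in
# effect order. Returns an n x 3 matrix with columns cl, v, ka.
#' @noRd
covariate_factor_table <- function(effects, coeffs, covtab) {
  n <- if (is.data.frame(covtab)) nrow(covtab) else 1L
  fac <- matrix(1, n, 3, dimnames = list(NULL, c("cl", "v", "ka")))
  ci <- 1L
  for (ef in effects) {
    th <- coeffs[ci:(ci + ef$df - 1L)]
    ci <- ci + ef$df
    x <- covtab[[ef$covariate]]
    if (is.null(x) || anyNA(x)) {
      stop_bad("missing covariate '", ef$covariate, "' required by effect ",
               effect_label(ef))
    }
    if (!is.null(ef$map)) x <- unname(ef$map[as.character(x)])
    f <- switch(ef$form,
      power = (x / ef$ref)^th,
      categorical = ifelse(x == ef$ref, 1, th),
      multilevel = {
        fl <- rep(1, n)
        other <- setdiff(ef$levels, ef$ref)
        for (j in seq_along(other)) fl[x == other[j]] <- th[j]
        fl
      })
    fac[, ef$param] <- fac[, ef$param] * f
  }
  fac
}

#' @noRd
covariate_factors <- function(effects, coeffs, covariates) {
  covtab <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (nrow(covtab) == 0) covtab <- data.frame(row.names = 1)
  covariate_factor_table(effects, coeffs, covtab)[1, ]
}

#' Cockcroft-Gault creatinine clearance
#'
#' \eqn{CRCL = (140 - \mathrm{age}) \cdot \mathrm{weight} / (72 \cdot
#' S_{cr})}, multiplied by 0.85 for females. Serum creatinine in mg/dL,
#' weight in kg, result in mL/min.
#'
#' @param age years (0-140; the age term vanishes at 140)
#' @param weight kg
#' @param scr serum creatinine (mg/dL)
#' @param sex 0/\"male\" or 1/\"female\"
#' @return creatinine clearance (mL/min)
#' @examples
#' cockcroft_gault(40, 72, 1.0, "male")  # 100
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  if (any(age < 0) || any(age > 140)) stop_bad("age must be in [0, 140]")
  check_positive(weight, "weight")
  check_positive(scr, "serum creatinine")
  female <- is_female(sex)
  (140 - age) * weight / (72 * scr) * ifelse(female, 0.85, 1)
}

#' @noRd
is_female <- function(sex) {
  if (is.character(sex)) {
    tolower(substr(sex, 1, 1)) == "f"
  } else {
    sex == 1
  }
}

#' Body mass index and lean body mass
#'
#' BMI = weight / height^2 (kg/m^2). Lean body mass uses the James
#' equations: males \eqn{1.10 W - 128 (W/H_{cm})^2}, females
#' \eqn{1.07 W - 148 (W/H_{cm})^2}.
#'
#' @param weight kg
#' @param height metres
#' @param sex 0/\"male\" or 1/\"female\"
#' @return data.frame with columns `bmi` (kg/m^2) and `lbm` (kg), with the
#'   LBM formula recorded in attribute `lbm_formula`
#' @examples
#' derived_covariates(80, 2.0, "male")
#' @export
derived_covariates <- function(weight, height, sex) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  female <- is_female(sex)
  ht_cm <- height * 100
  lbm <- ifelse(female,
                1.07 * weight - 148 * (weight / ht_cm)^2,
                1.10 * weight - 128 * (weight / ht_cm)^2)
  out <- data.frame(bmi = weight / height^2, lbm = lbm)
  attr(out, "lbm_formula") <- "James"
  out
}

#' Likelihood-ratio OFV thresholds
#'
#' Upper-tail chi-squared quantile used to judge a change in the objective
#' function value between nested models: 3.84 for 1 df at P = 0.05
#' (forward inclusion), 10.8 for 1 df at P = 0.001 and 16.3 for 3 df at
#' P = 0.001 (backward elimination).
#'
#' @param df degrees of freedom (parameters added)
#' @param alpha significance level
#' @param rounded round to 3 significant digits (the reporting convention);
#'   set `FALSE` for the raw quantile used in selection decisions
#' @return critical delta-OFV
#' @examples
#' lrt_threshold(1, 0.05)   # 3.84
#' lrt_threshold(1, 0.001)  # 10.8
#' lrt_threshold(3, 0.001)  # 16.3
#' @export
lrt_threshold <- function(df, alpha, rounded = TRUE) {
  if (any(df < 1)) stop_bad("df must be >= 1")
  if (any(alpha <= 0) || any(alpha >= 1)) stop_bad("alpha must be in (0, 1)")
  q <- qchisq(1 - alpha, df)
  if (rounded) signif(q, 3) else q
}

#' Pool rare categorical levels
#'
#' Levels with prevalence below `min_prop` are merged into their nearest
#' neighbouring level (by sorted level order; the smaller neighbour wins
#' ties), repeatedly, until every remaining level reaches the threshold. If
#' only one level survives the covariate carries no contrast and should be
#' dropped.
#'
#' @param x vector of observed category labels
#' @param min_prop minimum level prevalence (default 0.10)
#' @return list with `map` (named vector raw level -> pooled level),
#'   `levels` (pooled level set) and `dropped` (TRUE when < 2 levels remain)
#' @examples
#' pool_rare_levels(c(rep(1, 20), rep(2, 20), 3))
#' @export
pool_rare_levels <- function(x, min_prop = 0.10) {
  lev <- sort(unique(x))
  map <- setNames(lev, as.character(lev))
  repeat {
    pooled <- unname(map[as.character(x)])
    tab <- table(pooled)
    prop <- tab / length(x)
    if (length(tab) < 2 || all(prop >= min_prop)) break
    rare <- names(tab)[which.min(prop)]
    cur <- sort(unique(unname(map)))
    i <- match(rare, as.character(cur))
    neigh <- c(if (i > 1) cur[i - 1], if (i < length(cur)) cur[i + 1])
    counts <- tab[as.character(neigh)]
    target <- neigh[which.min(counts)]
    map[unname(map) == cur[i]] <- target
  }
  final <- sort(unique(unname(map)))
  list(map = map, levels = final, dropped = length(final) < 2)
}

#' Build the default candidate covariate set
#'
#' Constructs the screened covariate-parameter pairs: every clinical
#' covariate (daily dose, dose group, intakes/day, sex, weight, age, BMI,
#' LBM, creatinine clearance, serum creatinine, prothrombin time, bilirubin,
#' AST, ALT) on clearance; body-size covariates and sex additionally on
#' volume; dose and intakes/day additionally on Ka. Continuous covariates
#' are centred at the analysis-dataset median; categorical covariates are
#' pooled with [pool_rare_levels()] first, and dropped (with a log entry)
#' when fewer than two levels survive.
#'
#' @param study a `pk_study` object (its covariate table drives references
#'   and pooling)
#' @return list of [covariate_effect()] objects; dropped candidates are
#'   recorded in attribute `log`
#' @export
default_candidates <- function(study) {
  covtab <- study$covariates
  cont_cl <- intersect(
    c("DOSE", "NINT", "WT", "AGE", "BMI", "LBM", "CRCL", "CREA", "PT",
      "BILI", "AST", "ALT"), names(covtab))
  cands <- list()
  log <- character()
  add_cont <- function(param, cov) {
    covariate_effect(param, cov, "power", ref = median(covtab[[cov]]))
  }
  for (cov in cont_cl) cands[[length(cands) + 1L]] <- add_cont("cl", cov)
  for (cov in intersect(c("WT", "BMI", "LBM"), names(covtab))) {
    cands[[length(cands) + 1L]] <- add_cont("v", cov)
  }
  for (cov in intersect(c("DOSE", "NINT"), names(covtab))) {
    cands[[length(cands) + 1L]] <- add_cont("ka", cov)
  }
  add_cat <- function(param, cov) {
    pool <- pool_rare_levels(covtab[[cov]])
    if (pool$dropped) {
      log <<- c(log, paste0(param, "~", cov,
                            ": dropped, < 2 levels after 10% pooling"))
      return(NULL)
    }
    tab <- table(unname(pool$map[as.character(covtab[[cov]])]))
    ref <- as.numeric(names(tab)[which(tab == max(tab))])[1]
    if (length(pool$levels) == 2) {
      covariate_effect(param, cov, "categorical", ref = ref,
                       map = pool$map)
    } else {
      covariate_effect(param, cov, "multilevel", ref = ref,
                       levels = pool$levels, map = pool$map)
    }
  }
  for (pc in list(c("cl", "GRP"), c("cl", "SEX"), c("v", "SEX"))) {
    if (pc[2] %in% names(covtab)) {
      ef <- add_cat(pc[1], pc[2])
      if (!is.null(ef)) cands[[length(cands) + 1L]] <- ef
    }
  }
  attr(cands, "log") <- log
  cands
}
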