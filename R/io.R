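# Event-table dialect: CSV columns ID, TIME (h, 0-based from each subject's
# first dose), AMT (mg, doses only), DV (ng/mL, quantified observations
# only), EVID (1 dose / 0 observation), MDV (1 when DV missing), BLQ (0/1),
# followed by one covariate block repeated on every row. DV is stored in
# assay units (ng/mL) and converted to mg/L internally (x 1/1000).

CORE_COLS <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "BLQ")

#' Assemble a PK study object
#'
#' @param events event data.frame in the package dialect (see
#'   [read_pk_dataset()])
#' @param covariates one row per subject (column `ID` plus covariates)
#' @param lloq lower limit of quantification (ng/mL)
#' @param truth optional generator truth record
#' @param schedule optional sampling-window tags
#' @return validated object of class `pk_study`
#' @export
pk_study <- function(events, covariates, lloq = 5, truth = NULL,
                     schedule = NULL) {
  x <- structure(list(events = events, covariates = covariates, lloq = lloq,
                      truth = truth, schedule = schedule),
                 class = "pk_study")
  validate_pk_study(x)
  x
}

#' @noRd
validate_pk_study <- function(x) {
  ev <- x$events
  miss <- setdiff(CORE_COLS, names(ev))
  if (length(miss)) stop_bad("event table lacks column(s): ",
                             paste(miss, collapse = ", "))
  bad <- which(ev$BLQ == 1 & !is.na(ev$DV))
  if (length(bad)) stop_bad("row ", bad[1], ": BLQ = 1 but DV is present")
  bad <- which(ev$BLQ == 1 & ev$MDV != 1)
  if (length(bad)) stop_bad("row ", bad[1], ": BLQ = 1 requires MDV = 1")
  bad <- which(ev$EVID == 1 & (is.na(ev$AMT) | ev$AMT <= 0))
  if (length(bad)) stop_bad("row ", bad[1], ": dose row needs AMT > 0")
  bad <- which(ev$EVID == 0 & ev$MDV == 0 & (is.na(ev$DV) | ev$DV <= 0))
  if (length(bad)) stop_bad("row ", bad[1],
                            ": observation row with MDV = 0 needs DV > 0")
  for (id in unique(ev$ID)) {
    sub <- ev[ev$ID == id, ]
    if (is.unsorted(sub$TIME)) {
      r <- which(ev$ID == id)[which(diff(sub$TIME) < 0)[1] + 1L]
      stop_bad("row ", r, ": TIME not non-decreasing within subject ", id)
    }
    o <- sub$EVID == 0
    if (any(o) && any(sub$EVID == 1)) {
      first_dose <- min(sub$TIME[sub$EVID == 1])
      orphan <- which(o & sub$TIME < first_dose)
      if (length(orphan)) {
        stop_bad("row ", which(ev$ID == id)[orphan[1]],
                 ": observation before subject ", id, "'s first dose")
      }
    } else if (any(o)) {
      stop_bad("subject ", id, " has observations but no dose record")
    }
  }
  if (!is.null(x$covariates)) {
    if (!"ID" %in% names(x$covariates)) stop_bad("covariate table lacks ID")
    missing_ids <- setdiff(unique(ev$ID), x$covariates$ID)
    if (length(missing_ids)) {
      stop_bad("no covariate row for subject(s): ",
               paste(missing_ids, collapse = ", "))
    }
  }
  invisible(x)
}

#' @noRd
as_pk_study <- function(x) {
  if (inherits(x, "pk_study")) return(x)
  if (is.data.frame(x)) {
    covcols <- setdiff(names(x), CORE_COLS)
    covs <- x[!duplicated(x$ID), c("ID", covcols), drop = FALSE]
    rownames(covs) <- NULL
    return(pk_study(x[, CORE_COLS], covs))
  }
  stop_bad("cannot interpret object of class ", class(x)[1], " as a PK study")
}

#' @export
print.pk_study <- function(x, ...) {
  ev <- x$events
  nobs <- sum(ev$EVID == 0)
  cat("PK study dataset\n")
  cat(sprintf("  %d subjects, %d dose records, %d observations (%d BLQ at LLOQ %g ng/mL)\n",
              length(unique(ev$ID)), sum(ev$EVID == 1), nobs,
              sum(ev$BLQ == 1), x$lloq))
  if (!is.null(x$truth)) cat("  generator truth record attached\n")
  invisible(x)
}

#' Read a PK event dataset
#'
#' Reads the CSV event-table dialect (`ID, TIME, AMT, DV, EVID, MDV, BLQ`
#' plus covariate columns), validates its invariants (BLQ implies missing
#' DV, non-decreasing times, no observation before the first dose) with
#' row-numbered errors, and reports counts.
#'
#' @param path CSV file
#' @param lloq lower limit of quantification (ng/mL)
#' @param quiet suppress the row-count message
#' @return a `pk_study`
#' @export
read_pk_dataset <- function(path, lloq = 5, quiet = FALSE) {
  if (!file.exists(path)) stop_bad("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(CORE_COLS, names(df))
  if (length(unknown)) stop_bad("missing column(s): ",
                                paste(unknown, collapse = ", "))
  st <- as_pk_study(df)
  st$lloq <- lloq
  if (!quiet) {
    message(sprintf("%d rows: %d subjects, %d observations, %d BLQ",
                    nrow(df), length(unique(df$ID)), sum(df$EVID == 0),
                    sum(df$BLQ == 1)))
  }
  st
}

#' @noRd
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, trim = TRUE, scientific = FALSE,
                                 digits = 15)
  }, "")
  out
}

#' Write a PK event dataset
#'
#' Writes the event table (with the covariate block repeated on every row)
#' in the CSV dialect read by [read_pk_dataset()]. Numeric formatting is
#' deterministic, so write -> read -> write round-trips byte-for-byte.
#'
#' @param study a `pk_study`
#' @param path output CSV file
#' @return `path`, invisibly
#' @export
write_pk_dataset <- function(study, path) {
  study <- as_pk_study(study)
  ev <- study$events
  cov <- study$covariates
  covcols <- setdiff(names(cov), "ID")
  full <- cbind(ev, cov[match(ev$ID, cov$ID), covcols, drop = FALSE])
  txt <- vapply(names(full), function(cn) fmt_num(full[[cn]]),
                character(nrow(full)))
  lines <- c(paste(names(full), collapse = ","),
             apply(txt, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' YAML configuration carrying design overrides, initial estimates,
#' optimizer settings, the candidate covariate search space, replicate
#' counts and the master seed. Unknown top-level keys are rejected; the
#' full configuration and its hash are returned for echoing into run logs,
#' so reruns with the same hash reproduce all deterministic artifacts.
#'
#' @param path YAML file
#' @return the configuration list, with attributes `hash` and `yaml`
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("design", "init", "settings", "candidates", "replicates",
               "bootstrap", "seed", "outdir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) stop_bad("unknown config key(s): ",
                                paste(unknown, collapse = ", "))
  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) || cfg$seed %% 1 != 0)) {
    stop_bad("seed must be an integer")
  }
  for (k in c("replicates", "bootstrap")) {
    if (!is.null(cfg[[k]]) && (!is.numeric(cfg[[k]]) || cfg[[k]] < 2)) {
      stop_bad(k, " must be a number >= 2")
    }
  }
  attr(cfg, "hash") <- rlang::hash(cfg)
  attr(cfg, "yaml") <- yaml::as.yaml(cfg)
  cfg
}

#' Parameter-table summary of a fit
#'
#' Aggregates a [pk_fit()] (and optionally a [bootstrap_ci()] result) into
#' the conventional reporting table: estimate and RSE% per parameter,
#' bootstrap 95% CI when available, the between-subject SDs both on the log
#' scale and as approximate %CV (\eqn{100\sqrt{e^{\omega^2} - 1}}), and the
#' elimination half-life.
#'
#' @param fit a `pk_fit`
#' @param boot optional `pk_bootstrap` (see [bootstrap_ci()])
#' @return data.frame with columns parameter, estimate, rse_pct, ci_lo,
#'   ci_hi, cv_pct
#' @export
pk_report <- function(fit, boot = NULL) {
  stopifnot(inherits(fit, "pk_fit"))
  p <- fit$params
  est <- c(p$theta, p$cov_coeffs,
           omega_cl = unname(p$omega["cl"]), omega_v = unname(p$omega["v"]),
           omega_ka = unname(p$omega["ka"]), sigma = p$sigma)
  rse <- rep(NA_real_, length(est))
  names(rse) <- names(est)
  if (!is.null(fit$rse)) {
    common <- intersect(names(est), names(fit$rse))
    rse[common] <- fit$rse[common]
  }
  ci <- matrix(NA_real_, length(est), 2,
               dimnames = list(names(est), c("lo", "hi")))
  if (!is.null(boot)) {
    common <- intersect(rownames(boot$ci), names(est))
    ci[common, ] <- as.matrix(boot$ci[common, c("lo", "hi")])
  }
  cv <- rep(NA_real_, length(est))
  om <- grep("^(omega_|sigma)", names(est))
  cv[om] <- 100 * sqrt(exp(est[om]^2) - 1)
  out <- data.frame(parameter = names(est), estimate = unname(est),
                    rse_pct = unname(rse), ci_lo = ci[, 1], ci_hi = ci[, 2],
                    cv_pct = unname(cv), row.names = NULL)
  out <- rbind(out, data.frame(
    parameter = "t_half_h",
    estimate = unname(half_life(p$theta["tvcl"], p$theta["tvv"])),
    rse_pct = NA, ci_lo = NA, ci_hi = NA, cv_pct = NA))
  rownames(out) <- NULL
  out
}
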