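#' @noRd
stop_bad <- function(...) stop(..., call. = FALSE)

#' @noRd
check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_bad(what, " must be a positive finite number")
  }
  invisible(x)
}

# Inverse-CDF truncated-normal draw: consumes exactly length(n) uniforms,
# so per-subject random streams stay aligned whatever the bounds.
#' @noRd
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (lower >= upper) stop_bad("impossible truncation bounds [", lower, ", ", upper, "]")
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# Deterministic per-subject substream seed derived from a master seed.
# Kept below 2^31 - 1 so it is a valid R integer seed.
#' @noRd
substream_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 16807) %% 2147483647L)
}

#' @noRd
ng_per_mg_L <- 1000  # 1 mg/L = 1000 ng/mL

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
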