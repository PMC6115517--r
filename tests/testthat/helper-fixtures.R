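# Shared fixtures, built in code at test time.

# published adult baclofen parameters (generating truth for simulations)
truth_params <- function() pk_parameters()

# a 15-subject reduction of the four-group design for cheap replicate checks
small_design <- function() study_design(group_n = c(3, 4, 4, 4))

# cache a simulated 57-subject study + base fit per seed across test files
.fixture_env <- new.env(parent = emptyenv())

fixture_study <- function(seed) {
  key <- paste0("study", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_study(seed = seed)
  }
  .fixture_env[[key]]
}

fixture_fit <- function(seed) {
  key <- paste0("fit", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- pk_fit(fixture_study(seed),
                                  settings = pk_settings(compute_se = FALSE))
  }
  .fixture_env[[key]]
}

# one-compartment oral model solved by adaptive ODE integration (deSolve):
# the independent oracle for the closed-form concentration
ode_conc_oracle <- function(dose, t, cl, v, ka) {
  if (t == 0) return(0)
  rhs <- function(time, y, p) list(c(-ka * y[1], ka * y[1] - (cl / v) * y[2]))
  out <- deSolve::lsoda(c(gut = dose, central = 0), c(0, t), rhs, NULL,
                       rtol = 1e-11, atol = 1e-12)
  1000 * out[nrow(out), "central"] / v
}

# exact -2 log marginal likelihood of an eta-linear Gaussian model
# y_i = X_i eta_i + b_i + e, eta ~ N(0, diag(omega2)), e ~ N(0, sigma2 I)
exact_gaussian_m2ll <- function(y, X, b, omega2, sigma2) {
  n <- length(y)
  V <- diag(sigma2, n) + X %*% diag(omega2, length(omega2)) %*% t(X)
  r <- y - b
  as.numeric(n * log(2 * pi) + determinant(V)$modulus +
               t(r) %*% solve(V, r))
}
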