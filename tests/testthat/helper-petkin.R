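# Shared fixtures and independent oracles, all built in code.

# Closed-form integral of the Feng input from 0 to T (antiderivative
# oracle, independent of feng_eval).
feng_integral_closed <- function(p, T) {
  U <- T - p$tau
  if (U <= 0) return(0)
  int_ue <- function(a, u) exp(a * u) * (u / a - 1 / a^2) + 1 / a^2
  int_e <- function(a, u) (exp(a * u) - 1) / a
  p$A1 * int_ue(p$l1, U) -
    (p$A2 + p$A3) * int_e(p$l1, U) +
    p$A2 * int_e(p$l2, U) +
    p$A3 * int_e(p$l3, U)
}

# A smooth, fast default parent input for kinetics tests.
test_input_fun <- function() {
  p <- feng_params(tau = 0.5, A1 = 230, A2 = 12, A3 = 6,
                   l1 = -1.4, l2 = -0.25, l3 = -0.012)
  function(t) feng_eval(p, t)
}

# Direct stiff-ODE solution of the 2T model (independent oracle).
ode_tissue <- function(K1, k2, k3, k4, input_fun, times) {
  rhs <- function(t, y, parms) {
    cp <- input_fun(t)
    list(c(K1 * cp - (k2 + k3) * y[1] + k4 * y[2],
           k3 * y[1] - k4 * y[2]))
  }
  sol <- deSolve::lsoda(c(0, 0), c(0, times), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  rowSums(sol[-1, 2:3, drop = FALSE])
}

# Quick fit options for unit tests (fewer starts than the default 10).
quick_opts <- function(...) fit_options(n_starts = 4L, ...)
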