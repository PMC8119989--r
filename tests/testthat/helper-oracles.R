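# Independent oracles used across test files.

# Fixed-step classical RK4 integration of the distance-coupled system,
# with the rate forms written out inline (independent of the package's
# solver path).  Returns I/N sampled every `thin` steps.
rk4_prevalence <- function(beta_star, D_bar_star, nu, gamma, lambda1,
                           lambda2, D_star, N, S0, I0, R0, D0, form,
                           t_end, h = 1e-3, thin = 100L) {
  beta <- switch(form,
    beta1 = function(D) beta_star * (2 * D_bar_star / (D_bar_star + D))^nu,
    beta2 = function(D) beta_star * 2 * D_bar_star^nu /
      (D_bar_star^nu + D^nu),
    beta3 = function(D) beta_star * (D_bar_star / D)^nu,
    beta4 = function(D) beta_star * exp(1 - (D / D_bar_star)^nu))
  f <- function(y) {
    inc <- beta(y[4]) * y[1] * y[2] / N
    c(-inc, inc - gamma * y[2], gamma * y[2],
      -lambda1 * (y[4] - D_star) + lambda2 * y[2] / N)
  }
  nsteps <- round(t_end / h)
  y <- c(S0, I0, R0, D0)
  out_t <- numeric(nsteps %/% thin + 1L)
  out_p <- numeric(nsteps %/% thin + 1L)
  out_p[1] <- I0 / N
  j <- 1L
  for (k in seq_len(nsteps)) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (k %% thin == 0L) {
      j <- j + 1L
      out_t[j] <- k * h
      out_p[j] <- y[2] / N
    }
  }
  list(t = out_t, prevalence = out_p)
}

# Closed-form peak prevalence of the classical constant-rate SIR model
# (from the invariant I + S - ln(S)/R0 = const, peak at S = 1/R0),
# with compartments as fractions of N.
sir_peak_prevalence <- function(R0, S0 = 0.99999, I0 = 0.00001) {
  I0 + S0 - (1 + log(R0 * S0)) / R0
}

# Final susceptible fraction of the classical SIR model: the root of
# log(s) = -R0 (1 - s).
sir_final_size <- function(R0) {
  uniroot(function(s) log(s) + R0 * (1 - s),
          interval = c(1e-8, 1 - 1e-8), tol = 1e-12)$root
}

# Parameters/state for a run that reduces to classical SIR
# (lambda2 = 0, D0 = D*): R0 = beta*/gamma = 2.5 at D* = Dbar*.
classical_params <- function(beta_star = 0.5, gamma = 0.2)
  model_parameters(beta_star = beta_star, gamma = gamma, lambda2 = 0,
                   D_star = 1.05, nu = 1)
classical_init <- function() initial_state(D0 = 1.05)
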