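# Cumulative composite Simpson quadrature on a uniform grid.
#
# Returns F with F[k] ~ integral of f from x[1] to x[k], fourth-order
# accurate.  Even-offset points use the classical composite rule; the
# trailing single interval at odd offsets uses the asymmetric three-point
# rule h/12 * (5 f_k + 8 f_{k-1} - f_{k-2}).
cum_simpson <- function(y, h) {
  n <- length(y)
  out <- numeric(n)
  if (n < 2L) return(out)
  if (n == 2L) { out[2] <- h * (y[1] + y[2]) / 2; return(out) }
  out[2] <- h * (5 * y[1] + 8 * y[2] - y[3]) / 12
  for (k in 3:n)
    out[k] <- out[k - 2] + h * (y[k - 2] + 4 * y[k - 1] + y[k]) / 3
  # odd offsets beyond the first were built on out[k-2], which already
  # ends at an odd offset handled by the asymmetric rule, so nothing more
  # is needed: parity alternates and both chains are fourth order.
  out
}

# Total composite Simpson integral over the whole grid.
total_simpson <- function(y, h) cum_simpson(y, h)[length(y)]

# D'(t) reconstructed exactly from the model's distance law on the
# trajectory grid (no finite differencing).
distance_derivative <- function(traj) {
  p <- attr(traj, "params")
  -p$lambda1 * (traj$D - p$D_star) + p$lambda2 * traj$I / p$N
}

grid_step <- function(traj) {
  dt <- diff(traj$t)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("trajectory grid is not uniform; validators need the uniform ",
         "output grid produced by simulate_sir()", call. = FALSE)
  dt[1]
}
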