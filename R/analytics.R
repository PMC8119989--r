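#' Closed-form interaction-distance
#'
#' The distance equation is linear in \eqn{D} given the prevalence path,
#' so by an integrating factor
#' \deqn{D(t) = D_* + (D_0 - D_*) e^{-\lambda_1 t}
#'   + \frac{\lambda_2}{N}\int_0^t I(s)\, e^{-\lambda_1 (t-s)}\, ds.}
#' This evaluates that expression by cumulative composite Simpson
#' quadrature of the trajectory's infectious series, providing an
#' independent check on the integrated `D` column.
#'
#' @param traj a `sir_trajectory` from [simulate_sir()].
#' @param t_eval evaluation times; defaults to the trajectory grid.  Must
#'   lie within the trajectory span (off-grid points are spline
#'   interpolated).
#' @return Numeric vector of distances [m] at `t_eval`.
#' @export
closed_form_distance <- function(traj, t_eval = traj$t) {
  stopifnot(inherits(traj, "sir_trajectory"))
  if (any(t_eval < traj$t[1]) || any(t_eval > traj$t[length(traj$t)]))
    stop("`t_eval` outside the trajectory span", call. = FALSE)
  p <- attr(traj, "params"); init <- attr(traj, "init")
  h <- grid_step(traj)
  # e^{-l1 t} * cumulative integral of I(s) e^{+l1 s}
  conv <- exp(-p$lambda1 * traj$t) *
    cum_simpson(traj$I * exp(p$lambda1 * traj$t), h)
  Dcf <- p$D_star + (init$D0 - p$D_star) * exp(-p$lambda1 * traj$t) +
    (p$lambda2 / p$N) * conv
  if (identical(t_eval, traj$t)) return(Dcf)
  stats::spline(traj$t, Dcf, xout = t_eval)$y
}

#' Susceptible depletion log-identity
#'
#' Along any solution, expressing prevalence through the distance law and
#' integrating gives
#' \deqn{\ln\frac{S_0}{S(t)} = \frac{1}{\lambda_2}\int_{D_*}^{D(t)}
#'   \beta(u)\, du + \frac{\lambda_1}{\lambda_2}\int_0^t
#'   \beta(D(u))\,\{D(u) - D_*\}\, du.}
#' The first term is a line integral along the (generally non-monotone)
#' distance path and is evaluated in its path form
#' \eqn{\frac{1}{\lambda_2}\int_0^t \beta(D(u)) D'(u)\, du}, with
#' \eqn{D'} reconstructed exactly from the distance law.  The returned
#' residual series measures joint solver/quadrature consistency.
#'
#' @param traj a `sir_trajectory`; its `lambda2` must be positive (the
#'   identity divides by \eqn{\lambda_2}).
#' @return An `identity_report`: list with `t`, `residual` (absolute,
#'   per grid point), `max_residual` and `rule`.
#' @export
susceptible_identity <- function(traj) {
  stopifnot(inherits(traj, "sir_trajectory"))
  p <- attr(traj, "params"); init <- attr(traj, "init")
  if (p$lambda2 <= 0)
    stop("the susceptible identity divides by lambda2; lambda2 must be > 0",
         call. = FALSE)
  h <- grid_step(traj)
  beta <- transmission_rate(traj$D, attr(traj, "form"), p)
  term1 <- cum_simpson(beta * distance_derivative(traj), h) / p$lambda2
  term2 <- (p$lambda1 / p$lambda2) *
    cum_simpson(beta * (traj$D - p$D_star), h)
  lhs <- log(init$S0 / traj$S)
  res <- abs(lhs - term1 - term2)
  structure(list(t = traj$t, residual = res, max_residual = max(res),
                 rule = sprintf("cumulative composite Simpson, h = %g day", h)),
            class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  cat("Susceptible log-identity report\n")
  cat(sprintf("  max residual %.3e over %d grid points (%s)\n",
              x$max_residual, length(x$t), x$rule))
  invisible(x)
}

#' Final size of the epidemic
#'
#' The number of never-infected individuals as \eqn{t \to \infty}:
#' \deqn{S_\infty = S_0 \Big/ \exp\Big\{\frac{\lambda_1}{\lambda_2}
#'   \int_0^\infty \beta(\Delta D(u) + D_*)\, \Delta D(u)\, du\Big\},
#'   \qquad \Delta D := D - D_*.}
#' The integral is truncated at the trajectory horizon; because
#' \eqn{\Delta D} decays exponentially at rate \eqn{\lambda_1} once the
#' epidemic is over and \eqn{\beta(D) \le \beta(D_*)} for \eqn{D \ge D_*},
#' the neglected tail is at most
#' \eqn{\beta(D_*)\, \Delta D(t_{end})/\lambda_1}, reported alongside.
#'
#' @param traj a `sir_trajectory` integrated to near-equilibrium
#'   (`I/N < 1e-9` at the end) with `lambda2 > 0` and `D0 = D_star`.
#' @return List with `value` (the final-size estimate, units of `N`),
#'   `exponent_tail_bound` (bound on the truncated exponent mass) and
#'   `S_end` (the trajectory's own terminal susceptibles, for comparison).
#' @export
final_susceptibles <- function(traj) {
  stopifnot(inherits(traj, "sir_trajectory"))
  p <- attr(traj, "params"); init <- attr(traj, "init")
  if (p$lambda2 <= 0)
    stop("final-size identity requires lambda2 > 0", call. = FALSE)
  n <- nrow(traj)
  if (traj$I[n] / p$N >= 1e-9)
    stop("trajectory not near equilibrium (I/N = ", traj$I[n] / p$N,
         " at t_end); integrate further", call. = FALSE)
  h <- grid_step(traj)
  beta <- transmission_rate(traj$D, attr(traj, "form"), p)
  dD <- traj$D - p$D_star
  expo <- (p$lambda1 / p$lambda2) * total_simpson(beta * dD, h)
  tail <- if (p$lambda1 > 0)
    transmission_rate(p$D_star, attr(traj, "form"), p) * dD[n] / p$lambda1
  else Inf
  list(value = init$S0 / exp(expo),
       exponent_tail_bound = (p$lambda1 / p$lambda2) * tail,
       S_end = traj$S[n])
}

#' Final size, power-law special case
#'
#' For the power-law rate `beta3` with \eqn{\nu = 1},
#' \eqn{\beta(D)\Delta D = \beta_* \bar D_* (1 - D_*/D)}, so the
#' final-size exponent collapses to
#' \deqn{S_\infty = S_0 / \exp\{(\lambda_1/\lambda_2)\,
#'   \beta_* \bar D_*\, L(\infty)\},\qquad
#'   L(\tau) = \tau - D_* \int_0^\tau du/D(u),}
#' with \eqn{L} increasing.  Numerically equivalent to
#' [final_susceptibles()]; exposed as an independent cross-check.
#'
#' @param traj a `sir_trajectory` run with form `beta3` and `nu = 1`,
#'   integrated to near-equilibrium.
#' @return The final-size estimate (units of `N`).
#' @export
final_susceptibles_beta3 <- function(traj) {
  stopifnot(inherits(traj, "sir_trajectory"))
  p <- attr(traj, "params"); init <- attr(traj, "init")
  if (attr(traj, "form") != "beta3" || p$nu != 1)
    stop("special-case final size applies to beta3 with nu = 1", call. = FALSE)
  if (p$lambda2 <= 0)
    stop("final-size identity requires lambda2 > 0", call. = FALSE)
  n <- nrow(traj)
  if (traj$I[n] / p$N >= 1e-9)
    stop("trajectory not near equilibrium; integrate further", call. = FALSE)
  h <- grid_step(traj)
  L <- traj$t[n] - p$D_star * total_simpson(1 / traj$D, h)
  init$S0 / exp((p$lambda1 / p$lambda2) * p$beta_star * p$D_bar_star * L)
}

# interior strict local maxima of a series, plateau-tolerant
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  for (i in 2:(n - 1))
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) idx <- c(idx, i)
  idx
}

# topographic prominence of peak at index i
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- if (any(x[seq_len(i - 1)] > h)) {
    j <- max(which(x[seq_len(i - 1)] > h))
    min(x[j:i])
  } else min(x[1:i])
  right_range <- (i + 1):length(x)
  right <- if (any(x[right_range] > h)) {
    j <- i + min(which(x[right_range] > h))
    min(x[i:j])
  } else min(x[i:length(x)])
  h - max(left, right)
}

refine_quadratic <- function(t, x, i) {
  y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom >= 0) return(list(time = t[i], value = x[i]))  # degenerate
  delta <- 0.5 * (y1 - y3) / denom
  h <- t[i + 1] - t[i]
  list(time = t[i] + delta * h,
       value = y2 - 0.25 * (y1 - y3) * delta)
}

#' First epidemic peak
#'
#' Locates the first interior local maximum of the prevalence series and
#' refines its position by quadratic interpolation through the three
#' bracketing grid points.  If prevalence decreases monotonically from
#' \eqn{t = 0} (the subcritical regime \eqn{R_0 \le 1}), there is no
#' interior peak and the boundary maximum at \eqn{t = 0} is flagged.
#'
#' @param traj a `sir_trajectory`.
#' @return A `peak_summary`: list with `peak_time` [day],
#'   `peak_prevalence` (\eqn{I/N}), `index` (grid position) and
#'   `interior` (`FALSE` when no interior peak exists, in which case the
#'   other fields describe \eqn{t = 0}).
#' @export
find_first_peak <- function(traj) {
  stopifnot(inherits(traj, "sir_trajectory"))
  x <- traj$prevalence
  if (length(x) < 3L) stop("trajectory too short for peak detection",
                           call. = FALSE)
  idx <- local_maxima(x)
  if (length(idx) == 0L)
    return(structure(list(peak_time = traj$t[1], peak_prevalence = x[1],
                          index = 1L, interior = FALSE),
                     class = "peak_summary"))
  i <- idx[1]
  ref <- refine_quadratic(traj$t, x, i)
  structure(list(peak_time = ref$time, peak_prevalence = ref$value,
                 index = i, interior = TRUE),
            class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  if (x$interior)
    cat(sprintf("Epidemic peak: prevalence %.5f at t = %.2f days\n",
                x$peak_prevalence, x$peak_time))
  else
    cat("No interior epidemic peak (prevalence maximal at t = 0)\n")
  invisible(x)
}

#' All epidemic peaks above a prominence threshold
#'
#' Finds every interior local maximum of prevalence whose topographic
#' prominence is at least `min_prominence`, refines each quadratically,
#' and merges refined peaks closer than 0.5 day (keeping the higher one —
#' dense-output artefacts can split a single peak).  With \eqn{\lambda_2
#' = 0} the model reduces to classical constant-rate SIR and at most one
#' peak is returned; the distance feedback can break that unimodality and
#' produce several waves.
#'
#' @param traj a `sir_trajectory`.
#' @param min_prominence prominence threshold on the prevalence scale
#'   (fraction of `N`); the default `1e-4` suppresses solver ripple.
#' @return Data frame with columns `peak_time`, `peak_prevalence`,
#'   `index`, `prominence`, in time order (zero rows if none).
#' @export
find_all_peaks <- function(traj, min_prominence = 1e-4) {
  stopifnot(inherits(traj, "sir_trajectory"), min_prominence >= 0)
  x <- traj$prevalence
  empty <- data.frame(peak_time = numeric(0), peak_prevalence = numeric(0),
                      index = integer(0), prominence = numeric(0))
  if (length(x) < 3L) return(empty)
  idx <- local_maxima(x)
  if (length(idx) == 0L) return(empty)
  prom <- vapply(idx, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (length(idx) == 0L) return(empty)
  ref <- lapply(idx, function(i) refine_quadratic(traj$t, x, i))
  out <- data.frame(peak_time = vapply(ref, `[[`, numeric(1), "time"),
                    peak_prevalence = vapply(ref, `[[`, numeric(1), "value"),
                    index = idx, prominence = prom)
  # merge refined peaks within 0.5 day, keeping the higher
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (k in 2:nrow(out)) {
      prev <- max(which(keep[seq_len(k - 1)]))
      if (out$peak_time[k] - out$peak_time[prev] < 0.5) {
        if (out$peak_prevalence[k] > out$peak_prevalence[prev])
          keep[prev] <- FALSE else keep[k] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
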