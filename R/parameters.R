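#' Model parameters for the distance-coupled SIR system
#'
#' Bundles all rate and distance constants of the model.  Defaults are the
#' reference scenario used throughout the figure presets: \eqn{\beta_* =
#' 0.5}/day, \eqn{\bar D_* = 1.05} m, \eqn{\gamma = 0.2}/day (a five-day
#' infectious period), \eqn{\lambda_1 = 0.03}/day, \eqn{\lambda_2 = 0.3}
#' m/day, with compartments as fractions of a unit population.
#'
#' @param beta_star baseline transmission rate \eqn{\beta_*} [1/day], the
#'   value every rate form takes at the scaling distance.
#' @param D_bar_star scaling distance \eqn{\bar D_*} [m].
#' @param nu decay exponent \eqn{\nu > 0} controlling how steeply the
#'   transmission rate falls with distance.
#' @param gamma recovery rate \eqn{\gamma} [1/day].
#' @param lambda1 resistance rate \eqn{\lambda_1 \ge 0} [1/day]: how fast
#'   individuals return to their natural-distance.
#' @param lambda2 reaction velocity \eqn{\lambda_2 \ge 0} [m/day]:
#'   converts point prevalence into the speed of distancing.
#' @param D_star natural-distance \eqn{D_*} [m], the distance a society
#'   keeps in the absence of disease.
#' @param N total population size; defaults to 1 so that compartments are
#'   population fractions.
#'
#' @return An object of class `sir_parameters` (a validated named list).
#' @examples
#' p <- model_parameters(D_star = 0.75)
#' basic_reproduction_number("beta3", p)
#' @export
model_parameters <- function(beta_star = 0.5, D_bar_star = 1.05, nu = 1,
                             gamma = 0.2, lambda1 = 0.03, lambda2 = 0.3,
                             D_star = 1.05, N = 1) {
  p <- list(beta_star = beta_star, D_bar_star = D_bar_star, nu = nu,
            gamma = gamma, lambda1 = lambda1, lambda2 = lambda2,
            D_star = D_star, N = N)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter `", nm, "` must be a single finite number", call. = FALSE)
  }
  positive <- c("beta_star", "D_bar_star", "nu", "gamma", "D_star", "N")
  for (nm in positive)
    if (p[[nm]] <= 0)
      stop("parameter `", nm, "` must be > 0", call. = FALSE)
  for (nm in c("lambda1", "lambda2"))
    if (p[[nm]] < 0)
      stop("parameter `", nm, "` must be >= 0", call. = FALSE)
  structure(p, class = "sir_parameters")
}

#' @export
print.sir_parameters <- function(x, ...) {
  cat("Distance-coupled SIR parameters\n")
  cat(sprintf("  beta* = %g /day at scaling distance Dbar* = %g m (nu = %g)\n",
              x$beta_star, x$D_bar_star, x$nu))
  cat(sprintf("  gamma = %g /day, lambda1 = %g /day, lambda2 = %g m/day\n",
              x$gamma, x$lambda1, x$lambda2))
  cat(sprintf("  natural-distance D* = %g m (%s society), N = %g\n",
              x$D_star, classify_society(x$D_star), x$N))
  invisible(x)
}

#' Initial state of the distance-coupled SIR system
#'
#' @param S0,I0,R0 initial compartment sizes, in the same units as `N`
#'   (fractions when `N = 1`).  Defaults start an epidemic with one part in
#'   100,000 infectious.
#' @param D0 initial interaction-distance [m].  The figure scenarios all
#'   start at the natural-distance, `D0 = D_star`.
#' @param N total population the compartments must sum to (checked to
#'   within `tol`).
#' @param tol tolerance for the closure check `S0 + I0 + R0 == N`.
#'
#' @return An object of class `sir_state`.
#' @examples
#' initial_state(D0 = 0.75)
#' @export
initial_state <- function(S0 = 0.99999, I0 = 0.00001, R0 = 0, D0 = 1.05,
                          N = 1, tol = 1e-8) {
  vals <- c(S0 = S0, I0 = I0, R0 = R0, D0 = D0)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("initial state components must be finite numbers", call. = FALSE)
  if (S0 < 0 || I0 < 0 || R0 < 0)
    stop("S0, I0 and R0 must be non-negative", call. = FALSE)
  if (D0 <= 0)
    stop("D0 must be > 0", call. = FALSE)
  if (abs(S0 + I0 + R0 - N) > tol * max(1, N))
    stop("S0 + I0 + R0 must equal N (got ", S0 + I0 + R0,
         " for N = ", N, ")", call. = FALSE)
  structure(list(S0 = S0, I0 = I0, R0 = R0, D0 = D0),
            class = "sir_state")
}

#' @export
print.sir_state <- function(x, ...) {
  cat(sprintf("SIR initial state: S0 = %g, I0 = %g, R0 = %g, D0 = %g m\n",
              x$S0, x$I0, x$R0, x$D0))
  invisible(x)
}

#' Round half away from zero
#'
#' The convention used when comparing computed basic reproduction numbers
#' with one-decimal reference values (base R's `round()` rounds half to
#' even, which would turn 2.25 into 2.2 rather than 2.3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded with ties going away from zero.
#' @examples
#' round_half_away(c(2.25, -2.25), 1)
#' @export
round_half_away <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
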