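society_distances <- c(small = 0.75, medium = 1.05, large = 1.35)

new_preset <- function(name, params, init, form, horizon) {
  structure(list(name = name, params = params, init = init,
                 form = form, horizon = horizon),
            class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("Preset %s: %s, nu = %g, D* = %g m (%s), horizon %g days\n",
              x$name, x$form, x$params$nu, x$params$D_star,
              classify_society(x$params$D_star), x$horizon))
  invisible(x)
}

preset_init <- function(D_star) {
  initial_state(S0 = 0.99999, I0 = 0.00001, R0 = 0, D0 = D_star)
}

#' Figure-style scenario presets
#'
#' Builds the full catalogue of reference scenarios.  All share
#' \eqn{\beta_* = 0.5}, \eqn{\gamma = 0.2}, \eqn{\lambda_1 = 0.03},
#' \eqn{\lambda_2 = 0.3}, \eqn{\bar D_* = 1.05}, initial state
#' \eqn{S_0 = 0.99999}, \eqn{I_0 = 10^{-5}}, \eqn{R_0 = 0} and
#' \eqn{D_0 = D_*}:
#' \itemize{
#'   \item `fig3<a-d>_<society>`, `fig4<a-d>_<society>`,
#'     `fig5<a-d>_<society>`: the four rate forms (subplots a-d map to
#'     beta1-beta4) at \eqn{\nu = 0.5, 1, 1.5} respectively, for the
#'     small (0.75 m), medium (1.05 m) and large (1.35 m) societies.
#'   \item `fig6_<society>`: the power-law rate `beta3` at \eqn{\nu = 1}
#'     (distance and transmission-rate time-series scenario).
#'   \item `fig9_nu<nu>_<form>`: all four forms at
#'     \eqn{\nu \in \{1.5, 4.5, 7.5, 10.5\}} for the average society
#'     \eqn{D_* = \bar D_* = 1.05} (oscillatory regimes, \eqn{R_0 = 2.5}).
#' }
#'
#' @param horizon simulation horizon attached to every preset [day].
#' @return Named list of `scenario_preset` objects.
#' @examples
#' names(build_presets())[1:6]
#' @export
build_presets <- function(horizon = 500) {
  presets <- list()
  add <- function(name, nu, D_star, form) {
    p <- model_parameters(nu = nu, D_star = D_star)
    presets[[name]] <<- new_preset(name, p, preset_init(D_star), form, horizon)
  }
  figs <- c(`3` = 0.5, `4` = 1, `5` = 1.5)
  letters4 <- c(a = "beta1", b = "beta2", c = "beta3", d = "beta4")
  for (fg in names(figs))
    for (lt in names(letters4))
      for (soc in names(society_distances))
        add(sprintf("fig%s%s_%s", fg, lt, soc),
            figs[[fg]], society_distances[[soc]], letters4[[lt]])
  for (soc in names(society_distances))
    add(sprintf("fig6_%s", soc), 1, society_distances[[soc]], "beta3")
  for (nu in c(1.5, 4.5, 7.5, 10.5))
    for (form in rate_forms)
      add(sprintf("fig9_nu%g_%s", nu, form), nu, 1.05, form)
  presets
}

#' Simulate a named preset
#'
#' @param name a preset name from [build_presets()]; a base name such as
#'   `"fig9_nu1.5"` may be combined with a `form` override.
#' @param form optional transmission-rate form overriding the preset's.
#' @param t_end optional horizon override [day].
#' @param ... further arguments passed to [simulate_sir()].
#' @return A `sir_trajectory`.
#' @export
simulate_preset <- function(name, form = NULL, t_end = NULL, ...) {
  presets <- build_presets()
  if (!name %in% names(presets) && !is.null(form) &&
      paste0(name, "_", form) %in% names(presets))
    name <- paste0(name, "_", form)
  if (!name %in% names(presets))
    stop("unknown preset `", name, "`; see build_presets()", call. = FALSE)
  pr <- presets[[name]]
  simulate_sir(pr$params, pr$init,
               form = if (is.null(form)) pr$form else form,
               t_end = if (is.null(t_end)) pr$horizon else t_end, ...)
}

#' Basic reproduction numbers for the caption scenarios
#'
#' Evaluates \eqn{R_0 = \beta(D_*)/\gamma} over every (form, \eqn{\nu},
#' society) combination appearing in the figure scenarios, rounded to one
#' decimal with ties away from zero (the convention used for the printed
#' reference values).
#'
#' @param digits decimal places for rounding; `NULL` for unrounded.
#' @return Data frame with columns `form`, `nu`, `D_star`, `R0`.
#' @examples
#' subset(r0_table(), form == "beta3" & nu == 1)
#' @export
r0_table <- function(digits = 1) {
  grid <- rbind(
    expand.grid(form = rate_forms, nu = c(0.5, 1, 1.5),
                D_star = unname(society_distances),
                stringsAsFactors = FALSE),
    expand.grid(form = rate_forms, nu = c(4.5, 7.5, 10.5), D_star = 1.05,
                stringsAsFactors = FALSE))
  grid <- grid[order(grid$form, grid$nu, grid$D_star), ]
  rownames(grid) <- NULL
  grid$R0 <- mapply(function(form, nu, D_star) {
    basic_reproduction_number(form, model_parameters(nu = nu, D_star = D_star))
  }, grid$form, grid$nu, grid$D_star)
  if (!is.null(digits)) grid$R0 <- round_half_away(grid$R0, digits)
  grid
}

#' Peak size and timing parameter sweeps
#'
#' Reproduces the bar-chart experiments: first-peak prevalence and peak
#' time across one swept quantity for each of the three society types.
#' The base scenario is the power-law rate `beta3` with \eqn{\nu = 1.5},
#' \eqn{\lambda_1 = 0.03}, \eqn{\lambda_2 = 0.3} (swept quantities
#' replace their base value):
#' \describe{
#'   \item{`form`}{the four rate forms beta1-beta4.}
#'   \item{`nu`}{\eqn{\nu \in \{0.5, 1.0, 1.5, 2.0\}}.}
#'   \item{`lambda2`}{reaction velocity \eqn{\in \{0.2, 0.4, 0.6, 0.8\}}.}
#'   \item{`lambda1`}{resistance rate \eqn{\in \{0.02, 0.04, 0.06, 0.08\}}.}
#' }
#'
#' @param sweep which quantity to sweep.
#' @param values optional custom sweep values (a character vector of
#'   forms when `sweep = "form"`).
#' @param societies named vector of natural-distances [m].
#' @param horizon simulation horizon [day]; long enough that the first
#'   peak occurs well inside it at every grid point (asserted).
#' @param ... passed to [simulate_sir()].
#' @return Data frame with one row per (society, sweep value):
#'   `society`, `D_star`, `form`, `nu`, `lambda1`, `lambda2`, `R0`
#'   (unrounded), `peak_prevalence`, `peak_time`.  Rows are ordered by
#'   society, then sweep value, for reproducible diffs.
#' @examples
#' \donttest{sweep_peaks("lambda2")}
#' @export
sweep_peaks <- function(sweep = c("form", "nu", "lambda2", "lambda1"),
                        values = NULL,
                        societies = society_distances,
                        horizon = 500, ...) {
  sweep <- match.arg(sweep)
  if (is.null(values))
    values <- switch(sweep,
      form = rate_forms,
      nu = c(0.5, 1.0, 1.5, 2.0),
      lambda2 = c(0.2, 0.4, 0.6, 0.8),
      lambda1 = c(0.02, 0.04, 0.06, 0.08))
  rows <- list()
  for (soc in names(societies)) {
    for (v in values) {
      base <- list(nu = 1.5, lambda1 = 0.03, lambda2 = 0.3,
                   D_star = societies[[soc]])
      form <- "beta3"
      if (sweep == "form") form <- v else base[[sweep]] <- v
      params <- do.call(model_parameters, base)
      traj <- simulate_sir(params, preset_init(params$D_star), form,
                           t_end = horizon, ...)
      pk <- find_first_peak(traj)
      if (!pk$interior || pk$peak_time > 0.9 * horizon)
        stop("first peak not resolved within the sweep horizon at ",
             soc, ", ", sweep, " = ", v, call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        society = soc, D_star = params$D_star, form = form,
        nu = params$nu, lambda1 = params$lambda1, lambda2 = params$lambda2,
        R0 = basic_reproduction_number(form, params),
        peak_prevalence = pk$peak_prevalence, peak_time = pk$peak_time)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
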