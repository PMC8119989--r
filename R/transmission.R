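#' The four transmission-rate functional forms
#'
#' Tags identifying the available distance-dependent transmission rates.
#' All four are decreasing, convex in the interaction-distance \eqn{D},
#' vanish as \eqn{D \to \infty} and equal \eqn{\beta_*} at the scaling
#' distance \eqn{\bar D_*}:
#' \describe{
#'   \item{beta1}{\eqn{\beta_* [2\bar D_*/(\bar D_* + D)]^\nu}; finite
#'     limit \eqn{2^\nu \beta_*} at \eqn{D = 0}.}
#'   \item{beta2}{\eqn{\beta_*\, 2\bar D_*^\nu/(\bar D_*^\nu + D^\nu)};
#'     limit \eqn{2\beta_*} at \eqn{D = 0}.  Coincides with `beta1` when
#'     \eqn{\nu = 1}.}
#'   \item{beta3}{\eqn{\beta_* (\bar D_*/D)^\nu}; a power law, unbounded
#'     as \eqn{D \to 0^+}.}
#'   \item{beta4}{\eqn{\beta_* \exp[1 - (D/\bar D_*)^\nu]}; limit
#'     \eqn{e\beta_*} at \eqn{D = 0}.}
#' }
#' @export
rate_forms <- c("beta1", "beta2", "beta3", "beta4")

match_rate_form <- function(form) {
  if (!is.character(form) || length(form) != 1L || !form %in% rate_forms)
    stop("`form` must be one of ", paste(rate_forms, collapse = ", "),
         call. = FALSE)
  form
}

#' Distance-dependent transmission rate
#'
#' Evaluates one of the four transmission-rate forms (see [rate_forms])
#' at interaction-distance `D`.
#'
#' @param D interaction-distance [m]; vectorised.  Must be non-negative,
#'   and strictly positive for `beta3`, whose power law diverges at 0.
#' @param form one of `"beta1"`, `"beta2"`, `"beta3"`, `"beta4"`.
#' @param params an [model_parameters()] object (uses `beta_star`,
#'   `D_bar_star` and `nu`).
#'
#' @return Transmission rate(s) [1/day], same length as `D`.
#' @examples
#' p <- model_parameters(nu = 1.5)
#' transmission_rate(1.05, "beta3", p)  # = beta_star at the scaling distance
#' @export
transmission_rate <- function(D, form, params) {
  form <- match_rate_form(form)
  stopifnot(inherits(params, "sir_parameters"))
  if (any(!is.finite(D)) || any(D < 0))
    stop("`D` must be finite and non-negative", call. = FALSE)
  if (form == "beta3" && any(D == 0))
    stop("beta3 is unbounded at D = 0; D must be > 0", call. = FALSE)
  bs <- params$beta_star; Db <- params$D_bar_star; nu <- params$nu
  switch(form,
    beta1 = bs * (2 * Db / (Db + D))^nu,
    beta2 = bs * 2 * Db^nu / (Db^nu + D^nu),
    beta3 = bs * (Db / D)^nu,
    beta4 = bs * exp(1 - (D / Db)^nu))
}

#' Classify a society by its natural-distance
#'
#' Societies are typed by the average interpersonal distance their culture
#' maintains in the absence of disease: small for distances below 1 m,
#' medium for 1 m to 1.2 m inclusive, large above 1.2 m.
#'
#' @param D_star natural-distance [m]; vectorised, must be > 0.
#' @return Character vector with elements `"small"`, `"medium"` or
#'   `"large"`.
#' @examples
#' classify_society(c(0.75, 1.05, 1.35))
#' @export
classify_society <- function(D_star) {
  if (any(!is.finite(D_star)) || any(D_star <= 0))
    stop("`D_star` must be finite and > 0", call. = FALSE)
  ifelse(D_star < 1, "small", ifelse(D_star <= 1.2, "medium", "large"))
}

#' Basic reproduction number
#'
#' For the distance-coupled system started at the natural-distance
#' (`D0 = D_star`), linearisation about the disease-free state gives the
#' classical SIR threshold with the rate evaluated at the
#' natural-distance:
#' \deqn{R_0 = \beta_{\mathrm{form}}(D_*)/\gamma.}
#'
#' @inheritParams transmission_rate
#' @return The dimensionless ratio \eqn{R_0}.
#' @examples
#' basic_reproduction_number("beta3", model_parameters(D_star = 0.75))
#' @export
basic_reproduction_number <- function(form, params) {
  stopifnot(inherits(params, "sir_parameters"))
  if (params$gamma == 0)
    stop("gamma must be non-zero", call. = FALSE)
  transmission_rate(params$D_star, form, params) / params$gamma
}
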