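run_spec_keys <- c("extends", "form", "beta_star", "D_bar_star", "nu",
                   "gamma", "lambda1", "lambda2", "D_star", "N",
                   "S0", "I0", "R0", "D0", "horizon",
                   "rtol", "atol", "dt_out")

run_spec_defaults <- function() {
  list(form = "beta3", beta_star = 0.5, D_bar_star = 1.05, nu = 1,
       gamma = 0.2, lambda1 = 0.03, lambda2 = 0.3, D_star = 1.05, N = 1,
       S0 = 0.99999, I0 = 0.00001, R0 = 0, D0 = NULL, horizon = 500,
       rtol = 1e-8, atol = 1e-10, dt_out = 0.1)
}

build_run_spec <- function(vals) {
  defaults <- run_spec_defaults()
  if (!is.null(vals$extends)) {
    presets <- build_presets()
    if (!vals$extends %in% names(presets))
      stop("config error: unknown preset in `extends`: ", vals$extends,
           call. = FALSE)
    pr <- presets[[vals$extends]]
    defaults <- modifyList(defaults, c(
      unclass(pr$params),
      list(form = pr$form, horizon = pr$horizon,
           S0 = pr$init$S0, I0 = pr$init$I0, R0 = pr$init$R0,
           D0 = pr$init$D0)))
    vals$extends <- NULL
  }
  vals <- modifyList(defaults, vals)
  if (is.null(vals$D0)) vals$D0 <- vals$D_star

  params <- tryCatch(
    model_parameters(beta_star = vals$beta_star, D_bar_star = vals$D_bar_star,
                     nu = vals$nu, gamma = vals$gamma, lambda1 = vals$lambda1,
                     lambda2 = vals$lambda2, D_star = vals$D_star, N = vals$N),
    error = function(e) stop("config error: ", conditionMessage(e),
                             call. = FALSE))
  init <- tryCatch(
    initial_state(S0 = vals$S0, I0 = vals$I0, R0 = vals$R0, D0 = vals$D0,
                  N = vals$N),
    error = function(e) stop("config error: ", conditionMessage(e),
                             call. = FALSE))
  if (!vals$form %in% rate_forms)
    stop("config error: unknown form tag `", vals$form, "`", call. = FALSE)
  if (!is.numeric(vals$horizon) || vals$horizon <= 0)
    stop("config error: `horizon` must be > 0", call. = FALSE)
  structure(list(params = params, init = init, form = vals$form,
                 horizon = vals$horizon,
                 solver = list(rtol = vals$rtol, atol = vals$atol,
                               dt_out = vals$dt_out)),
            class = "run_spec")
}

#' Load a scenario configuration
#'
#' Reads a flat YAML scenario file.  Recognised keys are the model
#' parameters (`beta_star`, `D_bar_star`, `nu`, `gamma`, `lambda1`,
#' `lambda2`, `D_star`, `N`), the initial state (`S0`, `I0`, `R0`, `D0`),
#' the rate `form`, the `horizon`, solver settings (`rtol`, `atol`,
#' `dt_out`) and `extends: <preset name>` to start from a preset's
#' values.  Unspecified keys take the reference-scenario defaults
#' (beta3, \eqn{\nu = 1}, medium society); `D0` defaults to `D_star`.
#' Unknown keys are rejected.
#'
#' @param path path to a YAML file.
#' @return A validated `run_spec`: list with `params`, `init`, `form`,
#'   `horizon`, `solver`.
#' @seealso [write_run_spec()] for the lossless inverse.
#' @export
load_run_spec <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  # YAML 1.1 reads a bare `N` key as the boolean FALSE; map it back
  names(vals)[names(vals) == "FALSE"] <- "N"
  unknown <- setdiff(names(vals), run_spec_keys)
  if (length(unknown) > 0)
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  # YAML 1.1 resolves dot-less scientific notation (`1e-08`) as a string
  for (nm in setdiff(names(vals), c("form", "extends"))) {
    if (is.character(vals[[nm]])) {
      num <- suppressWarnings(as.numeric(vals[[nm]]))
      if (is.na(num))
        stop("config error: key `", nm, "` is not numeric", call. = FALSE)
      vals[[nm]] <- num
    }
  }
  build_run_spec(vals)
}

#' Write a scenario configuration
#'
#' Serialises a `run_spec` to YAML with 17 significant digits so that a
#' write-then-read round trip reproduces the spec exactly.
#'
#' @param spec a `run_spec` from [load_run_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_spec <- function(spec, path) {
  stopifnot(inherits(spec, "run_spec"))
  p <- spec$params; i <- spec$init
  vals <- list(form = spec$form,
               beta_star = p$beta_star, D_bar_star = p$D_bar_star,
               nu = p$nu, gamma = p$gamma,
               lambda1 = p$lambda1, lambda2 = p$lambda2,
               D_star = p$D_star, N = p$N,
               S0 = i$S0, I0 = i$I0, R0 = i$R0, D0 = i$D0,
               horizon = spec$horizon,
               rtol = spec$solver$rtol, atol = spec$solver$atol,
               dt_out = spec$solver$dt_out)
  fmt <- vapply(vals, function(v)
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v),
    character(1))
  keys <- names(vals)
  keys[keys == "N"] <- "\"N\""   # a bare N is a YAML 1.1 boolean
  writeLines(paste0(keys, ": ", fmt), path)
  invisible(path)
}

simulate_spec <- function(spec, t_end = NULL) {
  simulate_sir(spec$params, spec$init, spec$form,
               t_end = if (is.null(t_end)) spec$horizon else t_end,
               dt_out = spec$solver$dt_out,
               rtol = spec$solver$rtol, atol = spec$solver$atol)
}

#' Run the analytic validators on a scenario
#'
#' Simulates the scenario to `t_end` and checks: (i) the closed-form
#' (integrating-factor) distance against the integrated `D` series,
#' sup-norm tolerance `1e-5`; (ii) the susceptible log-identity, maximum
#' residual `1e-5`; (iii) the final-size expression against the terminal
#' susceptibles, relative tolerance `1e-3`; (iv) the distance bounds
#' \eqn{0 \le D - D_* < \lambda_2/\lambda_1} (for runs started at the
#' natural-distance).
#'
#' @param spec a `run_spec`, or a preset name.
#' @param t_end horizon for the validation run; the default 2000 days
#'   brings every reference scenario to effective equilibrium.
#' @param quiet suppress the per-check report.
#' @return Logical, `TRUE` when every check passes, with a `checks`
#'   attribute (data frame of check, value, tolerance, pass).
#' @export
validate_scenario <- function(spec, t_end = 2000, quiet = FALSE) {
  if (is.character(spec)) {
    pr <- build_presets()[[spec]]
    if (is.null(pr)) stop("unknown preset `", spec, "`", call. = FALSE)
    spec <- build_run_spec(list(extends = spec))
  }
  stopifnot(inherits(spec, "run_spec"))
  p <- spec$params
  traj <- simulate_spec(spec, t_end = t_end)

  checks <- list()
  add <- function(name, value, tol, pass) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, value = value, tolerance = tol, pass = pass)
  }
  d_err <- max(abs(closed_form_distance(traj) - traj$D))
  add("closed-form distance sup-norm", d_err, 1e-5, d_err < 1e-5)
  if (p$lambda2 > 0) {
    res <- susceptible_identity(traj)$max_residual
    add("susceptible log-identity residual", res, 1e-5, res < 1e-5)
    # long oscillatory regimes can still carry residual prevalence at
    # t_end; extend the run until the final-size precondition holds
    fs_traj <- traj
    t2 <- t_end
    while (fs_traj$I[nrow(fs_traj)] / p$N >= 1e-9 && t2 < 8 * t_end) {
      t2 <- 2 * t2
      fs_traj <- simulate_spec(spec, t_end = t2)
    }
    fs <- final_susceptibles(fs_traj)
    rel <- abs(fs$value - fs$S_end) / p$N
    add("final size vs terminal susceptibles", rel, 1e-3, rel < 1e-3)
  }
  dD <- traj$D - p$D_star
  if (abs(spec$init$D0 - p$D_star) < 1e-12) {
    add("distance floor D >= D*", min(dD), -1e-9, min(dD) >= -1e-9)
    if (p$lambda1 > 0)
      add("distance ceiling D - D* < lambda2/lambda1",
          max(dD), p$lambda2 / p$lambda1, max(dD) < p$lambda2 / p$lambda1)
  }
  out <- do.call(rbind, checks)
  ok <- all(out$pass)
  if (!quiet) {
    for (k in seq_len(nrow(out)))
      message(sprintf("  [%s] %-42s %.3e (tol %.3g)",
                      if (out$pass[k]) "ok" else "FAIL",
                      out$check[k], out$value[k], out$tolerance[k]))
  }
  structure(ok, checks = out)
}

cli_usage <- function() {
  paste(
    "usage: proxsir <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate --preset <name> | --config <file> [--form <tag>]",
    "           [--horizon <days>] --out <csv>",
    "  sweep    --sweep {form|nu|lambda1|lambda2} --out <csv>",
    "  r0-table --out <csv>",
    "  validate --preset <name> | --config <file> [--horizon <days>]",
    "  presets",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--") || i == length(args))
      stop("usage error: unexpected argument `", a, "`", call. = FALSE)
    flags[[substring(a, 3)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  known <- c("preset", "config", "form", "horizon", "out", "sweep",
             "min-prominence")
  unknown <- setdiff(names(flags), known)
  if (length(unknown) > 0)
    stop("usage error: unknown flag(s): --",
         paste(unknown, collapse = ", --"), call. = FALSE)
  flags
}

cli_spec_from_flags <- function(flags) {
  if (!is.null(flags$config)) {
    spec <- load_run_spec(flags$config)
  } else if (!is.null(flags$preset)) {
    presets <- build_presets()
    name <- flags$preset
    if (!name %in% names(presets) && !is.null(flags$form) &&
        paste0(name, "_", flags$form) %in% names(presets))
      name <- paste0(name, "_", flags$form)
    if (!name %in% names(presets))
      stop("unknown preset `", flags$preset, "`", call. = FALSE)
    spec <- build_run_spec(list(extends = name))
  } else stop("usage error: need --preset or --config", call. = FALSE)
  if (!is.null(flags$form)) {
    if (!flags$form %in% rate_forms)
      stop("usage error: unknown form tag `", flags$form, "`", call. = FALSE)
    spec$form <- flags$form
  }
  if (!is.null(flags$horizon)) spec$horizon <- as.numeric(flags$horizon)
  spec
}

write_plain_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
}

#' Command-line interface
#'
#' Entry point behind the `exec/proxsir` script.  Subcommands:
#' `simulate` (trajectory CSV), `sweep` (peak-sweep CSV), `r0-table`
#' (reproduction-number CSV), `validate` (analytic identity checks; exit
#' 0 only if all pass) and `presets` (catalogue listing).  All outputs
#' are deterministic: identical invocations produce byte-identical files.
#'
#' @param args character vector of command-line arguments, e.g.
#'   `c("simulate", "--preset", "fig6_small", "--out", "traj.csv")`.
#' @return Integer exit status, invisibly: 0 on success, 1 on
#'   computation or validation failure, 2 on usage error.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message(cli_usage())
    return(invisible(2L))
  }
  sub <- args[[1L]]
  rest <- args[-1L]
  status <- tryCatch({
    flags <- parse_flags(rest)
    switch(sub,
      "simulate" = {
        spec <- cli_spec_from_flags(flags)
        if (is.null(flags$out))
          stop("usage error: simulate needs --out", call. = FALSE)
        traj <- simulate_spec(spec)
        write_trajectory_csv(traj, flags$out)
        0L
      },
      "sweep" = {
        if (is.null(flags$sweep) || is.null(flags$out))
          stop("usage error: sweep needs --sweep and --out", call. = FALSE)
        write_plain_csv(sweep_peaks(flags$sweep), flags$out)
        0L
      },
      "r0-table" = {
        if (is.null(flags$out))
          stop("usage error: r0-table needs --out", call. = FALSE)
        write_plain_csv(r0_table(), flags$out)
        0L
      },
      "validate" = {
        spec <- cli_spec_from_flags(flags)
        horizon <- if (is.null(flags$horizon)) 2000 else
          as.numeric(flags$horizon)
        ok <- validate_scenario(spec, t_end = horizon)
        if (ok) 0L else {
          bad <- attr(ok, "checks")
          message("validation failed: ",
                  paste(bad$check[!bad$pass], collapse = "; "))
          1L
        }
      },
      "presets" = {
        for (pr in build_presets()) print(pr)
        0L
      },
      stop("usage error: unknown subcommand `", sub, "`", call. = FALSE))
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("proxsir: ", msg)
    if (grepl("^usage error", msg)) {
      message(cli_usage())
      2L
    } else 1L
  })
  invisible(status)
}
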