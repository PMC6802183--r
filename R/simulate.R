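#' Default solver settings
#'
#' Stiff integration (lsoda) with tolerances on the nanomolar concentration
#' scale, a scaled-derivative steady-state criterion, and a generous model
#' time horizon. `ss_tol` applies to `max_i |dx_i/dt| / (1 + |x_i|)`.
#'
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param ss_tol Steady-state tolerance on the scaled derivative norm.
#' @param t_max Maximum model time to spend searching for a steady state.
#' @param t_chunk Initial integration chunk; chunks double until `t_max`.
#' @return List of solver settings.
#' @export
solver_settings <- function(rtol = 1e-6, atol = 1e-9, ss_tol = 1e-8,
                            t_max = 1e6, t_chunk = 50) {
  list(rtol = rtol, atol = atol, ss_tol = ss_tol, t_max = t_max,
       t_chunk = t_chunk)
}

desolve_func <- function(plan, atp_nM, drugs, o2) {
  force(plan); force(atp_nM); force(drugs); force(o2)
  function(t, y, parms) list(rhs_compiled(plan, y, atp_nM, drugs, o2))
}

quiet_lsoda <- function(y, times, f, settings) {
  out <- tryCatch(
    withCallingHandlers(
      deSolve::lsoda(y, times, f, parms = NULL, rtol = settings$rtol,
                     atol = settings$atol, maxsteps = 50000),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (!is.null(out)) {
    istate <- attr(out, "istate")
    if (!is.null(istate) && istate[1] < 0) {
      # keep whatever portion integrated; caller decides on row count
      out <- out[seq_len(max(1, sum(stats::complete.cases(out)))), ,
                 drop = FALSE]
    }
  }
  out
}

env_inputs <- function(network, env) {
  list(atp_nM = atp_level(env$o2_fraction, network$atp) * 1000,
       drugs = env$drugs, o2 = env$o2_fraction)
}

#' Integrate a network to steady state
#'
#' Integrates with the stiff lsoda solver in doubling chunks; the system is
#' declared converged when the scaled derivative norm
#' `max_i |dx_i/dt|/(1+|x_i|)` stays below `ss_tol` at two consecutive chunk
#' ends. Solver failures are flagged (`converged = FALSE`), never raised, so
#' ensemble batches continue.
#'
#' @param network A `reaction_network`.
#' @param state0 Initial state (species order); must be non-negative.
#' @param env A [cell_env()].
#' @param settings [solver_settings()].
#' @param plan Optional cached [network_plan()].
#' @return Object of class `steady_state`: `state` (named vector),
#'   `converged`, `residual`, `t_elapsed`.
#' @export
integrate_to_steady_state <- function(network, state0, env = cell_env(),
                                      settings = solver_settings(),
                                      plan = NULL) {
  if (any(state0 < 0)) stop("state0 must be non-negative", call. = FALSE)
  if (is.null(plan)) plan <- network_plan(network)
  inp <- env_inputs(network, env)
  f <- desolve_func(plan, inp$atp_nM, inp$drugs, inp$o2)
  y <- as.numeric(state0)
  if (length(plan$clamped)) y[plan$clamped] <- env$o2_fraction
  t_now <- 0
  chunk <- settings$t_chunk
  resid <- function(yy) {
    dx <- rhs_compiled(plan, yy, inp$atp_nM, inp$drugs, inp$o2)
    max(abs(dx) / (1 + abs(yy)))
  }
  prev_ok <- FALSE
  repeat {
    out <- quiet_lsoda(y, c(0, chunk), f, settings)
    if (is.null(out) || nrow(out) < 2) {
      if (chunk > settings$t_chunk / 256) { # stiff spot: retry smaller chunk
        chunk <- chunk / 4
        next
      }
      return(structure(list(state = stats::setNames(y, network$species$id),
                            converged = FALSE, residual = resid(y),
                            t_elapsed = t_now), class = "steady_state"))
    }
    y <- as.numeric(out[nrow(out), -1])
    t_now <- t_now + chunk
    r <- resid(y)
    if (r < settings$ss_tol) {
      if (prev_ok) break
      prev_ok <- TRUE
    } else {
      prev_ok <- FALSE
    }
    if (t_now >= settings$t_max) break
    chunk <- min(chunk * 2, settings$t_max - t_now)
  }
  r <- resid(y)
  structure(list(state = stats::setNames(pmax(y, 0), network$species$id),
                 converged = r < settings$ss_tol, residual = r,
                 t_elapsed = t_now), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady_state: converged=%s residual=%.3g t=%.3g\n",
              x$converged, x$residual, x$t_elapsed))
  invisible(x)
}

condition_label <- function(env) {
  lab <- sprintf("o2=%g", env$o2_fraction)
  on <- env$drugs[env$drugs > 0]
  if (length(on)) {
    lab <- paste(lab, paste(sprintf("%s=%g", names(on), on), collapse = "|"),
                 sep = "|")
  }
  lab
}

#' Run a step-change perturbation protocol
#'
#' Every condition is integrated from the same converged normoxic baseline
#' state to its own steady state; conditions are independent (no
#' carry-over). Non-converged conditions are recorded, not raised.
#'
#' @param network A `reaction_network`.
#' @param baseline_state A converged normoxic steady state vector.
#' @param conditions List of [cell_env()] objects.
#' @param settings [solver_settings()].
#' @param plan Optional cached [network_plan()].
#' @return Object of class `protocol_result`: `baseline` (the supplied
#'   state) and `conditions`, a named list of `steady_state` objects keyed
#'   by condition label.
#' @export
run_step_protocol <- function(network, baseline_state, conditions,
                              settings = solver_settings(), plan = NULL) {
  if (is.null(plan)) plan <- network_plan(network)
  res <- lapply(conditions, function(env) {
    integrate_to_steady_state(network, baseline_state, env, settings, plan)
  })
  names(res) <- vapply(conditions, condition_label, "")
  structure(list(baseline = baseline_state, conditions = res),
            class = "protocol_result")
}

#' Sampled trajectory of the network
#'
#' @param network A `reaction_network`.
#' @param state0 Initial state.
#' @param env A [cell_env()].
#' @param t_grid Increasing time points; the first sample equals `state0`
#'   (clamped species overridden from `env`).
#' @param settings [solver_settings()].
#' @param plan Optional cached [network_plan()].
#' @return data.frame with a `time` column and one column per species;
#'   attribute `failed` is TRUE on a partial (solver-failure) trajectory.
#' @export
timecourse <- function(network, state0, env = cell_env(), t_grid,
                       settings = solver_settings(), plan = NULL) {
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  if (is.null(plan)) plan <- network_plan(network)
  inp <- env_inputs(network, env)
  f <- desolve_func(plan, inp$atp_nM, inp$drugs, inp$o2)
  y <- as.numeric(state0)
  if (length(plan$clamped)) y[plan$clamped] <- env$o2_fraction
  out <- quiet_lsoda(y, t_grid, f, settings)
  failed <- is.null(out) || nrow(out) < length(t_grid)
  if (is.null(out)) {
    out <- matrix(c(t_grid[1], y), nrow = 1)
  }
  df <- as.data.frame(out)
  names(df) <- c("time", network$species$id)
  attr(df, "failed") <- failed
  df
}
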