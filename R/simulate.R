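#' Integrate the network ODEs
#'
#' Integrates \eqn{dX_i/dt = k_i(F_i - X_i)} with a stiff-capable implicit
#' method (\code{deSolve}'s \code{lsoda}, switching automatically between
#' Adams and BDF), using the analytic Jacobian.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param x0 initial state, components in [0, 1].
#' @param stress_fn either a scalar stress level held constant, a
#'   \code{\link{stress_protocol}}, or a function of time returning the
#'   stress level.
#' @param times increasing vector of output times.
#' @param atol,rtol absolute and relative integration tolerances.
#' @return an object of class \code{"trajectory"}: list with \code{times}
#'   and a \code{states} matrix (one column per species).
#' @export
integrate_network <- function(spec, x0, stress_fn, times,
                              atol = 1e-10, rtol = 1e-8) {
  if (length(x0) != length(spec$species))
    stop("x0 length does not match species count")
  if (any(x0 < 0 | x0 > 1))
    stop("x0 components must lie in [0, 1]")
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least two points")
  sfun <- as_stress_fn(stress_fn)
  x0 <- as.numeric(x0)
  names(x0) <- spec$species
  fm <- fast_model_funs(spec)
  deriv <- function(t, y, parms) list(fm$rhs(y, sfun(t)))
  jac <- function(t, y, parms) fm$jac(y, sfun(t))
  out <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      jacfunc = jac, jactype = "fullusr",
                      method = "lsoda", atol = atol, rtol = rtol)
  if (attr(out, "istate")[1] < 0)
    stop_sim_failure("ODE integration failed to converge")
  structure(list(times = out[, 1],
                 states = out[, -1, drop = FALSE],
                 species = spec$species),
            class = "trajectory")
}

# lean right-hand-side / Jacobian closures for the integrators (no names,
# no input checks); exp() under/overflow saturates F at 0/1 without NaN
fast_model_funs <- function(spec) {
  k <- unname(spec$k); sigma <- spec$sigma; r0 <- unname(spec$r0)
  r <- unname(spec$r); sc <- unname(spec$stress_coupling)
  n <- length(k)
  id <- diag(k, n)
  list(
    rhs = function(y, s) {
      f <- 1 / (1 + exp(-sigma * (r0 + r %*% y + sc * s)))
      k * (f - y)
    },
    jac = function(y, s) {
      f <- drop(1 / (1 + exp(-sigma * (r0 + r %*% y + sc * s))))
      k * (sigma * f * (1 - f) * r) - id
    })
}

as_stress_fn <- function(stress_fn) {
  if (inherits(stress_fn, "stress_protocol"))
    return(function(t) stress_signal(stress_fn, t))
  if (is.numeric(stress_fn) && length(stress_fn) == 1L) {
    lev <- stress_fn
    return(function(t) lev)
  }
  if (is.function(stress_fn)) return(stress_fn)
  stop("stress_fn must be a scalar, a stress_protocol or a function")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "time points on [",
      format(min(x$times)), ",", format(max(x$times)), "], species:",
      paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

stop_sim_failure <- function(msg, vp_id = NULL) {
  stop(structure(class = c("vpaxis_sim_failure", "error", "condition"),
                 list(message = if (is.null(vp_id)) msg else
                   paste0(msg, " (VP ", vp_id, ")"),
                   call = sys.call(-1), vp_id = vp_id)))
}

stop_no_steady_state <- function(msg, vp_id = NULL) {
  stop(structure(class = c("vpaxis_no_steady_state", "vpaxis_sim_failure",
                           "error", "condition"),
                 list(message = if (is.null(vp_id)) msg else
                   paste0(msg, " (VP ", vp_id, ")"),
                   call = sys.call(-1), vp_id = vp_id)))
}

#' Find a steady state by relaxation
#'
#' Integrates at constant stress in chunks; after each chunk a Newton solve
#' is attempted from the trajectory endpoint, and the result is accepted as
#' the steady state only when it is linearly stable and the trajectory has
#' actually approached it (endpoint within \code{basin_tol}), so that the
#' residual criterion \eqn{\|dX/dt\|_\infty <} \code{ss_tol} is met at a
#' state the flow itself selected. A system that does not settle within
#' \code{t_max} time units (for example because the attractor is a limit
#' cycle) raises a condition of class \code{"vpaxis_no_steady_state"}.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param stress_level constant stress level (>= 0).
#' @param x0 initial state.
#' @param ss_tol steady-state residual tolerance (infinity norm).
#' @param t_max hard cap on relaxation time.
#' @param basin_tol distance within which the endpoint must approach the
#'   polished equilibrium before it is accepted.
#' @return the steady-state vector (named by species).
#' @export
find_steady_state <- function(spec, stress_level, x0,
                              ss_tol = 1e-9, t_max = 500,
                              basin_tol = 1e-4) {
  if (stress_level < 0) stop("stress_level must be >= 0")
  x <- as.numeric(x0)
  fm <- fast_model_funs(spec)
  deriv <- function(t, y, parms) list(fm$rhs(y, stress_level))
  jac <- function(t, y, parms) fm$jac(y, stress_level)
  accept <- function(x) {
    pol <- newton_polish(spec, stress_level, x)
    if (max(abs(net_rhs(spec, pol, stress_level))) >= min(ss_tol, 1e-10))
      return(NULL)
    if (max(abs(pol - x)) > basin_tol) return(NULL)
    ev <- eigen(net_jacobian(spec, pol, stress_level),
                only.values = TRUE)$values
    if (any(Re(ev) > 0)) return(NULL)
    pol
  }
  res <- accept(x)
  t_cur <- 0
  chunk <- 25
  while (is.null(res) && t_cur < t_max) {
    out <- withCallingHandlers(
      deSolve::ode(y = x, times = c(0, chunk / 5, chunk), func = deriv,
                   parms = NULL, jacfunc = jac, jactype = "fullusr",
                   method = "lsoda", atol = 1e-10, rtol = 1e-8,
                   maxsteps = 10000),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(out) < 3L) break   # integrator stalled; treated as no settle
    res <- accept(out[2, -1])
    if (is.null(res)) res <- accept(out[3, -1])
    x <- unname(out[nrow(out), -1])
    t_cur <- t_cur + chunk
  }
  if (is.null(res))
    stop_no_steady_state(sprintf(
      "no steady state reached within %g time units (residual %.3g)",
      t_max, max(abs(net_rhs(spec, x, stress_level)))))
  names(res) <- spec$species
  res
}

# damped Newton iterations toward the nearest equilibrium
newton_polish <- function(spec, stress_level, x, iter = 25L) {
  for (i in seq_len(iter)) {
    g <- net_rhs(spec, x, stress_level)
    if (max(abs(g)) < 1e-13) break
    step <- tryCatch(solve(net_jacobian(spec, x, stress_level), -g),
                     error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 0.5) step <- step * (0.5 / max(abs(step)))
    xn <- x + step
    if (max(abs(net_rhs(spec, xn, stress_level))) < max(abs(g))) x <- xn
    else break
  }
  names(x) <- spec$species
  x
}

#' Classify a stress response
#'
#' Compares post-stress to pre-stress steady-state cortisol: \code{"control"}
#' iff they agree within \code{tol}, \code{"higher"} if the post level
#' exceeds the pre level by more than \code{tol}, \code{"lower"} otherwise.
#'
#' @param ss_before_cor,ss_after_cor steady-state cortisol levels before and
#'   after the transient stress.
#' @param tol equality tolerance (> 0).
#' @return one of \code{"higher"}, \code{"lower"}, \code{"control"}.
#' @export
classify_response <- function(ss_before_cor, ss_after_cor, tol = 1e-3) {
  if (tol <= 0) stop("tol must be positive")
  d <- ss_after_cor - ss_before_cor
  if (abs(d) <= tol) "control" else if (d > 0) "higher" else "lower"
}

#' Run the transient stress protocol on one model instance
#'
#' The pre-stress steady state is found by relaxation from the unstimulated
#' all-zero state at the baseline stress level (a deterministic convention;
#' for bistable instances it selects the attractor whose basin contains the
#' rest state, i.e. the branch reached when the axis starts from low hormone
#' levels). The pulse is then integrated through the protocol, and the
#' post-stress steady state is found by continuing at baseline stress. The
#' response label is assigned from the cortisol component.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param protocol a \code{\link{stress_protocol}}.
#' @param response_species species used for labelling (default
#'   \code{"COR"}; for models without a COR species the first species is
#'   used).
#' @param label_tol equality tolerance passed to
#'   \code{\link{classify_response}}.
#' @param ss_tol,t_max steady-state settings, see
#'   \code{\link{find_steady_state}}.
#' @param n_out number of stored trajectory points across the pulse.
#' @param x0 initial state for the pre-stress relaxation (default: all
#'   zero).
#' @param vp_id optional identifier attached to error conditions.
#' @return an object of class \code{"stress_response"}: list with
#'   \code{ss_before}, \code{ss_after} (named vectors), \code{trajectory},
#'   \code{label}, and the levels \code{ss_before_cor}, \code{ss_after_cor}.
#' @export
run_stress_protocol <- function(spec, protocol,
                                response_species = NULL,
                                label_tol = 1e-3, ss_tol = 1e-9,
                                t_max = 500, n_out = 201,
                                x0 = rep(0, length(spec$species)),
                                vp_id = NULL) {
  if (is.null(response_species))
    response_species <- if ("COR" %in% spec$species) "COR" else
      spec$species[1]
  if (!response_species %in% spec$species)
    stop("unknown response species: ", response_species)
  ss_before <- with_vp_id(vp_id,
    find_steady_state(spec, protocol$baseline, x0, ss_tol, t_max))
  t_end <- protocol_end(protocol) + 2 * (protocol$t_peak - protocol$t_on)
  times <- seq(0, t_end, length.out = n_out)
  traj <- with_vp_id(vp_id,
    integrate_network(spec, ss_before, protocol, times))
  ss_after <- with_vp_id(vp_id,
    find_steady_state(spec, protocol$baseline,
                      traj$states[nrow(traj$states), ], ss_tol, t_max))
  label <- classify_response(ss_before[response_species],
                             ss_after[response_species], label_tol)
  structure(list(ss_before = ss_before, ss_after = ss_after,
                 trajectory = traj, label = label,
                 ss_before_cor = unname(ss_before[response_species]),
                 ss_after_cor = unname(ss_after[response_species]),
                 response_species = response_species),
            class = "stress_response")
}

# re-raise simulation failures with the offending VP attached
with_vp_id <- function(vp_id, expr) {
  if (is.null(vp_id)) return(expr)
  withCallingHandlers(expr, vpaxis_sim_failure = function(e) {
    e$vp_id <- vp_id
    e$message <- paste0(e$message, " (VP ", vp_id, ")")
    stop(e)
  })
}

#' @export
print.stress_response <- function(x, ...) {
  cat(sprintf("Stress response: %s (%s %.4f -> %.4f)\n", x$label,
              x$response_species, x$ss_before_cor, x$ss_after_cor))
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' @param traj a \code{"trajectory"}.
#' @param path output file; one \code{time} column plus one column per
#'   species.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
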