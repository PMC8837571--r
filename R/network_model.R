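#' Sigmoidal network model specification
#'
#' Constructs the parameterization of a standard-form sigmoidal network ODE
#' model
#' \deqn{dX_i/dt = k_i (F_i - X_i), \quad F_i = 1/(1+e^{-\sigma W_i}),
#'       \quad W_i = R_0^i + \sum_j R_j^i X_j + c_i \cdot Stress,}
#' where \eqn{X_i} is the (dimensionless, 0--1) activity of species \eqn{i},
#' \eqn{k_i} its relaxation rate, \eqn{\sigma} a global sigmoid steepness,
#' \eqn{R_0^i} a basal weight, \eqn{R_j^i} the signed influence of species
#' \eqn{j} on species \eqn{i}, and \eqn{c_i} the coupling of the external
#' stress input into \eqn{W_i}.
#'
#' @param species character vector of species names (order defines state
#'   order), e.g. \code{c("CRH","ACTH","COR","GR")}.
#' @param k per-species relaxation rates (1/time), all positive. A scalar is
#'   recycled.
#' @param sigma global sigmoid steepness, positive scalar.
#' @param r0 per-species basal weights \eqn{R_0^i}.
#' @param r square influence matrix; \code{r[i, j]} is \eqn{R_j^i}, the effect
#'   of species \code{j} (column) on species \code{i} (row).
#' @param stress_coupling per-species weight multiplying the stress input
#'   inside \eqn{W_i}.
#' @return An object of class \code{"network_spec"}.
#' @examples
#' sp <- network_spec(c("A", "B"), k = 1, sigma = 1,
#'                    r0 = c(-1, 0), r = matrix(0, 2, 2),
#'                    stress_coupling = c(1, 0))
#' net_rhs(sp, c(0.5, 0.5), stress = 0)
#' @export
network_spec <- function(species, k, sigma, r0, r,
                         stress_coupling = rep(0, length(species))) {
  species <- as.character(species)
  n <- length(species)
  if (n < 1L || anyDuplicated(species))
    stop("species must be a non-empty vector of unique names")
  k <- rep_len(as.numeric(k), n)
  r0 <- rep_len(as.numeric(r0), n)
  stress_coupling <- rep_len(as.numeric(stress_coupling), n)
  r <- as.matrix(r)
  if (!all(dim(r) == c(n, n)))
    stop("r must be a ", n, "x", n, " matrix")
  if (any(!is.finite(k)) || any(k <= 0)) stop("all k must be positive")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (any(!is.finite(r0)) || any(!is.finite(r)))
    stop("r0 and r must be finite")
  dimnames(r) <- list(species, species)
  names(k) <- names(r0) <- names(stress_coupling) <- species
  structure(list(species = species, k = k, sigma = as.numeric(sigma),
                 r0 = r0, r = r, stress_coupling = stress_coupling),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Sigmoidal network model:", length(x$species), "species (",
      paste(x$species, collapse = ", "), ")\n", sep = "")
  cat("sigma =", format(x$sigma), "\n")
  cat("k  :", paste(format(x$k), collapse = " "), "\n")
  cat("R0 :", paste(format(x$r0), collapse = " "), "\n")
  cat("stress coupling:", paste(format(x$stress_coupling), collapse = " "),
      "\n")
  cat("influence matrix R[target, source]:\n")
  print(x$r)
  invisible(x)
}

# ---- named-parameter resolution -------------------------------------------
# Flat parameter names used by sampling ranges, ML feature tables and the
# two-parameter continuation:
#   k_<sp>       relaxation rate of species <sp>
#   R0_<sp>      basal weight of species <sp>
#   R_<j>_<i>    influence of source species <j> on target species <i>
#   stress_<sp>  stress coupling into species <sp>
#   sigma        global steepness

resolve_param <- function(spec, name) {
  sp <- spec$species
  if (identical(name, "sigma"))
    return(list(field = "sigma"))
  m <- regmatches(name, regexec("^k_(.+)$", name))[[1]]
  if (length(m) && m[2] %in% sp)
    return(list(field = "k", i = match(m[2], sp)))
  m <- regmatches(name, regexec("^R0_(.+)$", name))[[1]]
  if (length(m) && m[2] %in% sp)
    return(list(field = "r0", i = match(m[2], sp)))
  m <- regmatches(name, regexec("^stress_(.+)$", name))[[1]]
  if (length(m) && m[2] %in% sp)
    return(list(field = "stress_coupling", i = match(m[2], sp)))
  for (j in sp) for (i in sp) {
    if (identical(name, paste0("R_", j, "_", i)))
      return(list(field = "r", i = match(i, sp), j = match(j, sp)))
  }
  stop("unknown parameter name: ", name, call. = FALSE)
}

#' Get or set a model parameter by name
#'
#' Parameters are addressed by flat names: \code{k_<sp>}, \code{R0_<sp>},
#' \code{stress_<sp>}, \code{sigma}, and \code{R_<j>_<i>} for the influence
#' of source species \code{<j>} on target species \code{<i>} (the weight
#' \eqn{R_j^i}).
#'
#' @param spec a \code{network_spec}.
#' @param name parameter name.
#' @param value replacement value (finite numeric scalar).
#' @return \code{spec_get} returns the numeric value; \code{spec_set} returns
#'   the modified spec.
#' @export
spec_get <- function(spec, name) {
  loc <- resolve_param(spec, name)
  switch(loc$field,
         sigma = spec$sigma,
         r = unname(spec$r[loc$i, loc$j]),
         unname(spec[[loc$field]][loc$i]))
}

#' @rdname spec_get
#' @export
spec_set <- function(spec, name, value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("value must be a finite numeric scalar")
  loc <- resolve_param(spec, name)
  if (loc$field == "sigma") {
    spec$sigma <- as.numeric(value)
  } else if (loc$field == "r") {
    spec$r[loc$i, loc$j] <- value
  } else {
    spec[[loc$field]][loc$i] <- value
  }
  spec
}

# ---- model right-hand side -------------------------------------------------

#' Soft-switch (logistic) activation
#'
#' \eqn{F(w) = 1/(1+e^{-\sigma w})}, the pseudo-steady-state activity of a
#' species receiving weighted input \eqn{w}. Guarded against overflow: extreme
#' inputs return values clamped strictly inside (0, 1), never NaN.
#'
#' @param w weighted input (any real, vectorized).
#' @param sigma steepness, positive.
#' @return values in the open interval (0, 1).
#' @export
soft_switch <- function(w, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  p <- stats::plogis(sigma * w)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Weighted input vector W
#'
#' \eqn{W_i = R_0^i + \sum_j R_j^i X_j + c_i \cdot Stress}; linear in the
#' state and in the stress level.
#'
#' @param spec a \code{network_spec}.
#' @param state species-activity vector (length = number of species).
#' @param stress scalar stress level.
#' @return numeric vector of weighted inputs, one per species.
#' @export
net_input <- function(spec, state, stress = 0) {
  if (length(state) != length(spec$species))
    stop("state length ", length(state), " does not match ",
         length(spec$species), " species")
  drop(spec$r0 + spec$r %*% as.numeric(state) +
         spec$stress_coupling * stress)
}

#' Model right-hand side
#'
#' \eqn{dX_i/dt = k_i (F_i(W_i) - X_i)}. Zero exactly at fixed points of the
#' sigmoid map.
#'
#' @inheritParams net_input
#' @return time-derivative vector.
#' @export
net_rhs <- function(spec, state, stress = 0) {
  spec$k * (soft_switch(net_input(spec, state, stress), spec$sigma) -
              as.numeric(state))
}

#' Analytic Jacobian of the right-hand side
#'
#' \eqn{J_{ij} = k_i (\sigma F_i (1-F_i) R_j^i - \delta_{ij})}.
#'
#' @inheritParams net_input
#' @return square matrix of state sensitivities.
#' @export
net_jacobian <- function(spec, state, stress = 0) {
  f <- soft_switch(net_input(spec, state, stress), spec$sigma)
  g <- spec$sigma * f * (1 - f)           # dF_i / dW_i
  spec$k * (g * spec$r) - diag(spec$k, length(spec$species))
}

# derivative of rhs with respect to the stress level (used by continuation)
net_rhs_dstress <- function(spec, state, stress) {
  f <- soft_switch(net_input(spec, state, stress), spec$sigma)
  spec$k * spec$sigma * f * (1 - f) * spec$stress_coupling
}

# ---- stress protocol -------------------------------------------------------

#' Transient stress protocol
#'
#' A piecewise-exponential stress pulse: constant \code{baseline} up to
#' \code{t_on}; exponential rise \code{baseline * exp(rate * (t - t_on))} on
#' \code{[t_on, t_peak]}; exponential decay at the same rate for
#' \code{t > t_peak}, clamped from below at \code{baseline}. The decay
#' prefactor is the exact peak value \code{baseline * exp(rate *
#' (t_peak - t_on))} so the signal is continuous at the peak.
#'
#' @param baseline resting stress level before and after the pulse.
#' @param t_on time at which the rise starts.
#' @param t_peak time of the maximum.
#' @param rate exponential rate of rise and decay (1/time).
#' @return an object of class \code{"stress_protocol"}.
#' @examples
#' pr <- stress_protocol()
#' stress_signal(pr, c(5, 12, 15, 40))
#' @export
stress_protocol <- function(baseline = 0.1, t_on = 10, t_peak = 15,
                            rate = 0.6) {
  if (baseline <= 0) stop("baseline must be positive")
  if (t_on >= t_peak) stop("t_on must precede t_peak")
  if (rate <= 0) stop("rate must be positive")
  structure(list(baseline = baseline, t_on = t_on, t_peak = t_peak,
                 rate = rate,
                 peak = baseline * exp(rate * (t_peak - t_on))),
            class = "stress_protocol")
}

#' @export
print.stress_protocol <- function(x, ...) {
  cat(sprintf(
    "Stress protocol: baseline %g, rise from t = %g, peak %.4g at t = %g, rate %g\n",
    x$baseline, x$t_on, x$peak, x$t_peak, x$rate))
  invisible(x)
}

#' Evaluate the stress signal
#'
#' @param protocol a \code{stress_protocol}.
#' @param t time (vectorized).
#' @return stress level at each time, never below the baseline.
#' @export
stress_signal <- function(protocol, t) {
  p <- protocol
  out <- rep(p$baseline, length(t))
  rise <- t > p$t_on & t <= p$t_peak
  out[rise] <- p$baseline * exp(p$rate * (t[rise] - p$t_on))
  dec <- t > p$t_peak
  out[dec] <- pmax(p$baseline, p$peak * exp(-p$rate * (t[dec] - p$t_peak)))
  out
}

# time after which the decaying pulse has returned to baseline
protocol_end <- function(protocol) {
  protocol$t_peak + (protocol$t_peak - protocol$t_on)
}
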