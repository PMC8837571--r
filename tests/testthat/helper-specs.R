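# shared fixtures and independent oracles for the test suite

# a random 4-species spec with bounded weights (not guaranteed bistable)
random_spec <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 4
  network_spec(c("CRH", "ACTH", "COR", "GR"),
               k = runif(n, 1, 10), sigma = runif(1, 0.5, 2),
               r0 = runif(n, -4, 0),
               r = matrix(runif(n * n, -2, 2), n, n),
               stress_coupling = c(runif(1, 0, 2), 0, 0, 0))
}

# brute-force weighted-input oracle: explicit double loop over terms
net_input_loop <- function(spec, state, stress) {
  n <- length(spec$species)
  w <- numeric(n)
  for (i in seq_len(n)) {
    acc <- spec$r0[i] + spec$stress_coupling[i] * stress
    for (j in seq_len(n)) acc <- acc + spec$r[i, j] * state[j]
    w[i] <- acc
  }
  w
}

# central finite-difference Jacobian of the right-hand side
fd_jacobian <- function(spec, state, stress, h = 1e-6) {
  n <- length(state)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    up <- state; dn <- state
    up[j] <- up[j] + h; dn[j] <- dn[j] - h
    J[, j] <- (net_rhs(spec, up, stress) - net_rhs(spec, dn, stress)) /
      (2 * h)
  }
  J
}

# 1-D root-count oracle for the self-activation toy: equilibria of
# x = F(r0 + r x + s) located by sign changes on a dense x grid + bisection
toy_roots <- function(spec, s, nx = 4001) {
  g <- function(x) soft_switch(spec$r0[1] + spec$r[1, 1] * x +
                                 spec$stress_coupling[1] * s,
                               spec$sigma) - x
  xs <- seq(0, 1, length.out = nx)
  gs <- g(xs)
  roots <- c()
  for (i in seq_len(nx - 1)) {
    if (gs[i] == 0) roots <- c(roots, xs[i])
    else if (gs[i] * gs[i + 1] < 0)
      roots <- c(roots, stats::uniroot(g, c(xs[i], xs[i + 1]),
                                       tol = 1e-12)$root)
  }
  roots
}

# fold oracle for the toy: stress values where the equilibrium count changes,
# refined by bisection on the count transition
toy_folds <- function(spec, s_range = c(-0.5, 2), ns = 401) {
  ss <- seq(s_range[1], s_range[2], length.out = ns)
  counts <- vapply(ss, function(s) length(toy_roots(spec, s)), numeric(1))
  folds <- c()
  for (i in seq_len(ns - 1)) {
    if (counts[i] == counts[i + 1]) next
    lo <- ss[i]; hi <- ss[i + 1]
    clo <- counts[i]
    for (b in 1:40) {
      mid <- (lo + hi) / 2
      if (length(toy_roots(spec, mid)) == clo) lo <- mid else hi <- mid
    }
    folds <- c(folds, (lo + hi) / 2)
  }
  folds
}

# bidirectional comparison of a traced branch set against a grid-scan of
# Newton equilibria at fixed stress slices
branch_matches_scan <- function(branches, spec, slices, tol = 1e-4,
                                grid_n = 5) {
  if (inherits(branches, "branch")) branches <- list(branches)
  for (s in slices) {
    oracle <- equilibria_scan(spec, s, grid_n = grid_n)
    found <- list()
    for (b in branches) found <- c(found, branch_states_at(b, s))
    for (o in oracle) {
      ok <- any(vapply(found, function(x) max(abs(x - o$state)) < tol,
                       logical(1)))
      if (!ok) return(sprintf("oracle equilibrium missed at stress %.4g", s))
    }
    for (x in found) {
      ok <- any(vapply(oracle, function(o) max(abs(x - o$state)) < tol,
                       logical(1)))
      if (!ok) return(sprintf("spurious branch point at stress %.4g", s))
    }
  }
  TRUE
}
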