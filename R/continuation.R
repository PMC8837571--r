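# Numerical continuation of equilibria for the sigmoidal network model:
# Newton equilibrium solves, pseudo-arclength branch tracing in the stress
# parameter, saddle-node (fold) and Hopf detection with bisection refinement,
# bistable-window extraction, and two-parameter fold following.

#' Solve for an equilibrium by Newton iteration
#'
#' Roots of the right-hand side at fixed stress, with the analytic Jacobian.
#' The returned point carries the Jacobian spectrum and a stability flag
#' (all eigenvalue real parts below \code{-stability_margin}); eigenvalues
#' within the margin of zero are reported as \code{marginal}, never silently
#' stable.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param stress stress level (held as a parameter).
#' @param guess initial state in [0, 1]^n.
#' @param tol residual tolerance (infinity norm).
#' @param max_iter Newton iteration cap.
#' @param stability_margin eigenvalue real-part threshold.
#' @return an object of class \code{"equilibrium_point"}: list with
#'   \code{stress}, \code{state}, \code{eigenvalues}, \code{stable},
#'   \code{marginal}, \code{residual}.
#' @export
newton_equilibrium <- function(spec, stress, guess, tol = 1e-11,
                               max_iter = 50, stability_margin = 1e-8) {
  x <- as.numeric(guess)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    g <- net_rhs(spec, x, stress)
    if (max(abs(g)) < tol) { conv <- TRUE; break }
    step <- tryCatch(solve(net_jacobian(spec, x, stress), -g),
                     error = function(e) NULL)
    if (is.null(step)) break
    # damped update: keep the iterate finite and roughly in range
    if (max(abs(step)) > 2) step <- step * (2 / max(abs(step)))
    x <- x + step
  }
  if (!conv && max(abs(net_rhs(spec, x, stress))) >= tol)
    stop(structure(class = c("vpaxis_newton_failure", "error", "condition"),
                   list(message = sprintf(
                     "Newton failed to converge at stress %.4g", stress),
                     call = sys.call(-1))))
  equilibrium_point(spec, x, stress, stability_margin)
}

equilibrium_point <- function(spec, x, stress, stability_margin = 1e-8) {
  ev <- eigen(net_jacobian(spec, x, stress), only.values = TRUE)$values
  names(x) <- spec$species
  structure(list(stress = stress, state = x, eigenvalues = ev,
                 stable = all(Re(ev) < -stability_margin),
                 marginal = any(abs(Re(ev)) <= stability_margin),
                 residual = max(abs(net_rhs(spec, x, stress)))),
            class = "equilibrium_point")
}

#' @export
print.equilibrium_point <- function(x, ...) {
  cat(sprintf("Equilibrium at stress %.5g (%s): %s\n", x$stress,
              if (x$marginal) "marginal" else
                if (x$stable) "stable" else "unstable",
              paste(sprintf("%s=%.4f", names(x$state), x$state),
                    collapse = " ")))
  invisible(x)
}

#' Exhaustive equilibrium scan at fixed stress
#'
#' Multi-start Newton from a regular grid of initial states in [0, 1]^n;
#' distinct converged roots are deduplicated by distance. Used to seed
#' branches and as an independent cross-check of continuation output.
#'
#' @inheritParams newton_equilibrium
#' @param grid_n grid points per dimension.
#' @param dedup_tol distance below which two roots are considered identical.
#' @return list of \code{"equilibrium_point"}s, sorted by the first species.
#' @export
equilibria_scan <- function(spec, stress, grid_n = 5, tol = 1e-11,
                            dedup_tol = 1e-6, stability_margin = 1e-8) {
  n <- length(spec$species)
  axes <- rep(list(seq(0.05, 0.95, length.out = grid_n)), n)
  grid <- as.matrix(expand.grid(axes))
  roots <- list()
  for (i in seq_len(nrow(grid))) {
    pt <- tryCatch(newton_equilibrium(spec, stress, grid[i, ], tol = tol,
                                      stability_margin = stability_margin),
                   vpaxis_newton_failure = function(e) NULL)
    if (is.null(pt)) next
    dup <- any(vapply(roots, function(r)
      max(abs(r$state - pt$state)) < dedup_tol, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- pt
  }
  roots[order(vapply(roots, function(r) r$state[1], numeric(1)))]
}

# ---- pseudo-arclength continuation ----------------------------------------

# corrector: Newton on c(f(x, s), t . (z - z_ref)) for z = c(x, s)
pa_correct <- function(spec, z, t_vec, z_ref, tol = 1e-10, max_iter = 8) {
  n <- length(z) - 1L
  for (it in seq_len(max_iter)) {
    x <- z[seq_len(n)]; s <- z[n + 1L]
    g <- c(net_rhs(spec, x, s), sum(t_vec * (z - z_ref)))
    if (max(abs(g)) < tol) return(list(z = z, iter = it))
    A <- rbind(cbind(net_jacobian(spec, x, s),
                     net_rhs_dstress(spec, x, s)),
               t_vec)
    step <- tryCatch(solve(A, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    z <- z + step
  }
  x <- z[seq_len(n)]; s <- z[n + 1L]
  if (max(abs(net_rhs(spec, x, s))) < tol) list(z = z, iter = max_iter)
  else NULL
}

# natural continuation: Newton in x at fixed stress
natural_point <- function(spec, stress, guess, ...) {
  tryCatch(newton_equilibrium(spec, stress, guess, ...),
           vpaxis_newton_failure = function(e) NULL)
}

# unit tangent of the equilibrium curve at z = c(x, s): null vector of the
# n x (n+1) matrix [J | df/ds], oriented along `orient` if given
branch_tangent <- function(spec, z, orient = NULL) {
  n <- length(z) - 1L
  A <- cbind(net_jacobian(spec, z[seq_len(n)], z[n + 1L]),
             net_rhs_dstress(spec, z[seq_len(n)], z[n + 1L]))
  v <- svd(A, nu = 0, nv = n + 1L)$v[, n + 1L]
  if (!is.null(orient) && sum(v * orient) < 0) v <- -v
  v
}

#' Trace an equilibrium branch versus stress
#'
#' Pseudo-arclength predictor-corrector continuation: secant predictor,
#' Newton corrector orthogonal to the secant, adaptive step halving on
#' corrector failure and growth on easy convergence. The method rounds
#' turning points (folds), so a single connected S-shaped branch is returned
#' as one ordered curve. Each accepted point satisfies the equilibrium
#' residual and carries the Jacobian spectrum and stability flag.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param stress_range numeric \code{c(lo, hi)}; tracing starts at \code{lo}
#'   and stops once the curve leaves the range (folds slightly below
#'   \code{lo} are rounded before stopping, see \code{overshoot}).
#' @param start initial state guess at \code{stress_range[1]} (default: the
#'   mid state, refined by Newton).
#' @param ds0,ds_min,ds_max initial, minimum and maximum arclength step.
#' @param max_points cap on the number of branch points.
#' @param overshoot how far below \code{stress_range[1]} the curve may run
#'   before tracing stops (lets the trace round folds just outside the
#'   window).
#' @param stability_margin eigenvalue real-part threshold for stability.
#' @return an object of class \code{"branch"}: list with \code{stress},
#'   \code{states} (matrix), \code{eigenvalues} (complex matrix),
#'   \code{stable}, \code{marginal}, the originating \code{spec}, and
#'   \code{termination} (one of \code{"range"}, \code{"step_underflow"},
#'   \code{"max_points"}).
#' @export
continue_branch <- function(spec, stress_range, start = NULL, ds0 = 0.01,
                            ds_min = 1e-5, ds_max = 0.05, max_points = 5000,
                            overshoot = 0.25 * diff(stress_range),
                            stability_margin = 1e-8) {
  stopifnot(length(stress_range) == 2L, stress_range[1] < stress_range[2])
  n <- length(spec$species)
  if (is.null(start)) start <- rep(0.5, n)
  p1 <- newton_equilibrium(spec, stress_range[1], start,
                           stability_margin = stability_margin)
  pts <- list(p1)
  z1 <- c(p1$state, stress_range[1])
  # second point by natural continuation a small step to the right
  ds <- ds0
  z2 <- NULL
  while (is.null(z2) && ds >= ds_min) {
    p2 <- natural_point(spec, stress_range[1] + ds, p1$state,
                        stability_margin = stability_margin)
    if (!is.null(p2) &&
        max(abs(p2$state - p1$state)) < 10 * ds) {
      z2 <- c(p2$state, p2$stress)
    } else ds <- ds / 2
  }
  if (is.null(z2))
    stop("could not take an initial continuation step")
  pts[[2]] <- p2
  termination <- "max_points"
  ds <- max(ds, ds0 / 4)
  lo <- stress_range[1] - overshoot
  hi <- stress_range[2]
  zprev <- z1; z <- z2
  while (length(pts) < max_points) {
    t_vec <- z - zprev
    t_vec <- t_vec / sqrt(sum(t_vec^2))
    accepted <- FALSE
    while (!accepted) {
      pred <- z + ds * t_vec
      cor <- pa_correct(spec, pred, t_vec, pred)
      if (!is.null(cor) &&
          sqrt(sum((cor$z - z)^2)) < 3 * ds + 1e-12) {
        accepted <- TRUE
      } else {
        ds <- ds / 2
        if (ds < ds_min) {
          termination <- "step_underflow"
          break
        }
      }
    }
    if (!accepted) break
    znew <- cor$z
    snew <- znew[n + 1L]
    if (snew > hi) {
      # clamp the final point onto the right boundary
      pb <- natural_point(spec, hi, znew[seq_len(n)],
                          stability_margin = stability_margin)
      if (!is.null(pb) &&
          max(abs(pb$state - znew[seq_len(n)])) < 5 * ds)
        pts[[length(pts) + 1L]] <- pb
      termination <- "range"
      break
    }
    if (snew < lo) {
      # exited below the window (past the fold-rounding allowance)
      termination <- "range"
      break
    }
    pts[[length(pts) + 1L]] <-
      equilibrium_point(spec, znew[seq_len(n)], snew, stability_margin)
    zprev <- z; z <- znew
    if (cor$iter <= 3) ds <- min(ds * 1.3, ds_max)
  }
  new_branch(spec, pts, termination)
}

new_branch <- function(spec, pts, termination) {
  states <- do.call(rbind, lapply(pts, function(p) p$state))
  colnames(states) <- spec$species
  structure(list(
    spec = spec,
    stress = vapply(pts, function(p) p$stress, numeric(1)),
    states = states,
    eigenvalues = do.call(rbind, lapply(pts, function(p) p$eigenvalues)),
    stable = vapply(pts, function(p) p$stable, logical(1)),
    marginal = vapply(pts, function(p) p$marginal, logical(1)),
    termination = termination), class = "branch")
}

#' @export
print.branch <- function(x, ...) {
  cat(sprintf(
    "Equilibrium branch: %d points, stress in [%.4g, %.4g], %d stable / %d unstable (termination: %s)\n",
    length(x$stress), min(x$stress), max(x$stress), sum(x$stable),
    sum(!x$stable), x$termination))
  invisible(x)
}

#' @export
as.data.frame.branch <- function(x, ...) {
  data.frame(stress = x$stress, x$states, stable = x$stable,
             check.names = FALSE)
}

#' Trace all equilibrium branches over a stress window
#'
#' Seeds one continuation from every distinct equilibrium found by a grid
#' scan at the left end of the range; branches whose seed already lies on a
#' previously traced curve are skipped, so the returned set covers the whole
#' window without duplicates.
#'
#' @inheritParams continue_branch
#' @param grid_n grid resolution for the seeding scan.
#' @param ... passed to \code{\link{continue_branch}}.
#' @return list of \code{"branch"} objects (class \code{"branch_set"}).
#' @export
continue_branches <- function(spec, stress_range, grid_n = 5, ...) {
  seeds <- equilibria_scan(spec, stress_range[1], grid_n = grid_n)
  branches <- list()
  for (sd in seeds) {
    covered <- FALSE
    for (br in branches) {
      at <- branch_states_at(br, stress_range[1], correct = FALSE)
      if (length(at) && any(vapply(at, function(st)
        max(abs(st - sd$state)) < 1e-5, logical(1)))) {
        covered <- TRUE; break
      }
    }
    if (covered) next
    branches[[length(branches) + 1L]] <-
      continue_branch(spec, stress_range, start = sd$state, ...)
  }
  structure(branches, class = "branch_set")
}

#' @export
print.branch_set <- function(x, ...) {
  cat("Branch set:", length(x), "branch(es)\n")
  for (br in x) print(br)
  invisible(x)
}

#' States of a branch at a fixed stress value
#'
#' Finds every crossing of the branch with the vertical line
#' \code{stress = s}, by linear interpolation of bracketing points,
#' optionally polished by Newton at fixed stress.
#'
#' @param branch a \code{"branch"}.
#' @param s stress value.
#' @param correct polish interpolated states with Newton (recommended).
#' @param dedup_tol distance for deduplicating crossings.
#' @return list of state vectors (possibly empty).
#' @export
branch_states_at <- function(branch, s, correct = TRUE, dedup_tol = 1e-5) {
  st <- branch$stress
  out <- list()
  for (i in seq_len(length(st) - 1L)) {
    lo <- min(st[i], st[i + 1L]); hi <- max(st[i], st[i + 1L])
    if (s < lo - 1e-12 || s > hi + 1e-12) next
    w <- if (hi > lo) (s - st[i]) / (st[i + 1L] - st[i]) else 0.5
    x <- (1 - w) * branch$states[i, ] + w * branch$states[i + 1L, ]
    if (correct) {
      pt <- natural_point(branch$spec, s, x)
      if (is.null(pt)) next
      x <- pt$state
    }
    dup <- any(vapply(out, function(o) max(abs(o - x)) < dedup_tol,
                      logical(1)))
    if (!dup) out[[length(out) + 1L]] <- x
  }
  out
}

# ---- bifurcation detection -------------------------------------------------

# bisection refinement along the curve between two nearby branch points.
# test_fn(z) returns a signed scalar; the refined point is where it crosses 0.
refine_on_curve <- function(spec, za, zb, test_fn, max_iter = 80,
                            z_tol = 1e-9) {
  fa <- test_fn(za)
  fb <- test_fn(zb)
  if (!is.finite(fa) || !is.finite(fb) || fa * fb > 0) return(NULL)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum((zb - za)^2)) < z_tol) break
    t_vec <- zb - za
    t_vec <- t_vec / sqrt(sum(t_vec^2))
    zm <- (za + zb) / 2
    cor <- pa_correct(spec, zm, t_vec, zm)
    if (is.null(cor)) break
    fm <- test_fn(cor$z)
    if (!is.finite(fm)) break
    if (fa * fm <= 0) { zb <- cor$z; fb <- fm } else { za <- cor$z; fa <- fm }
  }
  if (abs(fa) < abs(fb)) za else zb
}

new_bifurcation_point <- function(type, spec, z, stability_margin = 1e-8) {
  n <- length(spec$species)
  pt <- equilibrium_point(spec, z[seq_len(n)], z[n + 1L], stability_margin)
  structure(list(type = type, stress = pt$stress, state = pt$state,
                 eigenvalues = pt$eigenvalues), class = "bifurcation_point")
}

#' @export
print.bifurcation_point <- function(x, ...) {
  cat(sprintf("%s point at stress %.5g: %s\n",
              if (x$type == "fold") "Saddle-node" else "Hopf", x$stress,
              paste(sprintf("%s=%.4f", names(x$state), x$state),
                    collapse = " ")))
  invisible(x)
}

#' Detect saddle-node (fold) points along a branch
#'
#' Folds are located where the stress coordinate's derivative along
#' arclength changes sign, then refined by bisection on the curve until the
#' bracketing stress values agree to \code{stress_tol}. At each reported
#' fold the smallest-magnitude Jacobian eigenvalue is checked to be near
#' zero.
#'
#' @param branch a \code{"branch"}.
#' @param stress_tol refinement tolerance on the fold stress.
#' @param eig_tol required bound on the smallest-magnitude eigenvalue.
#' @return list of \code{"bifurcation_point"}s of type \code{"fold"}
#'   (possibly empty).
#' @export
detect_folds <- function(branch, stress_tol = 1e-4, eig_tol = 1e-3) {
  spec <- branch$spec
  st <- branch$stress
  m <- length(st)
  if (m < 3L) return(list())
  ds <- diff(st)
  out <- list()
  for (i in seq_len(m - 2L)) {
    if (ds[i] == 0 || ds[i + 1L] == 0) next
    if (sign(ds[i]) == sign(ds[i + 1L])) next
    za <- c(branch$states[i, ], st[i])
    zb <- c(branch$states[i + 2L, ], st[i + 2L])
    chord <- zb - za
    test <- function(z) {
      tv <- branch_tangent(spec, z, orient = chord)
      tv[length(z)]
    }
    zf <- refine_on_curve(spec, za, zb, test, z_tol = stress_tol * 1e-2)
    if (is.null(zf)) next
    bp <- new_bifurcation_point("fold", spec, zf)
    if (min(abs(bp$eigenvalues)) >= eig_tol) next
    dup <- any(vapply(out, function(o)
      abs(o$stress - bp$stress) < 10 * stress_tol &&
        max(abs(o$state - bp$state)) < 1e-3, logical(1)))
    if (!dup) out[[length(out) + 1L]] <- bp
  }
  out
}

# real part of the leading complex eigenvalue pair, NA if spectrum is real
complex_pair_re <- function(ev, im_min = 1e-3) {
  cx <- ev[Im(ev) > im_min]
  if (length(cx) == 0L) return(NA_real_)
  max(Re(cx))
}

#' Detect Hopf points along a branch
#'
#' A Hopf point is located where the real part of a complex-conjugate
#' eigenvalue pair changes sign while its imaginary part stays bounded away
#' from zero; crossings are refined by bisection on the curve.
#'
#' @param branch a \code{"branch"}.
#' @param re_tol required bound on the residual real part at the reported
#'   point.
#' @param im_min minimum imaginary part for a pair to count as complex.
#' @return list of \code{"bifurcation_point"}s of type \code{"hopf"}.
#' @export
detect_hopf <- function(branch, re_tol = 1e-4, im_min = 1e-3) {
  spec <- branch$spec
  n <- length(spec$species)
  m <- length(branch$stress)
  if (m < 2L) return(list())
  re_of_z <- function(z) {
    ev <- eigen(net_jacobian(spec, z[seq_len(n)], z[n + 1L]),
                only.values = TRUE)$values
    complex_pair_re(ev, im_min)
  }
  vals <- vapply(seq_len(m), function(i)
    complex_pair_re(branch$eigenvalues[i, ], im_min), numeric(1))
  out <- list()
  for (i in seq_len(m - 1L)) {
    if (!is.finite(vals[i]) || !is.finite(vals[i + 1L])) next
    if (vals[i] == 0 || sign(vals[i]) == sign(vals[i + 1L])) next
    za <- c(branch$states[i, ], branch$stress[i])
    zb <- c(branch$states[i + 1L, ], branch$stress[i + 1L])
    zf <- refine_on_curve(spec, za, zb, re_of_z, z_tol = 1e-10)
    if (is.null(zf)) next
    bp <- new_bifurcation_point("hopf", spec, zf)
    re_res <- complex_pair_re(bp$eigenvalues, im_min)
    if (is.finite(re_res) && abs(re_res) < re_tol)
      out[[length(out) + 1L]] <- bp
  }
  out
}

#' Bistable stress window(s) of a branch
#'
#' Stress intervals over which at least two stable equilibria coexist,
#' computed by counting stable branch segments crossing each value of a fine
#' stress grid; interval ends are snapped to detected fold stresses when one
#' lies within a grid step.
#'
#' @param branch a \code{"branch"} or a \code{"branch_set"}.
#' @param folds optional precomputed fold list (see
#'   \code{\link{detect_folds}}); detected from the branch when omitted.
#' @param grid_n resolution of the scanning grid.
#' @return a two-column matrix (columns \code{lo}, \code{hi}), one row per
#'   bistable window; zero rows when none.
#' @export
bistable_interval <- function(branch, folds = NULL, grid_n = 801) {
  branches <- if (inherits(branch, "branch_set")) branch else list(branch)
  if (is.null(folds))
    folds <- do.call(c, lapply(branches, detect_folds))
  fold_s <- vapply(folds, function(f) f$stress, numeric(1))
  rng <- range(unlist(lapply(branches, function(b) b$stress)))
  grid <- seq(rng[1], rng[2], length.out = grid_n)
  # stable segments: stress interval plus endpoint states, so that distinct
  # coexisting states can be told apart even when two traces overlap
  segs <- list()
  for (b in branches) {
    st <- b$stress
    for (i in seq_len(length(st) - 1L)) {
      if (!(b$stable[i] && b$stable[i + 1L])) next
      segs[[length(segs) + 1L]] <-
        list(s1 = st[i], s2 = st[i + 1L],
             x1 = b$states[i, ], x2 = b$states[i + 1L, ])
    }
  }
  count <- integer(grid_n)
  for (gi in seq_len(grid_n)) {
    s <- grid[gi]
    states <- list()
    for (sg in segs) {
      lo <- min(sg$s1, sg$s2); hi <- max(sg$s1, sg$s2)
      if (s < lo || s > hi) next
      w <- if (hi > lo) (s - sg$s1) / (sg$s2 - sg$s1) else 0.5
      x <- (1 - w) * sg$x1 + w * sg$x2
      dup <- any(vapply(states, function(o) max(abs(o - x)) < 5e-3,
                        logical(1)))
      if (!dup) states[[length(states) + 1L]] <- x
    }
    count[gi] <- length(states)
  }
  inside <- count >= 2L
  if (!any(inside)) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("lo", "hi"))))
  }
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  step <- grid[2] - grid[1]
  # coverage by stable segments stops one continuation step short of each
  # fold, so ends snap to a detected fold within the largest point spacing
  max_gap <- max(vapply(branches, function(b)
    max(abs(diff(b$stress)), 0), numeric(1)))
  snap_tol <- max(2 * step, 1.5 * max_gap)
  snap <- function(v) {
    if (length(fold_s)) {
      d <- abs(fold_s - v)
      if (min(d) < snap_tol) return(fold_s[which.min(d)])
    }
    v
  }
  iv <- cbind(lo = vapply(grid[starts[runs$values]], snap, numeric(1)),
              hi = vapply(grid[ends[runs$values]], snap, numeric(1)))
  iv[iv[, 1] < iv[, 2], , drop = FALSE]
}

#' Bifurcation summary of a model over a stress window
#'
#' Convenience wrapper: traces all branches, detects folds and Hopf points,
#' and extracts bistable windows.
#'
#' @inheritParams continue_branches
#' @return list with \code{branches}, \code{folds}, \code{hopf},
#'   \code{bistable} (matrix of windows).
#' @export
bifurcation_summary <- function(spec, stress_range, ...) {
  brs <- continue_branches(spec, stress_range, ...)
  folds <- do.call(c, lapply(brs, detect_folds))
  hopf <- do.call(c, lapply(brs, detect_hopf))
  list(branches = brs, folds = folds, hopf = hopf,
       bistable = bistable_interval(brs, folds = folds))
}

#' Export a branch as CSV
#'
#' @param branch a \code{"branch"}.
#' @param path output file: stress, one column per species, stability flag.
#' @export
write_branch_csv <- function(branch, path) {
  utils::write.csv(as.data.frame(branch), path, row.names = FALSE)
  invisible(path)
}

# ---- two-parameter fold continuation --------------------------------------

# augmented fold system G(u) = 0 for u = (x, v, s, p):
#   f(x, s, p) = 0, J(x, s, p) v = 0, |v|^2 - 1 = 0
fold_system <- function(spec, param, u) {
  n <- length(spec$species)
  x <- u[seq_len(n)]; v <- u[n + seq_len(n)]
  s <- u[2 * n + 1L]; p <- u[2 * n + 2L]
  sp <- spec_set(spec, param, p)
  J <- net_jacobian(sp, x, s)
  c(net_rhs(sp, x, s), drop(J %*% v), sum(v^2) - 1)
}

fold_system_jac <- function(spec, param, u, h = 1e-6) {
  m <- length(u)
  g0 <- fold_system(spec, param, u)
  J <- matrix(0, length(g0), m)
  for (j in seq_len(m)) {
    up <- u; um <- u
    up[j] <- up[j] + h; um[j] <- um[j] - h
    J[, j] <- (fold_system(spec, param, up) -
                 fold_system(spec, param, um)) / (2 * h)
  }
  J
}

fold_correct <- function(spec, param, u, t_vec, u_ref, tol = 1e-9,
                         max_iter = 12) {
  for (it in seq_len(max_iter)) {
    g <- c(fold_system(spec, param, u), sum(t_vec * (u - u_ref)))
    if (max(abs(g)) < tol) return(list(u = u, iter = it))
    A <- rbind(fold_system_jac(spec, param, u), t_vec)
    step <- tryCatch(solve(A, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    u <- u + step
  }
  NULL
}

#' Follow a saddle-node point in two parameters
#'
#' Continues the augmented fold system (equilibrium residual, singular
#' Jacobian null vector, unit normalization) in the plane of stress and a
#' second named parameter, by pseudo-arclength stepping in both directions
#' from the given fold. Every returned point satisfies the equilibrium and
#' singularity conditions within tolerance; the curve terminates cleanly
#' (with a recorded reason) when the second parameter leaves \code{range},
#' the corrector fails at the minimum step, or the fold degenerates.
#'
#' @param spec the \code{\link{network_spec}} in which \code{fold} was
#'   found.
#' @param fold a \code{"bifurcation_point"} of type \code{"fold"}.
#' @param param name of the second parameter (see \code{\link{spec_get}}).
#' @param range admissible \code{c(lo, hi)} window for the second
#'   parameter.
#' @param stress_range admissible window for stress.
#' @param ds0,ds_min,ds_max arclength step control.
#' @param max_points per-direction cap.
#' @return an object of class \code{"fold_curve"}: data frame with columns
#'   \code{stress}, the parameter, and one column per species; attributes
#'   \code{param} and \code{termination} (reasons for each direction).
#' @export
continue_fold <- function(spec, fold, param, range,
                          stress_range = c(-1, 10), ds0 = 0.02,
                          ds_min = 1e-6, ds_max = 0.1, max_points = 500) {
  if (!identical(fold$type, "fold")) stop("fold must be of type 'fold'")
  n <- length(spec$species)
  p0 <- spec_get(spec, param)
  J <- net_jacobian(spec, fold$state, fold$stress)
  ed <- eigen(J)
  i0 <- which.min(abs(ed$values))
  v0 <- Re(ed$vectors[, i0])
  v0 <- v0 / sqrt(sum(v0^2))
  u <- c(fold$state, v0, fold$stress, p0)
  # polish with the second parameter pinned at its nominal value
  pin <- c(rep(0, 2 * n + 1L), 1)
  cor <- fold_correct(spec, param, u, pin, u)
  if (is.null(cor))
    stop("initial fold point does not satisfy the singularity conditions")
  u0 <- cor$u
  tang <- function(u) {
    A <- fold_system_jac(spec, param, u)
    svd(A, nu = 0, nv = ncol(A))$v[, ncol(A)]
  }
  march <- function(dir) {
    pts <- list()
    u <- u0
    t_vec <- tang(u0) * dir
    ds <- ds0
    reason <- "max_points"
    while (length(pts) < max_points) {
      accepted <- FALSE
      while (!accepted) {
        pred <- u + ds * t_vec
        cor <- fold_correct(spec, param, pred, t_vec, pred)
        if (!is.null(cor) &&
            sqrt(sum((cor$u - u)^2)) < 3 * ds + 1e-10) {
          accepted <- TRUE
        } else {
          ds <- ds / 2
          if (ds < ds_min) { reason <- "step_underflow"; break }
        }
      }
      if (!accepted) break
      unew <- cor$u
      s <- unew[2 * n + 1L]; p <- unew[2 * n + 2L]
      if (p < range[1] || p > range[2] ||
          s < stress_range[1] || s > stress_range[2]) {
        reason <- "range"
        break
      }
      # fold degeneracy check: the zero eigenvalue must stay simple
      spn <- spec_set(spec, param, p)
      ev <- eigen(net_jacobian(spn, unew[seq_len(n)], s),
                  only.values = TRUE)$values
      if (sum(abs(ev) < 1e-5) > 1L) { reason <- "degenerate"; break }
      pts[[length(pts) + 1L]] <- unew
      t_new <- unew - u
      t_vec <- t_new / sqrt(sum(t_new^2))
      u <- unew
      if (cor$iter <= 4) ds <- min(ds * 1.3, ds_max)
    }
    list(pts = pts, reason = reason)
  }
  fwd <- march(1)
  bwd <- march(-1)
  us <- c(rev(bwd$pts), list(u0), fwd$pts)
  df <- do.call(rbind, lapply(us, function(u)
    data.frame(stress = u[2 * n + 1L], p = u[2 * n + 2L],
               t(u[seq_len(n)]))))
  names(df)[2] <- param
  names(df)[2 + seq_len(n)] <- spec$species
  rownames(df) <- NULL
  structure(df, param = param,
            termination = c(backward = bwd$reason, forward = fwd$reason),
            class = c("fold_curve", "data.frame"))
}

#' @export
print.fold_curve <- function(x, ...) {
  cat(sprintf("Fold curve in (stress, %s): %d points, %s in [%.4g, %.4g]\n",
              attr(x, "param"), nrow(x), attr(x, "param"),
              min(x[[2]]), max(x[[2]])))
  invisible(x)
}

#' Export a fold curve as CSV
#'
#' @param curve a \code{"fold_curve"}.
#' @param path output file.
#' @export
write_fold_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
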