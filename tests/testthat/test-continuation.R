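test_that("Newton equilibrium solves the decoupled system in closed form", {
  sp <- make_fixture("decoupled")
  pt <- newton_equilibrium(sp, 0, rep(0.5, 4))
  expect_equal(unname(pt$state), unname(soft_switch(sp$r0, sp$sigma)),
               tolerance = 1e-10)
  expect_equal(sort(Re(pt$eigenvalues)), sort(unname(-sp$k)),
               tolerance = 1e-9)
  expect_true(pt$stable)
  # starting at the equilibrium returns it unchanged
  pt2 <- newton_equilibrium(sp, 0, pt$state)
  expect_equal(pt2$state, pt$state)
  # an over-tight iteration cap raises a distinct failure
  vp1 <- hpa_example_vp("VP1")
  expect_error(newton_equilibrium(vp1, 0.1, c(1, 0, 1, 0), max_iter = 1),
               class = "vpaxis_newton_failure")
})

test_that("the decoupled branch is monotone with no bifurcations", {
  sp <- make_fixture("decoupled")
  sp <- spec_set(sp, "stress_CRH", 1.5)
  br <- continue_branch(sp, c(0, 2), start = rep(0.5, 4))
  expect_true(all(diff(br$stress) > 0))
  expect_true(all(br$stable))
  expect_length(detect_folds(br), 0)
  expect_length(detect_hopf(br), 0)
  expect_equal(nrow(bistable_interval(br)), 0)
  # each point matches the closed form F(r0 + c s) per species
  for (i in seq(1, length(br$stress), by = 7)) {
    expect_equal(unname(br$states[i, ]),
                 unname(soft_switch(sp$r0 + sp$stress_coupling *
                                      br$stress[i], sp$sigma)),
                 tolerance = 1e-8)
  }
})

test_that("the higher patient's branch is an S-curve with two folds", {
  vp1 <- hpa_example_vp("VP1")
  br <- continue_branch(vp1, c(0, 2), start = rep(0, 4))
  folds <- detect_folds(br)
  expect_length(folds, 2)
  fs <- sort(vapply(folds, `[[`, numeric(1), "stress"))
  expect_lt(fs[1], 0.1)        # baseline sits inside the bistable window
  expect_gt(fs[2], 0.1)
  # stability alternates across the folds along the connected curve
  runs <- rle(br$stable)
  expect_equal(length(runs$lengths), 3)
  expect_equal(runs$values, c(TRUE, FALSE, TRUE))
  # fold points are numerically singular
  for (f in folds) expect_lt(min(abs(f$eigenvalues)), 1e-3)
})

test_that("traced branches match the grid-scan Newton oracle both ways", {
  specs <- list(decoupled = make_fixture("decoupled"),
                toy = make_fixture("bistable-toy"),
                vp1 = hpa_example_vp("VP1"))
  slices <- seq(0.02, 1.98, length.out = 50)
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    brs <- continue_branches(sp, c(0, 2))
    expect_true(isTRUE(branch_matches_scan(brs, sp, slices)), label = nm)
  }
})

test_that("toy fold locations agree with the 1-D root-count oracle", {
  toy <- make_fixture("bistable-toy")
  brs <- continue_branches(toy, c(0, 2))
  folds <- sort(unlist(lapply(brs, function(b)
    vapply(detect_folds(b), `[[`, numeric(1), "stress"))))
  folds <- unique(round(folds, 6))
  oracle <- sort(toy_folds(toy))
  expect_length(folds, length(oracle))
  expect_lt(max(abs(folds - oracle)), 1e-4)
})

test_that("Hopf detection finds the oscillation onset with a clean crossing", {
  sp <- make_fixture("decoupled")
  br <- continue_branch(sp, c(0, 2), start = rep(0.5, 4))
  expect_length(detect_hopf(br), 0)   # real spectrum -k, no complex pair
  vp5 <- hpa_example_vp("VP5")
  br5 <- continue_branch(vp5, c(0, 2), start = rep(0, 4))
  hopf <- detect_hopf(br5)
  expect_gte(length(hopf), 1)
  h <- hopf[[1]]
  re <- Re(h$eigenvalues); im <- Im(h$eigenvalues)
  expect_lt(min(abs(re[im != 0])), 1e-4)
  expect_gt(max(abs(im)), 1e-3)
  # the branch loses stability at the Hopf point on the low-stress side
  expect_true(any(br5$stable[br5$stress < h$stress]))
  expect_true(any(!br5$stable[br5$stress > h$stress]))
})

test_that("bistable windows contain the baseline for VP1 but not VP2", {
  iv1 <- bistable_interval(continue_branches(hpa_example_vp("VP1"), c(0, 2)))
  expect_equal(nrow(iv1), 1)
  expect_lt(iv1[1, "lo"], 0.1)
  expect_gt(iv1[1, "hi"], 0.1)
  # upper end of the window is the upper fold
  br <- continue_branch(hpa_example_vp("VP1"), c(0, 2), start = rep(0, 4))
  fs <- vapply(detect_folds(br), `[[`, numeric(1), "stress")
  expect_equal(unname(iv1[1, "hi"]), max(fs), tolerance = 1e-6)
  iv2 <- bistable_interval(continue_branches(hpa_example_vp("VP2"), c(0, 2)))
  expect_false(any(iv2[, "lo"] <= 0.1 & iv2[, "hi"] >= 0.1))
})

test_that("stability flags agree with long-time integration at sampled points", {
  vp1 <- hpa_example_vp("VP1")
  br <- continue_branch(vp1, c(0, 2), start = rep(0, 4))
  idx <- round(seq(2, length(br$stress) - 1, length.out = 10))
  set.seed(5)
  for (i in idx) {
    x <- br$states[i, ]; s <- br$stress[i]
    if (br$marginal[i]) next
    pert <- pmin(pmax(x + runif(4, -1e-3, 1e-3), 0), 1)
    tr <- integrate_network(vp1, pert, s, seq(0, 40, length.out = 11))
    endd <- max(abs(tr$states[11, ] - x))
    if (br$stable[i]) expect_lt(endd, 1e-5) else expect_gt(endd, 1e-3)
  }
})

test_that("two-parameter fold following traces the saddle-node locus", {
  vp1 <- hpa_example_vp("VP1")
  br <- continue_branch(vp1, c(0, 2), start = rep(0, 4))
  folds <- detect_folds(br)
  upper <- folds[[which.max(vapply(folds, `[[`, numeric(1), "stress"))]]
  fc <- continue_fold(vp1, upper, "R_CRH_CRH", range = c(2.5, 8),
                      stress_range = c(-0.5, 4))
  expect_s3_class(fc, "fold_curve")
  expect_gt(nrow(fc), 5)
  # passes through the one-parameter fold at the nominal parameter value
  d <- abs(fc$R_CRH_CRH - 6) + abs(fc$stress - upper$stress)
  expect_lt(min(d), 1e-6)
  # every point satisfies equilibrium + singular-Jacobian conditions
  for (i in round(seq(1, nrow(fc), length.out = 8))) {
    spi <- spec_set(vp1, "R_CRH_CRH", fc$R_CRH_CRH[i])
    x <- as.numeric(fc[i, vp1$species])
    expect_lt(max(abs(net_rhs(spi, x, fc$stress[i]))), 1e-7)
    expect_lt(min(abs(eigen(net_jacobian(spi, x, fc$stress[i]),
                            only.values = TRUE)$values)), 1e-5)
  }
  # the fold ceases to exist below some self-weight, consistent with the
  # cured patient (self-weight 3) being monostable: cross-checked against
  # one-parameter diagrams at parameter slices
  pmin_curve <- min(fc$R_CRH_CRH)
  expect_gt(pmin_curve, 3)
  sp_low <- spec_set(vp1, "R_CRH_CRH", pmin_curve - 0.5)
  expect_length(detect_folds(continue_branch(sp_low, c(0, 2),
                                             start = rep(0, 4))), 0)
  sp_mid <- spec_set(vp1, "R_CRH_CRH", min(max(fc$R_CRH_CRH), 6))
  expect_gte(length(detect_folds(continue_branch(sp_mid, c(0, 2),
                                                 start = rep(0, 4)))), 1)
})

test_that("local root counts change by two across the fold curve", {
  vp1 <- hpa_example_vp("VP1")
  br <- continue_branch(vp1, c(0, 2), start = rep(0, 4))
  upper <- detect_folds(br)[[1]]
  fc <- continue_fold(vp1, upper, "R_CRH_CRH", range = c(4, 7),
                      stress_range = c(-0.5, 4))
  # probe the upper-fold sheet away from the cusp: self-weight near 5.2,
  # largest-stress crossing
  cand <- fc[abs(fc$R_CRH_CRH - 5.2) < 0.15, ]
  expect_gt(nrow(cand), 0)
  mid <- cand[which.max(cand$stress), ]
  spi <- spec_set(vp1, "R_CRH_CRH", mid$R_CRH_CRH)
  n_lo <- length(equilibria_scan(spi, mid$stress - 0.03, grid_n = 4))
  n_hi <- length(equilibria_scan(spi, mid$stress + 0.03, grid_n = 4))
  expect_equal(abs(n_lo - n_hi), 2)
})
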