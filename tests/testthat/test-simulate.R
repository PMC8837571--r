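test_that("decoupled trajectories match the exponential relaxation closed form", {
  sp <- make_fixture("decoupled")
  x0 <- c(0.9, 0.1, 0.6, 0.3)
  times <- seq(0, 5, length.out = 101)
  tr <- integrate_network(sp, x0, 0, times)
  fstar <- soft_switch(sp$r0, sp$sigma)
  exact <- sapply(seq_along(sp$k), function(i)
    fstar[i] + (x0[i] - fstar[i]) * exp(-sp$k[i] * times))
  expect_lt(max(abs(tr$states - exact)), 1e-6)
})

test_that("a trajectory started at a fixed point stays constant", {
  sp <- hpa_example_vp("VP1")
  ss <- find_steady_state(sp, 0.1, rep(0, 4))
  tr <- integrate_network(sp, ss, 0.1, seq(0, 50, length.out = 51))
  expect_lt(max(abs(sweep(tr$states, 2, ss))), 1e-7)
})

test_that("tightening tolerances moves the endpoint by less than the coarse tolerance", {
  sp <- hpa_example_vp("VP3")
  x0 <- rep(0.2, 4)
  times <- c(0, 25)
  coarse <- integrate_network(sp, x0, stress_protocol(), times,
                              atol = 1e-6, rtol = 1e-6)
  fine <- integrate_network(sp, x0, stress_protocol(), times,
                            atol = 1e-9, rtol = 1e-9)
  expect_lt(max(abs(coarse$states[2, ] - fine$states[2, ])), 1e-6)
})

test_that("trajectories started in [0,1] remain inside the unit box", {
  pr <- stress_protocol()
  for (seed in 1:10) {
    sp <- random_spec(seed)
    x0 <- runif(4)
    tr <- integrate_network(sp, x0, pr, seq(0, 40, length.out = 81))
    expect_true(all(tr$states > -1e-8 & tr$states < 1 + 1e-8))
  }
})

test_that("steady-state relaxation recovers the decoupled closed form", {
  sp <- make_fixture("decoupled")
  ss <- find_steady_state(sp, 0, rep(0.5, 4))
  expect_equal(unname(ss), unname(soft_switch(sp$r0, sp$sigma)),
               tolerance = 1e-9)
  # starting exactly at the equilibrium returns it unchanged
  ss2 <- find_steady_state(sp, 0, ss)
  expect_equal(unname(ss2), unname(ss), tolerance = 1e-10)
})

test_that("an oscillatory attractor raises a distinct non-convergence error", {
  sp <- hpa_example_vp("VP5")   # limit cycle at elevated constant stress
  expect_error(find_steady_state(sp, 0.8, rep(0.5, 4), t_max = 100),
               class = "vpaxis_no_steady_state")
})

test_that("classification partitions outcomes into exactly one label", {
  expect_equal(classify_response(0.30, 0.30, 0.01), "control")
  expect_equal(classify_response(0.20, 0.50, 0.01), "higher")
  expect_equal(classify_response(0.50, 0.20, 0.01), "lower")
  set.seed(4)
  for (i in 1:200) {
    b <- runif(1); a <- runif(1); tol <- runif(1, 1e-4, 0.2)
    lab <- classify_response(b, a, tol)
    hits <- c(control = abs(a - b) <= tol,
              higher = a > b + tol, lower = a < b - tol)
    expect_equal(sum(hits), 1L)
    expect_true(hits[[lab]])
  }
})

test_that("a feedback-free model has no stress memory", {
  sp <- make_fixture("decoupled")
  sp <- spec_set(sp, "stress_CRH", 1)   # couple the pulse in, no feedback
  r <- run_stress_protocol(sp, stress_protocol())
  expect_equal(r$label, "control")
  expect_equal(unname(r$ss_after), unname(r$ss_before), tolerance = 1e-6)
})

test_that("representative higher and lower patients are labelled as documented", {
  pr <- stress_protocol()
  r1 <- run_stress_protocol(hpa_example_vp("VP1"), pr)
  expect_equal(r1$label, "higher")
  r3 <- run_stress_protocol(hpa_example_vp("VP3"), pr)
  expect_equal(r3$label, "lower")
  # the lower response is carried by the GR latch
  expect_lt(r3$ss_before["GR"], 0.2)
  expect_gt(r3$ss_after["GR"], 0.8)
})

test_that("memory requires the stimulus: a flat pulse yields control", {
  flat <- stress_protocol(baseline = 0.1, rate = 1e-9)
  for (nm in c("VP1", "VP3")) {
    r <- run_stress_protocol(hpa_example_vp(nm), flat)
    expect_equal(r$label, "control")
  }
})

test_that("labels are robust to integrator tolerance over an order of magnitude", {
  pr <- stress_protocol()
  for (nm in c("VP1", "VP2", "VP3")) {
    sp <- hpa_example_vp(nm)
    lab1 <- run_stress_protocol(sp, pr, ss_tol = 1e-8)$label
    lab2 <- run_stress_protocol(sp, pr, ss_tol = 1e-9)$label
    expect_equal(lab1, lab2)
  }
})

test_that("simulation failures carry the virtual-patient identity", {
  sp <- hpa_example_vp("VP5")
  err <- tryCatch(
    simulate_vp(spec_set(sp, "stress_CRH", 8), stress_protocol(), id = "vp42"),
    vpaxis_sim_failure = function(e) e)
  if (inherits(err, "condition"))
    expect_match(conditionMessage(err), "vp42")
  else succeed("this parameterization converges; identity path untested here")
})

test_that("trajectories export to CSV with a time column per species", {
  sp <- make_fixture("decoupled")
  tr <- integrate_network(sp, rep(0.5, 4), 0, seq(0, 1, length.out = 11))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read.csv(path)
  expect_equal(names(back), c("time", sp$species))
  expect_equal(back$CRH, unname(tr$states[, "CRH"]))
})
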