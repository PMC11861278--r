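test_that("objective integrates trivial and constant trajectories exactly", {
  w <- control_weights()
  times <- seq(0, 15, length.out = 31)
  zero <- data.frame(time = times, S = 0, B = 0, P = 0, D = 0, M = 0,
                     C = 0, R = 0)
  u0 <- matrix(0, 31, 3)
  expect_equal(objective_value(zero, u0, w), 0)
  unitP <- zero; unitP$P <- 1
  expect_equal(objective_value(unitP, u0, w), 15)
  expect_error(objective_value(zero, matrix(0, 10, 3), w), "grid")
})

test_that("trapezoid objective matches a finer Simpson recomputation", {
  p <- baseline_params(ref_pop = 1e4)
  sc <- oc_scenario()
  times <- seq(0, 15, length.out = 151)
  states <- rk4_integrate(sc$params, sc$init, times)
  traj <- data.frame(time = times, states)
  u <- withr::with_seed(3, matrix(runif(151 * 3), 151, 3))
  w <- control_weights()
  J <- objective_value(traj, u, w)
  # Simpson on a 10x interpolated grid
  fine <- seq(0, 15, length.out = 1501)
  integrand <- w$W1 * traj$P + w$W2 * traj$D + w$W3 * traj$M + w$W4 * traj$C +
    0.5 * (w$W5 * u[, 1]^2 + w$W6 * u[, 2]^2 + w$W7 * u[, 3]^2)
  f_fine <- stats::approx(times, integrand, xout = fine)$y
  h <- fine[2] - fine[1]
  n <- length(fine)
  simpson <- h / 3 * (f_fine[1] + f_fine[n] +
                        4 * sum(f_fine[seq(2, n - 1, by = 2)]) +
                        2 * sum(f_fine[seq(3, n - 2, by = 2)]))
  expect_equal(J, simpson, tolerance = 1e-4)
})

test_that("the Hamiltonian reduces correctly in the degenerate corners", {
  p <- baseline_params()
  w <- control_weights()
  x <- random_positive_state(seed = 2)
  u <- c(0.2, 0.4, 0.1)
  lam <- withr::with_seed(5, rnorm(7))
  # zero adjoints: Hamiltonian equals the running cost
  L <- w$W1 * x[["P"]] + w$W2 * x[["D"]] + w$W3 * x[["M"]] + w$W4 * x[["C"]] +
    0.5 * (w$W5 * u[1]^2 + w$W6 * u[2]^2 + w$W7 * u[3]^2)
  expect_equal(oc_hamiltonian(x, rep(0, 7), u, p, w), L)
  # zero controls and zero weights: adjoint-weighted uncontrolled dynamics
  w0 <- control_weights(W1 = 0, W2 = 0, W3 = 0, W4 = 0,
                        W5 = 1e-12, W6 = 1e-12, W7 = 1e-12)
  expect_equal(oc_hamiltonian(x, lam, c(0, 0, 0), p, w0),
               sum(lam * depression_rhs(x, p)), tolerance = 1e-10)
})

test_that("dH/du matches the switching structure of the update law", {
  p <- baseline_params()
  w <- control_weights()
  x <- random_positive_state(seed = 9)
  lam <- withr::with_seed(10, rnorm(7))
  u <- c(0.3, 0.6, 0.2)
  h <- 1e-6
  for (i in 1:3) {
    up <- u; up[i] <- up[i] + h
    dn <- u; dn[i] <- dn[i] - h
    dHdu <- (oc_hamiltonian(x, lam, up, p, w) -
               oc_hamiltonian(x, lam, dn, p, w)) / (2 * h)
    expected <- switch(i,
      w$W5 * u[1] + (lam[5] - lam[3]) * x[["P"]],
      w$W6 * u[2] + (lam[6] - lam[4]) * x[["D"]],
      w$W7 * u[3] + (lam[7] - lam[6]) * x[["C"]])
    expect_equal(dHdu, expected, tolerance = 1e-6 * max(1, abs(expected)))
  }
})

test_that("adjoint rhs equals the central-difference Hamiltonian gradient", {
  for (seed in 1:6) {
    p <- random_valid_params(seed = seed + 200)
    x <- random_positive_state(seed = seed)
    lam <- withr::with_seed(seed, rnorm(7))
    u <- withr::with_seed(seed + 1, runif(3))
    w <- control_weights()
    got <- adjoint_rhs(x, lam, u, p, w)
    fd <- vapply(1:7, function(j) {
      h <- 1e-6 * max(abs(x[j]), 1e-3)
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- x[j] - h
      -(oc_hamiltonian(xp, lam, u, p, w) -
          oc_hamiltonian(xm, lam, u, p, w)) / (2 * h)
    }, numeric(1))
    expect_equal(got, fd, tolerance = 1e-6 * max(1, max(abs(fd))))
  }
})

test_that("state-cost weights enter exactly one adjoint equation each", {
  p <- baseline_params()
  x <- random_positive_state(seed = 30)
  lam <- withr::with_seed(31, rnorm(7))
  u <- c(0.1, 0.1, 0.1)
  base <- adjoint_rhs(x, lam, u, p, control_weights())
  bumped <- adjoint_rhs(x, lam, u, p, control_weights(W1 = 1.5))
  delta <- bumped - base
  expect_equal(delta[3], -0.5)       # only dLambda3/dt carries the P cost
  expect_equal(delta[-3], rep(0, 6))
})

test_that("printed adjoint transcription is close on the shared structure but
           differs in the treatment rows", {
  p <- baseline_params()
  x <- random_positive_state(seed = 40)
  lam <- withr::with_seed(41, rnorm(7))
  u <- c(0.2, 0.2, 0.2)
  w <- control_weights()
  exact <- adjoint_rhs(x, lam, u, p, w)
  printed <- adjoint_rhs_printed(x, lam, u, p, w)
  expect_length(printed, 7)
  # the printed M/C/R rows carry spurious transmission blocks
  expect_gt(max(abs(exact - printed)), 1e-6)
})

test_that("control update clips the stationary point into the box", {
  w <- control_weights()
  x <- c(S = 1, B = 1, P = 2, D = 1, M = 0, C = 3, R = 0)
  # zero switching function: control rests at max(lower, 0)
  lam <- rep(1, 7)
  expect_equal(optimal_control_update(x, lam, w), c(0, 0, 0))
  # (Lambda3 - Lambda5) P / W5 = 7 > b1 = 1 clips to the upper bound
  lam2 <- c(0, 0, 1 + 7 * w$W5 / 2, 0, 1 - 7 * w$W5 / 2, 0, 0)
  expect_equal(optimal_control_update(x, lam2, w)[1], 1)
  # masked controls are forced to zero whatever the adjoints say
  expect_equal(optimal_control_update(x, lam2, w,
                                      mask = c(FALSE, TRUE, TRUE))[1], 0)
})

test_that("clipped update minimizes the single-control Hamiltonian restriction", {
  p <- baseline_params()
  w <- control_weights()
  for (seed in 1:5) {
    x <- random_positive_state(seed = seed + 60)
    lam <- withr::with_seed(seed + 70, rnorm(7, sd = 5))
    u_star <- optimal_control_update(x, lam, w)
    grid <- seq(0, 1, length.out = 2001)
    for (i in 1:3) {
      hvals <- vapply(grid, function(g) {
        u <- u_star; u[i] <- g
        oc_hamiltonian(x, lam, u, p, w)
      }, numeric(1))
      expect_lt(abs(grid[which.min(hvals)] - u_star[i]), 1e-3)
    }
  }
})

test_that("pinned bounds reduce the sweep to a plain simulation", {
  sc <- oc_scenario()
  w <- control_weights(lower = c(0, 0, 0), upper = c(0, 0, 0))
  cfg <- oc_config(t_f = 10, n_grid = 101, max_iter = 5)
  res <- forward_backward_sweep(sc$params, sc$init, w, cfg)
  expect_true(res$converged)
  expect_true(all(as.matrix(res$controls[, -1]) == 0))
  times <- seq(0, 10, length.out = 101)
  plain <- rk4_integrate(sc$params, sc$init, times)
  expect_equal(as.matrix(res$trajectory[c("S", "B", "P", "D", "M", "C", "R")]),
               plain, tolerance = 1e-10)
  expect_equal(res$J, objective_value(res$trajectory, matrix(0, 101, 3),
                                      control_weights()))
})

test_that("the converged sweep improves on no control and respects
           transversality, bounds and stationarity", {
  sc <- oc_scenario()
  w <- control_weights()
  cfg <- oc_config(t_f = 15, n_grid = 301, tol = 1e-7, max_iter = 400)
  res <- forward_backward_sweep(sc$params, sc$init, w, cfg)
  expect_true(res$converged)
  # transversality holds exactly by construction
  expect_equal(max(abs(as.matrix(res$adjoints[nrow(res$adjoints), -1]))), 0)
  u <- as.matrix(res$controls[, -1])
  expect_true(all(u >= 0 - 1e-15 & u <= 1 + 1e-15))
  # improvement over the uncontrolled run
  times <- res$trajectory$time
  plain <- rk4_integrate(sc$params, sc$init, times)
  J0 <- objective_value(data.frame(time = times, plain),
                        matrix(0, length(times), 3), w)
  expect_lt(res$J, J0)
  # the objective decreases monotonically once the sweep settles
  tail_J <- tail(res$J_history, max(0, res$iterations - 5))
  expect_true(all(diff(tail_J) <= 1e-6 * abs(tail_J[-length(tail_J)])))
  # interior stationarity: dH/du ~ 0 where the box is inactive
  lamM <- as.matrix(res$adjoints[, -1])
  traj <- res$trajectory
  interior <- which(u[, 2] > 1e-3 & u[, 2] < 1 - 1e-3)
  if (length(interior) > 3) {
    for (i in interior[round(seq(1, length(interior), length.out = 4))]) {
      dHdu2 <- w$W6 * u[i, 2] + (lamM[i, 6] - lamM[i, 4]) * traj$D[i]
      expect_lt(abs(dHdu2), 1e-4 * max(1, abs(w$W6 * u[i, 2])))
    }
  }
})

test_that("costlier controls shrink the converged policy pointwise", {
  sc <- oc_scenario()
  cfg <- oc_config(t_f = 10, n_grid = 151, tol = 1e-6, max_iter = 300)
  cheap <- forward_backward_sweep(sc$params, sc$init, control_weights(), cfg)
  costly <- forward_backward_sweep(sc$params, sc$init,
                                   control_weights(W5 = 1500, W6 = 4000,
                                                   W7 = 5500), cfg)
  u_cheap <- as.matrix(cheap$controls[, -1])
  u_costly <- as.matrix(costly$controls[, -1])
  expect_true(all(u_costly <= u_cheap + 1e-8))
  expect_lt(mean(u_costly), mean(u_cheap))
})

test_that("strategy comparison: masks bind, baseline matches the plain run,
           G attains the lowest terminal D, pairs beat components on J", {
  sc <- oc_scenario()
  cfg <- oc_config(t_f = 15, n_grid = 201, tol = 1e-5, max_iter = 300)
  comp <- run_strategies(sc$params, sc$init, control_weights(), cfg)
  tab <- comp$table
  expect_equal(tab$strategy, c("baseline", "A", "B", "C", "D", "E", "F", "G"))
  expect_true(all(tab$converged))
  # baseline row equals an uncontrolled simulation
  times <- seq(0, 15, length.out = 201)
  plain <- rk4_integrate(sc$params, sc$init, times)
  expect_equal(tab$D_at_tf[1], unname(plain[201, "D"]), tolerance = 1e-12)
  # masks: strategy A never touches u2 or u3
  uA <- as.matrix(comp$results$A$controls[, -1])
  expect_true(all(uA[, 2:3] == 0))
  expect_gt(max(uA[, 1]), 0)
  J <- stats::setNames(tab$J, tab$strategy)
  D_tf <- stats::setNames(tab$D_at_tf, tab$strategy)
  # the comprehensive strategy wins on terminal burden
  expect_true(all(D_tf["G"] <= D_tf[c("A", "B", "C", "D", "E", "F")]))
  # two-control strategies beat both single-control components on J
  expect_lt(J[["D"]], min(J[["A"]], J[["B"]]))
  expect_lt(J[["E"]], min(J[["B"]], J[["C"]]))
  expect_lt(J[["F"]], min(J[["A"]], J[["C"]]))
  expect_lt(J[["G"]], min(J[["D"]], J[["E"]], J[["F"]]))
  # exports
  path <- withr::local_tempfile(fileext = ".csv")
  write_strategy_csv(comp, path)
  expect_equal(nrow(utils::read.csv(path)), 8)
  write_control_profile_csv(comp$results$G, path)
  expect_equal(names(utils::read.csv(path)), c("time", "u1", "u2", "u3"))
})
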