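# Nonlinear models, noisy simulation, and regression-based inference.

test_that("nonlinear model generation is deterministic without duplicates", {
  m1 <- gen_nonlinear_model(11)
  m2 <- gen_nonlinear_model(11)
  expect_identical(m1, m2)
  keys <- vapply(m1$links, function(l)
    paste(l$type, l$source, l$source2 %||% "", l$target), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_length(m1$links, 6)
})

test_that("constant mode holds N fixed; cell-coupled consumes it", {
  mc <- gen_nonlinear_model(21, input_mode = "constant")
  tc <- simulate_network(mc, t_end = 5)
  expect_true(all(tc$N == 1))
  mcc <- gen_nonlinear_model(21, input_mode = "cell_coupled")
  tcc <- simulate_network(mcc, t_end = 5)
  expect_lt(tcc$N[nrow(tcc)], 1)
  expect_true(all(diff(tcc$N) <= 1e-10))
})

test_that("pure degradation decays monotonically to zero", {
  m <- gen_nonlinear_model(1, basal_decay = 0.5)
  m$links <- list()
  m$k_in <- 1e-12
  tr <- simulate_network(m, t_end = 20)
  for (nd in c("P", "Q", "R")) {
    expect_true(all(diff(tr[[nd]]) < 0))
    expect_lt(tr[[nd]][nrow(tr)], 1e-3)
  }
})

test_that("trajectories are integration-converged", {
  m <- gen_nonlinear_model(31)
  a <- simulate_network(m, t_end = 10, dt = 0.1)
  b <- simulate_network(m, t_end = 10, dt = 0.05)
  shared <- b[seq(1, nrow(b), by = 2), ]
  err <- sqrt(mean((as.matrix(a[-1]) - as.matrix(shared[-1]))^2))
  expect_lt(err, 1e-4)
})

test_that("multiplicative noise has the declared level and is reproducible", {
  traj <- data.frame(time = 1:5000, y = rep(100, 5000))
  n1 <- add_noise(traj, level = 0.2, seed = 9)
  n2 <- add_noise(traj, level = 0.2, seed = 9)
  expect_identical(n1, n2)
  s <- sd(n1$y / 100 - 1)
  expect_lt(abs(s - 0.2), 3 * 0.2 / sqrt(2 * 4999))
  expect_identical(add_noise(traj, level = 0), traj)
  expect_true(all(add_noise(data.frame(y = rep(0.01, 100)), 3, seed = 1)$y >= 0))
})

test_that("the linear estimator recovers a known stable system", {
  A <- diag(c(-1, -2, -3))
  A[1, 2] <- 0.3; A[2, 3] <- 0.2
  y0 <- c(2, 1, 3)
  mexp <- function(M, t, v) {
    e <- eigen(M)
    Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors, v))
  }
  for (dt in c(0.02, 0.01)) {
    tt <- seq(0, 4, by = dt)
    Y <- t(sapply(tt, function(t) mexp(A, t, y0)))
    Ah <- estimate_linear(Y, dt = dt)
    bound <- 0.05 * max(abs(A)) * dt / 0.01
    expect_lt(max(abs(Ah - A)), bound)
  }
  # error shrinks roughly quadratically with dt
  e1 <- max(abs(estimate_linear(t(sapply(seq(0, 4, 0.02), mexp, M = A, v = y0)),
                                dt = 0.02) - A))
  e2 <- max(abs(estimate_linear(t(sapply(seq(0, 4, 0.01), mexp, M = A, v = y0)),
                                dt = 0.01) - A))
  expect_lt(e2, e1)
})

test_that("constant trajectories give a near-zero minimum-norm estimate", {
  Y <- matrix(1, 50, 3)
  expect_warning(A <- estimate_linear(Y, dt = 0.1), "minimum-norm")
  expect_lt(max(abs(A)), 1e-8)
})

test_that("edge detection thresholds |A| and records signs", {
  A <- matrix(c(0, 0.004, 0.02, -0.03, 0, 0.001, 0.006, -0.004, 0), 3, 3,
              dimnames = list(c("P", "Q", "R"), c("P", "Q", "R")))
  e <- detect_edges(A, 0.005)
  expect_false(any(grepl("P->Q", e, fixed = TRUE)))  # A[Q,P] = 0.004, below
  expect_true("P->R:+" %in% e)                       # A[R,P] = 0.02
  expect_true("Q->P:-" %in% e)                       # A[P,Q] = -0.03, signed
  expect_true("R->P:+" %in% e)                       # A[P,R] = 0.006
  expect_length(detect_edges(A, 0.05), 0)
})

test_that("true influences map links to signed cross-node edges", {
  m <- gen_nonlinear_model(41)
  ti <- true_influences(m)
  expect_true(all(grepl("^[PQR]->[PQR]:[+-]$", ti)))
  expect_equal(anyDuplicated(ti), 0L)
  # accuracy bounds
  expect_equal(edge_accuracy(ti, m), 1)
  expect_equal(edge_accuracy(character(0), m), 0)
  half <- ti[seq_len(floor(length(ti) / 2))]
  expect_equal(edge_accuracy(half, m), length(half) / length(ti))
})

test_that("accuracy is monotone non-increasing in the detection threshold", {
  m <- gen_nonlinear_model(51)
  tr <- simulate_network(m, t_end = 20)
  tr <- add_noise(tr, 0.2, seed = 5)
  A <- estimate_linear(tr)
  accs <- sapply(c(0.001, 0.005, 0.01, 0.05, 0.2),
                 function(th) edge_accuracy(detect_edges(A, th), m))
  expect_true(all(diff(accs) <= 0))
})

test_that("ensemble comparison is reproducible and returns both modes", {
  a <- compare_ensembles(n_models = 3, seed = 77, t_end = 10)
  b <- compare_ensembles(n_models = 3, seed = 77, t_end = 10)
  expect_identical(a, b)
  expect_true(all(a$acc_cell_coupled >= 0 & a$acc_cell_coupled <= 1))
  expect_true(all(a$acc_constant >= 0 & a$acc_constant <= 1))
})
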