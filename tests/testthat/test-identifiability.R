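# Random linear models and transfer-function identifiability.

test_that("model generation is deterministic and samples distinct edges", {
  m1 <- gen_linear_model(7)
  m2 <- gen_linear_model(7)
  expect_identical(m1, m2)
  m <- gen_linear_model(3, n_edges = 6)
  expect_equal(nrow(unique(m$edges[c("source", "target")])), 6)
  expect_true(all(m$edges$rate > 0.1 & m$edges$rate < 1))
  expect_error(gen_linear_model(1, n_edges = 7), "6 edges")
})

test_that("flux-form dynamics conserve mass absent input", {
  m <- gen_linear_model(5)
  ss <- phenosig:::.lin_state_space(m)
  pqr <- c("P", "Q", "R")
  # each edge moves mass between states: columns of the PQR block sum to 0
  expect_equal(unname(colSums(ss$A[pqr, pqr])), rep(0, 3))
})

test_that("sensitivities match a finite-difference perturbation of g", {
  for (mode in c("cell_coupled", "constant")) {
    m <- gen_linear_model(9, input_mode = mode)
    H <- transfer_sensitivities(m, quadrature_weights = FALSE)
    gfun <- function(model) {
      ss <- phenosig:::.lin_state_space(model)
      obs <- intersect(c("P", "Q", "R"), ss$states)
      Cm <- matrix(0, length(obs), length(ss$states),
                   dimnames = list(obs, ss$states))
      Cm[cbind(obs, obs)] <- 1
      out <- c()
      for (w in 10^seq(-2, 2, length.out = 32)) {
        g <- Cm %*% solve(diag(complex(imaginary = w), length(ss$states)) -
                            ss$A) %*% ss$B
        out <- c(out, Re(g), Im(g))
      }
      out
    }
    h <- 1e-6
    for (r in c(1, 4)) {
      mp <- m; mp$edges$rate[r] <- mp$edges$rate[r] + h
      mm <- m; mm$edges$rate[r] <- mm$edges$rate[r] - h
      fd <- (gfun(mp) - gfun(mm)) / (2 * h)
      expect_lt(max(abs(fd - H[, r])) / max(abs(H[, r])), 1e-6)
    }
  }
})

test_that("a duplicated sensitivity column kills both parameters", {
  H <- transfer_sensitivities(gen_linear_model(2))
  H2 <- cbind(H, H[, 1])
  r2 <- identifiability_report(H2)
  expect_false(r2$identifiable[1])
  expect_false(r2$identifiable[ncol(H2)])
  expect_equal(abs(r2$R[1, ncol(H2)]), 1)
})

test_that("identifiability report flags zero-sensitivity and collinearity", {
  H <- cbind(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0), c = c(0, 0, 1, 0))
  r <- identifiability_report(H)
  expect_true(all(r$identifiable))
  expect_equal(r$n_identifiable, 3)

  Hz <- cbind(a = rnorm(8), b = numeric(8))
  rz <- identifiability_report(Hz)
  expect_false(rz$identifiable["b"])
  expect_equal(rz$reason[2], "zero sensitivity")

  Hp <- cbind(a = 1:8, b = 2 * (1:8) + 3)   # proportional after centring
  rp <- identifiability_report(Hp)
  expect_false(any(rp$identifiable))
  expect_equal(abs(rp$R[1, 2]), 1)
})

test_that("R is symmetric with unit diagonal and entries in [-1, 1]", {
  for (s in 1:5) {
    H <- transfer_sensitivities(gen_linear_model(s * 11))
    R <- identifiability_report(H)$R
    expect_equal(R, t(R))
    expect_equal(unname(diag(R)), rep(1, ncol(H)))
    expect_true(all(abs(R[!is.na(R)]) <= 1 + 1e-12))
  }
})

test_that("identifiable set matches a Fisher-information eigen-analysis oracle", {
  thr <- 0.99
  for (s in 1:25) {
    m <- gen_linear_model(100 + s, input_mode = "cell_coupled")
    H <- transfer_sensitivities(m)
    rep_ <- identifiability_report(H, threshold = thr)
    # oracle: normalized FIM of centred columns; a pair is confounded iff
    # the smallest eigenvalue of its 2x2 normalized-FIM block is <= 1 - thr
    Hc <- scale(H, center = TRUE, scale = FALSE)
    norms <- sqrt(colSums(Hc^2))
    ok <- norms > 1e-12
    Hn <- sweep(Hc, 2, pmax(norms, 1e-300), "/")
    FIM <- crossprod(Hn)
    oracle <- logical(ncol(H))
    for (j in seq_len(ncol(H))) {
      if (!ok[j]) next
      confounded <- FALSE
      for (i in seq_len(ncol(H))) {
        if (i == j || !ok[i]) next
        ev <- eigen(FIM[c(i, j), c(i, j)], symmetric = TRUE,
                    only.values = TRUE)$values
        if (min(ev) <= 1 - thr) confounded <- TRUE
      }
      oracle[j] <- !confounded
    }
    expect_equal(unname(rep_$identifiable), oracle)
  }
})

test_that("observing more than one node raises identifiability on average", {
  # pairwise-correlation identifiability is not strictly monotone in the
  # observed set (an added output block can push a pairwise correlation
  # above threshold), but multi-node observation clearly beats a single
  # node across an ensemble
  sets <- list(c("R"), c("Q", "R"), c("P", "Q", "R"))
  means <- sapply(sets, function(obs) {
    mean(sapply(1:30, function(s) {
      H <- transfer_sensitivities(gen_linear_model(300 + s), observed = obs)
      identifiability_report(H)$n_identifiable
    }))
  })
  expect_gt(means[2], means[1])
  expect_gt(means[3], means[1])
})

test_that("input-mode comparison is reproducible and reports both counts", {
  a <- compare_input_modes(n_models = 5, seed = 42)
  b <- compare_input_modes(n_models = 5, seed = 42)
  expect_identical(a, b)
  expect_equal(a$delta, a$n_cell_coupled - a$n_constant)
  expect_true(all(a$n_cell_coupled >= 0 & a$n_cell_coupled <= 6))
})
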