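# Plate I/O, specific growth rates, and denoising.

test_that("plate CSV round-trips through read and write", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "plate.csv")
  times <- (0:40) / 6
  set.seed(1)
  df <- data.frame(time = times,
                   A1 = 0.05 * exp(0.4 * times) * (1 + 0.01 * rnorm(41)),
                   A2 = 0.05 * exp(0.3 * times))
  write.csv(df, csv, row.names = FALSE)
  layout <- list(A1 = list(strain = "mg", condition = "ctrl"),
                 A2 = list(strain = "bpro", condition = "ctrl"))
  curves <- read_plate_csv(csv, layout)
  expect_length(curves, 2)
  expect_equal(curves[[1]]$strain, "mg")
  expect_equal(curves[[2]]$strain, "bpro")
  expect_equal(curves[[1]]$times[2] - curves[[1]]$times[1], 1 / 6)

  csv2 <- file.path(dir, "plate2.csv")
  write_plate_csv(curves, csv2)
  curves2 <- read_plate_csv(csv2, layout)
  expect_equal(curves2[[1]]$od, curves[[1]]$od, tolerance = 1e-9)
  expect_equal(curves2[[2]]$od, curves[[2]]$od, tolerance = 1e-9)
})

test_that("unmapped wells are skipped with a warning; bad files error", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "plate.csv")
  df <- data.frame(time = (0:10) / 6, A1 = 1:11, A2 = 11:1)
  write.csv(df, csv, row.names = FALSE)
  layout <- list(A1 = list(strain = "mg", condition = "ctrl"))
  expect_warning(curves <- read_plate_csv(csv, layout), "unmapped")
  expect_length(curves, 1)

  df_shuffled <- df[c(3, 1, 2, 4:11), ]
  write.csv(df_shuffled, csv, row.names = FALSE)
  expect_error(read_plate_csv(csv, layout), "increasing")

  write.csv(data.frame(A1 = 1:11), csv, row.names = FALSE)
  expect_error(read_plate_csv(csv, layout), "time")
})

test_that("layout files parse from JSON", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "layout.json")
  jsonlite::write_json(list(A1 = list(strain = "mg", condition = "ctrl")),
                       path, auto_unbox = TRUE)
  lay <- read_layout(path)
  expect_equal(lay$A1$strain, "mg")
})

test_that("central-difference growth rate matches hand and closed-form values", {
  cv <- growth_curve(0:4, c(1, 1, 2, 3, 5))
  mu <- compute_growth_rate(cv)
  # interior points: (2-1)/(2*1*1), (3-1)/(2*1*2), (5-2)/(2*1*3)
  expect_equal(mu$mu, c(0.5, 0.5, 0.5))

  cv_const <- growth_curve(0:9, rep(2, 10))
  expect_true(all(compute_growth_rate(cv_const)$mu == 0))

  # exponential: mu_hat = sinh(r dt) / dt exactly, ~ 0.5006 at r=0.5, dt=1/6
  dt <- 1 / 6
  tt <- seq(0, 10, by = dt)
  cv_exp <- growth_curve(tt, exp(0.5 * tt))
  mu_exp <- compute_growth_rate(cv_exp)
  expect_equal(mu_exp$mu, rep(sinh(0.5 * dt) / dt, length(mu_exp$mu)),
               tolerance = 1e-10)
  expect_equal(sinh(0.5 * dt) / dt, 0.5006, tolerance = 1e-4)
})

test_that("growth rate converges to r for exponential curves as dt shrinks", {
  r <- 0.7
  for (dt in c(0.1, 0.05, 0.025)) {
    tt <- seq(0, 5, by = dt)
    mu <- compute_growth_rate(growth_curve(tt, 3 * exp(r * tt)))$mu
    bound <- r * (dt * r)^2 / 6 * 1.1
    expect_true(all(abs(mu - r) <= bound))
  }
})

test_that("log-OD variant agrees with OD variant for slow dynamics", {
  tt <- seq(0, 10, by = 1 / 6)
  cv <- growth_curve(tt, exp(0.1 * tt))
  expect_equal(compute_growth_rate(cv, method = "log")$mu,
               compute_growth_rate(cv)$mu, tolerance = 1e-3)
})

test_that("nonpositive interior OD errors unless permissive", {
  cv <- growth_curve(0:5, c(1, 2, 0, 2, 3, 4))
  expect_error(compute_growth_rate(cv), "OD <= 0")
  mu <- compute_growth_rate(cv, permissive = TRUE)
  expect_true(is.na(mu$mu[2]))
  expect_false(anyNA(mu$mu[-2]))
})

test_that("growth_curve validates its invariants", {
  expect_error(growth_curve(0:3, 1:4), "length >= 5")
  expect_error(growth_curve(c(0, 1, 2, 4, 5), rep(1, 5)), "uniform")
  expect_error(growth_curve(0:4, c(1, 2, -1, 1, 1)), "negative")
  expect_error(growth_curve(c(0, 1, 1, 2, 3), rep(1, 5)), "increasing")
})

test_that("denoising preserves smooth signals and suppresses noise", {
  expect_equal(denoise_curve(numeric(64)), numeric(64))

  t <- seq(0, 1, length.out = 128)
  poly <- 1 + 2 * t - t^2
  expect_lt(sqrt(mean((denoise_curve(poly) - poly)^2)), 1e-6)

  set.seed(42)
  tt <- seq(0, 1, length.out = 256)
  clean <- sin(2 * pi * 2 * tt)
  noisy <- clean + rnorm(256, sd = 0.1)
  den <- denoise_curve(noisy)
  expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))

  expect_error(denoise_curve(c(1, NA, 3)), "finite")
})

test_that("denoising is idempotent within one-threshold tolerance", {
  set.seed(3)
  x <- sin(seq(0, 20, length.out = 200)) + rnorm(200, sd = 0.2)
  d1 <- denoise_curve(x)
  d2 <- denoise_curve(d1)
  expect_lte(sqrt(mean((d2 - d1)^2)), sqrt(mean((d1 - x)^2)))
})
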