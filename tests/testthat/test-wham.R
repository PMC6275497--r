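# WHAM reweighting, state populations, state-conditioned forces.

test_that("a single unbiased window reduces to -kT log(histogram)", {
  set.seed(1)
  qs <- rbeta(20000, 2, 5)
  win <- list(list(q0 = 0, k_umb = 0,
                   samples = tibble::tibble(Q = qs, F_pN = 0)))
  prof <- wham(win, n_bins = 25, temperature = 291)
  h <- hist(qs, breaks = seq(0, 1, length.out = 26), plot = FALSE)
  kT <- kB_kj() * 291
  Gref <- -kT * log(h$counts / sum(h$counts))
  Gref <- Gref - min(Gref[is.finite(Gref)])
  ok <- h$counts > 0
  expect_equal(prof$G[ok], Gref[ok], tolerance = 1e-8)
})

test_that("WHAM recovers an analytic double-well profile within 0.1 kT", {
  dw <- double_well_windows()
  prof <- wham(dw$windows, n_bins = 50, temperature = dw$temperature)
  kT <- kB_kj() * dw$temperature
  # compare on well-sampled bins, up to an additive constant
  ok <- !is.na(prof$G) & prof$p > 5e-3
  diffs <- (prof$G - dw$G0_binned)[ok]
  expect_gte(sum(ok), 15)
  expect_lt(max(diffs - mean(diffs)), 0.1 * kT)
  expect_lt(max(-(diffs - mean(diffs))), 0.1 * kT)
})

test_that("the WHAM fixed point is insensitive to extra iterations", {
  dw <- double_well_windows(n_samples = 2000)
  p1 <- wham(dw$windows, temperature = 291, max_iter = 10000, tolerance = 1e-9)
  p2 <- wham(dw$windows, temperature = 291, max_iter = 20000, tolerance = 1e-9)
  ok <- !is.na(p1$G)
  expect_equal(p1$G[ok], p2$G[ok], tolerance = 1e-7)
})

test_that("non-overlapping windows fail loudly", {
  win <- list(
    list(q0 = 0.05, k_umb = 1e5, samples = tibble::tibble(Q = rnorm(200, 0.05, 0.003), F_pN = 0)),
    list(q0 = 0.95, k_umb = 1e5, samples = tibble::tibble(Q = rnorm(200, 0.95, 0.003), F_pN = 0)))
  expect_error(wham(win, temperature = 291, max_iter = 50), "overlap")
})

test_that("state_split handles symmetric, one-sided and uniform cases", {
  s <- tibble::tibble(Q = c(rep(0.25, 50), rep(0.75, 50)), weight = 1 / 100)
  expect_equal(unname(state_split(s)), c(0.5, 0.5))
  expect_equal(sum(state_split(s)), 1)
  s2 <- tibble::tibble(Q = rep(0.9, 10), weight = 0.1)
  expect_warning(ps <- state_split(s2), "degenerate")
  expect_equal(unname(ps), c(0, 1))
  # symmetric density about the boundary
  set.seed(2)
  s3 <- tibble::tibble(Q = c(runif(5000, 0, 0.5), runif(5000, 0.5, 1)),
                       weight = 1e-4)
  expect_equal(state_split(s3)[["P_f"]], 0.5, tolerance = 0.02)
})

test_that("mean_state_forces conditions correctly on state", {
  s <- tibble::tibble(Q = c(0.2, 0.3, 0.8, 0.9), F_pN = 5, weight = 0.25)
  f <- mean_state_forces(s)
  expect_equal(unname(f), c(5, 5))
  s2 <- tibble::tibble(Q = c(0.2, 0.3, 0.8, 0.9), F_pN = c(0, 0, 6, 10),
                       weight = 0.25)
  f2 <- mean_state_forces(s2)
  expect_equal(unname(f2), c(0, 8))
  # uniform weights equal simple conditional means
  s3 <- tibble::tibble(Q = runif(100), F_pN = rnorm(100), weight = 0.01)
  f3 <- mean_state_forces(s3)
  expect_equal(f3[["F_u"]], mean(s3$F_pN[s3$Q <= 0.5]))
  expect_equal(f3[["F_f"]], mean(s3$F_pN[s3$Q > 0.5]))
  # an empty state is NA with a warning
  s4 <- tibble::tibble(Q = rep(0.2, 5), F_pN = 1, weight = 0.2)
  expect_warning(f4 <- mean_state_forces(s4), "undefined")
  expect_true(is.na(f4[["F_f"]]))
})

test_that("vector-mean forces cancel a fluctuating direction but keep a load", {
  set.seed(3)
  n <- 5000
  th <- runif(n, 0, 2 * pi)
  mag <- abs(rnorm(n, 20, 5))
  s <- tibble::tibble(Q = rep(0.2, n), weight = 1 / n,
                      F_x = mag * cos(th), F_y = mag * sin(th), F_z = 0,
                      F_pN = mag)
  f <- suppressWarnings(mean_state_forces(s))
  expect_lt(f[["F_u"]], 2) # random directions: tension ~ 0
  s2 <- s
  s2$F_x <- 0; s2$F_y <- 0; s2$F_z <- mag
  f2 <- suppressWarnings(mean_state_forces(s2))
  expect_equal(f2[["F_u"]], mean(mag), tolerance = 1e-6) # aligned: full load
})
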