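# Reaction coordinate, Langevin integrator, constraints, umbrella sampling.

test_that("Q has the exact switching midpoint and saturating limits", {
  cm <- tibble::tibble(i = 1L, j = 2L, r0 = 0.5, eps = 1)
  mk <- function(r) matrix(c(0, 0, 0, r, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(compute_Q(mk(1.2 * 0.5), cm), 0.5) # term = 1/2 at lambda r0
  expect_gte(compute_Q(as.matrix(toy16$beads[, c("x", "y", "z")]),
                       toy16$contacts), 0.98)
  ext <- mk(5)
  expect_lt(compute_Q(ext, cm), 0.02)
  expect_error(compute_Q(mk(1), cm[0, ]), "empty contact map")
})

test_that("Q is invariant under rigid-body motion", {
  set.seed(4)
  pos <- as.matrix(toy16$beads[, c("x", "y", "z")]) +
    matrix(rnorm(48, sd = 0.1), ncol = 3)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  expect_equal(compute_Q(pos %*% R + 5, toy16$contacts),
               compute_Q(pos, toy16$contacts), tolerance = 1e-12)
})

test_that("trajectories are bit-reproducible under a fixed seed", {
  t1 <- run_trajectory(toy_sys, t_max = 20, seed = 31, start = "native")
  t2 <- run_trajectory(toy_sys, t_max = 20, seed = 31, start = "native")
  expect_identical(t1$frames, t2$frames)
  t3 <- run_trajectory(toy_sys, t_max = 20, seed = 32, start = "native")
  expect_false(identical(t1$frames$Q, t3$frames$Q))
})

test_that("constrained bond lengths are preserved through dynamics", {
  tr <- run_trajectory(toy_sys, t_max = 20, seed = 5, start = "native",
                       record_positions = TRUE, stride = 20)
  b <- toy_sys$bonds[toy_sys$bonds$constrained, ]
  for (f in seq_len(dim(tr$positions)[1])) {
    p <- tr$positions[f, , ]
    dev <- abs(sqrt(rowSums((p[b$i, ] - p[b$j, ])^2)) - b$r0)
    expect_lt(max(dev), 1e-6)
  }
})

test_that("the overdamped zero-temperature limit relaxes downhill", {
  set.seed(8)
  pos <- positions_of(toy_sys)
  pos <- pos + matrix(rnorm(length(pos), sd = 0.05), ncol = 3)
  tr <- run_trajectory(toy_sys, t_max = 4, dt = 0.002, seed = 1,
                       start = pos, friction = 50, temperature = 0,
                       stride = 40)
  e <- tr$frames$E
  expect_lt(tail(e, 1), head(e, 1))
  expect_true(all(diff(e) < 1e-6)) # non-increasing within tolerance
})

test_that("a single free particle equipartitions to kBT per dof", {
  bead <- toy16$beads[1, ]
  bead$bead <- 1L
  free_sys <- build_go_system(bead, toy16$contacts[0, ])
  tr <- run_trajectory(free_sys, t_max = 5000, dt = 0.005, seed = 77,
                       friction = 1, stride = 10, start = "current")
  # mean kinetic energy of 3 dof = 3/2 kB T
  expect_equal(mean(tr$frames$E_kin), 1.5 * kB_kj() * 291, tolerance = 0.02)
})

test_that("total energy is conserved in the frictionless (NVE) limit", {
  tr <- run_trajectory(toy_sys, t_max = 6, dt = 0.001, seed = 3,
                       start = "native", friction = 0, temperature = 291,
                       stride = 1)
  etot <- tr$frames$E + tr$frames$E_kin
  n_steps <- nrow(tr$frames)
  drift <- abs(tail(etot, 1) - etot[1]) / (n_steps * 16)
  expect_lt(drift, 1e-4) # kJ/mol per step per bead
})

test_that("the toy protein folds from extended at low temperature", {
  tr <- run_trajectory(toy_sys, t_max = 1500, seed = 21, start = "extended",
                       temperature = 150, stride = 100)
  expect_gt(max(tr$frames$Q), 0.7)
})

test_that("the default toy is two-state: bimodal Q histogram at 291 K", {
  tr <- run_trajectory(toy_sys, t_max = 30000, seed = 11, start = "native",
                       stride = 200)
  q <- tr$frames$Q
  expect_gt(mean(q < 0.3), 0.02) # unfolded basin occupied
  expect_gt(mean(q > 0.7), 0.35)  # folded basin occupied
  # a genuine dip: the barrier region is less occupied than either basin
  h <- hist(q, breaks = seq(0, 1, 0.05), plot = FALSE)$density
  barrier <- min(h[5:14])
  expect_lt(barrier, max(h[1:4]))
  expect_lt(barrier, max(h[15:20]))
})

test_that("umbrella sampling produces well-formed, biased windows", {
  sys <- tethered_system(12)
  us <- run_umbrella(sys, centers = seq(0, 1, length.out = 16), k_umb = 100,
                     t_per_window = 40, t_equil = 20, seed = 5)
  expect_length(us$windows, 16)
  expect_equal(vapply(us$windows, `[[`, numeric(1), "q0"),
               seq(0, 1, length.out = 16))
  # bias bookkeeping: V recomputable from (Q, Q0, k)
  w <- us$windows[[7]]
  expect_equal(w$samples$V_bias, 0.5 * w$k_umb * (w$samples$Q - w$q0)^2)
  expect_error(run_umbrella(sys, centers = c(0.5, 0.1)), "sorted")
})

test_that("a window centered at Q0 = 1 pulls the bare toy into the native basin", {
  us <- run_umbrella(toy_sys, centers = c(0.6, 1), k_umb = 100,
                     t_per_window = 80, t_equil = 40, seed = 9)
  expect_gt(mean(us$windows[[2]]$samples$Q), 0.8)
})

test_that("tether force fluctuates around zero without systematic pull", {
  # long-linker system, unfolded domain kept at moderate Q: average tension
  # must be far below the instantaneous thermal force scale sqrt(kT ks)
  sys <- tethered_system(24)
  tr <- run_trajectory(sys, t_max = 600, seed = 13, equil = 20000)
  f_vec <- c(mean(tr$frames$F_x), mean(tr$frames$F_y), mean(tr$frames$F_z))
  expect_lt(sqrt(sum(f_vec^2)), 60)
  expect_gt(sd(tr$frames$F_pN), 60) # thermal scale ~ 140 pN
})
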