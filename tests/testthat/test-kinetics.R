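# Bell escape rates, MFPT estimation, rate scaling, KMC vs the master
# equation, the preequilibrium closed form, and profile assembly.

test_that("the Bell rate reproduces its anchor points", {
  bp <- bell_params()
  expect_equal(bell_rate(0, bp), 3.4e-4)
  # closed-form doubling force: ln2 kT / dx ~ 8.70 pN at 291 K
  f2 <- kjmolnm_to_pn(log(2) * kB_kj() * 291 / 0.32)
  expect_equal(f2, 8.70, tolerance = 0.01)
  expect_equal(bell_rate(f2, bp), 2 * 3.4e-4, tolerance = 1e-10)
  # 20 pN: k0 exp(1.593) ~ 1.67e-3 s^-1
  expect_equal(bell_rate(20, bp), 3.4e-4 * exp(1.593), tolerance = 1e-3)
  expect_equal(bell_rate(20, bp), 1.67e-3, tolerance = 0.003)
  expect_error(bell_rate(Inf, bp), "finite")
  expect_warning(bell_params(k0 = 5e-3), "admissible")
  expect_warning(bell_params(dx = 0.9), "admissible")
})

test_that("censored MFPT matches hand-computed cases", {
  expect_equal(mfpt_censored(rep(1, 50), 50, 4)$mfpt, 1) # no censoring
  expect_equal(mfpt_censored(1, 2, 4)$mfpt, 5)           # (1*1 + 1*4)/1
  z <- mfpt_censored(numeric(0), 50, 4)
  expect_true(z$censored_bound)
  expect_equal(z$mfpt, 200)
  expect_error(mfpt_censored(1:3, 2, 1), "more events")
})

test_that("censored MFPT recovers the rate from censored exponential data", {
  set.seed(10)
  k <- 0.8
  t_sim <- 1.5 / k # ~ 30% of draws censored
  errs <- vapply(1:40, function(rep) {
    tt <- rexp(60, k)
    obs <- tt[tt <= t_sim]
    1 / mfpt_censored(obs, 60, t_sim)$mfpt - k
  }, numeric(1))
  # unbiased within 3 SE of the replicate mean
  expect_lt(abs(mean(errs)) / (sd(errs) / sqrt(length(errs))), 3)
})

test_that("rate scaling anchors the largest L and preserves ratios", {
  tbl <- tibble::tibble(L = c(21, 41, 61),
                        k_f_sim = c(2e-3, 8e-3, 2e-2),
                        k_u_sim = c(5e-2, 1e-2, 4e-3))
  rs <- scale_rates(tbl, k_u_iso_exp = 4.9e-4)
  expect_equal(rs$k_u[rs$L == 61], 4.9e-4) # exact anchor
  expect_equal(rs$k_u[1] / rs$k_u[3], tbl$k_u_sim[1] / tbl$k_u_sim[3])
  expect_equal(rs$k_f / rs$k_u, tbl$k_f_sim / tbl$k_u_sim) # stability preserved
  # doubling all simulated unfolding rates leaves the scaled output unchanged
  tbl2 <- tbl
  tbl2$k_u_sim <- 2 * tbl2$k_u_sim
  rs2 <- scale_rates(tbl2, k_u_iso_exp = 4.9e-4)
  expect_equal(rs2$k_u, rs$k_u)
  # a table already in target units gets unit factors
  tbl3 <- tbl
  tbl3$k_u_sim[3] <- 4.9e-4
  expect_equal(attr(scale_rates(tbl3, 4.9e-4), "factor_u"), 1)
  expect_error(scale_rates(tbl[1:2, ][c(1, 1), ], 4.9e-4), "exactly one row")
})

test_that("the degenerate scheme gives the analytic single exponential", {
  sch <- kinetic_scheme(0, 0, 3.4e-4, 0)
  res <- kmc_ffl(sch, t_total = 900, n_replicas = 20000, seed = 1)
  expect_equal(res$f_FL, 1 - exp(-3.4e-4 * 900), tolerance = 3 * res$se / res$f_FL)
  expect_equal(1 - exp(-3.4e-4 * 900), 0.264, tolerance = 0.002)
  expect_equal(kmc_ffl(sch, t_total = 0)$f_FL, 0)
  # survival is non-increasing
  expect_true(all(diff(res$survival$S) <= 0))
  expect_error(kinetic_scheme(0, 0, 0, 1), "zero total outflow")
  expect_error(kinetic_scheme(1, 0, 0, 0), "zero total outflow")
})

test_that("KMC agrees with the matrix-exponential master equation", {
  rates <- c(1e-4, 1e-3, 1e-2)
  t_tot <- 900
  for (kf in rates) {
    for (ku in rates) {
      for (ke in rates) {
        sch <- kinetic_scheme(kf, ku, ke, ke / 2)
        mc <- kmc_ffl(sch, t_tot, n_replicas = 1500,
                      seed = round(1e5 * (kf + 10 * ku + 100 * ke)))
        exact <- master_ffl(kf, ku, ke, ke / 2, t_tot)
        se <- max(mc$se, sqrt(exact * (1 - exact) / 1500))
        expect_lt(abs(mc$f_FL - exact), 3 * se + 1e-9)
      }
    }
  }
})

test_that("the preequilibrium closed form matches its limits", {
  bp <- bell_params()
  expect_equal(preeq_ffl(1, 0, 0, NA, t = 900, bp), 0.264, tolerance = 0.002)
  expect_equal(preeq_ffl(0.5, 0.5, 5, 15, t = 1e9, bp), 1)
  # monotone in t and in the folded-state force
  f1 <- preeq_ffl(0.4, 0.6, 3, 10, t = 900, bp)
  expect_gt(preeq_ffl(0.4, 0.6, 3, 15, t = 900, bp), f1)
  expect_gt(preeq_ffl(0.4, 0.6, 3, 10, t = 1800, bp), f1)
  expect_error(preeq_ffl(0.6, 0.6, 3, 10), "equal 1")
})

test_that("KMC and preequilibrium agree when exchange is fast", {
  bp <- bell_params()
  set.seed(1)
  for (case in 1:6) {
    pf <- runif(1, 0.05, 0.95)
    fu <- runif(1, 0, 8)
    ff <- runif(1, 5, 22)
    keu <- bell_rate(fu, bp)
    kef <- bell_rate(ff, bp)
    # folding/unfolding 100x faster than both escape rates
    ku <- 150 * max(keu, kef)
    kf <- ku * pf / (1 - pf)
    mc <- kmc_ffl(kinetic_scheme(kf, ku, keu, kef), 900,
                  n_replicas = 4000, seed = case)
    pe <- preeq_ffl(1 - pf, pf, fu, ff, 900, bp)
    expect_lt(abs(mc$f_FL - pe), 0.02)
  }
})

test_that("assemble_profile joins, solves and flags consistently", {
  summ <- tibble::tibble(L = c(10, 20, 30),
                         P_u = c(0.99, 0.4, 0.05),
                         P_f = c(0.01, 0.6, 0.95),
                         F_u_pN = c(3, 4, 2), F_f_pN = c(30, 18, 6))
  rates <- scale_rates(tibble::tibble(
    L = c(10, 20, 30), k_f_sim = c(1e4, 1.5e5, 1.9e5),
    k_u_sim = c(1e6, 1e5, 1e3)), k_u_iso_exp = 4.9e-4)
  prof <- assemble_profile(summ, rates, n_replicas = 3000, seed = 2)
  expect_true(all(prof$f_FL_kmc >= 0 & prof$f_FL_kmc <= 1))
  expect_true(all(abs(prof$f_FL_kmc - prof$f_FL_preeq) < 0.05))
  expect_equal(glance(prof)$n_L, 3)
  expect_error(assemble_profile(summ[1:2, ], rates), "different L grids")
})

test_that("profile RMSD is plain arithmetic over shared L", {
  pred <- tibble::tibble(L = c(10, 20, 30), f_FL = c(0.2, 0.6, 0.3))
  expect_equal(profile_rmsd(pred, pred), 0)
  off <- pred
  off$f_FL <- off$f_FL + 0.1
  expect_equal(profile_rmsd(off, pred), 0.1, tolerance = 1e-12)
  ex <- tibble::tibble(L = c(20, 30, 40), f_FL = c(0.5, 0.25, 0.1))
  expect_equal(profile_rmsd(pred, ex),
               sqrt(mean(c(0.6 - 0.5, 0.3 - 0.25)^2)))
  expect_error(profile_rmsd(pred, tibble::tibble(L = 99, f_FL = 0.1)),
               "no linker lengths|share")
})

test_that("experimental profile TSV reading validates its contract", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(L = c(21, 23), f_FL = c(0.1, 0.4)), path)
  df <- read_force_profile_tsv(path)
  expect_equal(df$L, c(21, 23))
  readr::write_tsv(tibble::tibble(L = 1, f_FL = 1.4), path)
  expect_error(read_force_profile_tsv(path), "\\[0, 1\\]")
})
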