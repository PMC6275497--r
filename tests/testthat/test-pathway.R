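# Transition-path extraction and mechanism statistics.

test_that("TP extraction follows the last-exit / first-entry rule", {
  q <- c(0.1, 0.2, 0.35, 0.25, 0.4, 0.8)
  tp <- extract_tps(q)
  expect_equal(tp$start, 4) # the 0.25 frame, last below 0.3
  expect_equal(tp$end, 6)   # the 0.8 frame, first above 0.7
  # monotone series: exactly one TP
  expect_equal(nrow(extract_tps(seq(0.1, 0.9, length.out = 9))), 1)
  # series confined to the barrier region: none
  expect_equal(nrow(extract_tps(rep(c(0.4, 0.6), 10))), 0)
})

test_that("TP extraction matches a brute-force segment scan", {
  set.seed(6)
  for (rep in 1:20) {
    q <- pmin(pmax(cumsum(rnorm(120, 0, 0.18)) %% 1.2, 0), 1)
    expect_equal(as.data.frame(extract_tps(q)),
                 as.data.frame(brute_force_tps(q)), info = paste("rep", rep))
  }
})

test_that("unfolding TPs mirror folding TPs", {
  q <- c(0.9, 0.8, 0.75, 0.72, 0.5, 0.2)
  tp <- extract_tps(q, direction = "unfolding")
  expect_equal(tp$start, 4) # last above 0.7
  expect_equal(tp$end, 6)   # first below 0.3
  expect_equal(nrow(extract_tps(q, direction = "folding")), 0)
})

test_that("contact states use the strict lambda r0 criterion", {
  cm <- tibble::tibble(i = 1L, j = 2L, r0 = 0.5, eps = 1)
  mk <- function(r) matrix(c(0, 0, 0, r, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(contact_states(mk(0.45), cm)[1, 1], 1L)
  expect_equal(contact_states(mk(0.6 - 1e-9), cm)[1, 1], 1L)
  expect_equal(contact_states(mk(0.6), cm)[1, 1], 0L) # boundary: not formed
  expect_equal(contact_states(mk(3), cm)[1, 1], 0L)
})

test_that("phi-values hit their exact limits and synthetic ground truth", {
  # all contacts always formed on TPs -> phi = 1; never formed -> phi = 0
  ens1 <- make_synthetic_tp_ensemble(
    synthetic_tp_spec(6, p_q_tp = 1, p_q_u = 0.1, p_tp_nn = 0.2,
                      n_frames = 2000, seed = 2))
  expect_true(all(phi_values(ens1)$phi == 1))
  ens0 <- make_synthetic_tp_ensemble(
    synthetic_tp_spec(6, p_q_tp = 0, p_q_u = 0.1, p_tp_nn = 0.2,
                      n_frames = 2000, seed = 2))
  expect_true(all(phi_values(ens0)$phi == 0))

  spec <- synthetic_tp_spec(10, p_q_tp = seq(0.1, 0.9, length.out = 10),
                            p_q_u = 0.1, p_tp_nn = 0.15, n_frames = 5e4,
                            seed = 4)
  ens <- make_synthetic_tp_ensemble(spec)
  phi <- phi_values(ens)
  truth <- ens$truth$phi
  n_tp <- sum(ens$frames$label == "TP")
  se <- sqrt(0.25 / n_tp) * 3 # conservative per-contact bound
  expect_equal(phi$residue, truth$residue)
  expect_true(all(abs(phi$phi - truth$phi) < 3 * se))
})

test_that("p(TP)_nn follows the harvest-specific closed forms", {
  expect_equal(p_tp_nn(0.05, 1, "folding"), 0.1 / 1.1)
  expect_equal(p_tp_nn(0, 1, "folding"), 0)
  expect_equal(p_tp_nn(0.05, 1, "unfolding", p_u = 0.25, p_f = 0.75),
               0.1 / (0.1 + (0.25 / 0.75)))
  expect_error(p_tp_nn(0.05, 1, "unfolding", p_u = 1, p_f = 0), "positive")
  expect_error(p_tp_nn(0.05, -1), "positive")
})

test_that("folding and unfolding p(TP)_nn agree for a reversible system", {
  # discrete two-state Markov oracle: at equilibrium p_U t_U = p_F t_F
  # (detailed balance), so both closed forms give the same p(TP)_nn
  t_tp <- 0.2
  k_f <- 0.5
  k_u <- 0.125
  p_f <- k_f / (k_f + k_u)
  p_u <- 1 - p_f
  t_f_mfpt <- 1 / k_f
  t_u_mfpt <- 1 / k_u
  expect_equal(p_tp_nn(t_tp, t_f_mfpt, "folding"),
               p_tp_nn(t_tp, t_u_mfpt, "unfolding", p_u = p_u, p_f = p_f))
})

test_that("p(TP|q)_nn reproduces Bayes limits and synthetic ground truth", {
  # independence: p(q|TP) = p(q)_nn for every contact -> result = p(TP)_nn
  spec_ind <- synthetic_tp_spec(6, p_q_tp = 0.3, p_q_u = 0.3, p_tp_nn = 0.2,
                                n_frames = 8e4, seed = 5)
  ens <- make_synthetic_tp_ensemble(spec_ind)
  res <- p_tp_given_q(ens, 0.2)
  expect_equal(res$p_tp_given_q, rep(0.2, 6), tolerance = 0.03)

  # a contact formed only on TPs -> p(TP|q) = 1
  spec_tp <- synthetic_tp_spec(3, p_q_tp = 1, p_q_u = 0, p_tp_nn = 0.3,
                               n_frames = 5000, seed = 6)
  res2 <- p_tp_given_q(make_synthetic_tp_ensemble(spec_tp), 0.3)
  expect_equal(res2$p_tp_given_q, rep(1, 3), tolerance = 1e-9)

  # general ground truth within sampling error at 1e5 frames
  spec <- synthetic_tp_spec(8, p_q_tp = c(0.9, 0.6, 0.4, 0.25),
                            p_q_u = c(0.05, 0.2, 0.3, 0.2), p_tp_nn = 0.12,
                            n_frames = 1e5, seed = 7)
  ens3 <- make_synthetic_tp_ensemble(spec)
  res3 <- p_tp_given_q(ens3, spec$p_tp_nn)
  expect_equal(res3$p_tp_given_q, ens3$truth$p_tp_given_q, tolerance = 0.02)
})

test_that("folded frames are excluded from nonnative statistics", {
  spec <- synthetic_tp_spec(4, p_q_tp = 0.5, p_q_u = 0.1, p_tp_nn = 0.2,
                            n_frames = 5000, n_folded = 2000, seed = 8)
  ens <- make_synthetic_tp_ensemble(spec)
  res <- p_tp_given_q(ens, 0.2)
  # if folded (all-formed) frames leaked in, p(q)_nn would be pulled far
  # above the nonnative mixture value
  expect_lt(max(abs(res$p_q_nn - (0.2 * 0.5 + 0.8 * 0.1))), 0.015)
})

test_that("TP ensembles built from simulated trajectories are consistent", {
  trajs <- lapply(1:4, function(s) {
    run_trajectory(toy_sys, t_max = 4000, seed = 300 + s, start = "extended",
                   stride = 40, record_positions = TRUE)
  })
  cm <- toy_sys$contacts
  ens <- tp_ensemble_from_trajectories(trajs, cm)
  expect_s3_class(ens, "tp_ensemble")
  if (ens$n_tp > 0) {
    # native frames carry essentially all contacts; extraction labels agree
    tp_rows <- ens$frames$label == "TP"
    expect_true(all(ens$frames$Q[tp_rows] >= 0.0))
    phi <- phi_values(ens)
    expect_true(all(phi$phi >= 0 & phi$phi <= 1))
  }
  # stride-2 subsampling leaves phi unchanged within tolerance
  if (ens$n_tp >= 3) {
    sub <- trajs
    for (k in seq_along(sub)) {
      keep <- seq(1, nrow(sub[[k]]$frames), by = 2)
      sub[[k]]$frames <- sub[[k]]$frames[keep, ]
      sub[[k]]$positions <- sub[[k]]$positions[keep, , , drop = FALSE]
    }
    ens2 <- tp_ensemble_from_trajectories(sub, cm)
    if (ens2$n_tp >= 3) {
      p1 <- phi_values(ens)
      p2 <- phi_values(ens2)
      expect_lt(mean(abs(p1$phi - p2$phi)), 0.15)
    }
  }
})

test_that("phi comparison applies the ddG filter and Spearman correlation", {
  phi <- tibble::tibble(residue = 1:5, phi = c(0.9, 0.7, 0.5, 0.3, 0.1))
  ref <- tibble::tibble(residue = 1:5,
                        phi_exp = c(0.85, 0.65, 0.45, 0.35, 0.15),
                        ddG = c(10, 9, 8, 12, 3)) # residue 5 filtered out
  cmp <- compare_phi(phi, ref)
  expect_equal(cmp$n, 4)
  expect_equal(cmp$spearman,
               cor(c(0.9, 0.7, 0.5, 0.3), c(0.85, 0.65, 0.45, 0.35),
                   method = "spearman"))
  expect_equal(cmp$spearman, 1)
  ref_rev <- ref
  ref_rev$phi_exp <- rev(ref_rev$phi_exp)
  expect_equal(compare_phi(phi, ref_rev)$spearman, -1)
  # too few pairs: undefined
  ref2 <- ref
  ref2$ddG <- c(10, 9, 1, 1, 1)
  expect_true(is.na(compare_phi(phi, ref2)$spearman))
})

test_that("mechanism reports rank contacts with lexicographic tie-breaks", {
  spec <- synthetic_tp_spec(5, p_q_tp = c(0.9, 0.9, 0.5, 0.2, 0.2),
                            p_q_u = 0.2, p_tp_nn = 0.25, n_frames = 2e4,
                            seed = 9)
  ens <- make_synthetic_tp_ensemble(spec)
  # mfpt chosen so the folding-harvest closed form returns the spec's
  # p(TP)_nn given the generator's TP segment length
  mfpt <- 2 * ens$t_tp * (1 - 0.25) / 0.25
  rep <- mechanism_report(ens, mfpt = mfpt)
  expect_s3_class(rep, "mechanism_report")
  top <- top_contacts(rep, 3)
  expect_equal(nrow(top), 3)
  expect_true(all(diff(rep$ranking$p_tp_given_q[!is.na(rep$ranking$p_tp_given_q)]) <= 1e-12))
  expect_equal(names(tidy(rep)),
               c("i", "j", "p_q_tp", "p_q_nn", "p_tp_given_q"))
})
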