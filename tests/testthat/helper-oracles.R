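# Independent oracles used to check the package's own solvers.

# Master-equation solution of the four-state arrest-escape scheme via the
# matrix exponential (states UA, FA, UR, FR; UR/FR absorbing).
master_ffl <- function(k_f, k_u, k_e_u, k_e_f, t) {
  G <- matrix(0, 4, 4) # generator, G[i, j] = rate i -> j
  G[1, 2] <- k_f
  G[1, 3] <- k_e_u
  G[2, 1] <- k_u
  G[2, 4] <- k_e_f
  diag(G) <- -rowSums(G)
  P <- as.matrix(Matrix::expm(G * t))
  P[1, 3] + P[1, 4]
}

# Brute-force transition-path extraction: every maximal (s, e) with
# q[s] < lo, q[e] > hi and all interior values inside [lo, hi].
brute_force_tps <- function(q, lo = 0.3, hi = 0.7) {
  out <- list()
  for (s in seq_along(q)) {
    if (q[s] >= lo) next
    for (e in seq_along(q)) {
      if (e <= s || q[e] <= hi) next
      inner <- if (e - s > 1) q[(s + 1):(e - 1)] else numeric(0)
      if (all(inner >= lo & inner <= hi)) {
        out[[length(out) + 1]] <- c(s, e)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = m[, 1], end = m[, 2])
}

# Draw samples from an analytic 1D free-energy profile under a harmonic
# bias, by inverse-CDF sampling on a fine grid; returns umbrella-style
# windows plus the analytic G for comparison.
double_well_windows <- function(n_samples = 12000, temperature = 291,
                                k_umb = 400, centers = seq(0.1, 0.9, by = 0.1),
                                seed = 42) {
  set.seed(seed)
  kT <- kB_kj() * temperature
  grid <- seq(0.001, 0.999, length.out = 4000)
  G0 <- 25 * (1 - ((grid - 0.5) / 0.35)^2)^2 # double well, ~10 kT barrier
  windows <- lapply(centers, function(c0) {
    V <- G0 + 0.5 * k_umb * (grid - c0)^2
    p <- exp(-(V - min(V)) / kT)
    qs <- grid[findInterval(runif(n_samples), cumsum(p) / sum(p)) + 1]
    list(q0 = c0, k_umb = k_umb,
         samples = tibble::tibble(Q = qs, F_pN = 0))
  })
  # analytic reference on the same 50-bin grid the WHAM result uses:
  # -kT log of the bin-integrated Boltzmann weight (comparing bin-averaged
  # quantities avoids binning bias where G0 is steep)
  edges <- seq(0, 1, length.out = 51)
  gb <- findInterval(grid, edges, all.inside = TRUE)
  w <- exp(-G0 / kT)
  pb <- vapply(1:50, function(b) sum(w[gb == b]), numeric(1))
  G0_binned <- ifelse(pb > 0, -kT * log(pb / sum(w)), NA_real_)
  list(windows = windows, grid = grid, G0 = G0, G0_binned = G0_binned,
       temperature = temperature)
}
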