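# Langevin dynamics, the reaction coordinate Q, and umbrella sampling.

#' Fraction of native contacts Q
#'
#' Smooth switching-function count of formed native contacts,
#' `Q = (1/N) sum_ij 1 / (1 + exp[gamma (r_ij - lambda r0_ij)])`, the
#' folding reaction coordinate. `lambda` > 1 accounts for fluctuations of a
#' formed contact; `gamma` sets the switching steepness.
#'
#' @param positions n x 3 coordinate matrix (nm) indexed by the contact
#'   map's bead indices, or a `bead_model`.
#' @param contacts a `contact_map` or any tibble with columns `i`, `j`,
#'   `r0`.
#' @param gamma switching steepness, nm^-1 (default 50).
#' @param lambda contact-width factor (default 1.2).
#' @return Q in (0, 1).
#' @export
compute_Q <- function(positions, contacts, gamma = 50, lambda = 1.2) {
  if (inherits(positions, "bead_model")) {
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  if (nrow(contacts) == 0) abort("empty contact map: Q is undefined")
  d <- positions[contacts$i, , drop = FALSE] - positions[contacts$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  g <- pmin(pmax(gamma * (r - lambda * contacts$r0), -40), 40)
  mean(1 / (1 + exp(g)))
}

new_cg_trajectory <- function(frames, positions, mobile_beads, metadata) {
  structure(list(frames = frames, positions = positions,
                 mobile_beads = mobile_beads, metadata = metadata),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", nrow(x$frames), " frames, dt = ", x$metadata$dt,
      " ps, T = ", x$metadata$temperature, " K, seed = ", x$metadata$seed,
      "\n", sep = "")
  if (!is.null(x$metadata$bias)) {
    cat("  umbrella bias k = ", x$metadata$bias$k_umb, " kJ/mol at Q0 = ",
        x$metadata$bias$q0, "\n", sep = "")
  }
  invisible(x)
}

.start_positions <- function(system, start) {
  if (is.matrix(start)) return(start)
  if (start == "current") return(positions_of(system))
  if (start == "native") {
    if (!is.null(system$tether)) {
      abort("start = \"native\" is only defined off the ribosome; pass explicit positions")
    }
    pos <- positions_of(system)
    pos[seq_len(system$n_domain), ] <- system$native_pos
    return(pos)
  }
  if (start == "extended") {
    if (!is.null(system$tether)) return(positions_of(system)) # threaded start
    n <- system$n_domain
    r0 <- system$bonds$r0[seq_len(n - 1)]
    z <- c(0, cumsum(r0))
    pos <- positions_of(system)
    pos[seq_len(n), ] <- cbind(0.02 * (seq_len(n) %% 2), 0, z)
    return(pos)
  }
  abort("start must be \"current\", \"native\", \"extended\" or a matrix")
}

#' Run a Langevin-dynamics trajectory
#'
#' Propagates the system with a BAOAB-splitting Langevin integrator;
#' all chain bonds except the force-reporting tether are held at their
#' native lengths by iterative constraint projection. Scaffold beads are
#' fixed in space. Per frame the time, Q, tether extension x and pulling
#' force F (pN) are recorded; full mobile-bead coordinates optionally.
#'
#' @param system a `cg_system`.
#' @param t_max trajectory length, ps.
#' @param dt time step, ps (default 0.002).
#' @param stride record every `stride`-th step.
#' @param seed integer seed; identical seeds give bit-identical
#'   trajectories.
#' @param bias optional umbrella bias `list(k_umb, q0)` (kJ/mol).
#' @param friction Langevin friction, ps^-1 (default 0.1; 0 gives the NVE
#'   limit).
#' @param temperature K; defaults to the system temperature.
#' @param start `"current"`, `"native"`, `"extended"`, or an n x 3 matrix.
#' @param equil equilibration steps discarded before recording.
#' @param record_positions store mobile-bead coordinates per frame?
#' @param constraint_tol bond-constraint tolerance, nm.
#' @return a `cg_trajectory`: `frames` tibble (`t`, `Q`, `x`, `F_pN`, `E`
#'   potential, `E_kin` kinetic),
#'   optional `positions` array (frame x mobile bead x 3), and metadata
#'   sufficient to re-run identically.
#' @export
run_trajectory <- function(system, t_max, dt = 0.002, stride = 100, seed = 1,
                           bias = NULL, friction = 0.1, temperature = NULL,
                           start = "current", equil = 0,
                           record_positions = FALSE, constraint_tol = 1e-8) {
  stopifnot(inherits(system, "cg_system"))
  temperature <- temperature %||% system$params$temperature
  n_steps <- max(1L, round(t_max / dt))
  packed <- .pack_system(system,
                         k_umb = if (!is.null(bias)) bias$k_umb else 0,
                         q0 = if (!is.null(bias)) bias$q0 else 0)
  pos <- .start_positions(system, start)
  set.seed(seed)
  res <- cpp_run(packed, pos, NULL, dt, friction, temperature,
                 as.integer(n_steps), as.integer(stride), as.integer(equil),
                 record_positions, constraint_tol, 20L, 0.3)
  nf <- res$n_frames
  frames <- tibble(t = res$t[seq_len(nf)], Q = res$Q[seq_len(nf)],
                   x = res$x[seq_len(nf)], F_pN = res$F_pN[seq_len(nf)],
                   E = res$E[seq_len(nf)], E_kin = res$E_kin[seq_len(nf)],
                   F_x = res$F_x[seq_len(nf)], F_y = res$F_y[seq_len(nf)],
                   F_z = res$F_z[seq_len(nf)])
  posarr <- NULL
  if (record_positions) {
    posarr <- aperm(array(res$positions, dim = c(3, res$n_mobile, nf)),
                    c(3, 2, 1))
  }
  meta <- list(seed = seed, dt = dt, stride = stride, friction = friction,
               temperature = temperature, bias = bias, equil = equil,
               t_max = t_max, system_hash = rlang::hash(system))
  out <- new_cg_trajectory(frames, posarr,
                           system$beads$bead[system$beads$mobile], meta)
  out$final <- list(pos = res$pos_final, vel = res$vel_final)
  out
}

new_umbrella_set <- function(windows, metadata) {
  structure(list(windows = windows, metadata = metadata),
            class = "umbrella_set")
}

#' @export
print.umbrella_set <- function(x, ...) {
  cat("<umbrella_set> ", length(x$windows), " windows, k_umb = ",
      x$metadata$k_umb_kcal, " kcal/mol, ",
      nrow(x$windows[[1]]$samples), " samples/window\n", sep = "")
  invisible(x)
}

#' Umbrella sampling along Q
#'
#' Runs one biased trajectory per window with the harmonic bias
#' `V = k_umb (Q - Q0)^2 / 2`. Windows are visited in ascending Q0 starting
#' from the system's current (extended) configuration; each window starts
#' from the final configuration of the previous one, which keeps adjacent
#' windows overlapping. A warning is emitted when adjacent Q histograms
#' share less than `min_overlap` probability mass (WHAM would then be
#' unreliable).
#'
#' @param system a `cg_system`.
#' @param centers window centers on \[0, 1\] (default 16, evenly spaced).
#' @param k_umb umbrella spring constant in kcal/mol (default 600;
#'   converted internally to kJ/mol).
#' @param t_per_window production time per window, ps.
#' @param t_equil equilibration time discarded per window, ps.
#' @param seed integer seed (window w uses `seed + w`).
#' @param dt,stride,friction,temperature as in [run_trajectory()].
#' @param min_overlap adjacent-histogram overlap warning threshold.
#' @return an `umbrella_set`; each window holds `q0`, `k_umb` (kJ/mol) and
#'   a `samples` tibble (`t`, `Q`, `x`, `F_pN`, `V_bias`).
#' @export
run_umbrella <- function(system, centers = seq(0, 1, length.out = 16),
                         k_umb = 600, t_per_window = 500, t_equil = 100,
                         seed = 1, dt = 0.002, stride = 50, friction = 0.1,
                         temperature = NULL, min_overlap = 0.02) {
  stopifnot(inherits(system, "cg_system"))
  if (is.unsorted(centers)) abort("window centers must be sorted ascending")
  if (any(centers < 0 | centers > 1)) abort("window centers must lie in [0, 1]")
  k_kj <- kcal_to_kj(k_umb)
  windows <- vector("list", length(centers))
  start <- .start_positions(system, "extended")
  for (w in seq_along(centers)) {
    tr <- run_trajectory(system, t_max = t_per_window, dt = dt,
                         stride = stride, seed = seed + w,
                         bias = list(k_umb = k_kj, q0 = centers[w]),
                         friction = friction, temperature = temperature,
                         start = start,
                         equil = round(t_equil / dt))
    samples <- tr$frames
    samples$V_bias <- 0.5 * k_kj * (samples$Q - centers[w])^2
    windows[[w]] <- list(q0 = centers[w], k_umb = k_kj, samples = samples,
                         seed = seed + w, final_pos = tr$final$pos)
    start <- tr$final$pos
  }
  for (w in seq_along(centers)[-1]) {
    br <- seq(0, 1, length.out = 51)
    h1 <- tabulate(findInterval(windows[[w - 1]]$samples$Q, br,
                                all.inside = TRUE), 50)
    h2 <- tabulate(findInterval(windows[[w]]$samples$Q, br,
                                all.inside = TRUE), 50)
    ov <- sum(pmin(h1 / sum(h1), h2 / sum(h2)))
    if (ov < min_overlap) {
      warn(sprintf(
        "umbrella windows %d (Q0 = %.2f) and %d (Q0 = %.2f) overlap by only %.1f%% of histogram mass; WHAM may fail",
        w - 1, centers[w - 1], w, centers[w], 100 * ov))
    }
  }
  temperature <- temperature %||% system$params$temperature
  new_umbrella_set(windows, list(
    centers = centers, k_umb_kcal = k_umb, k_umb_kj = k_kj,
    t_per_window = t_per_window, seed = seed, dt = dt, stride = stride,
    temperature = temperature, system_hash = rlang::hash(system),
    linker_length = system$linker_length))
}

#' Export reduced trajectory observables as TSV
#'
#' @param trajectory a `cg_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  readr::write_tsv(trajectory$frames, path)
  invisible(path)
}
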