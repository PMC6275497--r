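# Force-dependent arrest-escape kinetics: Bell escape rates, censored MFPT
# rate estimation, global rate scaling to experimental units, the four-state
# arrest/escape scheme (kinetic Monte Carlo and preequilibrium closed form),
# and force-profile assembly.

#' Bell-model parameters for arrest escape
#'
#' Phenomenological force dependence of the escape rate from translational
#' arrest, `k_e(F) = k0 exp(beta F dx)`. Defaults follow optical-tweezer
#' estimates for the SecM arrest peptide; values outside the experimentally
#' admissible ranges (k0 in 0.5e-4..20e-4 s^-1, dx in 0.1..0.8 nm) trigger a
#' validation warning, not an error.
#'
#' @param k0 zero-force escape rate, s^-1 (default 3.4e-4).
#' @param dx distance to the escape transition state, nm (default 0.32).
#' @param temperature K (default 291).
#' @return object of class `bell_params`.
#' @export
bell_params <- function(k0 = 3.4e-4, dx = 0.32, temperature = 291) {
  if (k0 <= 0 || dx <= 0) abort("k0 and dx must be positive")
  if (k0 < 0.5e-4 || k0 > 20e-4) {
    warn("k0 outside the experimentally admissible range 0.5e-4..20e-4 s^-1")
  }
  if (dx < 0.1 || dx > 0.8) {
    warn("dx outside the experimentally admissible range 0.1..0.8 nm")
  }
  structure(list(k0 = k0, dx = dx, temperature = temperature),
            class = "bell_params")
}

#' Force-dependent escape rate (Bell model)
#'
#' @param F_pN pulling force in pN (vectorized; finite).
#' @param params a [bell_params()] object.
#' @return escape rate(s), s^-1.
#' @export
bell_rate <- function(F_pN, params = bell_params()) {
  if (any(!is.finite(F_pN))) abort("force must be finite")
  F_kj <- pn_to_kjmolnm(F_pN)
  params$k0 * exp(F_kj * params$dx / (.kB * params$temperature))
}

#' Censored maximum-likelihood mean first-passage time
#'
#' `MFPT = [N_event * mean(t_event) + (N - N_event) * t_sim] / N_event`,
#' the maximum-likelihood estimator for exponentially distributed
#' first-passage times observed in `N` finite simulations of length
#' `t_sim`, of which only `N_event` reached the target. With no events the
#' MFPT is undefined; the censoring lower bound `N * t_sim` is returned
#' with `censored_bound = TRUE`.
#'
#' @param first_passage_times observed first-passage times (may be empty).
#' @param n_total total number of simulations N.
#' @param t_sim length of each simulation (same units).
#' @return list(`mfpt`, `n_events`, `censored_bound`).
#' @export
mfpt_censored <- function(first_passage_times, n_total, t_sim) {
  n_ev <- length(first_passage_times)
  if (n_ev > n_total) abort("more events than simulations")
  if (n_ev == 0) {
    return(list(mfpt = n_total * t_sim, n_events = 0L, censored_bound = TRUE))
  }
  mfpt <- (n_ev * mean(first_passage_times) + (n_total - n_ev) * t_sim) / n_ev
  list(mfpt = mfpt, n_events = as.integer(n_ev), censored_bound = FALSE)
}

#' Scale simulated rates to experimental units
#'
#' Coarse-grained rates are much faster than experiment; a single global
#' factor per rate type maps them onto the experimental scale. The
#' unfolding factor is fixed so that the scaled unfolding rate at the
#' largest linker length equals the isolated-domain experimental unfolding
#' rate. The folding factor either preserves the simulation model's
#' stability at the anchor L (`anchor = "simulation"`, the default -- both
#' factors are then equal and every per-L equilibrium constant is
#' preserved) or matches a supplied experimental folding rate
#' (`anchor = "experiment"`).
#'
#' @param rates tibble with columns `L`, `k_f_sim`, `k_u_sim` (internal
#'   units).
#' @param k_u_iso_exp experimental unfolding rate of the isolated domain,
#'   s^-1 (default 4.9e-4).
#' @param anchor `"simulation"` or `"experiment"`.
#' @param k_f_iso_exp experimental folding rate used when
#'   `anchor = "experiment"`.
#' @return a `rate_set` tibble (`L`, `k_f_sim`, `k_u_sim`, `k_f`, `k_u`)
#'   with the scaling factors in attributes `factor_f`, `factor_u`.
#' @export
scale_rates <- function(rates, k_u_iso_exp = 4.9e-4,
                        anchor = c("simulation", "experiment"),
                        k_f_iso_exp = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(all(c("L", "k_f_sim", "k_u_sim") %in% names(rates)))
  Lmax <- max(rates$L)
  row <- rates[rates$L == Lmax, ]
  if (nrow(row) != 1) abort("rate table must contain exactly one row at the largest L")
  if (row$k_u_sim <= 0) abort("anchor unfolding rate must be positive")
  factor_u <- k_u_iso_exp / row$k_u_sim
  factor_f <- if (anchor == "simulation") {
    factor_u # preserves k_f/k_u at every L
  } else {
    if (is.null(k_f_iso_exp)) abort("k_f_iso_exp required for anchor = \"experiment\"")
    k_f_iso_exp / row$k_f_sim
  }
  out <- as_tibble(rates)
  out$k_f <- out$k_f_sim * factor_f
  out$k_u <- out$k_u_sim * factor_u
  structure(out, class = c("rate_set", class(out)),
            factor_f = factor_f, factor_u = factor_u,
            k_u_iso_exp = k_u_iso_exp, anchor = anchor)
}

#' Four-state arrest-escape kinetic scheme
#'
#' States: unfolded-arrested (UA), folded-arrested (FA), and the absorbing
#' escaped states UR and FR. UA <-> FA with the folding/unfolding rates;
#' UA -> UR and FA -> FR with the force-dependent escape rates evaluated at
#' the state-conditioned mean forces.
#'
#' @param k_f,k_u folding and unfolding rates, s^-1.
#' @param k_e_u,k_e_f escape rates from the unfolded and folded arrested
#'   states, s^-1.
#' @return object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(k_f, k_u, k_e_u, k_e_f) {
  r <- c(k_f = k_f, k_u = k_u, k_e_u = k_e_u, k_e_f = k_e_f)
  if (any(!is.finite(r)) || any(r < 0)) abort("all rates must be finite and >= 0")
  if (k_f + k_e_u == 0) {
    abort("state UA has zero total outflow; the scheme cannot evolve")
  }
  if (k_f > 0 && k_u + k_e_f == 0) {
    abort("state FA is reachable but has zero total outflow")
  }
  structure(as.list(r), class = "kinetic_scheme")
}

#' Fraction full-length by kinetic Monte Carlo
#'
#' Simulates the four-state scheme with the rejection-free (BKL/Gillespie)
#' algorithm: at each step a uniform variate selects the transition in
#' proportion to its rate and time advances by `-log(u)/sum(rates)`.
#' Replicas start in UA at t = 0 (the unfolded nascent chain just emerged);
#' f_FL(t) is the fraction of replicas absorbed in UR or FR by `t_total`.
#'
#' @param scheme a [kinetic_scheme()].
#' @param t_total incubation time, s (default 900 = 15 min; use 1800 for
#'   30-min incubations).
#' @param n_replicas Monte Carlo replicas.
#' @param seed integer seed.
#' @return list with `f_FL`, its binomial standard error `se`, the survival
#'   function as a tibble `survival` (`t`, `S`), and per-replica escape
#'   times.
#' @export
kmc_ffl <- function(scheme, t_total = 900, n_replicas = 2000, seed = 1) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (t_total < 0) abort("t_total must be >= 0")
  if (t_total == 0) {
    return(list(f_FL = 0, se = 0,
                survival = tibble(t = 0, S = 1), t_escape = numeric(0)))
  }
  set.seed(seed)
  res <- cpp_kmc(scheme$k_f, scheme$k_u, scheme$k_e_u, scheme$k_e_f,
                 t_total, as.integer(n_replicas))
  escaped <- res$state %in% c(3L, 4L)
  f <- mean(escaped)
  te <- sort(res$t_escape[escaped])
  surv <- tibble(t = c(0, te), S = 1 - seq(0, length(te)) / n_replicas)
  list(f_FL = f, se = sqrt(f * (1 - f) / n_replicas), survival = surv,
       t_escape = res$t_escape)
}

#' Fraction full-length from the preequilibrium closed form
#'
#' When folding and unfolding are fast relative to escape, the arrested
#' states stay equilibrated and
#' `f_FL(t) = 1 - exp(-t [P_u k_e(F_u) + P_f k_e(F_f)])`.
#' An unpopulated state may carry an undefined (`NA`) force; it then
#' contributes nothing.
#'
#' @param P_u,P_f equilibrium populations (must sum to 1).
#' @param F_u,F_f state-conditioned mean forces, pN.
#' @param t incubation time, s.
#' @param bell a [bell_params()] object.
#' @return f_FL in \[0, 1\] (vectorized over L-indexed inputs).
#' @export
preeq_ffl <- function(P_u, P_f, F_u, F_f, t = 900, bell = bell_params()) {
  if (any(abs(P_u + P_f - 1) > 1e-8)) abort("P_u + P_f must equal 1")
  keu <- ifelse(P_u > 0, bell_rate(ifelse(is.na(F_u), 0, F_u), bell), 0)
  kef <- ifelse(P_f > 0, bell_rate(ifelse(is.na(F_f), 0, F_f), bell), 0)
  1 - exp(-t * (P_u * keu + P_f * kef))
}

#' Assemble a predicted force profile across linker lengths
#'
#' Joins the equilibrium summary (populations and state forces per L) with
#' the scaled folding/unfolding rates, evaluates the Bell escape rates at
#' the state-conditioned forces, and computes f_FL(L) both by the full
#' kinetic scheme (KMC) and by the preequilibrium closed form. L values
#' where the two solvers differ by more than `flag_threshold` are flagged
#' (the preequilibrium assumption is then suspect).
#'
#' @param summaries an `equilibrium_summary` (or compatible tibble with
#'   `L`, `P_u`, `P_f`, `F_u_pN`, `F_f_pN`).
#' @param rates a `rate_set` from [scale_rates()] covering the same L grid.
#' @param bell a [bell_params()] object.
#' @param t incubation time, s.
#' @param n_replicas KMC replicas per L.
#' @param seed integer seed.
#' @param flag_threshold solver-disagreement flag level (default 0.05).
#' @return a `force_profile` tibble (`L`, `P_f`, `F_u_pN`, `F_f_pN`, `k_f`,
#'   `k_u`, `k_e_u`, `k_e_f`, `f_FL_kmc`, `f_FL_se`, `f_FL_preeq`,
#'   `preeq_suspect`).
#' @export
assemble_profile <- function(summaries, rates, bell = bell_params(), t = 900,
                             n_replicas = 2000, seed = 1,
                             flag_threshold = 0.05) {
  s <- as_tibble(summaries)
  r <- as_tibble(rates)
  if (!setequal(s$L, r$L)) {
    abort("equilibrium summaries and rate table cover different L grids")
  }
  df <- dplyr::inner_join(s, r[, c("L", "k_f", "k_u")], by = "L")
  df <- df[order(df$L), ]
  keu <- bell_rate(ifelse(is.na(df$F_u_pN), 0, df$F_u_pN), bell)
  kef <- bell_rate(ifelse(is.na(df$F_f_pN), 0, df$F_f_pN), bell)
  kmc <- purrr::map2(seq_len(nrow(df)), df$L, function(k, Lk) {
    kmc_ffl(kinetic_scheme(df$k_f[k], df$k_u[k], keu[k], kef[k]),
            t_total = t, n_replicas = n_replicas, seed = seed + k)
  })
  df$k_e_u <- keu
  df$k_e_f <- kef
  df$f_FL_kmc <- vapply(kmc, `[[`, numeric(1), "f_FL")
  df$f_FL_se <- vapply(kmc, `[[`, numeric(1), "se")
  df$f_FL_preeq <- preeq_ffl(df$P_u, df$P_f, df$F_u_pN, df$F_f_pN, t, bell)
  df$preeq_suspect <- abs(df$f_FL_kmc - df$f_FL_preeq) > flag_threshold
  structure(df, class = c("force_profile", class(df)),
            bell = bell, t_incubation = t)
}

#' Root-mean-square difference between force profiles
#'
#' @param predicted tibble with `L` and a predicted `f_FL` column (first of
#'   `f_FL_kmc`, `f_FL_preeq`, `f_FL` present is used, or set `column`).
#' @param experimental tibble with columns `L` and `f_FL`.
#' @param column predicted column to compare.
#' @return RMSD over the shared L values.
#' @export
profile_rmsd <- function(predicted, experimental,
                         column = intersect(c("f_FL_kmc", "f_FL_preeq", "f_FL"),
                                            names(predicted))[1]) {
  if (is.na(column)) abort("no f_FL column found in predicted profile")
  shared <- intersect(predicted$L, experimental$L)
  if (length(shared) < 1) abort("profiles share no linker lengths")
  p <- predicted[[column]][match(shared, predicted$L)]
  e <- experimental$f_FL[match(shared, experimental$L)]
  sqrt(mean((p - e)^2))
}

#' Read an experimental force profile table
#'
#' Two-column TSV (`L`, `f_FL`).
#'
#' @param path TSV path.
#' @return tibble (`L`, `f_FL`).
#' @export
read_force_profile_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("L", "f_FL") %in% names(df))) {
    abort("expected columns 'L' and 'f_FL'")
  }
  if (any(df$f_FL < 0 | df$f_FL > 1, na.rm = TRUE)) {
    abort("f_FL values must lie in [0, 1]")
  }
  df
}

#' Export a force profile as TSV
#'
#' @param profile a `force_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_force_profile_tsv <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}
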