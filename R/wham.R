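# WHAM reweighting of umbrella windows into free-energy profiles, state
# populations and state-conditioned mean tether forces.

new_free_energy_profile <- function(df, temperature) {
  structure(as_tibble(df), class = c("free_energy_profile",
                                     class(as_tibble(df))),
            temperature = temperature)
}

#' Weighted-histogram (WHAM) reweighting of umbrella windows
#'
#' Solves the self-consistent WHAM equations on a uniform Q grid and
#' returns the unbiased free-energy profile G(Q) (kJ/mol, shifted so
#' min G = 0) plus an unbiased weight per sample, normalized over the
#' pooled samples. With a single unbiased window this reduces to
#' `G = -kB T log(histogram)`.
#'
#' @param windows an `umbrella_set` from [run_umbrella()], or a bare list of
#'   `list(q0, k_umb, samples)` windows (then `temperature` is required).
#' @param n_bins number of uniform Q bins (default 50).
#' @param tolerance convergence threshold on window free energies, kJ/mol.
#' @param max_iter maximum WHAM iterations.
#' @param temperature K (taken from the umbrella set when available).
#' @return a `free_energy_profile` tibble (`Q`, `G`, `p`) with attributes
#'   `samples` (pooled samples with a `weight` column) and `f_windows`
#'   (converged window free energies).
#' @export
wham <- function(windows, n_bins = 50, tolerance = 1e-7, max_iter = 10000,
                 temperature = NULL) {
  if (inherits(windows, "umbrella_set")) {
    temperature <- temperature %||% windows$metadata$temperature
    windows <- windows$windows
  }
  if (is.null(temperature)) abort("temperature must be supplied")
  if (length(windows) < 1) abort("need at least one umbrella window")
  kT <- .kB * temperature
  beta <- 1 / kT

  pooled <- dplyr::bind_rows(lapply(seq_along(windows), function(w) {
    s <- windows[[w]]$samples
    s$window <- w
    s
  }))
  W <- length(windows)
  Nw <- vapply(windows, function(w) nrow(w$samples), numeric(1))
  edges <- seq(0, 1, length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  bin <- findInterval(pooled$Q, edges, all.inside = TRUE)
  counts <- tabulate(bin, n_bins)

  # windows must form one connected component through shared bins,
  # otherwise their free energies cannot be stitched together
  occ <- vapply(seq_len(W), function(w) {
    tabulate(bin[pooled$window == w], n_bins) > 0
  }, logical(n_bins))
  comp <- rep(0L, W)
  comp[1] <- 1L
  repeat {
    grown <- FALSE
    for (w in which(comp == 0L)) {
      linked <- vapply(which(comp == 1L), function(v) {
        any(occ[, w] & occ[, v])
      }, logical(1))
      if (any(linked)) {
        comp[w] <- 1L
        grown <- TRUE
      }
    }
    if (!grown) break
  }
  if (any(comp == 0L)) {
    ov <- paste(sprintf("window %d (Q0 ~ %.2f): Q in [%.2f, %.2f]",
                        seq_len(W),
                        vapply(windows, `[[`, numeric(1), "q0"),
                        vapply(seq_len(W), function(w)
                          min(pooled$Q[pooled$window == w]), numeric(1)),
                        vapply(seq_len(W), function(w)
                          max(pooled$Q[pooled$window == w]), numeric(1))),
                collapse = "; ")
    abort(paste0("umbrella windows do not overlap (",
                 sum(comp == 0L), " window(s) share no Q bins with the rest); ",
                 "WHAM cannot stitch their free energies. ", ov))
  }

  # bias energy of window w evaluated at each bin center
  Vwb <- vapply(windows, function(w) 0.5 * w$k_umb * (mids - w$q0)^2,
                numeric(n_bins)) # n_bins x W
  f <- rep(0, W)
  for (it in seq_len(max_iter)) {
    denom <- rowSums(sweep(exp(-beta * sweep(Vwb, 2, f)), 2, Nw, `*`))
    p <- counts / denom
    p[counts == 0] <- 0
    psum <- sum(p)
    fnew <- -kT * log(colSums(p * exp(-beta * Vwb)) / psum)
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tolerance) break
  }
  if (delta >= tolerance) {
    ov <- paste(sprintf("window %d (Q0 ~ %.2f): n = %d", seq_len(W),
                        vapply(windows, `[[`, numeric(1), "q0"), as.integer(Nw)),
                collapse = "; ")
    abort(paste0("WHAM failed to converge in ", max_iter,
                 " iterations (last change ", signif(delta, 3),
                 " kJ/mol). Window overlap diagnostics: ", ov))
  }
  p <- p / sum(p)
  G <- ifelse(p > 0, -kT * log(p), NA_real_)
  G <- G - min(G, na.rm = TRUE)

  # per-sample unbiased weights (binless denominator at each sample's Q)
  Vws <- vapply(windows, function(w) 0.5 * w$k_umb * (pooled$Q - w$q0)^2,
                numeric(nrow(pooled)))
  denom_s <- rowSums(sweep(exp(-beta * sweep(Vws, 2, f)), 2, Nw, `*`))
  pooled$weight <- (1 / denom_s) / sum(1 / denom_s)

  out <- new_free_energy_profile(tibble(Q = mids, G = G, p = p), temperature)
  attr(out, "samples") <- pooled
  attr(out, "f_windows") <- f
  out
}

#' Split reweighted samples into unfolded and folded populations
#'
#' @param samples tibble with columns `Q` and `weight` (e.g. the `samples`
#'   attribute of a [wham()] profile).
#' @param boundary folded/unfolded boundary on Q (default 0.5).
#' @return named numeric vector `c(P_u, P_f)` summing to exactly 1.
#' @export
state_split <- function(samples, boundary = 0.5) {
  w <- samples$weight / sum(samples$weight)
  pf <- sum(w[samples$Q > boundary])
  if (pf == 0 || pf == 1) {
    warn(sprintf("all reweighted mass on one side of Q = %g (degenerate state split)",
                 boundary))
  }
  c(P_u = 1 - pf, P_f = pf)
}

#' State-conditioned mean tether forces
#'
#' Weighted mean pulling force within the unfolded (Q <= boundary) and
#' folded (Q > boundary) states. When the samples carry the tether force
#' vector (`F_x`, `F_y`, `F_z`), the magnitude of the weighted mean vector
#' is reported: the instantaneous scalar `ks (x - x0)` carries a radial
#' shell-entropy bias of about `2 kT / x` that averages out of the vector
#' mean when the chain is slack, so the vector estimator measures the
#' transmitted chain tension. Falls back to the scalar mean when only
#' `F_pN` is present. An unpopulated state yields `NA` with a warning;
#' downstream kinetics must then carry it with population weight zero.
#'
#' @param samples tibble with columns `Q`, `weight` and either
#'   `F_x`/`F_y`/`F_z` or `F_pN`.
#' @param boundary folded/unfolded boundary on Q.
#' @return named numeric vector `c(F_u, F_f)` in pN.
#' @export
mean_state_forces <- function(samples, boundary = 0.5) {
  fold <- samples$Q > boundary
  vec <- all(c("F_x", "F_y", "F_z") %in% names(samples))
  avg <- function(sel) {
    if (!any(sel)) return(NA_real_)
    w <- samples$weight[sel] / sum(samples$weight[sel])
    if (vec) {
      sqrt(sum(w * samples$F_x[sel])^2 + sum(w * samples$F_y[sel])^2 +
             sum(w * samples$F_z[sel])^2)
    } else {
      sum(samples$F_pN[sel] * w)
    }
  }
  out <- c(F_u = avg(!fold), F_f = avg(fold))
  if (anyNA(out)) {
    warn("a state has no samples; its mean force is undefined (NA)")
  }
  out
}

#' Equilibrium summary across linker lengths
#'
#' Runs WHAM on one umbrella set per linker length L and tabulates the
#' folded/unfolded populations and state-conditioned mean tether forces.
#'
#' @param umbrella_sets named or unnamed list of `umbrella_set` objects;
#'   linker lengths are taken from each set's metadata (or from `L`).
#' @param L optional integer vector of linker lengths overriding metadata.
#' @param boundary folded/unfolded boundary on Q.
#' @param ... passed to [wham()].
#' @return an `equilibrium_summary` tibble
#'   (`L`, `P_u`, `P_f`, `F_u_pN`, `F_f_pN`) with the per-L
#'   `free_energy_profile`s in the `profiles` attribute.
#' @export
summarize_per_L <- function(umbrella_sets, L = NULL, boundary = 0.5, ...) {
  if (is.null(L)) {
    L <- vapply(umbrella_sets, function(u) u$metadata$linker_length, numeric(1))
  }
  profiles <- vector("list", length(umbrella_sets))
  rows <- vector("list", length(umbrella_sets))
  for (k in seq_along(umbrella_sets)) {
    prof <- wham(umbrella_sets[[k]], ...)
    s <- attr(prof, "samples")
    pp <- state_split(s, boundary)
    ff <- suppressWarnings(mean_state_forces(s, boundary))
    profiles[[k]] <- prof
    rows[[k]] <- tibble(L = L[k], P_u = pp[["P_u"]], P_f = pp[["P_f"]],
                        F_u_pN = ff[["F_u"]], F_f_pN = ff[["F_f"]])
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$L), ]
  structure(out, class = c("equilibrium_summary", class(out)),
            profiles = profiles[order(L)], boundary = boundary)
}

#' Export an equilibrium summary as TSV
#'
#' @param summary an `equilibrium_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_equilibrium_tsv <- function(summary, path) {
  readr::write_tsv(as_tibble(summary), path)
  invisible(path)
}
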