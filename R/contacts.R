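# Native contact maps and the excluded-volume mixing rules.

new_contact_map <- function(df, criterion, min_sep) {
  df <- as_tibble(df)
  stopifnot(all(c("i", "j", "r0", "eps") %in% names(df)))
  if (any(df$i >= df$j)) abort("contact map requires i < j")
  if (any(df$r0 <= 0)) abort("contact distances must be positive")
  structure(df, class = c("contact_map", class(df)),
            criterion = criterion, min_sep = min_sep)
}

#' Build a native contact map from a structure
#'
#' Residue pairs are in native contact when any two heavy atoms are closer
#' than `heavy_atom_cutoff` and the sequence separation is at least
#' `min_separation`. The stored contact distance `r0` is the native
#' Calpha-Calpha distance (nm). When the input carries no side-chain heavy
#' atoms (e.g. a Calpha-only `bead_model`), a Calpha-distance criterion with
#' cutoff `ca_cutoff` is used instead and flagged in the output.
#'
#' @param structure an `atomic_structure` (Angstrom) or Calpha-only
#'   `bead_model` (nm).
#' @param heavy_atom_cutoff all-heavy-atom contact criterion, nm
#'   (default 0.45, i.e. 4.5 Angstrom).
#' @param min_separation minimum |i - j| (default 4).
#' @param ca_cutoff fallback Calpha-Calpha cutoff, nm.
#' @param eps uniform contact strength epsilon_c assigned to each pair,
#'   kJ/mol.
#' @return a `contact_map` tibble (`i`, `j`, `r0`, `eps`) with attributes
#'   `criterion` ("heavy-atom" or "ca-fallback") and `min_sep`.
#' @export
contact_map_from_structure <- function(structure, heavy_atom_cutoff = 0.45,
                                       min_separation = 4, ca_cutoff = 0.65,
                                       eps = 3.2) {
  if (inherits(structure, "bead_model")) {
    ca <- structure[structure$kind == "protein-CA", , drop = FALSE]
    pos <- as.matrix(ca[, c("x", "y", "z")])
    resid <- ca$resid
    heavy <- NULL
  } else {
    st <- structure[!structure$hetero & structure$element != "H", , drop = FALSE]
    ca <- st[st$atom == "CA", , drop = FALSE]
    pos <- as.matrix(ca[, c("x", "y", "z")]) / 10
    resid <- ca$resid
    has_side <- nrow(st) > 1.5 * nrow(ca) # more than backbone-only content
    heavy <- if (has_side) st else NULL
  }
  n <- length(resid)
  if (n < 2) abort("structure has fewer than two residues with coordinates")
  use_fallback <- is.null(heavy)
  if (use_fallback && !inherits(structure, "bead_model")) {
    warn("structure lacks side-chain heavy atoms; using Calpha-distance contact criterion")
  }
  out <- list()
  if (use_fallback) {
    dm <- as.matrix(stats::dist(pos))
    for (a in seq_len(n - 1)) {
      for (b in seq((a + 1), n)) {
        if (abs(resid[b] - resid[a]) < min_separation) next
        if (dm[a, b] < ca_cutoff) {
          out[[length(out) + 1]] <- tibble(i = resid[a], j = resid[b],
                                           r0 = dm[a, b])
        }
      }
    }
    criterion <- "ca-fallback"
  } else {
    hx <- as.matrix(heavy[, c("x", "y", "z")]) / 10
    hres <- heavy$resid
    split_idx <- split(seq_len(nrow(heavy)), hres)
    resids <- as.integer(names(split_idx))
    capos <- pos[match(resids, resid), , drop = FALSE]
    nn <- length(resids)
    for (a in seq_len(nn - 1)) {
      for (b in seq((a + 1), nn)) {
        if (abs(resids[b] - resids[a]) < min_separation) next
        da <- hx[split_idx[[a]], , drop = FALSE]
        db <- hx[split_idx[[b]], , drop = FALSE]
        # minimum heavy-atom pair distance between the two residues
        d2 <- outer(rowSums(da^2), rowSums(db^2), "+") - 2 * da %*% t(db)
        if (min(d2) < heavy_atom_cutoff^2) {
          r0 <- sqrt(sum((capos[a, ] - capos[b, ])^2))
          out[[length(out) + 1]] <- tibble(i = resids[a], j = resids[b], r0 = r0)
        }
      }
    }
    criterion <- "heavy-atom"
  }
  df <- if (length(out) > 0) dplyr::bind_rows(out) else
    tibble(i = integer(), j = integer(), r0 = numeric())
  df$eps <- rep(eps, nrow(df))
  new_contact_map(df, criterion = criterion, min_sep = min_separation)
}

#' Excluded-volume coefficients for a bead pair
#'
#' Coefficients (A, B, C) of the repulsive pair potential
#' `V(r) = eps * (A r^-12 - B r^-10 + C r^-6)` from the per-bead radii. The
#' effective contact distance is the arithmetic mean
#' `sigma_ij = (sigma_i + sigma_j) / 2`. The default rule (`"r12"`) keeps
#' only the r^-12 term, giving a strictly positive, monotonically repulsive
#' potential that is negligible beyond ~1.5 sigma_ij; `"mixed12106"` fills
#' in the 12-10-6 polynomial coefficients (sigma^12, 2 sigma^10, sigma^6),
#' which adds a physically irrelevant sub-milli-kT well just inside
#' sigma_ij (see the methods vignette for why "r12" is the default).
#'
#' @param sigma_i,sigma_j bead radii (nm), both positive.
#' @param rule mixing rule, `"r12"` (default) or `"mixed12106"`.
#' @return named numeric vector `A`, `B`, `C`, `sigma_eff`.
#' @export
repulsion_coefficients <- function(sigma_i, sigma_j,
                                   rule = c("r12", "mixed12106")) {
  rule <- match.arg(rule)
  if (any(sigma_i <= 0) || any(sigma_j <= 0)) {
    abort("bead radii must be positive")
  }
  s <- (sigma_i + sigma_j) / 2
  if (rule == "r12") {
    c(A = s^12, B = 0, C = 0, sigma_eff = s)
  } else {
    c(A = s^12, B = 2 * s^10, C = s^6, sigma_eff = s)
  }
}

#' Evaluate the repulsive pair potential
#'
#' @param r distance(s), nm.
#' @param coef coefficients from [repulsion_coefficients()].
#' @param eps interaction strength, kJ/mol.
#' @return potential energy, kJ/mol.
#' @export
repulsion_energy <- function(r, coef, eps = 0.001) {
  eps * (coef[["A"]] / r^12 - coef[["B"]] / r^10 + coef[["C"]] / r^6)
}
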