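# Synthetic fixtures: a desk-scale foldable bead chain, a toy exit tunnel,
# and labelled trajectory ensembles with known transition-path statistics.
# These stand in for a real protein domain and the large ribosomal subunit
# so every downstream stage can be exercised without structure downloads.

#' Generate a toy foldable bead chain with a defined native contact map
#'
#' Builds a compact two-state-foldable native geometry -- an antiparallel
#' beta-hairpin-like ladder or a pair of packed helices -- plus its native
#' contact map (all bead pairs closer than `contact_cutoff` with sequence
#' separation of at least `min_seq_sep`). A small seeded jitter breaks the
#' planarity of the ideal geometry. Contact strengths are uniform; the
#' default is calibrated so the resulting structure-based model is two-state
#' at 291 K (see the methods vignette).
#'
#' @param n_residues chain length (>= 10; default 16).
#' @param fold `"hairpin"` (16+ beads, thin), `"sheet"` (four- to
#'   six-strand flat meander), `"sandwich"` (two stacked sheets, globular;
#'   the fixture used for tethered linker-length families) or
#'   `"helix-pair"`.
#' @param contact_energy uniform native-contact well depth, kJ/mol
#'   (default 3.2, calibrated so the 16-bead hairpin exchanges between a
#'   bimodally separated folded and unfolded basin at 291 K).
#' @param seed integer seed (geometry jitter).
#' @param contact_cutoff Calpha contact criterion for the ground-truth map
#'   (nm); defaults to `strand_sep + 0.17` so ladder and diagonal pairs
#'   qualify.
#' @param strand_sep distance between paired strands (nm, hairpin/sheet
#'   folds). Wider hairpins (e.g. 0.8) are transversally too large to fold
#'   inside a tunnel that still threads a single chain freely.
#' @param min_seq_sep minimum |i - j| for a native contact.
#' @return list with elements `beads` (a `bead_model`), `contacts`
#'   (a `contact_map`), `fold`, and `seed`.
#' @export
make_toy_protein <- function(n_residues = 16,
                             fold = c("hairpin", "sheet", "sandwich", "helix-pair"),
                             contact_energy = 3.2, seed = 1,
                             contact_cutoff = NULL, strand_sep = 0.5,
                             min_seq_sep = 4) {
  contact_cutoff <- contact_cutoff %||% (strand_sep + 0.17)
  fold <- match.arg(fold)
  if (n_residues < 10) abort("n_residues must be >= 10")
  m <- n_residues %/% 2
  if (fold == "sandwich") {
    # two stacked four-strand antiparallel sheets (a beta-sandwich):
    # contacts run in two orthogonal directions, so the compact state can
    # neither flatten nor roll up -- it is globular, like a real Ig domain,
    # and cannot enter a tunnel a single chain threads freely
    rise <- 0.334
    zig <- 0.07
    sep <- 0.5
    gap <- 0.55
    ns <- 8L
    per <- n_residues %/% ns
    lens <- rep(per, ns)
    lens[ns] <- lens[ns] + n_residues - sum(lens)
    rows <- list()
    for (s in seq_len(ns)) {
      i <- seq_len(lens[s])
      zdir <- if (s %% 2 == 1) (i - 1) else (lens[s] - i)
      xs <- if (s <= 4) (s - 1) * sep else (8 - s) * sep
      ys <- if (s <= 4) 0 else gap
      rows[[s]] <- cbind(xs, ys + zig * ((i + s) %% 2), zdir * rise)
    }
    pos <- do.call(rbind, rows)
  } else if (fold == "sheet") {
    # four-strand antiparallel meander: cooperative like the hairpin but
    # transversally wide (~1.5 nm), so a tunnel that a single chain threads
    # freely still cannot accommodate the folded state
    rise <- 0.334
    zig <- 0.09
    sep <- 0.5
    ns <- if (n_residues >= 24) 6L else 4L
    per <- n_residues %/% ns
    lens <- rep(per, ns)
    lens[ns] <- lens[ns] + n_residues - sum(lens)
    rows <- list()
    for (s in seq_len(ns)) {
      i <- seq_len(lens[s])
      zdir <- if (s %% 2 == 1) (i - 1) else (lens[s] - i)
      rows[[s]] <- cbind((s - 1) * sep, zig * ((i + s) %% 2), zdir * rise)
    }
    pos <- do.call(rbind, rows)
  } else if (fold == "hairpin") {
    # two extended antiparallel strands, 0.5 nm apart, with a beta-like
    # Calpha zig-zag so that angle/dihedral terms are non-degenerate
    rise <- 0.334
    zig <- 0.09
    sep <- strand_sep
    i1 <- seq_len(m)
    i2 <- seq_len(n_residues - m)
    pos <- rbind(
      cbind(zig * (i1 %% 2), 0, (i1 - 1) * rise),
      cbind(sep + zig * ((i2 + 1) %% 2), 0, (m - i2) * rise))
  } else {
    # two packed antiparallel helices
    rise <- 0.15
    rad <- 0.23
    dtheta <- 100 * pi / 180
    i1 <- seq_len(m)
    i2 <- seq_len(n_residues - m)
    h1 <- cbind(rad * cos(i1 * dtheta), rad * sin(i1 * dtheta), (i1 - 1) * rise)
    h2 <- cbind(0.95 + rad * cos(-i2 * dtheta), rad * sin(-i2 * dtheta),
                (length(i2) - i2) * rise)
    pos <- rbind(h1, h2)
  }
  set.seed(seed)
  pos <- pos + matrix(rnorm(length(pos), sd = 0.015), ncol = 3)
  beads <- new_bead_model(tibble(
    bead = seq_len(n_residues), kind = "protein-CA",
    resid = seq_len(n_residues), resname = "TOY", chain = "A",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    sigma = unname(bead_radii()["protein-CA"]), mobile = TRUE))
  contacts <- contact_map_from_structure(beads, min_separation = min_seq_sep,
                                         ca_cutoff = contact_cutoff,
                                         eps = contact_energy)
  list(beads = beads, contacts = contacts, fold = fold, seed = seed)
}

#' Generate a toy exit-tunnel scaffold
#'
#' A cylindrical wall of immobile repulsive beads, closed by a disc at the
#' buried end and open at the exit, with a non-interacting anchor bead on
#' the axis at the buried end standing in for the last P atom of the A-site
#' tRNA. A short, narrower collar of wall beads surrounds the anchor,
#' mimicking the tight channel at the peptidyl-transferase center: it
#' restricts the transverse excursions of the tethered chain end so the
#' reported tether force measures chain tension rather than the radial
#' shell entropy of a free 3D spring (which alone would read
#' 2 kT / x0 ~ 21 pN). The overall geometry mimics the ~10 nm long
#' ribosomal exit tunnel.
#'
#' @param length tunnel length (nm).
#' @param radius tunnel radius (nm).
#' @param bead_spacing spacing of wall beads (nm).
#' @param constriction_radius radius of the collar around the anchor (nm);
#'   wide enough for a single chain to thread cheaply, narrow enough to
#'   suppress the shell-entropy force baseline.
#' @param constriction_length axial extent of the collar (nm).
#' @return a `ribosome_scaffold`; its tunnel annotation runs from the buried
#'   end (`axis_start`, anchor) to the open exit (`axis_end`).
#' @export
make_toy_tunnel <- function(length = 10, radius = 0.75, bead_spacing = 0.45,
                            constriction_radius = 0.9,
                            constriction_length = 0.9) {
  if (length <= 0 || radius <= 0 || bead_spacing <= 0) {
    abort("length, radius and bead_spacing must all be positive")
  }
  rows <- list()
  add <- function(kind, x, y, z) {
    rows[[base::length(rows) + 1]] <<- tibble(kind = kind, x = x, y = y, z = z)
  }
  # cylindrical wall, rings along +z
  n_ring <- max(6L, ceiling(2 * pi * radius / bead_spacing))
  for (z in seq(0, length, by = bead_spacing)) {
    th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring +
      (z / bead_spacing) * pi / n_ring # stagger adjacent rings
    add("wall", radius * cos(th), radius * sin(th), rep(z, n_ring))
  }
  # PTC-like pocket around the anchor: a collar extending below the tunnel
  # floor, sealed by a bottom disc, so the chain can only leave upward
  sp2 <- bead_spacing / 1.5
  n_c <- max(6L, ceiling(2 * pi * constriction_radius / sp2))
  for (z in seq(-0.6, constriction_length, by = sp2)) {
    th <- 2 * pi * (seq_len(n_c) - 1) / n_c + z
    add("cap", constriction_radius * cos(th), constriction_radius * sin(th),
        rep(z, n_c))
  }
  for (r in seq(sp2, constriction_radius, by = sp2)) { # bottom disc
    n_d <- max(4L, ceiling(2 * pi * r / sp2))
    th <- 2 * pi * (seq_len(n_d) - 1) / n_d
    add("cap", r * cos(th), r * sin(th), rep(-0.6, n_d))
  }
  # annulus joining collar and tunnel wall at the floor
  rr <- if (radius - bead_spacing / 2 > constriction_radius) {
    seq(constriction_radius, radius - bead_spacing / 2, by = sp2)
  } else numeric(0)
  for (r in rr) {
    n_d <- max(4L, ceiling(2 * pi * r / bead_spacing))
    th <- 2 * pi * (seq_len(n_d) - 1) / n_d
    add("cap", r * cos(th), r * sin(th), rep(0, n_d))
  }
  add("anchor", 0, 0, 0)
  df <- dplyr::bind_rows(rows)
  beads <- new_bead_model(tibble(
    bead = seq_len(nrow(df)), kind = df$kind, resid = seq_len(nrow(df)),
    resname = "TUN", chain = "R", x = df$x, y = df$y, z = df$z,
    sigma = unname(bead_radii()[df$kind]), mobile = FALSE))
  new_ribosome_scaffold(
    beads, anchor = beads$bead[beads$kind == "anchor"][1],
    tunnel = list(axis_start = c(0, 0, 0), axis_end = c(0, 0, length),
                  exit = c(0, 0, length), radius = radius,
                  length = length, bead_spacing = bead_spacing))
}

#' Specification for a synthetic labelled trajectory ensemble
#'
#' Defines the ground truth for a discrete frame ensemble: per-contact
#' formation probabilities on transition paths (TPs) and in nonnative
#' non-TP (unfolded) frames, the target fraction of nonnative frames on TPs,
#' and the segment structure. Contacts `k` connect pseudo-residues
#' `(k, k + 5)` of a notional chain, so per-residue phi-values have known
#' analytic values.
#'
#' @param n_contacts number of native contacts.
#' @param p_q_tp numeric vector (recycled) of per-contact formation
#'   probabilities on TPs.
#' @param p_q_u per-contact formation probabilities in unfolded (nonnative
#'   non-TP) frames.
#' @param p_tp_nn target fraction of nonnative frames on TPs.
#' @param n_frames total number of nonnative frames.
#' @param seg_len_tp length of each TP segment (frames).
#' @param n_folded number of folded frames appended (all contacts formed).
#' @param seed integer seed.
#' @return object of class `synthetic_tp_spec`.
#' @export
synthetic_tp_spec <- function(n_contacts, p_q_tp, p_q_u, p_tp_nn,
                              n_frames = 1e4, seg_len_tp = 20,
                              n_folded = 0, seed = 1) {
  p_q_tp <- rep_len(p_q_tp, n_contacts)
  p_q_u <- rep_len(p_q_u, n_contacts)
  if (any(p_q_tp < 0 | p_q_tp > 1) || any(p_q_u < 0 | p_q_u > 1) ||
      p_tp_nn < 0 || p_tp_nn > 1) {
    abort("all probabilities must lie in [0, 1]")
  }
  structure(list(n_contacts = n_contacts, p_q_tp = p_q_tp, p_q_u = p_q_u,
                 p_tp_nn = p_tp_nn, n_frames = as.integer(n_frames),
                 seg_len_tp = as.integer(seg_len_tp),
                 n_folded = as.integer(n_folded), seed = as.integer(seed)),
            class = "synthetic_tp_spec")
}

#' Generate a labelled trajectory ensemble from a synthetic specification
#'
#' Emits frames labelled `TP` / `unfolded` / `folded` with per-contact
#' binary formation states drawn independently from the spec's
#' probabilities. The number of TP frames is fixed (not sampled) so the
#' realized `p(TP)_nn` equals the spec up to segment-length rounding. The
#' ground-truth analytic values of every downstream estimator are attached
#' as the `truth` element.
#'
#' @param spec a [synthetic_tp_spec()].
#' @return a `tp_ensemble` (see [tp_ensemble()]) whose `truth` element holds
#'   `p_q_tp`, `p_q_nn`, `p_tp_given_q`, `p_tp_nn`, and per-residue `phi`.
#' @export
make_synthetic_tp_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_tp_spec"))
  set.seed(spec$seed)
  nc <- spec$n_contacts
  n_tp <- round(spec$p_tp_nn * spec$n_frames)
  n_u <- spec$n_frames - n_tp
  n_seg <- max(1L, n_tp %/% spec$seg_len_tp)
  labels <- c(rep("unfolded", n_u), rep("TP", n_tp))
  # interleave TP segments into the unfolded background
  seg_id <- integer(spec$n_frames)
  ord <- integer(0)
  u_per_gap <- n_u %/% (n_seg + 1)
  tp_lens <- rep(n_tp %/% n_seg, n_seg)
  if (n_seg > 0 && n_tp %% n_seg > 0) {
    tp_lens[seq_len(n_tp %% n_seg)] <- tp_lens[seq_len(n_tp %% n_seg)] + 1
  }
  lab <- character(0)
  seg <- integer(0)
  u_left <- n_u
  for (s in seq_len(n_seg)) {
    take <- min(u_per_gap, u_left)
    lab <- c(lab, rep("unfolded", take), rep("TP", tp_lens[s]))
    seg <- c(seg, rep(0L, take), rep(s, tp_lens[s]))
    u_left <- u_left - take
  }
  lab <- c(lab, rep("unfolded", u_left))
  seg <- c(seg, rep(0L, u_left))

  n_all <- length(lab) + spec$n_folded
  states <- matrix(0L, nrow = n_all, ncol = nc)
  is_tp <- lab == "TP"
  for (k in seq_len(nc)) {
    p <- ifelse(is_tp, spec$p_q_tp[k], spec$p_q_u[k])
    states[seq_along(lab), k] <- as.integer(runif(length(lab)) < p)
  }
  qv <- ifelse(is_tp, runif(length(lab), 0.31, 0.69),
               runif(length(lab), 0.05, 0.29))
  if (spec$n_folded > 0) {
    idx <- length(lab) + seq_len(spec$n_folded)
    states[idx, ] <- 1L
    lab <- c(lab, rep("folded", spec$n_folded))
    seg <- c(seg, rep(0L, spec$n_folded))
    qv <- c(qv, runif(spec$n_folded, 0.9, 0.99))
  }
  contacts <- tibble(i = seq_len(nc), j = seq_len(nc) + 5L,
                     r0 = 0.5, eps = 1)
  truth_p_q_nn <- spec$p_tp_nn * spec$p_q_tp + (1 - spec$p_tp_nn) * spec$p_q_u
  truth_ptpq <- ifelse(truth_p_q_nn > 0,
                       pmin(1, spec$p_q_tp * spec$p_tp_nn / truth_p_q_nn), NA)
  residues <- sort(unique(c(contacts$i, contacts$j)))
  phi <- vapply(residues, function(r) {
    ks <- which(contacts$i == r | contacts$j == r)
    mean(spec$p_q_tp[ks])
  }, numeric(1))
  tp_ensemble(
    frames = tibble(frame = seq_len(n_all), label = lab, segment = seg, Q = qv),
    states = states, contacts = contacts, direction = "folding",
    t_tp = spec$seg_len_tp,
    provenance = list(generator = "synthetic", spec = spec),
    truth = list(p_q_tp = spec$p_q_tp, p_q_u = spec$p_q_u,
                 p_q_nn = truth_p_q_nn, p_tp_given_q = truth_ptpq,
                 p_tp_nn = spec$p_tp_nn,
                 phi = tibble(residue = residues, phi = phi)))
}
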