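# Assembly of the simulatable coarse-grained system: structure-based
# intraprotein potential, excluded-volume interactions with the ribosome
# scaffold and linker, mutant perturbations, and the force-reporting tether.

# linker region of the longest (L = 63) experimental construct; shorter
# linkers take its C-terminal L residues (constructs were extended from the
# C toward the N terminus). Used for sequence bookkeeping only: linker beads
# are featureless repulsive beads.
.linker63 <- "ELSGSGKFAYGIKDPIYQKTLVPGQQNATWIVPPGQYFMMGDWMSSFSTPVWISQAQGIRAGP"

#' Default model parameters
#'
#' All tunable constants of the coarse-grained model in one place.
#' Energies kJ/mol, lengths nm, temperatures K.
#'
#' @param eps_repulsive strength of the soft protein-ribosome and linker
#'   repulsion (kJ/mol).
#' @param eps_protein intraprotein nonnative excluded-volume strength.
#' @param eps_wall toy-tunnel wall repulsion strength against the folded
#'   domain (a sparse single-shell bead wall needs a harder interaction than
#'   the densely packed ribosome surface to exclude a compact domain
#'   crisply).
#' @param eps_wall_linker wall repulsion strength against linker beads; kept
#'   soft so a single threading chain is only mildly confined (low
#'   background tension) while the folded domain is excluded.
#' @param ks tether spring constant (kJ mol^-1 nm^-2).
#' @param x0 tether rest length (nm), the approximate Calpha-Calpha spacing.
#' @param sigma_hp,eps_hp Lennard-Jones range (nm) and strength (kJ/mol) of
#'   optional hydrophobic ribosome-surface attractions.
#' @param weaken_factor default fraction by which mutant contact strengths
#'   are weakened.
#' @param contact_cutoff heavy-atom native-contact criterion (nm).
#' @param min_seq_sep minimum contact sequence separation.
#' @param q_gamma,q_lambda switching steepness (nm^-1) and width factor of
#'   the fraction-of-native-contacts coordinate Q.
#' @param angle_k harmonic angle constant (kJ mol^-1 rad^-2).
#' @param dihedral_contact_ratio native-contact : dihedral energy share
#'   (contacts carry this multiple of the total dihedral strength).
#' @param temperature simulation temperature (K).
#' @param mixing_rule excluded-volume mixing rule, see
#'   [repulsion_coefficients()].
#' @param cutoff nonbonded cutoff (nm); the soft r^-12 repulsion is
#'   far below thermal energy beyond ~1 nm.
#' @param mass bead mass (uniform; time is an internal unit, rates are
#'   rescaled to seconds downstream).
#' @return a named list of class `cg_params`.
#' @export
cg_params <- function(eps_repulsive = 0.001, eps_protein = 1, eps_wall = 100,
                      eps_wall_linker = 0.02,
                      ks = 3000, x0 = 0.38, sigma_hp = 0.6, eps_hp = 5,
                      weaken_factor = 0.4, contact_cutoff = 0.45,
                      min_seq_sep = 4, q_gamma = 50, q_lambda = 1.2,
                      angle_k = 40, dihedral_contact_ratio = 2,
                      temperature = 291, mixing_rule = "r12", cutoff = 0.9,
                      mass = 1) {
  structure(as.list(environment()), class = "cg_params")
}

.group_eps_matrix <- function(params) {
  g <- c("P", "L", "S", "W", "C", "A")
  m <- matrix(0, 6, 6, dimnames = list(g, g))
  m["P", "P"] <- params$eps_protein
  m["P", "L"] <- m["L", "P"] <- params$eps_repulsive
  m["L", "L"] <- params$eps_repulsive
  m["P", "S"] <- m["S", "P"] <- params$eps_repulsive
  m["L", "S"] <- m["S", "L"] <- params$eps_repulsive
  m["P", "W"] <- m["W", "P"] <- params$eps_wall
  m["L", "W"] <- m["W", "L"] <- params$eps_wall_linker
  # the PTC pocket ("cap" beads) excludes the domain like the tunnel wall
  # but stays soft for the threading chain
  m["P", "C"] <- m["C", "P"] <- params$eps_wall
  m["L", "C"] <- m["C", "L"] <- params$eps_wall_linker
  m # anchor group "A" and scaffold-scaffold stay at 0
}

.angle_between <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(ct, -1), 1))
}

.dihedral_between <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m1 * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

#' Build a simulatable structure-based (Go) system
#'
#' Assembles the full potential from a mobile protein bead model and its
#' native contact map: constrained pseudo-bonds along the chain, harmonic
#' angles and periodic dihedrals at their native values, attractive 12-10
#' wells at each native contact, and soft excluded-volume repulsion for all
#' remaining pairs (and against the scaffold, when given). Contact strengths
#' are taken from the map; the total dihedral strength is set to
#' 1/`dihedral_contact_ratio` of the total contact energy, split evenly.
#'
#' @param beads mobile `bead_model` of the protein domain.
#' @param contacts `contact_map` whose `i`, `j` are residue indices of
#'   `beads`.
#' @param scaffold optional `ribosome_scaffold`.
#' @param params a [cg_params()] list.
#' @return an object of class `cg_system`.
#' @export
build_go_system <- function(beads, contacts, scaffold = NULL,
                            params = cg_params()) {
  stopifnot(inherits(beads, "bead_model"))
  n <- nrow(beads)
  if (!all(beads$mobile)) abort("domain beads must all be mobile")
  ci <- match(contacts$i, beads$resid)
  cj <- match(contacts$j, beads$resid)
  if (anyNA(ci) || anyNA(cj)) {
    abort("contact map references residues absent from the bead model")
  }
  pos <- as.matrix(beads[, c("x", "y", "z")])
  bonds <- tibble(
    i = seq_len(n - 1), j = seq_len(n - 1) + 1L,
    r0 = sqrt(rowSums((pos[-n, , drop = FALSE] - pos[-1, , drop = FALSE])^2)),
    k = 0, constrained = TRUE)
  angles <- if (n >= 3) {
    idx <- seq_len(n - 2)
    tibble(i = idx, j = idx + 1L, k = idx + 2L,
           theta0 = vapply(idx, function(q)
             .angle_between(pos[q, ], pos[q + 1, ], pos[q + 2, ]), numeric(1)),
           kf = params$angle_k)
  } else tibble(i = integer(), j = integer(), k = integer(),
                theta0 = numeric(), kf = numeric())
  dihedrals <- if (n >= 4) {
    idx <- seq_len(n - 3)
    kd <- if (length(idx) > 0 && nrow(contacts) > 0) {
      sum(contacts$eps) / (params$dihedral_contact_ratio * length(idx))
    } else 0
    tibble(i = idx, j = idx + 1L, k = idx + 2L, l = idx + 3L,
           phi0 = vapply(idx, function(q)
             .dihedral_between(pos[q, ], pos[q + 1, ], pos[q + 2, ],
                               pos[q + 3, ]), numeric(1)),
           kf = kd)
  } else tibble(i = integer(), j = integer(), k = integer(), l = integer(),
                phi0 = numeric(), kf = numeric())
  contact_tbl <- tibble(i = ci, j = cj, resid_i = contacts$i,
                        resid_j = contacts$j, r0 = contacts$r0,
                        eps = contacts$eps)

  all_beads <- beads
  all_beads$group <- "P"
  anchor <- NULL
  tunnel <- NULL
  if (!is.null(scaffold)) {
    sb <- scaffold$beads
    grp <- ifelse(sb$kind == "anchor", "A",
                  ifelse(sb$kind == "wall", "W",
                         ifelse(sb$kind == "cap", "C", "S")))
    sb$group <- grp
    anchor_row <- match(scaffold$anchor, sb$bead)
    sb$bead <- n + seq_len(nrow(sb))
    anchor <- sb$bead[anchor_row]
    all_beads <- dplyr::bind_rows(all_beads, sb)
    tunnel <- scaffold$tunnel
  }
  sys <- structure(list(
    beads = all_beads, bonds = bonds, angles = angles, dihedrals = dihedrals,
    contacts = contact_tbl,
    hp_pairs = tibble(i = integer(), j = integer(), sigma = numeric(),
                      eps = numeric()),
    tether = NULL, anchor = anchor, tunnel = tunnel,
    n_domain = n, linker_length = 0L,
    native_pos = pos, params = params,
    provenance = list(contact_criterion = attr(contacts, "criterion"))),
    class = "cg_system")
  sys
}

#' @export
print.cg_system <- function(x, ...) {
  cat("<cg_system> ", x$n_domain, " domain beads",
      if (x$linker_length > 0) paste0(" + ", x$linker_length, " linker beads"),
      if (sum(!x$beads$mobile) > 0)
        paste0(" + ", sum(!x$beads$mobile), " scaffold beads"),
      "\n", sep = "")
  cat("  ", nrow(x$contacts), " native contacts; ",
      if (is.null(x$tether)) "no tether" else
        sprintf("tether ks = %g kJ/mol/nm^2, x0 = %g nm",
                x$tether$ks, x$tether$x0),
      "; T = ", x$params$temperature, " K\n", sep = "")
  invisible(x)
}

#' Append a nascent-chain linker and the force-reporting tether
#'
#' Adds `L` featureless repulsive linker beads C-terminally to the domain
#' and tethers the chain end to the scaffold anchor with a stiff harmonic
#' spring (the only unconstrained bond; its extension reports the pulling
#' force as F = ks (x - x0), positive when pulling). Initial coordinates
#' thread the chain, fully extended, along the tunnel axis out of the exit.
#'
#' @param system a `cg_system` built with a scaffold.
#' @param L number of linker residues between the domain C-terminus and the
#'   tether point (>= 1).
#' @param linker_sequence optional residue labels; defaults to the
#'   C-terminal `L` residues of the longest (63-residue) construct linker.
#' @return the extended `cg_system`.
#' @export
attach_linker_and_tether <- function(system, L, linker_sequence = NULL) {
  stopifnot(inherits(system, "cg_system"))
  if (L < 1) abort("L must be >= 1 (a direct domain-anchor tether is not a construct)")
  if (is.null(system$anchor)) {
    abort("system has no scaffold anchor; build with a ribosome scaffold first")
  }
  if (is.null(linker_sequence)) {
    if (L > nchar(.linker63)) {
      abort(paste0("L = ", L, " exceeds the available linker sequence (",
                   nchar(.linker63), " residues); supply linker_sequence"))
    }
    linker_sequence <- substr(.linker63, nchar(.linker63) - L + 1, nchar(.linker63))
  }
  if (nchar(linker_sequence) != L) {
    abort("linker_sequence length must equal L")
  }
  params <- system$params
  n0 <- nrow(system$beads)
  nd <- system$n_domain
  anchor_pos <- unlist(system$beads[system$beads$bead == system$anchor,
                                    c("x", "y", "z")])
  tun <- system$tunnel
  dirv <- if (!is.null(tun)) {
    d <- tun$axis_end - tun$axis_start
    d / sqrt(sum(d^2))
  } else c(0, 0, 1)

  # thread the whole chain, fully extended, along the axis: chain end at
  # x0 from the anchor, then linker, then the unfolded domain
  bond_r0 <- c(rep(0.38, L), rev(system$bonds$r0[seq_len(nd - 1)]))
  s <- params$x0 + c(0, cumsum(bond_r0))
  zig <- 0.02 * (seq_along(s) %% 2)
  perp <- if (abs(dirv[3]) < 0.9) {
    v <- c(dirv[2], -dirv[1], 0)
    v / sqrt(sum(v^2))
  } else c(1, 0, 0)
  chain_pos <- t(anchor_pos + outer(dirv, s) + outer(perp, zig))
  # chain order along the axis: linker bead L (chain end) ... linker 1,
  # domain bead nd (C-term) ... domain bead 1
  linker_pos <- chain_pos[L:1, , drop = FALSE]
  domain_pos <- chain_pos[L + (nd:1), , drop = FALSE]

  beads <- system$beads
  beads[seq_len(nd), c("x", "y", "z")] <- as.data.frame(domain_pos)
  lk <- tibble(
    bead = n0 + seq_len(L), kind = "linker", resid = seq_len(L),
    resname = strsplit(linker_sequence, "")[[1]], chain = "L",
    x = linker_pos[, 1], y = linker_pos[, 2], z = linker_pos[, 3],
    sigma = unname(bead_radii()["linker"]), mobile = TRUE, group = "L")
  beads <- dplyr::bind_rows(beads, lk)
  new_bonds <- tibble(
    i = c(nd, n0 + seq_len(L - 1)),
    j = c(n0 + 1L, n0 + seq_len(L - 1) + 1L),
    r0 = 0.38, k = 0, constrained = TRUE)
  if (L == 1) new_bonds <- new_bonds[1, , drop = FALSE]
  system$beads <- beads
  system$bonds <- dplyr::bind_rows(system$bonds, new_bonds)
  system$tether <- list(anchor = system$anchor, end = n0 + L,
                        ks = params$ks, x0 = params$x0)
  system$linker_length <- as.integer(L)
  system$linker_sequence <- linker_sequence
  system
}

#' Weaken all native contacts of one residue
#'
#' Multiplies the strength of every native contact involving `residue` by
#' `(1 - factor)`; used to model destabilizing point mutants (e.g. a 40%
#' weakening).
#'
#' @param system a `cg_system`.
#' @param residue residue index (as in the contact map).
#' @param factor fraction of strength removed, in \[0, 1\].
#' @return the modified system.
#' @export
weaken_residue_contacts <- function(system, residue, factor = NULL) {
  stopifnot(inherits(system, "cg_system"))
  factor <- factor %||% system$params$weaken_factor
  if (factor < 0 || factor > 1) abort("factor must be in [0, 1]")
  hit <- system$contacts$resid_i == residue | system$contacts$resid_j == residue
  if (!any(hit)) {
    abort(paste0("residue ", residue, " has no native contacts"))
  }
  system$contacts$eps[hit] <- system$contacts$eps[hit] * (1 - factor)
  system
}

#' Add hydrophobic attractions to ribosome surface residues
#'
#' Adds Lennard-Jones 12-6 pairs `V = 4 eps [(sigma/r)^12 - (sigma/r)^6]`
#' between a set of protein residues (e.g. those surrounding a mutated,
#' cavity-forming site) and hydrophobic residues on the ribosome surface.
#'
#' @param system a `cg_system` with a scaffold.
#' @param surface_beads scaffold bead ids carrying the attraction.
#' @param protein_residues domain residue indices involved.
#' @param sigma_hp,eps_hp interaction range (nm) and strength (kJ/mol);
#'   default from the system parameters (0.6 nm, 5 kJ/mol).
#' @return the modified system.
#' @export
add_hydrophobic_surface_attraction <- function(system, surface_beads,
                                               protein_residues,
                                               sigma_hp = NULL,
                                               eps_hp = NULL) {
  stopifnot(inherits(system, "cg_system"))
  sigma_hp <- sigma_hp %||% system$params$sigma_hp
  eps_hp <- eps_hp %||% system$params$eps_hp
  if (length(surface_beads) == 0 || length(protein_residues) == 0) {
    abort("both surface_beads and protein_residues must be non-empty")
  }
  if (!all(surface_beads %in% system$beads$bead[!system$beads$mobile])) {
    abort("surface_beads must be immobile scaffold bead ids")
  }
  dom <- system$beads[system$beads$group == "P", ]
  pi_ <- dom$bead[match(protein_residues, dom$resid)]
  if (anyNA(pi_)) abort("protein_residues absent from the domain")
  pairs <- expand.grid(i = pi_, j = surface_beads)
  system$hp_pairs <- dplyr::bind_rows(
    system$hp_pairs,
    tibble(i = pairs$i, j = pairs$j, sigma = sigma_hp, eps = eps_hp))
  system
}

#' Residues whose heavy atoms neighbour a given residue
#'
#' Convenience selector for selecting the protein residues involved in
#' surface attractions: all residues with any heavy atom within `cutoff` of
#' any heavy atom of `residue` in the native structure.
#'
#' @param structure an `atomic_structure`.
#' @param residue residue index.
#' @param cutoff distance cutoff, nm (default 0.45).
#' @return integer vector of residue indices (including `residue`).
#' @export
residues_near <- function(structure, residue, cutoff = 0.45) {
  st <- structure[!structure$hetero & structure$element != "H", ]
  ref <- as.matrix(st[st$resid == residue, c("x", "y", "z")]) / 10
  if (nrow(ref) == 0) abort("residue not found")
  other <- st[, c("resid", "x", "y", "z")]
  pos <- as.matrix(other[, c("x", "y", "z")]) / 10
  d2 <- outer(rowSums(pos^2), rowSums(ref^2), "+") - 2 * pos %*% t(ref)
  hits <- other$resid[apply(d2, 1, min) < cutoff^2]
  sort(unique(hits))
}

# ---- packing for the C++ core -----------------------------------------------

.pack_system <- function(system, k_umb = 0, q0 = 0) {
  b <- system$beads
  params <- system$params
  key <- paste(b$group, b$sigma)
  kinds <- unique(key)
  kind_idx <- match(key, kinds)
  K <- length(kinds)
  grp <- sub(" .*", "", kinds)
  sig <- as.numeric(sub(".* ", "", kinds))
  em <- .group_eps_matrix(params)
  pa <- pb <- pc <- pe <- matrix(0, K, K)
  for (a in seq_len(K)) {
    for (d in seq_len(K)) {
      cf <- repulsion_coefficients(sig[a], sig[d], rule = params$mixing_rule)
      pa[a, d] <- cf[["A"]]
      pb[a, d] <- cf[["B"]]
      pc[a, d] <- cf[["C"]]
      pe[a, d] <- em[grp[a], grp[d]]
    }
  }
  excl <- rbind(
    as.matrix(system$bonds[, c("i", "j")]),
    if (nrow(system$angles) > 0) as.matrix(system$angles[, c("i", "k")]),
    if (nrow(system$dihedrals) > 0) as.matrix(system$dihedrals[, c("i", "l")]),
    as.matrix(system$contacts[, c("i", "j")]),
    if (nrow(system$hp_pairs) > 0) as.matrix(system$hp_pairs[, c("i", "j")]),
    if (!is.null(system$tether)) cbind(system$tether$anchor, system$tether$end))
  storage.mode(excl) <- "integer"
  list(
    pos = as.matrix(b[, c("x", "y", "z")]),
    mobile = b$mobile,
    mass = rep(params$mass, nrow(b)),
    kind = kind_idx, nkind = K,
    bonds = matrix(as.integer(as.matrix(system$bonds[, c("i", "j")])), ncol = 2),
    bond_r0 = system$bonds$r0, bond_k = system$bonds$k,
    bond_constrained = system$bonds$constrained,
    angles = matrix(as.integer(as.matrix(system$angles[, c("i", "j", "k")])),
                    ncol = 3),
    angle_theta0 = system$angles$theta0, angle_k = system$angles$kf,
    dihedrals = matrix(as.integer(as.matrix(
      system$dihedrals[, c("i", "j", "k", "l")])), ncol = 4),
    dihedral_phi0 = system$dihedrals$phi0, dihedral_k = system$dihedrals$kf,
    contacts = matrix(as.integer(as.matrix(system$contacts[, c("i", "j")])),
                      ncol = 2),
    contact_r0 = system$contacts$r0, contact_eps = system$contacts$eps,
    pair_A = pa, pair_B = pb, pair_C = pc, pair_eps = pe,
    hp_pairs = matrix(as.integer(as.matrix(system$hp_pairs[, c("i", "j")])),
                      ncol = 2),
    hp_sigma = system$hp_pairs$sigma, hp_eps = system$hp_pairs$eps,
    has_tether = !is.null(system$tether),
    tether_i = if (!is.null(system$tether)) system$tether$anchor else 0L,
    tether_j = if (!is.null(system$tether)) system$tether$end else 0L,
    tether_ks = if (!is.null(system$tether)) system$tether$ks else 0,
    tether_x0 = if (!is.null(system$tether)) system$tether$x0 else 0,
    k_umb = k_umb, q0 = q0,
    q_gamma = params$q_gamma, q_lambda = params$q_lambda,
    cutoff = params$cutoff,
    exclusions = excl)
}

#' Potential energy, forces and observables of a configuration
#'
#' Evaluates the full potential at the given coordinates, returning the
#' per-term energy decomposition, the analytic forces, the fraction of
#' native contacts Q, and the tether extension/force when a tether is
#' present.
#'
#' @param system a `cg_system`.
#' @param positions optional n x 3 matrix (nm); defaults to the system's
#'   current coordinates.
#' @param bias optional umbrella bias `list(k_umb, q0)` with `k_umb` in
#'   kJ/mol.
#' @return list with `energy`, `terms`, `forces`, `Q`, `x`, `F_pN`.
#' @export
cg_energy <- function(system, positions = NULL, bias = NULL) {
  packed <- .pack_system(system,
                         k_umb = if (!is.null(bias)) bias$k_umb else 0,
                         q0 = if (!is.null(bias)) bias$q0 else 0)
  pos <- positions %||% packed$pos
  cpp_eval(packed, pos)
}

#' Current coordinates of a system
#'
#' @param system a `cg_system`.
#' @param mobile_only return only mobile beads?
#' @return n x 3 numeric matrix (nm).
#' @export
positions_of <- function(system, mobile_only = FALSE) {
  b <- system$beads
  if (mobile_only) b <- b[b$mobile, ]
  as.matrix(b[, c("x", "y", "z")])
}

#' Replace coordinates of a system
#'
#' @param system a `cg_system`.
#' @param positions n x 3 matrix covering all beads, or the mobile beads
#'   only (immobile rows are then left untouched).
#' @return the updated system.
#' @export
set_positions <- function(system, positions) {
  b <- system$beads
  if (nrow(positions) == nrow(b)) {
    b[, c("x", "y", "z")] <- as.data.frame(positions)
  } else if (nrow(positions) == sum(b$mobile)) {
    b[b$mobile, c("x", "y", "z")] <- as.data.frame(positions)
  } else {
    abort("positions must cover all beads or exactly the mobile beads")
  }
  system$beads <- b
  system
}
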