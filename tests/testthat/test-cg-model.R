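# The coarse-grained potential: contact maps, excluded volume, system
# assembly, mutant perturbations, tether.

test_that("heavy-atom contact criterion is a strict distance threshold", {
  # two 'residues' whose closest heavy atoms sit at 4.4 vs 4.6 Angstrom
  mk <- function(gap) {
    tibble::tibble(
      element = c("C", "C", "C", "C"),
      atom = c("CA", "CB", "CA", "CB"),
      resname = "ALA",
      resid = c(1L, 1L, 6L, 6L),
      chain = "A",
      x = c(0, 1, 10, 1 + gap), y = 0, z = 0,
      hetero = FALSE) |>
      structure(class = c("atomic_structure", class(tibble::tibble())))
  }
  expect_equal(nrow(contact_map_from_structure(mk(4.4), 0.45, 4)), 1)
  expect_equal(nrow(contact_map_from_structure(mk(4.6), 0.45, 4)), 0)
})

test_that("the toy contact list equals a brute-force all-pairs scan", {
  toy <- make_toy_protein(20, "hairpin", seed = 3)
  pos <- as.matrix(toy$beads[, c("x", "y", "z")])
  found <- list()
  for (i in 1:19) for (j in (i + 1):20) {
    if (j - i < 4) next
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < 0.67) {
      found[[length(found) + 1]] <- c(i, j)
    }
  }
  brute <- do.call(rbind, found)
  expect_equal(nrow(toy$contacts), nrow(brute))
  expect_equal(cbind(toy$contacts$i, toy$contacts$j), unname(brute))
})

test_that("repulsion coefficients give a monotone, fast-decaying barrier", {
  co <- repulsion_coefficients(0.45, 0.45)
  expect_equal(co[["sigma_eff"]], 0.45) # equal radii: effective distance = sigma
  # amino-acid / phosphate pair: negligible beyond 1.5 sigma
  cp <- repulsion_coefficients(0.45, 0.32)
  s <- cp[["sigma_eff"]]
  expect_lt(repulsion_energy(1.5 * s, cp), 1e-2 * repulsion_energy(s, cp))
  # strictly positive and monotone inside the core
  r <- seq(0.05, s, length.out = 200)
  v <- repulsion_energy(r, cp)
  expect_true(all(v > 0))
  expect_true(all(diff(v) < 0))
  expect_error(repulsion_coefficients(-0.1, 0.4), "positive")
})

test_that("the native configuration is the energy minimum of the Go system", {
  set.seed(5)
  e0 <- cg_energy(toy_sys)$energy
  pos <- positions_of(toy_sys)
  worst <- min(vapply(1:200, function(k) {
    cg_energy(toy_sys, pos + matrix(rnorm(length(pos), sd = 0.04),
                                    ncol = 3))$energy
  }, numeric(1)))
  expect_lt(e0, worst)
})

test_that("analytic forces match the numerical gradient for every term", {
  # perturbed toy with all term types active, including tether, bias and
  # hydrophobic pairs
  sys <- tethered_system(8)
  sys <- add_hydrophobic_surface_attraction(
    sys, surface_beads = sys$beads$bead[!sys$beads$mobile][1:3],
    protein_residues = c(2, 3))
  set.seed(9)
  pos <- positions_of(sys)
  mob <- sys$beads$mobile
  pos[mob, ] <- pos[mob, ] + matrix(rnorm(3 * sum(mob), sd = 0.03), ncol = 3)
  packed <- nascentfold:::.pack_system(sys, k_umb = 200, q0 = 0.5)
  e <- nascentfold:::cpp_eval(packed, pos)
  h <- 1e-6
  num <- matrix(0, nrow(pos), 3)
  for (i in which(mob)) {
    for (d in 1:3) {
      p1 <- pos; p1[i, d] <- p1[i, d] + h
      p2 <- pos; p2[i, d] <- p2[i, d] - h
      num[i, d] <- -(nascentfold:::cpp_eval(packed, p1)$energy -
                       nascentfold:::cpp_eval(packed, p2)$energy) / (2 * h)
    }
  }
  scale <- max(abs(num[mob, ]))
  expect_lt(max(abs(num[mob, ] - e$forces[mob, ])) / scale, 1e-4)
})

test_that("energy is invariant under rigid motion without scaffold or tether", {
  set.seed(2)
  pos <- positions_of(toy_sys) + matrix(rnorm(48, sd = 0.05), ncol = 3)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pos2 <- pos %*% R + matrix(rep(c(1, -2, 3), each = nrow(pos)), ncol = 3)
  expect_equal(cg_energy(toy_sys, pos2)$energy, cg_energy(toy_sys, pos)$energy,
               tolerance = 1e-10)
})

test_that("linker attachment and tether behave per construction", {
  expect_error(tethered_system(0), "L must be >= 1")
  sys <- tethered_system(6)
  expect_equal(sys$linker_length, 6L)
  expect_equal(sum(sys$beads$group == "L"), 6)
  expect_equal(sys$tether$ks, 3000)
  expect_equal(sys$tether$x0, 0.38)
  # linker sequence bookkeeping: C-terminal residues of the longest construct
  expect_equal(sys$linker_sequence, "GIRAGP")
  expect_error(attach_linker_and_tether(build_go_system(
    wide_hp$beads, wide_hp$contacts, toy_tun), 99), "exceeds")

  # tether at rest length: zero energy and force
  anchor_pos <- unlist(sys$beads[sys$beads$bead == sys$tether$anchor,
                                 c("x", "y", "z")])
  pos <- positions_of(sys)
  pos[sys$tether$end, ] <- anchor_pos + c(0, 0, 0.38)
  e <- cg_energy(sys, pos)
  expect_equal(e$terms[["tether"]], 0)
  expect_equal(e$F_pN, 0)
  # 0.1 nm displacement: |F| = 300 kJ/mol/nm ~ 498 pN
  pos[sys$tether$end, ] <- anchor_pos + c(0, 0, 0.48)
  e2 <- cg_energy(sys, pos)
  expect_equal(e2$F_pN, 3000 * 0.1 * 1.66054, tolerance = 1e-6)
  expect_equal(e2$F_pN, 498, tolerance = 0.01)
  # sign convention: pulling (x > x0) is positive
  expect_gt(e2$F_pN, 0)
})

test_that("weakening a residue's contacts scales exactly its own strengths", {
  sys <- toy_sys
  res <- sys$contacts$resid_i[1]
  hit <- sys$contacts$resid_i == res | sys$contacts$resid_j == res
  e_res <- sum(sys$contacts$eps[hit])
  w0 <- weaken_residue_contacts(sys, res, 0)
  expect_equal(w0$contacts$eps, sys$contacts$eps) # factor 0: identity
  w <- weaken_residue_contacts(sys, res, 0.4)
  expect_equal(sum(sys$contacts$eps) - sum(w$contacts$eps), 0.4 * e_res)
  expect_equal(w$contacts$eps[!hit], sys$contacts$eps[!hit])
  w1 <- weaken_residue_contacts(sys, res, 1)
  expect_true(all(w1$contacts$eps[hit] == 0)) # factor 1: nulled
  expect_error(weaken_residue_contacts(sys, 999), "no native contacts")
})

test_that("hydrophobic surface attractions follow the 12-6 form", {
  sys <- tethered_system(6)
  sb <- sys$beads$bead[!sys$beads$mobile][1]
  sys2 <- add_hydrophobic_surface_attraction(sys, sb, protein_residues = 1,
                                             sigma_hp = 0.6, eps_hp = 5)
  expect_equal(nrow(sys2$hp_pairs), 1)
  place <- function(r) {
    pos <- positions_of(sys2)
    surf <- unlist(sys2$beads[sys2$beads$bead == sb, c("x", "y", "z")])
    pos[1, ] <- surf + c(0, 0, r)
    cg_energy(sys2, pos)$terms[["hp"]] -
      cg_energy(sys, pos)$terms[["hp"]] # isolate the added pair
  }
  expect_equal(place(0.6), 0, tolerance = 1e-9)          # V(sigma) = 0
  expect_equal(place(2^(1 / 6) * 0.6), -5, tolerance = 1e-9) # LJ minimum -eps
  expect_lt(abs(place(5)), 1e-3)                          # decays to zero
  expect_error(add_hydrophobic_surface_attraction(sys, integer(0), 1),
               "non-empty")
})

test_that("contact weakening and surface attraction commute", {
  sys <- tethered_system(6)
  sb <- sys$beads$bead[!sys$beads$mobile][1:2]
  res <- sys$contacts$resid_i[1]
  a <- add_hydrophobic_surface_attraction(
    weaken_residue_contacts(sys, res, 0.4), sb, 1)
  b <- weaken_residue_contacts(
    add_hydrophobic_surface_attraction(sys, sb, 1), res, 0.4)
  expect_equal(a$contacts, b$contacts)
  expect_equal(a$hp_pairs, b$hp_pairs)
})

test_that("contacts may not reference linker beads", {
  bad <- wide_hp$contacts
  bad$j[1] <- 99L
  expect_error(build_go_system(wide_hp$beads, bad, toy_tun),
               "absent from the bead model")
})
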