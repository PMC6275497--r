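# Structure reading, coarse-graining and scaffold selection.

test_that("a minimal PDB round-trips through reading and coarse-graining", {
  path <- write_mini_pdb(withr::local_tempfile(fileext = ".pdb"))
  st <- read_structure(path)
  expect_s3_class(st, "atomic_structure")
  expect_equal(length(unique(st$resid)), 2)
  cg <- coarse_grain(st, "protein")
  expect_equal(nrow(cg), 2)
  expect_equal(cg$kind, rep("protein-CA", 2))
  # Calpha coordinates preserved (Angstrom -> nm)
  expect_equal(cg$x, c(1.458, 3.988) / 10, tolerance = 1e-8)
  expect_equal(cg$sigma, rep(0.45, 2))
})

test_that("a residue missing its Calpha is reported per residue", {
  path <- write_mini_pdb(withr::local_tempfile(fileext = ".pdb"), drop_ca = TRUE)
  st <- read_structure(path)
  miss <- missing_calpha(st)
  expect_equal(nrow(miss), 1)
  expect_equal(miss$resid, 2L)
  expect_error(coarse_grain(st, "protein"), "no CA atom")
})

test_that("unparseable files raise a format error naming the file", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", bad)
  expect_error(read_structure(bad), "parse|format|PDB", ignore.case = TRUE)
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")
})

test_that("RNA nucleotides coarse-grain to exactly three beads with fixed radii", {
  path <- write_mini_rna_pdb(withr::local_tempfile(fileext = ".pdb"))
  st <- read_structure(path)
  cg <- coarse_grain(st, "rna")
  expect_equal(nrow(cg), 3)
  expect_setequal(cg$kind, c("rna-P", "rna-C4p", "rna-N3"))
  expect_equal(cg$sigma[match(c("rna-P", "rna-C4p", "rna-N3"), cg$kind)],
               c(0.32, 0.51, 0.45))
  # a nucleotide missing one of P/C4'/N3 is an error naming the residue
  path2 <- write_mini_rna_pdb(withr::local_tempfile(fileext = ".pdb"),
                              drop_n3 = TRUE)
  expect_error(coarse_grain(read_structure(path2)), "N3")
})

test_that("bead counting laws hold for mixed protein/RNA input", {
  p1 <- write_mini_pdb(withr::local_tempfile(fileext = ".pdb"))
  p2 <- write_mini_rna_pdb(withr::local_tempfile(fileext = ".pdb"))
  st1 <- read_structure(p1)
  st2 <- read_structure(p2)
  st2$chain <- "B"
  mixed <- dplyr::bind_rows(st1, st2)
  class(mixed) <- class(st1)
  cg <- coarse_grain(mixed, "all")
  expect_equal(nrow(cg), 2 + 3 * 1) # n_aa + 3 n_nt
})

test_that("scaffold selection retains beads near the tunnel and the anchor", {
  tun <- make_toy_tunnel(6, 1.0, 0.35)
  b <- tun$beads
  b$mobile <- FALSE
  ann <- tun$tunnel
  all_kept <- select_scaffold(b, ann, cutoff_radius = Inf, anchor = tun$anchor)
  expect_equal(nrow(all_kept$beads), nrow(b))

  # monotonicity: larger cutoff retains a superset
  s1 <- select_scaffold(b, ann, cutoff_radius = 1.2, exit_cap_radius = 0,
                        anchor = tun$anchor)
  s2 <- select_scaffold(b, ann, cutoff_radius = 2.4, exit_cap_radius = 0,
                        anchor = tun$anchor)
  expect_true(all(s1$beads$bead %in% s2$beads$bead))

  # a distal decoy bead is dropped at finite cutoff
  decoy <- b[1, ]
  decoy$bead <- max(b$bead) + 1L
  decoy$x <- 50
  b2 <- dplyr::bind_rows(b, decoy)
  class(b2) <- class(b)
  kept <- select_scaffold(b2, ann, cutoff_radius = 2, exit_cap_radius = 2,
                          anchor = tun$anchor)
  expect_false(decoy$bead %in% kept$beads$bead)

  # an anchor that fails the geometric criterion is an error
  far_anchor <- b2
  far_anchor$x[far_anchor$bead == tun$anchor] <- 100
  expect_error(select_scaffold(far_anchor, ann, cutoff_radius = 2,
                               exit_cap_radius = 2, anchor = tun$anchor),
               "anchor")
})

test_that("bead models serialize to JSON and back at 1e-3 nm accuracy", {
  path <- withr::local_tempfile(fileext = ".json")
  write_bead_model(toy16$beads, path)
  back <- read_bead_model(path)
  expect_equal(as.data.frame(back), as.data.frame(toy16$beads),
               tolerance = 1e-6)
})
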