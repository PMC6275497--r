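# Reading atomic structures and coarse-graining them to the bead
# representation: one bead per amino acid at the Calpha position, three beads
# per RNA nucleotide (P, C4', N3).

#' Bead radii by bead kind
#'
#' Fixed excluded-volume radii (nm): amino acid 0.45, phosphate 0.32,
#' sugar 0.51, base 0.45. Toy fixture kinds (wall, cap, linker, anchor)
#' reuse the amino-acid radius.
#'
#' @return named numeric vector of radii in nm.
#' @export
bead_radii <- function() {
  c("protein-CA" = 0.45, "rna-P" = 0.32, "rna-C4p" = 0.51, "rna-N3" = 0.45,
    "linker" = 0.45, "wall" = 0.45, "cap" = 0.45, "anchor" = 0.45)
}

new_bead_model <- function(df) {
  stopifnot(all(c("bead", "kind", "resid", "resname", "chain",
                  "x", "y", "z", "sigma", "mobile") %in% names(df)))
  structure(as_tibble(df), class = c("bead_model", class(as_tibble(df))))
}

#' Read a protein/RNA structure from PDB or mmCIF
#'
#' Thin wrapper around [bio3d::read.pdb()] / [bio3d::read.cif()] returning a
#' tidy atom table. Only the first model is used and alternate locations
#' other than "A" are dropped. Coordinates are kept in Angstrom (the native
#' unit of both formats); [coarse_grain()] converts to nm.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format `"PDB"`, `"mmCIF"` or `"auto"` (by file extension).
#' @return a tibble of class `atomic_structure` with columns `element`,
#'   `atom`, `resname`, `resid`, `chain`, `x`, `y`, `z` (Angstrom), `hetero`.
#' @export
read_structure <- function(path, format = c("auto", "PDB", "mmCIF")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmCIF" else "PDB"
  }
  if (!file.exists(path)) abort(paste0("structure file not found: ", path))
  parsed <- tryCatch(
    if (format == "PDB") bio3d::read.pdb(path, multi = FALSE)
    else bio3d::read.cif(path),
    error = function(e) {
      abort(paste0("failed to parse ", format, " file '", path, "': ",
                   conditionMessage(e)))
    })
  at <- parsed$atom
  alt <- at$alt
  keep <- is.na(alt) | alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) {
    abort(paste0("no ATOM/HETATM records parsed from ", format, " file '",
                 path, "'"))
  }
  out <- tibble(
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1, 1), trimws(at$elesy)),
    atom = trimws(at$elety),
    resname = trimws(at$resid),
    resid = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "A", as.character(at$chain)),
    x = at$x, y = at$y, z = at$z,
    hetero = at$type == "HETATM")
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    abort("structure contains non-finite coordinates")
  }
  structure(out, class = c("atomic_structure", class(out)), source = path)
}

.rna_resnames <- c("A", "U", "G", "C", "RA", "RU", "RG", "RC",
                   "ADE", "URA", "GUA", "CYT")

.is_protein_residue <- function(res_atoms) any(res_atoms == "CA")

#' Coarse-grain an atomic structure to the bead representation
#'
#' Protein residues get one bead at the Calpha position; RNA nucleotides get
#' three beads at the P, C4' and N3 atom positions. Radii follow
#' [bead_radii()]. Positions are converted from Angstrom to nm.
#'
#' @param structure an `atomic_structure` from [read_structure()].
#' @param selection `"all"`, `"protein"` or `"rna"`.
#' @param mobile logical; are these beads mobile (default `TRUE`)? Scaffold
#'   construction marks beads immobile via [select_scaffold()].
#' @return a `bead_model` tibble.
#' @export
coarse_grain <- function(structure, selection = c("all", "protein", "rna"),
                         mobile = TRUE) {
  selection <- match.arg(selection)
  st <- structure[!structure$hetero, , drop = FALSE]
  radii <- bead_radii()
  rows <- list()
  errors <- character()
  for (key in unique(paste(st$chain, st$resid, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    res <- st[st$chain == parts[1] & st$resid == as.integer(parts[2]), ,
              drop = FALSE]
    is_rna <- res$resname[1] %in% .rna_resnames
    if (is_rna && selection != "protein") {
      need <- c("P", "C4'", "N3")
      kinds <- c("rna-P", "rna-C4p", "rna-N3")
      have <- match(need, res$atom)
      if (anyNA(have)) {
        errors <- c(errors, paste0("nucleotide ", res$resname[1], " ",
                                   parts[2], " (chain ", parts[1],
                                   ") missing atom(s): ",
                                   paste(need[is.na(have)], collapse = ", ")))
        next
      }
      for (b in seq_along(need)) {
        a <- res[have[b], ]
        rows[[length(rows) + 1]] <- tibble(
          kind = kinds[b], resid = a$resid, resname = a$resname,
          chain = a$chain, x = a$x / 10, y = a$y / 10, z = a$z / 10)
      }
    } else if (!is_rna && selection != "rna") {
      ca <- res[res$atom == "CA", , drop = FALSE]
      if (nrow(ca) == 0) {
        errors <- c(errors, paste0("residue ", res$resname[1], " ", parts[2],
                                   " (chain ", parts[1], ") has no CA atom"))
        next
      }
      a <- ca[1, ]
      rows[[length(rows) + 1]] <- tibble(
        kind = "protein-CA", resid = a$resid, resname = a$resname,
        chain = a$chain, x = a$x / 10, y = a$y / 10, z = a$z / 10)
    }
  }
  if (length(errors) > 0) {
    abort(paste0("coarse-graining failed:\n",
                 paste0("  - ", errors, collapse = "\n")))
  }
  df <- dplyr::bind_rows(rows)
  df <- df[order(df$chain, df$resid, match(df$kind, names(radii))), ]
  df$bead <- seq_len(nrow(df))
  df$sigma <- unname(radii[df$kind])
  df$mobile <- mobile
  new_bead_model(df[, c("bead", "kind", "resid", "resname", "chain",
                        "x", "y", "z", "sigma", "mobile")])
}

#' Validate Calpha completeness of a structure
#'
#' Returns, per chain, the protein residues lacking a Calpha atom. Used by
#' [read_structure()] consumers that need a per-residue error listing
#' without aborting.
#'
#' @param structure an `atomic_structure`.
#' @return tibble with columns `chain`, `resid`, `resname` (empty when
#'   complete).
#' @export
missing_calpha <- function(structure) {
  st <- structure[!structure$hetero & !(structure$resname %in% .rna_resnames), ]
  st |>
    dplyr::group_by(.data$chain, .data$resid, .data$resname) |>
    dplyr::summarise(has_ca = any(.data$atom == "CA"), .groups = "drop") |>
    dplyr::filter(!.data$has_ca) |>
    dplyr::select("chain", "resid", "resname")
}

.point_segment_distance <- function(p, a, b) {
  ab <- b - a
  tt <- sum((p - a) * ab) / sum(ab * ab)
  tt <- pmin(pmax(tt, 0), 1)
  proj <- a + tt * ab
  sqrt(sum((p - proj)^2))
}

new_ribosome_scaffold <- function(beads, anchor, tunnel) {
  stopifnot(anchor %in% beads$bead, !any(beads$mobile))
  structure(list(beads = beads, anchor = anchor, tunnel = tunnel),
            class = "ribosome_scaffold")
}

#' @export
print.ribosome_scaffold <- function(x, ...) {
  cat("<ribosome_scaffold> ", nrow(x$beads), " immobile beads, anchor bead ",
      x$anchor, "\n", sep = "")
  cat("  tunnel axis ",
      sprintf("(%.2f,%.2f,%.2f) -> (%.2f,%.2f,%.2f) nm",
              x$tunnel$axis_start[1], x$tunnel$axis_start[2],
              x$tunnel$axis_start[3], x$tunnel$axis_end[1],
              x$tunnel$axis_end[2], x$tunnel$axis_end[3]), "\n", sep = "")
  invisible(x)
}

#' Select the simulated subset of a ribosome bead model
#'
#' Retains beads near the exit-tunnel axis plus a hemispherical cap around
#' the exit; distal beads do not interact with the nascent chain and are
#' dropped. The tether anchor must satisfy the geometric criterion.
#'
#' @param beads a `bead_model` of the full (immobile) ribosome.
#' @param tunnel_annotation list with numeric `axis_start`, `axis_end` and
#'   `exit` positions (nm); `exit` defaults to `axis_end`.
#' @param cutoff_radius retain beads within this distance of the axis
#'   segment (nm, default 2).
#' @param exit_cap_radius additionally retain beads within this distance of
#'   the exit point (nm, default 6).
#' @param anchor bead id of the tether attachment point (last P atom of the
#'   A-site tRNA, or toy equivalent).
#' @return a `ribosome_scaffold`.
#' @export
select_scaffold <- function(beads, tunnel_annotation, cutoff_radius = 2,
                            exit_cap_radius = 6, anchor) {
  if (is.null(tunnel_annotation$axis_start) ||
      is.null(tunnel_annotation$axis_end)) {
    abort("tunnel_annotation must contain axis_start and axis_end")
  }
  a <- tunnel_annotation$axis_start
  b <- tunnel_annotation$axis_end
  ex <- tunnel_annotation$exit %||% b
  pos <- as.matrix(beads[, c("x", "y", "z")])
  d_axis <- apply(pos, 1, .point_segment_distance, a = a, b = b)
  d_exit <- sqrt(colSums((t(pos) - ex)^2))
  keep <- d_axis <= cutoff_radius | d_exit <= exit_cap_radius
  ai <- match(anchor, beads$bead)
  if (is.na(ai)) abort("anchor bead id not present in bead model")
  if (!keep[ai]) {
    abort("scaffold selection cutoff excludes the anchor bead; increase cutoff_radius")
  }
  out <- beads[keep, , drop = FALSE]
  out$mobile <- FALSE
  new_ribosome_scaffold(new_bead_model(out), anchor, tunnel_annotation)
}

#' Serialize / restore a bead model
#'
#' Writes a self-describing JSON document (kind, residue bookkeeping, radii,
#' coordinates in nm). Round-trips exactly at 1e-6 nm resolution.
#'
#' @param x a `bead_model`.
#' @param path output / input path.
#' @return `write_bead_model()` returns `path` invisibly;
#'   `read_bead_model()` returns a `bead_model`.
#' @export
write_bead_model <- function(x, path) {
  payload <- list(
    format = "nascentfold-bead-model", version = 1L,
    units = list(length = "nm"),
    beads = as.data.frame(x))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bead_model
#' @export
read_bead_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "nascentfold-bead-model")) {
    abort("not a nascentfold bead-model JSON file")
  }
  new_bead_model(as_tibble(payload$beads))
}
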