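# End-to-end pipeline: build -> umbrella per L -> WHAM -> rates -> force
# profile, with per-stage caching and a provenance manifest.

#' Pipeline configuration
#'
#' Validated configuration for a full per-variant run. With
#' `structure = "toy"` the synthetic fixtures are used; otherwise supply
#' paths to a protein structure and a ribosome structure.
#'
#' @param structure `"toy"` or a path to a protein PDB/mmCIF file.
#' @param ribosome path to a ribosome structure (ignored for toy runs).
#' @param L_grid linker lengths simulated (default `seq(21, 61, 2)`,
#'   matching the experimental construct series; toy runs typically use a
#'   shorter, smaller grid).
#' @param variant list: `list(type = "wild-type")`,
#'   `list(type = "weaken", residue =, factor =)`,
#'   `list(type = "delete-nterm", n =)`, or
#'   `list(type = "hydrophobic-surface", surface_beads =,
#'   protein_residues =)`.
#' @param toy_protein arguments passed to [make_toy_protein()].
#' @param toy_tunnel arguments passed to [make_toy_tunnel()].
#' @param params a [cg_params()] list.
#' @param umbrella list of [run_umbrella()] arguments (centers, k_umb,
#'   t_per_window, t_equil, dt, stride).
#' @param rates list: `n_replicas`, `t_max` (ps per replica) for the
#'   MFPT folding/unfolding runs; `k_u_iso_exp` anchor rate (s^-1).
#' @param bell a [bell_params()] object.
#' @param t_incubation incubation time, s (900 = 15 min; 1800 = 30 min).
#' @param kmc_replicas KMC replicas per L.
#' @param seed master integer seed; every stage derives its streams from
#'   it.
#' @param out_dir output/cache directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(structure = "toy", ribosome = NULL,
                            L_grid = seq(21, 61, 2),
                            variant = list(type = "wild-type"),
                            toy_protein = list(), toy_tunnel = list(),
                            params = cg_params(),
                            umbrella = list(), rates = list(),
                            bell = bell_params(), t_incubation = 900,
                            kmc_replicas = 2000, seed = 1,
                            out_dir = tempfile("nascentfold_run_")) {
  umbrella <- utils::modifyList(
    list(centers = seq(0, 1, length.out = 16), k_umb = 600,
         t_per_window = 500, t_equil = 100, dt = 0.002, stride = 50), umbrella)
  rates <- utils::modifyList(
    list(n_replicas = 6, t_max = 3000, k_u_iso_exp = 4.9e-4), rates)
  if (length(L_grid) < 1 || any(L_grid < 1)) abort("invalid L grid")
  if (t_incubation < 0) abort("t_incubation must be >= 0")
  if (!variant$type %in% c("wild-type", "weaken", "delete-nterm",
                           "hydrophobic-surface")) {
    abort(paste0("unknown variant type: ", variant$type))
  }
  structure(list(structure = structure, ribosome = ribosome, L_grid = L_grid,
                 variant = variant, toy_protein = toy_protein,
                 toy_tunnel = toy_tunnel, params = params,
                 umbrella = umbrella, rates = rates, bell = bell,
                 t_incubation = t_incubation, kmc_replicas = kmc_replicas,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Remove N-terminal residues from a domain model
#'
#' Strand-deletion mutants: drops the first `n` residues of the bead model
#' and prunes the contact map (no dangling contacts remain).
#'
#' @param beads domain `bead_model`.
#' @param contacts `contact_map`.
#' @param n number of N-terminal residues removed.
#' @return list(`beads`, `contacts`) with original residue numbering kept.
#' @export
delete_n_terminal <- function(beads, contacts, n) {
  keep_res <- sort(unique(beads$resid))[-seq_len(n)]
  if (length(keep_res) < 10) {
    abort("deletion would leave fewer than 10 residues")
  }
  b <- beads[beads$resid %in% keep_res, ]
  b$bead <- seq_len(nrow(b))
  cm <- contacts[contacts$i %in% keep_res & contacts$j %in% keep_res, ]
  list(beads = new_bead_model(b),
       contacts = new_contact_map(cm, attr(contacts, "criterion"),
                                  attr(contacts, "min_sep")))
}

#' Apply a variant specification to a built system
#'
#' Wild type is the identity; `weaken` rescales the mutated residue's
#' contact strengths; `hydrophobic-surface` wires ribosome-surface
#' attractions. N-terminal deletions act on the bead model before system
#' building (see [delete_n_terminal()]) and are rejected here.
#'
#' @param config a `pipeline_config` (its `variant` element is used).
#' @param system a `cg_system`.
#' @return the modified system.
#' @export
variant_apply <- function(config, system) {
  v <- config$variant
  switch(v$type,
    "wild-type" = system,
    "weaken" = weaken_residue_contacts(system, v$residue,
                                       v$factor %||% config$params$weaken_factor),
    "hydrophobic-surface" = add_hydrophobic_surface_attraction(
      system, v$surface_beads, v$protein_residues,
      v$sigma_hp %||% NULL, v$eps_hp %||% NULL),
    "delete-nterm" = abort("delete-nterm acts on the bead model; handled during the build stage"))
  }

.stage <- function(config, name, fun) {
  path <- file.path(config$out_dir, paste0(name, ".rds"))
  if (file.exists(path)) {
    return(readRDS(path))
  }
  val <- fun()
  saveRDS(val, path)
  val
}

.build_inputs <- function(config) {
  if (identical(config$structure, "toy")) {
    toy <- do.call(make_toy_protein,
                   utils::modifyList(list(seed = config$seed),
                                     config$toy_protein))
    scaffold <- do.call(make_toy_tunnel, config$toy_tunnel)
    beads <- toy$beads
    contacts <- toy$contacts
  } else {
    st <- read_structure(config$structure)
    beads <- coarse_grain(st, "protein")
    contacts <- contact_map_from_structure(
      st, heavy_atom_cutoff = config$params$contact_cutoff,
      min_separation = config$params$min_seq_sep)
    rb <- read_structure(config$ribosome)
    rb_beads <- coarse_grain(rb, "all", mobile = FALSE)
    if (is.null(config$ribosome_anchor) || is.null(config$ribosome_tunnel)) {
      abort("real-ribosome runs require tunnel annotation and anchor in the config")
    }
    scaffold <- select_scaffold(rb_beads, config$ribosome_tunnel,
                                anchor = config$ribosome_anchor)
  }
  if (identical(config$variant$type, "delete-nterm")) {
    del <- delete_n_terminal(beads, contacts, config$variant$n)
    beads <- del$beads
    contacts <- del$contacts
  }
  list(beads = beads, contacts = contacts, scaffold = scaffold)
}

#' Run the full pipeline
#'
#' Executes build -> umbrella sampling per linker length -> WHAM summary ->
#' MFPT rate estimation -> rate scaling -> force-profile assembly. Stage
#' results are cached as RDS files under `config$out_dir`; deleting a stage
#' file and re-running recomputes that stage and everything downstream of
#' it (earlier cached stages are reused). A JSON manifest records seeds,
#' stage hashes and the full configuration.
#'
#' @param config a [pipeline_config()].
#' @return list with `summary` (equilibrium summary), `rates`, `profile`
#'   (force profile), `systems` (per-L `cg_system`s) and `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  built <- .stage(config, "01_build", function() .build_inputs(config))

  systems <- .stage(config, "02_systems", function() {
    lapply(config$L_grid, function(L) {
      sys <- build_go_system(built$beads, built$contacts, built$scaffold,
                             config$params)
      sys <- attach_linker_and_tether(sys, L)
      variant_apply(config, sys)
    })
  })

  umbrellas <- .stage(config, "03_umbrella", function() {
    lapply(seq_along(systems), function(k) {
      do.call(run_umbrella, c(list(system = systems[[k]],
                                   seed = config$seed + 100 * k),
                              config$umbrella))
    })
  })

  summary <- .stage(config, "04_wham", function() {
    summarize_per_L(umbrellas, L = config$L_grid)
  })

  rate_tbl <- .stage(config, "05_rates", function() {
    rows <- lapply(seq_along(systems), function(k) {
      sys <- systems[[k]]
      us <- umbrellas[[k]]
      folded_start <- us$windows[[length(us$windows)]]$final_pos
      est <- .estimate_rates(sys, folded_start, config$rates,
                             seed = config$seed + 100 * k + 50,
                             dt = config$umbrella$dt)
      # folding rate by detailed balance with the umbrella-sampling
      # equilibrium constant: k_f = k_u * P_f / P_u. Direct folding MFPTs
      # at this scale are censoring-dominated whenever folding is slow, and
      # the kinetic scheme must share the equilibrium of the
      # preequilibrium solution.
      K <- summary$P_f[summary$L == config$L_grid[k]] /
        max(summary$P_u[summary$L == config$L_grid[k]], 1e-300)
      tibble(L = config$L_grid[k], k_f_sim = est$k_u * K,
             k_u_sim = est$k_u, k_u_censored = est$k_u_censored)
    })
    dplyr::bind_rows(rows)
  })

  rates <- scale_rates(rate_tbl, k_u_iso_exp = config$rates$k_u_iso_exp)

  profile <- .stage(config, "06_profile", function() {
    assemble_profile(summary, rates, bell = config$bell,
                     t = config$t_incubation,
                     n_replicas = config$kmc_replicas,
                     seed = config$seed + 7)
  })

  manifest <- list(
    package = "nascentfold",
    version = as.character(utils::packageVersion("nascentfold")),
    seed = config$seed,
    L_grid = config$L_grid,
    variant = config$variant,
    stages = lapply(
      setNames(nm = c("01_build", "02_systems", "03_umbrella", "04_wham",
                      "05_rates", "06_profile")),
      function(s) rlang::hash(readRDS(file.path(config$out_dir,
                                                paste0(s, ".rds"))))),
    created = as.character(Sys.time()))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)

  list(summary = summary, rates = rates, profile = profile,
       systems = systems, manifest_path = manifest_path)
}

# Unfolding MFPT estimation from an equilibrated folded configuration (the
# final frame of the Q0 = 1 umbrella window), with censoring handled by the
# maximum-likelihood estimator.
.estimate_rates <- function(sys, folded_start, rate_cfg, seed, dt = 0.002) {
  n <- rate_cfg$n_replicas
  t_max <- rate_cfg$t_max
  times <- numeric(0)
  for (r in seq_len(n)) {
    tr <- run_trajectory(sys, t_max = t_max, dt = dt, stride = 20,
                         seed = seed + 1000 + r, start = folded_start)
    hit <- which(tr$frames$Q < 0.3)[1]
    if (!is.na(hit)) times <- c(times, tr$frames$t[hit])
  }
  mu <- mfpt_censored(times, n, t_max)
  list(k_u = 1 / mu$mfpt, k_u_censored = mu$censored_bound)
}

#' Desk-scale toy study conditions
#'
#' The fixed conditions under which the synthetic linker-length family is
#' simulated: a wide 16-bead hairpin (strand separation 0.8 nm, contact
#' strength 1.5 kJ/mol, two-state at 291 K), a 6 nm x 1.0 nm toy exit
#' tunnel with a PTC pocket, linker lengths 8-28, 16 umbrella windows with
#' a 100 kcal/mol spring (gentler than the production-scale 600 kcal/mol
#' because the toy has ~20x fewer contacts, see the methods vignette), and
#' short MFPT runs for the folding/unfolding rates. Runs in minutes on one
#' CPU.
#'
#' @param seed master integer seed.
#' @param out_dir output/cache directory.
#' @return a [pipeline_config()].
#' @export
toy_study_config <- function(seed = 1, out_dir = tempfile("nascentfold_toy_")) {
  pipeline_config(
    structure = "toy",
    L_grid = c(8, 12, 16, 20, 24, 28),
    toy_protein = list(n_residues = 16, fold = "hairpin", strand_sep = 0.8,
                       contact_energy = 3),
    toy_tunnel = list(length = 6, radius = 1.0, bead_spacing = 0.35),
    umbrella = list(k_umb = 100, t_per_window = 250, t_equil = 80,
                    dt = 0.002, stride = 50),
    rates = list(n_replicas = 4, t_max = 600, k_u_iso_exp = 4.9e-4),
    kmc_replicas = 2000,
    seed = seed, out_dir = out_dir)
}
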