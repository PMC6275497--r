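# broom-style tidiers.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a coarse-grained system into its bead table
#'
#' @param x a `cg_system`.
#' @param ... unused.
#' @return tibble of beads (id, kind, group, residue bookkeeping,
#'   coordinates, radius, mobility).
#' @method tidy cg_system
#' @export
tidy.cg_system <- function(x, ...) {
  as_tibble(x$beads)
}

#' One-row summary of a coarse-grained system
#'
#' @param x a `cg_system`.
#' @param ... unused.
#' @return one-row tibble (bead/contact counts, linker length, tether
#'   constants, temperature).
#' @method glance cg_system
#' @export
glance.cg_system <- function(x, ...) {
  tibble(
    n_beads = nrow(x$beads), n_domain = x$n_domain,
    n_linker = x$linker_length, n_scaffold = sum(!x$beads$mobile),
    n_contacts = nrow(x$contacts),
    contact_energy = sum(x$contacts$eps),
    tethered = !is.null(x$tether),
    temperature = x$params$temperature)
}

#' Tidy an umbrella set into pooled samples
#'
#' @param x an `umbrella_set`.
#' @param ... unused.
#' @return tibble of samples with window index and center.
#' @method tidy umbrella_set
#' @export
tidy.umbrella_set <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$windows), function(w) {
    s <- x$windows[[w]]$samples
    s$window <- w
    s$q0 <- x$windows[[w]]$q0
    s
  }))
}

#' Tidy a free-energy profile
#'
#' @param x a `free_energy_profile`.
#' @param ... unused.
#' @return tibble (`Q`, `G`, `p`).
#' @method tidy free_energy_profile
#' @export
tidy.free_energy_profile <- function(x, ...) {
  tibble(Q = x$Q, G = x$G, p = x$p)
}

#' One-row summary of a force profile
#'
#' @param x a `force_profile`.
#' @param ... unused.
#' @return one-row tibble with the profile peak (L and height, full
#'   kinetic scheme), the maximum KMC/preequilibrium discrepancy, and the
#'   incubation time.
#' @method glance force_profile
#' @export
glance.force_profile <- function(x, ...) {
  k <- which.max(x$f_FL_kmc)
  tibble(
    peak_L = x$L[k], peak_f_FL = x$f_FL_kmc[k],
    max_solver_diff = max(abs(x$f_FL_kmc - x$f_FL_preeq)),
    n_L = nrow(x), t_incubation = attr(x, "t_incubation"))
}

#' Tidy a mechanism report into its per-contact table
#'
#' @param x a `mechanism_report`.
#' @param ... unused.
#' @return tibble (`i`, `j`, `p_q_tp`, `p_q_nn`, `p_tp_given_q`).
#' @method tidy mechanism_report
#' @export
tidy.mechanism_report <- function(x, ...) {
  x$contacts
}
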