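# Transition-path statistics: TP extraction, phi-values, and conditional
# contact importance p(TP|q_ij)_nn.

#' Construct a transition-path ensemble
#'
#' Container for labelled frames (`TP`, `unfolded`, `folded`) with
#' per-contact binary formation states. Folded frames are carried but
#' excluded from all nonnative ("nn") statistics.
#'
#' @param frames tibble with columns `frame`, `label`, `segment`, `Q`.
#' @param states integer matrix, frames x contacts, of 0/1 formation
#'   states.
#' @param contacts tibble (`i`, `j`, `r0`, ...) identifying each contact
#'   column.
#' @param direction `"folding"` or `"unfolding"` (the harvest direction).
#' @param t_tp optional mean transition-path time (same time units as the
#'   MFPTs used downstream).
#' @param provenance free-form list.
#' @param truth optional analytic ground truth (synthetic ensembles).
#' @return object of class `tp_ensemble`.
#' @export
tp_ensemble <- function(frames, states, contacts,
                        direction = c("folding", "unfolding"), t_tp = NULL,
                        provenance = list(), truth = NULL) {
  direction <- match.arg(direction)
  stopifnot(nrow(frames) == nrow(states), ncol(states) == nrow(contacts))
  if (!all(frames$label %in% c("TP", "unfolded", "folded"))) {
    abort("frame labels must be TP, unfolded or folded")
  }
  structure(list(frames = frames, states = states, contacts = contacts,
                 direction = direction, t_tp = t_tp,
                 n_tp = length(unique(frames$segment[frames$label == "TP"])),
                 provenance = provenance, truth = truth),
            class = "tp_ensemble")
}

#' @export
print.tp_ensemble <- function(x, ...) {
  cat("<tp_ensemble> ", nrow(x$frames), " frames (",
      sum(x$frames$label == "TP"), " TP, ",
      sum(x$frames$label == "unfolded"), " unfolded, ",
      sum(x$frames$label == "folded"), " folded), ",
      x$n_tp, " TPs, ", nrow(x$contacts), " contacts, ",
      x$direction, " harvest\n", sep = "")
  invisible(x)
}

#' Extract transition paths from a Q time series
#'
#' A folding TP runs from the last frame with Q < `q_low` before a barrier
#' crossing to the first frame with Q > `q_high` (thresholds reversed for
#' unfolding). Segments are maximal and non-overlapping; a trajectory that
#' never crosses both thresholds yields no TPs.
#'
#' @param trajectory a `cg_trajectory`, or a numeric Q series.
#' @param q_low,q_high unfolded/folded thresholds (defaults 0.3, 0.7).
#' @param direction `"folding"` or `"unfolding"`.
#' @return tibble (`start`, `end`) of frame indices (inclusive, both
#'   endpoints part of the TP).
#' @export
extract_tps <- function(trajectory, q_low = 0.3, q_high = 0.7,
                        direction = c("folding", "unfolding")) {
  direction <- match.arg(direction)
  q <- if (inherits(trajectory, "cg_trajectory")) trajectory$frames$Q
       else as.numeric(trajectory)
  if (direction == "unfolding") {
    # mirror: unfolding TPs run from last Q > q_high to first Q < q_low
    q <- 1 - q
    tmp <- q_low
    q_low <- 1 - q_high
    q_high <- 1 - tmp
  }
  out <- list()
  last_low <- NA_integer_
  for (k in seq_along(q)) {
    if (q[k] < q_low) {
      last_low <- k
    } else if (q[k] > q_high) {
      if (!is.na(last_low)) {
        out[[length(out) + 1]] <- tibble(start = last_low, end = k)
        last_low <- NA_integer_
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  dplyr::bind_rows(out)
}

#' Binary contact formation states of trajectory frames
#'
#' A contact is formed when `r_ij < lambda * r0_ij` (strict inequality;
#' a pair exactly at the boundary is not formed), the same midpoint as the
#' smooth switching function of Q.
#'
#' @param positions frames x beads x 3 array (e.g. a trajectory's
#'   `positions`), or a single n x 3 matrix.
#' @param contacts tibble with `i`, `j` (bead indices into the position
#'   array's second dimension) and `r0`.
#' @param lambda contact-width factor (default 1.2).
#' @return integer matrix frames x contacts of 0/1 states.
#' @export
contact_states <- function(positions, contacts, lambda = 1.2) {
  if (is.matrix(positions)) {
    positions <- array(positions, dim = c(1, dim(positions)))
  }
  nf <- dim(positions)[1]
  nc <- nrow(contacts)
  st <- matrix(0L, nf, nc)
  for (k in seq_len(nc)) {
    d <- positions[, contacts$i[k], , drop = FALSE] -
      positions[, contacts$j[k], , drop = FALSE]
    r <- sqrt(rowSums(matrix(d, nrow = nf)^2))
    st[, k] <- as.integer(r < lambda * contacts$r0[k])
  }
  st
}

#' Build a TP ensemble from simulated trajectories
#'
#' Labels every frame of each trajectory (TP per [extract_tps()]; otherwise
#' `folded` when Q > `q_high`, else `unfolded`), computes binary contact
#' states, and pools across trajectories. For folding harvests only the
#' portion of each trajectory up to its first folding event contributes
#' nonnative frames.
#'
#' @param trajectories list of `cg_trajectory` objects run with
#'   `record_positions = TRUE`.
#' @param contacts contact tibble (`i`, `j`, `r0`) in mobile-bead indexing.
#' @param q_low,q_high TP thresholds.
#' @param direction harvest direction.
#' @param lambda contact-formation criterion factor.
#' @return a `tp_ensemble`; `t_tp` is the mean TP duration in ps.
#' @export
tp_ensemble_from_trajectories <- function(trajectories, contacts,
                                          q_low = 0.3, q_high = 0.7,
                                          direction = c("folding", "unfolding"),
                                          lambda = 1.2) {
  direction <- match.arg(direction)
  frames_all <- list()
  states_all <- list()
  seg_counter <- 0L
  tp_times <- numeric(0)
  for (tr in trajectories) {
    if (is.null(tr$positions)) {
      abort("trajectories must be run with record_positions = TRUE")
    }
    q <- tr$frames$Q
    tps <- extract_tps(q, q_low, q_high, direction)
    lab <- ifelse(q > q_high, "folded", "unfolded")
    seg <- integer(length(q))
    for (s in seq_len(nrow(tps))) {
      idx <- tps$start[s]:tps$end[s]
      lab[idx] <- "TP"
      seg_counter <- seg_counter + 1L
      seg[idx] <- seg_counter
      tp_times <- c(tp_times, tr$frames$t[tps$end[s]] - tr$frames$t[tps$start[s]])
    }
    keep <- rep(TRUE, length(q))
    if (direction == "folding") {
      # nonnative statistics use the trajectory only up to the first
      # folding event; later frames would double-count the folded basin
      first_fold <- which(q > q_high)[1]
      if (!is.na(first_fold)) keep <- seq_along(q) <= first_fold
    }
    st <- contact_states(tr$positions, contacts, lambda)
    frames_all[[length(frames_all) + 1]] <-
      tibble(frame = which(keep), label = lab[keep], segment = seg[keep],
             Q = q[keep])
    states_all[[length(states_all) + 1]] <- st[keep, , drop = FALSE]
  }
  tp_ensemble(dplyr::bind_rows(frames_all), do.call(rbind, states_all),
              contacts, direction = direction,
              t_tp = if (length(tp_times) > 0) mean(tp_times) else NULL,
              provenance = list(n_trajectories = length(trajectories),
                                q_low = q_low, q_high = q_high,
                                lambda = lambda))
}

.p_q_tp <- function(ensemble) {
  tp <- ensemble$frames$label == "TP"
  if (!any(tp)) abort("ensemble contains no transition-path frames")
  colMeans(ensemble$states[tp, , drop = FALSE])
}

#' Per-residue phi-values from transition paths
#'
#' `phi(i)` is approximated by the mean, over residue i's native contacts,
#' of each contact's formation frequency on transition paths. Residues with
#' no native contacts are reported as missing (absent rows), never
#' zero-filled.
#'
#' @param ensemble a `tp_ensemble`.
#' @return tibble (`residue`, `phi`, `n_contacts`).
#' @export
phi_values <- function(ensemble) {
  pq <- .p_q_tp(ensemble)
  con <- ensemble$contacts
  residues <- sort(unique(c(con$i, con$j)))
  rows <- lapply(residues, function(r) {
    ks <- which(con$i == r | con$j == r)
    tibble(residue = r, phi = mean(pq[ks]), n_contacts = length(ks))
  })
  dplyr::bind_rows(rows)
}

#' Fraction of nonnative frames on transition paths
#'
#' For a folding harvest, `p(TP)_nn = 2 t_TP / (2 t_TP + t_F^mfpt)`; for an
#' unfolding harvest, `p(TP)_nn = 2 t_TP / (2 t_TP + (p_U/p_F) t_U^mfpt)`
#' with the equilibrium populations taken from umbrella sampling.
#'
#' @param t_tp mean transition-path time.
#' @param mfpt mean first-passage time (folding MFPT for folding harvests,
#'   unfolding MFPT for unfolding harvests; same time units as `t_tp`).
#' @param harvest `"folding"` or `"unfolding"`.
#' @param p_u,p_f equilibrium populations (unfolding harvest only).
#' @return p(TP)_nn in \[0, 1\].
#' @export
p_tp_nn <- function(t_tp, mfpt, harvest = c("folding", "unfolding"),
                    p_u = NULL, p_f = NULL) {
  harvest <- match.arg(harvest)
  if (is.null(t_tp) || is.null(mfpt)) {
    abort("both t_tp and mfpt are required (ensemble lacks a TP time?)")
  }
  if (t_tp < 0 || mfpt <= 0) abort("times must be positive")
  if (harvest == "folding") {
    2 * t_tp / (2 * t_tp + mfpt)
  } else {
    if (is.null(p_u) || is.null(p_f)) {
      abort("unfolding harvest requires p_u and p_f")
    }
    if (p_f <= 0) abort("p_f must be positive for an unfolding harvest")
    2 * t_tp / (2 * t_tp + (p_u / p_f) * mfpt)
  }
}

#' Conditional contact importance p(TP | q_ij)_nn
#'
#' Bayes inversion of the TP contact frequencies:
#' `p(TP|q)_nn = p(q|TP) p(TP)_nn / p(q)_nn`, computed over nonnative
#' frames only. For folding harvests `p(q)_nn` is the pooled nonnative
#' formation frequency; for unfolding harvests it is reconstructed as the
#' `p(TP)_nn`-weighted mixture of the TP and unfolded formation
#' frequencies. Values are clipped at 1 (with a warning) when sampling
#' noise pushes them above; contacts never formed in nonnative frames are
#' undefined (`NA`).
#'
#' @param ensemble a `tp_ensemble`.
#' @param p_tp_nn the fraction of nonnative frames on TPs (see
#'   [p_tp_nn()]).
#' @return tibble (`i`, `j`, `p_q_tp`, `p_q_nn`, `p_tp_given_q`).
#' @export
p_tp_given_q <- function(ensemble, p_tp_nn) {
  pq_tp <- .p_q_tp(ensemble)
  unf <- ensemble$frames$label == "unfolded"
  tp <- ensemble$frames$label == "TP"
  if (ensemble$direction == "unfolding") {
    pq_u <- colMeans(ensemble$states[unf, , drop = FALSE])
    pq_nn <- p_tp_nn * pq_tp + (1 - p_tp_nn) * pq_u
  } else {
    nn <- unf | tp
    pq_nn <- colMeans(ensemble$states[nn, , drop = FALSE])
  }
  val <- ifelse(pq_nn > 0, pq_tp * p_tp_nn / pq_nn, NA_real_)
  if (any(val > 1 + 1e-12, na.rm = TRUE)) {
    warn("p(TP|q)_nn exceeded 1 for some contacts (sampling noise); clipped")
  }
  val <- pmin(val, 1)
  tibble(i = ensemble$contacts$i, j = ensemble$contacts$j,
         p_q_tp = pq_tp, p_q_nn = pq_nn, p_tp_given_q = val)
}

#' Compare computed and reference phi-values
#'
#' Restricts the reference set to strongly destabilizing mutations
#' (|ddG| > `ddg_filter`), joins by residue, and reports the Spearman rank
#' correlation. With fewer than 3 surviving pairs the correlation is
#' undefined (`NA`).
#'
#' @param phi computed phi tibble (`residue`, `phi`).
#' @param reference tibble (`residue`, `phi_exp`, `ddG`); `ddG` in kJ/mol.
#' @param ddg_filter |ddG| threshold, kJ/mol (default 7).
#' @return list(`spearman`, `n`, `pairs`).
#' @export
compare_phi <- function(phi, reference, ddg_filter = 7) {
  stopifnot(all(c("residue", "phi_exp", "ddG") %in% names(reference)))
  ref <- reference[abs(reference$ddG) > ddg_filter, ]
  pairs <- dplyr::inner_join(phi, ref, by = "residue")
  r <- if (nrow(pairs) >= 3) {
    cor(pairs$phi, pairs$phi_exp, method = "spearman")
  } else NA_real_
  list(spearman = r, n = nrow(pairs), pairs = pairs)
}

#' Full mechanism report for a TP ensemble
#'
#' Bundles phi-values, per-contact importance statistics and the TP-time
#' bookkeeping into one object, with contacts ranked by `p_tp_given_q`
#' (ties broken lexicographically by (i, j)).
#'
#' @param ensemble a `tp_ensemble`.
#' @param mfpt mean first-passage time matching the harvest direction.
#' @param p_u,p_f equilibrium populations (unfolding harvests).
#' @return object of class `mechanism_report` with elements `phi`,
#'   `contacts`, `p_tp_nn`, `t_tp`, `ranking`.
#' @export
mechanism_report <- function(ensemble, mfpt, p_u = NULL, p_f = NULL) {
  ptp <- p_tp_nn(ensemble$t_tp, mfpt, harvest = ensemble$direction,
                 p_u = p_u, p_f = p_f)
  con <- p_tp_given_q(ensemble, ptp)
  ranking <- con[order(-con$p_tp_given_q, con$i, con$j), ]
  structure(list(phi = phi_values(ensemble), contacts = con,
                 p_tp_nn = ptp, t_tp = ensemble$t_tp, mfpt = mfpt,
                 ranking = ranking),
            class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat("<mechanism_report> ", nrow(x$phi), " residues, ",
      nrow(x$contacts), " contacts, p(TP)_nn = ", signif(x$p_tp_nn, 3),
      "\n", sep = "")
  invisible(x)
}

#' Top-k most important contacts
#'
#' @param report a `mechanism_report`.
#' @param k number of contacts (default 10).
#' @return tibble of the k highest-p(TP|q)_nn contacts.
#' @export
top_contacts <- function(report, k = 10) {
  head(report$ranking[!is.na(report$ranking$p_tp_given_q), ], k)
}
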