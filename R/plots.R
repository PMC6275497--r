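# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_errorbar labs theme_minimal scale_y_continuous sec_axis
NULL

#' Plot a free-energy profile G(Q)
#'
#' @param object a `free_energy_profile` from [wham()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot free_energy_profile
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  df <- as_tibble(object)[!is.na(object$G), ]
  ggplot(df, aes(x = .data$Q, y = .data$G)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "fraction of native contacts Q", y = "G(Q) [kJ/mol]") +
    theme_minimal()
}

#' Plot folded population and state forces against linker length
#'
#' @param object an `equilibrium_summary`.
#' @param ... unused.
#' @return a ggplot of F_u(L) (open), F_f(L) (filled) and P_f(L).
#' @method autoplot equilibrium_summary
#' @export
autoplot.equilibrium_summary <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(df, c("F_u_pN", "F_f_pN"),
                              names_to = "state", values_to = "F_pN")
  long$state <- ifelse(long$state == "F_u_pN", "unfolded (F_u)", "folded (F_f)")
  fmax <- max(long$F_pN, na.rm = TRUE)
  ggplot(long, aes(x = .data$L)) +
    geom_line(aes(y = .data$F_pN, linetype = .data$state)) +
    geom_point(aes(y = .data$F_pN, shape = .data$state)) +
    ggplot2::scale_shape_manual(values = c("unfolded (F_u)" = 1,
                                           "folded (F_f)" = 16)) +
    geom_line(aes(y = .data$P_f * fmax), colour = "cyan3") +
    scale_y_continuous(
      name = "mean tether force [pN]",
      sec.axis = sec_axis(~ . / fmax, name = "folded population P_f")) +
    labs(x = "linker length L [residues]") +
    theme_minimal()
}

#' Plot a predicted force profile f_FL(L)
#'
#' @param object a `force_profile`.
#' @param experimental optional experimental tibble (`L`, `f_FL`).
#' @param ... unused.
#' @return a ggplot comparing the full-kinetic and preequilibrium
#'   solutions (and experiment, when given).
#' @method autoplot force_profile
#' @export
autoplot.force_profile <- function(object, experimental = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$L)) +
    geom_line(aes(y = .data$f_FL_kmc, colour = "full kinetic scheme")) +
    geom_point(aes(y = .data$f_FL_kmc, colour = "full kinetic scheme")) +
    geom_errorbar(aes(ymin = .data$f_FL_kmc - .data$f_FL_se,
                      ymax = .data$f_FL_kmc + .data$f_FL_se,
                      colour = "full kinetic scheme"), width = 0.3) +
    geom_line(aes(y = .data$f_FL_preeq, colour = "preequilibrium")) +
    geom_point(aes(y = .data$f_FL_preeq, colour = "preequilibrium"),
               shape = 17) +
    labs(x = "linker length L [residues]", y = "fraction full-length f_FL",
         colour = NULL) +
    ggplot2::ylim(0, 1) +
    theme_minimal()
  if (!is.null(experimental)) {
    p <- p + geom_point(data = experimental,
                        aes(y = .data$f_FL, colour = "experiment"),
                        shape = 15)
  }
  p
}

#' Plot per-residue phi-values
#'
#' @param phi tibble (`residue`, `phi`) from [phi_values()].
#' @param reference optional tibble (`residue`, `phi_exp`).
#' @return a ggplot.
#' @export
plot_phi <- function(phi, reference = NULL) {
  p <- ggplot(phi, aes(x = .data$residue, y = .data$phi)) +
    geom_line() +
    geom_point() +
    labs(x = "residue", y = expression(phi)) +
    ggplot2::ylim(0, 1) +
    theme_minimal()
  if (!is.null(reference)) {
    p <- p + geom_point(data = reference,
                        aes(y = .data$phi_exp), colour = "red", shape = 15)
  }
  p
}
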