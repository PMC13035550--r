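#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_line geom_point
#'   geom_col geom_hline facet_wrap labs theme_bw
NULL

#' @export
ggplot2::autoplot

#' Plot a simulated cardiac cycle
#'
#' Pressure-volume loops for both ventricles plus pressure time courses.
#'
#' @param object An `rh_cycle`.
#' @param what `"loops"` or `"signals"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rh_cycle <- function(object, what = c("loops", "signals"), ...) {
  what <- match.arg(what)
  df <- as_tibble(object)
  if (what == "loops") {
    loops <- dplyr::bind_rows(
      tibble(ventricle = "LV", V = df$V_LV, P = df$P_LV),
      tibble(ventricle = "RV", V = df$V_RV, P = df$P_RV))
    ggplot(loops, aes(.data$V, .data$P)) +
      geom_path() +
      facet_wrap(~ventricle, scales = "free") +
      labs(x = "Volume (uL)", y = "Pressure (mmHg)") +
      theme_bw()
  } else {
    sig <- tidyr::pivot_longer(
      df[c("t", "P_LV", "P_RV", "P_SA", "P_PA")],
      -"t", names_to = "signal", values_to = "value")
    ggplot(sig, aes(.data$t, .data$value, colour = .data$signal)) +
      geom_line() +
      labs(x = "Time (s)", y = "Pressure (mmHg)") +
      theme_bw()
  }
}

#' Plot a force-pCa curve
#'
#' @param object An `rh_forcepca` tibble.
#' @param ... Unused.
#' @return A ggplot object (pCa axis reversed, as conventional).
#' @export
autoplot.rh_forcepca <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$pCa, .data$force_kPa)) +
    geom_line() +
    geom_point() +
    ggplot2::scale_x_reverse() +
    labs(x = "pCa", y = "Steady active stress (kPa)") +
    theme_bw()
}

#' Plot a sensitivity ranking
#'
#' Normalized per-animal sensitivities with the influence threshold.
#'
#' @param object An `rh_ranking` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rh_ranking <- function(object, ...) {
  df <- as_tibble(object)
  ord <- dplyr::distinct(df, .data$parameter, .data$rank)
  df$parameter <- factor(df$parameter,
                         levels = ord$parameter[order(ord$rank)])
  ggplot(df, aes(.data$parameter, .data$normalized)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = attr(object, "threshold"), linetype = 2) +
    labs(x = NULL, y = "Normalized sensitivity") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot linear-discriminant projections
#'
#' @param object An `rh_lda` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rh_lda <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(.data$projection, .data$feature_set, colour = .data$label)) +
    geom_point(alpha = 0.7,
               position = ggplot2::position_jitter(height = 0.1)) +
    labs(x = "LDA projection", y = NULL, colour = "condition") +
    theme_bw()
}
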