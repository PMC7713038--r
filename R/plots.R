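# Diagnostic plots (ggplot2, in Suggests).

#' Plot the mediolateral reaction force over time
#'
#' One panel per simulated angle; the dashed line marks zero reaction force
#' (loss of lateral support from the medial ridge).
#'
#' @param x A \code{simulation_result}, or a \code{sweep_result} run with
#'   \code{keep_results = TRUE}.
#' @return A ggplot object.
#' @export
plot_rcforce <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- rcforce_frame(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$rcforce_kN)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~aldfa, scales = "free_y") +
    ggplot2::labs(x = "time (s)",
                  y = "mediolateral reaction force (kN)") +
    ggplot2::theme_minimal()
}

#' Plot the 3D patellar displacement as plane projections
#'
#' Mediolateral vs craniocaudal and mediolateral vs proximodistal
#' projections of the patellar path relative to the displacement origin
#' (negative x = medial).
#'
#' @inheritParams plot_rcforce
#' @return A ggplot object.
#' @export
plot_displacement <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- displacement_frame(x)
  long <- rbind(
    data.frame(aldfa = df$aldfa, x = df$dx, y = df$dy,
               plane = "craniocaudal vs mediolateral"),
    data.frame(aldfa = df$aldfa, x = df$dx, y = df$dz,
               plane = "proximodistal vs mediolateral"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$aldfa)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~plane) +
    ggplot2::labs(x = "mediolateral displacement (mm, + lateral)",
                  y = "displacement (mm)", colour = "aLDFA") +
    ggplot2::theme_minimal()
}

rcforce_frame <- function(x) {
  if (inherits(x, "simulation_result")) {
    s <- mediolateral_reaction_series(x)
    s$aldfa <- factor(format_angle(x$aldfa_deg))
    return(s)
  }
  if (inherits(x, "sweep_result") && !is.null(x$results))
    return(do.call(rbind, lapply(x$results, function(r) {
      s <- mediolateral_reaction_series(r)
      s$aldfa <- factor(format_angle(r$aldfa_deg))
      s
    })))
  stop("need a simulation_result or a sweep_result with keep_results = TRUE")
}

displacement_frame <- function(x) {
  one <- function(r) {
    data.frame(aldfa = factor(format_angle(r$aldfa_deg)),
               dx = r$samples$pos_x_mm - r$displacement_origin[1],
               dy = r$samples$pos_y_mm - r$displacement_origin[2],
               dz = r$samples$pos_z_mm - r$displacement_origin[3])
  }
  if (inherits(x, "simulation_result")) return(one(x))
  if (inherits(x, "sweep_result") && !is.null(x$results))
    return(do.call(rbind, lapply(x$results, one)))
  stop("need a simulation_result or a sweep_result with keep_results = TRUE")
}
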