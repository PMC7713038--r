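# Luxation detection from the simulated reaction-force and displacement
# time series, and the aLDFA sweep.

#' Mediolateral patellofemoral reaction force series
#'
#' The x-component (mediolateral, + lateral) of the total contact force the
#' femur exerts on the patella: positive while the medial trochlear ridge
#' presses the patella laterally, zero without contact, and negative once
#' the contact geometry has reversed (the patella bearing on the outer face
#' of the ridge after leaving the groove).
#'
#' @param result A \code{simulation_result}.
#' @return data.frame with \code{time_s} and \code{rcforce_kN}.
#' @export
mediolateral_reaction_series <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  data.frame(time_s = result$samples$time_s,
             rcforce_kN = result$samples$rcforce_x_kN)
}

#' Detect patellar luxation in a simulation result
#'
#' Dual criterion: the run is luxated if, after the activation ramp, the
#' mediolateral reaction force drops to zero or below and stays there for at
#' least \code{sustain_window} seconds (separating true luxation from
#' transient rebound episodes), and the patella has displaced past the
#' ridge apex on the corresponding side. \code{first_zero_time} records the
#' first post-ramp zero touch of the reaction force (possibly a transient);
#' \code{onset_time} is the start of the first sustained episode during
#' which the displacement criterion is met.
#'
#' @param result A \code{simulation_result}, covering the full protocol.
#' @param sustain_window Minimum duration of the non-positive episode,
#'   seconds.
#' @param zero_tol Force tolerance for "zero", kN.
#' @return A \code{luxation_report}: list with \code{luxated},
#'   \code{onset_time}, \code{first_zero_time}, \code{direction}
#'   ("medial"/"lateral"/"none"), \code{max_medial_displacement} (mm,
#'   positive medial excursion relative to the displacement origin) and
#'   \code{aldfa_deg}.
#' @export
detect_luxation <- function(result, sustain_window = 0.5, zero_tol = 1e-9) {
  stopifnot(inherits(result, "simulation_result"))
  s <- result$samples
  total <- result$config$simulation$total_time %||% max(s$time_s)
  if (max(s$time_s) < total - 1e-9)
    stop("result does not cover the full protocol duration")
  ramp_end <- result$config$simulation$ramp_end %||% 5
  post <- s$time_s >= ramp_end
  t <- s$time_s[post]
  rc <- s$rcforce_x_kN[post]
  disp_x <- s$pos_x_mm[post] - result$displacement_origin[1]

  ## escape thresholds: ridge apex positions on either side of the groove
  w_neg <- result$profile$w_neg
  w_pos <- result$profile$w_pos

  ## A medial luxation shows as the loss of the lateral support of the
  ## medial ridge: rcforce sustained <= 0 with displacement past the medial
  ## apex. The mirror image (valgus geometry) shows as rcforce sustained
  ## >= 0 with displacement past the lateral apex; both are detected so
  ## that sagittal mirroring maps one onto the other.
  episode_onset <- function(flags, escaped) {
    runs <- rle(flags)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      i0 <- starts[k]; i1 <- ends[k]
      ## an episode running to the end of the protocol counts as sustained
      sustained <- (t[i1] - t[i0]) >= sustain_window || i1 == length(t)
      if (sustained && escaped(i0)) return(t[i0])
    }
    NULL
  }
  nonpos <- rc <= zero_tol
  nonneg <- rc >= -zero_tol
  onset_med <- episode_onset(nonpos,
                             function(i0) min(disp_x[i0:length(t)]) < -w_neg)
  onset_lat <- episode_onset(nonneg,
                             function(i0) max(disp_x[i0:length(t)]) > w_pos)
  if (!is.null(onset_med) && (is.null(onset_lat) || onset_med <= onset_lat)) {
    onset_time <- onset_med; direction <- "medial"
  } else if (!is.null(onset_lat)) {
    onset_time <- onset_lat; direction <- "lateral"
  } else {
    onset_time <- NULL; direction <- "none"
  }
  first_zero_time <- if (identical(direction, "lateral")) {
    if (any(nonneg)) t[which(nonneg)[1]] else NULL
  } else {
    if (any(nonpos)) t[which(nonpos)[1]] else NULL
  }
  structure(list(
    luxated = !is.null(onset_time),
    onset_time = onset_time,
    first_zero_time = first_zero_time,
    direction = direction,
    max_medial_displacement = max(0, -min(disp_x)),
    max_lateral_displacement = max(0, max(disp_x)),
    aldfa_deg = result$aldfa_deg
  ), class = "luxation_report")
}

#' @export
print.luxation_report <- function(x, ...) {
  cat(sprintf("<luxation_report: aLDFA %.1f deg -> %s>\n", x$aldfa_deg,
              if (x$luxated) sprintf("LUXATED (%s) at %.2f s", x$direction,
                                     x$onset_time)
              else "stable"))
  if (!is.null(x$first_zero_time))
    cat(sprintf("  first rcforce zero touch: %.2f s\n", x$first_zero_time))
  cat(sprintf("  max medial displacement: %.2f mm\n",
              x$max_medial_displacement))
  invisible(x)
}

#' Sweep the varus deformity over a set of aLDFA angles
#'
#' Builds the reference stifle once, bends it at the CORA to each target
#' angle, runs the full loading protocol and applies the luxation criterion.
#' Per-angle results are identical whether an angle is run alone or within
#' the sweep; single-run failures are recorded per angle and the sweep
#' continues.
#'
#' @param angles Degrees; default the thirteen-angle study set
#'   \code{c(95, 98, 100:110)}.
#' @param params A \code{\link{geometry_params}} describing the reference
#'   geometry.
#' @param sim_config,muscle_params,contact Model parameters.
#' @param sustain_window Passed to \code{\link{detect_luxation}}.
#' @param keep_results Keep the full per-angle \code{simulation_result}s
#'   (memory-heavy); reports are always kept.
#' @param verbose Print one line per angle.
#' @return A \code{sweep_result}: list with \code{reports} (per angle),
#'   \code{critical_angle}, \code{stable_max_angle}, \code{angles},
#'   \code{errors}, and optionally \code{results}.
#' @export
sweep_aldfa <- function(angles = default_sweep_angles(),
                        params = geometry_params(),
                        sim_config = simulation_config(),
                        muscle_params = hill_muscle_params(),
                        contact = contact_params(),
                        sustain_window = 0.5,
                        keep_results = FALSE,
                        verbose = FALSE) {
  if (!length(angles)) stop("angles must be non-empty")
  angles <- sort(unique(angles))
  base <- build_reference_stifle(params)
  reports <- list()
  results <- list()
  errors <- list()
  for (ang in angles) {
    key <- format_angle(ang)
    res <- tryCatch({
      g <- bend_at_cora(base, ang)
      run_simulation(g, sim_config, muscle_params, contact)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
      reports[[key]] <- NULL
      if (verbose) message(sprintf("aLDFA %s: FAILED (%s)", key,
                                   conditionMessage(res)))
      next
    }
    rep <- detect_luxation(res, sustain_window = sustain_window)
    reports[[key]] <- rep
    if (keep_results) results[[key]] <- res
    if (verbose)
      message(sprintf("aLDFA %s: %s", key,
                      if (rep$luxated) sprintf("luxated (%s) at %.2f s",
                                               rep$direction, rep$onset_time)
                      else "stable"))
  }
  lux <- vapply(reports, function(r) isTRUE(r$luxated), logical(1))
  lux_angles <- as.numeric(names(reports))[lux]
  stable_angles <- as.numeric(names(reports))[!lux]
  structure(list(
    angles = angles,
    reports = reports,
    critical_angle = if (any(lux)) min(lux_angles) else NULL,
    stable_max_angle = if (any(!lux)) max(stable_angles) else NULL,
    errors = errors,
    results = if (keep_results) results else NULL
  ), class = "sweep_result")
}

#' The default thirteen-angle study set
#' @return \code{c(95, 98, 100:110)} degrees.
#' @export
default_sweep_angles <- function() c(95, 98, 100:110)

format_angle <- function(ang) {
  if (abs(ang - round(ang)) < 1e-9) sprintf("%d", as.integer(round(ang)))
  else sprintf("%g", ang)
}

#' Critical and maximum-stable aLDFA of a sweep
#'
#' \code{critical_angle}: the minimum angle whose run luxated (NULL when all
#' runs are stable); \code{stable_max_angle}: the maximum angle whose run
#' stayed seated for the whole protocol (NULL when none did).
#'
#' @param sweep A \code{sweep_result}.
#' @return Degrees, or NULL.
#' @export
critical_angle <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  sweep$critical_angle
}

#' @rdname critical_angle
#' @export
stable_max_angle <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  sweep$stable_max_angle
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %d angles>\n", length(x$angles)))
  for (key in names(x$reports)) {
    r <- x$reports[[key]]
    cat(sprintf("  aLDFA %s: %s\n", key,
                if (isTRUE(r$luxated))
                  sprintf("luxated (%s), onset %.2f s", r$direction,
                          r$onset_time)
                else "stable"))
  }
  for (key in names(x$errors))
    cat(sprintf("  aLDFA %s: FAILED (%s)\n", key, x$errors[[key]]))
  cat(sprintf("  critical aLDFA: %s | max stable aLDFA: %s\n",
              x$critical_angle %||% "none", x$stable_max_angle %||% "none"))
  invisible(x)
}

#' Published luxation onset times (reference context)
#'
#' Onset times reported by the original CT-geometry finite-element study
#' that this simulator emulates at desk scale. They depend on that study's
#' subject-specific meshes and are shipped for context only; this package
#' does not attempt to reproduce them (see the methods vignette).
#'
#' @return data.frame with \code{aldfa_deg} and \code{onset_s}.
#' @export
luxation_reference_times <- function() {
  path <- system.file("extdata", "reference_onset_times.csv",
                      package = "stiflesim", mustWork = TRUE)
  utils::read.csv(path)
}
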