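#' Anterior-posterior range of a sway series
#'
#' Maximum minus minimum of the series restricted to the stable window
#' (default 30-60 s, presuming a 60-s run; pass `window = c(1, 5)` for
#' short optimization trials).
#'
#' @param time Time grid, s.
#' @param series Displacement series, m.
#' @param window Length-2 `(t_start, t_end)`, s.
#' @return Range in m.
#' @export
ap_range <- function(time, series, window = c(30, 60)) {
  if (window[1] < min(time) - 1e-9 || window[2] > max(time) + 1e-9)
    stop("window lies outside the recorded series")
  sel <- time >= window[1] - 1e-12 & time <= window[2] + 1e-12
  diff(range(series[sel]))
}

#' Joint angle correlations over the stable window
#'
#' Pearson correlations of joint-angle pairs (by default hip-knee,
#' hip-ankle and knee-ankle on the right side of a full plant; joint names
#' are matched as substrings of the trial's joint names).
#'
#' @param trial A `stance_trial`.
#' @param pairs List of length-2 character vectors of joint names.
#' @param window Length-2 window, s.
#' @return Named numeric vector of correlation coefficients (`NA` with a
#'   warning for zero-variance series).
#' @export
joint_correlations <- function(trial,
                               pairs = list(c("hip", "knee"),
                                            c("hip", "ankle"),
                                            c("knee", "ankle")),
                               window = c(30, 60)) {
  if (window[1] < min(trial$time) - 1e-9 || window[2] > max(trial$time) + 1e-9)
    stop("window lies outside the recorded trial")
  sel <- trial$time >= window[1] - 1e-12 & trial$time <= window[2] + 1e-12
  find_col <- function(jname) {
    hit <- which(colnames(trial$q_deg) == jname)
    if (!length(hit))
      hit <- grep(jname, colnames(trial$q_deg), fixed = TRUE)
    if (!length(hit)) stop("no joint matching '", jname, "' in the trial")
    hit[1]
  }
  out <- vapply(pairs, function(pr) {
    a <- trial$q_deg[sel, find_col(pr[1])]
    b <- trial$q_deg[sel, find_col(pr[2])]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance series; correlation undefined")
      return(NA_real_)
    }
    cor(a, b)
  }, 0)
  names(out) <- vapply(pairs, paste, "", collapse = "-")
  out
}

#' Activation range table
#'
#' Experimental muscle activation ranges (fractions of maximal voluntary
#' contraction) against which simulated window-mean activations are
#' compared.
#'
#' @param muscle Character vector of muscle labels.
#' @param lo,hi Lower and upper range limits in MVC fraction.
#' @param mode Optional mode values (must lie within the range when given).
#' @return A data.frame of class `activation_range_table`.
#' @export
activation_range_table <- function(muscle, lo, hi, mode = NA_real_) {
  stopifnot(length(muscle) == length(lo), length(lo) == length(hi))
  if (any(lo < 0 | hi > 1 | lo > hi))
    stop("need 0 <= lo <= hi <= 1 per row")
  if (any(!is.na(mode) & (mode < lo | mode > hi)))
    stop("mode values must lie within [lo, hi]")
  structure(data.frame(muscle = muscle, lo = lo, hi = hi, mode = mode,
                       stringsAsFactors = FALSE),
            class = c("activation_range_table", "data.frame"))
}

#' Deviation of simulated activations from an experimental range
#'
#' Zero when the window-mean activation lies within the range; the (signed)
#' overshoot above the upper limit, or the (negative) undershoot below the
#' lower limit, otherwise.  Muscles without a table row are reported as
#' `NA` (unevaluated), never as zero.
#'
#' @param a_mean Named numeric vector of window-mean activations.
#' @param table An [activation_range_table()].
#' @return Named numeric vector of deviations.
#' @export
activation_deviation <- function(a_mean, table) {
  i <- match(names(a_mean), table$muscle)
  dev <- ifelse(is.na(i), NA_real_,
                ifelse(a_mean > table$hi[i], a_mean - table$hi[i],
                       ifelse(a_mean < table$lo[i], a_mean - table$lo[i], 0)))
  setNames(as.numeric(dev), names(a_mean))
}

#' CoM phase portrait
#'
#' Pairs the CoM anterior-posterior displacement with its velocity (central
#' differences; one-sided at the ends) for phase-plane plotting.  A bounded
#' closed orbit indicates self-sustained, stable sway.
#'
#' @param trial A `stance_trial`.
#' @param window Optional length-2 window, s.
#' @return A data.frame with columns `time`, `com_x`, `com_vx`.
#' @export
phase_portrait <- function(trial, window = NULL) {
  t <- trial$time; x <- trial$com_x
  n <- length(t)
  v <- numeric(n)
  if (n >= 3) {
    v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    v[1] <- (x[2] - x[1]) / (t[2] - t[1])
    v[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  }
  out <- data.frame(time = t, com_x = x, com_vx = v)
  if (!is.null(window))
    out <- out[out$time >= window[1] & out$time <= window[2], ]
  out
}
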