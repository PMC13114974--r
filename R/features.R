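#' Potential window
#'
#' A half-open-free inclusive window on the potential axis, used to name the
#' feature regions of the fingerprints (e.g. the propionate area window
#' -230 to -30 mV).
#'
#' @param lo,hi window bounds in mV, `lo < hi`.
#' @return An object of class `potential_window`.
#' @export
potential_window <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo < hi)) stop(vg_error("window requires lo < hi", "vg_window_error"))
  structure(list(lo = lo, hi = hi), class = "potential_window")
}

# Accept a voltammogram or a sweep segment (list with potentials/currents),
# returned in recorded order.
.as_trace <- function(x) {
  if (inherits(x, "voltammogram")) {
    list(v = x$potentials, i = x$currents)
  } else if (is.list(x) && !is.null(x$potentials) && !is.null(x$currents)) {
    list(v = as.numeric(x$potentials), i = as.numeric(x$currents))
  } else {
    stop(vg_error("expected a voltammogram or a sweep segment", "vg_params_error"))
  }
}

# Ascending copy of a monotone trace segment.
.ascending <- function(tr) {
  if (tr$v[1] > tr$v[length(tr$v)]) list(v = rev(tr$v), i = rev(tr$i)) else tr
}

.interp_current <- function(tr, v) {
  a <- .ascending(tr)
  stats::approx(a$v, a$i, xout = v, ties = "ordered")$y
}

# Window segment with interpolated endpoint points prepended/appended.
.window_segment <- function(tr, lo, hi) {
  a <- .ascending(tr)
  if (lo < a$v[1] - 1e-9 || hi > a$v[length(a$v)] + 1e-9) {
    stop(vg_error("window outside the trace's potential range", "vg_window_error"))
  }
  inner <- which(a$v > lo & a$v < hi)
  vs <- c(lo, a$v[inner], hi)
  is <- c(.interp_current(a, lo), a$i[inner], .interp_current(a, hi))
  list(v = vs, i = is)
}

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Chord baseline correction over a feature window
#'
#' Subtracts the straight chord joining the trace's (interpolated) values at
#' the window endpoints from the currents inside the window. By
#' construction the residuals at both endpoints are exactly zero, and any
#' affine trace corrects to identically zero.
#'
#' @param vg a `voltammogram` or sweep segment.
#' @param w a [potential_window()] inside the trace's range.
#' @return A list with `potentials` (window grid including the interpolated
#'   endpoints), `residuals` (chord-corrected currents, uA), and `chord`
#'   (the baseline values).
#' @export
baseline_correct <- function(vg, w) {
  stopifnot(inherits(w, "potential_window"))
  seg <- .window_segment(.as_trace(vg), w$lo, w$hi)
  if (length(seg$v) < 2L) {
    stop(vg_error("window covers fewer than 2 points", "vg_window_error"))
  }
  chord <- seg$i[1] + (seg$v - w$lo) / (w$hi - w$lo) * (seg$i[length(seg$i)] - seg$i[1])
  list(potentials = seg$v, residuals = seg$i - chord, chord = chord)
}

#' Baseline-corrected windowed area
#'
#' Trapezoidal integral of the chord-corrected currents over the window,
#' in uA*mV. This is the paper-style area descriptor (B_A1, A_A2, ...).
#'
#' @inheritParams baseline_correct
#' @return Area in uA*mV.
#' @export
area_in_window <- function(vg, w) {
  bc <- baseline_correct(vg, w)
  .trapz(bc$potentials, bc$residuals)
}

#' Characteristic current at a potential
#'
#' Linear interpolation between the bracketing grid points; exact at grid
#' points. For CV pass the designated sweep segment.
#'
#' @param vg a `voltammogram` or sweep segment.
#' @param v query potential in mV, inside the trace range.
#' @return Current in uA.
#' @export
current_at <- function(vg, v) {
  tr <- .ascending(.as_trace(vg))
  if (v < tr$v[1] - 1e-9 || v > tr$v[length(tr$v)] + 1e-9) {
    stop(vg_error("query potential outside trace range", "vg_range_error"))
  }
  .interp_current(tr, v)
}

#' Characteristic potential at a current level
#'
#' Potential of the first crossing of the current level in scan order,
#' linearly interpolated within the bracketing segment. If the trace never
#' crosses the level a `vg_no_crossing` error is raised; the route
#' extractors substitute the potential of maximum current and set a quality
#' flag instead (see [extract_propionate_features()]).
#'
#' @param vg a `voltammogram` or sweep segment (scan order is respected).
#' @param i current level in uA.
#' @return Potential in mV of the first crossing.
#' @export
potential_at_current <- function(vg, i) {
  tr <- .as_trace(vg)
  n <- length(tr$v)
  hit <- which(tr$i == i)
  cross <- which((tr$i[-n] - i) * (tr$i[-1] - i) < 0)
  first_hit <- if (length(hit)) hit[1] else Inf
  first_cross <- if (length(cross)) cross[1] else Inf
  if (is.infinite(first_hit) && is.infinite(first_cross)) {
    stop(vg_error(sprintf("trace never crosses %g uA", i), "vg_no_crossing"))
  }
  if (first_hit <= first_cross) {
    return(tr$v[first_hit])
  }
  k <- first_cross
  f <- (i - tr$i[k]) / (tr$i[k + 1] - tr$i[k])
  tr$v[k] + f * (tr$v[k + 1] - tr$v[k])
}

#' Peak within a potential window
#'
#' Extremum of the recorded currents whose potentials fall inside the
#' window, with ties broken toward the lower potential. A peak sitting on
#' the edge of the window/trace overlap is allowed but flagged as a
#' boundary peak.
#'
#' @param vg a `voltammogram` or sweep segment.
#' @param w a [potential_window()] overlapping the trace.
#' @param sense `"max"` (oxidation/anodic peak) or `"min"` (reduction peak).
#' @return A list with `peak_current` (uA), `peak_potential` (mV) and
#'   logical `boundary`.
#' @export
peak_in_window <- function(vg, w, sense = c("max", "min")) {
  sense <- match.arg(sense)
  stopifnot(inherits(w, "potential_window"))
  tr <- .as_trace(vg)
  idx <- which(tr$v >= w$lo - 1e-9 & tr$v <= w$hi + 1e-9)
  if (!length(idx)) stop(vg_error("window does not overlap the trace", "vg_window_error"))
  vals <- tr$i[idx]
  target <- if (sense == "max") max(vals) else min(vals)
  cand <- idx[vals == target]
  best <- cand[which.min(tr$v[cand])]
  vwin <- tr$v[idx]
  list(peak_current = tr$i[best], peak_potential = tr$v[best],
       boundary = tr$v[best] %in% range(vwin))
}

#' Left half-wave area
#'
#' Integrates the chord-corrected waveform from `w$lo` up to `v_stop`
#' (typically the peak potential), reusing the chord of the full feature
#' window `w` rather than re-anchoring the baseline at `v_stop`. For a
#' symmetric peak centred in `w` this is exactly half the full-window area.
#'
#' @param vg a `voltammogram` or sweep segment.
#' @param w the full feature window whose chord defines the baseline.
#' @param v_stop upper integration limit in mV, `w$lo <= v_stop <= w$hi`.
#' @return Area in uA*mV.
#' @export
half_wave_area <- function(vg, w, v_stop) {
  stopifnot(inherits(w, "potential_window"))
  if (v_stop < w$lo || v_stop > w$hi) {
    stop(vg_error("v_stop must lie inside the feature window", "vg_window_error"))
  }
  if (v_stop == w$lo) return(0)
  bc <- baseline_correct(vg, w)
  keep <- bc$potentials <= v_stop
  vs <- c(bc$potentials[keep], v_stop)
  rs <- c(bc$residuals[keep],
          stats::approx(bc$potentials, bc$residuals, xout = v_stop,
                        ties = "ordered")$y)
  dup <- duplicated(vs)
  .trapz(vs[!dup], rs[!dup])
}

# ---- route extractors -------------------------------------------------------

.pot_at_current_or_peak <- function(tr, level) {
  tryCatch(list(value = potential_at_current(tr, level), flag = FALSE),
           vg_no_crossing = function(e) {
             t2 <- .as_trace(tr)
             list(value = t2$v[which.max(t2$i)], flag = TRUE)
           })
}

#' Propionate-route descriptors
#'
#' Six DPV descriptors from the esterification route, two preparation
#' streams, two replicate scans each: currents at -30 mV on the centrifuged
#' replicates (B_I1, B_I2), potentials at 1000 uA on the noncentrifuged
#' replicates (B_V1, B_V2), and chord-corrected areas over -230 to -30 mV
#' on the noncentrifuged replicates (B_A1, B_A2). The pairing of the 1/2
#' indices with replicate scans is a convention of this package (the
#' descriptor names do not define it); it is controlled by the order of the
#' supplied replicate lists.
#'
#' If a noncentrifuged trace never reaches 1000 uA, the potential of its
#' maximum current is substituted and recorded in the `flags` attribute.
#'
#' @param centrifuged list of two propionate-route DPV voltammograms
#'   (centrifuged stream replicates).
#' @param noncentrifuged list of two propionate-route DPV voltammograms
#'   (noncentrifuged stream replicates).
#' @return An object of class `propionate_features` (named list of the six
#'   descriptors) with a `flags` attribute.
#' @export
extract_propionate_features <- function(centrifuged, noncentrifuged) {
  stopifnot(length(centrifuged) == 2L, length(noncentrifuged) == 2L)
  for (vg in c(centrifuged, noncentrifuged)) {
    if (!inherits(vg, "voltammogram") ||
        vg$params$route != "propionate_esterification") {
      stop(vg_error("all traces must be propionate-route DPV", "vg_params_error"))
    }
  }
  w <- potential_window(-230, -30)
  v1 <- .pot_at_current_or_peak(noncentrifuged[[1]], 1000)
  v2 <- .pot_at_current_or_peak(noncentrifuged[[2]], 1000)
  out <- list(
    B_I1 = current_at(centrifuged[[1]], -30),
    B_I2 = current_at(centrifuged[[2]], -30),
    B_V1 = v1$value,
    B_V2 = v2$value,
    B_A1 = area_in_window(noncentrifuged[[1]], w),
    B_A2 = area_in_window(noncentrifuged[[2]], w)
  )
  if (!all(is.finite(unlist(out)))) {
    stop(vg_error("non-finite propionate descriptor", "vg_numeric_error"))
  }
  flags <- character(0)
  if (v1$flag) flags <- c(flags, "B_V1_no_crossing")
  if (v2$flag) flags <- c(flags, "B_V2_no_crossing")
  structure(out, class = "propionate_features", flags = flags)
}

#' Butyrate-route descriptors
#'
#' Four CV descriptors from the alkaline-dissociation route: the forward
#' (anodic) current at 175 mV (C_I1), the reduction peak current on the
#' reverse sweep (C_I2, a minimum), the forward-sweep potential at 10 uA
#' (C_V1), and the chord-corrected area of the reverse sweep over the
#' descending 500-to-110 mV segment, reported with positive orientation
#' (C_A1). The forward oxidation peak current is also reported separately
#' as `oxidation_peak` since it is described alongside C_I1 in the source
#' protocol but is not part of the modeling four-tuple.
#'
#' @param vg a butyrate-route CV `voltammogram`.
#' @return An object of class `butyrate_features` with a `flags` attribute
#'   and an `oxidation_peak` attribute.
#' @export
extract_butyrate_features <- function(vg) {
  if (!inherits(vg, "voltammogram") ||
      vg$params$route != "butyrate_dissociation") {
    stop(vg_error("expected a butyrate-route CV trace", "vg_params_error"))
  }
  sw <- split_cv_sweeps(vg)
  v1 <- .pot_at_current_or_peak(sw$forward, 10)
  red <- peak_in_window(sw$reverse,
                        potential_window(min(sw$reverse$potentials),
                                         max(sw$reverse$potentials)),
                        sense = "min")
  out <- list(
    C_I1 = current_at(sw$forward, 175),
    C_I2 = red$peak_current,
    C_V1 = v1$value,
    C_A1 = area_in_window(sw$reverse, potential_window(110, 500))
  )
  if (!all(is.finite(unlist(out)))) {
    stop(vg_error("non-finite butyrate descriptor", "vg_numeric_error"))
  }
  ox <- peak_in_window(sw$forward,
                       potential_window(min(sw$forward$potentials),
                                        max(sw$forward$potentials)),
                       sense = "max")
  structure(out, class = "butyrate_features",
            flags = if (v1$flag) "C_V1_no_crossing" else character(0),
            oxidation_peak = ox$peak_current)
}

#' Total-SCFA-route descriptors
#'
#' Five DPV descriptors from the total esterification route. Low-potential
#' region -200 to 100 mV: peak current A_I1, peak potential A_V1, and the
#' left half-wave area A_A1 integrated from -200 mV up to A_V1 using the
#' full-window chord. High-potential region: the characteristic current at
#' 985 mV (A_I2) and the chord-corrected area over 800 to 985 mV (A_A2).
#'
#' @param vg a total-route DPV `voltammogram`.
#' @return An object of class `total_features` with a `flags` attribute.
#' @export
extract_total_features <- function(vg) {
  if (!inherits(vg, "voltammogram") ||
      vg$params$route != "total_esterification") {
    stop(vg_error("expected a total-route DPV trace", "vg_params_error"))
  }
  w1 <- potential_window(-200, 100)
  pk <- peak_in_window(vg, w1, sense = "max")
  out <- list(
    A_I1 = pk$peak_current,
    A_V1 = pk$peak_potential,
    A_A1 = half_wave_area(vg, w1, pk$peak_potential),
    A_I2 = current_at(vg, 985),
    A_A2 = area_in_window(vg, potential_window(800, 985))
  )
  if (!all(is.finite(unlist(out)))) {
    stop(vg_error("non-finite total-SCFA descriptor", "vg_numeric_error"))
  }
  structure(out, class = "total_features",
            flags = if (pk$boundary) "A_V1_boundary_peak" else character(0))
}

#' Assemble the 10-feature cross-information vector
#'
#' Fixed-order concatenation of the six propionate-route and four
#' butyrate-route descriptors, used as the input of the propionate/butyrate
#' network.
#'
#' @param p a `propionate_features` object.
#' @param b a `butyrate_features` object.
#' @return Named numeric vector of length 10 in the order
#'   B_I1, B_I2, B_V1, B_V2, B_A1, B_A2, C_I1, C_I2, C_V1, C_A1.
#' @export
assemble_pb_vector <- function(p, b) {
  stopifnot(inherits(p, "propionate_features"), inherits(b, "butyrate_features"))
  c(B_I1 = p$B_I1, B_I2 = p$B_I2, B_V1 = p$B_V1, B_V2 = p$B_V2,
    B_A1 = p$B_A1, B_A2 = p$B_A2,
    C_I1 = b$C_I1, C_I2 = b$C_I2, C_V1 = b$C_V1, C_A1 = b$C_A1)
}

#' Assemble the 7-feature hierarchical total-SCFA vector
#'
#' The five total-route descriptors followed by the auxiliary predicted
#' propionate (P1) and butyrate (B1) concentrations in mM.
#'
#' @param t a `total_features` object.
#' @param p1,b1 predicted propionate and butyrate in mM (non-negative).
#' @return Named numeric vector of length 7 in the order
#'   A_I1, A_V1, A_A1, A_I2, A_A2, P1, B1.
#' @export
assemble_total_vector <- function(t, p1, b1) {
  stopifnot(inherits(t, "total_features"))
  if (p1 < 0 || b1 < 0) {
    stop(vg_error("auxiliary concentrations must be non-negative",
                  "vg_params_error"))
  }
  c(A_I1 = t$A_I1, A_V1 = t$A_V1, A_A1 = t$A_A1, A_I2 = t$A_I2,
    A_A2 = t$A_A2, P1 = p1, B1 = b1)
}
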