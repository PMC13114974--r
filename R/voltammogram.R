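#' Scan parameters for a voltammetric measurement
#'
#' Describes one potential program: differential pulse voltammetry (DPV) or
#' cyclic voltammetry (CV), together with the pretreatment route the scan
#' belongs to. The three routes pair with fixed techniques: the propionate
#' and total-SCFA esterification routes are read by DPV, the butyrate
#' alkaline-dissociation route by CV.
#'
#' @param technique "DPV" or "CV".
#' @param v_start,v_end start and end potentials in mV; must differ.
#' @param route one of "propionate_esterification", "butyrate_dissociation",
#'   "total_esterification".
#' @param pulse_height,pulse_width,step_height DPV pulse program (mV, ms,
#'   mV); required for DPV, forbidden for CV.
#' @param scan_rate CV scan rate in mV/s; required for CV, forbidden for DPV.
#' @return An object of class `scan_params`.
#' @examples
#' scan_params("DPV", -600, 2000, "propionate_esterification",
#'             pulse_height = 150, pulse_width = 2, step_height = 5)
#' @export
scan_params <- function(technique = c("DPV", "CV"), v_start, v_end, route,
                        pulse_height = NULL, pulse_width = NULL,
                        step_height = NULL, scan_rate = NULL) {
  technique <- match.arg(technique)
  route <- match.arg(route, c("propionate_esterification",
                              "butyrate_dissociation",
                              "total_esterification"))
  stopifnot(is.numeric(v_start), is.numeric(v_end),
            length(v_start) == 1L, length(v_end) == 1L)
  if (v_start == v_end) {
    stop(vg_error("v_start and v_end must differ", "vg_params_error"))
  }
  if (technique == "DPV") {
    if (is.null(pulse_height) || is.null(pulse_width) || is.null(step_height)) {
      stop(vg_error("DPV requires pulse_height, pulse_width and step_height",
                    "vg_params_error"))
    }
    if (!is.null(scan_rate)) {
      stop(vg_error("scan_rate is a CV parameter", "vg_params_error"))
    }
  } else {
    if (is.null(scan_rate)) {
      stop(vg_error("CV requires scan_rate", "vg_params_error"))
    }
    if (!is.null(pulse_height) || !is.null(pulse_width) || !is.null(step_height)) {
      stop(vg_error("pulse parameters are DPV-only", "vg_params_error"))
    }
  }
  expected <- c(propionate_esterification = "DPV",
                butyrate_dissociation = "CV",
                total_esterification = "DPV")
  if (technique != expected[[route]]) {
    stop(vg_error(sprintf("route '%s' is measured by %s, not %s",
                          route, expected[[route]], technique),
                  "vg_params_error"))
  }
  structure(list(technique = technique, v_start = v_start, v_end = v_end,
                 pulse_height = pulse_height, pulse_width = pulse_width,
                 step_height = step_height, scan_rate = scan_rate,
                 route = route),
            class = "scan_params")
}

#' Default scan programs for the three pretreatment routes
#'
#' The published protocols: propionate esterification DPV from -600 to
#' 2000 mV (pulse height 150 mV, pulse width 2 ms, step height 5 mV);
#' butyrate dissociation CV from -600 to 1100 mV at 200 mV/s; total-SCFA
#' esterification DPV from -600 to 1200 mV (pulse height 100 mV, pulse
#' width 50 ms; step height defaults to 5 mV, unstated in the protocol).
#'
#' @param route pretreatment route name.
#' @return A `scan_params` object.
#' @export
default_scan_params <- function(route = c("propionate_esterification",
                                          "butyrate_dissociation",
                                          "total_esterification")) {
  route <- match.arg(route)
  switch(route,
    propionate_esterification = scan_params("DPV", -600, 2000, route,
      pulse_height = 150, pulse_width = 2, step_height = 5),
    butyrate_dissociation = scan_params("CV", -600, 1100, route,
      scan_rate = 200),
    total_esterification = scan_params("DPV", -600, 1200, route,
      pulse_height = 100, pulse_width = 50, step_height = 5))
}

vg_error <- function(msg, class) {
  errorCondition(msg, class = c(class, "vg_error"))
}

#' Construct and validate a voltammogram
#'
#' A voltammogram is one recorded sweep: a potential vector (mV), the
#' matching currents (uA), the scan program, and sample metadata. DPV traces
#' must be strictly monotone in potential; CV traces must have exactly one
#' turning point (forward then reverse sweep). All potentials must lie
#' within the programmed range.
#'
#' @param potentials numeric, mV, in recorded order.
#' @param currents numeric, uA, same length.
#' @param params a [scan_params()] object.
#' @param stream preparation stream: "centrifuged", "noncentrifuged" or
#'   "standard".
#' @param replicate_id small integer distinguishing replicate scans.
#' @param sample_id free-text sample identifier.
#' @return An object of class `voltammogram`.
#' @export
voltammogram <- function(potentials, currents, params,
                         stream = c("standard", "centrifuged", "noncentrifuged"),
                         replicate_id = 1L, sample_id = "sample") {
  stream <- match.arg(stream)
  if (!inherits(params, "scan_params")) {
    stop(vg_error("params must be a scan_params object", "vg_params_error"))
  }
  if (!is.numeric(potentials) || !is.numeric(currents)) {
    stop(vg_error("potentials and currents must be numeric", "vg_numeric_error"))
  }
  if (length(potentials) != length(currents)) {
    stop(vg_error("potentials and currents differ in length", "vg_length_error"))
  }
  if (length(potentials) < 3L) {
    stop(vg_error("a voltammogram needs at least 3 points", "vg_length_error"))
  }
  if (anyNA(potentials) || anyNA(currents)) {
    stop(vg_error("NA values in trace", "vg_numeric_error"))
  }
  lo <- min(params$v_start, params$v_end)
  hi <- max(params$v_start, params$v_end)
  if (any(potentials < lo - 1e-9) || any(potentials > hi + 1e-9)) {
    stop(vg_error("potentials outside the programmed range", "vg_range_error"))
  }
  d <- diff(potentials)
  if (params$technique == "DPV") {
    if (!(all(d > 0) || all(d < 0))) {
      stop(vg_error("DPV potentials must be strictly monotone",
                    "vg_monotonic_error"))
    }
  } else {
    sgn <- sign(d)
    if (any(sgn == 0) || length(rle(sgn)$values) != 2L) {
      stop(vg_error(
        "CV potentials must be piecewise monotone with exactly one turning point",
        "vg_monotonic_error"))
    }
  }
  structure(list(potentials = as.numeric(potentials),
                 currents = as.numeric(currents),
                 params = params, stream = stream,
                 replicate_id = as.integer(replicate_id),
                 sample_id = as.character(sample_id)),
            class = "voltammogram")
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf("<voltammogram> %s (%s route), %d points, %g..%g mV, stream=%s, sample=%s\n",
              x$params$technique, x$params$route, length(x$potentials),
              x$potentials[1], x$potentials[length(x$potentials)],
              x$stream, x$sample_id))
  invisible(x)
}

#' @export
length.voltammogram <- function(x) length(x$potentials)

#' Read a voltammogram trace from CSV
#'
#' The interchange format is a two-column CSV with the exact header
#' `potential_mV,current_uA` and numeric rows, comma-separated with dot
#' decimals. Row order is preserved as recorded.
#'
#' @param path CSV file path.
#' @param params scan program for the trace ([scan_params()]).
#' @param stream,sample_id,replicate_id metadata; see [voltammogram()].
#' @return A validated `voltammogram`.
#' @export
read_voltammogram <- function(path, params,
                              stream = "standard", sample_id = "sample",
                              replicate_id = 1L) {
  lines <- readLines(path)
  if (length(lines) == 0L || trimws(lines[1]) != "potential_mV,current_uA") {
    stop(vg_error(sprintf("expected header 'potential_mV,current_uA' in %s", path),
                  "vg_header_error"))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 3L) {
    stop(vg_error("fewer than 3 data rows", "vg_length_error"))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop(vg_error("malformed row: expected two comma-separated fields",
                  "vg_numeric_error"))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) {
    stop(vg_error("non-numeric value in data rows", "vg_numeric_error"))
  }
  voltammogram(m[, 1], m[, 2], params, stream = stream,
               replicate_id = replicate_id, sample_id = sample_id)
}

#' Write a voltammogram trace to CSV
#'
#' Emits the fixed header `potential_mV,current_uA` and one row per point at
#' full double precision, so that read/write round-trips are bit-exact.
#'
#' @param vg a `voltammogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_voltammogram <- function(vg, path) {
  stopifnot(inherits(vg, "voltammogram"))
  rows <- sprintf("%.17g,%.17g", vg$potentials, vg$currents)
  writeLines(c("potential_mV,current_uA", rows), path)
  invisible(path)
}

#' Split a cyclic voltammogram into forward and reverse sweeps
#'
#' The forward sweep runs up to and including the turning point; the reverse
#' sweep is the remainder, so concatenating the two reproduces the input
#' exactly. The oxidation (anodic) branch of an upward-first scan is the
#' forward sweep.
#'
#' @param vg a CV `voltammogram`.
#' @return A list with elements `forward` and `reverse`, each a list of
#'   `potentials` and `currents` in recorded order.
#' @export
split_cv_sweeps <- function(vg) {
  stopifnot(inherits(vg, "voltammogram"))
  if (vg$params$technique != "CV") {
    stop(vg_error("split_cv_sweeps requires a CV trace", "vg_params_error"))
  }
  p <- vg$potentials
  turn <- if (p[2] > p[1]) which.max(p) else which.min(p)
  list(
    forward = list(potentials = p[seq_len(turn)],
                   currents = vg$currents[seq_len(turn)]),
    reverse = list(potentials = p[seq(turn + 1L, length(p))],
                   currents = vg$currents[seq(turn + 1L, length(p))])
  )
}

#' Read scan parameters from a key = value config file
#'
#' Plain-text, TOML-like: one `key = value` pair per line, `#` comments.
#' Recognized keys mirror [scan_params()] fields (`technique`, `v_start`,
#' `v_end`, `route`, `pulse_height`, `pulse_width`, `step_height`,
#' `scan_rate`).
#'
#' @param path config file path.
#' @return A `scan_params` object.
#' @export
read_scan_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) {
    stop(vg_error("malformed config line (expected key = value)",
                  "vg_config_error"))
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  vals <- gsub('^"|"$', "", vals)
  get_num <- function(k) if (k %in% keys) as.numeric(vals[match(k, keys)]) else NULL
  get_chr <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
  scan_params(technique = get_chr("technique"),
              v_start = get_num("v_start"), v_end = get_num("v_end"),
              route = get_chr("route"),
              pulse_height = get_num("pulse_height"),
              pulse_width = get_num("pulse_width"),
              step_height = get_num("step_height"),
              scan_rate = get_num("scan_rate"))
}
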