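#' Configuration for the synthetic voltammogram generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' descriptor values that follow the standard-mixture calibration anchors
#' linearly in concentration, replicate noise at the printed anchor SDs,
#' constant blank backgrounds at 0 mM, and a sample-dependent fecal-matrix
#' distortion (multiplicative gain, additive drift, potential shift, soft
#' saturation) strong enough to break single-feature linear calibration.
#' Waveforms are Gaussian peaks plus simple backgrounds and ramps: the
#' generator is constrained to reproduce descriptors, not instrument
#' waveform shapes.
#'
#' @param seed integer seed controlling all sampling.
#' @param grid_step potential grid step in mV.
#' @param total_range total-SCFA sampling range in mM (the cohort's span).
#' @param ratio_alpha Dirichlet weights for the acetate:propionate:butyrate
#'   molar ratio, centred on the canonical 60:25:15 colonic ratio.
#' @param ref_noise_rel relative SD of the GC-MS-like reference labels.
#' @param gain_sdlog,drift_sd,shift_sd,i_sat matrix-distortion model:
#'   per-sample gain ~ lognormal(0, `gain_sdlog`), additive drift ~
#'   N(0, `drift_sd` uA), potential shift ~ N(0, `shift_sd` mV), and soft
#'   saturation I -> `i_sat` * tanh(I / `i_sat`) (uA; `Inf` disables it).
#' @param noise_sd replicate-noise SDs for descriptors without printed
#'   anchors (uA, mV, or uA*mV as appropriate).
#' @param slopes intercept/slope pairs (in the descriptor's units vs mM of
#'   its driving analyte) for the descriptor-concentration relations that
#'   have no printed calibration anchors: `B_I` (centrifuged current at
#'   -30 mV vs propionate), `C_red` (reduction-peak amplitude vs butyrate),
#'   `A_I2` and `A_A2` (high-potential current/area vs the total-route
#'   driver).
#' @param ester_weights relative esterification sensitivities of propionate
#'   and butyrate on the total route (acetate is 1): the total-route
#'   descriptors respond to acetate + w_p x propionate + w_b x butyrate
#'   rather than to the plain total, emulating acid-dependent ester yields.
#'   The standard-mixture calibration (propionate/butyrate fixed, acetate
#'   varied) cannot see this, but it makes the plain 5-descriptor total
#'   model composition-confounded -- the ambiguity the auxiliary P1/B1
#'   inputs resolve.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, grid_step = 5,
                         total_range = c(1.32, 21.32),
                         ratio_alpha = c(acetate = 12, propionate = 5, butyrate = 3),
                         ref_noise_rel = 0.02,
                         gain_sdlog = 0.4, drift_sd = 1.5, shift_sd = 8,
                         i_sat = 1800,
                         noise_sd = list(B_I = 0.1, B_V_onset = 3,
                                         C_red = 0.2, A_I2 = 0.15, A_A2 = 8),
                         slopes = list(B_I = c(1, 2.5), C_red = c(2, 3),
                                       A_I2 = c(2, 1.2), A_A2 = c(20, 15)),
                         ester_weights = c(propionate = 0.5, butyrate = 0.4)) {
  stopifnot(grid_step > 0, length(total_range) == 2L,
            total_range[1] < total_range[2],
            gain_sdlog >= 0, drift_sd >= 0, shift_sd >= 0, i_sat > 0,
            all(lengths(slopes) == 2L), all(ester_weights >= 0))
  structure(list(seed = as.integer(seed), grid_step = grid_step,
                 total_range = total_range, ratio_alpha = ratio_alpha,
                 ref_noise_rel = ref_noise_rel,
                 matrix = list(gain_sdlog = gain_sdlog, drift_sd = drift_sd,
                               shift_sd = shift_sd, i_sat = i_sat),
                 noise_sd = noise_sd, slopes = slopes,
                 ester_weights = ester_weights),
            class = "synth_config")
}

.gauss <- function(v, center, sigma) exp(-((v - center)^2) / (2 * sigma^2))

# Piecewise-linear anchor interpolation. Means extrapolate linearly with the
# end-segment slopes; SDs (noise scales) extend as end-point constants so they
# stay non-negative.
.anchor_fun <- function(descriptor, column = "mean") {
  a <- load_calibration_anchors()
  a <- a[a$descriptor == descriptor, ]
  a <- a[order(a$conc_mM), ]
  x <- a$conc_mM; y <- a[[column]]
  linear <- column == "mean"
  function(conc) {
    out <- stats::approx(x, y, xout = conc, rule = 2)$y
    if (linear) {
      lo <- conc < x[1]; hi <- conc > x[length(x)]
      if (any(lo)) {
        s <- (y[2] - y[1]) / (x[2] - x[1])
        out[lo] <- y[1] + s * (conc[lo] - x[1])
      }
      if (any(hi)) {
        k <- length(x)
        s <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
        out[hi] <- y[k] + s * (conc[hi] - x[k])
      }
    }
    out
  }
}

.conc_triplet <- function(conc) {
  out <- c(propionate = 0, butyrate = 0, total = 0)
  conc <- unlist(conc)
  out[names(conc)] <- conc
  if (any(out < 0)) stop(vg_error("concentrations must be >= 0", "vg_params_error"))
  out
}

#' Generate a synthetic standard-mixture voltammogram
#'
#' Renders one route trace whose extracted calibration descriptors equal the
#' anchor-interpolated targets at the requested concentration (exactly, up
#' to grid discretisation, when `noise = FALSE`). A zero concentration
#' reproduces the printed blank background level of the corresponding
#' descriptor. With `noise = TRUE`, descriptor-level Gaussian jitter at the
#' anchor SDs (or the configured SDs for unanchored descriptors) is drawn
#' from the current RNG stream, or from `seed` if given.
#'
#' @param route pretreatment route (see [default_scan_params()]).
#' @param conc named concentrations in mM; any of `propionate`, `butyrate`,
#'   `total` (missing entries are 0).
#' @param cfg a [synth_config()].
#' @param noise logical; add replicate noise.
#' @param stream preparation stream; the propionate route distinguishes
#'   `"centrifuged"` (current descriptors) from `"noncentrifuged"`
#'   (potential and area descriptors).
#' @param replicate_id,sample_id trace metadata.
#' @param seed optional seed for the replicate noise.
#' @return A `voltammogram`.
#' @export
generate_standard_trace <- function(route, conc, cfg = synth_config(),
                                    noise = FALSE,
                                    stream = "standard", replicate_id = 1L,
                                    sample_id = "synthetic", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cc <- .conc_triplet(conc)
  params <- default_scan_params(route)
  step <- cfg$grid_step
  jit <- function(sd) if (noise) stats::rnorm(1, 0, sd) else 0
  if (route == "propionate_esterification") {
    v <- seq(-600, 2000, by = step)
    if (identical(stream, "centrifuged")) {
      bg <- 0.2 + 0.001 * (v + 600)
      sl <- cfg$slopes$B_I
      target <- sl[1] + sl[2] * cc[["propionate"]] + jit(cfg$noise_sd$B_I)
      amp <- target - (0.2 + 0.001 * (-30 + 600))
      i <- bg + amp * .gauss(v, -30, 50)
    } else {
      bg <- 2 + 0.003 * (v + 600)
      a_target <- .anchor_fun("B_A1")(cc[["propionate"]]) +
        jit(.anchor_fun("B_A1", "sd")(cc[["propionate"]]))
      unit <- voltammogram(v, .gauss(v, -130, 40), params,
                           stream = "standard", sample_id = "unit")
      ua <- area_in_window(unit, potential_window(-230, -30))
      v_on <- 1400 - 25 * cc[["propionate"]] + jit(cfg$noise_sd$B_V_onset)
      i <- bg + (a_target / ua) * .gauss(v, -130, 40) + pmax(0, v - v_on) * 2.5
    }
  } else if (route == "butyrate_dissociation") {
    vf <- seq(-600, 1100, by = step)
    vr <- seq(1100 - step, -600, by = -step)
    b <- cc[["butyrate"]]
    base_f <- function(v) (1 + 0.2 * b) + 0.004 * (v + 600)
    c_i1 <- .anchor_fun("C_I1")(b) + jit(.anchor_fun("C_I1", "sd")(b))
    amp_ox <- (c_i1 - base_f(175)) / .gauss(175, 300, 60)
    i_f <- base_f(vf) + amp_ox * .gauss(vf, 300, 60)
    slr <- cfg$slopes$C_red
    a_red <- (base_f(250) - 1.5) - (-(slr[1] + slr[2] * b) + jit(cfg$noise_sd$C_red))
    i_r <- base_f(vr) - 1.5 - a_red * .gauss(vr, 250, 60)
    v <- c(vf, vr); i <- c(i_f, i_r)
  } else if (route == "total_esterification") {
    v <- seq(-600, 1200, by = step)
    # composition-weighted esterification driver; equals the nominal total
    # when only `total` is specified (the calibration-standard situation)
    w <- cfg$ester_weights
    acetate <- max(0, cc[["total"]] - cc[["propionate"]] - cc[["butyrate"]])
    total <- acetate + w[["propionate"]] * cc[["propionate"]] +
      w[["butyrate"]] * cc[["butyrate"]]
    a_a1 <- .anchor_fun("A_A1")(total) + jit(.anchor_fun("A_A1", "sd")(total))
    unit_lo <- voltammogram(v, .gauss(v, -50, 45), params,
                            stream = "standard", sample_id = "unit")
    ua_lo <- half_wave_area(unit_lo, potential_window(-200, 100), -50)
    amp_lo <- a_a1 / ua_lo
    a_a2 <- cfg$slopes$A_A2[1] + cfg$slopes$A_A2[2] * total + jit(cfg$noise_sd$A_A2)
    unit_hi <- voltammogram(v, .gauss(v, 900, 40), params,
                            stream = "standard", sample_id = "unit")
    ua_hi <- area_in_window(unit_hi, potential_window(800, 985))
    amp_hi <- a_a2 / ua_hi
    a_i2 <- cfg$slopes$A_I2[1] + cfg$slopes$A_I2[2] * total + jit(cfg$noise_sd$A_I2)
    wall_985 <- a_i2 - 1 - amp_hi * .gauss(985, 900, 40) - amp_lo * .gauss(985, -50, 45)
    i <- 1 + amp_lo * .gauss(v, -50, 45) + amp_hi * .gauss(v, 900, 40) +
      pmax(0, v - 800) * (wall_985 / 185)
  } else {
    stop(vg_error("unknown route", "vg_params_error"))
  }
  voltammogram(v, i, params, stream = stream,
               replicate_id = replicate_id, sample_id = sample_id)
}

#' Draw one sample's matrix-distortion parameters
#'
#' A fecal sample's matrix is common to all its pretreatment aliquots, so
#' one draw is shared across that sample's routes.
#'
#' @param cfg a [synth_config()].
#' @param sample_seed optional seed for the draw.
#' @return A list with `gain`, `drift`, `shift`, `i_sat`.
#' @export
matrix_draw <- function(cfg = synth_config(), sample_seed = NULL) {
  if (!is.null(sample_seed)) set.seed(sample_seed)
  m <- cfg$matrix
  list(gain = stats::rlnorm(1, 0, m$gain_sdlog),
       drift = stats::rnorm(1, 0, m$drift_sd),
       shift = stats::rnorm(1, 0, m$shift_sd),
       i_sat = m$i_sat)
}

#' Apply a fecal-matrix distortion to a trace
#'
#' In order: potential shift (currents re-sampled at V - shift, edges
#' extended), multiplicative gain, additive drift, then soft saturation
#' I -> i_sat * tanh(I / i_sat). With zero-width draws and infinite
#' saturation the transform is the identity.
#'
#' @param vg a `voltammogram`.
#' @param cfg a [synth_config()].
#' @param draw a [matrix_draw()] list, or `NULL` to draw one from
#'   `sample_seed`/the current RNG.
#' @param sample_seed optional seed used when `draw` is `NULL`.
#' @return The distorted `voltammogram`.
#' @export
apply_matrix_effect <- function(vg, cfg = synth_config(), draw = NULL,
                                sample_seed = NULL) {
  stopifnot(inherits(vg, "voltammogram"))
  if (is.null(draw)) draw <- matrix_draw(cfg, sample_seed)
  shift_seg <- function(v, i, delta) {
    if (delta == 0) return(i)
    a <- if (v[1] > v[length(v)]) list(v = rev(v), i = rev(i)) else list(v = v, i = i)
    out <- stats::approx(a$v, a$i, xout = v - delta, rule = 2, ties = "ordered")$y
    out
  }
  if (vg$params$technique == "CV") {
    sw <- split_cv_sweeps(vg)
    i <- c(shift_seg(sw$forward$potentials, sw$forward$currents, draw$shift),
           shift_seg(sw$reverse$potentials, sw$reverse$currents, draw$shift))
  } else {
    i <- shift_seg(vg$potentials, vg$currents, draw$shift)
  }
  i <- draw$gain * i + draw$drift
  if (is.finite(draw$i_sat)) i <- draw$i_sat * tanh(i / draw$i_sat)
  voltammogram(vg$potentials, i, vg$params, stream = vg$stream,
               replicate_id = vg$replicate_id, sample_id = vg$sample_id)
}

#' Render all route traces for one sample
#'
#' Two centrifuged and two noncentrifuged propionate-route replicates, one
#' butyrate-route CV, and one total-route DPV, optionally distorted by a
#' shared matrix draw.
#'
#' @param conc named concentrations in mM (`propionate`, `butyrate`, `total`).
#' @param cfg a [synth_config()].
#' @param noise logical; replicate noise on the descriptor targets.
#' @param draw optional shared [matrix_draw()]; `NULL` leaves traces clean.
#' @param sample_id trace metadata.
#' @return A list with `prop_cent` (list of 2), `prop_noncent` (list of 2),
#'   `butyrate`, `total`.
#' @export
generate_sample_traces <- function(conc, cfg = synth_config(), noise = TRUE,
                                   draw = NULL, sample_id = "synthetic") {
  mk <- function(route, stream, rep) {
    vg <- generate_standard_trace(route, conc, cfg, noise = noise,
                                  stream = stream, replicate_id = rep,
                                  sample_id = sample_id)
    if (!is.null(draw)) vg <- apply_matrix_effect(vg, cfg, draw) else vg
  }
  list(
    prop_cent = list(mk("propionate_esterification", "centrifuged", 1L),
                     mk("propionate_esterification", "centrifuged", 2L)),
    prop_noncent = list(mk("propionate_esterification", "noncentrifuged", 1L),
                        mk("propionate_esterification", "noncentrifuged", 2L)),
    butyrate = mk("butyrate_dissociation", "standard", 1L),
    total = mk("total_esterification", "standard", 1L)
  )
}

#' Extract the full 15-descriptor set from one sample's traces
#'
#' @param traces output of [generate_sample_traces()] (or equivalently
#'   structured measured traces).
#' @return Named numeric vector: the 10 propionate/butyrate descriptors
#'   followed by the 5 total-route descriptors.
#' @export
extract_sample_features <- function(traces) {
  p <- extract_propionate_features(traces$prop_cent, traces$prop_noncent)
  b <- extract_butyrate_features(traces$butyrate)
  t <- extract_total_features(traces$total)
  c(assemble_pb_vector(p, b),
    A_I1 = t$A_I1, A_V1 = t$A_V1, A_A1 = t$A_A1, A_I2 = t$A_I2, A_A2 = t$A_A2)
}

#' Generate a synthetic cohort with ground truth
#'
#' Samples concentrations (total SCFAs uniform over the configured range,
#' acetate:propionate:butyrate from a Dirichlet centred on 60:25:15),
#' renders every route trace, optionally applies a shared per-sample matrix
#' distortion (`fecal = TRUE`), extracts all descriptors, and attaches
#' GC-MS-like reference labels (truth plus small relative noise; the total
#' reference is the sum of the three analyte references, so mass balance
#' holds in the labels as well as the truth).
#'
#' @param n number of samples.
#' @param cfg a [synth_config()]; `cfg$seed` (plus `seed_offset`) fixes the
#'   cohort.
#' @param fecal logical; apply matrix distortion.
#' @param seed_offset integer stream offset so disjoint cohorts can be drawn
#'   from one config.
#' @param id_prefix sample-id prefix.
#' @param noise logical; replicate noise on descriptors and reference
#'   labels (disable for exact round-trip checks).
#' @return A data frame: `sample_id`, 15 feature columns, ground truth
#'   (`acetate_mM`, `propionate_mM`, `butyrate_mM`, `total_mM`) and
#'   reference labels (`ref_prop`, `ref_but`, `ref_total`).
#' @export
generate_cohort <- function(n, cfg = synth_config(), fecal = FALSE,
                            seed_offset = 0L, id_prefix = "syn",
                            noise = TRUE) {
  stopifnot(n >= 1)
  set.seed(cfg$seed + 7919L * as.integer(seed_offset))
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    total <- stats::runif(1, cfg$total_range[1], cfg$total_range[2])
    g <- stats::rgamma(3, shape = cfg$ratio_alpha)
    ratio <- g / sum(g)
    conc <- c(propionate = total * ratio[2], butyrate = total * ratio[3],
              total = total)
    acetate <- total * ratio[1]
    draw <- if (fecal) matrix_draw(cfg) else NULL
    traces <- generate_sample_traces(conc, cfg, noise = noise, draw = draw,
                                     sample_id = sprintf("%s_%03d", id_prefix, k))
    feats <- extract_sample_features(traces)
    ref <- c(conc[["propionate"]], conc[["butyrate"]], acetate) *
      (1 + if (noise) stats::rnorm(3, 0, cfg$ref_noise_rel) else 0)
    rows[[k]] <- data.frame(sample_id = sprintf("%s_%03d", id_prefix, k),
                            as.list(feats),
                            acetate_mM = acetate,
                            propionate_mM = conc[["propionate"]],
                            butyrate_mM = conc[["butyrate"]],
                            total_mM = total,
                            ref_prop = ref[1], ref_but = ref[2],
                            ref_total = sum(ref))
  }
  do.call(rbind, rows)
}
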