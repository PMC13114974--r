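test_that("noise-free generator traces hit the calibration anchors", {
  cfg <- synth_config()
  anchors <- load_calibration_anchors()

  for (conc in c(0, 1, 2, 3)) {
    tr <- generate_standard_trace("propionate_esterification",
                                  c(propionate = conc), cfg,
                                  stream = "noncentrifuged")
    want <- anchors$mean[anchors$descriptor == "B_A1" & anchors$conc_mM == conc]
    expect_equal(area_in_window(tr, potential_window(-230, -30)), want,
                 tolerance = 1e-8)
  }
  for (conc in c(0, 1, 2, 3)) {
    vg <- generate_standard_trace("butyrate_dissociation",
                                  c(butyrate = conc), cfg)
    want <- anchors$mean[anchors$descriptor == "C_I1" & anchors$conc_mM == conc]
    expect_equal(extract_butyrate_features(vg)$C_I1, want, tolerance = 1e-8)
  }
  for (conc in c(0, 5, 10, 15, 20)) {
    vg <- generate_standard_trace("total_esterification",
                                  c(total = conc), cfg)
    want <- anchors$mean[anchors$descriptor == "A_A1" & anchors$conc_mM == conc]
    expect_equal(extract_total_features(vg)$A_A1, want, tolerance = 1e-8)
  }
})

test_that("anchored descriptors increase strictly with concentration", {
  cfg <- synth_config()
  ba1 <- vapply(seq(0, 4, by = 0.5), function(p) {
    tr <- generate_standard_trace("propionate_esterification",
                                  c(propionate = p), cfg,
                                  stream = "noncentrifuged")
    area_in_window(tr, potential_window(-230, -30))
  }, numeric(1))
  expect_true(all(diff(ba1) > 0))

  ci1 <- vapply(seq(0, 4, by = 0.5), function(b) {
    extract_butyrate_features(
      generate_standard_trace("butyrate_dissociation", c(butyrate = b), cfg))$C_I1
  }, numeric(1))
  expect_true(all(diff(ci1) > 0))

  aa1 <- vapply(seq(0, 20, by = 2.5), function(tt) {
    extract_total_features(
      generate_standard_trace("total_esterification", c(total = tt), cfg))$A_A1
  }, numeric(1))
  expect_true(all(diff(aa1) > 0))
})

test_that("replicate noise is reproducible under a fixed seed", {
  cfg <- synth_config()
  a <- generate_standard_trace("total_esterification", c(total = 8), cfg,
                               noise = TRUE, seed = 99)
  b <- generate_standard_trace("total_esterification", c(total = 8), cfg,
                               noise = TRUE, seed = 99)
  expect_identical(a$currents, b$currents)
  c <- generate_standard_trace("total_esterification", c(total = 8), cfg,
                               noise = TRUE, seed = 100)
  expect_false(identical(a$currents, c$currents))
})

test_that("the null matrix draw is the identity transform", {
  cfg0 <- synth_config(gain_sdlog = 0, drift_sd = 0, shift_sd = 0, i_sat = Inf)
  vg <- generate_standard_trace("total_esterification", c(total = 12), cfg0)
  out <- apply_matrix_effect(vg, cfg0, matrix_draw(cfg0, sample_seed = 1))
  expect_identical(out$currents, vg$currents)
})

test_that("a pure gain scales area descriptors exactly", {
  cfg <- synth_config()
  draw <- list(gain = 1.2, drift = 0, shift = 0, i_sat = Inf)
  vg <- generate_standard_trace("propionate_esterification",
                                c(propionate = 2), cfg,
                                stream = "noncentrifuged")
  a0 <- area_in_window(vg, potential_window(-230, -30))
  a1 <- area_in_window(apply_matrix_effect(vg, cfg, draw),
                       potential_window(-230, -30))
  expect_equal(a1, 1.2 * a0, tolerance = 1e-12)

  # drift is removed by the chord; shift moves the CV fingerprint coherently
  draw2 <- list(gain = 1, drift = 3, shift = 0, i_sat = Inf)
  a2 <- area_in_window(apply_matrix_effect(vg, cfg, draw2),
                       potential_window(-230, -30))
  expect_equal(a2, a0, tolerance = 1e-9)
})

test_that("default matrix distortion breaks single-feature calibration", {
  cfg <- synth_config(seed = 17)
  co <- generate_cohort(30, cfg, fecal = TRUE, seed_offset = 4)
  fit <- stats::lm(propionate_mM ~ B_A1, data = co)
  expect_lt(summary(fit)$r.squared, 0.7)
  # while the clean calibration is near-perfect
  clean <- generate_cohort(30, cfg, fecal = FALSE, seed_offset = 5)
  fit2 <- stats::lm(propionate_mM ~ B_A1, data = clean)
  expect_gt(summary(fit2)$r.squared, 0.9)
})

test_that("cohorts close the mass balance and respect the sampling ranges", {
  cfg <- synth_config(seed = 2)
  co <- generate_cohort(40, cfg, fecal = TRUE, seed_offset = 6)
  expect_equal(nrow(co), 40)
  expect_equal(co$acetate_mM + co$propionate_mM + co$butyrate_mM, co$total_mM,
               tolerance = 1e-12)
  expect_true(all(co$total_mM >= cfg$total_range[1] &
                  co$total_mM <= cfg$total_range[2]))
  expect_equal(co$ref_total, co$ref_prop + co$ref_but +
                 (co$ref_total - co$ref_prop - co$ref_but))
  # determinism
  co2 <- generate_cohort(40, cfg, fecal = TRUE, seed_offset = 6)
  expect_identical(co, co2)
})

test_that("clean noise-free cohorts sit on the anchor-interpolated lines", {
  cfg <- synth_config(seed = 8)
  co <- generate_cohort(10, cfg, fecal = FALSE, noise = FALSE, seed_offset = 7)
  anchors <- load_calibration_anchors()
  sub <- anchors[anchors$descriptor == "C_I1", ]
  want <- stats::approx(sub$conc_mM, sub$mean, xout = co$butyrate_mM,
                        rule = 2)$y
  inside <- co$butyrate_mM <= max(sub$conc_mM)
  expect_equal(co$C_I1[inside], want[inside], tolerance = 1e-8)
  # reference labels equal the truth when noise is off
  expect_equal(co$ref_prop, co$propionate_mM, tolerance = 1e-12)
})
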