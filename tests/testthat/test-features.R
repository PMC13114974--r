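test_that("chord baseline correction removes affine backgrounds exactly", {
  v <- seq(-600, 2000, by = 10)
  vg <- dpv_from(v, 3 + 0.02 * v)
  bc <- baseline_correct(vg, potential_window(-230, -30))
  expect_equal(max(abs(bc$residuals)), 0)
  expect_equal(area_in_window(vg, potential_window(-230, -30)), 0)

  # residuals vanish at the window endpoints for any trace
  set.seed(4)
  vg2 <- random_dpv(80)
  bc2 <- baseline_correct(vg2, potential_window(-100, 900))
  expect_equal(bc2$residuals[1], 0)
  expect_equal(bc2$residuals[length(bc2$residuals)], 0)

  expect_error(baseline_correct(vg, potential_window(-700, 0)),
               class = "vg_window_error")
})

test_that("a symmetric triangular peak keeps its height and half-base area", {
  v <- seq(-600, 2000, by = 5)
  h <- 10; center <- -130; base <- 100
  tri <- pmax(0, h * (1 - abs(v - center) / (base / 2)))
  vg <- dpv_from(v, 2 + tri)
  w <- potential_window(-230, -30)
  bc <- baseline_correct(vg, w)
  expect_equal(max(bc$residuals), h)
  # triangle area 1/2 * base * height on a flat background
  expect_equal(area_in_window(vg, w), 0.5 * base * h)
  # symmetric peak centred in the window: half-wave area is half the total
  expect_equal(half_wave_area(vg, w, center), 0.5 * area_in_window(vg, w))
})

test_that("area operators match the brute-force quadrature oracle", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(20:200, 1)
    vg <- random_dpv(n)
    lo <- runif(1, -580, 1000)
    hi <- lo + runif(1, 50, 900)
    got <- area_in_window(vg, potential_window(lo, hi))
    want <- oracle_chord_area(vg$potentials, vg$currents, lo, hi)$area
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("baseline residuals match independent point-by-point subtraction", {
  set.seed(8)
  vg <- random_dpv(20)
  bc <- baseline_correct(vg, potential_window(-400, 1500))
  want <- oracle_chord_area(vg$potentials, vg$currents, -400, 1500)
  expect_equal(bc$potentials, want$potentials)
  expect_equal(bc$residuals, want$residuals, tolerance = 1e-12)
})

test_that("windowed area is additive over subwindows sharing the full chord", {
  set.seed(9)
  for (k in 1:20) {
    vg <- random_dpv(60)
    lo <- -500; hi <- 1500; mid <- runif(1, -400, 1400)
    full <- area_in_window(vg, potential_window(lo, hi))
    left <- half_wave_area(vg, potential_window(lo, hi), mid)
    # right part = full - left by construction of the shared chord
    expect_equal(left + (full - left), full)
    expect_equal(half_wave_area(vg, potential_window(lo, hi), hi), full,
                 tolerance = 1e-12)
  }
})

test_that("interpolated currents are exact at nodes and linear between", {
  vg <- dpv_from(c(0, 10, 20), c(2, 4, 8), route = "total_esterification")
  expect_equal(current_at(vg, 10), 4)
  expect_equal(current_at(vg, 5), 3)
  expect_error(current_at(vg, 25), class = "vg_range_error")

  set.seed(10)
  vg2 <- random_dpv(70)
  for (q in runif(50, -600, 2000)) {
    expect_equal(current_at(vg2, q),
                 oracle_interp(vg2$potentials, vg2$currents, q),
                 tolerance = 1e-12)
  }
})

test_that("potential_at_current takes the first crossing in scan order", {
  # monotone ramp I(V) = V/10 on [0, 1000]
  v <- seq(0, 1000, by = 10)
  vg <- dpv_from(v, v / 10, route = "total_esterification")
  expect_equal(potential_at_current(vg, 50), 500)

  # a level crossed twice: earlier crossing wins
  set.seed(11)
  v2 <- seq(-600, 2000, by = 20)
  i2 <- 5 * sin(v2 / 300) + rnorm(length(v2), 0, 0.1)
  vg2 <- dpv_from(v2, i2)
  level <- 2
  crossings <- oracle_crossings(v2, i2, level)
  expect_gt(length(crossings), 1)
  expect_equal(potential_at_current(vg2, level), min(crossings[1]),
               tolerance = 1e-12)

  # flat trace below the level: named failure
  vg3 <- dpv_from(seq(-600, 0, by = 100), rep(1, 7))
  expect_error(potential_at_current(vg3, 10), class = "vg_no_crossing")
})

test_that("peak finding matches exhaustive scan with lower-potential ties", {
  set.seed(12)
  for (k in 1:30) {
    vg <- random_dpv(60)
    w <- potential_window(-400, 1600)
    pk <- peak_in_window(vg, w, "max")
    want <- oracle_peak(vg$potentials, vg$currents, -400, 1600, "max")
    expect_equal(pk$peak_current, want$current)
    expect_equal(pk$peak_potential, want$potential)
    mn <- peak_in_window(vg, w, "min")
    wantm <- oracle_peak(vg$potentials, vg$currents, -400, 1600, "min")
    expect_equal(mn$peak_current, wantm$current)
  }

  # tie broken toward the lower potential
  vg_tie <- dpv_from(c(0, 10, 20, 30), c(1, 5, 5, 1),
                     route = "total_esterification")
  pk <- peak_in_window(vg_tie, potential_window(0, 30), "max")
  expect_equal(pk$peak_potential, 10)

  # monotone segment peaks at the window boundary, flagged
  vg_mono <- dpv_from(seq(0, 100, by = 10), seq(0, 10, by = 1),
                      route = "total_esterification")
  pk2 <- peak_in_window(vg_mono, potential_window(20, 80), "max")
  expect_equal(pk2$peak_potential, 80)
  expect_true(pk2$boundary)
})

test_that("asymmetric half-wave areas match brute-force integration", {
  # two-segment asymmetric peak: steep rise, slow fall
  v <- seq(-600, 1200, by = 5)
  peak <- ifelse(v < -50, pmax(0, (v + 150) / 100) * 8,
                 pmax(0, 1 - (v + 50) / 300) * 8)
  vg <- dpv_from(v, 1 + peak, route = "total_esterification")
  w <- potential_window(-200, 100)
  got <- half_wave_area(vg, w, -50)
  full <- oracle_chord_area(v, 1 + peak, -200, 100)
  keep <- full$potentials <= -50
  vs <- full$potentials[keep]; rs <- full$residuals[keep]
  want <- sum(diff(vs) * (rs[-1] + rs[-length(rs)]) / 2)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("propionate extraction maps streams and replicates as declared", {
  cfg <- synth_config()
  conc <- c(propionate = 1.5)
  cent <- generate_standard_trace("propionate_esterification", conc, cfg,
                                  stream = "centrifuged")
  noncent <- generate_standard_trace("propionate_esterification", conc, cfg,
                                     stream = "noncentrifuged")
  # identical replicates give identical descriptor pairs
  p <- extract_propionate_features(list(cent, cent), list(noncent, noncent))
  expect_equal(p$B_I1, p$B_I2)
  expect_equal(p$B_V1, p$B_V2)
  expect_equal(p$B_A1, p$B_A2)
  expect_equal(p$B_I1, current_at(cent, -30))
  expect_equal(p$B_A1, area_in_window(noncent, potential_window(-230, -30)))
  expect_length(attr(p, "flags"), 0)

  # a trace never reaching 1000 uA falls back to the max-current potential
  v <- seq(-600, 2000, by = 10)
  weak <- dpv_from(v, 5 * exp(-((v - 100) / 200)^2),
                   stream = "noncentrifuged")
  p2 <- extract_propionate_features(list(cent, cent), list(weak, weak))
  expect_setequal(attr(p2, "flags"), c("B_V1_no_crossing", "B_V2_no_crossing"))
  expect_equal(p2$B_V1, 100)
})

test_that("butyrate extraction follows the declared sweep assignments", {
  cfg <- synth_config()
  vg <- generate_standard_trace("butyrate_dissociation", c(butyrate = 2), cfg)
  b <- extract_butyrate_features(vg)
  sw <- split_cv_sweeps(vg)
  expect_equal(b$C_I1, current_at(sw$forward, 175))
  expect_equal(b$C_I2, min(sw$reverse$currents))
  # C_A1 equals a brute-force trapezoid on the reverse segment
  want <- oracle_chord_area(sw$reverse$potentials, sw$reverse$currents,
                            110, 500)$area
  expect_equal(b$C_A1, want, tolerance = 1e-9)

  # symmetric reversible couple: reduction peak mirrors the oxidation peak
  v <- cv_grid(5)
  g <- exp(-((v - 300) / 60)^2 / 2)
  up <- seq_along(v) <= which.max(v)
  i <- ifelse(up, 20 * g, -20 * g)
  vg2 <- cv_from(v, i)
  b2 <- extract_butyrate_features(vg2)
  ox <- attr(b2, "oxidation_peak")
  expect_equal(b2$C_I2, -ox)
})

test_that("total-route extraction follows the two-region definitions", {
  cfg <- synth_config()
  vg <- generate_standard_trace("total_esterification", c(total = 10), cfg)
  t <- extract_total_features(vg)
  pk <- peak_in_window(vg, potential_window(-200, 100), "max")
  expect_equal(t$A_I1, pk$peak_current)
  expect_equal(t$A_V1, pk$peak_potential)
  expect_true(t$A_V1 >= -200 && t$A_V1 <= 100)
  expect_equal(t$A_A1, half_wave_area(vg, potential_window(-200, 100), t$A_V1))
  expect_equal(t$A_I2, current_at(vg, 985))
  expect_equal(t$A_A2, area_in_window(vg, potential_window(800, 985)))

  # generator peak sits at -50 mV on this grid
  expect_equal(t$A_V1, -50)
})

test_that("feature vectors assemble in fixed order", {
  cfg <- synth_config()
  traces <- generate_sample_traces(c(propionate = 1, butyrate = 1, total = 5),
                                   cfg, noise = FALSE)
  p <- extract_propionate_features(traces$prop_cent, traces$prop_noncent)
  b <- extract_butyrate_features(traces$butyrate)
  t <- extract_total_features(traces$total)

  pb <- assemble_pb_vector(p, b)
  expect_length(pb, 10)
  expect_identical(names(pb), pb_feature_names())
  expect_equal(unname(pb["C_I1"]), b$C_I1)

  tv <- assemble_total_vector(t, 1.2, 0.8)
  expect_length(tv, 7)
  expect_identical(names(tv), total_hier_feature_names())
  expect_equal(unname(tv[c("P1", "B1")]), c(1.2, 0.8))
  expect_error(assemble_total_vector(t, -0.1, 0.8), class = "vg_params_error")
})
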