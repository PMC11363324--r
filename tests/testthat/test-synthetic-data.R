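test_that("generators are seed-reproducible and leak no RNG state", {
  s <- frame_spec(rep(c("water1", "direct"), 5L), jitter_sd = 0.05, seed = 3L)
  g1 <- gen_bridge_frames(s)
  g2 <- gen_bridge_frames(s)
  expect_identical(g1, g2)

  t1 <- curve_truth(6.34, 65, noise_sd = 5, seed = 8L)
  expect_identical(gen_dose_response(t1), gen_dose_response(t1))

  a1 <- apex_truth(n_proteins = 60L,
                   changing_ids = "P0001",
                   indicator_map = list(plasma_membrane = c("P0051", "P0052"),
                                        early_endosome = c("P0053", "P0054"),
                                        lysosome = c("P0055", "P0056")),
                   seed = 4L)
  expect_identical(gen_apex_timecourse(a1), gen_apex_timecourse(a1))

  m1 <- mpe_truth(10.18, seed = 12L)
  expect_identical(gen_mpe_doses(m1), gen_mpe_doses(m1))

  # the global RNG stream is untouched by a generator call
  set.seed(77)
  before <- .Random.seed
  invisible(gen_dose_response(t1))
  expect_identical(.Random.seed, before)
})

test_that("frame truth labels are realized by construction", {
  labs <- rep(c("direct", "water1", "water2", "none"), times = c(5, 10, 7, 3))
  g <- gen_bridge_frames(frame_spec(labs, jitter_sd = 0, seed = 21L))
  expect_equal(classify_frames(g$frames)$label, g$truth$label)

  # jitter re-sampling keeps the designed class (frequencies match truth)
  labs2 <- sample(rep(c("water1", "none"), c(40, 60)))
  g2 <- gen_bridge_frames(frame_spec(labs2, jitter_sd = 0.05, seed = 22L))
  cl <- classify_frames(g2$frames)
  expect_equal(cl$label, g2$truth$label)
  expect_equal(mean(cl$label == "water1"), 0.4)

  # an impossible jitter request fails explicitly
  expect_error(gen_bridge_frames(frame_spec("water1", jitter_sd = 5,
                                            seed = 1L), max_tries = 10L),
               "impossible geometry")
  expect_error(frame_spec("waterX"), "unknown class")
  expect_error(frame_spec(character(0)), "at least one")
})

test_that("zero-noise 4PL responses lie exactly on the closed-form curve", {
  tr <- curve_truth(7.09, 71, hill = 1.2, noise_sd = 0, seed = 1L)
  d <- gen_dose_response(tr)
  expect_equal(d$response_pct,
               fourpl(d$conc_M, 71, 7.09, 1.2, 0), tolerance = 1e-12)
  # midpoint example
  expect_equal(fourpl(10^-7.09, 71, 7.09, 1.2, 0), 35.5)
  expect_error(curve_truth(7, 50, n_reps = 0), "n_reps")
  expect_error(curve_truth(7, 50, n_conc = 3), "n_conc")
})

test_that("APEX truth validates its invariants", {
  expect_error(apex_truth(mixing_series = matrix(c(0.5, 0.4, 0.0), 1),
                          time_points = 0, effect_profile = 0),
               "sum to 1")
  expect_error(apex_truth(indicator_map = list(a = "P0001", b = "P0001")),
               "disjoint")
  expect_error(apex_truth(changing_ids = "Q9999"), "changing_ids")
  tr <- apex_truth()
  expect_true(all(abs(rowSums(tr$mixing_series) - 1) < 1e-12))
})

test_that("constant plasma-membrane mixing deconvolves to (1,0,0) noiselessly", {
  mix <- matrix(rep(c(1, 0, 0), each = 6), nrow = 6)
  tr <- apex_truth(n_proteins = 60L, changing_ids = "P0001",
                   effect_profile = rep(0, 6),
                   indicator_map = list(plasma_membrane = c("P0041", "P0042"),
                                        early_endosome = c("P0043", "P0044"),
                                        lysosome = c("P0045", "P0046")),
                   mixing_series = mix, null_sd = 0, ref_noise_sd = 0,
                   seed = 2L)
  g <- gen_apex_timecourse(tr)
  co <- deconvolve_timecourse(g$data, tr$indicator_map)
  expect_equal(unname(as.matrix(co[, c("plasma_membrane", "early_endosome",
                                       "lysosome")])),
               matrix(rep(c(1, 0, 0), each = 18), ncol = 3),
               tolerance = 1e-9)
  expect_true(all(co$residual_norm < 1e-6 * max(g$data$intensity)))
})

test_that("a null APEX matrix yields no hits at the joint gate", {
  tr <- apex_truth(n_proteins = 120L, changing_ids = "P0001",
                   effect_profile = rep(0, 6), seed = 31L,
                   indicator_map = list(plasma_membrane = sprintf("P01%02d", 1:4),
                                        early_endosome = sprintf("P01%02d", 5:8),
                                        lysosome = sprintf("P01%02d", 9:12)))
  g <- gen_apex_timecourse(tr)
  res <- apex_pipeline(g$data, tr$indicator_map)
  expect_equal(sum(res$hits$hit), 0L)
})

test_that("%MPE generation is bounded and centred on the log-logistic", {
  tr <- mpe_truth(10, slope = 2, doses = c(3, 10, 30), n_subjects = 200L,
                  noise_sd = 10, seed = 6L)
  m <- gen_mpe_doses(tr)
  expect_true(all(m$mpe_pct >= 0 & m$mpe_pct <= 100))
  # saturating dose approaches the ceiling in the noiseless limit
  m0 <- gen_mpe_doses(mpe_truth(10, slope = 2, doses = c(3, 10, 3000),
                                noise_sd = 0, seed = 1L))
  expect_gt(min(m0$mpe_pct[m0$dose_mg_kg == 3000]), 99.9)
  expect_error(mpe_truth(10, doses = c(3, 3, 30)), "increasing")
  expect_error(mpe_truth(-1), "positive")
})
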