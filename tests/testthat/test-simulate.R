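test_that("noiseless simulation round-trips the generating size", {
  g <- make_globule()
  cur <- simulate_curve(g, add_noise = FALSE)
  fit <- guinier_fit(cur)
  rg_gen <- guinier_fit(saxs_curve(cur$q, attr(cur, "metadata")$ideal_I))$rg
  # same curve, but the simulated one carries sigma weights in the fit
  expect_equal(fit$rg, rg_gen, tolerance = 2e-3)
  expect_true(all(cur$sigma > 0))
})

test_that("simulation is seed-reproducible and sigma scales with SNR", {
  m <- fixture_dimer()
  a <- simulate_curve(m, seed = 5)
  b <- simulate_curve(m, seed = 5)
  expect_identical(a$I, b$I)
  c2 <- simulate_curve(m, noise = noise_model(snr = 1000), seed = 5)
  expect_true(all(c2$sigma <= a$sigma + 1e-12))
})

test_that("chi2 of the generating model against its own noisy curve is ~1", {
  m <- fixture_dimer()
  cur <- simulate_curve(m, seed = 42)
  ideal <- saxs_curve(cur$q, attr(cur, "metadata")$ideal_I)
  f <- chi2_fit(cur, ideal)
  expect_equal(f$chi2, 1, tolerance = 0.15)
  expect_equal(f$scale, 1, tolerance = 0.01)
})

test_that("a 20-degree hinge bend is distinguishable at high-precision noise", {
  m <- fixture_dimer()
  d20 <- make_decoys(m, 20)[[1]]
  dat <- simulate_curve(d20, noise = noise_model(snr = 1000), seed = 11)
  straight <- debye_intensity(m, dat$q, form_factor = "sphere")
  expect_gt(chi2_fit(dat, straight)$chi2, 1.5)
})

test_that("detector geometry converts to the advertised q range", {
  # 12 keV, 1.5 m: q at a ~250 mm radial position reaches ~1 A^-1;
  # the configured 0.008-0.5 A^-1 window sits well inside it
  expect_equal(q_from_geometry(0), 0)
  expect_gt(q_from_geometry(250), 0.5)
  expect_lt(q_from_geometry(2), 0.009)
})
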