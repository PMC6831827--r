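test_that("Debye limits and closed forms", {
  m2 <- two_center_model(12)
  q <- c(0, 0.05, 0.1, 0.3)
  cur <- debye_intensity(m2, q, weights = c(1, 1), method = "direct")
  expect_equal(cur$I[1], 4) # (sum f)^2 at q = 0
  expect_equal(cur$I[-1], 2 * (1 + sin(q[-1] * 12) / (q[-1] * 12)),
               tolerance = 1e-12)
})

test_that("histogram acceleration matches the direct double sum", {
  m <- fixture_dimer() # 338 centers
  q <- seq(0.01, 0.5, length.out = 40)
  a <- debye_intensity(m, q, method = "histogram")
  b <- debye_intensity(m, q, method = "direct")
  expect_lt(max(abs(a$I - b$I) / b$I), 0.005)
})

test_that("Debye reciprocity: P(r) route agrees with the double sum", {
  m <- fixture_dimer()
  pr <- pr_from_structure(m, bin_width = 0.25, smear = 0)
  q <- seq(0.01, 0.5, length.out = 30)
  via_pr <- pr_to_saxs(pr, q)
  direct <- debye_intensity(m, q, method = "direct")
  expect_lt(max(abs(via_pr$I - direct$I) / direct$I), 0.01)
})

test_that("Guinier fit recovers synthetic and spherical references", {
  q <- seq(0.0085, 0.05, length.out = 200)
  cur <- saxs_curve(q, 100 * exp(-q^2 * 63.4^2 / 3))
  # exact exponential: lm warns about a perfect fit
  g <- suppressWarnings(guinier_fit(cur, qmin = 0.0085, qmax = 0.018))
  expect_equal(g$rg, 63.4, tolerance = 1e-6)
  expect_equal(g$i0, 100, tolerance = 1e-6)
  # solid sphere: Rg -> sqrt(3/5) R as the window shrinks
  R <- 30
  qs <- seq(1e-3, 0.05, length.out = 400)
  sp <- sphere_curve(R, qs)
  gs <- guinier_fit(sp, qmin = 1e-3, qmax = 0.012)
  expect_equal(gs$rg, sqrt(3 / 5) * R, tolerance = 0.01)
  expect_error(guinier_fit(saxs_curve(q[1:6], rep(1, 6))), "slope|window")
  neg <- saxs_curve(q, 100 * exp(-q^2 * 100^2 / 3) - 50)
  expect_error(guinier_fit(neg, qmin = 0.03, qmax = 0.05), "non-positive")
})

test_that("Guinier on a noiseless globular simulation recovers Rg within 2%", {
  g <- make_globule()
  cur <- simulate_curve(g, add_noise = FALSE)
  fit <- guinier_fit(cur)
  # reference includes the residue-sphere form-factor contribution
  rg_ref <- sqrt(model_rg(g, weights = rep(1, nrow(g)))^2 +
                   3 * (sqrt(3 / 5) * jiptandem:::default_residue_radius())^2)
  expect_equal(fit$rg, rg_ref, tolerance = 0.02)
})

test_that("dimensionless Kratky of the Guinier law peaks at (sqrt(3), 3/e)", {
  q <- seq(1e-4, 0.2, length.out = 5000)
  rg <- 30
  cur <- saxs_curve(q, 100 * exp(-q^2 * rg^2 / 3))
  k <- dimensionless_kratky(cur, rg = rg, i0 = 100)
  pk <- kratky_peak(k)
  expect_equal(pk$height, 3 / exp(1), tolerance = 1e-4)
  expect_equal(pk$qrg, sqrt(3), tolerance = 1e-3)
  # flat curve: monotone increasing, maximum at the cutoff boundary
  flat <- saxs_curve(q, rep(100, length(q)))
  kf <- dimensionless_kratky(flat, rg = rg, i0 = 100, cutoff = 5)
  expect_true(all(diff(kf$y) > 0))
  expect_equal(kratky_peak(kf)$qrg, max(kf$qrg[kf$qrg <= 5]))
})

test_that("P(r) from structure: histogram, smearing and moments", {
  m2 <- two_center_model(20)
  pr <- pr_from_structure(m2, bin_width = 1, smear = 0, weights = c(1, 1))
  expect_equal(pr$r[which.max(pr$p)], 20)
  expect_equal(sum(pr$p > 0), 1L) # single occupied bin
  m <- fixture_dimer()
  prm <- pr_from_structure(m)
  s <- pr_summary(prm)
  expect_equal(s$mode_r, 17, tolerance = 3 / 17)
  expect_equal(s$dmax, max_extent(m))
  # Rg from P(r) equals the coordinate Rg within 1% (smearing adds ~0.2%)
  expect_equal(s$rg, model_rg(m), tolerance = 0.01)
})

test_that("indirect transform recovers a known P(r)", {
  set.seed(42)
  R <- 30
  r <- seq(0, 2 * R, length.out = 101)
  x <- r / (2 * R)
  p_true <- r^2 * (1 - 1.5 * x + 0.5 * x^3)
  pr0 <- jiptandem:::new_pair_distribution(r, p_true, dmax = 2 * R)
  q <- seq(0.008, 0.35, length.out = 300)
  ideal <- pr_to_saxs(pr0, q)
  sig <- 0.005 * max(ideal$I) * sqrt(ideal$I / max(ideal$I) + 0.01)
  dat <- saxs_curve(q, ideal$I + rnorm(length(q), 0, sig), sig)
  fit <- ift_pr(dat, dmax = 60)
  l2 <- sqrt(sum((fit$p / sqrt(sum(fit$p^2)) -
                    p_true / sqrt(sum(p_true^2)))^2))
  expect_lt(l2, 0.05)
  expect_equal(attr(fit, "rg"), sqrt(sum(r^2 * p_true) / (2 * sum(p_true))),
               tolerance = 0.01)
  expect_lt(attr(fit, "chi2"), 1.5)
})

test_that("indirect transform localizes an isolated pair distance", {
  m2 <- two_center_model(20)
  q <- seq(0.01, 0.6, length.out = 250)
  cur <- debye_intensity(m2, q, weights = c(1, 1), method = "direct")
  cross <- cur$I - 2 # remove the self term; the pair term remains
  dat <- saxs_curve(q, cross, rep(0.01, length(q)))
  fit <- ift_pr(dat, dmax = 30)
  expect_equal(attr(fit, "mode_r"), 20, tolerance = 2 / 20)
})

test_that("Porod/MoW mass: dimer simulation, sphere volume, scale invariance", {
  m <- fixture_dimer()
  cur <- simulate_curve(m, seed = 7)
  g <- guinier_fit(cur)
  est <- porod_mow_mass(cur, g)
  fx <- fixture_seqs()
  dimer_kda <- 2 * sequence_mass_kda(extract_region(fx$jip3, 22, 187))
  expect_equal(est$mass_kda, dimer_kda, tolerance = 0.10)
  # intensity scaling cancels
  cur2 <- saxs_curve(cur$q, cur$I * 37, cur$sigma * 37)
  est2 <- porod_mow_mass(cur2, guinier_fit(cur2))
  expect_equal(est2$mass_kda, est$mass_kda, tolerance = 1e-6)
  # solid sphere: apparent volume approaches the true volume once the
  # integration window extends well past the particle's Porod region
  R <- 25
  qs <- seq(5e-4, 1.0, length.out = 3000)
  sp <- sphere_curve(R, qs)
  gs <- guinier_fit(sp, qmin = 5e-4, qmax = 0.012)
  es <- porod_mow_mass(sp, gs, q_m = 1.0)
  expect_equal(es$apparent_volume, 4 / 3 * pi * R^3, tolerance = 0.05)
  expect_error(porod_mow_mass(saxs_curve(cur$q[cur$q < 0.3], cur$I[cur$q < 0.3]), g),
               "reaches only")
})

test_that("chi-square fitting: exact match, known scale, invariances", {
  q <- seq(0.01, 0.4, length.out = 500)
  model <- saxs_curve(q, 1000 * exp(-q^2 * 100))
  dat_exact <- saxs_curve(q, model$I, sigma = rep(1, 500))
  f0 <- chi2_fit(dat_exact, model)
  expect_equal(f0$chi2, 0)
  expect_equal(f0$scale, 1)
  set.seed(11)
  dat <- saxs_curve(q, 2 * model$I + rnorm(500), sigma = rep(1, 500))
  f <- chi2_fit(dat, model)
  expect_equal(f$scale, 2, tolerance = 1e-3)
  expect_equal(f$chi2, 1, tolerance = 0.1)
  # rescaling the model curve is absorbed by the fitted scale
  f2 <- chi2_fit(dat, saxs_curve(q, model$I * 1e4))
  expect_equal(f2$chi2, f$chi2, tolerance = 1e-9)
  expect_error(chi2_fit(saxs_curve(q, model$I), model), "uncertainties")
  short <- saxs_curve(q[100:400], model$I[100:400])
  expect_error(chi2_fit(dat, short), "cover")
})

test_that("curve io round-trips the 3-column dialect and converts units", {
  q <- seq(0.01, 0.3, length.out = 50)
  cur <- saxs_curve(q, exp(-q^2 * 500), sigma = rep(0.01, 50))
  path <- withr::local_tempfile(fileext = ".dat")
  write_saxs(cur, path, comment = "# synthetic")
  back <- read_saxs(path)
  expect_equal(back$q, cur$q, tolerance = 1e-6)
  expect_equal(back$I, cur$I, tolerance = 1e-6)
  expect_equal(back$sigma, cur$sigma, tolerance = 1e-6)
  # nm^-1 input converts to A^-1
  writeLines(c("# q(nm^-1) I sigma",
               sprintf("%.8e %.6e %.6e", q * 10, cur$I, cur$sigma)), path)
  conv <- read_saxs(path, q_unit = "nm^-1")
  expect_equal(conv$q, cur$q, tolerance = 1e-6)
})
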