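test_that("perturbation: identity at zero amplitude, determinism, clash-free", {
  m <- fixture_dimer()
  expect_identical(perturb_flexible(m, amplitude_deg = 0), m)
  set.seed(7); p1 <- perturb_flexible(m)
  set.seed(7); p2 <- perturb_flexible(m)
  expect_identical(p1, p2)
  expect_gte(jiptandem:::min_nonbonded_distance(p1, 2L), 2.5)
})

test_that("perturbation keeps rigid bodies internally rigid", {
  m <- fixture_dimer()
  set.seed(3)
  p <- perturb_flexible(m, amplitude_deg = 25)
  for (rng in list(c(26, 66), c(78, 176))) {
    X0 <- as.matrix(m[m$resno >= rng[1] & m$resno <= rng[2], c("x", "y", "z")])
    X1 <- as.matrix(p[p$resno >= rng[1] & p$resno <= rng[2], c("x", "y", "z")])
    expect_lt(jiptandem:::kabsch_rmsd(X1, X0), 1e-6)
  }
})

test_that("tail-only moves preserve the dimer two-fold exactly", {
  m <- fixture_dimer()
  tails <- flexibility_mask(rigid = list(c(26, 176)),
                            flexible = list(c(19, 25), c(177, 187)))
  set.seed(5)
  for (i in 1:5) {
    p <- perturb_flexible(m, tails, amplitude_deg = 20)
    expect_lt(dimer_symmetry_rmsd(p), 0.1)
  }
})

test_that("linker perturbations explore a broad Rg range", {
  m <- fixture_dimer()
  set.seed(9)
  rgs <- replicate(250, model_rg(perturb_flexible(m, linker_only_mask())))
  expect_gte(diff(range(c(rgs, model_rg(m)))), 3.5)
})

test_that("decoys bend deterministically and shorten the particle", {
  m <- fixture_dimer()
  expect_identical(make_decoys(m, 0)[[1]], m)
  dec <- make_decoys(m, c(10, 20, 30))
  ext <- vapply(dec, max_extent, numeric(1))
  expect_true(all(diff(ext) < 0))
  expect_equal(vapply(dec, hinge_angle, numeric(1)), c(10, 20, 30),
               tolerance = 0.02)
})

test_that("refinement against self-data is a no-op improvement", {
  m <- fixture_dimer()
  dat <- simulate_curve(m, noise = noise_model(snr = 1000), seed = 21)
  rr <- refine_against_saxs(m, dat,
                            settings = refinement_settings(population = 8,
                                                           generations = 5,
                                                           n_runs = 1, seed = 2))
  expect_equal(rr$chi2_final, 1, tolerance = 0.2)
  expect_lte(rr$chi2_final, rr$chi2_initial)
  expect_lt(jiptandem:::kabsch_rmsd(as.matrix(rr$best[, c("x", "y", "z")]),
                                    as.matrix(m[, c("x", "y", "z")])), 3)
})

test_that("best-so-far chi2 trace never increases", {
  m <- fixture_dimer()
  d10 <- make_decoys(m, 10)[[1]]
  dat <- simulate_curve(d10, noise = noise_model(snr = 1000), seed = 31)
  rr <- refine_against_saxs(m, dat,
                            settings = refinement_settings(population = 8,
                                                           generations = 8,
                                                           n_runs = 2, seed = 4))
  for (tr in split(rr$trace$chi2, rr$trace$run)) {
    expect_true(all(diff(tr) <= 1e-12))
  }
  expect_error(refine_against_saxs(m, saxs_curve(dat$q, dat$I)),
               "uncertainties")
})

test_that("pool generation: zero amplitude collapses, extension is bounded", {
  m <- fixture_dimer()
  frozen <- generate_pool(m, linker_only_mask(amplitude_deg = 0), n = 10,
                          seed = 1)
  expect_true(all(abs(frozen$rg - frozen$rg[1]) < 1e-9))
  pool <- generate_pool(m, n = 150, seed = 3)
  # the straight start is the most extended conformer reachable by bending
  expect_lte(max(pool$rg), rg_from_beads(beads_per_residue(m)) + 1)
  # pool-mean Rg is stable across seeds
  pool2 <- generate_pool(m, n = 150, seed = 4)
  expect_lt(abs(mean(pool$rg) - mean(pool2$rg)), 0.5)
})

test_that("ensemble selection recovers a planted conformer and shifts with the data", {
  m <- fixture_dimer()
  pool <- generate_pool(m, n = 150, seed = 3)
  # data generated from the most extended pool member
  ext <- which.max(pool$rg)
  target <- jiptandem:::with_xyz(m, pool$xyz[[ext]])
  dat <- simulate_curve(target, noise = noise_model(snr = 1000), seed = 12)
  sel <- select_ensemble(pool, dat, ensemble_settings(n_runs = 2, seed = 2))
  expect_lte(sel$chi2, sel$chi2_best_single + 1e-9)
  expect_lt(abs(sel$mean_rg_selected - pool$rg[ext]), 1)
  expect_gt(sel$mean_rg_selected, sel$mean_rg_pool)
  # reproducibility
  sel2 <- select_ensemble(pool, dat, ensemble_settings(n_runs = 2, seed = 2))
  expect_identical(sel$members, sel2$members)
  expect_identical(sel$chi2, sel2$chi2)
})
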