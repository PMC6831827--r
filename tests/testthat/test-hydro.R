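test_that("bead construction: census, radii, total mass", {
  m <- fixture_dimer()
  b <- beads_per_residue(m)
  expect_equal(nrow(b), 338L) # 2 x (GSH + 22-187)
  expect_true(all(b$radius == 4.9))
  fx <- fixture_seqs()
  expect_equal(sum(b$weight) / 1000,
               2 * sequence_mass_kda(extract_region(fx$jip3, 22, 187)),
               tolerance = 0.1 / 40)
  single <- beads_per_residue(new_protein_model(
    data.frame(chain = "A", resno = 1L, res = "G", x = 0, y = 0, z = 0)))
  expect_equal(nrow(single), 1L)
})

test_that("bead Rg closed forms and the assembled-model prediction", {
  b1 <- bead_model(c(0, 0, 0), radius = 5)
  expect_equal(rg_from_beads(b1), sqrt(3 / 5) * 5)
  b2 <- bead_model(rbind(c(0, 0, 0), c(0, 0, 10)), radius = 1e-6)
  expect_equal(rg_from_beads(b2), 5, tolerance = 1e-6)
  m <- fixture_dimer()
  expect_equal(rg_from_beads(beads_per_residue(m)), 64, tolerance = 3 / 64)
})

test_that("Kirkwood Rh closed forms and invariances", {
  a <- 5
  expect_equal(kirkwood_rh(bead_model(c(0, 0, 0), radius = a)), a / 10)
  two <- bead_model(rbind(c(0, 0, 0), c(0, 0, 2 * a)), radius = a)
  expect_equal(kirkwood_rh(two), (4 * a / 3) / 10, tolerance = 1e-12)
  # rigid rotation + translation leave Rh unchanged
  m <- fixture_dimer()
  b <- beads_per_residue(m)
  R <- jiptandem:::rotation3(c(1, 2, 3), 1.1)
  xyz2 <- sweep(cbind(b$x, b$y, b$z) %*% t(R), 2, c(10, -5, 3), "+")
  b2 <- bead_model(xyz2, radius = b$radius, weight = b$weight)
  expect_equal(kirkwood_rh(b2), kirkwood_rh(b), tolerance = 1e-9)
  expect_error(kirkwood_rh(bead_model(rbind(c(0, 0, 0), c(0, 0, 0)), radius = 1)),
               "coincident")
})

test_that("frictional ratio of any multi-bead model is at least 1", {
  # volume-equivalent-sphere comparison on dissimilar shapes
  shapes <- list(
    beads_per_residue(fixture_dimer()),
    beads_per_residue(make_globule(15, 5.1))
  )
  for (b in shapes) {
    rh <- kirkwood_rh(b)
    fr <- frictional_ratio(rh, sum(b$weight) / 1000)
    expect_gte(fr, 1 - 0.02)
  }
})

test_that("Svedberg relation and frictional ratio reproduce the tandem values", {
  expect_equal(sedimentation_coefficient(40.6, 0.73, 4.4), 2.2,
               tolerance = 0.2 / 2.2)
  # s -> 0 as Rh grows; doubling mass doubles s
  expect_lt(sedimentation_coefficient(40.6, 0.73, 4400),
            sedimentation_coefficient(40.6, 0.73, 4.4) / 100)
  expect_equal(sedimentation_coefficient(81.2, 0.73, 4.4),
               2 * sedimentation_coefficient(40.6, 0.73, 4.4))
  expect_error(sedimentation_coefficient(40.6, 1.2, 4.4), "sediment")
  expect_equal(frictional_ratio(4.4, 40.6), 1.9, tolerance = 0.15 / 1.9)
  expect_equal(frictional_ratio(3.5, 29.6), 1.75, tolerance = 0.05 / 1.75)
  # compact sphere: Rh equal to the anhydrous radius gives f/f0 = 1
  r0 <- (3 * 40.6e3 * 0.73 / (4 * pi * 6.02214076e23))^(1 / 3) * 1e7
  expect_equal(frictional_ratio(r0, 40.6), 1, tolerance = 1e-9)
})

test_that("Svedberg closure: s computed two ways agrees to 1e-6", {
  sol <- solvent_conditions()
  mass <- 40.6; vbar <- 0.73; rh <- 4.4
  s1 <- sedimentation_coefficient(mass, vbar, rh, sol)
  fr <- frictional_ratio(rh, mass, vbar)
  r0 <- rh / fr
  s2 <- sedimentation_coefficient(mass, vbar, r0 * fr, sol)
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("hydro_predict summarizes the pipeline quantities coherently", {
  m <- fixture_dimer()
  h <- hydro_predict(m)
  b <- beads_per_residue(m)
  expect_equal(h$rg_a, rg_from_beads(b))
  expect_equal(h$rh_nm, kirkwood_rh(b))
  expect_equal(h$s_sved,
               sedimentation_coefficient(h$mass_kda, h$vbar, h$rh_nm))
  expect_equal(h$f_ratio, frictional_ratio(h$rh_nm, h$mass_kda, h$vbar))
  g <- glance(h)
  expect_equal(g$rh_nm, h$rh_nm)
})
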