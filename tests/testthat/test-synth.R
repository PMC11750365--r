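test_that("generated tables validate, start at the designed grid, and are
           deterministic under a seed", {
  nm <- noise_model(cv = 0.15, seed = 42)
  t1 <- gen_assay_table(fixture_params(), noise = nm)
  t2 <- gen_assay_table(fixture_params(), noise = nm)
  expect_identical(t1, t2)
  expect_silent(validate_assay_table(t1))
  expect_setequal(unique(t1$assay_type),
                  c("mono_1", "mono_2", "inter_1", "inter_2",
                    "feed_1", "feed_2"))
  expect_setequal(unique(t1$n0[t1$assay_type == "mono_1"]),
                  c(5, 50, 100, 300, 600, 1000))
  expect_setequal(unique(t1$n0[t1$assay_type == "mono_2"]),
                  c(0.0095, 0.59, 0.13, 1.64, 3.91, 7.66, 9.24))
  expect_true(all(t1$competitor_density[t1$assay_type == "inter_1"] == 1.33))
  expect_true(all(t1$competitor_density[t1$assay_type == "inter_2"] == 100))
  expect_true(all(t1$duration_days[grepl("feed", t1$assay_type)] == 1))
  # frond counts are integers under noise
  expect_true(all(t1$n_final[t1$assay_type == "mono_1"] ==
                  round(t1$n_final[t1$assay_type == "mono_1"])))
})

test_that("a monoculture started at carrying capacity stays there (cv = 0)", {
  truth <- fixture_params()
  d <- design_spec()
  d$mono_1$levels <- c(5, 1 / truth$a11)
  tab <- gen_assay_table(truth, d, noise_model(cv = 0))
  atK <- tab$assay_type == "mono_1" & tab$n0 == 1 / truth$a11
  expect_equal(tab$n_final[atK], tab$n0[atK], tolerance = 1e-9)
})

test_that("reset emulation mode differs from the clamped idealization", {
  truth <- fixture_params()
  clamp <- gen_assay_table(truth, noise = noise_model(cv = 0))
  reset <- gen_assay_table(truth, noise = noise_model(cv = 0),
                           fixed_mode = "reset")
  i1c <- clamp$n_final[clamp$assay_type == "inter_1"]
  i1r <- reset$n_final[reset$assay_type == "inter_1"]
  # competitor regrows between daily resets, so suppression is stronger
  expect_true(all(i1r <= i1c + 1e-9))
  expect_gt(max(abs(i1r - i1c) / i1c), 0.01)
  # non-fixed assays are unaffected by the mode
  expect_equal(clamp$n_final[clamp$assay_type == "mono_1"],
               reset$n_final[reset$assay_type == "mono_1"])
})

test_that("microcosm endpoints reflect the benefit condition and collapse", {
  truth <- fixture_params()   # beta1/beta2 < a12/a22
  mc <- gen_microcosm(truth, n_rep = 3, noise = noise_model(cv = 0))
  g <- per_capita_growth(mc$n1_0, pmax(mc$n1_final, 1e-12), mc$duration_days)
  g0 <- tapply(g[mc$n_herbivores == 0], mc$treatment[mc$n_herbivores == 0], mean)
  g1 <- tapply(g[mc$n_herbivores == 1], mc$treatment[mc$n_herbivores == 1], mean)
  # focal grows faster with one herbivore in every starting combination
  expect_true(all(g1 > vapply(
    sub("_h1$", "_h0", names(g1)), function(k) g0[[k]], numeric(1))))
  # two herbivores: both species collapse below 1% of start by day 150
  p2 <- truth; p2$Nh <- 2
  tr <- simulate_model(p2, c(300, 4.1), t_end = 150, times = 150)
  expect_lt(tr$N1[nrow(tr)], 0.01 * 300)
  expect_lt(tr$N2[nrow(tr)], 0.01 * 4.1)
  # cv = 0 microcosm equals the deterministic simulation at day 14
  p0 <- truth; p0$Nh <- 0
  det <- simulate_model(p0, c(1000, 0.9), t_end = 14, times = 14)
  row <- mc$n_herbivores == 0 & mc$n1_0 == 1000 & mc$replicate == 1
  expect_equal(mc$n1_final[row], det$N1[nrow(det)], tolerance = 1e-8)
})

test_that("field series reproduces the normalized-fitness formula", {
  ctr <- c(10, 20, 30, 40)
  fs <- gen_field_series(2 * ctr, ctr)
  expect_equal(fs$nfc, rep(0.5, 4))
  expect_equal(gen_field_series(ctr, ctr)$nfc, rep(0, 4))
  nm <- noise_model(cv = 0.1, seed = 2)
  expect_identical(gen_field_series(2 * ctr, ctr, nm),
                   gen_field_series(2 * ctr, ctr, nm))
  expect_error(gen_field_series(1, 1), "length")
})

test_that("noise model contracts hold", {
  expect_error(noise_model(cv = -0.1), "cv")
  expect_error(noise_model(cv = 0.2), "seed")
  expect_false(noise_model(cv = 0)$integerize)
  expect_true(noise_model(cv = 0.1, seed = 1)$integerize)
})
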