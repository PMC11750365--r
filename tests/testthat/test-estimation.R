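# Round-trip and contract tests for the assay estimators. The synthetic
# generator (numerical integration) and the estimators (closed-form
# constant-environment solution) are independent routes to the same model,
# so noiseless recovery is a genuine two-sided check.

noiseless_table <- function(truth = positive_truth(), n_rep = NULL) {
  gen_assay_table(truth, design_spec(n_rep), noise_model(cv = 0))
}

test_that("monoculture estimator recovers (r, a) from a noiseless gradient", {
  tab <- noiseless_table()
  m1 <- estimate_intraspecific(tab[tab$assay_type == "mono_1", ])
  expect_equal(m1$r, 0.3, tolerance = 1e-6)
  expect_equal(m1$a, 0.001, tolerance = 1e-6)
  expect_identical(m1$method, "ode-fit")
  m2 <- estimate_intraspecific(tab[tab$assay_type == "mono_2", ],
                               method = "growth-regression")
  # growth-regression is the biased closed form: right scale, not exact
  expect_equal(m2$r, 0.7, tolerance = 0.35)
  expect_identical(m2$method, "growth-regression")
})

test_that("flat per-capita growth gives a = 0 under growth-regression", {
  rec <- data.frame(assay_type = "mono_1", replicate = 1:3,
                    n0 = c(10, 100, 1000),
                    n_final = c(10, 100, 1000) * exp(0.2 * 7),
                    duration_days = 7, competitor_density = 0,
                    n_herbivores = 0, reset_times = "")
  m <- estimate_intraspecific(rec, method = "growth-regression")
  expect_equal(m$a, 0)
  expect_equal(m$r, 0.2, tolerance = 1e-12)
})

test_that("single-density designs are rejected as non-identifiable", {
  rec <- data.frame(assay_type = "mono_1", replicate = 1:3, n0 = 100,
                    n_final = c(180, 190, 200), duration_days = 7,
                    competitor_density = 0, n_herbivores = 0,
                    reset_times = "")
  expect_error(estimate_intraspecific(rec), "distinct initial densities")
})

test_that("interspecific estimator recovers a12/a21, including zero effect", {
  tab <- noiseless_table()
  i1 <- estimate_interspecific(tab[tab$assay_type == "inter_1", ],
                               r = 0.3, a_ii = 0.001)
  expect_equal(i1$a_ij, 0.09, tolerance = 1e-6)
  # zero interspecific effect: identical growth with and without competitor
  truth0 <- fixture_params()  # a21 = 0
  tab0 <- gen_assay_table(truth0, noise = noise_model(cv = 0))
  i2 <- estimate_interspecific(tab0[tab0$assay_type == "inter_2", ],
                               r = 0.7, a_ii = 0.1)
  expect_lt(abs(i2$a_ij), 1e-7)
  # growth-regression route with matched monocultures
  g2 <- estimate_interspecific(tab0[tab0$assay_type == "inter_2", ],
                               r = 0.7, a_ii = 0.1,
                               method = "growth-regression",
                               mono_records = tab0[tab0$assay_type == "mono_2", ])
  expect_lt(abs(g2$a_ij), 1e-7)
  # design errors
  rec <- tab[tab$assay_type == "inter_1", ]
  rec$competitor_density <- 0
  expect_error(estimate_interspecific(rec, 0.3, 0.001), "design error")
})

test_that("consumption estimator recovers beta and enforces both arms", {
  tab <- noiseless_table()
  f1 <- estimate_consumption(tab[tab$assay_type == "feed_1", ],
                             r = 0.3, a_ii = 0.001)
  expect_equal(f1$beta, 0.6, tolerance = 1e-6)
  # equal arms -> beta 0 under the closed-form contrast
  rec <- data.frame(assay_type = "feed_1", replicate = c(1:3, 1:3),
                    n0 = 100, n_final = 120, duration_days = 1,
                    competitor_density = 0, n_herbivores = c(1, 1, 1, 0, 0, 0),
                    reset_times = "")
  f0 <- estimate_consumption(rec, r = 0.3, a_ii = 0.001,
                             method = "growth-regression")
  expect_equal(f0$beta, 0)
  expect_error(estimate_consumption(rec[rec$n_herbivores > 0, ], 0.3, 0.001),
               "both a herbivore arm and a control arm")
  # negative estimates are floored with a warning, raw value kept
  rec$n_final[rec$n_herbivores > 0] <- 150
  expect_warning(fneg <- estimate_consumption(rec, 0.3, 0.001,
                                              method = "growth-regression"),
                 "floored")
  expect_equal(fneg$beta, 0)
  expect_lt(fneg$beta_raw, 0)
})

test_that("estimate_all recovers the full truth and reports missing assays", {
  tab <- noiseless_table()
  est <- estimate_all(tab)
  expect_equal(unname(est$point), unname(truth_vec(positive_truth())),
               tolerance = 1e-6)
  expect_error(estimate_all(tab[tab$assay_type != "feed_1", ]), "feed_1")
})

test_that("bootstrap is deterministic, degenerate when noiseless, and zeroes
           coefficients whose interval spans 0", {
  tab <- gen_assay_table(fixture_params(), design_spec(4),
                         noise_model(cv = 0.1, seed = 7))
  b1 <- bootstrap_params(tab, n_boot = 60, seed = 11)
  b2 <- bootstrap_params(tab, n_boot = 60, seed = 11)
  expect_identical(b1, b2)                       # byte-identical under seed
  expect_true(all(b1$lower <= b1$upper))
  expect_true(all(b1$lower <= b1$point + 1e-9) &&
              all(b1$point <= b1$upper + 1e-9))
  # a21 is 0 in truth: its interval spans 0 and the zeroed variant drops it
  expect_identical(unname(b1$zeroed["a21"]), 0)
  changed <- names(b1$point)[b1$zeroed != b1$point]
  spans <- names(b1$point)[b1$lower <= 0 & b1$upper >= 0]
  expect_true(all(changed %in% spans))
  # noiseless table: no sampling variability. Replicate resampling returns
  # identical tables (width exactly 0); residual resampling only sees the
  # integrator-vs-closed-form numerical floor.
  b0 <- bootstrap_params(noiseless_table(), n_boot = 30, seed = 1,
                         resample = "replicate")
  expect_true(all(b0$upper - b0$lower < 1e-9))
  br <- bootstrap_params(noiseless_table(), n_boot = 30, seed = 1)
  expect_true(all((br$upper - br$lower) / abs(br$point) < 1e-6))
  expect_error(bootstrap_params(tab, n_boot = 60), "seed")
})

test_that("estimation JSON serialisation carries points, intervals and meta", {
  tab <- gen_assay_table(fixture_params(), design_spec(4),
                         noise_model(cv = 0.1, seed = 3))
  b <- bootstrap_params(tab, n_boot = 30, seed = 5)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_estimation(b, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$a11$point, unname(b$point["a11"]), tolerance = 1e-12)
  expect_equal(j$n_boot, 30)
  expect_equal(j$a21$zeroed, 0)
})
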