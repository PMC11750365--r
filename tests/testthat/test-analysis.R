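test_that("isoclines are zero-growth loci and match hand values", {
  p <- model_params(r1 = 1, r2 = 1, a11 = 0.1, a12 = 0.5, a21 = 0,
                    a22 = 0.2, beta1 = 0, beta2 = 0, Nh = 0)
  expect_equal(isocline(p, 0, species = 1), 1 / 0.1)   # 1/a11 at N2 = 0
  expect_equal(isocline(p, 2, species = 1), 0)          # (1 - 0.5*2)/0.1
  set.seed(3)
  for (i in 1:25) {
    q <- random_params()
    n2 <- runif(5, 0, 0.8 / q$a22)
    n1 <- isocline(q, n2, species = 1)
    pos <- n1 > 0
    for (j in which(pos)) {
      f <- rhs(c(n1[j], n2[j]), q)
      expect_lt(abs(f[1]) / (q$r1 * n1[j]), 1e-12)
    }
  }
})

test_that("invasion analysis reproduces the resident equilibria and verdicts", {
  # no herbivore: residents identical, verdict neutral
  p <- model_params(r1 = 0.3, r2 = 0.5, a11 = 0.01, a12 = 0.1, a21 = 0,
                    a22 = 0.5, beta1 = 0.1, beta2 = 0.2, Nh = 0)
  inv <- invasion_analysis(p)
  expect_equal(inv$N2w, 2)
  expect_equal(inv$N2wo, 2)
  expect_identical(inv$benefit, "neutral")
  # beta1/beta2 = 0.1 < a12/a22 = 2 -> benefit
  q <- model_params(r1 = 0.3, r2 = 0.5, a11 = 0.01, a12 = 0.004, a21 = 0,
                    a22 = 0.002, beta1 = 0.02, beta2 = 0.2, Nh = 1)
  expect_identical(invasion_analysis(q)$benefit, "benefit")
  expect_gt(invasion_analysis(q)$margin, 0)
  # boundary beta1/beta2 == a12/a22 -> exactly neutral
  b <- model_params(r1 = 0.3, r2 = 0.5, a11 = 0.01, a12 = 0.05, a21 = 0,
                    a22 = 0.1, beta1 = 0.25, beta2 = 0.5, Nh = 1)
  expect_identical(invasion_analysis(b)$benefit, "neutral")
  expect_equal(invasion_analysis(b)$margin, 0)
  # resident collapse flag and N2w floor
  cl <- model_params(r1 = 0.3, r2 = 0.5, a11 = 0.01, a12 = 0.05, a21 = 0,
                     a22 = 0.1, beta1 = 0.1, beta2 = 1.5, Nh = 1)
  expect_true(invasion_analysis(cl)$resident_collapsed)
  expect_equal(invasion_analysis(cl)$N2w, 0)
})

test_that("herbivory_benefit is the coefficient-ratio rule with edge cases", {
  base <- list(r1 = 0.3, r2 = 0.5, a11 = 0.01, a22 = 0.1, Nh = 1)
  mk <- function(a12, beta1, beta2)
    do.call(model_params, c(base, list(a12 = a12, a21 = 0, beta1 = beta1,
                                       beta2 = beta2)))
  expect_identical(herbivory_benefit(mk(0.05, 0, 0.3))$verdict, "benefit")
  expect_identical(herbivory_benefit(mk(0, 0.2, 0.3))$verdict, "harm")
  expect_error(herbivory_benefit(mk(0.05, 0.2, 0)), "beta2")
  # verdict equals the IGR comparison on the interior-resident domain
  set.seed(17)
  for (i in 1:300) {
    p <- random_params(nh_choices = 1:2, interior_resident = TRUE)
    expect_identical(herbivory_benefit(p)$verdict,
                     invasion_analysis(p)$benefit)
  }
})

test_that("benefit verdict is density- and herbivore-number-independent", {
  set.seed(23)
  for (i in 1:20) {
    p <- random_params(nh_choices = 1, interior_resident = TRUE,
                       beta_max = 0.4)
    v <- herbivory_benefit(p)$verdict
    for (nh in c(0.5, 1, 2)) {           # stays within beta2*Nh < 1
      q <- p; q$Nh <- nh
      expect_identical(invasion_analysis(q)$benefit, v)
    }
  }
})

test_that("classify_outcome covers the canonical cases", {
  # mutual invasibility without herbivores
  p <- model_params(r1 = 0.3, r2 = 0.5, a11 = 0.01, a12 = 0.002, a21 = 0.004,
                    a22 = 0.1, beta1 = 0, beta2 = 0, Nh = 0)
  expect_identical(classify_outcome(p)$label, "coexistence")
  # both brackets negative under heavy herbivory
  q <- model_params(r1 = 0.3, r2 = 0.5, a11 = 0.01, a12 = 0.002, a21 = 0,
                    a22 = 0.1, beta1 = 0.8, beta2 = 0.9, Nh = 2)
  expect_identical(classify_outcome(q)$label, "both_collapse")
  # founder control: each cross effect exceeds the rival self-limitation
  f <- model_params(r1 = 0.3, r2 = 0.5, a11 = 0.01, a12 = 0.3, a21 = 0.03,
                    a22 = 0.1, beta1 = 0, beta2 = 0, Nh = 0)
  expect_identical(classify_outcome(f)$label, "founder_control")
})

test_that("classification agrees with the simulation oracle", {
  set.seed(29)
  n <- 40
  ok <- 0
  for (i in seq_len(n)) {
    p <- random_params(igr_margin = 0.01)
    if (classify_outcome(p)$label == sim_outcome(p)) ok <- ok + 1
  }
  expect_gte(ok / n, 0.99)
})

test_that("collapse_search finds the minimal collapsing herbivore number", {
  mk <- function(b1, b2) model_params(r1 = 0.3, r2 = 0.5, a11 = 0.01,
                                      a12 = 0.002, a21 = 0, a22 = 0.1,
                                      beta1 = b1, beta2 = b2, Nh = 0)
  expect_equal(collapse_search(mk(0.6, 0.7), 5)$min_collapse_Nh, 2L)
  expect_equal(collapse_search(mk(1.1, 1.2), 5)$min_collapse_Nh, 1L)
  res <- collapse_search(mk(0, 0), 5)
  expect_true(is.na(res$min_collapse_Nh))
  expect_equal(nrow(res$outcomes), 5)
  expect_error(collapse_search(mk(1, 1), 0), ">= 1")
})
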