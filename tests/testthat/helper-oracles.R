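# Shared helpers: random parameter draws and the simulation oracle used to
# cross-check the analytic outcome classification.

truth_vec <- function(p) {
  unlist(p[c("r1", "r2", "a11", "a12", "a21", "a22", "beta1", "beta2")])
}

# all-positive ground truth for strict relative round-trip checks
positive_truth <- function() {
  model_params(r1 = 0.3, r2 = 0.7, a11 = 0.001, a12 = 0.09, a21 = 2e-4,
               a22 = 0.1, beta1 = 0.6, beta2 = 1.1)
}

# Random valid parameter set. Cross coefficients are drawn relative to the
# competitor's self-limitation so all outcome classes occur. With
# `igr_margin` the draw is rejected until both invasion growth rates are
# bounded away from 0 (relative to r) and the herbivory brackets away from
# their collapse boundary.
random_params <- function(igr_margin = 0, nh_choices = 0:2,
                          beta_max = 0.8, interior_resident = FALSE) {
  repeat {
    nh <- sample(nh_choices, 1)
    b2 <- runif(1, if (interior_resident) 1e-3 else 0, beta_max)
    if (interior_resident && nh > 0) b2 <- min(b2, 0.99 / nh)
    p <- model_params(
      r1 = runif(1, 0.2, 1), r2 = runif(1, 0.2, 1),
      a11 = 1 / runif(1, 10, 1000), a22 = 1 / runif(1, 1, 100),
      a12 = 1, a21 = 1, beta1 = runif(1, 0, beta_max), beta2 = b2, Nh = nh)
    p$a12 <- runif(1, 0, 2) * p$a22
    p$a21 <- runif(1, 0, 2) * p$a11
    if (igr_margin > 0) {
      oc <- classify_outcome(p)
      if (abs(oc$IGR1) <= igr_margin * p$r1 ||
          abs(oc$IGR2) <= igr_margin * p$r2 ||
          abs(1 - p$beta1 * p$Nh) <= 0.02 ||
          abs(1 - p$beta2 * p$Nh) <= 0.02) next
    }
    return(p)
  }
}

# Long-run endpoint classification by simulation. Residents start at their
# herbivory-adjusted equilibrium, invaders at 0.2% of their carrying scale;
# a species is extinct when it ends below eps_frac of its start.
sim_outcome <- function(p, eps_frac = 0.01) {
  K1 <- max(0, 1 - p$beta1 * p$Nh) / p$a11
  K2 <- max(0, 1 - p$beta2 * p$Nh) / p$a22
  oc <- classify_outcome(p)
  t_end <- min(30000, max(300, 25 / max(min(abs(oc$IGR1), abs(oc$IGR2)),
                                        1e-3)))
  run <- function(init) {
    tr <- simulate_model(p, init, t_end = t_end, times = t_end)
    c(tr$N1[nrow(tr)], tr$N2[nrow(tr)])
  }
  surv <- function(end, init)
    c(end[1] > eps_frac * init[1], end[2] > eps_frac * init[2])
  iA <- c(max(K1, 0.002 / p$a11), 0.002 / p$a22)
  iB <- c(0.002 / p$a11, max(K2, 0.002 / p$a22))
  sA <- surv(run(iA), iA)
  sB <- surv(run(iB), iB)
  if (!any(sA) && !any(sB)) return("both_collapse")
  w1 <- sA[1] && !sA[2]
  w2 <- sB[2] && !sB[1]
  if (w1 && w2) return("founder_control")
  if ((sA[1] && sA[2]) || (sB[1] && sB[2])) return("coexistence")
  if (w1 || (sB[1] && !sB[2])) return("species1_excludes")
  if (w2 || (sA[2] && !sA[1])) return("species2_excludes")
  "ambiguous"
}
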