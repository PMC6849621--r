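test_that("growth rates match hand-evaluated dynamics", {
  ex <- three_species_example()
  # absorbing extinction and single-species logistic equilibrium
  expect_equal(growth_rate(c(0, 0, 0), ex$traits, ex$alpha), rep(0, 3))
  one <- species_traits(c = 0.4, d = 0.1, h = 0.9)
  expect_equal(growth_rate(one$k, one, competition_matrix(matrix(1))), 0)

  # random positive states against the scalar oracle
  pars <- ref_params()
  set.seed(51)
  for (k in 1:20) {
    n <- runif(3, 0, 0.8)
    expect_equal(growth_rate(n, ex$traits, ex$alpha), rate_oracle(n, pars))
  }
  expect_error(growth_rate(c(0.1, 0.2), ex$traits, ex$alpha), "dimension")
  expect_error(growth_rate(c(-0.1, 0.2, 0.1), ex$traits, ex$alpha),
               "non-negative")
})

test_that("pairwise equilibria agree with long-time integration", {
  ex <- three_species_example(h = 1)
  eq <- pairwise_equilibrium(ex$traits, ex$alpha)
  expect_equal(unname(eq$n_star), c(0.498, 0.190), tolerance = 1e-3)
  ode <- integrate_to_steady_state(c(0.05, 0.05, 0), ex$traits, ex$alpha)
  expect_true(ode$converged)
  expect_equal(unname(ode$state[1:2]), unname(eq$n_star), tolerance = 1e-6)

  # no interaction decouples the species
  tr <- species_traits(c = c(0.5, 0.8), d = 0.1, h = 1)
  eye <- competition_matrix(diag(2))
  eq0 <- pairwise_equilibrium(tr, eye)
  expect_equal(unname(eq0$n_star), tr$k)

  # infeasibility clip: k_i < alpha_ij * k_j excludes species i
  tr2 <- species_traits(c = c(0.12, 1.5), d = 0.1, h = 1)
  al2 <- competition_matrix(rbind(c(1, 0.9), c(0.2, 1)))
  eq2 <- pairwise_equilibrium(tr2, al2)
  expect_equal(unname(eq2$n_star[1]), 0)
  expect_equal(unname(eq2$n_star[2]), tr2$k[2])

  expect_error(pairwise_equilibrium(tr, competition_matrix(rbind(c(1, 2), c(0.5, 1)))),
               "degenerate")
})

test_that("the fugitive equilibrates on top of the residents", {
  ex <- three_species_example(h = 1)
  eq <- pairwise_equilibrium(ex$traits, ex$alpha)
  n3 <- fugitive_equilibrium(ex$traits, ex$alpha, eq$n_star)
  expect_equal(n3, 0.1383, tolerance = 1e-3)
  ode <- integrate_to_steady_state(c(0.05, 0.05, 0.05), ex$traits, ex$alpha)
  expect_equal(unname(ode$state[3]), n3, tolerance = 1e-6)

  # decoupled or empty residents leave the fugitive at its own k
  expect_equal(fugitive_equilibrium(ex$traits, ex$alpha, c(0, 0)),
               ex$traits$k[3])
  al0 <- ex$alpha; al0[3, 1:2] <- 0
  expect_equal(fugitive_equilibrium(ex$traits, competition_matrix(al0),
                                    eq$n_star),
               ex$traits$k[3])
  # misuse: a "fugitive" that impacts a resident
  bad <- ex$alpha; bad[1, 3] <- 0.2
  expect_error(fugitive_equilibrium(ex$traits, competition_matrix(bad),
                                    eq$n_star), "fugitive")
})

test_that("steady-state integration is flagged, clipped and convergent", {
  one <- species_traits(c = 0.4, d = 0.1, h = 1)
  ode <- integrate_to_steady_state(0.01, one, competition_matrix(matrix(1)))
  expect_true(ode$converged)
  expect_equal(unname(ode$state), one$k, tolerance = 1e-6)

  dead <- species_traits(c = c(0.2, 0.3), d = 0.5, h = 0.5)  # all k < 0
  ode2 <- integrate_to_steady_state(c(0.3, 0.3), dead, competition_matrix(diag(2)))
  expect_true(ode2$converged)
  expect_equal(unname(ode2$state), c(0, 0), tolerance = 1e-6)
  expect_true(all(ode2$state >= 0))
})

test_that("closed forms match integration on random feasible communities", {
  set.seed(52)
  tried <- 0
  for (k in 1:30) {
    repeat {
      tried <- tried + 1
      cc <- c(runif(1, 0.1, 0.5), runif(1, 0.8, 2), runif(1, 0.1, 0.4))
      d <- runif(1, 0.02, 0.08)
      al <- rbind(c(1, runif(1, 0, 0.3), 0),
                  c(runif(1, 0.4, 1.4), 1, 0),
                  c(runif(1, 0, 0.6), runif(1, 0, 0.6), 1))
      tr <- species_traits(c = cc, d = d, h = 1)
      closed <- community_equilibrium(tr, competition_matrix(al))
      if (all(closed > 0.02)) break
    }
    ode <- integrate_to_steady_state(rep(0.05, 3), tr, competition_matrix(al))
    expect_true(ode$converged)
    expect_equal(unname(ode$state), unname(closed), tolerance = 1e-6)
    # growth is exactly zero at the interior closed-form equilibrium
    expect_lt(max(abs(growth_rate(closed, tr, competition_matrix(al)))),
              1e-10)
  }
  expect_lt(tried, 500)
})

test_that("habitat degradation orders the extinctions canary, keystone, weed", {
  ex <- three_species_example()
  scan <- extinction_scan(ex$traits, ex$alpha)
  th <- scan$thresholds
  expect_equal(scan$order, c("canary", "keystone", "weed"))
  # independent algebraic root-finding oracle on the equilibria in h
  canary_h <- uniroot(function(h) {
    k <- h - c(0.1 / 0.2, 0.1 / 1.6, 0.1 / 0.18)
    n1 <- (k[1] - 0.01 * k[2]) / (1 - 0.015)
    n2 <- (k[2] - 1.5 * k[1]) / (1 - 0.015)
    k[3] - 0.5 * n1 - 0.3 * n2
  }, c(0.6, 0.95), tol = 1e-9)$root
  keystone_h <- uniroot(function(h) (h - 0.5) - 0.01 * (h - 0.0625),
                        c(0.3, 0.7), tol = 1e-9)$root
  expect_equal(th$h_extinct[th$species == "canary"], canary_h,
               tolerance = 1e-3)
  expect_equal(th$h_extinct[th$species == "keystone"], keystone_h,
               tolerance = 1e-3)
  expect_equal(th$h_extinct[th$species == "weed"], 0.0625,
               tolerance = 1e-3)
  expect_true(all(scan$equilibria[, -1] >= 0))

  # identical non-interacting species go extinct together at h = d/c
  two <- species_traits(c = 0.5, d = 0.1, h = 1)
  two <- rbind(two, two)
  class(two) <- c("species_traits", "data.frame")
  scan2 <- extinction_scan(two, competition_matrix(diag(2)))
  expect_equal(scan2$thresholds$h_extinct, rep(0.2, 2), tolerance = 1e-3)
})
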