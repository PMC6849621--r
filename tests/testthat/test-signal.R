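test_that("the worked disorder-biodiversity triple differences exactly", {
  disorder <- data.frame(date = c(1898, 1900, 1903),
                         temperature = c(41.35, 38.59, 36.98))
  diversity <- data.frame(date = c(1898, 1900, 1903),
                          n2 = c(18.64, 21.71, 19.90),
                          richness = c(20, 23, 21))
  paired <- pair_series(disorder, diversity)
  expect_equal(nrow(paired), 3)
  diffs <- first_differences(paired)
  expect_equal(diffs$d_temperature, c(-2.76, -1.61))
  expect_equal(diffs$d_n2, c(3.07, -1.81))
  expect_equal(diffs$date, c(1898, 1900))
})

test_that("pairing validates date alignment", {
  a <- data.frame(date = 1:3, temperature = c(10, 11, 12))
  b <- data.frame(date = 4:6, n2 = c(2, 3, 4), richness = c(3, 4, 5))
  expect_error(pair_series(a, b), "no common dates")
  b2 <- data.frame(date = c(1, 2, 9), n2 = c(2, 3, 4), richness = c(3, 4, 5))
  expect_error(pair_series(a, b2), "misaligned")
  one <- pair_series(a[1, ], data.frame(date = 1, n2 = 2, richness = 3))
  expect_equal(nrow(one), 1)
})

test_that("first differences of degenerate series behave", {
  flat <- data.frame(date = 1:5, temperature = rep(4, 5), n2 = rep(2, 5),
                     richness = rep(3, 5))
  expect_true(all(first_differences(flat)$d_temperature == 0))
  lin <- data.frame(date = 1:5, temperature = 2 * (1:5), n2 = 3 * (1:5),
                    richness = 1:5)
  expect_equal(unique(first_differences(lin)$d_temperature), 2)
  expect_error(first_differences(flat[1, ]), "at least two")
})

test_that("sequential correlations recover exact and null relationships", {
  # exact anti-phase: y = -x + const gives pretransition r = -1
  d <- data.frame(date = 1:30,
                  d_temperature = sin(1:30),
                  d_n2 = -sin(1:30) + 0.3,
                  d_richness = rep(1, 30))
  sc <- sequential_correlations(d)
  expect_true(all(abs(sc$pre_r + 1) < 1e-12))

  # full-series window equals the direct-formula global correlation
  set.seed(61)
  d2 <- data.frame(date = 1:20, d_temperature = rnorm(20),
                   d_n2 = rnorm(20), d_richness = rnorm(20))
  sc2 <- sequential_correlations(d2, window = 21)
  expect_equal(nrow(sc2), 1)
  orc <- pearson_oracle(d2$d_temperature, d2$d_n2)
  expect_equal(sc2$pre_r, orc$r)
  expect_equal(sc2$pre_p, orc$p)
  expect_true(is.na(sc2$lead_r))

  # independent channels: sliding-window coefficients centre on zero
  set.seed(62)
  d3 <- data.frame(date = 1:3000, d_temperature = rnorm(3000),
                   d_n2 = rnorm(3000), d_richness = rnorm(3000))
  sc3 <- sequential_correlations(d3)
  expect_lt(abs(mean(sc3$pre_r)), 0.06)

  # zero-variance channel is missing, not zero
  d4 <- data.frame(date = 1:25, d_temperature = rep(1, 25),
                   d_n2 = rnorm(25), d_richness = rnorm(25))
  sc4 <- sequential_correlations(d4)
  expect_true(all(is.na(sc4$pre_r)))
})

test_that("the regime rule table reproduces the documented calls", {
  expect_equal(classify_regime(-0.51, 0.04, 0.24), "keystone-favored")
  expect_equal(classify_regime(0, 1, 0), "indeterminate")
  expect_equal(classify_regime(0.6, 0.01, -0.1), "weed-favored")
  expect_equal(classify_regime(0.35, 0.4, 0), "canary-favored")
  expect_equal(classify_regime(-0.51, 0.04, -0.4), "indeterminate")
  expect_equal(classify_regime(NA, NA, 0.2), "indeterminate")
  # vectorised over dates
  expect_equal(classify_regime(c(-0.51, 0.6), c(0.04, 0.01), c(0.24, -0.1)),
               c("keystone-favored", "weed-favored"))
})

test_that("every correlation is invariant under monotone re-dating", {
  core <- generate_core(scenario_config(phase = "anti", seed = 9), 60)
  warped <- perturb_dates(core, "compaction", strength = 2.7)
  run <- function(co) {
    paired <- pair_series(disorder_series(co), core_diversity(co))
    sequential_correlations(first_differences(paired))
  }
  a <- run(core); b <- run(warped)
  expect_identical(a$pre_r, b$pre_r)
  expect_identical(a$pre_p, b$pre_p)
  expect_identical(a$lead_r, b$lead_r)
  expect_identical(a$lead_p, b$lead_p)
})

test_that("window sensitivity is consistent and peaks at the engineered scale", {
  core <- generate_core(scenario_config(phase = "anti", seed = 10), 120)
  ws <- window_sensitivity(core, c(15))
  sc <- sequential_correlations(
    first_differences(pair_series(disorder_series(core),
                                  core_diversity(core))))
  expect_equal(ws$r, sc$pre_r[nrow(sc)])

  # cores built on 15-section phase alternation favour a 15-point window
  wins <- sapply(1:8, function(s) {
    co <- generate_core(scenario_config(phase = "anti", seed = s), 120)
    w <- window_sensitivity(co, c(9, 15, 21))
    w$window[which.max(w$abs_r)]
  })
  expect_gte(sum(wins == 15), 5)
  expect_error(window_sensitivity(core, c(80)), "exceeds")
})
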