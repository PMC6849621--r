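test_that("trait draws respect the functional regions", {
  set.seed(91)
  reg <- trait_regions()
  # canaries never deliver impact
  for (k in 1:50) expect_equal(draw_species("canary", reg)$deliver_mult, 0)
  # 1000 keystone draws all dominate a reference weed:
  # alpha_ji - alpha_ij > 0 against every weed draw
  weed <- draw_species("weed", reg)
  ok <- replicate(1000, {
    ks <- draw_species("keystone", reg)
    delivered <- reg$base["weed", "keystone"] * weed$receive_mult * ks$deliver_mult
    received <- reg$base["keystone", "weed"] * ks$receive_mult * weed$deliver_mult
    delivered - received > 0
  })
  expect_true(all(ok))
  expect_error(trait_regions(c_weed = c(0.01, 0.02)), "contradictory")
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- sim_config(seed = 3, replicates = 2)
  sch <- forcing_schedule(periods = c(60L, 60L, 60L))
  a <- run_simulation(cfg, sch)
  b <- run_simulation(cfg, sch)
  expect_identical(a$series, b$series)
  expect_identical(a$correlations, b$correlations)
  c2 <- run_simulation(sim_config(seed = 4, replicates = 2), sch)
  expect_false(identical(a$series, c2$series))
})

test_that("certain death empties the community in one step", {
  cfg <- sim_config(seed = 1)
  com <- ecodisorder:::new_community(cfg)
  set.seed(1)
  after <- abm_step(com, d_t = 2, cfg)  # dt * d = 1
  expect_true(all(after$N == 0))
})

test_that("a lone species fluctuates around its logistic equilibrium", {
  cfg <- sim_config(seed = 2)
  com <- list(category = "keystone", c = 0.2, deliver_mult = 1,
              receive_mult = 1, N = 100L, id = "k1", next_id = 1L)
  set.seed(2)
  acc <- numeric(900)
  for (t in 1:1300) {
    com <- abm_step(com, 0.1, cfg)
    if (t > 400) acc[t - 400] <- com$N
  }
  k <- 1 - 0.1 / 0.2
  expect_equal(mean(acc) / cfg$capacity, k, tolerance = 0.1)
})

test_that("the expected one-step change matches the rate equation", {
  cfg <- sim_config(seed = 7)
  base <- cfg$regions$base
  com0 <- list(category = c("keystone", "weed"), c = c(0.20, 1.60),
               deliver_mult = c(1, 1), receive_mult = c(1, 1),
               N = c(120L, 60L), id = c("k1", "w1"), next_id = 2L)
  d <- 0.1
  nt <- com0$N / cfg$capacity
  M <- base[com0$category, com0$category]; diag(M) <- 1
  comp <- as.vector(M %*% nt)
  birth <- pmin(1, cfg$dt * com0$c * pmax(0, 1 - comp))
  exact <- com0$N * ((1 - cfg$dt * d) * (1 + birth) - 1)
  set.seed(7)
  reps <- 10000
  deltas <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    deltas[r, ] <- abm_step(com0, d, cfg)$N - com0$N
  }
  se <- apply(deltas, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(deltas) - exact) < 4 * se))
  # the exact expectation is the rate equation up to O(dt^2)
  rate <- (com0$c * (1 - comp) - d) * com0$N * cfg$dt
  expect_true(all(abs(exact - rate) <= cfg$dt^2 * com0$c * d * com0$N + 1e-9))
})

test_that("a closed community keeps its composition after equilibration", {
  # keystones self-limit more than they limit each other's guild-mates
  # (within-role impact 0.7 < 1), so a closed all-keystone community
  # coexists stably; with no invasions and no toggling its composition
  # is static
  cfg <- sim_config(init_species = c(canary = 0L, keystone = 3L, weed = 0L),
                    invasion_p = 0, init_frac = 0.1, seed = 11,
                    replicates = 2)
  sch <- forcing_schedule(periods = c(100L, 100L, 100L), toggle_amp = 0,
                          rise_to = 0.1)
  out <- run_simulation(cfg, sch)
  ks <- out$series[out$series$category == "keystone", ]
  expect_true(all(ks$species_count == 3L))
  expect_true(all(out$series$species_count[out$series$category != "keystone"] == 0L))
})

test_that("canaries stay the rarest category under default forcing", {
  out <- run_simulation(sim_config(seed = 5, replicates = 4),
                        forcing_schedule())
  per_cat <- tapply(out$series$species_count, out$series$category, mean)
  expect_lt(per_cat[["canary"]], per_cat[["keystone"]])
  expect_lt(per_cat[["canary"]], per_cat[["weed"]])
})

test_that("toggling alone drives the negative correlation phase", {
  # control: toggling from the outset (no constant-d lead-in) still
  # produces the negative disorder-diversity correlation in period 2
  rs <- sapply(1:2, function(s) {
    out <- run_simulation(sim_config(seed = s, replicates = 6),
                          forcing_schedule(periods = c(1L, 360L, 239L)))
    out$summary$mean_r[2]
  })
  expect_true(all(rs < 0))
})
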