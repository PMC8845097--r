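test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(extinction = 0.1), "pure-birth")
  expect_error(sim_config(n_taxa = 2), "n_taxa")
  expect_error(sim_config(shift_factor = 0.5), "shift_factor")
  expect_error(sim_config(rate_var = -1), "rate_var")
})

test_that("simulated Yule trees are ultrametric with the right size", {
  tt <- simulate_yule_shift(sim_config(n_taxa = 24, seed = 11))
  expect_equal(ape::Ntip(tt$tree), 24)
  expect_equal(ape::Nnode(tt$tree), 23)
  root_age <- tt$ages[chronobounds:::root_node(tt$tree)]
  depth <- ape::node.depth.edgelength(tt$tree)[1:24]
  expect_lt(diff(range(depth)), 1e-9 * root_age)
  expect_true(all(tt$tree$edge.length > 0))
  expect_true(is.na(tt$shift_crown))  # no shift requested
  # ages are consistent with branch time lengths
  durations <- tt$ages[tt$tree$edge[, 1]] - tt$ages[tt$tree$edge[, 2]]
  expect_equal(durations, tt$tree$edge.length)
})

test_that("simulation is reproducible given a seed", {
  a <- simulate_yule_shift(sim_config(n_taxa = 10, shift_factor = 10, seed = 5))
  b <- simulate_yule_shift(sim_config(n_taxa = 10, shift_factor = 10, seed = 5))
  expect_identical(a, b)
  ra <- draw_branch_rates(a, 0.05, 0.00025, seed = 9)
  rb <- draw_branch_rates(b, 0.05, 0.00025, seed = 9)
  expect_identical(ra$rates, rb$rates)
  expect_identical(molecularize(ra, noise = "poisson", seed = 3),
                   molecularize(rb, noise = "poisson", seed = 3))
})

test_that("the marked clade diversifies faster than the background", {
  set.seed(314)
  cfg <- sim_config(n_taxa = 24, shift_factor = 10)
  shifted_sizes <- integer(0)
  for (i in 1:100) {
    tt <- simulate_yule_shift(cfg, seed = NULL)
    if (is.na(tt$shift_crown)) next
    clade_tips <- length(ape::extract.clade(tt$tree, tt$shift_crown)$tip.label)
    shifted_sizes <- c(shifted_sizes, clade_tips)
  }
  expect_gt(length(shifted_sizes), 90)  # marked lineage almost always splits
  # marked at 4 lineages: a neutral lineage would average ~24/4 = 6 tips;
  # a 10-fold speciation advantage must push the clade well above that
  expect_gt(mean(shifted_sizes), 10)
})

test_that("lognormal branch rates match their real-space mean and variance", {
  set.seed(42)
  draws <- chronobounds:::lognormal_mv(10000, 0.05, 0.00025)
  expect_gt(mean(draws), 0.048)
  expect_lt(mean(draws), 0.052)
  expect_gt(var(draws), 2e-4)
  expect_lt(var(draws), 3e-4)
  expect_identical(chronobounds:::lognormal_mv(10, 0.05, 0),
                   rep(0.05, 10))
})

test_that("molecularize produces exact or Poisson-noised lengths", {
  tt <- simulate_yule_shift(sim_config(n_taxa = 8, seed = 2))
  tt <- draw_branch_rates(tt, 0.05, 0.00025, seed = 2)
  exact <- molecularize(tt, noise = "none")
  expect_equal(exact$edge.length, tt$rates * tt$tree$edge.length)
  # zero rate gives zero length under both models
  tt0 <- tt; tt0$rates <- rep(0, length(tt$rates))
  expect_equal(molecularize(tt0, noise = "none")$edge.length,
               rep(0, length(tt$rates)))
  expect_equal(molecularize(tt0, noise = "poisson", seed = 1)$edge.length,
               rep(0, length(tt$rates)))
  # Poisson mean: duration 2, rate 0.05, 50k sites -> 0.1 within 4 SE
  cherry <- structure(list(
    tree = read_tree("(A:2,B:2);"), ages = c(0, 0, 2),
    shift_crown = NA_integer_, rates = NULL), class = "time_tree")
  cherry$rates <- c(0.05, 0.05)
  set.seed(99)
  draws <- replicate(500, molecularize(cherry, sites = 50000,
                                       noise = "poisson")$edge.length)
  se <- sqrt(0.1 / 50000 / length(draws))
  expect_lt(abs(mean(draws) - 0.1), 4 * se)
})

test_that("coverage is total under true-envelope bounds and noiseless lengths", {
  cfg <- sim_config(n_taxa = 24, shift_factor = 10, noise = "none", seed = 60)
  rep_out <- run_coverage_experiment(cfg, reps = 10)
  expect_equal(rep_out$coverage, 1.0)
  expect_equal(rep_out$n_infeasible, 0L)
  expect_equal(nrow(rep_out$per_node), 10 * 23)
  expect_true(all(rep_out$per_node$true_age <= rep_out$per_node$U + 1e-9))
  expect_true(all(rep_out$per_node$true_age >= rep_out$per_node$L - 1e-9))
})

test_that("the crown calibration lifts only minima, and only consistently", {
  cfg <- sim_config(n_taxa = 24, shift_factor = 10, noise = "none", seed = 61)
  plain <- run_coverage_experiment(cfg, reps = 10, calibration_mode = "none")
  calib <- run_coverage_experiment(cfg, reps = 10,
                                   calibration_mode = "min_at_shift_crown")
  # same seed, same replicates: the calibration never loosens either bound
  expect_equal(plain$per_node$true_age, calib$per_node$true_age)
  tol <- 1e-9 * pmax(1, abs(plain$per_node$L))
  expect_true(all(calib$per_node$L >= plain$per_node$L - tol))
  expect_true(all(calib$per_node$U <= plain$per_node$U + tol))
  # the calibrated node's minimum is at least 90% of its true age
  expect_true(all(calib$calibrated$L >= 0.9 * calib$calibrated$true_age -
                    1e-9 * pmax(1, calib$calibrated$true_age)))
  expect_equal(calib$coverage, 1.0)
})

test_that("experiment preconditions are enforced", {
  cfg <- sim_config(seed = 1)
  expect_error(run_coverage_experiment(cfg, reps = 0), "reps")
  expect_error(run_coverage_experiment(cfg, reps = 2,
                                       calibration_mode = "min_at_shift_crown"),
               "shift_factor")
})
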