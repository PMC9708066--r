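# Synthetic-data generators: determinism, structure, round-trips,
# scenario construction.

test_that("Yule trees are binary, ultrametric and seeded", {
  t2 <- generate_yule_tree(2, seed = 1)
  h <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(h[1], h[2], tolerance = 1e-12)

  tr <- generate_yule_tree(60, seed = 1)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(ape::is.binary(tr))
  expect_false(anyDuplicated(tr$tip.label) > 0)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-12)

  # seeded determinism: identical newick strings
  expect_identical(write_newick(generate_yule_tree(60, seed = 1)),
                   write_newick(generate_yule_tree(60, seed = 1)))
  # binary-tree identity: n - 1 internal nodes
  t200 <- generate_yule_tree(200, seed = 2)
  expect_equal(t200$Nnode, 199)
  expect_error(generate_yule_tree(1), "at least 2")
})

test_that("lambda-BM simulation honours its degenerate limits", {
  tr <- generate_yule_tree(30, seed = 3)
  # zero rate: all tips at the root state
  x0 <- simulate_lambda_bm(tr, sigma2 = 0, root_state = 7)
  expect_equal(unname(x0), rep(7, 30))
  expect_error(simulate_lambda_bm(tr, 1, 0, lambda = 1.2), "\\[0, 1\\]")
  # seeded determinism
  expect_identical(simulate_lambda_bm(tr, 1, 0, 1, seed = 4),
                   simulate_lambda_bm(tr, 1, 0, 1, seed = 4))
})

test_that("lambda = 0 removes shared history between sister tips", {
  tr <- parse_newick("((A:1,B:1):9,(C:1,D:1):9);")
  reps <- 400
  set.seed(5)
  m <- t(vapply(seq_len(reps), function(i)
    simulate_lambda_bm(tr, sigma2 = 1, root_state = 0, lambda = 0),
    numeric(4)))
  # sister correlation ~ 0 despite 9 units of shared path (under
  # lambda = 1 it would be 0.9)
  expect_lt(abs(cor(m[, "A"], m[, "B"])), 0.2)
  # variance ~ sigma2 * tip height = 10
  expect_equal(var(m[, "A"]), 10, tolerance = 0.25 * 10)
})

test_that("lambda = 1 tip covariance approaches sigma2 x phylo covariance", {
  tr <- generate_yule_tree(20, seed = 6)
  sigma2 <- 2
  reps <- 600
  set.seed(7)
  m <- t(vapply(seq_len(reps), function(i)
    simulate_lambda_bm(tr, sigma2 = sigma2, root_state = 0, lambda = 1),
    numeric(20)))
  emp <- cov(m)
  expected <- sigma2 * phylo_covariance(tr)
  expect_lt(max(abs(emp - expected[colnames(m), colnames(m)])), 0.5)
})

test_that("TPC observations sit on the curve when noiseless and are seeded", {
  p <- ss_params(0.3, 0.65, 3, celsius_to_kelvin(30))
  obs <- generate_tpc_observations(p, noise_cv = 0, replicates = 3)
  expect_equal(obs$rate, obs$true_rate)
  expect_equal(obs$rate,
               ss_evaluate(p, celsius_to_kelvin(obs$temp)))
  expect_equal(nrow(obs), 3 * 7)
  o1 <- generate_tpc_observations(p, noise_cv = 0.1, seed = 8)
  o2 <- generate_tpc_observations(p, noise_cv = 0.1, seed = 8)
  expect_identical(o1, o2)
  expect_error(generate_tpc_observations(p, assay_temps = c(10, 5)),
               "increasing")
  expect_error(generate_tpc_observations(p, noise_cv = -1), "noise_cv")
})

test_that("multiplicative noise has the requested CV and unit mean", {
  p <- ss_params(0.3, 0.65, 3, celsius_to_kelvin(30))
  obs <- generate_tpc_observations(p, assay_temps = c(20, 21),
                                   noise_cv = 0.2, replicates = 4000,
                                   seed = 9)
  fac <- obs$rate / obs$true_rate
  expect_equal(mean(fac), 1, tolerance = 0.01)
  expect_equal(sd(fac), 0.2, tolerance = 0.015)
})

test_that("assay batches invert the derivation chain exactly", {
  rec <- generate_assay_batch(true_mu = 0.4, true_R = 0.12, true_atp = 7,
                              C0_cells = 1e5, mean_diameter = 1.2,
                              duration = 4)
  d <- derive_traits(rec)
  expect_equal(d$mu, 0.4, tolerance = 1e-12)
  expect_equal(d$R, 0.12, tolerance = 1e-12)
  expect_equal(d$atp, 7, tolerance = 1e-12)
  # zero growth: counts equal, Rtot = R * C0 * t
  rec0 <- generate_assay_batch(true_mu = 0, true_R = 0.3, true_atp = 5,
                               C0_cells = 5e4, mean_diameter = 1,
                               duration = 2)
  expect_equal(rec0$final_count, rec0$initial_count)
  C0 <- culture_biomass(5e4, sphere_volume(1))
  expect_equal(rec0$Rtot, 0.3 * C0 * 2)
  expect_error(generate_assay_batch(0.1, 0.1, 1, C0_cells = 0),
               "positive")
})

test_that("community scenario reproduces the designed sorting pattern", {
  scen <- generate_community_scenario(seed = 1)
  tr <- scen$traits
  expect_equal(sort(unique(tr$isolation_mode)), c("sorting", "standard"))
  expect_setequal(tr$isolate_id, scen$tree$tip.label)
  srt <- tr[tr$isolation_mode == "sorting", ]
  # cold isolates biased upward, warm ones on the 1:1 line
  cold <- srt$incubation_temp == 4
  warm <- srt$incubation_temp >= 30
  expect_gt(mean(srt$topt[cold] - srt$incubation_temp[cold]), 4)
  expect_lt(abs(mean(srt$topt[warm] - srt$incubation_temp[warm])), 2)
  # quadratic preferred with the default cold offset, across seeds
  for (s in 1:3) {
    sc <- generate_community_scenario(seed = s)
    st <- sc$traits[sc$traits$isolation_mode == "sorting", ]
    cmp <- quadratic_vs_linear(st$incubation_temp, st$topt)
    expect_lt(cmp$p_value, 0.05)
  }
})

test_that("zero cold offset leaves the sorting response linear", {
  pref_quad <- vapply(1:5, function(s) {
    sc <- generate_community_scenario(cold_offset = 0, seed = s)
    st <- sc$traits[sc$traits$isolation_mode == "sorting", ]
    quadratic_vs_linear(st$incubation_temp, st$topt)$p_value < 0.05
  }, logical(1))
  # the quadratic term should essentially never be needed
  expect_lte(sum(pref_quad), 1)
})

test_that("phylum labels follow the optimum and carry the r/K contrast", {
  scen <- generate_community_scenario(seed = 2)
  tr <- scen$traits
  expect_true(all(tr$phylum[tr$topt >= 30] == "Firmicutes"))
  expect_true(all(tr$phylum[tr$topt < 30] == "Proteobacteria"))
  rs <- rank_sum_test(tr$mu_max[tr$phylum == "Firmicutes"],
                      tr$mu_max[tr$phylum == "Proteobacteria"])
  expect_lt(rs$p_value, 0.05)
  # the optimum carries strong phylogenetic signal by construction
  lam <- estimate_lambda(scen$tree,
                         stats::setNames(tr$topt, tr$isolate_id),
                         transform = "log")
  expect_gt(lam$value, 0.8)
})

test_that("scenario generation is a pure function of its seed", {
  s1 <- generate_community_scenario(seed = 11)
  s2 <- generate_community_scenario(seed = 11)
  expect_identical(s1$traits, s2$traits)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
})
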