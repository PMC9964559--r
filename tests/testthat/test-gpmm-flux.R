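test_that("protein abundance models behave as configured", {
  m <- matrix(c(7.5, 4, 0, 1), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(estimate_protein_abundance(m), m)  # alpha = 1 identity
  expect_equal(estimate_protein_abundance(m, list(name = "power", alpha = 0.5))["g2", "s1"], 2)
  expect_equal(estimate_protein_abundance(m, list(name = "power", alpha = 0.3))["g1", "s2"], 0)
  expect_error(estimate_protein_abundance(m, list(name = "mystery")),
               "configuration error")
  custom <- list(name = function(x, k) k * x, k = 2)
  expect_equal(estimate_protein_abundance(m, custom), 2 * m)
})

test_that("Michaelis-Menten bounds combine kcat, enzyme level and reversibility", {
  net <- metabolic_network(
    metabolites = data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    reactions = data.frame(
      id = c("Rirr", "Rrev", "Rfree"),
      name = c("Rirr", "Rrev", "Rfree"),
      reversible = c(FALSE, TRUE, TRUE),
      lb = c(0, -1000, -1000), ub = c(1000, 1000, 1000),
      gpr = c("gX", "gX", ""), subsystem = ""),
    stoich = list(Rirr = c(A = -1, B = 1), Rrev = c(A = -1, B = 1),
                  Rfree = c(A = -1, B = 1)))
  kin <- data.frame(reaction_id = c("Rirr", "Rrev"), kcat_f = 3, kcat_b = 1)
  b <- compute_bounds(net, c(gX = 2), kin, scale = 1)
  expect_equal(b$lb, c(0, -2, -1000))
  expect_equal(b$ub, c(6, 6, 1000))
  # no enzyme, no flux
  b0 <- compute_bounds(net, c(gX = 0), kin)
  expect_equal(unname(unlist(b0[1, c("lb", "ub")])), c(0, 0))
  # enzyme bounds never widen model defaults
  netn <- net; netn$reactions$ub[1] <- 4
  expect_equal(compute_bounds(netn, c(gX = 100), kin)$ub[1], 4)
  # default kcat = table median for unlisted reactions
  net2 <- net; net2$reactions$gpr[3] <- "gX"
  b2 <- compute_bounds(net2, c(gX = 2), kin)
  expect_equal(b2$ub[3], 2 * stats::median(kin$kcat_f))
  expect_error(compute_bounds(net, c(gX = 1), kin, scale = 0), "positive")
})

test_that("fba solves the chain example and reports infeasibility context", {
  sol <- fba(chain_network(cap = 5), config = gpmm_config())
  expect_equal(sol$objective, 5, tolerance = 1e-8)
  expect_equal(unname(sol$flux[c("EX_A", "AB", "BIO")]), c(-5, 5, 5),
               tolerance = 1e-8)
  net0 <- apply_medium(chain_network(), list(EX_A = c(0, 0)))
  expect_equal(fba(net0, config = gpmm_config())$objective, 0, tolerance = 1e-9)
})

test_that("fba matches the brute-force oracle on random toy polytopes", {
  for (seed in 1:8) {
    lp <- random_lp_network(seed)
    got <- lp_solve_bounded(lp$w, lp$S, rep(0, nrow(lp$S)), lp$lb, lp$ub)
    want <- fba_brute_force(lp$S, lp$lb, lp$ub, lp$w)
    expect_equal(got$status, "optimal")
    expect_equal(got$objective, want$objective, tolerance = 1e-6,
                 label = paste("seed", seed))
  }
})

test_that("fba obeys LP scaling and bound-relaxation monotonicity", {
  net <- chain_network(cap = 3)
  base <- fba(net, config = gpmm_config())$objective
  # doubling the binding enzyme bound doubles the optimum while the
  # exchange stays non-binding
  net2 <- net; net2$reactions$ub[net2$reactions$id == "AB"] <- 6
  expect_equal(fba(net2, config = gpmm_config())$objective, 2 * base,
               tolerance = 1e-8)
  # relaxing any single bound never decreases the optimum
  for (i in seq_len(nrow(net$reactions))) {
    netr <- net
    netr$reactions$ub[i] <- netr$reactions$ub[i] + 5
    expect_gte(fba(netr, config = gpmm_config())$objective, base - 1e-9)
    netr <- net
    netr$reactions$lb[i] <- netr$reactions$lb[i] - 5
    netr$reactions$reversible[i] <- TRUE
    expect_gte(fba(netr, config = gpmm_config())$objective, base - 1e-9)
  }
})

test_that("sampled points are feasible, symmetric on a free loop, and deterministic", {
  cfg <- gpmm_config(n_mcmc_samples = 2000, warmup_points = 100, thinning = 1,
                     random_seed = 5)
  sf <- sample_fluxes(loop_network(), config = cfg, use_objective = FALSE)
  S <- stoich_matrix(loop_network())
  expect_lt(max(abs(S %*% sf$points)), 1e-6)
  expect_true(all(sf$points >= -2 - 1e-6 & sf$points <= 2 + 1e-6))
  expect_lt(abs(sf$mean[["F1"]]), 0.1)  # uniform on [-2,2] has mean 0

  sf2 <- sample_fluxes(loop_network(), config = cfg, use_objective = FALSE)
  expect_identical(sf$points, sf2$points)  # same seed, same chain
  cfg2 <- cfg; cfg2$random_seed <- 6
  expect_false(identical(sample_fluxes(loop_network(), config = cfg2,
                                       use_objective = FALSE)$points, sf$points))
})

test_that("gamma = 1 with a unique optimum collapses the sampler to the vertex", {
  net <- chain_network(cap = 5)
  cfg <- gpmm_config(optimum_fraction = 1, n_mcmc_samples = 50,
                     warmup_points = 20, thinning = 2, random_seed = 2)
  sf <- sample_fluxes(net, config = cfg)
  expect_lt(max(abs(sf$points - sf$mean)), 1e-6)
  expect_equal(sf$mean[["BIO"]], 5, tolerance = 1e-6)
})

test_that("sampler respects the near-optimality half-space", {
  co <- shared_cohort()
  net <- co$network
  cfg <- cohort_gpmm_config(co, n_mcmc_samples = 100, warmup_points = 50,
                            thinning = 2)
  ab <- estimate_protein_abundance(co$expression)[, 1]
  bounds <- compute_bounds(net, ab, co$kinetics, scale = cfg$scale)
  sf <- sample_fluxes(net, bounds, cfg)
  w <- stats::setNames(numeric(nrow(net$reactions)), net$reactions$id)
  w[c("BIOMASS", "DM_atp")] <- 1
  vals <- drop(crossprod(sf$points, w))
  expect_true(all(vals >= 0.9 * sf$optimum - 1e-6))
  S <- stoich_matrix(net)
  expect_lt(max(abs(S %*% sf$points)), 1e-6)
})

test_that("essential reactions are the bridges of the objective path", {
  cfg <- gpmm_config()
  expect_setequal(essential_reactions(chain_network(), config = cfg),
                  c("EX_A", "AB", "BIO"))
  ess <- essential_reactions(parallel_network(), config = cfg)
  expect_setequal(ess, c("EX_A", "BIO"))  # neither isozyme route alone
  # brute-force knockout agreement on a branched generated network
  net <- make_toy_network(synthetic_spec(n_pathways = 2))
  base <- fba(net, config = cfg)$objective
  expect_gt(base, 0)
  want <- character(0)
  S <- stoich_matrix(net)
  w <- stats::setNames(numeric(nrow(net$reactions)), net$reactions$id)
  w[c("BIOMASS", "DM_atp")] <- 1
  for (i in seq_len(nrow(net$reactions))) {
    lb <- net$reactions$lb; ub <- net$reactions$ub
    lb[i] <- ub[i] <- 0
    res <- fba_brute_force(S, lb, ub, w)
    if (res$status != "optimal" || res$objective < 1e-6 * base)
      want <- c(want, net$reactions$id[i])
  }
  expect_setequal(essential_reactions(net, config = cfg), want)
  net0 <- apply_medium(chain_network(), list(EX_A = c(0, 0)))
  expect_error(essential_reactions(net0, config = cfg), "baseline")
})
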