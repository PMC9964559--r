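# Shared fixtures, built in code. The expensive synthetic cohort + flux
# matrix pair is memoised so several test files can reuse one replicate.

toy_model_path <- function() {
  system.file("extdata", "toy_model.json", package = "fluxprog")
}

# EX_A (lb -10) -> A; A -> B capped at 5; B -> biomass sink.
chain_network <- function(cap = 5) {
  metabolic_network(
    metabolites = data.frame(id = c("A", "B"), name = c("A", "B"),
                             compartment = "c"),
    reactions = data.frame(
      id = c("EX_A", "AB", "BIO"),
      name = c("EX_A", "AB", "BIO"),
      reversible = c(TRUE, FALSE, FALSE),
      lb = c(-10, 0, 0), ub = c(1000, cap, 1000),
      gpr = "", subsystem = c("exchange", "toy", "biomass")),
    stoich = list(EX_A = c(A = -1), AB = c(A = -1, B = 1), BIO = c(B = -1)),
    objective = list(biomass = "BIO", atp = NULL, weights = 1))
}

# Two isozyme routes A -> B in parallel, plus exchange and sink.
parallel_network <- function() {
  metabolic_network(
    metabolites = data.frame(id = c("A", "B"), name = c("A", "B"),
                             compartment = "c"),
    reactions = data.frame(
      id = c("EX_A", "AB1", "AB2", "BIO"),
      name = c("EX_A", "AB1", "AB2", "BIO"),
      reversible = c(TRUE, FALSE, FALSE, FALSE),
      lb = c(-10, 0, 0, 0), ub = c(1000, 1000, 1000, 1000),
      gpr = "", subsystem = ""),
    stoich = list(EX_A = c(A = -1), AB1 = c(A = -1, B = 1),
                  AB2 = c(A = -1, B = 1), BIO = c(B = -1)),
    objective = list(biomass = "BIO", atp = NULL, weights = 1))
}

# A 1-dimensional free loop: two reversible reactions A<->B carrying the
# same flux, bounds [-2, 2]; no objective.
loop_network <- function() {
  metabolic_network(
    metabolites = data.frame(id = c("A", "B"), name = c("A", "B"),
                             compartment = "c"),
    reactions = data.frame(
      id = c("F1", "F2"), name = c("F1", "F2"),
      reversible = TRUE, lb = -2, ub = 2, gpr = "", subsystem = ""),
    stoich = list(F1 = c(A = -1, B = 1), F2 = c(B = -1, A = 1)))
}

# Memoised default synthetic cohort and its flux matrix. Unit tests use
# a scaled-down sampler (200 retained, thin 5) to stay inside the test
# budget; the acceptance tests use the full spec'd settings.
.fixture_cache <- new.env(parent = emptyenv())

merge_bounds_for_test <- function(net, bounds) {
  lb <- net$reactions$lb; ub <- net$reactions$ub
  i <- match(bounds$reaction_id, net$reactions$id)
  lb[i] <- bounds$lb; ub[i] <- bounds$ub
  list(lb = lb, ub = ub)
}

shared_cohort <- function() {
  if (is.null(.fixture_cache$cohort))
    .fixture_cache$cohort <- simulate_cohort(synthetic_spec(random_seed = 404))
  .fixture_cache$cohort
}

shared_flux <- function() {
  if (is.null(.fixture_cache$flux)) {
    co <- shared_cohort()
    cfg <- cohort_gpmm_config(co, n_mcmc_samples = 200, warmup_points = 100,
                              thinning = 5)
    .fixture_cache$flux <- flux_matrix(co$network, co$expression, co$kinetics, cfg)
  }
  .fixture_cache$flux
}
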