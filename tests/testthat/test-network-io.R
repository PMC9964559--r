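test_that("GPR rules parse and evaluate with min/sum semantics", {
  ab <- c(gA = 2, gB = 3, gC = 1)
  expect_equal(evaluate_gpr("(gA and gB)", ab), 2)
  expect_equal(evaluate_gpr("(gA or gB)", ab), 5)
  # hand evaluation: min(2,3)=2, then 2+1 through the OR
  expect_equal(evaluate_gpr("((gA and gB) or gC)", ab), 3)
  expect_identical(evaluate_gpr("", ab), Inf)
  expect_equal(evaluate_gpr("gA", c(gA = 7.25)), 7.25)
  expect_error(parse_gpr("gA and (gB"), "parse error")
  expect_error(parse_gpr("gA & gB"), "parse error")
  expect_error(parse_gpr("and gA"), "parse error")
})

test_that("GPR evaluation is monotone and handles missing genes per policy", {
  set.seed(11)
  rule <- "((gA and gB) or (gC and gD) or gE)"
  for (i in 1:20) {
    ab <- stats::setNames(runif(5, 0, 10), c("gA", "gB", "gC", "gD", "gE"))
    v0 <- evaluate_gpr(rule, ab)
    bump <- sample(5, 1)
    ab2 <- ab; ab2[bump] <- ab2[bump] + runif(1, 0, 5)
    expect_gte(evaluate_gpr(rule, ab2), v0)
  }
  ab <- c(gA = 2, gB = 4)
  # median imputation: gC -> median(2,4) = 3
  expect_equal(evaluate_gpr("(gA or gC)", ab, missing = "median"), 5)
  expect_equal(evaluate_gpr("(gA or gC)", ab, missing = "zero"), 2)
  expect_identical(evaluate_gpr("(gA or gC)", ab, missing = "skip"), Inf)
})

test_that("JSON fixture loads with expected composition and round-trips", {
  net <- read_model(toy_model_path())
  expect_s3_class(net, "metabolic_network")
  expect_equal(nrow(net$reactions), 4)
  expect_equal(nrow(net$metabolites), 3)
  expect_equal(sort(net$genes), c("g1", "g2"))
  expect_setequal(exchange_reactions(net), c("EX_A", "SINK_C"))

  tmp <- withr::local_tempfile(fileext = ".json")
  write_model(net, tmp)
  net2 <- read_model(tmp)
  expect_equal(net2$reactions, net$reactions)
  expect_equal(net2$stoich, net$stoich)
  expect_equal(net2$metabolites, net$metabolites)
  expect_equal(sort(net2$genes), sort(net$genes))
})

test_that("SBML round-trip preserves ids, stoichiometry, bounds, GPRs, subsystems", {
  net <- read_model(toy_model_path())
  tmp <- withr::local_tempfile(fileext = ".xml")
  write_model(net, tmp, format = "sbml")
  net2 <- read_model(tmp, format = "sbml")
  expect_equal(net2$reactions$id, net$reactions$id)
  expect_equal(net2$reactions$lb, net$reactions$lb)
  expect_equal(net2$reactions$ub, net$reactions$ub)
  expect_equal(net2$reactions$subsystem, net$reactions$subsystem)
  expect_equal(lapply(net2$stoich, sort), lapply(net$stoich, sort))
  # GPR trees equivalent (string may re-parenthesize)
  expect_equal(parse_gpr(net2$reactions$gpr[3]), parse_gpr(net$reactions$gpr[3]))
  # toy network from the generator survives the same round trip
  net3 <- make_toy_network(synthetic_spec())
  write_model(net3, tmp, format = "sbml")
  net4 <- read_model(tmp)
  expect_equal(net4$reactions$subsystem, net3$reactions$subsystem)
  expect_equal(lapply(net4$stoich, sort), lapply(net3$stoich, sort))
})

test_that("malformed models are rejected with informative errors", {
  net <- read_model(toy_model_path())
  tmp <- withr::local_tempfile(fileext = ".xml")
  write_model(net, tmp, format = "sbml")
  txt <- readLines(tmp)
  # reaction referencing an undeclared species
  bad <- sub('species="A_c"', 'species="GHOST_c"', txt)
  writeLines(bad, tmp)
  expect_error(read_model(tmp), "undeclared|GHOST")

  dup <- jsonlite::read_json(toy_model_path())
  dup$reactions[[2]]$id <- "EX_A"
  tmp2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(dup, tmp2, auto_unbox = TRUE)
  expect_error(read_model(tmp2), "duplicate")

  tmp3 <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", tmp3)
  expect_error(read_model(tmp3), "malformed")
})

test_that("apply_medium sets listed bounds and closes unlisted uptake", {
  net <- read_model(toy_model_path())
  net2 <- apply_medium(net, list(EX_A = c(-10, 1000)))
  expect_equal(net2$reactions$lb[net2$reactions$id == "EX_A"], -10)

  # empty medium closes every exchange: no internal source, objective 0
  net3 <- apply_medium(net, list(), close_unlisted = TRUE)
  ex <- exchange_reactions(net3)
  expect_true(all(net3$reactions$lb[net3$reactions$id %in% ex] >= 0))
  sol <- fba(net3, config = gpmm_config())
  expect_equal(sol$objective, 0, tolerance = 1e-9)

  # uptake-only exchange
  net4 <- apply_medium(net, list(EX_A = c(-5, 0)))
  i <- net4$reactions$id == "EX_A"
  expect_equal(unname(c(net4$reactions$lb[i], net4$reactions$ub[i])), c(-5, 0))

  expect_error(apply_medium(net, list(NOPE = c(-1, 1))), "NOPE")
  expect_error(apply_medium(net, list(R1 = c(-1, 1))), "not exchange")
})

test_that("network validation enforces the structural invariants", {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c")
  rxn <- function(lb, ub, rev = FALSE)
    data.frame(id = "R", name = "R", reversible = rev, lb = lb, ub = ub,
               gpr = "", subsystem = "")
  sto <- list(R = c(A = -1, B = 1))
  expect_error(metabolic_network(mets, rxn(5, 1), sto), "lb > ub")
  expect_error(metabolic_network(mets, rxn(-1, 1, rev = FALSE), sto),
               "irreversible")
  expect_error(metabolic_network(mets, rxn(0, 1),
                                 list(R = c(A = -1, GHOST = 1))), "undeclared")
  expect_error(metabolic_network(data.frame(id = c("A", "A"), name = "A",
                                            compartment = "c"),
                                 rxn(0, 1), sto), "duplicate")
})
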