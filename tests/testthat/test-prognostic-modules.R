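test_that("find_prognostic_reactions keeps planted signal and respects alpha", {
  co <- shared_cohort()
  fm <- shared_flux()
  tr <- ground_truth(co)
  pr <- find_prognostic_reactions(fm, co$survival)
  for (m in names(tr$membership)) {
    expect_true(all(tr$membership[[m]] %in% pr$reaction_id),
                label = paste("planted module recovered:", m))
  }
  expect_true(all(pr$logrank_p < 0.01))
  # alpha = 0 with strict inequality returns nothing
  expect_equal(nrow(find_prognostic_reactions(fm, co$survival, alpha = 0)), 0)
  # constant-flux reactions are skipped and reported
  fm2 <- rbind(fm, CONST = 1)
  pr2 <- find_prognostic_reactions(fm2, co$survival)
  expect_true("CONST" %in% attr(pr2, "skipped"))
})

test_that("direction matches the planted hazard coefficients", {
  co <- shared_cohort()
  pr <- find_prognostic_reactions(shared_flux(), co$survival)
  tr <- ground_truth(co)
  # protective pathway (beta < 0): chain reactions must be direction +1
  prot <- intersect(paste0("R1_", 1:3), pr$reaction_id)
  harm <- intersect(paste0("R2_", 1:3), pr$reaction_id)
  expect_true(all(pr$direction[pr$reaction_id %in% prot] == 1))
  expect_true(all(pr$direction[pr$reaction_id %in% harm] == -1))
})

test_that("extract_modules drops singletons and splits correlation blocks", {
  set.seed(77)
  n <- 60
  z1 <- rnorm(n); z2 <- rnorm(n)
  mk <- function(base, sd) base + rnorm(n, 0, sd)
  flux <- rbind(a1 = mk(z1, 0.1), a2 = mk(z1, 0.1), a3 = mk(z1, 0.1),
                b1 = mk(z2, 0.1), b2 = mk(z2, 0.1),
                iso = rnorm(n))
  colnames(flux) <- sprintf("S%d", 1:n)
  prog <- data.frame(reaction_id = rownames(flux),
                     logrank_p = 0.001, direction = 1L)
  mods <- extract_modules(flux, prog, R_threshold = 0.8)
  grp <- split(mods$reaction_id, mods$module_id)
  expect_length(grp, 2)
  expect_true(any(vapply(grp, setequal, TRUE, y = c("a1", "a2", "a3"))))
  expect_true(any(vapply(grp, setequal, TRUE, y = c("b1", "b2"))))
  expect_false("iso" %in% mods$reaction_id)  # singular node dropped

  # R_threshold = 1 keeps only exactly monotone duplicates
  flux2 <- rbind(flux, a1dup = 2 * flux["a1", ] + 3)
  prog2 <- rbind(prog, data.frame(reaction_id = "a1dup", logrank_p = 0.001,
                                  direction = 1L))
  mods2 <- extract_modules(flux2, prog2, R_threshold = 0.999999)
  expect_setequal(mods2$reaction_id, c("a1", "a1dup"))

  # stricter min_neighbors removes the 2-block
  mods3 <- extract_modules(flux, prog, R_threshold = 0.8, min_neighbors = 2)
  expect_setequal(mods3$reaction_id, c("a1", "a2", "a3"))
})

test_that("module extraction is invariant to sample and reaction ordering", {
  co <- shared_cohort()
  fm <- shared_flux()
  pr <- find_prognostic_reactions(fm, co$survival)
  m1 <- extract_modules(fm, pr)
  set.seed(5)
  fm2 <- fm[sample(nrow(fm)), sample(ncol(fm))]
  m2 <- extract_modules(fm2, pr[sample(nrow(pr)), ], )
  expect_equal(split(m1$reaction_id, m1$module_id),
               split(m2$reaction_id, m2$module_id))
})

test_that("anti-correlated prognostic members join one module via |rho|", {
  set.seed(12)
  n <- 50
  z <- rnorm(n)
  flux <- rbind(up = z + rnorm(n, 0, 0.05), dn = -z + rnorm(n, 0, 0.05))
  colnames(flux) <- sprintf("S%d", 1:n)
  prog <- data.frame(reaction_id = c("up", "dn"), logrank_p = 0.001,
                     direction = c(1L, -1L))
  mods <- extract_modules(flux, prog)
  expect_equal(length(unique(mods$module_id)), 1)
  expect_true(all(mods$mixed_direction))
})

test_that("differential_flux computes noiseless contrasts and the no-shrinkage limit", {
  set.seed(8)
  n1 <- n0 <- 6
  samples <- sprintf("S%d", 1:(n1 + n0))
  groups <- stats::setNames(rep(c("high", "low"), c(n1, n0)), samples)
  # exact 1-unit difference on log2 scale with near-zero noise
  base <- matrix(2^(8 + rnorm(n1 + n0, 0, 1e-8)), 1)
  flux <- rbind(base * rep(c(2, 1), c(n1, n0)))
  flux <- rbind(flux, matrix(2^rnorm(20 * (n1 + n0), 5, 1), 20))
  rownames(flux) <- c("hit", sprintf("bg%d", 1:20))
  colnames(flux) <- samples
  d <- differential_flux(flux, groups)
  expect_equal(d$log2fc[d$reaction_id == "hit"], 1, tolerance = 1e-6)
  expect_false(any(d$raw_scale))

  # prior_df = 0: moderated t equals the ordinary two-sample t exactly
  d0 <- differential_flux(flux, groups, prior_df = 0)
  y <- log2(flux)
  tor <- plain_t(y, names(groups)[groups == "high"], names(groups)[groups == "low"])
  expect_equal(d0$t_mod, unname(tor), tolerance = 1e-12)
  expect_equal(d0$df_total, rep(n1 + n0 - 2, nrow(flux)))

  # sign-indefinite reactions are analyzed raw and flagged
  flux2 <- rbind(flux, signed = rnorm(n1 + n0))
  d2 <- differential_flux(flux2, groups)
  expect_true(d2$raw_scale[d2$reaction_id == "signed"])
})

test_that("variance shrinkage matches limma's empirical Bayes", {
  skip_if_not_installed("limma")
  set.seed(13)
  n1 <- n0 <- 5
  G <- 120
  samples <- sprintf("S%d", 1:(n1 + n0))
  groups <- stats::setNames(rep(c("high", "low"), c(n1, n0)), samples)
  y <- matrix(rnorm(G * (n1 + n0), 8, sqrt(rchisq(G, 4) / 4)), G)
  dimnames(y) <- list(sprintf("r%d", 1:G), samples)
  d <- differential_flux(2^y, groups)
  design <- cbind(1, groups == "high")
  fit <- limma::eBayes(limma::lmFit(y, design))
  expect_equal(attr(d, "df_prior"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(d, "var_prior"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(d$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(d$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
  # shrinkage moves each t toward the prior-pooled value
  dord <- differential_flux(2^y, groups, prior_df = 0)
  s2 <- (dord$log2fc / dord$t_mod)^2 / (1 / n1 + 1 / n0)
  shrunk_up <- s2 < attr(d, "var_prior")
  expect_true(all(abs(d$t_mod[shrunk_up]) <= abs(dord$t_mod[shrunk_up]) + 1e-9))
  expect_true(all(abs(d$t_mod[!shrunk_up]) >= abs(dord$t_mod[!shrunk_up]) - 1e-9))
})

test_that("WDA arithmetic follows the worked examples", {
  # pathway of 20 fluxes: 6 up, 2 down, 40 significant network-wide
  # Weight = 8/40 = 0.2 ; WDA = 100 * 0.2 * (6-2)/20 = 4
  d <- data.frame(
    reaction_id = sprintf("r%d", 1:60),
    significant = rep(c(TRUE, FALSE, TRUE, FALSE), c(8, 12, 32, 8)),
    direction = rep(c(1L, -1L, 1L), c(6, 2, 52)))
  smap <- stats::setNames(rep(c("P", "Q"), c(20, 40)), d$reaction_id)
  w <- wda_scores(d, smap)
  expect_equal(w$weight[w$subsystem == "P"], 0.2)
  expect_equal(w$wda[w$subsystem == "P"], 4)

  # maximal case: all 10 fluxes of the only significant pathway increase
  d2 <- data.frame(reaction_id = sprintf("r%d", 1:30),
                   significant = rep(c(TRUE, FALSE), c(10, 20)),
                   direction = 1L)
  smap2 <- stats::setNames(rep(c("P", "Q"), c(10, 20)), d2$reaction_id)
  w2 <- wda_scores(d2, smap2)
  expect_equal(w2$weight[w2$subsystem == "P"], 1)
  expect_equal(w2$wda[w2$subsystem == "P"], 100)
  expect_equal(w2$wda[w2$subsystem == "Q"], 0)  # untouched pathway
})

test_that("WDA invariants: sign, bound, and weights summing to one", {
  set.seed(19)
  for (i in 1:15) {
    G <- 50
    d <- data.frame(reaction_id = sprintf("r%d", 1:G),
                    significant = runif(G) < 0.3,
                    direction = sample(c(1L, -1L), G, TRUE))
    smap <- stats::setNames(sample(LETTERS[1:5], G, TRUE), d$reaction_id)
    w <- wda_scores(d, smap)
    expect_true(all(abs(w$wda) <= 100 + 1e-12))
    expect_equal(sign(w$wda), sign(w$n_increased - w$n_decreased))
    T_ <- sum(d$significant)
    if (T_ > 0) expect_equal(sum(w$weight), 1)
    k <- w$n_increased + w$n_decreased
    bound <- ifelse(w$n_fluxes > 0, 100 * k^2 / (T_ * w$n_fluxes), 0)
    expect_true(all(abs(w$wda) <= bound + 1e-9))
  }
})
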