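## Synthetic cohorts with planted prognosis-associated flux modules.
##
## The stated world: a small connected network of P linear enzymatic
## pathways, each fed by an uptake exchange and drained by a terminal
## export, plus a biomass sink drawing a little of every pathway's
## terminal metabolite and an ATP branch off pathway 1. Expression has
## log-normal marginals (mu_g ~ N(3, 1) on log-FPKM); genes of a planted
## module share a latent activity z (loading lambda) on top of noise
## sigma, which propagates through Michaelis-Menten bounds into
## correlated flux modules. Survival is exponential with log-hazard
## linear in the planted activities, censoring uniform on (0, C_max].

#' Specification of a synthetic cohort
#'
#' Defaults are the package's stated simulation world: 150 samples,
#' three 3-reaction pathways of which two carry planted effects
#' (|beta| = 0.7: one protective, one harmful), loading lambda = 0.95,
#' expression noise sigma = 0.1 (log scale), baseline hazard 0.05/month
#' (median ~14 months, glioblastoma-like) and uniform censoring on
#' (0, 75] months (~30% censored).
#'
#' @param n_samples cohort size (>= 20).
#' @param n_pathways number of pathways (>= 2).
#' @param reactions_per_pathway enzymatic chain length (>= 2).
#' @param planted list of `list(pathway = index, beta = log-hazard
#'   coefficient per unit activity)`; |beta| <= 2.
#' @param lambda latent-factor loading in [0, 1].
#' @param sigma log-scale expression noise sd.
#' @param baseline_hazard events per month.
#' @param c_max censoring window upper end (months).
#' @param random_seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 150L, n_pathways = 3L,
                           reactions_per_pathway = 3L,
                           planted = list(list(pathway = 1L, beta = -0.7),
                                          list(pathway = 2L, beta = 0.7)),
                           lambda = 0.95, sigma = 0.1,
                           baseline_hazard = 0.05, c_max = 75,
                           random_seed = 1L) {
  stopifnot(n_samples >= 20, n_pathways >= 2, reactions_per_pathway >= 2,
            lambda >= 0, lambda <= 1, sigma >= 0, baseline_hazard > 0,
            c_max > 0)
  for (p in planted) {
    stopifnot(p$pathway >= 1, p$pathway <= n_pathways, abs(p$beta) <= 2)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_pathways = as.integer(n_pathways),
                 reactions_per_pathway = as.integer(reactions_per_pathway),
                 planted = planted, lambda = lambda, sigma = sigma,
                 baseline_hazard = baseline_hazard, c_max = c_max,
                 random_seed = as.integer(random_seed)),
            class = "synthetic_spec")
}

subsystem_names <- function(P) {
  base <- c("nucleotide interconversion", "purine recycling",
            "folate metabolism", "glutathione metabolism",
            "fructose and mannose metabolism")
  if (P <= length(base)) base[seq_len(P)] else
    c(base, paste0("pathway ", seq(length(base) + 1, P)))
}

#' Build the toy metabolic network for a synthetic spec
#'
#' One uptake exchange, a linear enzymatic chain (one gene per reaction,
#' except the first pathway whose first two reactions carry an AND and
#' an OR rule) and a terminal-export exchange per pathway; a biomass
#' sink drawing 0.05 of every terminal metabolite (capacity 2); an ATP
#' branch off pathway 1 with its own demand (capacity 2). Objective =
#' biomass + ATP demand. The exchanges of a pathway share its subsystem
#' label: mass balance ties their flux to the chain's, exactly as a
#' transport or exchange reaction sits inside a pathway's flux module.
#'
#' @param spec a [synthetic_spec()].
#' @return a validated [metabolic_network()] whose FBA optimum is
#'   positive under default bounds.
#' @export
make_toy_network <- function(spec) {
  P <- spec$n_pathways; K <- spec$reactions_per_pathway
  subs <- subsystem_names(P)
  mets <- list(); rxns <- list(); stoich <- list()
  add_met <- function(id, comp = "c") mets[[length(mets) + 1]] <<-
    data.frame(id = id, name = id, compartment = comp, stringsAsFactors = FALSE)
  add_rxn <- function(id, sto, lb, ub, gpr = "", subsystem = "", rev = lb < 0) {
    rxns[[length(rxns) + 1]] <<- data.frame(
      id = id, name = id, reversible = rev, lb = lb, ub = ub, gpr = gpr,
      subsystem = subsystem, stringsAsFactors = FALSE)
    stoich[[id]] <<- sto
  }
  for (p in seq_len(P)) {
    for (j in 0:K) add_met(sprintf("M%d_%d_c", p, j))
    add_rxn(sprintf("EX_M%d", p), stats::setNames(-1, sprintf("M%d_0_c", p)),
            lb = -50, ub = 1000, subsystem = subs[p])
    for (j in seq_len(K)) {
      gpr <- if (p == 1 && j == 1) sprintf("(g%d_%da and g%d_%db)", p, j, p, j)
      else if (p == 1 && j == 2) sprintf("(g%d_%da or g%d_%db)", p, j, p, j)
      else sprintf("g%d_%d", p, j)
      add_rxn(sprintf("R%d_%d", p, j),
              stats::setNames(c(-1, 1), sprintf("M%d_%d_c", p, c(j - 1, j))),
              lb = 0, ub = 1000, gpr = gpr, subsystem = subs[p])
    }
    add_rxn(sprintf("EX_T%d", p), stats::setNames(-1, sprintf("M%d_%d_c", p, K)),
            lb = 0, ub = 1000, subsystem = subs[p])
  }
  add_met("atp_c")
  # draw coefficients are deliberately small: the objective branch must
  # not compete with the planted pathways for mass, or biomass/ATP flux
  # would leak survival signal into non-planted reactions
  add_rxn("ATPS", stats::setNames(c(-0.02, 1), c(sprintf("M1_%d_c", K), "atp_c")),
          lb = 0, ub = 1000, gpr = "g_atp", subsystem = "energy metabolism")
  add_rxn("DM_atp", c(atp_c = -1), lb = 0, ub = 2, subsystem = "energy metabolism")
  add_rxn("BIOMASS",
          stats::setNames(rep(-0.01, P), sprintf("M%d_%d_c", seq_len(P), K)),
          lb = 0, ub = 2, subsystem = "biomass")
  metabolic_network(do.call(rbind, mets), do.call(rbind, rxns), stoich,
                    objective = list(biomass = "BIOMASS", atp = "DM_atp",
                                     weights = c(1, 1)))
}

#' Simulate a full synthetic cohort
#'
#' Generates the toy network, a kinetics table (kcat_f log-normal around
#' 25/min), expression with planted latent activities, and exponential
#' survival with uniform censoring. Fully reproducible from
#' `spec$random_seed`; the caller's RNG state is untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_cohort` list: `network`, `kinetics`,
#'   `expression` (gene x sample FPKM), `survival`, `truth`
#'   (`membership`, `z`, `subtype`, `planted`), `spec`.
#' @export
simulate_cohort <- function(spec) {
  net <- make_toy_network(spec)
  withr_seed(spec$random_seed, {
    P <- spec$n_pathways; K <- spec$reactions_per_pathway
    n <- spec$n_samples
    subs <- subsystem_names(P)
    enz <- net$reactions$id[nzchar(net$reactions$gpr)]
    kinetics <- data.frame(
      reaction_id = enz,
      kcat_f = exp(stats::rnorm(length(enz), log(25), 0.3)),
      kcat_b = exp(stats::rnorm(length(enz), log(12), 0.3)),
      source = "default", stringsAsFactors = FALSE)

    genes <- net$genes
    samples <- sprintf("S%03d", seq_len(n))
    mu <- stats::setNames(stats::rnorm(length(genes), 3, 1), genes)
    z <- matrix(stats::rnorm(length(spec$planted) * n), length(spec$planted), n,
                dimnames = list(vapply(spec$planted, function(p) subs[p$pathway],
                                       character(1)), samples))
    gene_module <- rep(NA_integer_, length(genes))
    names(gene_module) <- genes
    for (m in seq_along(spec$planted)) {
      p <- spec$planted[[m]]$pathway
      mg <- unique(unlist(lapply(net$reactions$gpr[net$reactions$subsystem == subs[p]],
                                 gpr_genes)))
      gene_module[mg] <- m
    }
    logf <- matrix(stats::rnorm(length(genes) * n, 0, spec$sigma),
                   length(genes), n, dimnames = list(genes, samples))
    logf <- logf + mu
    for (g in genes) {
      m <- gene_module[[g]]
      if (!is.na(m)) logf[g, ] <- logf[g, ] + spec$lambda * z[m, ]
    }
    expr <- exp(logf)

    betas <- vapply(spec$planted, function(p) p$beta, numeric(1))
    loghaz <- drop(crossprod(z, betas))
    rate <- spec$baseline_hazard * exp(loghaz)
    Tt <- stats::rexp(n, rate)
    U <- stats::runif(n, 0, spec$c_max)
    surv <- survival_records(samples, pmax(pmin(Tt, U), 1e-6),
                             as.integer(Tt <= U))
    surv$idh1_mutant <- 0L

    membership <- lapply(seq_along(spec$planted), function(m) {
      p <- spec$planted[[m]]$pathway
      sort(net$reactions$id[net$reactions$subsystem == subs[p]])
    })
    names(membership) <- rownames(z)
    subtype <- subtype_truth(spec, z)
    structure(list(network = net, kinetics = kinetics, expression = expr,
                   survival = surv,
                   truth = list(membership = membership, z = z,
                                subtype = subtype, planted = spec$planted),
                   spec = spec),
              class = "synthetic_cohort")
  })
}

## true concordant labels from the sign pattern of z for the most
## protective (beta < 0) and most harmful (beta > 0) planted modules
subtype_truth <- function(spec, z) {
  betas <- vapply(spec$planted, function(p) p$beta, numeric(1))
  if (!any(betas < 0) || !any(betas > 0))
    return(stats::setNames(rep(NA_character_, ncol(z)), colnames(z)))
  pos <- which.min(betas)  # protective: high activity -> longer survival
  neg <- which.max(betas)
  lab <- rep("other", ncol(z))
  lab[z[pos, ] > 0 & z[neg, ] < 0] <- "concordant_good"
  lab[z[pos, ] < 0 & z[neg, ] > 0] <- "concordant_bad"
  stats::setNames(lab, colnames(z))
}

#' Default flux-estimation config for a synthetic cohort
#'
#' The synthetic world's stated modeling settings: `scale = 0.01`
#' (bridging FPKM-scale abundances times kcat ~25/min down to chain
#' capacities of a few umol/min/L, so the enzyme bounds -- not the
#' medium -- are the binding constraints), gamma = 0.9, and the spec's
#' sampler defaults. `...` overrides any [gpmm_config()] field.
#'
#' @param cohort a `synthetic_cohort`.
#' @param ... overrides passed to [gpmm_config()].
#' @return a [gpmm_config()].
#' @export
cohort_gpmm_config <- function(cohort, ...) {
  args <- utils::modifyList(
    list(scale = 0.01, random_seed = cohort$spec$random_seed), list(...))
  do.call(gpmm_config, args)
}

#' Ground-truth tables of a synthetic cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @return list `membership` (planted module -> member reaction ids),
#'   `z` (module x sample latent activities), `subtype` (named truth
#'   labels), `planted` (the spec's planted list).
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort$truth
}

#' Write a synthetic cohort in the pipeline's on-disk formats
#'
#' Emits `model.json`, `expression.tsv` (gene_id + one column per
#' sample), `kinetics.tsv`, `clinical.tsv` (sample_id, time_months,
#' event, idh1_mutant) and `truth.json`, so synthetic runs exercise the
#' same I/O paths as real data.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(cohort$network, file.path(dir, "model.json"))
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$kinetics, file.path(dir, "kinetics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clin <- data.frame(sample_id = cohort$survival$sample_id,
                     time_months = cohort$survival$time,
                     event = cohort$survival$event,
                     idh1_mutant = cohort$survival$idh1_mutant)
  utils::write.table(clin, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(membership = cohort$truth$membership,
                            z = as.data.frame(t(cohort$truth$z)),
                            subtype = as.list(cohort$truth$subtype),
                            planted = cohort$truth$planted),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
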