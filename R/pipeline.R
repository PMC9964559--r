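## Pipeline orchestration: a flat "key: value" config (pars.txt style;
## JSON also accepted), staged outputs as TSV/JSON, and a manifest that
## fully determines the outputs (config + seeds + input hashes).

#' Read a pipeline configuration
#'
#' Accepts a flat text file of `key: value` lines (`#` comments allowed,
#' `=` also accepted as separator) or a JSON object, or a ready-made
#' list. Numeric- and logical-looking values are coerced. Defaults are
#' filled for every threshold the pipeline uses.
#'
#' @param x path or named list.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(x) {
  cfg <- if (is.list(x)) x
  else if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
  else {
    lines <- readLines(x, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    kv <- regmatches(lines, regexec("^([^:=]+)[:=](.*)$", lines))
    bad <- vapply(kv, length, integer(1)) != 3
    if (any(bad)) stop("config parse error at line(s): ",
                       paste(lines[bad], collapse = "; "))
    vals <- lapply(kv, function(m) {
      v <- trimws(m[3])
      if (grepl("^-?[0-9.eE+-]+$", v) && !is.na(suppressWarnings(as.numeric(v))))
        as.numeric(v)
      else if (tolower(v) %in% c("true", "false")) as.logical(toupper(v))
      else v
    })
    stats::setNames(vals, vapply(kv, function(m) trimws(m[2]), character(1)))
  }
  defaults <- list(
    flux_unit = "umol/min/L", expr_type = "FPKM",
    optimum_fraction = 0.9, n_mcmc_samples = 1000, warmup_points = 500,
    thinning = 40, scale = 1, default_kcat = "median", missing_gene = "median",
    abundance_alpha = 1,
    alpha_prognosis = 0.01, alpha_diff = 0.01, r_threshold = 0.8,
    min_neighbors = 1, min_group_size = 5,
    exclude_idh1_mutant = TRUE, random_seed = 1, close_unlisted_exchanges = TRUE)
  cfg <- utils::modifyList(defaults, cfg)
  for (k in c("alpha_prognosis", "alpha_diff", "r_threshold"))
    if (cfg[[k]] <= 0 || cfg[[k]] >= 1) stop("config: ", k, " must be in (0,1)")
  structure(cfg, class = c("pipeline_config", "list"))
}

config_gpmm <- function(cfg) {
  gpmm_config(
    biomass_reaction_id = cfg$biomass_reaction_id %||% NULL,
    atp_demand_reaction_id = cfg$atp_demand_reaction_id %||% NULL,
    optimum_fraction = cfg$optimum_fraction,
    n_mcmc_samples = cfg$n_mcmc_samples, warmup_points = cfg$warmup_points,
    thinning = cfg$thinning, random_seed = cfg$random_seed,
    abundance_model = list(name = "power", alpha = cfg$abundance_alpha),
    scale = cfg$scale, default_kcat = cfg$default_kcat,
    missing_gene = cfg$missing_gene)
}

#' Run the full analysis pipeline
#'
#' Stages: cohort filter -> per-sample fluxes -> prognostic reactions ->
#' modules -> representative selection + pair scan -> subtype summary ->
#' differential flux (concordant-good vs concordant-bad) -> WDA. Every
#' stage writes its TSV/JSON under `outdir`; a `manifest.json` records
#' config, seeds, input hashes and per-stage row counts. Re-running the
#' same config reproduces identical outputs.
#'
#' @param config path or list, see [read_pipeline_config()]. Must name
#'   `model_path`, `expression_path`, `kinetics_path`, `clinical_path`
#'   (and optionally `uptake_path`) plus `output_dir`.
#' @param verbose print stage progress.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  cfg <- read_pipeline_config(config)
  outdir <- cfg$output_dir %||% stop("config: output_dir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  inputs <- c(model = cfg$model_path, expression = cfg$expression_path,
              kinetics = cfg$kinetics_path, clinical = cfg$clinical_path,
              uptake = cfg$uptake_path %||% NA_character_)
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("fluxprog")),
                   input_md5 = as.list(tools::md5sum(inputs[!is.na(inputs)])),
                   stages = list(), status = "ok", failed_stage = NULL)
  finish <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }
  run_stage <- function(name, fun) {
    say("stage: ", name)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      manifest$stages[[name]] <<- list(error = conditionMessage(res))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- res$log
    res$value
  }
  on.exit(finish())

  surv <- run_stage("cohort", function() {
    s <- read_clinical(cfg$clinical_path,
                       exclude_idh1_mutant = isTRUE(cfg$exclude_idh1_mutant))
    list(value = s, log = list(n_samples = nrow(s),
                               n_excluded_idh1 = attr(s, "n_excluded_idh1")))
  })
  flux <- run_stage("fluxes", function() {
    net <- read_model(cfg$model_path)
    if (!is.null(cfg$uptake_path))
      net <- apply_medium(net, read_uptake(cfg$uptake_path),
                          close_unlisted = isTRUE(cfg$close_unlisted_exchanges))
    expr <- read_expression(cfg$expression_path)
    expr <- expr[, intersect(colnames(expr), surv$sample_id), drop = FALSE]
    kin <- read_kinetics(cfg$kinetics_path)
    fm <- flux_matrix(net, expr, kin, config_gpmm(cfg), verbose = verbose)
    write_flux_matrix(fm, file.path(outdir, "fluxes.tsv"))
    .fluxprog_env$net <- net
    list(value = fm, log = list(n_reactions = nrow(fm), n_samples = ncol(fm)))
  })
  prog <- run_stage("prognosis", function() {
    pr <- find_prognostic_reactions(flux, surv, alpha = cfg$alpha_prognosis)
    utils::write.table(pr, file.path(outdir, "prognostic_reactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = pr, log = list(n_prognostic = nrow(pr),
                                n_skipped_constant = length(attr(pr, "skipped"))))
  })
  mods <- run_stage("modules", function() {
    md <- extract_modules(flux, prog, R_threshold = cfg$r_threshold,
                          min_neighbors = cfg$min_neighbors)
    utils::write.table(md, file.path(outdir, "modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = md, log = list(n_modules = length(unique(md$module_id)),
                                n_member_reactions = nrow(md)))
  })
  pairs <- run_stage("pair_scan", function() {
    ps <- scan_pairs(mods, flux, surv, prog, min_group_size = cfg$min_group_size)
    utils::write.table(ps, file.path(outdir, "pair_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = ps, log = list(n_pairs = nrow(ps),
                                skipped = attr(ps, "skipped") %||% character(0)))
  })
  subtype <- run_stage("subtype", function() {
    if (nrow(pairs) == 0) stop("no module pair passed the scan")
    best <- pairs[1, ]
    asg <- assign_subtype(best$sign_pos * flux[best$rep_pos, ],
                          best$sign_neg * flux[best$rep_neg, ])
    out <- data.frame(sample_id = names(asg$labels), label = unname(asg$labels),
                      flux_pos = unname(flux[best$rep_pos, names(asg$labels)]),
                      flux_neg = unname(flux[best$rep_neg, names(asg$labels)]))
    utils::write.table(out, file.path(outdir, "subtype_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- summarize_subtype(asg, surv)
    summ$pair <- list(module_pos = best$module_pos, module_neg = best$module_neg,
                      rep_pos = best$rep_pos, rep_neg = best$rep_neg)
    jsonlite::write_json(summ, file.path(outdir, "subtype_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(value = list(assignment = asg, summary = summ),
         log = list(n_good = sum(asg$labels == "concordant_good"),
                    n_bad = sum(asg$labels == "concordant_bad")))
  })
  diff <- run_stage("differential_flux", function() {
    lab <- subtype$assignment$labels
    conc <- lab[lab != "other"]
    groups <- stats::setNames(ifelse(conc == "concordant_good", "high", "low"),
                              names(conc))
    df <- differential_flux(flux, groups, alpha = cfg$alpha_diff)
    utils::write.table(df, file.path(outdir, "differential_flux.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = df, log = list(n_significant = sum(df$significant)))
  })
  run_stage("wda", function() {
    net <- .fluxprog_env$net
    smap <- stats::setNames(net$reactions$subsystem, net$reactions$id)
    wda <- wda_scores(diff, smap)
    utils::write.table(wda, file.path(outdir, "wda.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = wda, log = list(n_pathways = nrow(wda)))
  })
  finish()
}
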