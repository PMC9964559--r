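## Combined two-module metabolic subtypes.
##
## Given one positively prognostic module (high flux -> longer survival)
## and one negatively prognostic module, each sample is median-split on
## the two representative fluxes independently. The concordant-good
## class is high-in-positive AND low-in-negative (the "N+P-" pattern:
## high nucleotide-interconversion, low purine-recycling activity); the
## concordant-bad class is the exact complement; everything else is
## "other".

#' Select a module's representative reaction
#'
#' The member with the smallest log-rank p; ties break
#' lexicographically by reaction id, so selection is deterministic.
#'
#' @param members character vector of module member reaction ids.
#' @param prognosis data.frame from [find_prognostic_reactions()].
#' @return a reaction id.
#' @export
select_representative <- function(members, prognosis) {
  stopifnot(length(members) >= 1)
  p <- prognosis$logrank_p[match(members, prognosis$reaction_id)]
  if (anyNA(p)) stop("select_representative: member(s) missing from prognosis table: ",
                     paste(members[is.na(p)], collapse = ", "))
  # members of a tight module share the same split up to label swap, so
  # their p-values tie up to floating point; compare with a relative
  # tolerance or the tie-break would be decided by ulp noise
  near <- p <= min(p) * (1 + 1e-9) + 1e-300
  sort(members[near])[1]
}

#' Assign combined two-module subtypes
#'
#' Median-splits the two flux vectors independently and labels each
#' sample `concordant_good` (high positive-module flux and low
#' negative-module flux), `concordant_bad` (the complement pattern) or
#' `other`.
#'
#' @param flux_pos named sample -> flux vector of the positive-direction
#'   representative.
#' @param flux_neg same samples, negative-direction representative.
#' @return list `labels` (named character vector) and `splits` (the two
#'   high/low label vectors).
#' @export
assign_subtype <- function(flux_pos, flux_neg) {
  if (!setequal(names(flux_pos), names(flux_neg)))
    stop("assign_subtype: the two flux vectors must cover the same samples")
  flux_neg <- flux_neg[names(flux_pos)]
  sp <- median_split(flux_pos)
  sn <- median_split(flux_neg)
  lab <- rep("other", length(sp))
  lab[sp == "high" & sn == "low"] <- "concordant_good"
  lab[sp == "low" & sn == "high"] <- "concordant_bad"
  list(labels = stats::setNames(lab, names(flux_pos)),
       splits = list(pos = sp, neg = sn))
}

#' Scan all positive/negative module pairs
#'
#' For every ordered pair of modules with a positive-direction and a
#' negative-direction member (pairs of equal direction use the
#' analogous high/low concordance on the first vs second module),
#' computes the subtype assignment and compares the two concordant
#' classes by log-rank and Cox. Pairs whose concordant classes fall
#' below `min_group_size` are skipped and reported in the `skipped`
#' attribute. Result rows are sorted by log-rank p (ties by module
#' ids), so the ranking is deterministic.
#'
#' @param modules data.frame from [extract_modules()].
#' @param flux reactions x samples matrix.
#' @param surv data.frame from [survival_records()].
#' @param prognosis data.frame from [find_prognostic_reactions()].
#' @param min_group_size minimum concordant class size (default 5).
#' @return data.frame `module_pos`, `module_neg`, `rep_pos`, `rep_neg`,
#'   `n_good`, `n_bad`, `hr`, `logrank_p`, sorted ascending by p.
#' @export
scan_pairs <- function(modules, flux, surv, prognosis, min_group_size = 5L) {
  mod_ids <- unique(modules$module_id)
  if (length(mod_ids) < 2) stop("scan_pairs: need at least two modules")
  rep_of <- vapply(mod_ids, function(m)
    select_representative(modules$reaction_id[modules$module_id == m], prognosis),
    character(1))
  # roles follow the representative's OWN prognosis direction: inside a
  # module, anti-correlated members (e.g. the uptake exchange of a
  # pathway) flip sign relative to the majority, and using the module
  # majority would invert the high/low axis of the subtype split
  dir_of <- prognosis$direction[match(rep_of, prognosis$reaction_id)]
  names(dir_of) <- mod_ids
  rows <- list(); skipped <- list()
  pairs_idx <- utils::combn(mod_ids, 2, simplify = FALSE)
  for (ab in pairs_idx) {
    # orient each representative into a protective axis: the positive
    # role gets a flux whose HIGH side means longer survival, the
    # negative role one whose HIGH side means shorter survival. A
    # same-direction pair uses the negated flux of one member (median
    # splits are rank-based, so negation is the exact complement split),
    # which yields the analogous high/high vs low/low concordance.
    a <- ab[1]; b <- ab[2]
    da <- dir_of[[a]]; db <- dir_of[[b]]
    if (da >= 0 && db < 0) { pos <- a; neg <- b; sp <- 1; sn <- 1 }
    else if (da < 0 && db >= 0) { pos <- b; neg <- a; sp <- 1; sn <- 1 }
    else if (da >= 0 && db >= 0) { pos <- a; neg <- b; sp <- 1; sn <- -1 }
    else { pos <- a; neg <- b; sp <- -1; sn <- 1 }
    fp <- sp * flux[rep_of[[pos]], colnames(flux)]
    fn <- sn * flux[rep_of[[neg]], colnames(flux)]
    a <- pos; b <- neg
    asg <- tryCatch(assign_subtype(fp, fn), error = function(e) NULL)
    if (is.null(asg)) next
    n_good <- sum(asg$labels == "concordant_good")
    n_bad <- sum(asg$labels == "concordant_bad")
    if (n_good < min_group_size || n_bad < min_group_size) {
      skipped[[length(skipped) + 1]] <- sprintf("%s/%s (n_good=%d, n_bad=%d)",
                                                a, b, n_good, n_bad)
      next
    }
    conc <- asg$labels[asg$labels != "other"]
    lr <- logrank(conc, surv)
    cx <- tryCatch(cox_univariate(conc, surv), error = function(e) NULL)
    rows[[length(rows) + 1]] <- data.frame(
      module_pos = a, module_neg = b,
      rep_pos = rep_of[[a]], rep_neg = rep_of[[b]],
      sign_pos = sp, sign_neg = sn,
      n_good = n_good, n_bad = n_bad,
      hr = if (is.null(cx)) NA_real_ else cx$hr,
      logrank_p = lr$p_value, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_pos = character(0), module_neg = character(0),
               rep_pos = character(0), rep_neg = character(0),
               sign_pos = integer(0), sign_neg = integer(0),
               n_good = integer(0), n_bad = integer(0),
               hr = numeric(0), logrank_p = numeric(0))
  out <- out[order(out$logrank_p, out$module_pos, out$module_neg), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- unlist(skipped)
  out
}

#' Summarize a subtype assignment against survival
#'
#' Cox hazard ratio (concordant-good vs concordant-bad), log-rank p,
#' class sizes and frequencies, Kaplan-Meier medians per class and for
#' the rest of the cohort, and median-survival gains
#' `(median_good - median_ref) / median_ref * 100`. Gains involving a
#' median that is not reached are `NA`.
#'
#' @param assignment list from [assign_subtype()] (or a named label
#'   vector with levels concordant_good/concordant_bad/other).
#' @param surv data.frame from [survival_records()].
#' @return list of summary fields (see Details).
#' @export
summarize_subtype <- function(assignment, surv) {
  labels <- if (is.list(assignment)) assignment$labels else assignment
  n <- table(factor(labels, levels = c("concordant_good", "concordant_bad", "other")))
  if (n[["concordant_good"]] == 0 || n[["concordant_bad"]] == 0)
    stop("summarize_subtype: concordant classes must be non-empty")
  conc <- labels[labels != "other"]
  cx <- cox_univariate(conc, surv)
  lr <- logrank(conc, surv)
  med3 <- km_median(labels, surv)
  rest <- stats::setNames(ifelse(labels == "concordant_good", "good", "rest"),
                          names(labels))
  med_rest <- km_median(rest, surv)
  gain <- function(a, b) if (is.na(a) || is.na(b) || b == 0) NA_real_ else (a - b) / b * 100
  good_med <- med3[["concordant_good"]]
  list(
    n = as.list(n),
    frequency = as.list(stats::setNames(as.numeric(n) / sum(n), names(n))),
    hr = cx$hr, hr_ci = cx$ci, cox_p = cx$p_value,
    logrank_p = lr$p_value,
    median_survival = as.list(med3),
    median_rest_of_cohort = med_rest[["rest"]],
    gain_vs_bad_pct = gain(good_med, med3[["concordant_bad"]]),
    gain_vs_rest_pct = gain(good_med, med_rest[["rest"]]))
}
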