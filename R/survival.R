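## Survival statistics implemented from first principles: median-split
## group labels, the two-group log-rank test, Kaplan-Meier product-limit
## estimates, and univariate Cox regression (Efron or Breslow ties).
## The CRAN survival package is used only as an independent oracle in
## the test-suite, never here.

#' Survival records constructor/validator
#'
#' @param sample_id character vector.
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicators (1 = death observed).
#' @return data.frame with the three columns, validated.
#' @export
survival_records <- function(sample_id, time, event) {
  stopifnot(length(sample_id) == length(time), length(time) == length(event))
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  data.frame(sample_id = as.character(sample_id), time = as.numeric(time),
             event = as.integer(event), stringsAsFactors = FALSE)
}

#' Median-split classification
#'
#' Labels a sample `"high"` iff its value is strictly larger than the
#' cohort median ("larger than the median" rule: ties at the median go
#' to `"low"`).
#'
#' @param values named numeric vector (sample -> value), >= 4 samples.
#' @return named character vector of `"high"`/`"low"` labels.
#' @export
median_split <- function(values) {
  if (length(values) < 4) stop("median_split: need at least 4 samples")
  if (is.null(names(values))) stop("median_split: values must be named by sample")
  if (max(values) - min(values) <= 0)
    stop("median_split: all values identical; split undefined")
  med <- stats::median(values)
  stats::setNames(ifelse(values > med, "high", "low"), names(values))
}

align_groups <- function(labels, surv) {
  idx <- match(surv$sample_id, names(labels))
  keep <- !is.na(idx)
  data.frame(time = surv$time[keep], event = surv$event[keep],
             label = unname(labels[idx[keep]]), stringsAsFactors = FALSE)
}

## pick the covariate-1 level: "high" when present, else last in sort order
reference_levels <- function(label) {
  lv <- sort(unique(label))
  if (length(lv) != 2) stop("exactly two groups required, got: ",
                            paste(lv, collapse = ", "))
  if ("high" %in% lv) c(setdiff(lv, "high"), "high") else lv
}

#' Two-group log-rank test
#'
#' At each distinct event time, accumulates observed minus expected
#' events in the index group with the hypergeometric variance; the
#' statistic is chi-square with 1 df, two-sided, no continuity
#' correction.
#'
#' @param labels named two-level labels (sample -> group); the `"high"`
#'   level (or the sort-last level) is the index group.
#' @param surv data.frame from [survival_records()].
#' @return list with `statistic`, `p_value`, `observed`, `expected` (index
#'   group), `n_events`, and `zero_events` flag (p = 1 by convention when
#'   no events at all).
#' @export
logrank <- function(labels, surv) {
  d <- align_groups(labels, surv)
  lv <- reference_levels(d$label)
  g1 <- d$label == lv[2]
  if (!any(g1) || all(g1)) stop("logrank: both groups must be non-empty")
  if (sum(d$event) == 0)
    return(list(statistic = 0, p_value = 1, observed = 0, expected = 0,
                n_events = 0L, zero_events = TRUE))
  times <- sort(unique(d$time[d$event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at_risk <- d$time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    ev <- d$time == t & d$event == 1
    dd <- sum(ev); d1 <- sum(ev & g1)
    O1 <- O1 + d1
    E1 <- E1 + dd * n1 / n
    if (n > 1) V <- V + dd * (n1 / n) * (1 - n1 / n) * (n - dd) / (n - 1)
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       observed = O1, expected = E1, n_events = sum(d$event),
       zero_events = FALSE)
}

#' Kaplan-Meier curve for one group
#'
#' @param time,event vectors for the group.
#' @return data.frame `time`, `n_risk`, `n_event`, `surv` (product-limit
#'   estimate after each distinct event time).
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event))
  times <- sort(unique(time[event == 1]))
  s <- 1
  rows <- lapply(times, function(t) {
    n <- sum(time >= t); dd <- sum(time == t & event == 1)
    s <<- s * (1 - dd / n)
    data.frame(time = t, n_risk = n, n_event = dd, surv = s)
  })
  if (!length(rows)) return(data.frame(time = numeric(0), n_risk = integer(0),
                                       n_event = integer(0), surv = numeric(0)))
  do.call(rbind, rows)
}

#' Kaplan-Meier median survival per group
#'
#' Median = earliest event time at which the product-limit estimate
#' drops to 0.5 or below; `NA` ("not reached") when the curve never
#' does.
#'
#' @param labels named group labels (any number of levels).
#' @param surv data.frame from [survival_records()].
#' @return named numeric vector, one median (months) per group level.
#' @export
km_median <- function(labels, surv) {
  d <- align_groups(labels, surv)
  lv <- sort(unique(d$label))
  out <- stats::setNames(rep(NA_real_, length(lv)), lv)
  for (g in lv) {
    cur <- km_curve(d$time[d$label == g], d$event[d$label == g])
    hit <- which(cur$surv <= 0.5 + 1e-12)
    if (length(hit)) out[g] <- cur$time[hit[1]]
  }
  out
}

#' Univariate Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the partial likelihood for a single
#' binary covariate (index group = `"high"`, or the sort-last level),
#' with Efron (default) or Breslow handling of tied event times. The
#' hazard ratio is `exp(beta)` for index vs reference; the 95% CI comes
#' from the observed information. Monotone likelihoods (complete
#' separation) are flagged and reported as divergent.
#'
#' @param labels named two-level labels.
#' @param surv data.frame from [survival_records()].
#' @param ties `"efron"` or `"breslow"`.
#' @return list `hr`, `beta`, `se`, `ci` (length 2), `p_value`,
#'   `divergent`.
#' @export
cox_univariate <- function(labels, surv, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  d <- align_groups(labels, surv)
  lv <- reference_levels(d$label)
  x <- as.numeric(d$label == lv[2])
  if (sum(d$event[x == 1]) < 1 || sum(d$event[x == 0]) < 1)
    stop("cox_univariate: both groups need at least one event")
  beta <- 0; divergent <- FALSE
  for (iter in seq_len(30)) {
    gh <- cox_grad_hess(beta, d$time, d$event, x, ties)
    if (gh$info <= 1e-12) { divergent <- TRUE; break }
    step <- gh$grad / gh$info
    step <- max(min(step, 2), -2)  # damp wild steps
    beta <- beta + step
    if (abs(beta) > 15) { divergent <- TRUE; break }
    if (abs(gh$grad) < 1e-10) break
  }
  gh <- cox_grad_hess(beta, d$time, d$event, x, ties)
  se <- if (gh$info > 0) 1 / sqrt(gh$info) else Inf
  z <- if (is.finite(se) && se > 0) beta / se else NA_real_
  list(hr = exp(beta), beta = beta, se = se,
       ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       p_value = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
       divergent = divergent)
}

cox_grad_hess <- function(beta, time, event, x, ties) {
  ll <- 0; grad <- 0; info <- 0
  ex <- exp(beta * x)
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    Dset <- time == t & event == 1
    dd <- sum(Dset)
    s0R <- sum(ex[risk]); s1R <- sum(x[risk] * ex[risk]); s2R <- sum(x[risk]^2 * ex[risk])
    s0D <- sum(ex[Dset]); s1D <- sum(x[Dset] * ex[Dset]); s2D <- sum(x[Dset]^2 * ex[Dset])
    sx <- sum(x[Dset])
    ll <- ll + beta * sx
    for (l in seq_len(dd) - 1) {
      f <- if (ties == "efron") l / dd else 0
      phi <- s0R - f * s0D
      a <- s1R - f * s1D
      b <- s2R - f * s2D
      ll <- ll - log(phi)
      grad <- grad - a / phi
      info <- info + b / phi - (a / phi)^2
    }
    grad <- grad + sx
  }
  list(loglik = ll, grad = grad, info = info)
}
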