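## Weighted differential-abundance (WDA) pathway scores.
##
## For a pathway (subsystem) with n fluxes of which k_up are
## significantly increased and k_down significantly decreased:
##   Weight = (k_up + k_down) / T,  T = total significant fluxes network-wide
##   WDA    = 100 * Weight * (k_up - k_down) / n
## so |WDA| <= 100, the sign follows the net direction, and pathways
## untouched by significant changes score 0.

#' Weighted differential-abundance pathway scores
#'
#' @param diff data.frame from [differential_flux()] (needs
#'   `reaction_id`, `significant`, `direction`).
#' @param subsystem_map named character vector, reaction id -> subsystem.
#'   Reactions without a subsystem entry (or with an empty label) are
#'   excluded with a warning and do not enter any denominator.
#' @return data.frame `subsystem`, `n_fluxes`, `n_increased`,
#'   `n_decreased`, `weight`, `wda`, sorted by decreasing |wda|.
#' @export
wda_scores <- function(diff, subsystem_map) {
  sub <- subsystem_map[diff$reaction_id]
  missing <- is.na(sub) | !nzchar(sub)
  if (any(missing)) {
    warning("wda_scores: ", sum(missing),
            " reaction(s) without subsystem excluded: ",
            paste(utils::head(diff$reaction_id[missing], 5), collapse = ", "))
    diff <- diff[!missing, , drop = FALSE]
    sub <- sub[!missing]
  }
  total_sig <- sum(diff$significant)
  subsystems <- sort(unique(c(unname(sub),
                              unname(subsystem_map[nzchar(subsystem_map)]))))
  rows <- lapply(subsystems, function(s) {
    in_s <- sub == s
    n <- sum(in_s)
    up <- sum(diff$significant[in_s] & diff$direction[in_s] > 0)
    down <- sum(diff$significant[in_s] & diff$direction[in_s] < 0)
    weight <- if (total_sig > 0) (up + down) / total_sig else 0
    data.frame(subsystem = s, n_fluxes = n, n_increased = up,
               n_decreased = down, weight = weight,
               wda = if (n > 0) 100 * weight * (up - down) / n else 0,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(subsystem = character(0), n_fluxes = integer(0),
                      n_increased = integer(0), n_decreased = integer(0),
                      weight = numeric(0), wda = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$wda), out$subsystem), , drop = FALSE]
  rownames(out) <- NULL
  out
}
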