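## Prognosis-associated reactions and correlation modules.
##
## Each reaction's mean flux is median-split and tested by log-rank;
## reactions below the significance threshold are nodes of a graph with
## an edge whenever |Spearman rho| across samples exceeds R_threshold.
## Non-singular nodes (degree >= min_neighbors) form modules as the
## connected components of that graph.

#' Find prognosis-associated reactions
#'
#' For every reaction: median-split its flux across samples, log-rank
#' test the two groups, keep strict `p < alpha`. Direction comes from
#' the sign of the Cox log-hazard (direction +1: high flux -> lower
#' hazard -> longer survival). Constant-flux reactions cannot be split
#' and are skipped (returned in the `skipped` attribute).
#'
#' @param flux reactions x samples mean-flux matrix.
#' @param surv data.frame from [survival_records()].
#' @param alpha strict significance threshold (default 0.01).
#' @return data.frame `reaction_id`, `logrank_p`, `direction`,
#'   `cox_beta`, `hr`; attribute `"skipped"` lists untestable reactions.
#' @export
find_prognostic_reactions <- function(flux, surv, alpha = 0.01) {
  stopifnot(is.matrix(flux), !is.null(rownames(flux)))
  skipped <- character(0)
  rows <- list()
  for (rid in rownames(flux)) {
    v <- flux[rid, ]
    if (max(v) - min(v) <= 1e-12) { skipped <- c(skipped, rid); next }
    labels <- median_split(v)
    lr <- logrank(labels, surv)
    if (lr$p_value < alpha) {
      cx <- tryCatch(cox_univariate(labels, surv), error = function(e) NULL)
      beta <- if (is.null(cx)) NA_real_ else cx$beta
      rows[[rid]] <- data.frame(
        reaction_id = rid, logrank_p = lr$p_value,
        direction = if (!is.na(beta) && beta < 0) 1L else -1L,
        cox_beta = beta, hr = if (is.null(cx)) NA_real_ else cx$hr,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction_id = character(0), logrank_p = numeric(0),
               direction = integer(0), cox_beta = numeric(0), hr = numeric(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Group prognostic reactions into correlation modules
#'
#' Builds a graph on the prognostic reactions with an edge when
#' `|cor| > R_threshold` (Spearman by default) across samples, drops
#' singular nodes (degree < `min_neighbors`), and reports the connected
#' components of the remainder as modules. A module's direction is the
#' majority direction of its members; mixed-direction components are
#' flagged, not resolved.
#'
#' @param flux reactions x samples matrix restricted (internally) to the
#'   prognostic reactions.
#' @param prognosis data.frame from [find_prognostic_reactions()].
#' @param R_threshold correlation threshold (default 0.8, strict `>`).
#' @param min_neighbors minimum degree to keep a node (default 1).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame `module_id`, `reaction_id`, `direction`,
#'   `mixed_direction`; modules are numbered by their lexicographically
#'   smallest member so the result is invariant to input order.
#' @export
extract_modules <- function(flux, prognosis, R_threshold = 0.8,
                            min_neighbors = 1L,
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ids <- sort(intersect(prognosis$reaction_id, rownames(flux)))
  if (length(ids) < 2)
    return(data.frame(module_id = character(0), reaction_id = character(0),
                      direction = integer(0), mixed_direction = logical(0)))
  cm <- stats::cor(t(flux[ids, , drop = FALSE]), method = method)
  adj <- abs(cm) > R_threshold
  diag(adj) <- FALSE
  keep <- rowSums(adj) >= min_neighbors
  ids <- ids[keep]
  if (length(ids) == 0)
    return(data.frame(module_id = character(0), reaction_id = character(0),
                      direction = integer(0), mixed_direction = logical(0)))
  adj <- adj[keep, keep, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  dirmap <- stats::setNames(prognosis$direction, prognosis$reaction_id)
  out <- list()
  for (k in seq_len(comp$no)) {
    members <- sort(ids[comp$membership == k])
    dirs <- dirmap[members]
    maj <- if (sum(dirs > 0) >= sum(dirs < 0)) 1L else -1L
    out[[k]] <- data.frame(module_id = members[1], reaction_id = members,
                           direction = maj,
                           mixed_direction = length(unique(dirs)) > 1,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$module_id, out$reaction_id), , drop = FALSE]
  # stable human-readable ids M1, M2, ... in order of smallest member
  key <- unique(out$module_id)
  out$module_id <- paste0("M", match(out$module_id, key))
  rownames(out) <- NULL
  out
}
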