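## The metabolic network container and its structural operations.
##
## A `metabolic_network` is an S3 list with:
##   metabolites: data.frame(id, name, compartment)
##   reactions:   data.frame(id, name, reversible, lb, ub, gpr, subsystem)
##   stoich:      named list, reaction id -> named numeric vector of
##                metabolite coefficients (negative = consumed)
##   genes:       character vector of gene ids
##   objective:   list(biomass, atp, weights) or NULL
## Fluxes are in umol/min/L throughout; negative exchange flux = uptake
## (COBRA convention).

#' Construct a metabolic network
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `name`, `reversible`,
#'   `lb`, `ub`, `gpr`, `subsystem`.
#' @param stoich named list (one entry per reaction id) of named numeric
#'   vectors mapping metabolite ids to signed coefficients.
#' @param genes character vector of gene ids; defaults to the union of
#'   genes appearing in GPR rules.
#' @param objective optional `list(biomass =, atp =, weights = c(biomass, atp))`.
#' @return object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, stoich, genes = NULL,
                              objective = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("name")) {
    if (is.null(metabolites[[col]])) metabolites[[col]] <- metabolites$id
    if (is.null(reactions[[col]])) reactions[[col]] <- reactions$id
  }
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(reactions$gpr, function(g) gpr_genes(g))))
    genes <- sort(genes)
  }
  net <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoich = stoich[reactions$id], genes = genes, objective = objective),
    class = "metabolic_network")
  validate_network(net)
  net
}

#' Validate a metabolic network's invariants
#'
#' Checks unique ids, non-empty compartments, bound ordering
#' (`lb <= ub`, irreversible implies `lb >= 0`), stoichiometry referencing
#' only declared metabolites, single-metabolite exchange reactions, and
#' GPR genes contained in the gene list.
#'
#' @param net a `metabolic_network`.
#' @return `net`, invisibly; stops with a validation error otherwise.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  m <- net$metabolites; r <- net$reactions
  if (anyDuplicated(m$id)) stop("validation error: duplicate metabolite ids: ",
                                paste(m$id[duplicated(m$id)], collapse = ", "))
  if (anyDuplicated(r$id)) stop("validation error: duplicate reaction ids: ",
                                paste(r$id[duplicated(r$id)], collapse = ", "))
  if (any(!nzchar(m$compartment))) stop("validation error: empty compartment on metabolite(s): ",
                                        paste(m$id[!nzchar(m$compartment)], collapse = ", "))
  if (any(r$lb > r$ub)) stop("validation error: lb > ub for reaction(s): ",
                             paste(r$id[r$lb > r$ub], collapse = ", "))
  bad_rev <- !r$reversible & r$lb < 0
  if (any(bad_rev)) stop("validation error: irreversible reaction with lb < 0: ",
                         paste(r$id[bad_rev], collapse = ", "))
  if (!setequal(names(net$stoich), r$id) || length(net$stoich) != nrow(r))
    stop("validation error: stoichiometry entries do not match reaction ids")
  for (rid in r$id) {
    s <- net$stoich[[rid]]
    if (length(s) == 0) stop("validation error: reaction with empty stoichiometry: ", rid)
    unknown <- setdiff(names(s), m$id)
    if (length(unknown)) stop("validation error: reaction ", rid,
                              " references undeclared metabolite(s): ",
                              paste(unknown, collapse = ", "))
  }
  gpr_g <- unique(unlist(lapply(r$gpr, gpr_genes)))
  missing_g <- setdiff(gpr_g, net$genes)
  if (length(missing_g)) stop("validation error: GPR gene(s) absent from gene list: ",
                              paste(missing_g, collapse = ", "))
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network: %d reactions, %d metabolites, %d genes\n",
              nrow(x$reactions), nrow(x$metabolites), length(x$genes)))
  cat(sprintf("  exchanges: %d; subsystems: %d\n",
              length(exchange_reactions(x)),
              length(unique(x$reactions$subsystem[nzchar(x$reactions$subsystem)]))))
  if (!is.null(x$objective))
    cat(sprintf("  objective: biomass=%s atp=%s\n",
                x$objective$biomass %||% "-", x$objective$atp %||% "-"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stoichiometric matrix
#'
#' @param net a `metabolic_network`.
#' @return dense metabolites x reactions matrix with dimnames.
#' @export
stoich_matrix <- function(net) {
  S <- matrix(0, nrow(net$metabolites), nrow(net$reactions),
              dimnames = list(net$metabolites$id, net$reactions$id))
  for (rid in net$reactions$id) {
    s <- net$stoich[[rid]]
    S[names(s), rid] <- s
  }
  S
}

#' Exchange reactions of a network
#'
#' An exchange (boundary) reaction touches exactly one metabolite;
#' negative flux is uptake into the system.
#'
#' @param net a `metabolic_network`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(net) {
  net$reactions$id[vapply(net$stoich, length, integer(1)) == 1L]
}

#' Apply a growth-medium uptake table to a network
#'
#' Replaces bounds on the listed exchange reactions and, by default,
#' closes uptake (`lb = 0`) on every unlisted exchange, so the medium
#' table fully determines what the network may import. Non-exchange
#' reactions are untouched.
#'
#' @param net a `metabolic_network`.
#' @param uptake named list / data.frame: exchange reaction id -> `c(lb, ub)`
#'   in umol/min/L, or a data.frame with columns `reaction_id`, `lb`, `ub`.
#' @param close_unlisted close uptake on unlisted exchanges (default `TRUE`).
#' @return the modified network.
#' @export
apply_medium <- function(net, uptake, close_unlisted = TRUE) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.data.frame(uptake)) {
    stopifnot(all(c("reaction_id", "lb", "ub") %in% names(uptake)))
    uptake <- stats::setNames(
      lapply(seq_len(nrow(uptake)), function(i) c(uptake$lb[i], uptake$ub[i])),
      uptake$reaction_id)
  }
  ex <- exchange_reactions(net)
  unknown <- setdiff(names(uptake), ex)
  if (length(unknown)) stop("apply_medium: not exchange reactions of this network: ",
                            paste(unknown, collapse = ", "))
  idx <- match(net$reactions$id, ex, nomatch = 0L) > 0L
  if (close_unlisted) {
    unlisted <- idx & !(net$reactions$id %in% names(uptake))
    net$reactions$lb[unlisted] <- pmax(net$reactions$lb[unlisted], 0)
  }
  for (rid in names(uptake)) {
    i <- match(rid, net$reactions$id)
    net$reactions$lb[i] <- uptake[[rid]][1]
    net$reactions$ub[i] <- uptake[[rid]][2]
    net$reactions$reversible[i] <- uptake[[rid]][1] < 0
  }
  validate_network(net)
  net
}
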