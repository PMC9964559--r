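## Model readers/writers.
##
## Two formats:
##  * a minimal JSON dialect used for fixtures and synthetic networks:
##      {"id": ..., "metabolites":[{id,name,compartment}],
##       "reactions":[{id,name,stoichiometry:{met:coef},lb,ub,reversible,
##                     gpr,subsystem}],
##       "genes":[...], "objective":{biomass,atp,weights}}
##  * SBML Level 3 with the FBC package (flux bounds as parameters,
##    geneProductAssociation trees, optional groups:group subsystems).

#' Read a metabolic model
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; default guesses from the extension
#'   (`.xml`/`.sbml` -> sbml, otherwise json).
#' @return a validated [metabolic_network()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_model: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "json"
  }
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Write a metabolic model
#'
#' @param net a `metabolic_network`.
#' @param path output file path.
#' @param format `"json"` or `"sbml"` (default from extension as in
#'   [read_model()]).
#' @return `path`, invisibly.
#' @export
write_model <- function(net, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "json"
  }
  switch(format, json = write_model_json(net, path), sbml = write_model_sbml(net, path))
  invisible(path)
}

read_model_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("read_model: malformed JSON in ", path,
                                         ": ", conditionMessage(e), call. = FALSE))
  for (field in c("metabolites", "reactions")) {
    if (is.null(x[[field]])) stop("read_model: missing '", field, "' in ", path)
  }
  mets <- do.call(rbind, lapply(x$metabolites, function(m) {
    if (is.null(m$id)) stop("read_model: metabolite without id in ", path)
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c", stringsAsFactors = FALSE)
  }))
  rxn_rows <- lapply(x$reactions, function(r) {
    if (is.null(r$id)) stop("read_model: reaction without id in ", path)
    if (is.null(r$stoichiometry) || length(r$stoichiometry) == 0)
      stop("read_model: reaction '", r$id, "' has no stoichiometry")
    lb <- as.numeric(r$lb %||% if (isTRUE(r$reversible)) -1000 else 0)
    ub <- as.numeric(r$ub %||% 1000)
    data.frame(id = r$id, name = r$name %||% r$id,
               reversible = as.logical(r$reversible %||% (lb < 0)),
               lb = lb, ub = ub, gpr = as.character(r$gpr %||% ""),
               subsystem = as.character(r$subsystem %||% ""),
               stringsAsFactors = FALSE)
  })
  rxns <- do.call(rbind, rxn_rows)
  stoich <- stats::setNames(lapply(x$reactions, function(r) {
    vapply(r$stoichiometry, as.numeric, numeric(1))
  }), rxns$id)
  genes <- if (!is.null(x$genes)) unlist(x$genes) else NULL
  objective <- if (!is.null(x$objective)) {
    list(biomass = x$objective$biomass %||% NULL,
         atp = x$objective$atp %||% NULL,
         weights = as.numeric(unlist(x$objective$weights %||% c(1, 1))))
  }
  metabolic_network(mets, rxns, stoich, genes = genes, objective = objective)
}

write_model_json <- function(net, path) {
  rxns <- lapply(seq_len(nrow(net$reactions)), function(i) {
    r <- net$reactions[i, ]
    list(id = r$id, name = r$name,
         stoichiometry = as.list(net$stoich[[r$id]]),
         lb = r$lb, ub = r$ub, reversible = r$reversible,
         gpr = r$gpr, subsystem = r$subsystem)
  })
  mets <- lapply(seq_len(nrow(net$metabolites)), function(i) {
    m <- net$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  out <- list(id = "fluxprog_model", metabolites = mets, reactions = rxns,
              genes = as.list(net$genes))
  if (!is.null(net$objective)) out$objective <- net$objective
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## ---- SBML L3 + FBC ----

SBML_NS <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
             g = "http://www.sbml.org/sbml/level3/version1/groups/version1")

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("read_model: malformed SBML in ", path,
                                           ": ", conditionMessage(e), call. = FALSE))
  sp <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", SBML_NS)
  if (length(sp) == 0) stop("read_model: no species found in ", path)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  boundary_ids <- mets$id[boundary]
  mets <- mets[!boundary, , drop = FALSE]

  params <- xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter", SBML_NS)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  gps <- xml2::xml_find_all(doc, "//fbc:listOfGeneProducts/fbc:geneProduct", SBML_NS)
  gp_lab <- xml2::xml_attr(gps, "fbc:label", ns = SBML_NS)
  gp_ids <- xml2::xml_attr(gps, "fbc:id", ns = SBML_NS)
  gp_label <- stats::setNames(ifelse(is.na(gp_lab), gp_ids, gp_lab), gp_ids)

  rx <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", SBML_NS)
  if (length(rx) == 0) stop("read_model: no reactions found in ", path)
  stoich <- list(); rows <- vector("list", length(rx))
  for (i in seq_along(rx)) {
    node <- rx[[i]]
    rid <- xml2::xml_attr(node, "id")
    sto <- c(sbml_speciesrefs(node, "s:listOfReactants/s:speciesReference", -1),
             sbml_speciesrefs(node, "s:listOfProducts/s:speciesReference", +1))
    unknown <- setdiff(names(sto), c(mets$id, boundary_ids))
    if (length(unknown)) stop("validation error: reaction '", rid,
                              "' references undeclared species: ",
                              paste(unknown, collapse = ", "))
    sto <- sto[names(sto) %in% mets$id]  # drop boundary species
    if (length(sto) == 0) stop("read_model: reaction '", rid,
                               "' has no (non-boundary) species in ", path)
    lbref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns = SBML_NS)
    ubref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns = SBML_NS)
    rev <- xml2::xml_attr(node, "reversible") %in% c("true", NA)
    lb <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]] else if (rev) -1000 else 0
    ub <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else 1000
    gpa <- xml2::xml_find_first(node, "fbc:geneProductAssociation", SBML_NS)
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      tree <- sbml_gpa_tree(xml2::xml_child(gpa), gp_label)
      deparse_gpr(tree)
    }
    rows[[i]] <- data.frame(
      id = rid,
      name = ifelse(is.na(xml2::xml_attr(node, "name")), rid, xml2::xml_attr(node, "name")),
      reversible = rev, lb = lb, ub = ub, gpr = gpr,
      subsystem = "", stringsAsFactors = FALSE)
    stoich[[rid]] <- sto
  }
  rxns <- do.call(rbind, rows)

  # subsystems from groups:group if present
  grp <- xml2::xml_find_all(doc, "//g:group", SBML_NS)
  for (gnode in grp) {
    gname <- xml2::xml_attr(gnode, "g:name", ns = SBML_NS)
    if (is.na(gname)) gname <- xml2::xml_attr(gnode, "g:id", ns = SBML_NS)
    members <- xml2::xml_attr(
      xml2::xml_find_all(gnode, ".//g:member", SBML_NS), "g:idRef", ns = SBML_NS)
    rxns$subsystem[rxns$id %in% members] <- gname
  }

  genes <- sort(unique(unname(gp_label)))
  obj <- xml2::xml_find_first(doc, "//fbc:listOfObjectives/fbc:objective", SBML_NS)
  objective <- NULL
  if (!inherits(obj, "xml_missing")) {
    fo <- xml2::xml_find_all(obj, ".//fbc:fluxObjective", SBML_NS)
    rids <- xml2::xml_attr(fo, "fbc:reaction", ns = SBML_NS)
    coefs <- as.numeric(xml2::xml_attr(fo, "fbc:coefficient", ns = SBML_NS))
    if (length(rids)) {
      objective <- list(biomass = rids[1],
                        atp = if (length(rids) > 1) rids[2] else NULL,
                        weights = coefs)
    }
  }
  metabolic_network(mets, rxns, stoich, genes = genes, objective = objective)
}

sbml_speciesrefs <- function(node, xpath, sign) {
  refs <- xml2::xml_find_all(node, xpath, SBML_NS)
  if (length(refs) == 0) return(stats::setNames(numeric(0), character(0)))
  st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
  st[is.na(st)] <- 1
  stats::setNames(sign * st, xml2::xml_attr(refs, "species"))
}

sbml_gpa_tree <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "fbc:geneProduct", ns = SBML_NS)
    return(unname(gp_label[ref]) %||% ref)
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    return(list(op = nm, args = lapply(kids, sbml_gpa_tree, gp_label = gp_label)))
  }
  stop("read_model: unsupported geneProductAssociation node <", nm, ">")
}

write_model_sbml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  con <- textConnection("sbml_out", "w", local = TRUE)
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', SBML_NS[["s"]], '" xmlns:fbc="', SBML_NS[["fbc"]],
    '" xmlns:groups="', SBML_NS[["g"]],
    '" level="3" version="1" fbc:required="false" groups:required="false">')
  w('<model id="fluxprog_model" fbc:strict="false">')
  comps <- unique(net$metabolites$compartment)
  w('<listOfCompartments>')
  for (cp in comps) w('<compartment id="', esc(cp), '" constant="true"/>')
  w('</listOfCompartments>')
  w('<listOfSpecies>')
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    w('<species id="', esc(m$id), '" name="', esc(m$name), '" compartment="',
      esc(m$compartment),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>')
  }
  w('</listOfSpecies>')
  w('<listOfParameters>')
  for (i in seq_len(nrow(net$reactions))) {
    r <- net$reactions[i, ]
    w('<parameter id="lb_', i, '" value="', format(r$lb, digits = 17), '" constant="true"/>')
    w('<parameter id="ub_', i, '" value="', format(r$ub, digits = 17), '" constant="true"/>')
  }
  w('</listOfParameters>')
  w('<fbc:listOfGeneProducts>')
  for (j in seq_along(net$genes)) {
    w('<fbc:geneProduct fbc:id="gp_', j, '" fbc:label="', esc(net$genes[j]), '"/>')
  }
  w('</fbc:listOfGeneProducts>')
  gp_id <- stats::setNames(paste0("gp_", seq_along(net$genes)), net$genes)
  w('<listOfReactions>')
  for (i in seq_len(nrow(net$reactions))) {
    r <- net$reactions[i, ]
    w('<reaction id="', esc(r$id), '" name="', esc(r$name), '" reversible="',
      tolower(as.character(r$reversible)), '" fast="false" fbc:lowerFluxBound="lb_',
      i, '" fbc:upperFluxBound="ub_', i, '">')
    s <- net$stoich[[r$id]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      w('<listOfReactants>')
      for (mid in names(reac)) w('<speciesReference species="', esc(mid),
                                 '" stoichiometry="', format(-reac[[mid]], digits = 17),
                                 '" constant="true"/>')
      w('</listOfReactants>')
    }
    if (length(prod)) {
      w('<listOfProducts>')
      for (mid in names(prod)) w('<speciesReference species="', esc(mid),
                                 '" stoichiometry="', format(prod[[mid]], digits = 17),
                                 '" constant="true"/>')
      w('</listOfProducts>')
    }
    if (nzchar(r$gpr)) {
      w('<fbc:geneProductAssociation>')
      w(sbml_gpa_xml(parse_gpr(r$gpr), gp_id))
      w('</fbc:geneProductAssociation>')
    }
    w('</reaction>')
  }
  w('</listOfReactions>')
  if (!is.null(net$objective)) {
    w('<fbc:listOfObjectives fbc:activeObjective="obj">')
    w('<fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('<fbc:listOfFluxObjectives>')
    ids <- c(net$objective$biomass, net$objective$atp)
    wts <- rep_len(net$objective$weights %||% 1, length(ids))
    for (k in seq_along(ids)) {
      w('<fbc:fluxObjective fbc:reaction="', esc(ids[k]), '" fbc:coefficient="',
        format(wts[k], digits = 17), '"/>')
    }
    w('</fbc:listOfFluxObjectives>')
    w('</fbc:objective>')
    w('</fbc:listOfObjectives>')
  }
  subs <- unique(net$reactions$subsystem[nzchar(net$reactions$subsystem)])
  if (length(subs)) {
    w('<groups:listOfGroups>')
    for (k in seq_along(subs)) {
      w('<groups:group groups:id="grp_', k, '" groups:kind="partonomy" groups:name="',
        esc(subs[k]), '">')
      w('<groups:listOfMembers>')
      for (rid in net$reactions$id[net$reactions$subsystem == subs[k]]) {
        w('<groups:member groups:idRef="', esc(rid), '"/>')
      }
      w('</groups:listOfMembers>')
      w('</groups:group>')
    }
    w('</groups:listOfGroups>')
  }
  w('</model>')
  w('</sbml>')
  close(con)
  writeLines(sbml_out, path)
}

sbml_gpa_xml <- function(node, gp_id) {
  if (is.character(node)) {
    return(paste0('<fbc:geneProductRef fbc:geneProduct="', gp_id[[node]], '"/>'))
  }
  inner <- paste(vapply(node$args, sbml_gpa_xml, character(1), gp_id = gp_id),
                 collapse = "")
  paste0("<fbc:", node$op, ">", inner, "</fbc:", node$op, ">")
}
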