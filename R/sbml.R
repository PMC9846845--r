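## Minimal SBML Level 3 + FBC v2 support: enough to round-trip
## constraint-based models (species with boundary flags, reactions with
## stoichiometry, reversibility, flux-bound parameters and gene-product
## associations).  Kinetic laws, units, compartments beyond a default, and
## annotations are out of scope.

.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.local_find <- function(node, name) {
  xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))
}

.attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", name, "$"), names(at))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

.gpr_from_node <- function(node) {
  nm <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  if (nm == "geneProductRef") return(.attr_any(node, "geneProduct"))
  parts <- vapply(kids, .gpr_from_node, character(1))
  if (nm == "and") paste0("(", paste(parts, collapse = " and "), ")")
  else if (nm == "or") paste0("(", paste(parts, collapse = " or "), ")")
  else if (length(parts) == 1) parts
  else stop("unsupported gene association element: ", nm, call. = FALSE)
}

#' Read an SBML Level 3 (FBC) constraint-based model
#'
#' @param path SBML file.
#' @param default_bound bound magnitude used when a reaction carries no FBC
#'   flux-bound parameters.
#' @return a [FluxModel-class].
#' @export
readSBML <- function(path, default_bound = 1000) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  species <- .local_find(doc, "species")
  if (!length(species))
    stop("malformed SBML: no species found in ", path, call. = FALSE)
  mets <- data.frame(
    id = vapply(species, function(s) .attr_any(s, "id"), character(1)),
    boundary = vapply(species, function(s)
      identical(.attr_any(s, "boundaryCondition"), "true"), logical(1)))

  params <- .local_find(doc, "parameter")
  pval <- setNames(
    vapply(params, function(p) as.numeric(.attr_any(p, "value")),
           numeric(1)),
    vapply(params, function(p) .attr_any(p, "id"), character(1)))

  rx_nodes <- .local_find(doc, "reaction")
  stoich <- list(); gpr <- character()
  rx <- data.frame(id = character(), reversible = logical(),
                   lb = numeric(), ub = numeric())
  for (rn in rx_nodes) {
    rid <- .attr_any(rn, "id")
    rev <- identical(.attr_any(rn, "reversible"), "true")
    lbp <- .attr_any(rn, "lowerFluxBound")
    ubp <- .attr_any(rn, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]]
          else if (rev) -default_bound else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]]
          else default_bound
    st <- numeric()
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in xml2::xml_children(.local_find(rn, side))) {
        sp <- .attr_any(sr, "species")
        co <- .attr_any(sr, "stoichiometry")
        co <- if (is.na(co)) 1 else as.numeric(co)
        st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0) + sgn * co
      }
    }
    ga <- .local_find(rn, "geneProductAssociation")
    if (length(ga)) {
      kid <- xml2::xml_children(ga[[1]])
      if (length(kid)) gpr[rid] <- .gpr_from_node(kid[[1]])
    }
    stoich[[rid]] <- st[st != 0]
    rx <- rbind(rx, data.frame(id = rid, reversible = rev, lb = lb, ub = ub))
  }
  new("FluxModel", metabolites = mets, reactions = rx,
      stoichiometry = stoich, gpr = gpr)
}

.gpr_tokens <- function(expr) {
  expr <- gsub("([()])", " \\1 ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.gpr_parse <- function(toks) {
  pos <- 1L
  parse_expr <- function() {
    lhs <- parse_term()
    while (pos <= length(toks) && tolower(toks[pos]) == "or") {
      pos <<- pos + 1L
      lhs <- list(op = "or", args = list(lhs, parse_term()))
    }
    lhs
  }
  parse_term <- function() {
    lhs <- parse_atom()
    while (pos <= length(toks) && tolower(toks[pos]) == "and") {
      pos <<- pos + 1L
      lhs <- list(op = "and", args = list(lhs, parse_atom()))
    }
    lhs
  }
  parse_atom <- function() {
    tk <- toks[pos]
    if (tk == "(") {
      pos <<- pos + 1L
      e <- parse_expr()
      if (pos > length(toks) || toks[pos] != ")")
        stop("unbalanced parentheses in GPR", call. = FALSE)
      pos <<- pos + 1L
      e
    } else {
      pos <<- pos + 1L
      list(op = "gene", id = tk)
    }
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in GPR", call. = FALSE)
  out
}

.gpr_genes <- function(expr) {
  toks <- .gpr_tokens(expr)
  toks[!tolower(toks) %in% c("and", "or", "(", ")")]
}

## max over OR (isozymes), min over AND (complex subunits);
## genes with no ratio are neutral (1)
.gpr_eval <- function(expr, ratios) {
  ev <- function(node) {
    if (node$op == "gene")
      return(if (node$id %in% names(ratios)) ratios[[node$id]] else 1)
    vals <- vapply(node$args, ev, numeric(1))
    if (node$op == "or") max(vals) else min(vals)
  }
  ev(.gpr_parse(.gpr_tokens(expr)))
}

.gpr_to_xml <- function(parent, node, ns_prefix = "fbc") {
  if (node$op == "gene") {
    xml2::xml_add_child(parent, paste0(ns_prefix, ":geneProductRef"),
                        "fbc:geneProduct" = node$id)
  } else {
    el <- xml2::xml_add_child(parent, paste0(ns_prefix, ":", node$op))
    for (a in node$args) .gpr_to_xml(el, a, ns_prefix)
  }
}

#' Write a flux model as SBML Level 3 + FBC
#'
#' @param model a [FluxModel-class].
#' @param path output path.
#' @export
writeSBML <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = .FBC_NS, level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "true")
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(loc, "compartment", id = "c", constant = "true")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model@metabolites))) {
    m <- model@metabolites[i, ]
    xml2::xml_add_child(los, "species", id = m$id, compartment = "c",
                        constant = "false", hasOnlySubstanceUnits = "false",
                        boundaryCondition = tolower(as.character(m$boundary)))
  }
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  rx <- model@reactions
  for (i in seq_len(nrow(rx))) {
    for (side in c("lb", "ub"))
      xml2::xml_add_child(lop, "parameter",
                          id = paste0(side, "_", rx$id[i]),
                          value = format(rx[[side]][i], digits = 15),
                          constant = "true")
  }
  genes <- unique(unlist(lapply(model@gpr, .gpr_genes)))
  if (length(genes)) {
    logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(logp, "fbc:geneProduct", "fbc:id" = g,
                          "fbc:label" = g)
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(rx))) {
    rid <- rx$id[i]
    rn <- xml2::xml_add_child(lor, "reaction", id = rid,
                              reversible = tolower(as.character(
                                rx$reversible[i])),
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0("lb_", rid),
                              "fbc:upperFluxBound" = paste0("ub_", rid))
    st <- model@stoichiometry[[rid]]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(subs))
        xml2::xml_add_child(lre, "speciesReference", species = m,
                            stoichiometry = format(-subs[[m]], digits = 15),
                            constant = "true")
    }
    if (length(prods)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prods))
        xml2::xml_add_child(lpr, "speciesReference", species = m,
                            stoichiometry = format(prods[[m]], digits = 15),
                            constant = "true")
    }
    if (rid %in% names(model@gpr)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      .gpr_to_xml(ga, .gpr_parse(.gpr_tokens(model@gpr[[rid]])))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
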