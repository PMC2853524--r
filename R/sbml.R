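# SBML input/output.
#
# Written files are SBML Level 3 Version 1 with the fbc (version 2) package:
# flux bounds as referenced parameters, gene associations as
# fbc:geneProductAssociation trees, the objective as fbc:listOfObjectives.
# On read, both that dialect and the older COBRA-style Level 2 encoding
# (bounds in kineticLaw LOWER_BOUND/UPPER_BOUND parameters, GPRs in
# `<notes>` "GENE_ASSOCIATION:" lines) are accepted, since genome-scale
# models from the 2010 era predate fbc.

SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML ids must be SId; metabolite/reaction ids are prefixed on write and
# stripped on read so arbitrary ids round-trip.
sid <- function(x, prefix) paste0(prefix, gsub("[^A-Za-z0-9_]", "_", x))

#' Write a metabolic model to SBML
#'
#' Emits SBML Level 3 Version 1 with the fbc version-2 package: species,
#' reactions with parameter-referenced flux bounds, gene products with
#' `fbc:geneProductAssociation` trees, and the model objective.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_sbml()]
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  doc <- xml2::xml_new_root("sbml",
                            xmlns = SBML_L3_NS, "xmlns:fbc" = FBC_NS,
                            level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "false")

  comps <- unique(model$metabolites$compartment)
  if (length(comps)) {
    lc <- xml2::xml_add_child(mdl, "listOfCompartments")
    for (cp in comps)
      xml2::xml_add_child(lc, "compartment", id = sid(cp, "C_"), name = cp,
                          constant = "true")
  }

  if (nrow(model$metabolites)) {
    ls <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (i in seq_len(nrow(model$metabolites))) {
      m <- model$metabolites[i, ]
      sp <- xml2::xml_add_child(ls, "species", id = sid(m$id, "M_"),
                                name = m$name,
                                compartment = sid(m$compartment, "C_"),
                                hasOnlySubstanceUnits = "false",
                                boundaryCondition = "false", constant = "false")
      if (!is.na(m$formula) && nzchar(m$formula))
        xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
  }

  # shared flux-bound parameters
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  bounds <- unique(c(model$reactions$lower_bound, model$reactions$upper_bound))
  bound_id <- function(b) sid(paste0("bnd_", format(b, digits = 15)), "P_")
  for (b in bounds)
    xml2::xml_add_child(lp, "parameter", id = bound_id(b),
                        value = format(b, digits = 17), constant = "true")

  genes <- character(0)
  if (nrow(model$reactions)) {
    lr <- xml2::xml_add_child(mdl, "listOfReactions")
    for (i in seq_len(nrow(model$reactions))) {
      r <- model$reactions[i, ]
      rx <- xml2::xml_add_child(lr, "reaction", id = sid(r$id, "R_"),
                                name = r$name,
                                reversible = if (r$lower_bound < 0) "true" else "false",
                                fast = "false",
                                "fbc:lowerFluxBound" = bound_id(r$lower_bound),
                                "fbc:upperFluxBound" = bound_id(r$upper_bound))
      if (!is.na(r$subsystem) && nzchar(r$subsystem)) {
        nt <- xml2::xml_add_child(rx, "notes")
        bd <- xml2::xml_add_child(nt, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
        xml2::xml_add_child(bd, "p", paste0("SUBSYSTEM: ", r$subsystem))
        xml2::xml_add_child(bd, "p", paste0("KIND: ", r$kind))
      } else {
        nt <- xml2::xml_add_child(rx, "notes")
        bd <- xml2::xml_add_child(nt, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
        xml2::xml_add_child(bd, "p", paste0("KIND: ", r$kind))
      }
      s <- model$stoichiometry[[r$id]]
      rea <- s[s < 0]; pro <- s[s > 0]
      if (length(rea)) {
        ln <- xml2::xml_add_child(rx, "listOfReactants")
        for (k in seq_along(rea))
          xml2::xml_add_child(ln, "speciesReference",
                              species = sid(names(rea)[k], "M_"),
                              stoichiometry = format(abs(rea[k]), digits = 17),
                              constant = "true")
      }
      if (length(pro)) {
        ln <- xml2::xml_add_child(rx, "listOfProducts")
        for (k in seq_along(pro))
          xml2::xml_add_child(ln, "speciesReference",
                              species = sid(names(pro)[k], "M_"),
                              stoichiometry = format(pro[k], digits = 17),
                              constant = "true")
      }
      if (nzchar(r$gene_association)) {
        genes <- unique(c(genes, gpr_genes(r$gene_association)))
        ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
        add_gpr_node(ga, parse_gpr(r$gene_association))
      }
    }
  }

  if (length(genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = sid(g, "G_"),
                          "fbc:label" = g)
  }

  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  for (rid in names(model$objective))
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = sid(rid, "R_"),
                        "fbc:coefficient" = format(model$objective[[rid]],
                                                   digits = 17))

  ok <- tryCatch({ xml2::write_xml(doc, path); TRUE },
                 error = function(e) stop("cannot write SBML to '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

# GPR boolean expression -> nested list(op = "and"/"or"/"gene", args/gene)
parse_gpr <- function(txt) {
  toks <- regmatches(txt, gregexpr("\\(|\\)|[^()[:space:]]+", txt))[[1]]
  pos <- 1L
  parse_or <- function() {
    lhs <- parse_and()
    args <- list(lhs)
    while (pos <= length(toks) && tolower(toks[pos]) == "or") {
      pos <<- pos + 1L
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) lhs else list(op = "or", args = args)
  }
  parse_and <- function() {
    lhs <- parse_atom()
    args <- list(lhs)
    while (pos <= length(toks) && tolower(toks[pos]) == "and") {
      pos <<- pos + 1L
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) lhs else list(op = "and", args = args)
  }
  parse_atom <- function() {
    if (pos > length(toks)) stop("malformed gene association: '", txt, "'", call. = FALSE)
    tk <- toks[pos]
    if (tk == "(") {
      pos <<- pos + 1L
      e <- parse_or()
      if (pos > length(toks) || toks[pos] != ")")
        stop("unbalanced parentheses in gene association: '", txt, "'", call. = FALSE)
      pos <<- pos + 1L
      return(e)
    }
    pos <<- pos + 1L
    list(op = "gene", gene = tk)
  }
  out <- parse_or()
  if (pos <= length(toks))
    stop("trailing tokens in gene association: '", txt, "'", call. = FALSE)
  out
}

add_gpr_node <- function(parent, node) {
  if (node$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = sid(node$gene, "G_"))
  } else {
    el <- xml2::xml_add_child(parent, if (node$op == "and") "fbc:and" else "fbc:or")
    for (a in node$args) add_gpr_node(el, a)
  }
}

gpr_node_to_string <- function(node, top = TRUE) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(xml2::xml_attr(node, "geneProduct"))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, gpr_node_to_string, character(1), top = FALSE)
  joined <- paste(parts, collapse = if (nm == "and") " and " else " or ")
  if (top) joined else paste0("(", joined, ")")
}

#' Read a metabolic model from SBML
#'
#' Accepts SBML Level 3 with the fbc package (bounds as referenced
#' parameters, `fbc:geneProductAssociation` GPRs, `fbc:listOfObjectives`)
#' as well as legacy Level 2 COBRA-style files (bounds in kineticLaw
#' `LOWER_BOUND`/`UPPER_BOUND` parameters, GPRs in notes
#' `GENE_ASSOCIATION:` lines).
#'
#' @param path an SBML file.
#' @param default_bound bound magnitude used when a reaction carries no
#'   explicit bounds (lower is 0 for irreversible reactions).
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path, default_bound = 1000) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML XML in '", path, "': ", conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)  # work name-wise; fbc elements keep distinct names
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("no <model> element in '", path, "'", call. = FALSE)

  strip <- function(x, prefix) ifelse(startsWith(x, prefix),
                                      substring(x, nchar(prefix) + 1L), x)

  comp_nodes <- xml2::xml_find_all(mdl, ".//listOfCompartments/compartment")
  comp_name <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
           strip(xml2::xml_attr(comp_nodes, "id"), "C_"),
           xml2::xml_attr(comp_nodes, "name")),
    xml2::xml_attr(comp_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  sp_sids <- xml2::xml_attr(sp_nodes, "id")
  metabolites <- data.frame(
    id = strip(sp_sids, "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  strip(sp_sids, "M_"), xml2::xml_attr(sp_nodes, "name")),
    compartment = unname(comp_name[xml2::xml_attr(sp_nodes, "compartment")]),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula"),
    stringsAsFactors = FALSE)
  metabolites$compartment[is.na(metabolites$compartment)] <-
    xml2::xml_attr(sp_nodes, "compartment")[is.na(metabolites$compartment)]
  # legacy boundary species (COBRA "_b" convention) are not balanced and are
  # dropped from stoichiometry so exchanges stay single-metabolite
  boundary <- sp_sids[xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"]
  keep <- !(sp_sids %in% boundary)
  metabolites <- metabolites[keep, , drop = FALSE]
  sid2met <- stats::setNames(metabolites$id, sp_sids[keep])

  par_nodes <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  n <- length(rx_nodes)
  rid <- character(n); rname <- character(n)
  lbv <- numeric(n); ubv <- numeric(n); gpr <- character(n)
  subsys <- rep(NA_character_, n); kind <- rep(NA_character_, n)
  stoich <- vector("list", n)
  bad_species <- character(0)

  gp_nodes <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gp_nodes, "label")),
           strip(xml2::xml_attr(gp_nodes, "id"), "G_"),
           xml2::xml_attr(gp_nodes, "label")),
    xml2::xml_attr(gp_nodes, "id"))

  for (i in seq_len(n)) {
    rx <- rx_nodes[[i]]
    rsid <- xml2::xml_attr(rx, "id")
    rid[i] <- strip(rsid, "R_")
    rname[i] <- xml2::xml_attr(rx, "name")
    if (is.na(rname[i])) rname[i] <- rid[i]
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")

    # bounds: fbc attributes, then kineticLaw parameters, then defaults
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    kl <- xml2::xml_find_all(rx, "./kineticLaw//parameter")
    kl_val <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")),
                              xml2::xml_attr(kl, "id"))
    lbv[i] <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) par_val[[lb_ref]]
      else if ("LOWER_BOUND" %in% names(kl_val)) kl_val[["LOWER_BOUND"]]
      else if (rev) -default_bound else 0
    ubv[i] <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) par_val[[ub_ref]]
      else if ("UPPER_BOUND" %in% names(kl_val)) kl_val[["UPPER_BOUND"]]
      else default_bound

    srefs <- function(xpath, sign) {
      nodes <- xml2::xml_find_all(rx, xpath)
      if (!length(nodes)) return(numeric(0))
      sids <- xml2::xml_attr(nodes, "species")
      coef <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      coef[is.na(coef)] <- 1
      drop <- sids %in% boundary
      sids <- sids[!drop]; coef <- coef[!drop]
      if (!length(sids)) return(numeric(0))
      mids <- sid2met[sids]
      if (anyNA(mids)) {
        bad_species <<- c(bad_species, rid[i])
        mids[is.na(mids)] <- sids[is.na(mids)]
      }
      stats::setNames(sign * coef, unname(mids))
    }
    s <- c(srefs("./listOfReactants/speciesReference", -1),
           srefs("./listOfProducts/speciesReference", +1))
    # merge duplicate species references
    if (length(s)) {
      merged <- tapply(s, names(s), sum)[unique(names(s))]
      s <- stats::setNames(as.numeric(merged), names(merged))
    }
    stoich[[i]] <- s

    # GPR: fbc association, else notes GENE_ASSOCIATION line
    ga <- xml2::xml_find_first(rx, "./*[local-name()='geneProductAssociation']")
    if (!inherits(ga, "xml_missing")) {
      kids <- xml2::xml_children(ga)
      if (length(kids)) {
        txt <- gpr_node_to_string(kids[[1]])
        # map geneProduct SIds back to labels
        for (gid in names(gp_label))
          txt <- gsub(paste0("\\b", gid, "\\b"), gp_label[[gid]], txt)
        txt <- gsub("\\bG_", "", txt)
        gpr[i] <- txt
      } else gpr[i] <- ""
    } else {
      notes <- xml2::xml_text(xml2::xml_find_all(rx, "./notes//p"))
      if (!length(notes)) notes <- xml2::xml_text(xml2::xml_find_all(rx, "./notes"))
      hit <- grep("GENE[ _]?ASSOCIATION *:", notes, value = TRUE)
      gpr[i] <- if (length(hit)) trimws(sub(".*GENE[ _]?ASSOCIATION *: *", "", hit[[1]])) else ""
    }
    notes <- xml2::xml_text(xml2::xml_find_all(rx, "./notes//p"))
    sub_hit <- grep("^ *SUBSYSTEM *:", notes, value = TRUE)
    if (length(sub_hit)) subsys[i] <- trimws(sub("^ *SUBSYSTEM *: *", "", sub_hit[[1]]))
    kind_hit <- grep("^ *KIND *:", notes, value = TRUE)
    if (length(kind_hit)) kind[i] <- trimws(sub("^ *KIND *: *", "", kind_hit[[1]]))
  }

  if (length(bad_species))
    stop("stoichiometry references undeclared species in reactions: ",
         paste(unique(bad_species), collapse = ", "), call. = FALSE)

  # objective: fbc active objective, else empty (constructor falls back to biomass)
  objective <- NULL
  fo <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfObjectives']/*[local-name()='objective'][1]//*[local-name()='fluxObjective']")
  if (length(fo)) {
    objective <- stats::setNames(as.numeric(xml2::xml_attr(fo, "coefficient")),
                                 strip(xml2::xml_attr(fo, "reaction"), "R_"))
  }

  reactions <- data.frame(id = rid, name = rname, lower_bound = lbv,
                          upper_bound = ubv, gene_association = gpr,
                          subsystem = subsys, kind = kind,
                          stringsAsFactors = FALSE)
  metabolic_model(metabolites, reactions, stats::setNames(stoich, rid),
                  objective = objective)
}
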