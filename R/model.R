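#' Stoichiometric metabolic model container
#'
#' A `metabolic_model` bundles a metabolite table, a reaction table with flux
#' bounds and gene-protein-reaction (GPR) associations, the per-reaction
#' stoichiometry, and an objective (by default the biomass reaction with
#' weight 1). The stoichiometric matrix S (metabolites x reactions) is derived
#' on demand with [stoichiometric_matrix()].
#'
#' Reaction kinds follow the usual constraint-based conventions:
#' `exchange` reactions move a single metabolite across the system boundary
#' (uptake is a negative flux, so uptake limits are set via the lower bound),
#' `transport` reactions move a species between compartments, `biomass` is the
#' lumped growth reaction whose flux is the specific growth rate (1/h), and
#' `maintenance` covers fixed ATP-drain style reactions.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment` and
#'   optionally `formula`. Ids must be non-empty and unique.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gene_association` (boolean expression over gene ids using
#'   `and`/`or`/parentheses, `""` for none), and optionally `subsystem` and
#'   `kind` (one of `"enzymatic"`, `"transport"`, `"exchange"`, `"biomass"`,
#'   `"maintenance"`; `NA` entries are inferred, see [infer_reaction_kinds()]).
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of signed coefficients over metabolite ids (negative =
#'   consumed, positive = produced).
#' @param objective named numeric vector of reaction weights. Defaults to
#'   weight 1 on the (single) biomass reaction when one can be identified.
#' @return An object of class `metabolic_model`.
#' @seealso [read_sbml()], [write_sbml()], [model_summary()], [solve_fba()]
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            objective = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula))
    metabolites$formula <- rep(NA_character_, nrow(metabolites))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$subsystem))
    reactions$subsystem <- rep(NA_character_, nrow(reactions))
  if (is.null(reactions$gene_association))
    reactions$gene_association <- rep("", nrow(reactions))
  reactions$gene_association[is.na(reactions$gene_association)] <- ""
  if (is.null(reactions$kind))
    reactions$kind <- rep(NA_character_, nrow(reactions))

  if (nrow(reactions) > 0L) {
    stoichiometry <- stoichiometry[reactions$id]
  } else {
    stoichiometry <- list()
  }
  m <- structure(list(metabolites = metabolites,
                      reactions = reactions,
                      stoichiometry = stoichiometry,
                      objective = objective),
                 class = "metabolic_model")
  m$reactions$kind <- infer_reaction_kinds(m)
  if (is.null(objective)) {
    bm <- m$reactions$id[m$reactions$kind == "biomass"]
    m$objective <- if (length(bm) >= 1L) stats::setNames(1, bm[[1L]]) else numeric(0)
  }
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique non-empty metabolite and reaction
#' ids, `lower_bound <= upper_bound`, stoichiometry referencing only declared
#' metabolites, exchange reactions touching exactly one metabolite, and
#' objective weights referencing existing reactions.
#'
#' @param model a `metabolic_model`.
#' @return `model`, invisibly; errors describe every violation found.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met <- model$metabolites; rxn <- model$reactions
  problems <- character(0)
  if (nrow(met) > 0L) {
    if (anyNA(met$id) || any(!nzchar(met$id)))
      problems <- c(problems, "empty metabolite id")
    if (anyDuplicated(met$id))
      problems <- c(problems, sprintf("duplicate metabolite ids: %s",
                                      paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  }
  if (nrow(rxn) > 0L) {
    if (anyDuplicated(rxn$id))
      problems <- c(problems, sprintf("duplicate reaction ids: %s",
                                      paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
    bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
    if (length(bad))
      problems <- c(problems, sprintf("lower_bound > upper_bound for: %s",
                                      paste(bad, collapse = ", ")))
    unknown <- vapply(rxn$id, function(rid) {
      s <- model$stoichiometry[[rid]]
      any(!(names(s) %in% met$id))
    }, logical(1))
    if (any(unknown))
      problems <- c(problems,
                    sprintf("stoichiometry references undeclared species in reactions: %s",
                            paste(rxn$id[unknown], collapse = ", ")))
    nmet <- vapply(model$stoichiometry[rxn$id], length, integer(1))
    bad_ex <- rxn$id[rxn$kind == "exchange" & nmet != 1L]
    if (length(bad_ex))
      problems <- c(problems, sprintf("exchange reactions must reference exactly one metabolite: %s",
                                      paste(bad_ex, collapse = ", ")))
  }
  if (length(model$objective) && !all(names(model$objective) %in% rxn$id))
    problems <- c(problems, "objective references unknown reaction ids")
  if (length(problems))
    stop("invalid metabolic model:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(model)
}

#' Infer reaction kinds from structure and id patterns
#'
#' Reactions without an explicit kind are classified: single-metabolite
#' reactions are `exchange`; reactions whose id matches `biomass_pattern` /
#' `maintenance_pattern` are `biomass` / `maintenance`; reactions moving the
#' same chemical species between two compartments are `transport`; everything
#' else is `enzymatic`. Explicit kinds are kept as-is.
#'
#' @param model a `metabolic_model`.
#' @param biomass_pattern,maintenance_pattern regular expressions matched
#'   case-insensitively against reaction ids and names.
#' @return character vector of kinds, one per reaction.
#' @export
infer_reaction_kinds <- function(model,
                                 biomass_pattern = "biomass|growth",
                                 maintenance_pattern = "maint|atpm") {
  rxn <- model$reactions
  if (nrow(rxn) == 0L) return(character(0))
  met <- model$metabolites
  # chemical species = metabolite id stripped of a compartment suffix
  species <- sub("_[a-zA-Z0-9]+$", "", met$id)
  names(species) <- met$id
  comp <- stats::setNames(met$compartment, met$id)
  kinds <- rxn$kind
  for (i in seq_len(nrow(rxn))) {
    if (!is.na(kinds[i]) && nzchar(kinds[i])) next
    s <- model$stoichiometry[[rxn$id[i]]]
    tag <- paste(rxn$id[i], rxn$name[i])
    if (grepl(biomass_pattern, tag, ignore.case = TRUE)) {
      kinds[i] <- "biomass"
    } else if (grepl(maintenance_pattern, tag, ignore.case = TRUE)) {
      kinds[i] <- "maintenance"
    } else if (length(s) == 1L) {
      kinds[i] <- "exchange"
    } else {
      sp <- unique(species[names(s)])
      cp <- unique(comp[names(s)])
      kinds[i] <- if (length(sp) < length(s) && length(cp) > 1L) "transport" else "enzymatic"
    }
  }
  kinds
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @param sparse return a `Matrix::sparseMatrix` (default) or a dense matrix.
#' @return metabolites x reactions matrix with dimnames; entry (i, j) is the
#'   signed coefficient of metabolite i in reaction j.
#' @export
stoichiometric_matrix <- function(model, sparse = TRUE) {
  validate_model(model)
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    s <- model$stoichiometry[[rxn_ids[j]]]
    if (length(s) == 0L) next
    ii <- c(ii, match(names(s), met_ids))
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, as.numeric(s))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  if (sparse) S else as.matrix(S)
}

# tokens of a GPR string that are gene ids (everything except and/or)
gpr_genes <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character(0))
  toks <- strsplit(gsub("[()]", " ", gpr), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  unique(toks[!tolower(toks) %in% c("and", "or")])
}

#' Map genes to the reactions they are associated with
#'
#' A gene maps to reaction j iff it occurs anywhere in reaction j's GPR
#' expression (isozymes via `or` and complex members via `and` are treated
#' alike for matching purposes). Reactions with empty associations contribute
#' nothing.
#'
#' Placeholder tokens (`Unknown`, `s0001`-style) are kept in the map but
#' recorded in the `"placeholder"` attribute so downstream accounting can
#' flag them.
#'
#' @param model a `metabolic_model`.
#' @return named list: gene id -> character vector of reaction ids.
#' @export
gene_reaction_map <- function(model) {
  rxn <- model$reactions
  out <- list()
  for (i in seq_len(nrow(rxn))) {
    for (g in gpr_genes(rxn$gene_association[i])) {
      out[[g]] <- c(out[[g]], rxn$id[i])
    }
  }
  out <- lapply(out, unique)
  ph <- grepl("^(unknown|s[0-9]{4,})$", names(out), ignore.case = TRUE)
  attr(out, "placeholder") <- names(out)[ph]
  out
}

#' Structural summary of a model
#'
#' Counts metabolites, reactions by kind (the kinds partition the reaction
#' set), gene-associated (enzyme-catalyzed) reactions, and distinct genes.
#'
#' @param model a `metabolic_model`.
#' @return list with `n_metabolites`, `n_reactions`, `reactions_by_kind`
#'   (named integer vector), `n_gene_associated_reactions`, `n_genes`.
#' @export
model_summary <- function(model) {
  validate_model(model)
  rxn <- model$reactions
  kinds <- c("enzymatic", "transport", "exchange", "biomass", "maintenance")
  by_kind <- vapply(kinds, function(k) sum(rxn$kind == k), integer(1))
  grm <- gene_reaction_map(model)
  list(n_metabolites = nrow(model$metabolites),
       n_reactions = nrow(rxn),
       reactions_by_kind = by_kind,
       n_gene_associated_reactions = sum(nzchar(rxn$gene_association)),
       n_genes = length(grm))
}

#' @export
print.metabolic_model <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf("metabolic_model: %d metabolites, %d reactions (%s), %d genes\n",
              s$n_metabolites, s$n_reactions,
              paste(sprintf("%s %d", names(s$reactions_by_kind), s$reactions_by_kind),
                    collapse = ", "),
              s$n_genes))
  if (length(x$objective))
    cat("objective:", paste(sprintf("%s (%g)", names(x$objective), x$objective),
                            collapse = " + "), "\n")
  invisible(x)
}

#' Export metabolite and reaction tables as TSV
#'
#' Mirrors the usual supplementary-table layout: a metabolite table
#' (id, name, compartment, formula) and a reaction table
#' (id, name, equation, lower_bound, upper_bound, genes, subsystem, kind).
#'
#' @param model a `metabolic_model`.
#' @param metabolite_path,reaction_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_model_tables <- function(model, metabolite_path, reaction_path) {
  validate_model(model)
  utils::write.table(model$metabolites, metabolite_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  eq <- vapply(model$reactions$id, function(rid) {
    s <- model$stoichiometry[[rid]]
    lhs <- s[s < 0]; rhs <- s[s > 0]
    fmt <- function(v) paste(sprintf("%g %s", abs(v), names(v)), collapse = " + ")
    arrow <- if (model$reactions$lower_bound[match(rid, model$reactions$id)] < 0) "<=>" else "-->"
    paste(fmt(lhs), arrow, fmt(rhs))
  }, character(1))
  rt <- data.frame(id = model$reactions$id, name = model$reactions$name,
                   equation = eq,
                   lower_bound = model$reactions$lower_bound,
                   upper_bound = model$reactions$upper_bound,
                   genes = model$reactions$gene_association,
                   subsystem = model$reactions$subsystem,
                   kind = model$reactions$kind,
                   stringsAsFactors = FALSE)
  utils::write.table(rt, reaction_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(metabolite_path, reaction_path))
}
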