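# Core container for a conventional genome-scale metabolic model.
#
# Everything tabular: metabolites, reactions and the stoichiometry (one row
# per nonzero coefficient, consumption negative / production positive). This
# keeps models pipeable and serialisable; sparse/dense matrices are built on
# demand by the LP layer.

#' Construct a conventional stoichiometric model
#'
#' @param metabolites tibble with columns `id`, and optionally `name`,
#'   `compartment`, `provenance`.
#' @param reactions tibble with columns `id`, `lb`, `ub`, and optionally
#'   `name`, `gpr`, `subsystem`, `provenance`.
#' @param stoich tibble with columns `reaction`, `metabolite`, `coef`
#'   (consumption negative, production positive).
#' @param genes character vector of gene ids (defaults to genes mentioned in
#'   GPRs).
#' @param objective id of the single objective (biomass) reaction.
#' @param annotation named list of free-form annotations; the element
#'   `met_xref` (named character: external id -> model metabolite id) is used
#'   when merging underground reactions.
#' @return an object of class `stoich_model`.
#' @export
stoich_model <- function(metabolites, reactions, stoich, genes = NULL,
                         objective, annotation = list()) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  stoich <- as_tibble(stoich)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  if (!"provenance" %in% names(metabolites)) metabolites$provenance <- "native"
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  if (!"provenance" %in% names(reactions)) reactions$provenance <- "native"
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(reactions$gpr, gpr_genes)))
  }
  m <- structure(
    list(
      metabolites = metabolites[, c("id", "name", "compartment", "provenance")],
      reactions = reactions[, c("id", "name", "lb", "ub", "gpr", "subsystem",
                                "provenance")],
      stoich = stoich[, c("reaction", "metabolite", "coef")],
      genes = as.character(genes),
      objective = objective,
      annotation = annotation
    ),
    class = "stoich_model"
  )
  validate_stoich_model(m)
}

#' Validate a stoichiometric model
#'
#' Checks id uniqueness, metabolite resolution, bound ordering and the
#' presence of exactly one objective reaction.
#'
#' @param m a `stoich_model`.
#' @return `m`, invisibly unchanged, or an error describing the violation.
#' @export
validate_stoich_model <- function(m) {
  if (anyDuplicated(m$metabolites$id)) {
    abort(paste("duplicate metabolite ids:",
                paste(unique(m$metabolites$id[duplicated(m$metabolites$id)]),
                      collapse = ", ")))
  }
  if (anyDuplicated(m$reactions$id)) {
    abort(paste("duplicate reaction ids:",
                paste(unique(m$reactions$id[duplicated(m$reactions$id)]),
                      collapse = ", ")))
  }
  unknown <- setdiff(m$stoich$metabolite, m$metabolites$id)
  if (length(unknown)) {
    abort(paste("stoichiometry references unknown metabolites:",
                paste(unknown, collapse = ", ")))
  }
  unknown_r <- setdiff(m$stoich$reaction, m$reactions$id)
  if (length(unknown_r)) {
    abort(paste("stoichiometry references unknown reactions:",
                paste(unknown_r, collapse = ", ")))
  }
  bad <- m$reactions$id[m$reactions$lb > m$reactions$ub]
  if (length(bad)) {
    abort(paste("lower bound exceeds upper bound for:", paste(bad, collapse = ", ")))
  }
  if (length(m$objective) != 1L || !m$objective %in% m$reactions$id) {
    abort("model must designate exactly one existing objective reaction")
  }
  m
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ", length(x$genes), " genes\n",
      sep = "")
  cat("  objective: ", x$objective, "\n", sep = "")
  und <- sum(x$reactions$provenance == "underground")
  if (und > 0) cat("  underground reactions: ", und, "\n", sep = "")
  invisible(x)
}

#' Dense stoichiometric matrix of a model
#'
#' @param m a `stoich_model` (or `coral_model`).
#' @param metabolites,reactions optional id subsets (default: all, model order).
#' @return numeric matrix, metabolites in rows, reactions in columns.
#' @export
stoich_matrix <- function(m, metabolites = NULL, reactions = NULL) {
  mets <- metabolites %||% m$metabolites$id
  rxns <- reactions %||% m$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  st <- m$stoich[m$stoich$metabolite %in% mets & m$stoich$reaction %in% rxns, ]
  S[cbind(match(st$metabolite, mets), match(st$reaction, rxns))] <- st$coef
  S
}

# stoichiometry of one reaction as named vector
reaction_stoich <- function(m, rxn) {
  st <- m$stoich[m$stoich$reaction == rxn, ]
  setNames(st$coef, st$metabolite)
}

add_reaction_rows <- function(stoich, rxn, coefs) {
  bind_rows(stoich, tibble(reaction = rxn, metabolite = names(coefs),
                           coef = unname(coefs)))
}
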