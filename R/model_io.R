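# Readers/writers for conventional GEMs (community JSON schema and SBML
# level 3 with the FBC v2 extension), underground-reaction tables, plus the
# duplicate-reaction screen used after merging underground reactions.

#' Read a conventional genome-scale model
#'
#' @param path file path.
#' @param format `"json"` (community/BiGG JSON schema) or `"sbml"`
#'   (level 3 + FBC v2); default guessed from the file extension.
#' @return a [stoich_model()].
#' @export
read_gem <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("model file not found:", path))
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format, json = read_gem_json(path), sbml = read_gem_sbml(path))
}

#' Write a conventional genome-scale model
#'
#' @param m a [stoich_model()].
#' @param path output path.
#' @param format `"json"` or `"sbml"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_gem <- function(m, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format, json = write_gem_json(m, path), sbml = write_gem_sbml(m, path))
  invisible(path)
}

read_gem_json <- function(path) {
  d <- tryCatch(jsonlite::read_json(path),
                error = function(e) abort(paste("malformed JSON model:", conditionMessage(e))))
  for (f in c("metabolites", "reactions")) {
    if (is.null(d[[f]])) abort(paste0("malformed JSON model: missing '", f, "'"))
  }
  mets <- tibble(
    id = map_chr(d$metabolites, "id"),
    name = map_chr(d$metabolites, ~ .x$name %||% .x$id),
    compartment = map_chr(d$metabolites, ~ .x$compartment %||% "c")
  )
  rxns <- tibble(
    id = map_chr(d$reactions, "id"),
    name = map_chr(d$reactions, ~ .x$name %||% .x$id),
    lb = map_dbl(d$reactions, ~ .x$lower_bound %||% -1000),
    ub = map_dbl(d$reactions, ~ .x$upper_bound %||% 1000),
    gpr = map_chr(d$reactions, ~ .x$gene_reaction_rule %||% ""),
    subsystem = map_chr(d$reactions, ~ .x$subsystem %||% ""),
    provenance = map_chr(d$reactions, ~ .x$provenance %||% "native"),
    obj = map_dbl(d$reactions, ~ .x$objective_coefficient %||% 0)
  )
  stoich <- list_rbind(map2(d$reactions, rxns$id, function(r, id) {
    if (is.null(r$metabolites) || length(r$metabolites) == 0) {
      return(tibble(reaction = character(), metabolite = character(), coef = double()))
    }
    tibble(reaction = id, metabolite = names(r$metabolites),
           coef = as.numeric(unlist(r$metabolites)))
  }))
  obj <- rxns$id[rxns$obj != 0]
  if (length(obj) != 1L) {
    abort(paste("model must designate exactly one objective reaction, found",
                length(obj)))
  }
  genes <- if (!is.null(d$genes)) map_chr(d$genes, "id") else NULL
  ann <- d$annotation %||% list()
  if (!is.null(ann$met_xref)) ann$met_xref <- unlist(ann$met_xref)
  stoich_model(mets, rxns[, setdiff(names(rxns), "obj")], stoich,
               genes = genes, objective = obj, annotation = ann)
}

write_gem_json <- function(m, path) {
  rx <- m$reactions
  out <- list(
    id = m$annotation$model_id %||% "model",
    version = "1",
    metabolites = pmap(m$metabolites, function(id, name, compartment, provenance) {
      list(id = id, name = name, compartment = compartment)
    }),
    reactions = pmap(rx, function(id, name, lb, ub, gpr, subsystem, provenance) {
      st <- reaction_stoich(m, id)
      list(id = id, name = name, metabolites = as.list(st),
           lower_bound = lb, upper_bound = ub, gene_reaction_rule = gpr,
           subsystem = subsystem, provenance = provenance,
           objective_coefficient = if (id == m$objective) 1 else 0)
    }),
    genes = lapply(m$genes, function(g) list(id = g, name = g))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- SBML level 3 + FBC v2 (hand-rolled on xml2: no SBML package in R) ----

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# SBML SIds cannot start with a digit or contain arbitrary characters; the
# community convention prefixes R_/M_/G_ and we keep it for interoperability.
sbml_sid <- function(x) gsub("[^A-Za-z0-9_]", "__", x)

write_gem_sbml <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('  <model id="', sbml_sid(m$annotation$model_id %||% "model"),
    '" fbc:strict="true">')
  comps <- unique(m$metabolites$compartment)
  w("    <listOfCompartments>")
  for (cpt in comps) {
    w('      <compartment id="', sbml_sid(cpt), '" constant="true"/>')
  }
  w("    </listOfCompartments>")
  w("    <listOfSpecies>")
  for (i in seq_len(nrow(m$metabolites))) {
    mt <- m$metabolites[i, ]
    w('      <species id="M_', sbml_sid(mt$id), '" name="', xml_escape(mt$name),
      '" compartment="', sbml_sid(mt$compartment),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>')
  }
  w("    </listOfSpecies>")
  w("    <listOfParameters>")
  bounds <- sort(unique(c(m$reactions$lb, m$reactions$ub)))
  for (i in seq_along(bounds)) {
    w('      <parameter id="par_bound_', i, '" value="',
      format(bounds[i], digits = 17), '" constant="true"/>')
  }
  w("    </listOfParameters>")
  if (length(m$genes)) {
    w("    <fbc:listOfGeneProducts>")
    for (g in m$genes) {
      w('      <fbc:geneProduct fbc:id="G_', sbml_sid(g), '" fbc:label="',
        xml_escape(g), '"/>')
    }
    w("    </fbc:listOfGeneProducts>")
  }
  w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  w("        <fbc:listOfFluxObjectives>")
  w('          <fbc:fluxObjective fbc:reaction="R_', sbml_sid(m$objective),
    '" fbc:coefficient="1"/>')
  w("        </fbc:listOfFluxObjectives>")
  w("      </fbc:objective>")
  w("    </fbc:listOfObjectives>")
  w("    <listOfReactions>")
  gpr_to_fbc <- function(ast, indent) {
    pad <- strrep(" ", indent)
    if (is.character(ast)) {
      return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="G_',
                    sbml_sid(ast), '"/>'))
    }
    tag <- if (ast$op == "and") "fbc:and" else "fbc:or"
    c(paste0(pad, "<", tag, ">"),
      unlist(lapply(ast$args, gpr_to_fbc, indent = indent + 2)),
      paste0(pad, "</", tag, ">"))
  }
  for (i in seq_len(nrow(m$reactions))) {
    r <- m$reactions[i, ]
    st <- reaction_stoich(m, r$id)
    w('      <reaction id="R_', sbml_sid(r$id), '" name="', xml_escape(r$name),
      '" reversible="', if (r$lb < 0) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="par_bound_', match(r$lb, bounds),
      '" fbc:upperFluxBound="par_bound_', match(r$ub, bounds), '">')
    subs <- st[st < 0]
    prods <- st[st > 0]
    if (length(subs)) {
      w("        <listOfReactants>")
      for (k in seq_along(subs)) {
        w('          <speciesReference species="M_', sbml_sid(names(subs)[k]),
          '" stoichiometry="', format(-subs[k], digits = 17), '" constant="true"/>')
      }
      w("        </listOfReactants>")
    }
    if (length(prods)) {
      w("        <listOfProducts>")
      for (k in seq_along(prods)) {
        w('          <speciesReference species="M_', sbml_sid(names(prods)[k]),
          '" stoichiometry="', format(prods[k], digits = 17), '" constant="true"/>')
      }
      w("        </listOfProducts>")
    }
    ast <- parse_gpr(r$gpr)
    if (!is.null(ast)) {
      w("        <fbc:geneProductAssociation>")
      w(gpr_to_fbc(ast, 10))
      w("        </fbc:geneProductAssociation>")
    }
    w("      </reaction>")
  }
  w("    </listOfReactions>")
  w("  </model>")
  w("</sbml>")
  invisible(path)
}

strip_prefix <- function(x, prefix) {
  if (!length(x)) return(character(0))
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

read_gem_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste("malformed SBML:", conditionMessage(e))))
  find_all <- function(node, name) {
    xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))
  }
  attr_any <- function(node, name) {
    # attribute with or without the fbc prefix
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
    v
  }
  sp <- find_all(doc, "species")
  if (length(sp) == 0) abort("malformed SBML: no species found")
  mets <- tibble(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"), xml2::xml_attr(sp, "id")),
    compartment = xml2::xml_attr(sp, "compartment")
  )
  gp <- find_all(doc, "geneProduct")
  gene_label <- setNames(
    dplyr::coalesce(vapply(gp, attr_any, "", "label"),
                    strip_prefix(vapply(gp, attr_any, "", "id"), "G_")),
    vapply(gp, attr_any, "", "id")
  )
  params <- find_all(doc, "parameter")
  par_val <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                      xml2::xml_attr(params, "id"))
  fbc_to_gpr <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr_any(node, "geneProduct")
      lbl <- gene_label[[ref]] %||% strip_prefix(ref, "G_")
      return(lbl)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, fbc_to_gpr, "")
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }
  rx_nodes <- find_all(doc, "reaction")
  if (length(rx_nodes) == 0) abort("malformed SBML: no reactions found")
  rx <- list_rbind(map(rx_nodes, function(rn) {
    rid <- strip_prefix(xml2::xml_attr(rn, "id"), "R_")
    lb_ref <- attr_any(rn, "lowerFluxBound")
    ub_ref <- attr_any(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) par_val[[lb_ref]] else
      if (identical(xml2::xml_attr(rn, "reversible"), "true")) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) par_val[[ub_ref]] else 1000
    gpa <- xml2::xml_find_first(rn, ".//*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (length(kids) == 0) "" else fbc_to_gpr(kids[[1]])
    }
    tibble(id = rid,
           name = dplyr::coalesce(xml2::xml_attr(rn, "name"), rid),
           lb = lb, ub = ub, gpr = gpr, subsystem = "", provenance = "native")
  }))
  stoich <- list_rbind(map(rx_nodes, function(rn) {
    rid <- strip_prefix(xml2::xml_attr(rn, "id"), "R_")
    reac <- xml2::xml_find_all(rn, ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    prod <- xml2::xml_find_all(rn, ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    bind_rows(
      tibble(reaction = rid,
             metabolite = strip_prefix(xml2::xml_attr(reac, "species"), "M_"),
             coef = -as.numeric(xml2::xml_attr(reac, "stoichiometry"))),
      tibble(reaction = rid,
             metabolite = strip_prefix(xml2::xml_attr(prod, "species"), "M_"),
             coef = as.numeric(xml2::xml_attr(prod, "stoichiometry")))
    )
  }))
  unknown <- setdiff(stoich$metabolite, mets$id)
  if (length(unknown)) {
    abort(paste("SBML reaction references unknown species:",
                paste(unknown, collapse = ", ")))
  }
  fo <- find_all(doc, "fluxObjective")
  if (length(fo) == 0) abort("SBML model lacks an objective (fbc:fluxObjective)")
  obj <- strip_prefix(attr_any(fo[[1]], "reaction"), "R_")
  genes <- unname(gene_label[vapply(gp, attr_any, "", "id")])
  stoich_model(mets, rx, stoich, genes = if (length(genes)) genes else NULL,
               objective = obj)
}

# ---- underground reactions ----------------------------------------------

#' Read / write an underground-reaction table (TSV)
#'
#' Columns: `reaction`, `equation` (semicolon-separated `metabolite:coef`
#' pairs, consumption negative), `lb`, `ub`, `gpr`. Metabolite ids are either
#' host-model ids or external ids resolvable through the host model's
#' `annotation$met_xref` map.
#'
#' @param path TSV path.
#' @return tibble of class `underground_set` with list-column `stoich`.
#' @export
read_underground_table <- function(path) {
  if (!file.exists(path)) abort(paste("underground table not found:", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  underground_set(tibble(
    reaction = d$reaction,
    stoich = lapply(d$equation, parse_equation),
    lb = d$lb, ub = d$ub, gpr = d$gpr %||% ""
  ))
}

#' @rdname read_underground_table
#' @param und an `underground_set`.
#' @export
write_underground_table <- function(und, path) {
  readr::write_tsv(tibble(
    reaction = und$reaction,
    equation = map_chr(und$stoich, deparse_equation),
    lb = und$lb, ub = und$ub, gpr = und$gpr
  ), path, progress = FALSE)
  invisible(path)
}

parse_equation <- function(eq) {
  parts <- strsplit(trimws(eq), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) abort(paste("cannot parse equation term:", parts[bad][1]))
  setNames(as.numeric(trimws(vapply(kv, `[`, "", 2))),
           trimws(vapply(kv, `[`, "", 1)))
}

deparse_equation <- function(st) {
  paste(paste0(names(st), ":", format(unname(st), digits = 15, trim = TRUE)),
        collapse = ";")
}

#' Construct an underground-reaction set
#'
#' @param x tibble with columns `reaction`, `stoich` (list of named numeric
#'   vectors), `lb`, `ub`, `gpr`.
#' @return tibble of class `underground_set`.
#' @export
underground_set <- function(x) {
  x <- as_tibble(x)
  need <- c("reaction", "stoich", "lb", "ub", "gpr")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste("underground set lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  x$gpr[is.na(x$gpr)] <- ""
  if (anyDuplicated(x$reaction)) abort("duplicate underground reaction ids")
  class(x) <- c("underground_set", class(x))
  x
}

#' Merge underground reactions into a host model
#'
#' Metabolite ids are resolved by exact match against the host namespace
#' first, then through the host's `annotation$met_xref` cross-reference map;
#' unresolvable ids fail loudly. Merged reactions (and any metabolites or
#' genes they introduce) are tagged `provenance = "underground"`.
#'
#' @param m host [stoich_model()].
#' @param und an [underground_set()]; an empty set returns `m` unchanged.
#' @return merged `stoich_model`.
#' @export
merge_underground <- function(m, und) {
  if (is.null(und) || nrow(und) == 0) return(m)
  clash <- intersect(und$reaction, m$reactions$id)
  if (length(clash)) {
    abort(paste("underground reaction ids already in host model:",
                paste(clash, collapse = ", ")))
  }
  xref <- m$annotation$met_xref %||% character()
  resolve <- function(ids) {
    out <- ifelse(ids %in% m$metabolites$id, ids,
                  unname(xref[ids]))
    out
  }
  all_ids <- unique(unlist(lapply(und$stoich, names)))
  resolved <- resolve(all_ids)
  unmatched <- all_ids[is.na(resolved)]
  if (length(unmatched)) {
    abort(paste("underground metabolites not resolvable to host namespace:",
                paste(unmatched, collapse = ", ")))
  }
  mets <- m$metabolites
  new_rx <- tibble(
    id = und$reaction, name = und$reaction, lb = und$lb, ub = und$ub,
    gpr = und$gpr, subsystem = "underground", provenance = "underground"
  )
  new_st <- list_rbind(map2(und$stoich, und$reaction, function(st, rid) {
    tibble(reaction = rid, metabolite = unname(resolve(names(st))),
           coef = unname(st))
  }))
  new_genes <- setdiff(unique(unlist(lapply(und$gpr, gpr_genes))), m$genes)
  stoich_model(
    mets,
    bind_rows(m$reactions, new_rx),
    bind_rows(m$stoich, new_st),
    genes = c(m$genes, new_genes),
    objective = m$objective,
    annotation = m$annotation
  )
}

#' Screen for duplicate or highly similar reactions
#'
#' Computes cosine similarity between all pairs of stoichiometric-matrix
#' columns and reports pairs at or above the threshold. Reactions with an
#' all-zero column are skipped with a warning (cosine undefined).
#'
#' @param m a [stoich_model()].
#' @param threshold similarity threshold in (0, 1]; default 0.90.
#' @return tibble (`reaction_a`, `reaction_b`, `similarity`), unordered pairs
#'   listed once with `reaction_a` < `reaction_b`.
#' @export
find_duplicate_reactions <- function(m, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  S <- stoich_matrix(m)
  nrm <- sqrt(colSums(S^2))
  zero <- nrm == 0
  if (any(zero)) {
    warn(paste("skipping reactions with empty stoichiometry:",
               paste(colnames(S)[zero], collapse = ", ")))
    S <- S[, !zero, drop = FALSE]
    nrm <- nrm[!zero]
  }
  if (ncol(S) < 2) {
    return(tibble(reaction_a = character(), reaction_b = character(),
                  similarity = double()))
  }
  sim <- crossprod(S) / outer(nrm, nrm)
  idx <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
  tibble(
    reaction_a = colnames(S)[idx[, 1]],
    reaction_b = colnames(S)[idx[, 2]],
    similarity = sim[idx]
  ) |> arrange(dplyr::desc(.data$similarity))
}

#' Remove the second member of each duplicate pair
#'
#' @inheritParams find_duplicate_reactions
#' @return model with later-listed duplicates dropped.
#' @export
remove_duplicate_reactions <- function(m, threshold = 0.90) {
  dups <- find_duplicate_reactions(m, threshold)
  drop <- setdiff(unique(dups$reaction_b), m$objective)
  if (!length(drop)) return(m)
  m$reactions <- m$reactions[!m$reactions$id %in% drop, ]
  m$stoich <- m$stoich[!m$stoich$reaction %in% drop, ]
  validate_stoich_model(m)
}
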