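# YAML dialect for restructured (subpool) models. The network, pool wiring,
# ordering rows and the subpool registry are all serialised so that a
# write -> read round trip reproduces the model exactly; numbers are written
# at full precision and list order is preserved, so two writes of the same
# model are byte-identical.

#' Write a restructured model to YAML
#'
#' @param m a `coral_model`.
#' @param path output path (conventionally `.coral.yaml`).
#' @return `path`, invisibly.
#' @export
write_coral_model <- function(m, path) {
  if (!inherits(m, "coral_model")) abort("write_coral_model expects a coral_model")
  num <- function(x) ifelse(is.infinite(x), ifelse(x > 0, ".inf", "-.inf"),
                            format(x, digits = 17, trim = TRUE, scientific = FALSE))
  doc <- list(
    coral_model = list(
      version = 1L,
      form = m$form,
      ordering = m$ordering,
      objective = m$objective,
      pool = list(ptot = m$pool$ptot, sigma = m$pool$sigma, f = m$pool$f,
                  etot = m$pool$etot),
      metabolites = pmap(m$metabolites, function(id, name, compartment, provenance) {
        list(id = id, name = name, compartment = compartment,
             provenance = provenance)
      }),
      reactions = pmap(m$reactions, function(id, name, lb, ub, gpr, subsystem,
                                             provenance, origin) {
        st <- reaction_stoich(m, id)
        list(id = id, name = name, lb = lb, ub = ub, gpr = gpr,
             subsystem = subsystem, provenance = provenance,
             origin = origin, metabolites = as.list(st))
      }),
      genes = as.list(m$genes),
      enzymes = pmap(m$enzymes, function(enzyme, mw, genes, pool_met, supply_rxn) {
        list(id = enzyme, mw = mw, genes = genes, pool_met = pool_met,
             supply_rxn = supply_rxn)
      }),
      registry = pmap(m$registry %||% tibble(), function(enzyme, subpool, rank,
                                                         reaction, direction,
                                                         kcat, mw, ratio, main,
                                                         met, draw_rxn) {
        list(enzyme = enzyme, subpool = subpool, rank = rank,
             reaction = reaction, direction = direction, kcat = kcat,
             mw = mw, ratio = ratio, main = main, met = met,
             draw_rxn = draw_rxn)
      }),
      constraints = if (nrow(m$constraints)) {
        lapply(seq_len(nrow(m$constraints)), function(k) {
          cid <- m$constraints$con_id[k]
          tr <- m$con_terms[m$con_terms$con_id == cid, ]
          list(id = cid, sense = m$constraints$sense[k],
               rhs = m$constraints$rhs[k],
               terms = map2(tr$reaction, tr$coef,
                            function(r, co) list(reaction = r, coef = co)))
        })
      } else list(),
      gpr_map = pmap(m$gpr_map %||% tibble(), function(original, derived) {
        list(original = original, derived = derived)
      }),
      underground_reactions = as.list(m$annotation$underground_reactions %||%
                                        character())
    )
  )
  writeLines(yaml::as.yaml(doc, precision = 15, indent.mapping.sequence = TRUE),
             path)
  invisible(path)
}

#' Read a restructured model from YAML
#'
#' Validates on load: every registry subpool must have its pool-draw
#' pseudoreaction and subpool pseudometabolite present in the network, and
#' every enzyme its supply pseudoreaction.
#'
#' @param path YAML file from [write_coral_model()].
#' @return a `coral_model`.
#' @export
read_coral_model <- function(path) {
  if (!file.exists(path)) abort(paste("model file not found:", path))
  doc <- yaml::read_yaml(path)
  d <- doc$coral_model
  if (is.null(d)) abort("not a coral model YAML (missing top-level coral_model)")
  mets <- list_rbind(map(d$metabolites, as_tibble))
  rx <- list_rbind(map(d$reactions, function(r) {
    tibble(id = r$id, name = r$name, lb = as.numeric(r$lb),
           ub = as.numeric(r$ub), gpr = r$gpr %||% "",
           subsystem = r$subsystem %||% "", provenance = r$provenance,
           origin = r$origin %||% NA_character_)
  }))
  st <- list_rbind(map(d$reactions, function(r) {
    if (length(r$metabolites) == 0) {
      return(tibble(reaction = character(), metabolite = character(),
                    coef = double()))
    }
    tibble(reaction = r$id, metabolite = names(r$metabolites),
           coef = as.numeric(unlist(r$metabolites)))
  }))
  out <- stoich_model(mets, rx[, setdiff(names(rx), "origin")], st,
                      genes = unlist(d$genes) %||% character(),
                      objective = d$objective,
                      annotation = list(
                        underground_reactions = unlist(d$underground_reactions) %||%
                          character()))
  out$reactions$origin <- rx$origin
  out$pool <- pool_config(d$pool$ptot, d$pool$sigma, d$pool$f)
  out$form <- d$form
  out$ordering <- d$ordering
  out$enzymes <- list_rbind(map(d$enzymes, function(e) {
    tibble(enzyme = e$id, mw = as.numeric(e$mw), genes = e$genes,
           pool_met = e$pool_met, supply_rxn = e$supply_rxn)
  }))
  out$registry <- if (length(d$registry)) {
    list_rbind(map(d$registry, function(r) {
      tibble(enzyme = r$enzyme, subpool = r$subpool, rank = as.integer(r$rank),
             reaction = r$reaction, direction = r$direction,
             kcat = as.numeric(r$kcat), mw = as.numeric(r$mw),
             ratio = as.numeric(r$ratio), main = isTRUE(r$main),
             met = r$met, draw_rxn = r$draw_rxn)
    }))
  } else NULL
  cons <- list(); terms <- list()
  for (co in d$constraints) {
    cons[[length(cons) + 1L]] <- tibble(con_id = co$id, sense = co$sense,
                                        rhs = as.numeric(co$rhs))
    terms[[length(terms) + 1L]] <- list_rbind(map(co$terms, function(t) {
      tibble(con_id = co$id, reaction = t$reaction, coef = as.numeric(t$coef))
    }))
  }
  out$constraints <- if (length(cons)) list_rbind(cons) else
    tibble(con_id = character(), sense = character(), rhs = double())
  out$con_terms <- if (length(terms)) list_rbind(terms) else
    tibble(con_id = character(), reaction = character(), coef = double())
  out$gpr_map <- if (length(d$gpr_map)) list_rbind(map(d$gpr_map, as_tibble)) else
    tibble(original = character(), derived = character())
  out$catalysis <- if (!is.null(out$registry)) {
    out$registry |> select("reaction", "enzyme", "direction", "kcat", "mw")
  } else NULL
  class(out) <- c("coral_model", class(out))
  validate_coral_model(out)
}

#' Validate a restructured model's pool wiring
#'
#' @param m a `coral_model`.
#' @return `m` invisibly, or an error naming the broken wiring.
#' @export
validate_coral_model <- function(m) {
  if (!is.null(m$registry)) {
    missing_draw <- setdiff(m$registry$draw_rxn, m$reactions$id)
    if (length(missing_draw)) {
      abort(paste("registry subpool(s) missing their pool-draw pseudoreaction:",
                  paste(missing_draw, collapse = ", ")))
    }
    missing_met <- setdiff(m$registry$met, m$metabolites$id)
    if (length(missing_met)) {
      abort(paste("registry subpool(s) missing their pseudometabolite:",
                  paste(missing_met, collapse = ", ")))
    }
    missing_rxn <- setdiff(m$registry$reaction, m$reactions$id)
    if (length(missing_rxn)) {
      abort(paste("registry references absent catalysed reaction(s):",
                  paste(missing_rxn, collapse = ", ")))
    }
  }
  missing_supply <- setdiff(m$enzymes$supply_rxn, m$reactions$id)
  if (length(missing_supply)) {
    abort(paste("enzyme(s) missing their pool-supply pseudoreaction:",
                paste(missing_supply, collapse = ", ")))
  }
  unknown_con <- setdiff(m$con_terms$reaction, m$reactions$id)
  if (length(unknown_con)) {
    abort(paste("constraints reference absent reaction(s):",
                paste(unknown_con, collapse = ", ")))
  }
  m
}
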