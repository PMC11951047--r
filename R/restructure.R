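# Restructuring a conventional GEM + enzyme table into a subpool model.
#
# Pipeline: (i) GPR simplification — isozyme (OR) branches become duplicate
# reactions, complex (AND) branches become chained partial reactions, so
# every catalysed reaction has exactly one enzyme; (ii) direction split of
# reversible catalysed reactions; (iii) GECKO-style enzyme layer — one
# pseudometabolite per enzyme, consumed at MW/kcat per unit flux, supplied
# from a finite total protein pool; (iv) subpool split — each enzyme's pool
# feeds one subpool per catalysed (reaction, direction), ranked by ascending
# MW/kcat (rank 1 = main reaction, the largest kcat); (v) optional ordering
# constraints prioritising efficient subpools.
#
# Unit conventions: MW g/mmol, kcat 1/h, fluxes mmol/gDW/h. Pool and subpool
# pseudometabolites are carried in mass units (g/gDW): the protein-pool
# exchange bound is Etot = Ptot * f * sigma, supply and draw pseudoreactions
# are 1:1 in mass, and a catalysed reaction consumes its subpool with the
# pseudo-stoichiometric coefficient MW/kcat. Molar usages E = flux/MW are
# reported by the solution accessors.

#' Protein-pool parameters
#'
#' @param ptot total protein content (g protein / gDW); default 0.61.
#' @param sigma average enzyme saturation factor (dimensionless); default 0.5.
#' @param f fraction of the proteome covered by model enzymes; default 0.5.
#' @return list with `ptot`, `sigma`, `f` and the derived pool bound
#'   `etot = ptot * f * sigma` (g/gDW).
#' @export
pool_config <- function(ptot = 0.61, sigma = 0.5, f = 0.5) {
  stopifnot(ptot > 0, sigma > 0, f > 0)
  list(ptot = ptot, sigma = sigma, f = f, etot = ptot * f * sigma)
}

ensure_origin <- function(m) {
  if (!"origin" %in% names(m$reactions)) m$reactions$origin <- m$reactions$id
  m
}

#' Split reactions catalysed by isozymes or enzyme complexes
#'
#' OR branches of each reaction's GPR become duplicate reactions (one per
#' alternative catalyst, suffix `_EXP_k`); an AND conjunction of k enzymes
#' becomes k partial reactions chained head-to-tail through k-1 linking
#' pseudometabolites (suffix `_PART_k`), so all partials carry equal flux and
#' jointly reproduce the original stoichiometry. Each derived reaction is
#' catalysed by exactly one enzyme. Genes without an enzyme record leave the
#' reaction enzyme-free with a warning.
#'
#' @param m a [stoich_model()].
#' @param enz an [enzyme_table()].
#' @return model with derived reactions, a `gpr_map` (original -> derived)
#'   and a `catalysis` table (reaction, enzyme, direction placeholder).
#' @export
split_complex_gprs <- function(m, enz) {
  m <- ensure_origin(m)
  es <- enzyme_summary(enz)
  enz_genes <- setNames(strsplit(es$genes, ";"), es$enzyme)
  enz_rxns <- split(enz$reaction, enz$enzyme)
  gpr_map <- list()
  catalysis <- list()
  rx_out <- list()
  st_out <- list()
  met_add <- list()

  for (i in seq_len(nrow(m$reactions))) {
    r <- m$reactions[i, ]
    branches <- gpr_dnf(r$gpr)
    # catalysts of a branch: enzymes with a kcat record for this reaction
    # whose full gene set lies inside the branch
    branch_cats <- lapply(branches, function(B) {
      cand <- es$enzyme[vapply(es$enzyme, function(e) {
        all(trimws(enz_genes[[e]]) %in% B) &&
          r$origin %in% enz_rxns[[e]]
      }, logical(1))]
      cand
    })
    if (length(branches) == 0 || all(lengths(branch_cats) == 0)) {
      if (length(branches) > 0) {
        warn(paste0("reaction ", r$id,
                    ": no enzyme record for GPR genes; left enzyme-free"))
      }
      rx_out[[length(rx_out) + 1L]] <- r
      st_out[[length(st_out) + 1L]] <-
        m$stoich[m$stoich$reaction == r$id, ]
      gpr_map[[length(gpr_map) + 1L]] <- tibble(original = r$id, derived = r$id)
      next
    }
    st <- reaction_stoich(m, r$id)
    multi <- length(branches) > 1L
    for (b in seq_along(branches)) {
      cats <- branch_cats[[b]]
      rid_b <- if (multi) paste0(r$id, "_EXP_", b) else r$id
      gpr_b <- paste(branches[[b]], collapse = " and ")
      if (length(cats) == 0) {
        warn(paste0("reaction ", r$id, " branch ", b,
                    ": no enzyme record; branch left enzyme-free"))
        cats <- character()
      }
      if (length(cats) <= 1L) {
        rx_out[[length(rx_out) + 1L]] <- r |>
          mutate(id = rid_b, gpr = gpr_b,
                 provenance = if (multi) "partial" else .data$provenance)
        st_out[[length(st_out) + 1L]] <-
          tibble(reaction = rid_b, metabolite = names(st), coef = unname(st))
        gpr_map[[length(gpr_map) + 1L]] <- tibble(original = r$id, derived = rid_b)
        if (length(cats) == 1L) {
          catalysis[[length(catalysis) + 1L]] <-
            tibble(reaction = rid_b, enzyme = cats)
        }
      } else {
        # chain of partial reactions through linking pseudometabolites
        k <- length(cats)
        subs <- st[st < 0]
        prods <- st[st >= 0]
        links <- paste0("link_", rid_b, "_", seq_len(k - 1L))
        met_add[[length(met_add) + 1L]] <- tibble(
          id = links, name = links, compartment = "pseudo", provenance = "link"
        )
        for (p in seq_len(k)) {
          pid <- paste0(rid_b, "_PART_", p)
          coefs <- c(
            if (p == 1L) subs else setNames(-1, links[p - 1L]),
            if (p == k) prods else setNames(1, links[p])
          )
          rx_out[[length(rx_out) + 1L]] <- r |>
            mutate(id = pid, gpr = gpr_b, provenance = "partial")
          st_out[[length(st_out) + 1L]] <-
            tibble(reaction = pid, metabolite = names(coefs), coef = unname(coefs))
          gpr_map[[length(gpr_map) + 1L]] <- tibble(original = r$id, derived = pid)
          catalysis[[length(catalysis) + 1L]] <-
            tibble(reaction = pid, enzyme = cats[p])
        }
      }
    }
  }
  out <- stoich_model(
    bind_rows(m$metabolites, list_rbind(met_add)),
    list_rbind(rx_out),
    list_rbind(st_out),
    genes = m$genes,
    objective = m$objective,
    annotation = m$annotation
  )
  out$reactions$origin <- list_rbind(rx_out)$origin
  out$gpr_map <- list_rbind(gpr_map)
  out$catalysis <- if (length(catalysis)) list_rbind(catalysis) else
    tibble(reaction = character(), enzyme = character())
  out
}

#' Split reversible catalysed reactions into irreversible directions
#'
#' Each catalysed reaction with a negative lower bound is replaced by a
#' forward copy (bounds `[max(0, lb_fwd), ub]`) and a reversed copy
#' `<id>_REV` with flipped stoichiometry and bounds `[0, -lb]`. Each
#' direction is a distinct catalytic activity: `fwd` and `rev` kcat entries
#' attach to the respective copies; a direction with no kcat record is left
#' enzyme-free with a warning.
#'
#' @param m model from [split_complex_gprs()].
#' @param enz an [enzyme_table()].
#' @return model with directional catalysis table (reaction, enzyme,
#'   direction, kcat, mw).
#' @export
split_reversible_catalyzed <- function(m, enz) {
  m <- ensure_origin(m)
  if (is.null(m$catalysis)) abort("run split_complex_gprs() first")
  es <- enzyme_summary(enz)
  rx <- m$reactions
  new_rx <- list()
  new_st <- list()
  cat_rows <- list()
  extra_map <- list()
  kcat_of <- function(e, orig, dir) {
    hit <- enz$kcat[enz$enzyme == e & enz$reaction == orig & enz$direction == dir]
    if (length(hit)) hit[1] else NA_real_
  }
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    e <- m$catalysis$enzyme[m$catalysis$reaction == r$id]
    st <- reaction_stoich(m, r$id)
    catalyzed <- length(e) == 1L
    if (!catalyzed || r$lb >= 0) {
      new_rx[[length(new_rx) + 1L]] <- r
      new_st[[length(new_st) + 1L]] <-
        tibble(reaction = r$id, metabolite = names(st), coef = unname(st))
      if (catalyzed) {
        kc <- kcat_of(e, r$origin, "fwd")
        if (is.na(kc)) {
          warn(paste0("no fwd kcat for enzyme ", e, " on ", r$origin,
                      "; reaction ", r$id, " left enzyme-free"))
        } else {
          cat_rows[[length(cat_rows) + 1L]] <-
            tibble(reaction = r$id, enzyme = e, direction = "fwd", kcat = kc,
                   mw = es$mw[es$enzyme == e])
        }
      }
      next
    }
    # reversible catalysed reaction: fwd copy + _REV copy
    new_rx[[length(new_rx) + 1L]] <- r |> mutate(lb = 0)
    new_st[[length(new_st) + 1L]] <-
      tibble(reaction = r$id, metabolite = names(st), coef = unname(st))
    rev_id <- paste0(r$id, "_REV")
    new_rx[[length(new_rx) + 1L]] <- r |>
      mutate(id = rev_id, lb = 0, ub = -r$lb)
    new_st[[length(new_st) + 1L]] <-
      tibble(reaction = rev_id, metabolite = names(st), coef = -unname(st))
    extra_map[[length(extra_map) + 1L]] <-
      tibble(original = r$origin, derived = rev_id)
    for (dir in c("fwd", "rev")) {
      kc <- kcat_of(e, r$origin, dir)
      target <- if (dir == "fwd") r$id else rev_id
      if (is.na(kc)) {
        warn(paste0("no ", dir, " kcat for enzyme ", e, " on ", r$origin,
                    "; reaction ", target, " left enzyme-free"))
      } else {
        cat_rows[[length(cat_rows) + 1L]] <-
          tibble(reaction = target, enzyme = e, direction = dir, kcat = kc,
                 mw = es$mw[es$enzyme == e])
      }
    }
  }
  out <- stoich_model(
    m$metabolites, list_rbind(new_rx), list_rbind(new_st),
    genes = m$genes, objective = m$objective, annotation = m$annotation
  )
  out$reactions$origin <- list_rbind(new_rx)$origin
  out$gpr_map <- bind_rows(m$gpr_map, list_rbind(extra_map))
  out$catalysis <- if (length(cat_rows)) list_rbind(cat_rows) else
    tibble(reaction = character(), enzyme = character(),
           direction = character(), kcat = double(), mw = double())
  out
}

#' Add the GECKO-form enzyme layer (shared pools)
#'
#' Adds one protein pseudometabolite per enzyme, consumed by each catalysed
#' reaction at MW/kcat, a usage pseudoreaction supplying it from the total
#' protein pool, and the pool exchange bounded by `pool$etot`.
#'
#' @param m model from [split_reversible_catalyzed()].
#' @param enz an [enzyme_table()].
#' @param pool a [pool_config()].
#' @return a `coral_model` in GECKO form (`form = "gecko"`).
#' @export
build_ec_layer <- function(m, enz, pool = pool_config()) {
  if (is.null(m$catalysis) || !"kcat" %in% names(m$catalysis)) {
    abort("run split_complex_gprs() and split_reversible_catalyzed() first")
  }
  lbs <- m$reactions$lb[match(m$catalysis$reaction, m$reactions$id)]
  if (any(lbs < 0)) {
    abort(paste("catalysed reactions left reversible (split directions first):",
                paste(m$catalysis$reaction[lbs < 0], collapse = ", ")))
  }
  used <- sort(unique(m$catalysis$enzyme))
  es <- enzyme_summary(enz) |> filter(.data$enzyme %in% used)
  mets <- bind_rows(
    m$metabolites,
    tibble(id = "prot_pool", name = "total protein pool", compartment = "pseudo",
           provenance = "pseudo"),
    tibble(id = paste0("prot_", es$enzyme), name = paste0("enzyme pool ", es$enzyme),
           compartment = "pseudo", provenance = "pseudo")
  )
  rx <- bind_rows(
    m$reactions,
    tibble(id = "prot_pool_exchange", name = "protein pool exchange",
           lb = 0, ub = pool$etot, gpr = "", subsystem = "pseudo",
           provenance = "pseudo", origin = NA_character_),
    tibble(id = paste0("usage_prot_", es$enzyme),
           name = paste0("usage of enzyme ", es$enzyme),
           lb = 0, ub = Inf, gpr = "", subsystem = "pseudo",
           provenance = "pseudo", origin = NA_character_)
  )
  st <- bind_rows(
    m$stoich,
    tibble(reaction = "prot_pool_exchange", metabolite = "prot_pool", coef = 1),
    tibble(reaction = paste0("usage_prot_", es$enzyme),
           metabolite = "prot_pool", coef = -1),
    tibble(reaction = paste0("usage_prot_", es$enzyme),
           metabolite = paste0("prot_", es$enzyme), coef = 1),
    tibble(reaction = m$catalysis$reaction,
           metabolite = paste0("prot_", m$catalysis$enzyme),
           coef = -m$catalysis$mw / m$catalysis$kcat)
  )
  out <- stoich_model(mets, rx, st, genes = m$genes, objective = m$objective,
                      annotation = m$annotation)
  out$reactions$origin <- rx$origin
  out$gpr_map <- m$gpr_map
  out$catalysis <- m$catalysis
  out$pool <- pool
  out$enzymes <- es |>
    mutate(pool_met = paste0("prot_", .data$enzyme),
           supply_rxn = paste0("usage_prot_", .data$enzyme))
  out$form <- "gecko"
  out$ordering <- "off"
  out$constraints <- tibble(con_id = character(), sense = character(), rhs = double())
  out$con_terms <- tibble(con_id = character(), reaction = character(), coef = double())
  class(out) <- c("coral_model", class(out))
  out
}

#' Split each enzyme pool into per-reaction subpools
#'
#' Every enzyme catalysing K (reaction, direction) activities gets K subpool
#' pseudometabolites and K pool-draw pseudoreactions; each catalysed reaction
#' is rewired from the shared enzyme pseudometabolite to its own subpool
#' (same MW/kcat coefficient). Ranks are assigned by ascending MW/kcat, so
#' rank 1 — the main reaction — carries the enzyme's largest kcat; ties are
#' broken by reaction id (deterministic).
#'
#' @param ec a GECKO-form `coral_model` from [build_ec_layer()].
#' @return a `coral_model` with `form = "subpool"` and a populated subpool
#'   registry.
#' @export
split_subpools <- function(ec) {
  if (!inherits(ec, "coral_model") || ec$form != "gecko") {
    abort("split_subpools() expects a GECKO-form model from build_ec_layer()")
  }
  reg <- ec$catalysis |>
    arrange(.data$enzyme, .data$mw / .data$kcat, .data$reaction) |>
    group_by(.data$enzyme) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    mutate(
      subpool = paste0(.data$enzyme, "_", .data$rank),
      ratio = .data$mw / .data$kcat,
      main = .data$rank == 1L,
      met = paste0("subpool_", .data$enzyme, "_", .data$rank),
      draw_rxn = paste0("draw_", .data$enzyme, "_", .data$rank)
    ) |>
    select("enzyme", "subpool", "rank", "reaction", "direction", "kcat",
           "mw", "ratio", "main", "met", "draw_rxn")
  mets <- bind_rows(
    ec$metabolites,
    tibble(id = reg$met, name = paste0("subpool ", reg$subpool),
           compartment = "pseudo", provenance = "pseudo")
  )
  rx <- bind_rows(
    ec$reactions,
    tibble(id = reg$draw_rxn, name = paste0("draw of subpool ", reg$subpool),
           lb = 0, ub = Inf, gpr = "", subsystem = "pseudo",
           provenance = "pseudo", origin = NA_character_)
  )
  # rewire: catalysed reactions consume their subpool instead of the shared
  # enzyme pseudometabolite
  st <- ec$stoich
  hit <- match(paste(st$reaction, st$metabolite),
               paste(reg$reaction, paste0("prot_", reg$enzyme)))
  st$metabolite[!is.na(hit)] <- reg$met[hit[!is.na(hit)]]
  st <- bind_rows(
    st,
    tibble(reaction = reg$draw_rxn,
           metabolite = paste0("prot_", reg$enzyme), coef = -1),
    tibble(reaction = reg$draw_rxn, metabolite = reg$met, coef = 1)
  )
  out <- stoich_model(mets, rx, st, genes = ec$genes, objective = ec$objective,
                      annotation = ec$annotation)
  out$reactions$origin <- rx$origin
  out$gpr_map <- ec$gpr_map
  out$catalysis <- ec$catalysis
  out$pool <- ec$pool
  out$enzymes <- ec$enzymes
  out$registry <- reg
  out$form <- "subpool"
  out$ordering <- "off"
  out$constraints <- ec$constraints
  out$con_terms <- ec$con_terms
  class(out) <- c("coral_model", class(out))
  out
}

#' Add catalytic-efficiency ordering constraints between subpools
#'
#' For each enzyme, constrains attainable subpool velocities so that less
#' efficient (higher MW/kcat) subpools cannot outrun more efficient ones:
#' `kcat[i+1] * E[s,i+1] <= kcat[i] * E[s,i]` along consecutive ranks
#' (`mode = "chain"`, default), against the main subpool only
#' (`"vs_main"`), as velocity equalities (`"equality"`), or none (`"off"`).
#'
#' @param m subpool-form `coral_model`.
#' @param mode ordering topology.
#' @return model with ordering rows in `constraints` / `con_terms`.
#' @export
add_ordering_constraints <- function(m, mode = c("chain", "vs_main", "equality", "off")) {
  mode <- match.arg(mode)
  if (is.null(m$registry)) abort("run split_subpools() first")
  keep <- !startsWith(m$constraints$con_id, "order_")
  m$constraints <- m$constraints[keep, ]
  m$con_terms <- m$con_terms[m$con_terms$con_id %in% m$constraints$con_id, ]
  m$ordering <- mode
  if (mode == "off") return(m)
  cons <- list()
  terms <- list()
  for (e in unique(m$registry$enzyme)) {
    reg_e <- m$registry |> filter(.data$enzyme == e) |> arrange(.data$rank)
    K <- nrow(reg_e)
    if (K < 2) next
    pairs <- if (mode == "vs_main") {
      cbind(1L, 2:K)
    } else {
      cbind(seq_len(K - 1L), 2:K)
    }
    for (p in seq_len(nrow(pairs))) {
      hi <- pairs[p, 1]; lo <- pairs[p, 2]
      cid <- paste0("order_", e, "_", hi, "_", lo)
      cons[[length(cons) + 1L]] <- tibble(
        con_id = cid,
        sense = if (mode == "equality") "eq" else "le",
        rhs = 0
      )
      # draws are in mass units; MW cancels within an enzyme
      terms[[length(terms) + 1L]] <- tibble(
        con_id = cid,
        reaction = c(reg_e$draw_rxn[lo], reg_e$draw_rxn[hi]),
        coef = c(reg_e$kcat[lo], -reg_e$kcat[hi])
      )
    }
  }
  m$constraints <- bind_rows(m$constraints, list_rbind(cons))
  m$con_terms <- bind_rows(m$con_terms, list_rbind(terms))
  m
}

#' Restructure a conventional GEM into a subpool model
#'
#' Convenience pipeline: optional underground merge, GPR simplification,
#' direction split, GECKO-form enzyme layer, subpool split and ordering
#' constraints.
#'
#' @param m a [stoich_model()].
#' @param enz an [enzyme_table()].
#' @param und optional [underground_set()] merged before restructuring.
#' @param pool a [pool_config()].
#' @param ordering ordering-constraint mode (see [add_ordering_constraints()]).
#' @return a subpool-form `coral_model`.
#' @export
restructure <- function(m, enz, und = NULL, pool = pool_config(),
                        ordering = c("chain", "vs_main", "equality", "off")) {
  ordering <- match.arg(ordering)
  if (!is.null(und)) {
    m <- merge_underground(m, und)
    m$annotation$underground_reactions <-
      unique(c(m$annotation$underground_reactions, und$reaction))
  }
  if (is.null(m$annotation$underground_reactions)) {
    m$annotation$underground_reactions <-
      m$reactions$id[m$reactions$provenance == "underground"]
  }
  m |>
    split_complex_gprs(enz) |>
    split_reversible_catalyzed(enz) |>
    build_ec_layer(enz, pool) |>
    split_subpools() |>
    add_ordering_constraints(ordering)
}

#' @export
print.coral_model <- function(x, ...) {
  cat("<coral_model> form=", x$form, ", ordering=", x$ordering, "\n", sep = "")
  cat("  ", nrow(x$reactions), " reactions, ", nrow(x$metabolites),
      " metabolites, ", nrow(x$enzymes), " enzymes",
      if (!is.null(x$registry)) paste0(", ", nrow(x$registry), " subpools"),
      "\n", sep = "")
  cat("  protein pool Etot = ", x$pool$etot, " g/gDW; objective: ",
      x$objective, "\n", sep = "")
  invisible(x)
}

# reactions whose origin is an underground reaction (including derived
# duplicates/partials/direction splits)
underground_reaction_ids <- function(m) {
  und <- m$annotation$underground_reactions %||% character()
  ori <- if ("origin" %in% names(m$reactions)) m$reactions$origin else m$reactions$id
  m$reactions$id[(!is.na(ori) & ori %in% und) |
                   m$reactions$provenance == "underground"]
}
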