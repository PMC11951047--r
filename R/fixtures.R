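# Synthetic toy models with controlled promiscuity structure, and a dense
# brute-force LP oracle assembled through an independent code path (explicit
# velocity/ordering/budget rows over (v, E) variables instead of
# pseudometabolite wiring). Everything is deterministic under the spec seed.

#' Specification for a synthetic fixture
#'
#' @param n_steps length of the backbone pathway (substrate -> ... -> biomass
#'   precursor); must be >= 1 and >= `length(profile)`.
#' @param profile integer vector: number of catalysed reactions (subpools)
#'   per backbone enzyme; enzyme j catalyses backbone step j plus
#'   `profile[j] - 1` side reactions.
#' @param kcat_range log-uniform kcat range (1/h).
#' @param mw_range uniform enzyme MW range (g/mmol).
#' @param productive_fraction fraction of side reactions that duplicate the
#'   main conversion (and can therefore compensate for it); the rest are
#'   dead ends.
#' @param n_underground number of underground side reactions (each assigned
#'   to an existing promiscuous enzyme and shipped as a separate
#'   underground-reaction set).
#' @param and_steps,or_steps how many of the backbone steps beyond
#'   `length(profile)` get a two-enzyme complex (AND) or isozyme pair (OR)
#'   GPR; remaining extra steps are enzyme-free.
#' @param uptake substrate uptake bound (mmol/gDW/h).
#' @param seed RNG seed; fixed seed gives byte-identical fixtures.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_steps = 4, profile = c(1, 2, 3),
                         kcat_range = c(1e2, 1e4), mw_range = c(10, 50),
                         productive_fraction = 0.5, n_underground = 0,
                         and_steps = 0, or_steps = 0, uptake = 10, seed = 1) {
  stopifnot(n_steps >= 0, all(profile >= 1), kcat_range[1] > 0,
            mw_range[1] > 0, productive_fraction >= 0, productive_fraction <= 1,
            n_underground >= 0, and_steps >= 0, or_steps >= 0)
  if (length(profile) + and_steps + or_steps > n_steps) {
    abort("profile/and/or enzymes exceed the number of backbone steps")
  }
  structure(list(n_steps = n_steps, profile = as.integer(profile),
                 kcat_range = kcat_range, mw_range = mw_range,
                 productive_fraction = productive_fraction,
                 n_underground = as.integer(n_underground),
                 and_steps = as.integer(and_steps),
                 or_steps = as.integer(or_steps),
                 uptake = uptake, seed = as.integer(seed)),
            class = "fixture_spec")
}

with_fixture_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic toy model with known promiscuity structure
#'
#' Builds a linear backbone pathway feeding a biomass reaction, assigns one
#' enzyme per leading backbone step with the requested number of side
#' reactions (productive duplicates of the main conversion or dead ends,
#' with strictly lower kcats), optional complex/isozyme steps, and optional
#' underground side reactions attached to promiscuous enzymes.
#'
#' @param spec a [fixture_spec()].
#' @return list with `model` ([stoich_model()]), `enzymes`
#'   ([enzyme_table()]), `underground` ([underground_set()] or `NULL`) and
#'   the `spec`.
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_steps < 1) abort("fixture has no productive route to biomass")
  with_fixture_seed(spec$seed, {
    n <- spec$n_steps
    mets <- tibble(id = paste0("M", 0:n))
    rx <- list(tibble(id = "EX_substrate", lb = 0, ub = spec$uptake, gpr = ""))
    st <- list(tibble(reaction = "EX_substrate", metabolite = "M0", coef = 1))
    enz_rows <- list()
    rkcat <- function(k) {
      sort(exp(stats::runif(k, log(spec$kcat_range[1]), log(spec$kcat_range[2]))),
           decreasing = TRUE)
    }
    rmw <- function() stats::runif(1, spec$mw_range[1], spec$mw_range[2])
    add_rxn <- function(id, from, to, gpr = "", ub = 1000) {
      rx[[length(rx) + 1L]] <<- tibble(id = id, lb = 0, ub = ub, gpr = gpr)
      st[[length(st) + 1L]] <<- tibble(
        reaction = id, metabolite = c(from, to), coef = c(-1, 1))
    }
    n_base <- length(spec$profile)
    for (j in seq_len(n_base)) {
      e <- paste0("E", j); g <- paste0("g", j)
      K <- spec$profile[j]
      kcats <- rkcat(K)
      mw <- rmw()
      main_id <- paste0("STEP", j)
      add_rxn(main_id, paste0("M", j - 1), paste0("M", j), gpr = g)
      enz_rows[[length(enz_rows) + 1L]] <- tibble(
        enzyme = e, genes = g, mw = mw, reaction = main_id,
        direction = "fwd", kcat = kcats[1])
      if (K > 1) {
        productive <- stats::runif(K - 1) < spec$productive_fraction
        for (s in seq_len(K - 1)) {
          sid <- paste0("SIDE_", e, "_", s)
          if (productive[s]) {
            add_rxn(sid, paste0("M", j - 1), paste0("M", j), gpr = g)
          } else {
            dmet <- paste0("DEAD_", e, "_", s)
            mets <- bind_rows(mets, tibble(id = dmet))
            add_rxn(sid, paste0("M", j - 1), dmet, gpr = g)
          }
          enz_rows[[length(enz_rows) + 1L]] <- tibble(
            enzyme = e, genes = g, mw = mw, reaction = sid,
            direction = "fwd", kcat = kcats[s + 1])
        }
      }
    }
    extra <- setdiff(seq_len(n), seq_len(n_base))
    kinds <- c(rep("and", spec$and_steps), rep("or", spec$or_steps))
    kinds <- c(kinds, rep("free", length(extra) - length(kinds)))
    for (i in seq_along(extra)) {
      j <- extra[i]
      id <- paste0("STEP", j)
      if (kinds[i] == "free") {
        add_rxn(id, paste0("M", j - 1), paste0("M", j))
      } else if (kinds[i] == "and") {
        ga <- paste0("g", j, "a"); gb <- paste0("g", j, "b")
        add_rxn(id, paste0("M", j - 1), paste0("M", j),
                gpr = paste(ga, "and", gb))
        for (gg in c(ga, gb)) {
          enz_rows[[length(enz_rows) + 1L]] <- tibble(
            enzyme = paste0("E", gg), genes = gg, mw = rmw(), reaction = id,
            direction = "fwd", kcat = rkcat(1))
        }
      } else {
        ga <- paste0("g", j, "a"); gb <- paste0("g", j, "b")
        add_rxn(id, paste0("M", j - 1), paste0("M", j),
                gpr = paste(ga, "or", gb))
        for (gg in c(ga, gb)) {
          enz_rows[[length(enz_rows) + 1L]] <- tibble(
            enzyme = paste0("E", gg), genes = gg, mw = rmw(), reaction = id,
            direction = "fwd", kcat = rkcat(1))
        }
      }
    }
    rx[[length(rx) + 1L]] <- tibble(id = "BIOMASS", lb = 0, ub = 1000, gpr = "")
    st[[length(st) + 1L]] <- tibble(reaction = "BIOMASS",
                                    metabolite = paste0("M", n), coef = -1)
    enz <- enzyme_table(list_rbind(enz_rows))
    und <- NULL
    if (spec$n_underground > 0) {
      counts <- table(enz$enzyme)
      prom <- names(counts[counts >= 2])
      if (!length(prom)) prom <- names(counts)
      und_rows <- list()
      for (u in seq_len(spec$n_underground)) {
        e <- prom[(u - 1L) %% length(prom) + 1L]
        main_rxn <- enz$reaction[enz$enzyme == e][1]
        # bypass: substrate of the enzyme's main step straight to the end
        from <- st[[which(map_chr(rx, "id") == main_rxn)[1]]]
        from_met <- from$metabolite[from$coef < 0][1]
        uid <- paste0("UND", u)
        und_rows[[length(und_rows) + 1L]] <- tibble(
          reaction = uid,
          stoich = list(setNames(c(-1, 1), c(from_met, paste0("M", n)))),
          lb = 0, ub = 1000, gpr = enz$genes[enz$enzyme == e][1])
        # underground activity joins the enzyme's subpool set with a low kcat
        enz <- enzyme_table(bind_rows(
          enz,
          tibble(enzyme = e, genes = enz$genes[enz$enzyme == e][1],
                 mw = enz$mw[enz$enzyme == e][1], reaction = uid,
                 direction = "fwd",
                 kcat = min(enz$kcat[enz$enzyme == e]) * 0.5)
        ))
      }
      und <- underground_set(list_rbind(und_rows))
    }
    model <- stoich_model(mets, list_rbind(rx), list_rbind(st),
                          objective = "BIOMASS")
    list(model = model, enzymes = enz, underground = und, spec = spec)
  })
}

# ---- canonical hand-built fixtures --------------------------------------

toy2 <- function(rx, st, mets, objective = "BIOMASS") {
  stoich_model(tibble(id = mets), rx, st, objective = objective)
}

linear_rx <- function(id, from, to, lb = 0, ub = 1000, gpr = "") {
  list(rx = tibble(id = id, lb = lb, ub = ub, gpr = gpr),
       st = tibble(reaction = id,
                   metabolite = c(from, to)[!is.na(c(from, to))],
                   coef = c(if (!is.na(from)) -1, if (!is.na(to)) 1)))
}

build_toy <- function(parts, mets, objective = "BIOMASS") {
  toy2(list_rbind(map(parts, "rx")), list_rbind(map(parts, "st")), mets,
       objective)
}

enz_row <- function(enzyme, gene, mw, reaction, kcat, direction = "fwd") {
  tibble(enzyme = enzyme, genes = gene, mw = mw, reaction = reaction,
         direction = direction, kcat = kcat)
}

#' Canonical test fixtures
#'
#' Small hand-built models, each isolating one structural feature the
#' analyses rely on: a direct-transfer promiscuous enzyme (the side reaction
#' duplicates the main conversion), a deep-rank rescuer (rank 2 is a dead
#' end, rank 3 compensates), a non-promiscuous essential pair, a redundant
#' isozyme-backed pair, an AND complex, an OR isozyme pair, and a
#' tied-kcat enzyme. Each element carries `model`, `enzymes`,
#' `underground` (possibly `NULL`) and `pool`.
#'
#' @param name one fixture name, or `NULL` for the full named list.
#' @return a fixture (list) or named list of fixtures.
#' @export
fixture_suite <- function(name = NULL) {
  suite <- list(
    direct_transfer = {
      parts <- list(
        linear_rx("EX_substrate", NA, "A", ub = 10),
        linear_rx("R_MAIN", "A", "B", gpr = "gE"),
        linear_rx("R_SIDE", "A", "B", gpr = "gE"),
        linear_rx("R_EXTRA", "B", "C", gpr = "gC"),
        linear_rx("EX_C", "C", NA),
        linear_rx("BIOMASS", "B", NA)
      )
      list(
        model = build_toy(parts, c("A", "B", "C")),
        enzymes = enzyme_table(bind_rows(
          enz_row("E", "gE", 10, "R_MAIN", 3600),
          enz_row("E", "gE", 10, "R_SIDE", 3500),
          enz_row("EC", "gC", 10, "R_EXTRA", 3600)
        )),
        underground = NULL,
        pool = pool_config(ptot = 0.61, sigma = 0.5, f = 0.5)
      )
    },
    deep_rescuer = {
      parts <- list(
        linear_rx("EX_substrate", NA, "A", ub = 10),
        linear_rx("R_MAIN", "A", "B", gpr = "gE"),
        linear_rx("R_DEAD", "A", "D", gpr = "gE"),
        linear_rx("R_RESCUE", "A", "B", gpr = "gE"),
        linear_rx("BIOMASS", "B", NA)
      )
      list(
        model = build_toy(parts, c("A", "B", "D")),
        enzymes = enzyme_table(bind_rows(
          enz_row("E", "gE", 10, "R_MAIN", 3600),
          enz_row("E", "gE", 10, "R_DEAD", 1800),
          enz_row("E", "gE", 10, "R_RESCUE", 900)
        )),
        underground = NULL,
        pool = pool_config()
      )
    },
    essential_pair = {
      parts <- list(
        linear_rx("EX_substrate", NA, "A", ub = 10),
        linear_rx("R1", "A", "B", gpr = "gP"),
        linear_rx("R2", "B", "C", gpr = "gQ"),
        linear_rx("BIOMASS", "C", NA)
      )
      list(
        model = build_toy(parts, c("A", "B", "C")),
        enzymes = enzyme_table(bind_rows(
          enz_row("P", "gP", 10, "R1", 3600),
          enz_row("Q", "gQ", 10, "R2", 3600)
        )),
        underground = NULL,
        pool = pool_config()
      )
    },
    redundant_pair = {
      parts <- list(
        linear_rx("EX_substrate", NA, "A", ub = 10),
        linear_rx("R1A", "A", "B", gpr = "g1a"),
        linear_rx("R1B", "A", "B", gpr = "g1b"),
        linear_rx("R2A", "B", "C", gpr = "g2a"),
        linear_rx("R2B", "B", "C", gpr = "g2b"),
        linear_rx("BIOMASS", "C", NA)
      )
      list(
        model = build_toy(parts, c("A", "B", "C")),
        enzymes = enzyme_table(bind_rows(
          enz_row("X1A", "g1a", 10, "R1A", 3600),
          enz_row("X1B", "g1b", 10, "R1B", 3600),
          enz_row("X2A", "g2a", 10, "R2A", 3600),
          enz_row("X2B", "g2b", 10, "R2B", 3600)
        )),
        underground = NULL,
        pool = pool_config()
      )
    },
    and_complex = {
      parts <- list(
        linear_rx("EX_substrate", NA, "A", ub = 10),
        linear_rx("R1", "A", "B", gpr = "ga and gb"),
        linear_rx("BIOMASS", "B", NA)
      )
      list(
        model = build_toy(parts, c("A", "B")),
        enzymes = enzyme_table(bind_rows(
          enz_row("Ea", "ga", 10, "R1", 3600),
          enz_row("Eb", "gb", 20, "R1", 1800)
        )),
        underground = NULL,
        pool = pool_config()
      )
    },
    or_isozymes = {
      parts <- list(
        linear_rx("EX_substrate", NA, "A", ub = 10),
        linear_rx("R1", "A", "B", gpr = "g1 or g2"),
        linear_rx("BIOMASS", "B", NA)
      )
      list(
        model = build_toy(parts, c("A", "B")),
        enzymes = enzyme_table(bind_rows(
          enz_row("I1", "g1", 10, "R1", 3600),
          enz_row("I2", "g2", 30, "R1", 7200)
        )),
        underground = NULL,
        pool = pool_config()
      )
    },
    tied_kcat = {
      parts <- list(
        linear_rx("EX_substrate", NA, "A", ub = 10),
        linear_rx("R1", "A", "B", gpr = "gT"),
        linear_rx("R2", "A", "B", gpr = "gT"),
        linear_rx("R3", "A", "B", gpr = "gT"),
        linear_rx("BIOMASS", "B", NA)
      )
      list(
        model = build_toy(parts, c("A", "B")),
        enzymes = enzyme_table(bind_rows(
          enz_row("T", "gT", 10, "R1", 90 * 40),
          enz_row("T", "gT", 10, "R2", 30 * 40),
          enz_row("T", "gT", 10, "R3", 30 * 40)
        )),
        underground = NULL,
        pool = pool_config()
      )
    }
  )
  if (is.null(name)) suite else {
    if (!name %in% names(suite)) {
      abort(paste("unknown fixture:", name))
    }
    suite[[name]]
  }
}

# ---- independent dense-LP oracle ----------------------------------------

#' Brute-force oracle solve on a subpool model
#'
#' Assembles the optimization problem through an independent code path:
#' dense stoichiometric rows over network reactions only, explicit molar
#' subpool-usage variables tied to fluxes by velocity rows
#' (`v_j = kcat * E_{s,i}`, or `<=` on request), explicit ordering rows from
#' the registry, and an explicit mass budget `sum(MW * E) <= Etot` — no
#' pool/subpool pseudometabolites or pseudoreactions are used. Ground truth
#' for the main solve path on small fixtures.
#'
#' @param m subpool-form `coral_model` (network part must have <= 200
#'   reaction columns).
#' @param objective `"growth"` (max biomass), `"total_usage"` (min molar
#'   pool usage), `list(flux = id)` or `list(subpool = id)` for FVA-style
#'   targets.
#' @param sense `"max"` or `"min"` (ignored for the two scalar objectives,
#'   which fix their natural direction unless overridden).
#' @param fixed_mu,underground scenario controls, as in the main path.
#' @param blocked subpool ids forced to zero (ordering rows in which a
#'   blocked subpool dominates are dropped, mirroring the documented
#'   blocking semantics).
#' @param wt_band optional tibble (`subpool`, `lo`, `hi`) of molar usage
#'   bounds (wild-type flexibility band).
#' @param velocity_sense `"eq"` (usage equals flux/kcat, the wiring
#'   semantics) or `"le"` (usage may exceed flux/kcat).
#' @return list: `status`, `objective`, `flux` (named), `usage` (named by
#'   subpool, mmol/gDW).
#' @export
oracle_solve <- function(m, objective = "growth", sense = NULL,
                         fixed_mu = NULL, underground = TRUE,
                         blocked = character(), wt_band = NULL,
                         velocity_sense = c("eq", "le")) {
  velocity_sense <- match.arg(velocity_sense)
  if (is.null(m$registry)) abort("oracle_solve needs a subpool-form coral_model")
  reg <- m$registry
  net_rx <- m$reactions |> filter(.data$provenance != "pseudo")
  if (nrow(net_rx) > 200) abort("oracle size guard: > 200 network reactions")
  v_vars <- net_rx$id
  e_vars <- paste0("E_", reg$subpool)
  vars <- c(v_vars, e_vars)

  bnd <- model_bounds(m, underground = underground, fixed_mu = fixed_mu)
  bnd <- bnd[match(v_vars, bnd$reaction), ]
  lb <- c(bnd$lb, rep(0, nrow(reg)))
  ub <- c(bnd$ub, rep(Inf, nrow(reg)))
  names(lb) <- names(ub) <- vars
  if (length(blocked)) {
    bad <- setdiff(blocked, reg$subpool)
    if (length(bad)) abort(paste("unknown subpool(s):", paste(bad, collapse = ", ")))
    ub[paste0("E_", blocked)] <- 0
  }
  if (!is.null(wt_band) && nrow(wt_band) > 0) {
    lb[paste0("E_", wt_band$subpool)] <- wt_band$lo
    ub[paste0("E_", wt_band$subpool)] <- wt_band$hi
  }

  net_mets <- m$metabolites |> filter(!.data$provenance %in% "pseudo")
  S <- stoich_matrix(m, metabolites = net_mets$id, reactions = v_vars)
  eq <- lapply(seq_len(nrow(S)), function(i) {
    nz <- which(S[i, ] != 0)
    list(terms = setNames(S[i, nz], v_vars[nz]), rhs = 0)
  })
  eq <- eq[vapply(eq, function(r) length(r$terms) > 0, logical(1))]
  le <- list()

  # velocity rows: v_j - kcat * E = 0 (or <= 0)
  for (i in seq_len(nrow(reg))) {
    row <- list(terms = setNames(c(1, -reg$kcat[i]),
                                 c(reg$reaction[i], e_vars[i])), rhs = 0)
    if (velocity_sense == "eq") eq[[length(eq) + 1L]] <- row else
      le[[length(le) + 1L]] <- row
  }

  # ordering rows from the registry (independent of m$con_terms); a blocked
  # enzyme's whole hierarchy is released, mirroring the main path
  blocked_enzymes <- unique(reg$enzyme[reg$subpool %in% blocked])
  if (m$ordering != "off") {
    for (e in setdiff(unique(reg$enzyme), blocked_enzymes)) {
      rr <- reg |> filter(.data$enzyme == e) |> arrange(.data$rank)
      if (nrow(rr) < 2) next
      prs <- if (m$ordering == "vs_main") cbind(1L, 2:nrow(rr)) else
        cbind(seq_len(nrow(rr) - 1L), 2:nrow(rr))
      for (p in seq_len(nrow(prs))) {
        hi <- prs[p, 1]; lo <- prs[p, 2]
        row <- list(terms = setNames(
          c(rr$kcat[lo], -rr$kcat[hi]),
          paste0("E_", c(rr$subpool[lo], rr$subpool[hi]))), rhs = 0)
        if (m$ordering == "equality") eq[[length(eq) + 1L]] <- row else
          le[[length(le) + 1L]] <- row
      }
    }
  }

  # mass budget
  le[[length(le) + 1L]] <- list(
    terms = setNames(reg$mw, e_vars), rhs = m$pool$etot)

  if (identical(objective, "growth")) {
    obj <- setNames(1, m$objective); maximize <- TRUE
  } else if (identical(objective, "total_usage")) {
    obj <- setNames(rep(1, length(e_vars)), e_vars); maximize <- FALSE
  } else if (is.list(objective) && !is.null(objective$flux)) {
    obj <- setNames(1, objective$flux); maximize <- identical(sense, "max")
  } else if (is.list(objective) && !is.null(objective$subpool)) {
    obj <- setNames(1, paste0("E_", objective$subpool))
    maximize <- identical(sense, "max")
  } else {
    abort("unknown oracle objective")
  }
  if (!is.null(sense)) maximize <- identical(sense, "max")

  res <- solve_lp(lp_problem(vars, obj, lb, ub, eq = eq, le = le,
                             maximize = maximize))
  list(
    status = res$status,
    objective = res$objective,
    flux = if (!is.null(res$x)) res$x[v_vars] else NULL,
    usage = if (!is.null(res$x)) setNames(res$x[e_vars], reg$subpool) else NULL
  )
}
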