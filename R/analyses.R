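# Optimization analyses on (subpool) models: FBA, flux and subpool-usage
# variability analysis, and the parsimonious wild-type subpool allocation.

new_solution <- function(m, res, kind = "fba") {
  fluxes <- if (!is.null(res$x)) {
    tibble(reaction = names(res$x), flux = unname(res$x))
  } else {
    tibble(reaction = character(), flux = double())
  }
  growth <- if (!is.null(res$x)) unname(res$x[m$objective]) else NA_real_
  usage <- pools <- NULL
  if (!is.null(m$registry) && !is.null(res$x)) {
    usage <- m$registry |>
      mutate(mass = unname(res$x[.data$draw_rxn]),
             usage = .data$mass / .data$mw) |>
      select("enzyme", "subpool", "rank", "reaction", "kcat", "mw",
             "mass", "usage")
  }
  if (!is.null(m$enzymes) && !is.null(res$x)) {
    pools <- m$enzymes |>
      mutate(mass = unname(res$x[.data$supply_rxn]),
             usage = .data$mass / .data$mw) |>
      select("enzyme", "mw", "mass", "usage")
  }
  structure(list(
    status = res$status, objective = res$objective, growth = growth,
    fluxes = fluxes, usage = usage, pools = pools, kind = kind,
    model_objective = m$objective
  ), class = "coral_solution")
}

#' @export
print.coral_solution <- function(x, ...) {
  cat("<coral_solution> [", x$kind, "] status=", x$status,
      ", objective=", format(x$objective, digits = 8),
      ", growth=", format(x$growth, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the objective (biomass by default) subject to steady state,
#' bounds, protein-pool wiring and any ordering constraints of the model.
#'
#' @param m a `stoich_model` or `coral_model`.
#' @param objective reaction id to optimize (default: the model objective).
#' @param underground include underground-derived reactions (`FALSE` blocks
#'   them, both bounds zero).
#' @param fixed_mu optionally fix the biomass flux (chemostat condition).
#' @param maximize direction.
#' @return a `coral_solution`.
#' @export
fba <- function(m, objective = NULL, underground = TRUE, fixed_mu = NULL,
                maximize = TRUE) {
  objective <- objective %||% m$objective
  bounds <- model_bounds(m, underground = underground, fixed_mu = fixed_mu)
  p <- model_lp(m, obj = setNames(1, objective), bounds = bounds,
                maximize = maximize)
  new_solution(m, solve_lp(p), kind = "fba")
}

fva_scenario_meta <- function(underground, fixed_mu) {
  tibble(underground = underground,
         fixed_mu = if (is.null(fixed_mu)) NA_real_ else fixed_mu)
}

fva_run <- function(m, targets, bounds, obj_fun) {
  probs <- list()
  for (t in targets) {
    for (dir in c(FALSE, TRUE)) {
      probs[[length(probs) + 1L]] <-
        model_lp(m, obj = obj_fun(t), bounds = bounds, maximize = dir)
    }
  }
  res <- solve_lp(probs)
  tibble(
    target = targets,
    min = map_dbl(seq_along(targets), ~ res[[2 * .x - 1]]$objective),
    max = map_dbl(seq_along(targets), ~ res[[2 * .x]]$objective),
    status = map_chr(seq_along(targets), function(k) {
      st <- c(res[[2 * k - 1]]$status, res[[2 * k]]$status)
      if (all(st == "optimal")) "optimal" else st[st != "optimal"][1]
    })
  )
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux under the model constraints,
#' optionally with growth fixed (chemostat) and/or underground reactions
#' blocked. Ranges are computed by independent per-target solves.
#'
#' @inheritParams fba
#' @param reactions target reaction ids; default all network (non-pseudo)
#'   reactions.
#' @return tibble of class `coral_fva` (`target`, `min`, `max`, `status`,
#'   scenario columns).
#' @export
fva_flux <- function(m, reactions = NULL, fixed_mu = NULL, underground = TRUE) {
  targets <- reactions %||%
    m$reactions$id[m$reactions$provenance != "pseudo"]
  bad <- setdiff(targets, m$reactions$id)
  if (length(bad)) abort(paste("unknown FVA targets:", paste(bad, collapse = ", ")))
  bounds <- model_bounds(m, underground = underground, fixed_mu = fixed_mu)
  out <- fva_run(m, targets, bounds, function(t) setNames(1, t))
  out <- bind_cols(out, fva_scenario_meta(underground, fixed_mu)[rep(1, nrow(out)), ])
  class(out) <- c("coral_fva", class(out))
  attr(out, "kind") <- "flux"
  out
}

#' Subpool-usage variability analysis
#'
#' As [fva_flux()], but targets are the subpool draw pseudoreactions and
#' ranges are reported as molar enzyme usage (mmol/gDW).
#'
#' @inheritParams fva_flux
#' @param subpools subpool ids (registry `subpool` column); default all.
#' @return tibble of class `coral_fva` with columns as [fva_flux()].
#' @export
fva_subpools <- function(m, subpools = NULL, fixed_mu = NULL, underground = TRUE) {
  if (is.null(m$registry)) abort("subpool FVA needs a subpool-form coral_model")
  reg <- m$registry
  if (!is.null(subpools)) {
    bad <- setdiff(subpools, reg$subpool)
    if (length(bad)) abort(paste("unknown subpools:", paste(bad, collapse = ", ")))
    reg <- reg[reg$subpool %in% subpools, ]
  }
  bounds <- model_bounds(m, underground = underground, fixed_mu = fixed_mu)
  out <- fva_run(m, reg$draw_rxn, bounds, function(t) setNames(1, t))
  out$target <- reg$subpool
  out$min <- out$min / reg$mw
  out$max <- out$max / reg$mw
  out <- bind_cols(out, fva_scenario_meta(underground, fixed_mu)[rep(1, nrow(out)), ])
  class(out) <- c("coral_fva", class(out))
  attr(out, "kind") <- "subpool"
  out
}

#' Parsimonious wild-type subpool allocation
#'
#' At a fixed growth rate, minimizes the total molar enzyme pool usage
#' (equivalently the total subpool draw) to obtain the reference wild-type
#' allocation used by the defect simulations.
#'
#' @inheritParams fba
#' @param fixed_mu growth rate to fix (1/h); must be feasible.
#' @return a `coral_solution` (kind `"pfba"`).
#' @export
pfba_subpools <- function(m, fixed_mu, underground = TRUE) {
  if (is.null(m$enzymes)) abort("pfba_subpools needs a coral_model")
  bounds <- model_bounds(m, underground = underground, fixed_mu = fixed_mu)
  obj <- setNames(1 / m$enzymes$mw, m$enzymes$supply_rxn)
  p <- model_lp(m, obj = obj, bounds = bounds, maximize = FALSE)
  res <- solve_lp(p)
  if (res$status != "optimal") {
    abort(paste0("wild-type problem is ", res$status, " at mu = ", fixed_mu))
  }
  new_solution(m, res, kind = "pfba")
}
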