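# Simulation of metabolic defects: blocking main (rank-1) or side (rank-k)
# subpools against a parsimonious wild-type reference, pairwise blocks, and
# conventional double gene knockouts for comparison.
#
# Blocking semantics: a blocked subpool's draw gets bounds [0, 0]. All other
# subpools are held to the wild-type allocation within a flexibility band
# (default 5%); every subpool of a blocked enzyme is freed from the band so
# the pool can redistribute, and the blocked enzyme's ordering rows are
# dropped — with usage tied to flux, a zeroed main subpool would otherwise
# force every side subpool to zero through the ordering chain, suppressing
# exactly the compensation the analysis is meant to observe.

#' Wild-type reference allocation
#'
#' Runs the parsimonious subpool allocation ([pfba_subpools()]) at a fixed
#' growth rate and packages the per-subpool usages used to constrain defect
#' simulations.
#'
#' @param m subpool-form `coral_model`.
#' @param fixed_mu wild-type growth rate (1/h). A chemostat-like rate below
#'   the batch maximum leaves protein-budget slack for subpool
#'   redistribution; at the protein-limited optimum most blocks are lethal
#'   because the flexibility band pins all fluxes near wild type while side
#'   reactions need more enzyme mass per unit flux.
#' @param band flexibility band fraction (default 0.05).
#' @param zero usages below this (mmol/gDW) count as unused; their band is
#'   `[0, zero]` rather than a proportional one (otherwise subpools unused in
#'   the wild type could never become active).
#' @param underground scenario toggle.
#' @return object of class `wt_reference`: `usage` tibble, `mu`, `band`,
#'   `zero`, and the underlying `solution`.
#' @export
wt_reference <- function(m, fixed_mu, band = 0.05, zero = CORAL_ZERO,
                         underground = TRUE) {
  stopifnot(band >= 0, band < 1)
  sol <- pfba_subpools(m, fixed_mu = fixed_mu, underground = underground)
  structure(list(
    usage = sol$usage |> select("enzyme", "subpool", "rank", "mass", "usage"),
    mu = fixed_mu, band = band, zero = zero, underground = underground,
    solution = sol
  ), class = "wt_reference")
}

#' @export
print.wt_reference <- function(x, ...) {
  used <- sum(x$usage$usage > x$zero)
  cat("<wt_reference> mu=", x$mu, " 1/h, band=", x$band * 100, "%, ",
      used, "/", nrow(x$usage), " subpools in use\n", sep = "")
  invisible(x)
}

# draw-reaction bounds (mass units) implementing the wild-type band with the
# blocked enzyme(s) freed; band_level = "pool" bands the per-enzyme supply
# instead and leaves draws free
defect_bounds <- function(m, wt, blocked_subpools,
                          band_level = c("subpool", "pool"),
                          underground = TRUE) {
  band_level <- match.arg(band_level)
  reg <- m$registry
  bounds <- model_bounds(m, underground = underground)
  freed_enzymes <- unique(reg$enzyme[reg$subpool %in% blocked_subpools])
  if (!is.null(wt)) {
    wt_mass <- setNames(wt$usage$mass, wt$usage$subpool)
    if (band_level == "subpool") {
      for (i in seq_len(nrow(reg))) {
        sp <- reg$subpool[i]
        if (reg$enzyme[i] %in% freed_enzymes) next
        mref <- wt_mass[[sp]]
        if (mref / reg$mw[i] > wt$zero) {
          bounds <- set_bounds(bounds, reg$draw_rxn[i],
                               lb = (1 - wt$band) * mref,
                               ub = (1 + wt$band) * mref)
        } else {
          bounds <- set_bounds(bounds, reg$draw_rxn[i],
                               lb = 0, ub = wt$zero * reg$mw[i])
        }
      }
    } else {
      pool_mass <- wt$usage |>
        group_by(.data$enzyme) |>
        summarise(mass = sum(.data$mass), .groups = "drop")
      for (i in seq_len(nrow(pool_mass))) {
        e <- pool_mass$enzyme[i]
        if (e %in% freed_enzymes) next
        supply <- m$enzymes$supply_rxn[m$enzymes$enzyme == e]
        mref <- pool_mass$mass[i]
        if (mref / m$enzymes$mw[m$enzymes$enzyme == e] > wt$zero) {
          bounds <- set_bounds(bounds, supply, lb = (1 - wt$band) * mref,
                               ub = (1 + wt$band) * mref)
        } else {
          bounds <- set_bounds(bounds, supply, lb = 0,
                               ub = wt$zero * m$enzymes$mw[m$enzymes$enzyme == e])
        }
      }
    }
  }
  for (sp in blocked_subpools) {
    bounds <- set_bounds(bounds, reg$draw_rxn[reg$subpool == sp], lb = 0, ub = 0)
  }
  bounds
}

defect_problem <- function(m, wt, blocked_subpools, band_level = "subpool",
                           underground = TRUE) {
  reg <- m$registry
  bounds <- defect_bounds(m, wt, blocked_subpools, band_level, underground)
  blocked_enzymes <- unique(reg$enzyme[reg$subpool %in% blocked_subpools])
  model_lp(m, obj = setNames(1, m$objective), bounds = bounds, maximize = TRUE,
           freed_draws = reg$draw_rxn[reg$enzyme %in% blocked_enzymes])
}

defect_report_row <- function(m, blocked, res, mu_wt) {
  mu_del <- if (res$status == "optimal") res$objective else 0
  lethal <- res$status != "optimal" || mu_del <= 1e-6
  tibble(
    blocked = paste(blocked, collapse = "+"),
    status = res$status,
    mu_del = mu_del,
    mu_wt = mu_wt,
    ratio = if (mu_wt > 0) mu_del / mu_wt else NA_real_,
    ratio_wt_del = if (!lethal) mu_wt / mu_del else Inf,
    lethal = lethal
  )
}

# per-subpool redistribution of the blocked enzyme's pool
redistribution_table <- function(m, wt, enzyme, res) {
  reg <- m$registry |> filter(.data$enzyme == !!enzyme) |> arrange(.data$rank)
  usage_del <- if (!is.null(res$x)) unname(res$x[reg$draw_rxn]) / reg$mw else
    rep(NA_real_, nrow(reg))
  pool_del <- sum(usage_del)
  wtu <- wt$usage |> filter(.data$enzyme == !!enzyme)
  tibble(
    enzyme = enzyme, subpool = reg$subpool, rank = reg$rank,
    usage_wt = wtu$usage[match(reg$subpool, wtu$subpool)],
    usage_del = usage_del,
    share_del = if (!is.na(pool_del) && pool_del > 0) usage_del / pool_del else
      rep(NA_real_, nrow(reg))
  )
}

classify_redistribution <- function(redist, band = 0.05, zero = CORAL_ZERO) {
  main_wt <- redist$usage_wt[redist$rank == 1]
  sides <- redist |> filter(.data$rank > 1)
  if (nrow(sides) == 0) return(NA_character_)
  e2 <- sides$usage_del[sides$rank == 2]
  if (length(e2) == 0) e2 <- 0
  if (length(main_wt) && main_wt > zero &&
      abs(e2 - main_wt) <= band * main_wt) {
    return("a")
  }
  if (e2 <= zero) return("d")
  top <- sides$rank[which.max(sides$usage_del)]
  if (top == 2) "b" else "c"
}

#' Block the main subpool of one enzyme
#'
#' Solves the growth-maximization problem with the enzyme's rank-1 (main)
#' subpool forced to zero, all other enzymes held to the wild-type
#' allocation within the flexibility band, and every subpool of the blocked
#' enzyme freed so its pool can redistribute.
#'
#' @param m subpool-form `coral_model`.
#' @param wt a [wt_reference()] computed on the same model.
#' @param enzyme enzyme id to block.
#' @param band_level `"subpool"` (default) bands each subpool draw;
#'   `"pool"` bands per-enzyme totals instead.
#' @param underground scenario toggle.
#' @return one-row tibble of class `defect_report` with the redistribution
#'   table of the blocked enzyme in `attr(, "redistribution")`.
#' @export
block_main_single <- function(m, wt, enzyme, band_level = "subpool",
                              underground = TRUE) {
  reg <- m$registry
  if (!enzyme %in% reg$enzyme) abort(paste("unknown enzyme:", enzyme))
  blocked <- reg$subpool[reg$enzyme == enzyme & reg$rank == 1L]
  p <- defect_problem(m, wt, blocked, band_level, underground)
  res <- solve_lp(p)
  rep <- defect_report_row(m, blocked, res, wt$mu)
  rep$enzyme <- enzyme
  redist <- redistribution_table(m, wt, enzyme, res)
  rep$class <- classify_redistribution(redist, wt$band, wt$zero)
  attr(rep, "redistribution") <- redist
  class(rep) <- c("defect_report", class(rep))
  rep
}

#' Screen single main-reaction blocks over all enzymes
#'
#' Runs [block_main_single()] for every enzyme (one batched solve), flags
#' enzymes whose main subpool was used in the wild type and whose block is
#' non-lethal, and classifies the redistribution of each flagged enzyme:
#' (a) near-direct transfer to rank 2 (within the band), (b) majority to
#' rank 2 with the remainder spread, (c) majority to a rank above 2,
#' (d) nothing to rank 2.
#'
#' @inheritParams block_main_single
#' @return tibble of class `defect_screen`, one row per enzyme, with
#'   redistribution tables in `attr(, "redistribution")` (named list).
#' @export
screen_single_blocks <- function(m, wt, band_level = "subpool",
                                 underground = TRUE) {
  enzymes <- m$enzymes$enzyme
  reg <- m$registry
  probs <- lapply(enzymes, function(e) {
    defect_problem(m, wt, reg$subpool[reg$enzyme == e & reg$rank == 1L],
                   band_level, underground)
  })
  res <- solve_lp(probs)
  rows <- list()
  redists <- list()
  for (k in seq_along(enzymes)) {
    e <- enzymes[k]
    rep <- defect_report_row(m, reg$subpool[reg$enzyme == e & reg$rank == 1L],
                             res[[k]], wt$mu)
    rep$enzyme <- e
    redist <- redistribution_table(m, wt, e, res[[k]])
    rep$wt_main_usage <- redist$usage_wt[redist$rank == 1]
    rep$flagged <- rep$wt_main_usage > wt$zero & !rep$lethal
    rep$class <- if (rep$flagged) classify_redistribution(redist, wt$band, wt$zero)
      else NA_character_
    rows[[k]] <- rep
    redists[[e]] <- redist
  }
  out <- list_rbind(rows) |>
    select("enzyme", "blocked", "status", "mu_del", "mu_wt", "ratio",
           "ratio_wt_del", "lethal", "wt_main_usage", "flagged", "class")
  attr(out, "redistribution") <- redists
  class(out) <- c("defect_screen", class(out))
  out
}

block_pairs_impl <- function(m, rank, mu_wt, underground, pairs) {
  reg <- m$registry
  have <- reg |> filter(.data$rank == !!rank)
  skipped <- setdiff(m$enzymes$enzyme, have$enzyme)
  if (length(skipped)) {
    inform(paste0(length(skipped), " enzyme(s) lack a rank-", rank,
                  " subpool and are skipped"))
  }
  enz <- sort(have$enzyme)
  if (is.null(pairs)) {
    if (length(enz) < 2) {
      return(tibble(enzyme_a = character(), enzyme_b = character()))
    }
    cmb <- utils::combn(enz, 2)
    pairs <- tibble(enzyme_a = cmb[1, ], enzyme_b = cmb[2, ])
  } else {
    pairs <- as_tibble(pairs)
    names(pairs)[1:2] <- c("enzyme_a", "enzyme_b")
    bad <- setdiff(c(pairs$enzyme_a, pairs$enzyme_b), enz)
    if (length(bad)) {
      abort(paste("enzymes lacking the requested rank:", paste(bad, collapse = ", ")))
    }
  }
  if (is.null(mu_wt)) {
    ref <- fba(m, underground = underground)
    if (ref$status != "optimal") abort("unblocked model infeasible")
    mu_wt <- ref$objective
  }
  sub_of <- setNames(have$subpool, have$enzyme)
  probs <- pmap(pairs, function(enzyme_a, enzyme_b, ...) {
    defect_problem(m, wt = NULL,
                   blocked_subpools = c(sub_of[[enzyme_a]], sub_of[[enzyme_b]]),
                   underground = underground)
  })
  res <- solve_lp(probs)
  promiscuous <- m$registry |>
    group_by(.data$enzyme) |>
    summarise(K = max(.data$rank), .groups = "drop")
  is_prom <- setNames(promiscuous$K >= 2, promiscuous$enzyme)
  out <- list_rbind(map(seq_len(nrow(pairs)), function(k) {
    r <- defect_report_row(m, c(sub_of[[pairs$enzyme_a[k]]],
                                sub_of[[pairs$enzyme_b[k]]]),
                           res[[k]], mu_wt)
    r$enzyme_a <- pairs$enzyme_a[k]
    r$enzyme_b <- pairs$enzyme_b[k]
    r
  }))
  out |>
    mutate(
      rank = rank,
      affected = .data$mu_del < 0.99 * .data$mu_wt,
      promiscuity = dplyr::case_when(
        is_prom[.data$enzyme_a] & is_prom[.data$enzyme_b] ~ "both",
        is_prom[.data$enzyme_a] | is_prom[.data$enzyme_b] ~ "one",
        TRUE ~ "neither"
      )
    ) |>
    select("enzyme_a", "enzyme_b", "rank", "status", "mu_del", "mu_wt",
           "ratio", "ratio_wt_del", "lethal", "affected", "promiscuity") |>
    (\(d) { class(d) <- c("pair_screen", class(d)); d })()
}

#' Block pairs of main subpools
#'
#' For every unordered pair of enzymes, forces both rank-1 subpools to zero
#' and maximizes growth (no wild-type band), reporting the growth ratio
#' against the wild-type rate and whether the pair crosses the 1% impact
#' threshold.
#'
#' @param m subpool-form `coral_model`.
#' @param mu_wt wild-type growth rate for the ratio; `NULL` (default) uses
#'   the unblocked optimum. The conventional chemostat-style choice is 0.1.
#' @param pairs optional two-column table of enzyme pairs (default: all).
#' @param underground scenario toggle.
#' @return tibble of class `pair_screen`.
#' @export
block_main_pairs <- function(m, mu_wt = NULL, pairs = NULL, underground = TRUE) {
  block_pairs_impl(m, rank = 1L, mu_wt = mu_wt, underground = underground,
                   pairs = pairs)
}

#' Block pairs of side subpools at a given rank
#'
#' As [block_main_pairs()] but zeroing the rank-`k` subpools of both
#' enzymes; enzymes without a rank-`k` subpool are skipped.
#'
#' @inheritParams block_main_pairs
#' @param rank side-subpool rank k >= 2.
#' @export
block_side_pairs <- function(m, rank, mu_wt = NULL, pairs = NULL,
                             underground = TRUE) {
  stopifnot(rank >= 2)
  block_pairs_impl(m, rank = as.integer(rank), mu_wt = mu_wt,
                   underground = underground, pairs = pairs)
}

#' Double gene knockouts on a conventional model
#'
#' For each gene pair, evaluates every reaction's GPR with both genes FALSE,
#' zeroes the bounds of reactions whose GPR fails, and maximizes growth.
#'
#' @param gem conventional [stoich_model()] (not enzyme-constrained).
#' @param pairs two-column table/matrix of gene ids.
#' @param underground scenario toggle.
#' @return tibble (`gene_a`, `gene_b`, `status`, `mu_ko`, `mu_wt`, `ratio`,
#'   `lethal`).
#' @export
double_gene_knockout <- function(gem, pairs, underground = TRUE) {
  pairs <- as_tibble(pairs, .name_repair = "minimal")
  names(pairs)[1:2] <- c("gene_a", "gene_b")
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), gem$genes)
  if (length(unknown)) {
    abort(paste("unknown gene(s):", paste(unknown, collapse = ", ")))
  }
  base_bounds <- model_bounds(gem, underground = underground)
  wt <- solve_lp(model_lp(gem, obj = setNames(1, gem$objective),
                          bounds = base_bounds))
  if (wt$status != "optimal") abort("wild-type model infeasible")
  mu_wt <- wt$objective
  asts <- lapply(gem$reactions$gpr, parse_gpr)
  probs <- pmap(pairs, function(gene_a, gene_b, ...) {
    ko <- c(gene_a, gene_b)
    dead <- gem$reactions$id[!vapply(asts, eval_gpr, logical(1), knocked = ko)]
    b <- base_bounds
    if (length(dead)) b <- set_bounds(b, dead, lb = 0, ub = 0)
    model_lp(gem, obj = setNames(1, gem$objective), bounds = b)
  })
  res <- solve_lp(probs)
  tibble(
    gene_a = pairs$gene_a,
    gene_b = pairs$gene_b,
    status = map_chr(res, "status"),
    mu_ko = map_dbl(res, ~ if (.x$status == "optimal") .x$objective else 0),
    mu_wt = mu_wt
  ) |>
    mutate(ratio = .data$mu_ko / .data$mu_wt,
           lethal = .data$status != "optimal" | .data$mu_ko <= 1e-6)
}
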