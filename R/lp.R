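# Solver-agnostic linear-programming layer.
#
# Problems are plain lists (sparse triplet constraint rows, bounds, dense
# objective); batches of problems are solved in one call to the backend. The
# default backend delegates to scipy.optimize.linprog (HiGHS) through a
# `python` subprocess — problems are written to a JSON file, the worker in
# inst/python/lp_worker.py solves the whole batch and writes results back.
# The backend is behind this one function so another LP engine exposing
# rows/cols can be swapped in.

LP_INF <- 1e30

#' Construct a linear program
#'
#' @param obj named numeric: objective coefficients by variable (missing
#'   variables get 0).
#' @param vars character vector of variable names (column order).
#' @param lb,ub named or positional bounds (length of `vars`).
#' @param eq,le lists of constraint rows: each `list(terms = named numeric,
#'   rhs = scalar)`, equality and <= respectively.
#' @param maximize logical.
#' @return list of class `lp_problem`.
#' @export
lp_problem <- function(vars, obj, lb, ub, eq = list(), le = list(),
                       maximize = TRUE) {
  n <- length(vars)
  obj_full <- setNames(numeric(n), vars)
  obj_full[names(obj)] <- obj
  triplets <- function(rows) {
    if (!length(rows)) {
      return(list(i = integer(), j = integer(), x = double(), rhs = double(),
                  m = 0L))
    }
    i <- integer(); j <- integer(); x <- double(); rhs <- double()
    for (k in seq_along(rows)) {
      terms <- rows[[k]]$terms
      idx <- match(names(terms), vars)
      if (anyNA(idx)) {
        abort(paste("constraint references unknown variable:",
                    paste(names(terms)[is.na(idx)], collapse = ", ")))
      }
      i <- c(i, rep.int(k, length(terms)))
      j <- c(j, idx)
      x <- c(x, unname(terms))
      rhs <- c(rhs, rows[[k]]$rhs)
    }
    list(i = i - 1L, j = j - 1L, x = x, rhs = rhs, m = length(rows))
  }
  structure(list(
    vars = vars, obj = unname(obj_full),
    lb = unname(lb), ub = unname(ub),
    eq = triplets(eq), le = triplets(le),
    maximize = isTRUE(maximize)
  ), class = "lp_problem")
}

lp_python <- function() {
  p <- Sys.getenv("CORAL_PYTHON", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) abort("no python interpreter found for the LP backend")
  p
}

#' Solve a batch of linear programs
#'
#' @param problems list of [lp_problem()] objects (a single problem is
#'   accepted too).
#' @return list of results: `status` ("optimal", "infeasible", "unbounded"
#'   or "error"), `objective`, and `x` (named numeric solution vector).
#' @export
solve_lp <- function(problems) {
  single <- inherits(problems, "lp_problem")
  if (single) problems <- list(problems)
  payload <- lapply(problems, function(p) {
    list(n = length(p$vars), obj = p$obj,
         lb = pmax(pmin(p$lb, LP_INF), -LP_INF),
         ub = pmax(pmin(p$ub, LP_INF), -LP_INF),
         eq = p$eq, le = p$le, maximize = p$maximize)
  })
  inp <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  on.exit(unlink(c(inp, out)), add = TRUE)
  jsonlite::write_json(payload, inp, digits = NA, auto_unbox = FALSE,
                       null = "null")
  worker <- system.file("python", "lp_worker.py", package = "coral")
  if (!nzchar(worker)) {
    # during development (pkgload) fall back to the source tree
    worker <- file.path("inst", "python", "lp_worker.py")
  }
  status <- system2(lp_python(), c(shQuote(worker), shQuote(inp), shQuote(out)),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(out)) {
    abort("LP backend failed (python/scipy unavailable or worker error)")
  }
  res <- jsonlite::read_json(out, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  out_list <- map2(res, problems, function(r, p) {
    x <- if (!is.null(r$x)) setNames(as.numeric(r$x), p$vars) else NULL
    if (!is.null(x)) x[x == 0] <- 0  # normalise IEEE negative zeros
    obj <- if (is.null(r$objective)) NA_real_ else as.numeric(r$objective)
    if (!is.na(obj) && obj == 0) obj <- 0
    list(status = r$status, objective = obj, x = x)
  })
  if (single) out_list[[1]] else out_list
}

# ---- model -> LP assembly ------------------------------------------------

#' Reaction bounds of a model as a tibble
#'
#' @param m a `stoich_model` or `coral_model`.
#' @param underground if `FALSE`, reactions originating from underground
#'   reactions get both bounds set to zero (the "underground off" scenario).
#' @param fixed_mu if given, the objective reaction is fixed to this value.
#' @return tibble (`reaction`, `lb`, `ub`).
#' @export
model_bounds <- function(m, underground = TRUE, fixed_mu = NULL) {
  b <- m$reactions |> select(reaction = "id", "lb", "ub")
  if (!underground) {
    off <- underground_reaction_ids(m)
    b <- b |> mutate(lb = if_else(.data$reaction %in% off, 0, .data$lb),
                     ub = if_else(.data$reaction %in% off, 0, .data$ub))
  }
  if (!is.null(fixed_mu)) {
    b <- b |> mutate(lb = if_else(.data$reaction == m$objective, fixed_mu, .data$lb),
                     ub = if_else(.data$reaction == m$objective, fixed_mu, .data$ub))
  }
  b
}

set_bounds <- function(bounds, reaction, lb = NULL, ub = NULL) {
  i <- match(reaction, bounds$reaction)
  if (anyNA(i)) abort(paste("unknown reaction in bound override:",
                            paste(reaction[is.na(i)], collapse = ", ")))
  if (!is.null(lb)) bounds$lb[i] <- lb
  if (!is.null(ub)) bounds$ub[i] <- ub
  bounds
}

# constraint rows of a coral model (ordering etc.) as lp rows, optionally
# dropping ordering rows that touch any of `freed_draws` — when an enzyme is
# blocked, its whole efficiency hierarchy is released so the pool can
# redistribute to deeper subpools (a zeroed main subpool would otherwise
# force every side subpool to zero through the ordering chain).
model_constraint_rows <- function(m, freed_draws = character()) {
  cons <- m$constraints
  if (is.null(cons) || nrow(cons) == 0) return(list(eq = list(), le = list()))
  terms <- m$con_terms
  drop_ids <- character()
  if (length(freed_draws)) {
    drop_ids <- unique(terms$con_id[terms$reaction %in% freed_draws &
                                      startsWith(terms$con_id, "order_")])
  }
  cons <- cons[!cons$con_id %in% drop_ids, ]
  rows <- lapply(seq_len(nrow(cons)), function(k) {
    tr <- terms[terms$con_id == cons$con_id[k], ]
    list(terms = setNames(tr$coef, tr$reaction), rhs = cons$rhs[k],
         sense = cons$sense[k])
  })
  list(eq = rows[vapply(rows, function(r) r$sense == "eq", logical(1))],
       le = rows[vapply(rows, function(r) r$sense == "le", logical(1))])
}

# assemble the LP for a model: S v = 0, bounds, extra constraint rows
model_lp <- function(m, obj, bounds = NULL, maximize = TRUE,
                     freed_draws = character()) {
  bounds <- bounds %||% model_bounds(m)
  vars <- bounds$reaction
  met_rows <- m$stoich |>
    mutate(row = match(.data$metabolite, m$metabolites$id),
           col = match(.data$reaction, vars))
  eq_trip <- list(i = met_rows$row - 1L, j = met_rows$col - 1L,
                  x = met_rows$coef, rhs = rep(0, nrow(m$metabolites)),
                  m = nrow(m$metabolites))
  extra <- model_constraint_rows(m, freed_draws)
  p <- lp_problem(vars = vars, obj = obj, lb = bounds$lb, ub = bounds$ub,
                  eq = extra$eq, le = extra$le, maximize = maximize)
  # splice the stoichiometric rows in front of any extra equality rows
  p$eq <- list(
    i = c(eq_trip$i, p$eq$i + eq_trip$m),
    j = c(eq_trip$j, p$eq$j),
    x = c(eq_trip$x, p$eq$x),
    rhs = c(eq_trip$rhs, p$eq$rhs),
    m = eq_trip$m + p$eq$m
  )
  p
}
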