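# broom-style accessors for fitted/solved objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solution into a per-reaction flux table
#'
#' @param x a `coral_solution`.
#' @param what `"fluxes"` (default), `"usage"` (per-subpool molar usage) or
#'   `"pools"` (per-enzyme totals).
#' @param ... unused.
#' @return tibble.
#' @method tidy coral_solution
#' @export
tidy.coral_solution <- function(x, what = c("fluxes", "usage", "pools"), ...) {
  what <- match.arg(what)
  out <- x[[what]]
  if (is.null(out)) {
    abort(paste0("solution carries no '", what, "' component"))
  }
  as_tibble(out)
}

#' One-row summary of a solution
#' @param x a `coral_solution`.
#' @param ... unused.
#' @method glance coral_solution
#' @export
glance.coral_solution <- function(x, ...) {
  tibble(kind = x$kind, status = x$status, objective = x$objective,
         growth = x$growth,
         total_usage = if (!is.null(x$pools)) sum(x$pools$usage) else NA_real_,
         total_mass = if (!is.null(x$pools)) sum(x$pools$mass) else NA_real_)
}

#' Tidy a variability result
#' @param x a `coral_fva`.
#' @param ... unused.
#' @return tibble with a `range` column added.
#' @method tidy coral_fva
#' @export
tidy.coral_fva <- function(x, ...) {
  as_tibble(x) |> mutate(range = .data$max - .data$min)
}

#' One-row summary of a variability result
#' @param x a `coral_fva`.
#' @param ... unused.
#' @method glance coral_fva
#' @export
glance.coral_fva <- function(x, ...) {
  tibble(kind = attr(x, "kind") %||% "flux",
         n_targets = nrow(x),
         n_optimal = sum(x$status == "optimal"),
         median_range = stats::median(x$max - x$min, na.rm = TRUE),
         underground = x$underground[1],
         fixed_mu = x$fixed_mu[1])
}

#' Tidy a defect screen
#' @param x a `defect_screen` or `pair_screen`.
#' @param ... unused.
#' @method tidy defect_screen
#' @export
tidy.defect_screen <- function(x, ...) as_tibble(x)

#' @rdname tidy.defect_screen
#' @method tidy pair_screen
#' @export
tidy.pair_screen <- function(x, ...) as_tibble(x)

#' One-row summary of a single-block screen
#' @param x a `defect_screen`.
#' @param ... unused.
#' @method glance defect_screen
#' @export
glance.defect_screen <- function(x, ...) {
  tibble(n_enzymes = nrow(x), n_lethal = sum(x$lethal),
         n_flagged = sum(x$flagged),
         n_class_a = sum(x$class == "a", na.rm = TRUE),
         n_class_b = sum(x$class == "b", na.rm = TRUE),
         n_class_c = sum(x$class == "c", na.rm = TRUE),
         n_class_d = sum(x$class == "d", na.rm = TRUE))
}

#' One-row summary of a pair-block screen
#' @param x a `pair_screen`.
#' @param ... unused.
#' @method glance pair_screen
#' @export
glance.pair_screen <- function(x, ...) {
  tibble(n_pairs = nrow(x), n_lethal = sum(x$lethal),
         n_affected = sum(x$affected),
         n_affected_promiscuous = sum(x$affected & x$promiscuity != "neither"),
         min_ratio = min(x$ratio, na.rm = TRUE))
}
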