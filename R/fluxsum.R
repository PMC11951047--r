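# Metabolite-centric flux-sum analysis: phi_i = 0.5 * sum_j |S_ij v_j|,
# a proxy for metabolite turnover, and wild-type vs defect differences.

#' Flux-sums of a solution
#'
#' Computes `phi_i = 0.5 * sum_j |S_ij * v_j|` for every metabolite. At
#' steady state this equals both the production and the consumption half of
#' the metabolite's turnover. Pseudometabolites (protein pools, subpools,
#' complex-linking metabolites) are excluded by default — they are
#' accounting devices, not chemistry.
#'
#' @param m the model the solution was computed on.
#' @param solution a `coral_solution` (or a tibble with `reaction`, `flux`).
#' @param include_pseudo include pool/subpool/link pseudometabolites.
#' @return tibble of class `flux_sums` (`metabolite`, `phi`).
#' @export
flux_sums <- function(m, solution, include_pseudo = FALSE) {
  fluxes <- if (inherits(solution, "coral_solution")) solution$fluxes else
    as_tibble(solution)
  if (!all(c("reaction", "flux") %in% names(fluxes))) {
    abort("solution must provide reaction and flux columns")
  }
  missing_rxn <- setdiff(m$reactions$id, fluxes$reaction)
  if (length(missing_rxn)) {
    abort(paste("solution lacks fluxes for model reactions:",
                paste(head(missing_rxn, 5), collapse = ", ")))
  }
  mets <- m$metabolites
  if (!include_pseudo) {
    mets <- mets |> filter(!.data$provenance %in% c("pseudo", "link"))
  }
  v <- setNames(fluxes$flux, fluxes$reaction)
  out <- m$stoich |>
    filter(.data$metabolite %in% mets$id) |>
    mutate(term = abs(.data$coef * v[.data$reaction])) |>
    group_by(.data$metabolite) |>
    summarise(phi = 0.5 * sum(.data$term), .groups = "drop")
  out <- tibble(metabolite = mets$id) |>
    left_join(out, by = "metabolite") |>
    mutate(phi = dplyr::coalesce(.data$phi, 0))
  class(out) <- c("flux_sums", class(out))
  out
}

#' Flux-sum differences between a defect and the wild type
#'
#' Subtracts wild-type flux-sums from defect flux-sums
#' (`delta = phi_del - phi_wt`; positive means increased turnover in the
#' defect).
#'
#' @param wt,del `flux_sums` tibbles on the same metabolite namespace.
#' @param common_only restrict to metabolites present in both (default);
#'   otherwise the union is used with missing values as 0.
#' @return tibble (`metabolite`, `phi_wt`, `phi_del`, `delta`).
#' @export
flux_sum_delta <- function(wt, del, common_only = TRUE) {
  wt <- as_tibble(wt)[, c("metabolite", "phi")]
  del <- as_tibble(del)[, c("metabolite", "phi")]
  if (common_only) {
    out <- inner_join(rename(wt, phi_wt = "phi"), rename(del, phi_del = "phi"),
                      by = "metabolite")
    if (nrow(out) == 0) {
      warn("no metabolites common to both flux-sum vectors")
    }
  } else {
    out <- dplyr::full_join(rename(wt, phi_wt = "phi"),
                            rename(del, phi_del = "phi"), by = "metabolite") |>
      mutate(phi_wt = dplyr::coalesce(.data$phi_wt, 0),
             phi_del = dplyr::coalesce(.data$phi_del, 0))
  }
  out |> mutate(delta = .data$phi_del - .data$phi_wt)
}
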