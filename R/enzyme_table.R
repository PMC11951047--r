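# Enzyme data: molecular weights and turnover numbers per catalysed
# (reaction, direction). One row per (enzyme, reaction, direction); an
# enzyme's MW and genes must agree across its rows.

#' Construct an enzyme table
#'
#' @param x tibble/data.frame with columns `enzyme`, `genes` (";"-separated
#'   gene ids), `mw` (g/mmol), `reaction`, `direction` (`"fwd"` or `"rev"`),
#'   `kcat` (1/h).
#' @return validated tibble of class `enzyme_table`.
#' @export
enzyme_table <- function(x) {
  x <- as_tibble(x)
  need <- c("enzyme", "genes", "mw", "reaction", "direction", "kcat")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste("enzyme table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  x <- x[, need]
  if (any(x$mw <= 0)) abort("enzyme MW must be > 0")
  if (any(x$kcat <= 0)) abort("enzyme kcat must be > 0")
  if (!all(x$direction %in% c("fwd", "rev"))) {
    abort("direction must be 'fwd' or 'rev'")
  }
  key <- paste(x$enzyme, x$reaction, x$direction)
  if (anyDuplicated(key)) {
    abort(paste("duplicate (enzyme, reaction, direction) entries:",
                paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  inconsistent <- x |>
    group_by(.data$enzyme) |>
    summarise(n_mw = dplyr::n_distinct(.data$mw),
              n_genes = dplyr::n_distinct(.data$genes)) |>
    filter(.data$n_mw > 1 | .data$n_genes > 1)
  if (nrow(inconsistent)) {
    abort(paste("inconsistent MW or genes within enzyme:",
                paste(inconsistent$enzyme, collapse = ", ")))
  }
  class(x) <- c("enzyme_table", class(x))
  x
}

#' Read / write an enzyme table as TSV
#'
#' Columns: `enzyme`, `genes` (";"-separated), `MW_g_per_mmol`, `reaction`,
#' `direction`, `kcat_per_h`. A `kcat_per_s` column is accepted instead of
#' `kcat_per_h` and converted (x3600) at read time.
#'
#' @param path TSV file path.
#' @return an `enzyme_table`.
#' @export
read_enzyme_table <- function(path) {
  if (!file.exists(path)) abort(paste("enzyme table not found:", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("kcat_per_s" %in% names(d) && !"kcat_per_h" %in% names(d)) {
    d$kcat_per_h <- d$kcat_per_s * 3600
  }
  enzyme_table(tibble(
    enzyme = d$enzyme, genes = d$genes, mw = d$MW_g_per_mmol,
    reaction = d$reaction, direction = d$direction, kcat = d$kcat_per_h
  ))
}

#' @rdname read_enzyme_table
#' @param enz an `enzyme_table`.
#' @export
write_enzyme_table <- function(enz, path) {
  readr::write_tsv(tibble(
    enzyme = enz$enzyme, genes = enz$genes, MW_g_per_mmol = enz$mw,
    reaction = enz$reaction, direction = enz$direction, kcat_per_h = enz$kcat
  ), path, progress = FALSE)
  invisible(path)
}

# enzyme -> (mw, genes) summary, one row per enzyme
enzyme_summary <- function(enz) {
  enz |>
    group_by(.data$enzyme) |>
    summarise(mw = .data$mw[1], genes = .data$genes[1], .groups = "drop")
}

# gene id -> enzyme ids catalogue (an enzyme may list several genes)
gene_enzyme_map <- function(enz) {
  es <- enzyme_summary(enz)
  tibble(
    enzyme = rep(es$enzyme, lengths(strsplit(es$genes, ";"))),
    gene = unlist(strsplit(es$genes, ";"))
  ) |> mutate(gene = trimws(.data$gene))
}
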