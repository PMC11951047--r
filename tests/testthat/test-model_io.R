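test_that("JSON round trip is identity on ids, stoichiometry, bounds, GPRs", {
  m <- fixture_suite("direct_transfer")$model
  f <- withr::local_tempfile(fileext = ".json")
  write_gem(m, f)
  m2 <- read_gem(f)
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_identical(m2$reactions$lb, m$reactions$lb)
  expect_identical(m2$reactions$ub, m$reactions$ub)
  expect_identical(m2$reactions$gpr, m$reactions$gpr)
  expect_identical(m2$objective, m$objective)
  expect_equal(dplyr::arrange(m2$stoich, reaction, metabolite),
               dplyr::arrange(m$stoich, reaction, metabolite))
})

test_that("SBML round trip preserves network, bounds, objective and GPRs", {
  fx <- random_fixture(11)
  m <- merge_underground(fx$model, fx$underground)
  f <- withr::local_tempfile(fileext = ".xml")
  write_gem(m, f)
  m2 <- read_gem(f)
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lb, m$reactions$lb)
  expect_equal(m2$reactions$ub, m$reactions$ub)
  expect_identical(m2$objective, m$objective)
  expect_equal(dplyr::arrange(m2$stoich, reaction, metabolite),
               dplyr::arrange(m$stoich, reaction, metabolite))
  # GPRs may be reparenthesised; compare as DNF
  expect_true(all(mapply(function(a, b) identical(gpr_dnf(a), gpr_dnf(b)),
                         m2$reactions$gpr, m$reactions$gpr)))
})

test_that("malformed models are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".json")
  # reaction citing an unknown metabolite
  writeLines(jsonlite::toJSON(list(
    metabolites = list(list(id = "A", compartment = "c")),
    reactions = list(list(id = "R1", metabolites = list(A = -1, GHOST = 1),
                          lower_bound = 0, upper_bound = 10,
                          objective_coefficient = 1)),
    genes = list()
  ), auto_unbox = TRUE), f)
  expect_error(read_gem(f), "GHOST")
  # no objective designated
  writeLines(jsonlite::toJSON(list(
    metabolites = list(list(id = "A", compartment = "c")),
    reactions = list(list(id = "R1", metabolites = list(A = 1),
                          lower_bound = 0, upper_bound = 10)),
    genes = list()
  ), auto_unbox = TRUE), f)
  expect_error(read_gem(f), "objective")
  expect_error(read_gem("no/such/file.json"), "not found")
})

test_that("FBA growth on a written JSON model matches COBRApy", {
  # independent cross-check of the JSON dialect and the LP layer: the same
  # model solved by cobra must give the same optimum
  fx <- fixture_suite("redundant_pair")
  f <- withr::local_tempfile(fileext = ".json")
  write_gem(fx$model, f)
  out <- withr::local_tempfile(fileext = ".txt")
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import cobra, sys",
    sprintf("m = cobra.io.load_json_model('%s')", f),
    "sol = m.optimize()",
    sprintf("open('%s','w').write(str(sol.objective_value))", out)
  ), script)
  status <- system2("python", shQuote(script), stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  mu_cobra <- as.numeric(readLines(out, warn = FALSE))
  mu_ours <- fba(fx$model)$objective
  expect_close(mu_ours, mu_cobra, 1e-6)
})

test_that("merging an empty underground set is the identity", {
  m <- fixture_suite("essential_pair")$model
  empty <- underground_set(tibble::tibble(
    reaction = character(), stoich = list(), lb = double(), ub = double(),
    gpr = character()
  ))
  m2 <- merge_underground(m, empty)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gem(m, f1, format = "json"); write_gem(m2, f2, format = "json")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("underground merge adds tagged reactions and resolves annotations", {
  m <- fixture_suite("essential_pair")$model
  m$annotation$met_xref <- c(ext_B = "B")
  und <- underground_set(tibble::tibble(
    reaction = c("U1", "U2"),
    stoich = list(c(A = -1, C = 1), c(ext_B = -1, C = 1)),
    lb = 0, ub = 1000, gpr = c("", "gU")
  ))
  m2 <- merge_underground(m, und)
  expect_equal(nrow(m2$reactions), nrow(m$reactions) + 2)
  expect_identical(m2$reactions$provenance[m2$reactions$id %in% c("U1", "U2")],
                   c("underground", "underground"))
  expect_true("gU" %in% m2$genes)
  # cross-referenced metabolite resolved to host id
  expect_identical(m2$stoich$metabolite[m2$stoich$reaction == "U2" &
                                          m2$stoich$coef < 0], "B")
  # unresolvable metabolite fails loudly, naming the id
  bad <- underground_set(tibble::tibble(
    reaction = "U3", stoich = list(c(NOWHERE = -1, C = 1)),
    lb = 0, ub = 10, gpr = ""
  ))
  expect_error(merge_underground(m, bad), "NOWHERE")
  # id clash fails
  clash <- underground_set(tibble::tibble(
    reaction = "R1", stoich = list(c(A = -1, B = 1)), lb = 0, ub = 1, gpr = ""
  ))
  expect_error(merge_underground(m, clash), "already in host")
})

test_that("duplicate screen finds identical and near-identical columns", {
  m <- stoich_model(
    metabolites = tibble::tibble(id = c("A", "B", "C")),
    reactions = tibble::tibble(id = paste0("R", 1:5), lb = 0, ub = 10),
    stoich = tibble::tibble(
      reaction = c("R1", "R1", "R2", "R2", "R3", "R4", "R4", "R4"),
      metabolite = c("A", "B", "A", "B", "C", "A", "B", "C"),
      coef = c(1, -1, 1, -1, 1, 1, -1, 0.5)
    ),
    objective = "R5"
  )
  expect_warning(d <- find_duplicate_reactions(m, 0.9), "R5")
  # identical pair at similarity 1
  expect_true(any(d$reaction_a == "R1" & d$reaction_b == "R2" &
                    abs(d$similarity - 1) < 1e-12))
  # hand-computed: (1,-1,0) vs (1,-1,0.5): 2 / (sqrt(2) * sqrt(2.25))
  sim_expected <- 2 / (sqrt(2) * sqrt(2.25))
  row <- d[d$reaction_a %in% c("R1", "R2") & d$reaction_b == "R4", ]
  expect_equal(row$similarity, rep(sim_expected, nrow(row)), tolerance = 1e-12)
  # disjoint metabolites: no pair with R3
  expect_false(any(d$reaction_a == "R3" | d$reaction_b == "R3"))
})

test_that("duplicate detection is symmetric and threshold-monotone", {
  fx <- random_fixture(23)
  m <- fx$model
  d_low <- suppressWarnings(find_duplicate_reactions(m, 0.5))
  d_high <- suppressWarnings(find_duplicate_reactions(m, 0.95))
  key <- function(d) paste(pmin(d$reaction_a, d$reaction_b),
                           pmax(d$reaction_a, d$reaction_b))
  expect_true(all(key(d_high) %in% key(d_low)))
  expect_true(all(d_low$reaction_a != d_low$reaction_b))
  # removal drops one member of each pair
  m2 <- suppressWarnings(remove_duplicate_reactions(m, 0.9999))
  expect_true(nrow(m2$reactions) <= nrow(m$reactions))
})

test_that("enzyme tables validate and round-trip through TSV", {
  fx <- random_fixture(5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_enzyme_table(fx$enzymes, f)
  e2 <- read_enzyme_table(f)
  expect_equal(as.data.frame(e2), as.data.frame(fx$enzymes))
  expect_error(enzyme_table(transform(as.data.frame(fx$enzymes),
                                      kcat = kcat * 0)), "kcat")
  bad <- as.data.frame(fx$enzymes)
  expect_error(enzyme_table(rbind(bad, bad[1, ])), "duplicate")
  # per-second kcats convert on read
  d <- readr::read_tsv(f, show_col_types = FALSE)
  d$kcat_per_s <- d$kcat_per_h / 3600
  d$kcat_per_h <- NULL
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(d, f2)
  e3 <- read_enzyme_table(f2)
  expect_equal(e3$kcat, e2$kcat, tolerance = 1e-12)
})

test_that("underground tables round-trip through TSV", {
  fx <- random_fixture(7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_underground_table(fx$underground, f)
  u2 <- read_underground_table(f)
  expect_identical(u2$reaction, fx$underground$reaction)
  expect_equal(u2$stoich, fx$underground$stoich)
  expect_equal(u2$lb, fx$underground$lb)
})
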