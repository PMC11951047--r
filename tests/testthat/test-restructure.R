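test_that("AND complexes become chained partials with coupled flux", {
  fx <- fixture_suite("and_complex")
  m2 <- split_complex_gprs(fx$model, fx$enzymes)
  parts <- m2$gpr_map$derived[m2$gpr_map$original == "R1"]
  expect_length(parts, 2)
  expect_true(all(grepl("_PART_", parts)))
  expect_equal(sum(m2$metabolites$provenance == "link"), 1)
  # the chained pair reproduces the original feasible set: same max growth
  # when enzymes are effectively unconstrained
  big <- pool_config(ptot = 1e6)
  cm <- restructure(fx$model, fx$enzymes, pool = big)
  expect_close(fba(cm)$objective, fba(fx$model)$objective, 1e-9)
  # partials carry equal flux in any feasible solution
  sol <- fba(cm)
  v <- setNames(sol$fluxes$flux, sol$fluxes$reaction)
  expect_close(v[parts[1]], v[parts[2]], 1e-9)
})

test_that("OR isozymes become duplicate reactions, one enzyme each", {
  fx <- fixture_suite("or_isozymes")
  m2 <- split_complex_gprs(fx$model, fx$enzymes)
  dups <- m2$gpr_map$derived[m2$gpr_map$original == "R1"]
  expect_length(dups, 2)
  expect_true(all(grepl("_EXP_", dups)))
  expect_identical(sort(m2$catalysis$enzyme[m2$catalysis$reaction %in% dups]),
                   c("I1", "I2"))
})

test_that("(g1 and g2) or g3 expands to a 2-chain plus a singleton", {
  m <- chain_model()
  m$reactions$gpr[m$reactions$id == "R1"] <- "(g1 and g2) or g3"
  enz <- enzyme_table(tibble::tibble(
    enzyme = c("E1", "E2", "E3"), genes = c("g1", "g2", "g3"), mw = 10,
    reaction = "R1", direction = "fwd", kcat = c(100, 200, 300)
  ))
  m2 <- split_complex_gprs(m, enz)
  derived <- m2$gpr_map$derived[m2$gpr_map$original == "R1"]
  expect_length(derived, 3)  # two partials + one singleton duplicate
  expect_length(grep("_PART_", derived), 2)
  expect_equal(nrow(m2$catalysis), 3)
})

test_that("GPR genes without enzyme records leave the reaction enzyme-free", {
  m <- chain_model()
  m$reactions$gpr[m$reactions$id == "R1"] <- "g_unknown"
  enz <- enzyme_table(tibble::tibble(
    enzyme = "EX", genes = "gx", mw = 10, reaction = "OTHER",
    direction = "fwd", kcat = 100
  ))
  expect_warning(m2 <- split_complex_gprs(m, enz), "enzyme-free")
  expect_equal(nrow(m2$catalysis[m2$catalysis$reaction == "R1", ]), 0)
})

test_that("reversible catalysed reactions split into directional copies", {
  m <- chain_model()
  m$reactions$lb[m$reactions$id == "R1"] <- -5
  enz <- enzyme_table(tibble::tibble(
    enzyme = "E1", genes = "g1", mw = 10, reaction = "R1",
    direction = c("fwd", "rev"), kcat = c(100, 50)
  ))
  m2 <- m |> split_complex_gprs(enz) |> split_reversible_catalyzed(enz)
  expect_true("R1_REV" %in% m2$reactions$id)
  expect_equal(m2$reactions$lb[m2$reactions$id == "R1"], 0)
  expect_equal(m2$reactions$ub[m2$reactions$id == "R1_REV"], 5)
  # flipped stoichiometry
  s_f <- m2$stoich[m2$stoich$reaction == "R1", ]
  s_r <- m2$stoich[m2$stoich$reaction == "R1_REV", ]
  expect_equal(s_r$coef[match(s_f$metabolite, s_r$metabolite)], -s_f$coef)
  # each direction is its own catalytic activity
  expect_equal(sort(m2$catalysis$direction), c("fwd", "rev"))
  # a direction without a kcat record is enzyme-free, with a warning
  enz1 <- enzyme_table(tibble::tibble(
    enzyme = "E1", genes = "g1", mw = 10, reaction = "R1",
    direction = "fwd", kcat = 100
  ))
  expect_warning(
    m3 <- m |> split_complex_gprs(enz1) |> split_reversible_catalyzed(enz1),
    "rev kcat"
  )
  expect_equal(nrow(m3$catalysis), 1)
})

test_that("enzyme layer enforces the closed-form protein budget", {
  # one enzyme (MW 40 g/mmol, kcat 3600 1/h) on one reaction with budget
  # 0.04 g/gDW: max usage = 0.001 mmol/gDW, max flux = 3.6 mmol/gDW/h
  m <- chain_model(uptake = 1000)
  enz <- enzyme_table(tibble::tibble(
    enzyme = "E1", genes = "g1", mw = 40, reaction = "R1",
    direction = "fwd", kcat = 3600
  ))
  pool <- pool_config(ptot = 0.04, sigma = 1, f = 1)
  cm <- restructure(m, enz, pool = pool)
  sol <- fba(cm)
  expect_close(sol$objective, 3.6, 1e-9)
  expect_close(sol$usage$usage[sol$usage$subpool == "E1_1"], 0.001, 1e-9)
  # with a large budget, flux is limited by substrate bounds only
  cm2 <- restructure(chain_model(uptake = 10), enz, pool = pool_config(1e6))
  expect_close(fba(cm2)$objective, 10, 1e-9)
  # unsplit reversible catalysed reaction is refused
  m_rev <- chain_model()
  m_rev$reactions$lb[m_rev$reactions$id == "R1"] <- -5
  pre <- split_complex_gprs(m_rev, enz)
  pre$catalysis <- tibble::tibble(reaction = "R1", enzyme = "E1",
                                  direction = "fwd", kcat = 3600, mw = 40)
  expect_error(build_ec_layer(pre, enz), "reversible")
})

test_that("subpool ranks follow ascending MW/kcat with rank 1 the largest kcat", {
  m <- stoich_model(
    metabolites = tibble::tibble(id = c("A", "B")),
    reactions = tibble::tibble(id = c("EX", "R1", "R2", "R3", "BIOMASS"),
                               lb = 0, ub = c(10, rep(1000, 4)),
                               gpr = c("", "g", "g", "g", "")),
    stoich = tibble::tibble(
      reaction = c("EX", "R1", "R1", "R2", "R2", "R3", "R3", "BIOMASS"),
      metabolite = c("A", "A", "B", "A", "B", "A", "B", "B"),
      coef = c(1, -1, 1, -1, 1, -1, 1, -1)
    ),
    objective = "BIOMASS"
  )
  enz <- enzyme_table(tibble::tibble(
    enzyme = "E", genes = "g", mw = 10, reaction = c("R1", "R2", "R3"),
    direction = "fwd", kcat = c(100, 10, 1)
  ))
  cm <- restructure(m, enz)
  reg <- cm$registry
  expect_identical(reg$reaction[order(reg$rank)], c("R1", "R2", "R3"))
  expect_true(reg$main[reg$rank == 1])
  expect_identical(reg$rank, 1:3)
  # non-promiscuous enzyme: exactly one subpool, rank 1
  fx <- fixture_suite("essential_pair")
  reg2 <- restructured_fixture("essential_pair")$registry
  expect_equal(nrow(reg2), 2)
  expect_true(all(reg2$rank == 1L))
})

test_that("tied MW/kcat ranks break deterministically by reaction id", {
  cm <- restructured_fixture("tied_kcat")
  reg <- cm$registry |> dplyr::arrange(rank)
  expect_identical(reg$reaction, c("R1", "R2", "R3"))
  # either tie order gives the same optimum: compare against a model whose
  # tied reactions are named to force the opposite order
  fx <- fixture_suite("tied_kcat")
  swap <- function(x) ifelse(x == "R2", "R3x", ifelse(x == "R3", "R2x", x))
  m2 <- fx$model
  m2$reactions$id <- swap(m2$reactions$id)
  m2$stoich$reaction <- swap(m2$stoich$reaction)
  e2 <- fx$enzymes
  e2$reaction <- swap(e2$reaction)
  cm2 <- restructure(m2, enzyme_table(as.data.frame(e2)), pool = fx$pool)
  reg2 <- cm2$registry |> dplyr::arrange(rank)
  expect_identical(reg2$reaction, c("R1", "R2x", "R3x"))  # opposite tie order
  expect_close(fba(cm2)$objective, fba(cm)$objective, 1e-9)
  expect_close(oracle_solve(cm2, "growth")$objective,
               oracle_solve(cm, "growth")$objective, 1e-9)
})

test_that("subpool split is a pure refinement of the shared-pool model", {
  for (seed in c(3, 4)) {
    fx <- random_fixture(seed)
    gecko <- fx$model |>
      split_complex_gprs(fx$enzymes) |>
      split_reversible_catalyzed(fx$enzymes) |>
      build_ec_layer(fx$enzymes, pool_config())
    sub_off <- add_ordering_constraints(split_subpools(gecko), "off")
    sub_on <- add_ordering_constraints(sub_off, "chain")
    mu_g <- fba(gecko)$objective
    mu_off <- fba(sub_off)$objective
    mu_on <- fba(sub_on)$objective
    expect_close(mu_off, mu_g, 1e-6)
    expect_true(mu_on <= mu_off + 1e-6 * max(1, mu_off))
  }
})

test_that("solutions conserve enzyme pools and respect the mass budget", {
  cm <- random_coral(13)
  sol <- fba(cm)
  # per enzyme: sum of subpool draws equals the pool supply
  per_enz <- sol$usage |>
    dplyr::group_by(enzyme) |>
    dplyr::summarise(mass = sum(mass), .groups = "drop") |>
    dplyr::left_join(sol$pools, by = "enzyme", suffix = c("_draws", "_pool"))
  expect_true(all(abs(per_enz$mass_draws - per_enz$mass_pool) <= 1e-6))
  # budget: total enzyme mass within Etot
  expect_true(sum(sol$pools$mass) <= cm$pool$etot + 1e-6)
  # steady state: S v = 0
  S <- stoich_matrix(cm)
  v <- setNames(sol$fluxes$flux, sol$fluxes$reaction)[colnames(S)]
  expect_true(max(abs(S %*% v)) <= 1e-6)
})

test_that("blocking a subpool draw forces zero flux through its reaction", {
  cm <- restructured_fixture("direct_transfer")
  reg <- cm$registry
  draw <- reg$draw_rxn[reg$subpool == "E_1"]
  b <- model_bounds(cm)
  b <- coral:::set_bounds(b, draw, lb = 0, ub = 0)
  p <- coral:::model_lp(cm, obj = setNames(1, cm$objective), bounds = b,
                        freed_draws = draw)
  res <- solve_lp(p)
  expect_identical(res$status, "optimal")
  expect_lt(abs(res$x[reg$reaction[reg$subpool == "E_1"]]), 1e-8)
})

test_that("restructuring is byte-identical across reruns", {
  fx <- random_fixture(21)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_coral_model(restructure(fx$model, fx$enzymes, und = fx$underground), f1)
  write_coral_model(restructure(fx$model, fx$enzymes, und = fx$underground), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ordering modes add the expected constraint rows", {
  cm <- restructured_fixture("deep_rescuer")  # 3 subpools, chain
  expect_equal(sum(startsWith(cm$constraints$con_id, "order_")), 2)
  vs <- add_ordering_constraints(cm, "vs_main")
  expect_equal(sum(startsWith(vs$constraints$con_id, "order_")), 2)
  expect_true(all(grepl("_1_", vs$constraints$con_id[startsWith(vs$constraints$con_id, "order_")])))
  off <- add_ordering_constraints(cm, "off")
  expect_equal(sum(startsWith(off$constraints$con_id, "order_")), 0)
  eqm <- add_ordering_constraints(cm, "equality")
  expect_true(all(eqm$constraints$sense[startsWith(eqm$constraints$con_id, "order_")] == "eq"))
  # a single-subpool enzyme adds no rows
  ep <- restructured_fixture("essential_pair")
  expect_equal(nrow(ep$constraints), 0)
})
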