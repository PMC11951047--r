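test_that("direct-transfer enzyme: main block is rescued by rank 2", {
  cm <- restructured_fixture("direct_transfer")
  mu_max <- fba(cm)$objective
  wt <- wt_reference(cm, fixed_mu = mu_max)
  rep <- block_main_single(cm, wt, "E")
  expect_false(rep$lethal)
  # growth-neutral compensation
  expect_close(rep$mu_del, mu_max, 1e-6)
  redist <- attr(rep, "redistribution")
  # the rank-2 subpool takes over the pool within the 5% band
  e2_del <- redist$usage_del[redist$rank == 2]
  e1_wt <- redist$usage_wt[redist$rank == 1]
  expect_true(abs(e2_del - e1_wt) <= 0.05 * e1_wt)
  expect_identical(rep$class, "a")
  # redistribution shares of the pool sum to one
  expect_close(sum(redist$share_del), 1, 1e-9)
})

test_that("single blocks respect restriction monotonicity at the WT optimum", {
  for (name in c("direct_transfer", "deep_rescuer", "redundant_pair")) {
    cm <- restructured_fixture(name)
    mu_max <- fba(cm)$objective
    wt <- wt_reference(cm, fixed_mu = mu_max)
    scr <- screen_single_blocks(cm, wt)
    expect_true(all(scr$mu_del <= mu_max * (1 + wt$band) + 1e-6))
  }
})

test_that("deep-rank rescuer bypasses a useless rank-2 subpool", {
  cm <- restructured_fixture("deep_rescuer")
  mu_max <- fba(cm)$objective
  wt <- wt_reference(cm, fixed_mu = mu_max)
  rep <- block_main_single(cm, wt, "E")
  expect_false(rep$lethal)
  redist <- attr(rep, "redistribution")
  # rank 2 is a dead end; rank 3 carries the pathway
  expect_lt(redist$usage_del[redist$rank == 2], 1e-8)
  expect_gt(redist$usage_del[redist$rank == 3], 0)
  expect_true(rep$class %in% c("c", "d"))
  # cross-check the defect optimum against the dense oracle
  reg <- cm$registry
  band <- dplyr::left_join(reg, wt$usage, by = c("enzyme", "subpool", "rank")) |>
    dplyr::filter(enzyme != "E") |>
    dplyr::mutate(lo = ifelse(usage > wt$zero, 0.95 * usage, 0),
                  hi = ifelse(usage > wt$zero, 1.05 * usage, wt$zero)) |>
    dplyr::select(subpool, lo, hi)
  o <- oracle_solve(cm, "growth", blocked = "E_1", wt_band = band)
  expect_close(rep$mu_del, o$objective, 1e-6)
})

test_that("blocking an enzyme unused in the wild type is neutral", {
  cm <- restructured_fixture("direct_transfer")
  mu_max <- fba(cm)$objective
  wt <- wt_reference(cm, fixed_mu = mu_max)
  # EC (on the spur reaction) carries no WT usage
  expect_lt(wt$usage$usage[wt$usage$enzyme == "EC"], wt$zero)
  rep <- block_main_single(cm, wt, "EC")
  expect_false(rep$lethal)
  expect_true(rep$ratio >= 1 - wt$band - 1e-6)
  scr <- screen_single_blocks(cm, wt)
  expect_false(scr$flagged[scr$enzyme == "EC"])
  expect_true(scr$flagged[scr$enzyme == "E"])
})

test_that("an essential enzyme with no side activity is lethal to block", {
  cm <- restructured_fixture("essential_pair")
  mu_max <- fba(cm)$objective
  wt <- wt_reference(cm, fixed_mu = mu_max)
  rep <- block_main_single(cm, wt, "P")
  expect_true(rep$lethal)
  expect_equal(rep$ratio, 0)
})

test_that("pair blocks: redundancy, lethality and order independence", {
  cm <- restructured_fixture("redundant_pair")
  pr <- block_main_pairs(cm)
  # isozyme-backed pairs are neutral
  r_red <- pr$ratio[pr$enzyme_a == "X1A" & pr$enzyme_b == "X2A"]
  expect_close(r_red, 1, 1e-6)
  # both isozymes of one step blocked: lethal
  r_let <- pr$ratio[pr$enzyme_a == "X1A" & pr$enzyme_b == "X1B"]
  expect_equal(r_let, 0)
  expect_true(all(pr$ratio <= 1 + 1e-6))
  # order independence
  pr_swapped <- block_main_pairs(cm, pairs = tibble::tibble(a = "X2A", b = "X1A"))
  expect_close(pr_swapped$mu_del, pr$mu_del[pr$enzyme_a == "X1A" &
                                              pr$enzyme_b == "X2A"], 1e-9)
  # non-promiscuous essential pair on its own fixture
  ep <- restructured_fixture("essential_pair")
  pe <- block_main_pairs(ep)
  expect_true(all(pe$lethal))
  expect_true(all(pe$promiscuity == "neither"))
})

test_that("pair-block optima agree with the dense oracle grid", {
  cm <- random_coral(61)
  mu_wt <- fba(cm)$objective
  pr <- block_main_pairs(cm, mu_wt = mu_wt)
  reg <- cm$registry
  for (k in seq_len(nrow(pr))) {
    blocked <- reg$subpool[reg$rank == 1 &
                             reg$enzyme %in% c(pr$enzyme_a[k], pr$enzyme_b[k])]
    o <- oracle_solve(cm, "growth", blocked = blocked)
    mu_oracle <- if (o$status == "optimal") o$objective else 0
    expect_close(pr$mu_del[k], mu_oracle, 1e-6)
  }
})

test_that("side-pair blocks skip enzymes without the rank and hurt less", {
  cm <- random_coral(61)
  expect_message(s2 <- block_side_pairs(cm, rank = 2), "skipped")
  expect_true(all(s2$rank == 2))
  mu_wt <- fba(cm)$objective
  p1 <- block_main_pairs(cm, mu_wt = mu_wt)
  # for the enzymes present in both screens, side blocks are never worse
  # than the corresponding main blocks
  j <- dplyr::inner_join(as.data.frame(s2), as.data.frame(p1),
                         by = c("enzyme_a", "enzyme_b"), suffix = c("_side", "_main"))
  if (nrow(j)) expect_true(all(j$ratio_side >= j$ratio_main - 1e-6))
})

test_that("double knockouts follow GPR boolean logic", {
  fx <- fixture_suite("redundant_pair")
  gem <- fx$model
  # brute-force oracle: evaluate GPRs by hand and zero dead reactions
  pairs <- t(utils::combn(gem$genes, 2))
  ko <- double_gene_knockout(gem, pairs)
  for (k in seq_len(nrow(pairs))) {
    dead <- gem$reactions$id[!vapply(gem$reactions$gpr, eval_gpr, logical(1),
                                     knocked = pairs[k, ])]
    m2 <- gem
    m2$reactions$lb[m2$reactions$id %in% dead] <- 0
    m2$reactions$ub[m2$reactions$id %in% dead] <- 0
    expect_close(ko$mu_ko[k], fba(m2)$objective, 1e-9)
  }
  # isozyme pair on an essential step: lethal
  expect_true(ko$lethal[ko$gene_a == "g1a" & ko$gene_b == "g1b"])
  # genes on different redundant steps: unaffected
  expect_equal(ko$ratio[ko$gene_a == "g1a" & ko$gene_b == "g2b"], 1)
  expect_error(double_gene_knockout(gem, cbind("g1a", "ghost")), "ghost")
})

test_that("subpool blocking retains growth that gene knockout destroys", {
  # same defect, two formalisms: blocking only the main subpool keeps the
  # side activity available; knocking out the gene removes both
  fx <- fixture_suite("direct_transfer")
  cm <- restructured_fixture("direct_transfer")
  mu_max <- fba(cm)$objective
  wt <- wt_reference(cm, fixed_mu = mu_max)
  r_coral <- block_main_single(cm, wt, "E")$ratio
  ko <- double_gene_knockout(fx$model, cbind("gE", "gC"))
  expect_true(r_coral >= ko$ratio + 0.5)  # coral ~1, knockout 0
  expect_true(ko$lethal)
})
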